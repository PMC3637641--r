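#' Plot-ready data tables from a Rank Products result
#'
#' `ri_plot_data()` gives the ratio-intensity view (log2 ratio of group mean
#' intensities vs log2 of their product); `volcano_plot_data()` gives, per
#' probe, the log2 rank product of its better direction vs log2 fold change,
#' with a significance flag at `p_cutoff`.
#'
#' @param result An `rp_result`.
#' @param p_cutoff Significance threshold used to flag probes (default
#'   1e-4).
#' @return A tibble.
#' @export
ri_plot_data <- function(result, p_cutoff = 1e-4) {
  stopifnot(inherits(result, "rp_result"))
  t <- result$table
  tibble(
    probe_id = t$probe_id,
    log2_ratio = log2(t$fc_ratio_of_means),
    log2_product = 2 * t$avg_log2,
    regulation = dplyr::case_when(
      t$p_up <= p_cutoff ~ "up",
      t$p_down <= p_cutoff ~ "down",
      TRUE ~ "not significant")
  )
}

#' @rdname ri_plot_data
#' @export
volcano_plot_data <- function(result, p_cutoff = 1e-4) {
  stopifnot(inherits(result, "rp_result"))
  t <- result$table
  up_better <- t$rp_up <= t$rp_down
  tibble(
    probe_id = t$probe_id,
    log2_rp = log2(ifelse(up_better, t$rp_up, t$rp_down)),
    log2_fc = log2(t$fc),
    direction = ifelse(up_better, "up", "down"),
    significant = ifelse(up_better, t$p_up, t$p_down) <= p_cutoff
  )
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)))
  })
}

#' Run the full multi-study analysis pipeline
#'
#' Chains the package end to end: per-study Rank Products analysis, sample
#' clustering, detection filtering, strict (or length-targeted) list
#' construction, symbol collapsing, cross-study comparison matrices, the
#' k-way intersection signature, and (optionally) hypergeometric enrichment
#' of the first study's combined list against a supplied annotation.
#' Every output table is written as tab-separated text under `out_dir`,
#' together with newick dendrograms, plot-data tables, and a run log
#' recording the seed, permutation count, and probe counts after every
#' filtering step. Re-running with the same inputs and seed reproduces the
#' outputs byte for byte.
#'
#' @param studies Named list of [expression_study()] objects (e.g. the
#'   `studies` element of [simulate_multi_study()]), or a
#'   [multi_study_config()] which is simulated first.
#' @param out_dir Output directory (created if missing).
#' @param n_permutations Permutations B for the Rank Products null.
#' @param seed Integer master seed; per-study seeds are derived from it.
#' @param p_max,pfp_max Strict list cutoffs.
#' @param detection_mode,detection_threshold,detection_p Detection filter
#'   settings (see [detection_filter()]); `detection_mode = "none"` skips
#'   the filter.
#' @param target_length Optional extended-list length; when given,
#'   [size_targeted_list()] replaces the strict cutoffs.
#' @param annotation Optional long-format annotation table (see
#'   [hypergeom_enrich()]).
#'
#' @return Invisibly, a list with the per-study results, the study list
#'   set, the comparison matrix, the signature, and output paths.
#' @export
run_pipeline <- function(studies, out_dir,
                         n_permutations = 200, seed = 1L,
                         p_max = 1e-4, pfp_max = 0.05,
                         detection_mode = "fraction_present",
                         detection_threshold = 0.2, detection_p = 0.01,
                         target_length = NULL, annotation = NULL) {
  truth <- NULL
  if (inherits(studies, "multi_study_config")) {
    sim <- pipeline_stage("simulate", simulate_multi_study(studies))
    truth <- sim$truth
    studies <- sim$studies
  }
  if (!is.list(studies) || is.null(names(studies)) ||
      !all(vapply(studies, inherits, logical(1), "expression_study"))) {
    abort("`studies` must be a named list of expression_study objects")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("rpmeta pipeline | seed=%d B=%d p_max=%g pfp_max=%g",
                         seed, n_permutations, p_max, pfp_max))

  results <- list()
  lists <- list()
  for (i in seq_along(studies)) {
    nm <- names(studies)[i]
    study <- studies[[i]]
    res <- pipeline_stage(
      paste0("rankprod:", nm),
      rp_analyze(study, n_permutations = n_permutations,
                 seed = (seed * 977L + i) %% .Machine$integer.max))
    n_in <- nrow(res$table)
    readr::write_tsv(res$table, file.path(out_dir, paste0(nm, "_rp.tsv")))
    readr::write_tsv(ri_plot_data(res, p_max),
                     file.path(out_dir, paste0(nm, "_ri_plot.tsv")))
    readr::write_tsv(volcano_plot_data(res, p_max),
                     file.path(out_dir, paste0(nm, "_volcano_plot.tsv")))
    if (ncol(study$matrix) >= 3) {
      dend <- pipeline_stage(paste0("cluster:", nm), cluster_samples(study))
      dendrogram_newick(dend, file.path(out_dir, paste0(nm, "_dendrogram.nwk")))
    }
    if (detection_mode != "none") {
      res <- pipeline_stage(
        paste0("detection_filter:", nm),
        detection_filter(res, study, detection_mode = detection_mode,
                         detection_threshold = detection_threshold,
                         detection_p = detection_p))
    }
    n_filt <- nrow(res$table)
    per_dir <- lapply(c(up = "up", down = "down"), function(d) {
      gl <- pipeline_stage(
        paste0("listbuild:", nm, ":", d),
        if (is.null(target_length)) {
          apply_cutoffs(res, d, p_max = p_max, pfp_max = pfp_max)
        } else {
          size_targeted_list(res, d, target_length = target_length,
                             pfp_max = pfp_max)
        })
      suppressMessages(collapse_to_symbols(gl))
    })
    per_dir <- suppressMessages(disjoin_directions(per_dir$up, per_dir$down))
    for (d in c("up", "down")) {
      write_gene_list(per_dir[[d]],
                      file.path(out_dir, paste0(nm, "_", d, "_list.tsv")))
    }
    log_lines <- c(log_lines, sprintf(
      "%s: probes_in=%d after_detection=%d up_list=%d down_list=%d",
      nm, n_in, n_filt, nrow(per_dir$up), nrow(per_dir$down)))
    results[[nm]] <- res
    lists[[nm]] <- per_dir
  }

  set <- pipeline_stage("study_list_set", study_list_set(lists))
  cm <- NULL
  sig <- NULL
  if (length(set) >= 2) {
    cm <- pipeline_stage("comparison_matrix", comparison_matrix(set))
    readr::write_tsv(as_tibble(cm), file.path(out_dir, "comparison_matrix.tsv"))
    sig <- pipeline_stage("signature", intersect_signature(set))
    readr::write_tsv(tidy(sig), file.path(out_dir, "signature.tsv"))
    readr::write_tsv(sig$venn_counts, file.path(out_dir, "venn_counts.tsv"))
    shared <- pipeline_stage(
      "shared_gene_table", shared_gene_table(set, names(set)[1]))
    readr::write_tsv(shared$combined, file.path(out_dir, "shared_genes.tsv"))
  }
  if (!is.null(annotation)) {
    first <- names(set)[1]
    enr <- pipeline_stage(
      "enrichment",
      suppressMessages(hypergeom_enrich(
        c(set[[first]]$up$symbol, set[[first]]$down$symbol), annotation)))
    readr::write_tsv(as_tibble(enr), file.path(out_dir, "enrichment.tsv"))
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(results = results, lists = lists, set = set,
                 comparison = cm, signature = sig, truth = truth,
                 out_dir = out_dir))
}
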