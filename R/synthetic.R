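#' Simulation settings for a single two-group expression study
#'
#' Describes the synthetic data model: a log2-scale expression matrix for
#' `n_case` + `n_control` samples with i.i.d. Gaussian noise, a configurable
#' number of planted up- and down-regulated genes with a constant log2
#' effect on every probe of the gene, MAS5-like present/absent calls, and a
#' many-to-one probeset-to-symbol map (1-3 probesets per gene).
#'
#' Defaults mirror a small nasal-brushing microarray design: 5 cases vs
#' 5 controls, a 2-fold (1 log2 unit) planted effect, 0.25 log2 units of
#' residual noise, and roughly 10% of genes not expressed in the tissue.
#'
#' @param n_genes Number of genes (symbols) on the platform.
#' @param n_case,n_control Samples per group (must be >= 1).
#' @param n_up_true,n_down_true Number of genes planted up-/down-regulated in
#'   cases. `n_up_true + n_down_true` must not exceed the number of expressed
#'   genes.
#' @param effect_log2fc Planted |log2 fold change| for regulated genes.
#' @param baseline_mean_log2,baseline_sd_log2 Mean and SD of per-gene baseline
#'   log2 intensity.
#' @param noise_sd_log2 SD of i.i.d. Gaussian noise per probe x sample.
#' @param probes_per_gene_prob Probabilities for a gene being measured by
#'   1, 2 or 3 probesets.
#' @param present_prob_expressed,present_prob_unexpressed Per-cell probability
#'   of a Present detection call for expressed / unexpressed genes.
#' @param frac_unexpressed Fraction of genes not expressed in the tissue
#'   (low baseline, mostly Absent calls); regulated genes are always drawn
#'   from the expressed set.
#' @param seed Integer seed; identical seeds give bit-identical studies.
#'
#' @return A `sim_config` list.
#' @seealso [simulate_study()], [multi_study_config()]
#' @export
sim_config <- function(n_genes = 1000, n_case = 5, n_control = 5,
                       n_up_true = 50, n_down_true = 50,
                       effect_log2fc = 1,
                       baseline_mean_log2 = 8, baseline_sd_log2 = 1.5,
                       noise_sd_log2 = 0.25,
                       probes_per_gene_prob = c(0.85, 0.12, 0.03),
                       present_prob_expressed = 0.9,
                       present_prob_unexpressed = 0.05,
                       frac_unexpressed = 0.1,
                       seed = 1L) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes", min = 2L),
    n_case = check_count(n_case, "n_case"),
    n_control = check_count(n_control, "n_control"),
    n_up_true = check_count(n_up_true, "n_up_true", min = 0L),
    n_down_true = check_count(n_down_true, "n_down_true", min = 0L),
    effect_log2fc = as.numeric(effect_log2fc),
    baseline_mean_log2 = as.numeric(baseline_mean_log2),
    baseline_sd_log2 = check_positive(baseline_sd_log2, "baseline_sd_log2"),
    noise_sd_log2 = check_positive(noise_sd_log2, "noise_sd_log2"),
    probes_per_gene_prob = as.numeric(probes_per_gene_prob),
    present_prob_expressed = check_prob(present_prob_expressed,
                                        "present_prob_expressed"),
    present_prob_unexpressed = check_prob(present_prob_unexpressed,
                                          "present_prob_unexpressed"),
    frac_unexpressed = check_prob(frac_unexpressed, "frac_unexpressed"),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$effect_log2fc < 0) abort("`effect_log2fc` must be >= 0")
  if (length(cfg$probes_per_gene_prob) != 3 ||
      any(cfg$probes_per_gene_prob < 0)) {
    abort("`probes_per_gene_prob` must be 3 nonnegative weights (1,2,3 probes)")
  }
  n_expressed <- cfg$n_genes - round(cfg$frac_unexpressed * cfg$n_genes)
  if (cfg$n_up_true + cfg$n_down_true > n_expressed) {
    abort("n_up_true + n_down_true exceeds the number of expressed genes")
  }
  structure(cfg, class = "sim_config")
}

# Detection p-values: strongly right-skewed toward 0 for Present cells,
# uniform for Absent cells, so both filter dialects (fraction Present and
# "detected at p < 0.01 in a fraction of samples") have signal to act on.
detection_pvalue <- function(present) {
  p <- runif(length(present))
  p[present] <- rbeta(sum(present), 0.4, 60)
  p
}

#' Simulate one two-group expression study with known ground truth
#'
#' Generates an [expression_study()] following the model described in
#' [sim_config()]: per-gene baselines, a constant planted log2 effect on all
#' probes of regulated genes, i.i.d. Gaussian noise, Bernoulli Present calls
#' with skewed-low detection p-values for Present cells.
#'
#' @param config A [sim_config()].
#' @param study_name Name stored in the study object.
#' @param symbols Optional character vector of `n_genes` symbols to use as the
#'   gene universe (defaults to `GENE0001...`).
#' @param true_up,true_down Optional symbol sets overriding the random choice
#'   of regulated genes (used by [simulate_multi_study()] to coordinate
#'   overlap across studies). Must be disjoint subsets of `symbols`.
#'
#' @return A list with elements `study` (an `expression_study`) and `truth`
#'   (list with `true_up`, `true_down` symbol vectors and a `probe_map`
#'   tibble: probe_id, symbol, expressed, direction).
#' @export
simulate_study <- function(config, study_name = "sim_study", symbols = NULL,
                           true_up = NULL, true_down = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)
  n_genes <- config$n_genes
  if (is.null(symbols)) {
    symbols <- sprintf("GENE%04d", seq_len(n_genes))
  }
  if (length(symbols) != n_genes || anyDuplicated(symbols)) {
    abort("`symbols` must be `n_genes` unique symbols")
  }

  n_unexpr <- round(config$frac_unexpressed * n_genes)
  unexpressed <- if (n_unexpr > 0) sample(symbols, n_unexpr) else character()
  expressed <- setdiff(symbols, unexpressed)

  if (is.null(true_up) && is.null(true_down)) {
    de <- sample(expressed, config$n_up_true + config$n_down_true)
    true_up <- head(de, config$n_up_true)
    true_down <- setdiff(de, true_up)
  } else {
    true_up <- as.character(true_up %||% character())
    true_down <- as.character(true_down %||% character())
    if (length(intersect(true_up, true_down)) > 0) {
      abort("`true_up` and `true_down` must be disjoint")
    }
    if (!all(c(true_up, true_down) %in% symbols)) {
      abort("planted symbols must belong to the gene universe")
    }
    # planted genes are expressed by construction
    unexpressed <- setdiff(unexpressed, c(true_up, true_down))
    expressed <- setdiff(symbols, unexpressed)
  }

  n_probes_per_gene <- sample.int(3L, n_genes, replace = TRUE,
                                  prob = config$probes_per_gene_prob)
  gene_of_probe <- rep(seq_len(n_genes), times = n_probes_per_gene)
  n_probes <- length(gene_of_probe)
  probe_ids <- sprintf("ps%05d_at", seq_len(n_probes))
  probe_symbols <- symbols[gene_of_probe]

  n_samples <- config$n_case + config$n_control
  group <- rep(c("case", "control"), c(config$n_case, config$n_control))

  gene_baseline <- rnorm(n_genes, config$baseline_mean_log2,
                         config$baseline_sd_log2)
  gene_baseline[symbols %in% unexpressed] <-
    gene_baseline[symbols %in% unexpressed] - 3 * config$baseline_sd_log2
  probe_offset <- rnorm(n_probes, 0, 0.2)
  probe_baseline <- gene_baseline[gene_of_probe] + probe_offset

  direction <- rep("none", n_probes)
  direction[probe_symbols %in% true_up] <- "up"
  direction[probe_symbols %in% true_down] <- "down"
  effect <- config$effect_log2fc *
    (direction == "up") - config$effect_log2fc * (direction == "down")

  mat <- matrix(probe_baseline, n_probes, n_samples) +
    outer(effect, as.numeric(group == "case")) +
    matrix(rnorm(n_probes * n_samples, 0, config$noise_sd_log2),
           n_probes, n_samples)
  colnames(mat) <- paste0(ifelse(group == "case", "case_", "ctrl_"),
                          c(seq_len(config$n_case), seq_len(config$n_control)))

  p_present <- ifelse(probe_symbols %in% expressed,
                      config$present_prob_expressed,
                      config$present_prob_unexpressed)
  present <- matrix(rbinom(n_probes * n_samples, 1,
                           rep(p_present, n_samples)) == 1,
                    n_probes, n_samples)
  call <- matrix(ifelse(present, "P", "A"), n_probes, n_samples,
                 dimnames = dimnames(mat))
  det_p <- matrix(detection_pvalue(as.vector(present)), n_probes, n_samples,
                  dimnames = dimnames(mat))

  study <- expression_study(
    matrix = mat, group = group, probe_ids = probe_ids,
    symbols = probe_symbols, detection_call = call, detection_p = det_p,
    study_name = study_name
  )
  truth <- list(
    true_up = sort(true_up), true_down = sort(true_down),
    probe_map = tibble(
      probe_id = probe_ids, symbol = probe_symbols,
      expressed = probe_symbols %in% expressed,
      direction = direction
    )
  )
  list(study = study, truth = truth)
}

#' Simulation settings for several partially overlapping studies
#'
#' Configures a set of studies whose true differentially expressed (DE)
#' symbol sets overlap in controlled ways: a concordant core shared by all
#' studies, an inverted set (up in the first study, down in the others, and
#' vice versa), and per-study private DE genes. Gene universes overlap by
#' `platform_overlap_fraction`, emulating distinct array platforms.
#'
#' @param study_configs List of >= 2 [sim_config()] objects (per-study seeds
#'   are derived from `seed` and the study index).
#' @param shared_up_fraction,shared_down_fraction Fraction of each study's
#'   planted up/down genes drawn from the concordant shared core.
#' @param inverted_fraction Fraction of each study's planted genes whose
#'   direction is inverted relative to the first study.
#' @param platform_overlap_fraction Fraction of each study's gene universe
#'   shared across all platforms.
#' @param seed Integer master seed.
#'
#' @return A `multi_study_config` list.
#' @export
multi_study_config <- function(study_configs,
                               shared_up_fraction = 0.3,
                               shared_down_fraction = 0.3,
                               inverted_fraction = 0.1,
                               platform_overlap_fraction = 0.8,
                               seed = 1L) {
  if (!is.list(study_configs) || length(study_configs) < 2 ||
      !all(vapply(study_configs, inherits, logical(1), "sim_config"))) {
    abort("`study_configs` must be a list of >= 2 sim_config objects")
  }
  su <- check_prob(shared_up_fraction, "shared_up_fraction")
  sd_ <- check_prob(shared_down_fraction, "shared_down_fraction")
  iv <- check_prob(inverted_fraction, "inverted_fraction")
  if (su + iv > 1 || sd_ + iv > 1) {
    abort("shared fraction + inverted_fraction must be <= 1 per direction")
  }
  structure(
    list(study_configs = study_configs,
         shared_up_fraction = su, shared_down_fraction = sd_,
         inverted_fraction = iv,
         platform_overlap_fraction =
           check_prob(platform_overlap_fraction, "platform_overlap_fraction"),
         seed = check_count(seed, "seed", min = 0L)),
    class = "multi_study_config"
  )
}

#' Simulate several studies with controlled cross-study overlap
#'
#' @param config A [multi_study_config()].
#'
#' @return A list with `studies` (named list of `expression_study`) and
#'   `truth`: `shared_up`, `shared_down`, `inverted_up`, `inverted_down`
#'   (symbols up in study 1 / down elsewhere, and vice versa), and
#'   `per_study` (named list of `list(up, down)` symbol sets).
#' @export
simulate_multi_study <- function(config) {
  stopifnot(inherits(config, "multi_study_config"))
  withr::local_seed(config$seed)
  cfgs <- config$study_configs
  S <- length(cfgs)
  n_genes <- vapply(cfgs, `[[`, integer(1), "n_genes")
  n_core <- round(config$platform_overlap_fraction * min(n_genes))
  core <- sprintf("CORE%05d", seq_len(n_core))

  universes <- lapply(seq_len(S), function(s) {
    n_priv <- n_genes[s] - n_core
    if (n_priv < 0) abort("platform overlap larger than a study's universe")
    c(core, sprintf("S%dPRIV%05d", s, seq_len(n_priv)))
  })

  n_up <- vapply(cfgs, `[[`, integer(1), "n_up_true")
  n_down <- vapply(cfgs, `[[`, integer(1), "n_down_true")
  n_shared_up <- round(config$shared_up_fraction * min(n_up))
  n_shared_down <- round(config$shared_down_fraction * min(n_down))
  n_inv_up <- round(config$inverted_fraction * min(n_up))
  n_inv_down <- round(config$inverted_fraction * min(n_down))

  need_core <- n_shared_up + n_shared_down + n_inv_up + n_inv_down
  if (need_core > n_core) {
    abort("shared/inverted design needs more genes than the common core holds")
  }
  pool <- sample(core, need_core)
  shared_up <- head(pool, n_shared_up); pool <- setdiff(pool, shared_up)
  shared_down <- head(pool, n_shared_down); pool <- setdiff(pool, shared_down)
  inverted_up <- head(pool, n_inv_up); pool <- setdiff(pool, inverted_up)
  inverted_down <- head(pool, n_inv_down)

  per_study <- vector("list", S)
  studies <- vector("list", S)
  names(per_study) <- names(studies) <- paste0("study", seq_len(S))
  for (s in seq_len(S)) {
    # inverted genes follow study 1's direction there, the opposite elsewhere
    up_s <- c(shared_up, if (s == 1) inverted_up else inverted_down)
    down_s <- c(shared_down, if (s == 1) inverted_down else inverted_up)
    priv <- setdiff(universes[[s]], c(core))
    n_priv_up <- n_up[s] - length(up_s)
    n_priv_down <- n_down[s] - length(down_s)
    if (n_priv_up < 0 || n_priv_down < 0) {
      abort("per-study DE counts smaller than the shared+inverted design")
    }
    if (n_priv_up + n_priv_down > length(priv)) {
      abort("not enough private genes to hold study-specific DE genes")
    }
    priv_de <- sample(priv, n_priv_up + n_priv_down)
    up_s <- c(up_s, head(priv_de, n_priv_up))
    down_s <- c(down_s, priv_de[seq_len(n_priv_down) + n_priv_up])
    per_study[[s]] <- list(up = sort(up_s), down = sort(down_s))

    cfg_s <- cfgs[[s]]
    cfg_s$seed <- (config$seed * 131L + s) %% .Machine$integer.max
    res <- simulate_study(structure(cfg_s, class = "sim_config"),
                          study_name = names(studies)[s],
                          symbols = universes[[s]],
                          true_up = up_s, true_down = down_s)
    studies[[s]] <- res$study
  }
  list(
    studies = studies,
    truth = list(shared_up = sort(shared_up), shared_down = sort(shared_down),
                 inverted_up = sort(inverted_up),
                 inverted_down = sort(inverted_down),
                 per_study = per_study)
  )
}

#' Simulate a qPCR plate with planted fold changes
#'
#' Emits CT values obeying the exponential amplification model
#' `E^(-CT) proportional to input amount`: for a gene with planted fold change
#' `F` and efficiency `E`, case samples have `CT = CT0 - log(F)/log(E)`.
#' A per-sample loading offset and per-replicate Gaussian noise (both with SD
#' `ct_noise_sd`) are added; 3 technical replicates per gene x sample.
#' Reference genes must be included with fold change 1.
#'
#' @param genes Character vector of gene symbols on the plate.
#' @param fold_changes Named numeric: planted linear fold change (case vs
#'   control) per gene.
#' @param efficiencies Named numeric: per-gene amplification factor in
#'   (1, 2.2] (2 = 100% efficiency).
#' @param reference_genes Symbols used for normalization; must be in `genes`
#'   with fold change 1.
#' @param n_case,n_control Biological samples per group.
#' @param ct_noise_sd SD (cycles) of replicate noise and sample loading
#'   offsets.
#' @param seed Integer seed.
#'
#' @return A [qpcr_plate()] object.
#' @export
simulate_qpcr_plate <- function(genes, fold_changes, efficiencies,
                                reference_genes = intersect(
                                  c("ACTB", "GAPDH"), genes),
                                n_case = 6, n_control = 5,
                                ct_noise_sd = 0.1, seed = 1L) {
  genes <- as.character(genes)
  if (length(reference_genes) < 1) abort("at least one reference gene required")
  if (!all(reference_genes %in% genes)) {
    abort(sprintf("missing reference gene(s): %s",
                  paste(setdiff(reference_genes, genes), collapse = ", ")))
  }
  if (!all(genes %in% names(fold_changes)) ||
      !all(genes %in% names(efficiencies))) {
    abort("`fold_changes` and `efficiencies` must cover every gene")
  }
  if (any(abs(fold_changes[reference_genes] - 1) > 1e-12)) {
    abort("reference genes must have planted fold change 1")
  }
  if (any(efficiencies[genes] <= 1 | efficiencies[genes] > 2.2)) {
    abort("efficiencies must be amplification factors in (1, 2.2]")
  }
  n_case <- check_count(n_case, "n_case")
  n_control <- check_count(n_control, "n_control")
  withr::local_seed(check_count(seed, "seed", min = 0L))

  samples <- c(paste0("case_", seq_len(n_case)),
               paste0("ctrl_", seq_len(n_control)))
  group <- rep(c("case", "control"), c(n_case, n_control))
  ct0 <- setNames(runif(length(genes), 20, 28), genes)
  loading <- setNames(rnorm(length(samples), 0, ct_noise_sd), samples)

  grid <- tidyr::expand_grid(gene = genes, sample = samples,
                             replicate = 1:3)
  grid$group <- group[match(grid$sample, samples)]
  shift <- log(fold_changes[grid$gene]) / log(efficiencies[grid$gene])
  grid$ct <- ct0[grid$gene] -
    ifelse(grid$group == "case", shift, 0) +
    loading[grid$sample] +
    rnorm(nrow(grid), 0, ct_noise_sd)
  qpcr_plate(grid[, c("gene", "sample", "group", "replicate", "ct")],
             efficiencies = efficiencies[genes],
             reference_genes = reference_genes)
}
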