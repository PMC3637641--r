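#' Construct a qPCR plate
#'
#' Long-format CT measurements with per-gene amplification efficiencies and
#' one or more reference (housekeeping) genes used for normalization.
#'
#' @param wells Data frame with columns `gene`, `sample`, `group`
#'   (`"case"`/`"control"`), `replicate`, `ct` (cycles, > 0).
#' @param efficiencies Named numeric of per-gene efficiencies. Accepted
#'   either as linear amplification factors in (1, 2.2] (2 = perfect
#'   doubling) or as percentages in (0, 120] (100 = factor 2); percentages
#'   are converted to factors internally via `E = 1 + pct/100`.
#' @param reference_genes Character vector of reference gene symbols; must
#'   be measured on the plate.
#'
#' @return An object of class `qpcr_plate`.
#' @export
qpcr_plate <- function(wells, efficiencies, reference_genes) {
  wells <- as_tibble(wells)
  need <- c("gene", "sample", "group", "replicate", "ct")
  if (!all(need %in% names(wells))) {
    abort(paste("`wells` needs columns:", paste(need, collapse = ", ")))
  }
  if (!all(wells$group %in% c("case", "control"))) {
    abort("group must be \"case\" or \"control\"")
  }
  if (any(!is.finite(wells$ct) | wells$ct <= 0)) {
    abort("CT values must be positive and finite")
  }
  genes <- unique(wells$gene)
  if (length(reference_genes) < 1) abort("at least one reference gene required")
  if (!all(reference_genes %in% genes)) {
    abort(sprintf("reference gene(s) not on plate: %s",
                  paste(setdiff(reference_genes, genes), collapse = ", ")))
  }
  if (!all(genes %in% names(efficiencies))) {
    abort(sprintf("missing efficiency for: %s",
                  paste(setdiff(genes, names(efficiencies)), collapse = ", ")))
  }
  e <- as.numeric(efficiencies)
  names(e) <- names(efficiencies)
  pctish <- e > 2.2  # percentages, e.g. Table-style "97"
  e[pctish] <- 1 + e[pctish] / 100
  if (any(e <= 1 | e > 2.2)) {
    abort("efficiencies must be factors in (1, 2.2] or percentages in (0, 120]")
  }
  structure(list(wells = wells, efficiencies = e,
                 reference_genes = as.character(reference_genes)),
            class = "qpcr_plate")
}

#' @export
print.qpcr_plate <- function(x, ...) {
  cat(sprintf("<qpcr_plate> %d genes x %d samples (%d wells); refs: %s\n",
              length(unique(x$wells$gene)), length(unique(x$wells$sample)),
              nrow(x$wells), paste(x$reference_genes, collapse = ", ")))
  invisible(x)
}

#' Amplification efficiency from a dilution standard curve
#'
#' Fits the least-squares slope of mean CT against log10 of relative input
#' over a dilution series (e.g. five-fold: 1, 1/5, 1/25, ...). The
#' amplification factor is `E = 10^(-1/slope)`; a perfectly doubling primer
#' pair has slope -3.3219 and E = 2 (100% efficiency, where percentage
#' efficiency is `(E - 1) * 100`).
#'
#' @param dilutions Numeric vector of relative input amounts, strictly
#'   decreasing, >= 3 points (e.g. `5^-(0:4)`).
#' @param cts Mean CT at each dilution point.
#'
#' @return An object of class `standard_curve`: `slope`, `intercept`,
#'   `efficiency` (linear factor), `efficiency_pct`, `r_squared`,
#'   `in_gate` (TRUE when efficiency is within 90-110%), and the input
#'   points.
#' @export
efficiency_from_standard_curve <- function(dilutions, cts) {
  if (length(dilutions) < 3) abort("need >= 3 dilution points")
  if (length(cts) != length(dilutions)) {
    abort("`cts` must be parallel to `dilutions`")
  }
  if (any(diff(dilutions) >= 0)) {
    abort("`dilutions` must be strictly decreasing input amounts")
  }
  x <- log10(dilutions)
  fit <- lm(cts ~ x)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) abort("standard-curve slope must be negative")
  e <- 10^(-1 / slope)
  pct <- (e - 1) * 100
  structure(
    list(slope = slope, intercept = unname(coef(fit)[1]),
         efficiency = e, efficiency_pct = pct,
         r_squared = suppressWarnings(summary(fit)$r.squared),
         in_gate = pct >= 90 && pct <= 110,
         dilutions = dilutions, cts = cts),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> slope %.4f, E = %.3f (%.1f%%), R2 = %.4f [%s]\n",
    x$slope, x$efficiency, x$efficiency_pct, x$r_squared,
    if (x$in_gate) "within 90-110% gate" else "OUTSIDE 90-110% gate"))
  invisible(x)
}

#' @describeIn efficiency_from_standard_curve One-row tidy summary.
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         efficiency = x$efficiency, efficiency_pct = x$efficiency_pct,
         r_squared = x$r_squared, in_gate = x$in_gate)
}

# Technical replicates averaged first, then per-group mean CT per gene.
group_mean_ct <- function(plate, gene) {
  w <- plate$wells[plate$wells$gene == gene, ]
  if (nrow(w) == 0) abort(sprintf("gene '%s' not on plate", gene))
  per_sample <- dplyr::summarise(
    dplyr::group_by(w, .data$sample, .data$group),
    ct = mean(.data$ct), .groups = "drop")
  if (!all(c("case", "control") %in% per_sample$group)) {
    abort(sprintf("gene '%s' is not measured in both groups", gene))
  }
  list(per_sample = per_sample,
       case = mean(per_sample$ct[per_sample$group == "case"]),
       control = mean(per_sample$ct[per_sample$group == "control"]))
}

#' Efficiency-corrected relative fold change (Pfaffl method)
#'
#' Computes `FC = E_target^dCT_target / E_ref^dCT_ref`, where
#' `dCT = mean CT(control) - mean CT(case)` (technical replicates averaged
#' per sample first, then group means). With several reference genes the
#' geometric mean of the per-reference ratios is returned. When all
#' efficiencies equal 2, this reduces exactly to the classical `2^-ddCT`
#' value.
#'
#' @param plate A [qpcr_plate()].
#' @param target Gene symbol to quantify (must not be a reference gene).
#' @param references Reference genes (default: the plate's).
#'
#' @return One-row tibble: `gene`, `fold_change` (linear, case vs control),
#'   `display_fc` (down-regulation shown as negative reciprocal, e.g.
#'   0.3 -> -3.3), `dct_target`, and the per-reference ratios in a packed
#'   list column `per_reference`.
#' @export
pfaffl_fold_change <- function(plate, target,
                               references = plate$reference_genes) {
  stopifnot(inherits(plate, "qpcr_plate"))
  if (target %in% references) abort("target must not be a reference gene")
  tg <- group_mean_ct(plate, target)
  dct_t <- tg$control - tg$case
  e_t <- plate$efficiencies[[target]]
  ratios <- vapply(references, function(r) {
    rf <- group_mean_ct(plate, r)
    dct_r <- rf$control - rf$case
    e_r <- plate$efficiencies[[r]]
    (e_t^dct_t) / (e_r^dct_r)
  }, numeric(1))
  fc <- exp(mean(log(ratios)))
  tibble(gene = target, fold_change = fc,
         display_fc = if (fc < 1) -1 / fc else fc,
         dct_target = dct_t,
         per_reference = list(tibble(reference = references,
                                     ratio = unname(ratios))))
}

#' Group-difference tests on reference-normalized dCT values
#'
#' Forms per-sample normalized dCT values (target CT minus the mean of the
#' reference-gene CTs in the same sample, technical replicates averaged
#' first) and runs two-sided Student's t and Wilcoxon rank-sum tests
#' between the case and control groups.
#'
#' @param plate A [qpcr_plate()].
#' @param target Gene symbol to test.
#' @param references Reference genes (default: the plate's).
#'
#' @return One-row tibble: `gene`, `p_t_test`, `p_wilcoxon`, `n_case`,
#'   `n_control`.
#' @export
group_difference_test <- function(plate, target,
                                  references = plate$reference_genes) {
  stopifnot(inherits(plate, "qpcr_plate"))
  tg <- group_mean_ct(plate, target)$per_sample
  ref_ct <- purrr::map_dfr(references, function(r) {
    x <- group_mean_ct(plate, r)$per_sample
    x$gene <- r
    x
  }) |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(ref_ct = mean(.data$ct), .groups = "drop")
  d <- dplyr::left_join(tg, ref_ct, by = "sample")
  d$dct <- d$ct - d$ref_ct
  n_case <- sum(d$group == "case")
  n_control <- sum(d$group == "control")
  if (n_case < 2 || n_control < 2) {
    abort("need >= 2 samples per group for a group-difference test")
  }
  x <- d$dct[d$group == "case"]
  y <- d$dct[d$group == "control"]
  tibble(gene = target,
         p_t_test = tryCatch(t.test(x, y)$p.value,
                             error = function(e) NA_real_),
         p_wilcoxon = {
           pw <- suppressWarnings(wilcox.test(x, y)$p.value)
           if (is.nan(pw)) 1 else pw  # fully tied groups carry no evidence
         },
         n_case = n_case, n_control = n_control)
}
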