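#' Pairwise rank matrix for one direction
#'
#' For each of the `k = n_case * n_control` case-control sample pairs, genes
#' are ranked by the pairwise log-ratio (case - control): for
#' `direction = "up"` rank 1 is the most up-regulated gene in that pair, for
#' `direction = "down"` rank 1 is the most down-regulated. Ties get average
#' ranks.
#'
#' @param study An [expression_study()].
#' @param direction `"up"` or `"down"`.
#'
#' @return Numeric matrix, probes x k, of within-pair ranks. Column names
#'   identify the sample pair.
#' @export
pairwise_rank_matrix <- function(study, direction = c("up", "down")) {
  stopifnot(inherits(study, "expression_study"))
  direction <- match_direction(match.arg(direction))
  cases <- study$matrix[, study$group == "case", drop = FALSE]
  ctrls <- study$matrix[, study$group == "control", drop = FALSE]
  k <- ncol(cases) * ncol(ctrls)
  out <- matrix(NA_real_, nrow(study$matrix), k)
  cn <- character(k)
  idx <- 0L
  sign <- if (direction == "up") -1 else 1
  for (i in seq_len(ncol(cases))) {
    for (j in seq_len(ncol(ctrls))) {
      idx <- idx + 1L
      ratio <- cases[, i] - ctrls[, j]
      out[, idx] <- rank(sign * ratio, ties.method = "average")
      cn[idx] <- paste0(colnames(cases)[i], ".vs.", colnames(ctrls)[j])
    }
  }
  dimnames(out) <- list(study$probe_ids, cn)
  out
}

#' Rank product of a rank matrix
#'
#' Geometric mean of each gene's ranks over the `k` pairwise comparisons,
#' computed in log space so large `N * k` do not overflow. A gene ranked
#' first in every comparison has rank product 1; consistently top-ranked
#' genes have small rank products.
#'
#' @param rank_matrix Numeric matrix of positive ranks (probes x comparisons),
#'   e.g. from [pairwise_rank_matrix()].
#'
#' @return Numeric vector of rank products, one per row.
#' @export
rank_product <- function(rank_matrix) {
  if (!is.matrix(rank_matrix)) rank_matrix <- as.matrix(rank_matrix)
  if (any(rank_matrix <= 0)) abort("ranks must be positive")
  exp(rowMeans(log(rank_matrix)))
}

#' Permutation null distribution of the rank product
#'
#' Under the null hypothesis the order of all genes is random in every
#' comparison, so each null draw consists of `k` independent uniform random
#' permutations of `1..n_genes` used as rank columns; the rank product is
#' computed per gene. `n_permutations` such draws give a pooled reference
#' distribution of `n_permutations * n_genes` null rank products.
#'
#' @param n_genes Number of genes N (>= 2).
#' @param k Number of pairwise comparisons.
#' @param n_permutations Number of null permutations B (default 1000).
#' @param seed Integer seed; the draw is reproducible.
#'
#' @return Numeric matrix `n_permutations` x `n_genes` of null rank products.
#' @export
rp_permutation_null <- function(n_genes, k, n_permutations = 1000, seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", min = 2L)
  k <- check_count(k, "k")
  B <- check_count(n_permutations, "n_permutations")
  withr::local_seed(check_count(seed, "seed", min = 0L))
  out <- matrix(NA_real_, B, n_genes)
  for (b in seq_len(B)) {
    s <- numeric(n_genes)
    for (i in seq_len(k)) {
      s <- s + log(sample.int(n_genes))
    }
    out[b, ] <- exp(s / k)
  }
  out
}

#' Structure-preserving null distribution of the rank product
#'
#' Simulates `n_permutations` complete null experiments with the same number
#' of genes and replicates as the real one: each draw generates an
#' exchangeable expression matrix (i.i.d. continuous values) for
#' `n_case + n_control` samples and recomputes the pairwise rank matrix and
#' rank products. Because the `k = n_case * n_control` pairwise comparisons
#' share samples, their rank columns are correlated; this null reproduces
#' that correlation exactly (unlike [rp_permutation_null()], whose columns
#' are independent) and is what calibrates the p-values of [rp_analyze()].
#'
#' @param n_genes Number of genes N.
#' @param n_case,n_control Replicates per group.
#' @param n_permutations Number of null experiments B.
#' @param seed Integer seed.
#'
#' @return Numeric matrix `n_permutations` x `n_genes` of null rank
#'   products.
#' @export
rp_experiment_null <- function(n_genes, n_case, n_control,
                               n_permutations = 1000, seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", min = 2L)
  n_case <- check_count(n_case, "n_case")
  n_control <- check_count(n_control, "n_control")
  B <- check_count(n_permutations, "n_permutations")
  withr::local_seed(check_count(seed, "seed", min = 0L))
  k <- n_case * n_control
  out <- matrix(NA_real_, B, n_genes)
  for (b in seq_len(B)) {
    x <- matrix(runif(n_genes * (n_case + n_control)), n_genes)
    s <- numeric(n_genes)
    for (i in seq_len(n_case)) {
      for (j in seq_len(n_control)) {
        s <- s + log(rank(-(x[, i] - x[, n_case + j]),
                          ties.method = "average"))
      }
    }
    out[b, ] <- exp(s / k)
  }
  out
}

#' Rank Products differential expression analysis
#'
#' Runs the Rank Products statistic in both directions on a two-group study:
#' all `n_case * n_control` pairwise log-ratios are ranked per comparison,
#' rank products are formed, and significance is calibrated against
#' `n_permutations` random-order permutations. For each gene `g` and
#' direction, the expected number of false positives is
#' `E_g = #(null RP <= RP_g, pooled over permutations and genes) / B`, the
#' p-value is `p_g = E_g / N` (floored at `1/(B*N)`), and the percentage of
#' false prediction (the FDR analogue) is `pfp_g = E_g / rank_g` where
#' `rank_g` is the gene's position in the direction's RP-sorted list.
#'
#' The same permutation draw calibrates both directions: the null is
#' direction-symmetric, so one reference sample serves both orderings.
#' By default the null preserves the replicate structure
#' ([rp_experiment_null()]): the pairwise comparisons share samples, so
#' their rank columns are positively correlated, and a null of independent
#' random rank columns ([rp_permutation_null()], available as
#' `null = "independent"`) would understate the spread of the observed rank
#' products and miscalibrate tail p-values.
#'
#' Fold change is reported two ways (the log-scale data admit both
#' conventions): `fc` = `2^(mean case - mean control)` of the log2 values,
#' and `fc_ratio_of_means` = ratio of linear-scale group means.
#'
#' @param study An [expression_study()].
#' @param n_permutations Number of permutations B (default 1000).
#' @param seed Integer seed for the permutation null.
#' @param null `"experiment"` (default; replicate-structure-preserving) or
#'   `"independent"` (independent uniform rank columns).
#'
#' @return An object of class `rp_result`; see [tidy.rp_result()] for the
#'   per-probe table (columns `probe_id, symbol, fc, fc_ratio_of_means`, and
#'   `rp, rank, p, pfp` per direction).
#' @export
rp_analyze <- function(study, n_permutations = 1000, seed = 1L,
                       null = c("experiment", "independent")) {
  stopifnot(inherits(study, "expression_study"))
  null <- match.arg(null)
  B <- check_count(n_permutations, "n_permutations")
  N <- nrow(study$matrix)

  ranks_up <- pairwise_rank_matrix(study, "up")
  ranks_down <- pairwise_rank_matrix(study, "down")
  k <- ncol(ranks_up)
  rp_up <- unname(rank_product(ranks_up))
  rp_down <- unname(rank_product(ranks_down))

  null_rp <- if (null == "experiment") {
    rp_experiment_null(N, sum(study$group == "case"),
                       sum(study$group == "control"), B, seed)
  } else {
    rp_permutation_null(N, k, B, seed)
  }
  null_rp <- sort(as.vector(null_rp))
  stat_for <- function(rp) {
    e <- findInterval(rp, null_rp) / B
    rank <- rank(rp, ties.method = "first")
    p <- pmax(e / N, 1 / (B * N))
    list(e = e, rank = rank, p = p, pfp = e / rank)
  }
  up <- stat_for(rp_up)
  down <- stat_for(rp_down)

  mc <- unname(rowMeans(study$matrix[, study$group == "case", drop = FALSE]))
  mx <- unname(rowMeans(study$matrix[, study$group == "control", drop = FALSE]))
  lc <- unname(rowMeans(2^study$matrix[, study$group == "case", drop = FALSE]))
  lx <- unname(rowMeans(2^study$matrix[, study$group == "control", drop = FALSE]))

  table <- tibble(
    probe_id = study$probe_ids,
    symbol = if (is.null(study$symbols)) NA_character_ else study$symbols,
    fc = 2^(mc - mx),
    fc_ratio_of_means = lc / lx,
    avg_log2 = (mc + mx) / 2,
    rp_up = rp_up, rank_up = up$rank, e_up = up$e,
    p_up = up$p, pfp_up = up$pfp,
    rp_down = rp_down, rank_down = down$rank, e_down = down$e,
    p_down = down$p, pfp_down = down$pfp
  )
  structure(
    list(table = table, n_probes = N, k = k, n_permutations = B,
         seed = seed, study_name = study$study_name,
         n_case = sum(study$group == "case"),
         n_control = sum(study$group == "control"),
         universe_size = N),
    class = "rp_result"
  )
}

#' @export
print.rp_result <- function(x, ...) {
  cat(sprintf(
    "<rp_result> %s: %d probes, k = %d pairwise comparisons, B = %d permutations\n",
    x$study_name, x$n_probes, x$k, x$n_permutations))
  cat(sprintf("  significant at p < 1e-4 & pfp < 0.05: %d up, %d down\n",
              sum(x$table$p_up <= 1e-4 & x$table$pfp_up <= 0.05),
              sum(x$table$p_down <= 1e-4 & x$table$pfp_down <= 0.05)))
  invisible(x)
}

#' Tidy a Rank Products result
#'
#' @param x An `rp_result`.
#' @param ... Unused.
#' @return The per-probe tibble of statistics.
#' @export
tidy.rp_result <- function(x, ...) {
  x$table
}

#' One-row summary of a Rank Products result
#'
#' @param x An `rp_result`.
#' @param ... Unused.
#' @return One-row tibble: study, dimensions, permutation settings, counts of
#'   probes passing the conventional strict cutoffs (p <= 1e-4, pfp <= 0.05).
#' @export
glance.rp_result <- function(x, ...) {
  tibble(
    study = x$study_name, n_probes = x$n_probes,
    n_case = x$n_case, n_control = x$n_control,
    k = x$k, n_permutations = x$n_permutations, seed = x$seed,
    n_up_strict = sum(x$table$p_up <= 1e-4 & x$table$pfp_up <= 0.05),
    n_down_strict = sum(x$table$p_down <= 1e-4 & x$table$pfp_down <= 0.05)
  )
}
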