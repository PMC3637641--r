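#' Hypergeometric over-representation analysis
#'
#' Tests each annotation term for over-representation of a gene list within
#' a universe, the statistic behind classical GO-term enrichment tables:
#' `p = P(X >= k)` under Hypergeometric(universe `N_u`, term size `K`,
#' list size `n`), fold enrichment `(k/n)/(K/N_u)`, and Benjamini-Hochberg
#' FDR computed independently within each annotation category. The EASE
#' variant (jackknifed: one list hit removed before taking the tail) is
#' available as a switch.
#'
#' @param list_symbols Character vector of gene symbols (the list). Symbols
#'   outside the universe are dropped with a message.
#' @param annotation Long-format data frame with columns `term_id`,
#'   `term_name`, `category`, `symbol` (one row per term-gene pair), e.g.
#'   from [read_gmt()].
#' @param universe Character vector of background symbols. Defaults to all
#'   symbols in `annotation`.
#' @param min_count Minimum list hits `k` for a term to be reported.
#' @param ease Use the EASE-adjusted tail (k - 1 successes).
#'
#' @return An `enrichment_result` tibble: `category, term_id, term_name, k,
#'   n, K, N_u, p, fold_enrichment, fdr`, sorted by p within category.
#' @export
hypergeom_enrich <- function(list_symbols, annotation, universe = NULL,
                             min_count = 2, ease = FALSE) {
  annotation <- as_tibble(annotation)
  need <- c("term_id", "term_name", "category", "symbol")
  if (!all(need %in% names(annotation))) {
    abort(paste("`annotation` needs columns:", paste(need, collapse = ", ")))
  }
  annotation$symbol <- normalize_symbols(annotation$symbol)
  universe <- normalize_symbols(universe %||% unique(annotation$symbol))
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty universe")
  list_symbols <- unique(normalize_symbols(list_symbols))
  outside <- setdiff(list_symbols, universe)
  if (length(outside) > 0) {
    inform(sprintf("dropping %d list symbol(s) outside the universe",
                   length(outside)))
    list_symbols <- setdiff(list_symbols, outside)
  }
  n <- length(list_symbols)
  N_u <- length(universe)

  terms <- dplyr::distinct(annotation, .data$category, .data$term_id,
                           .data$term_name)
  res <- purrr::pmap_dfr(terms, function(category, term_id, term_name) {
    members <- intersect(
      annotation$symbol[annotation$term_id == term_id &
                          annotation$category == category],
      universe)
    K <- length(members)
    k <- length(intersect(members, list_symbols))
    if (k < min_count || K == 0) return(NULL)
    q <- if (ease) k - 2 else k - 1  # P(X >= k), EASE removes one hit
    p <- phyper(max(q, -1), K, N_u - K, n, lower.tail = FALSE)
    tibble(category = category, term_id = term_id, term_name = term_name,
           k = k, n = n, K = K, N_u = N_u, p = min(p, 1),
           fold_enrichment = (k / n) / (K / N_u))
  })
  if (nrow(res) == 0) {
    res <- tibble(category = character(), term_id = character(),
                  term_name = character(), k = integer(), n = integer(),
                  K = integer(), N_u = integer(), p = numeric(),
                  fold_enrichment = numeric(), fdr = numeric())
  } else {
    res <- res |>
      dplyr::group_by(.data$category) |>
      dplyr::mutate(fdr = p.adjust(.data$p, method = "BH")) |>
      dplyr::arrange(.data$p, .by_group = TRUE) |>
      dplyr::ungroup()
  }
  structure(res, class = c("enrichment_result", class(tibble())))
}

#' GSEA-style weighted running-sum enrichment score
#'
#' Walks a ranked gene list: at members of `gene_set` ("hits") the running
#' sum increases by `|weight|^w / sum(|weight|^w over hits)`, at non-members
#' it decreases by `1/(L - n_hits)`. The enrichment score (ES) is the
#' running-sum value of largest magnitude, positive when the set
#' concentrates at the top of the ranking, negative at the bottom.
#'
#' Convention for the degenerate case where the gene set covers the entire
#' list: no misses exist, no deviation between hit and miss mass can be
#' measured, and `ES = 0` is returned.
#'
#' @param ranked_symbols Character vector: the full list, best rank first.
#' @param gene_set Character vector of member symbols; must intersect the
#'   list.
#' @param weights Optional nonnegative per-position weights parallel to
#'   `ranked_symbols` (e.g. |ranking statistic|); default all 1.
#' @param w Weighting exponent (0 = classical unweighted Kolmogorov-Smirnov
#'   walk, 1 = weighted; default 1).
#'
#' @return An object of class `gsea_result`: `es`, `running_sum` (length L),
#'   `hit_positions`, `p` (`NA` until [gsea_pvalue()] is run), plus the
#'   inputs needed to recompute.
#' @export
gsea_enrichment_score <- function(ranked_symbols, gene_set, weights = NULL,
                                  w = 1) {
  ranked_symbols <- normalize_symbols(ranked_symbols)
  gene_set <- unique(normalize_symbols(gene_set))
  L <- length(ranked_symbols)
  if (anyDuplicated(ranked_symbols)) abort("ranked list has duplicate symbols")
  weights <- weights %||% rep(1, L)
  if (length(weights) != L || any(weights < 0)) {
    abort("`weights` must be nonnegative and parallel to the ranked list")
  }
  hit <- ranked_symbols %in% gene_set
  n_hits <- sum(hit)
  if (n_hits == 0) abort("gene set is disjoint from the ranked list")
  if (n_hits == L) {
    running <- cumsum(rep(1 / L, L))
    return(structure(list(es = 0, running_sum = running,
                          hit_positions = seq_len(L), p = NA_real_,
                          gene_set_size = n_hits, w = w),
                     class = "gsea_result"))
  }
  wts <- abs(weights)^w
  incr <- numeric(L)
  incr[hit] <- wts[hit] / sum(wts[hit])
  incr[!hit] <- -1 / (L - n_hits)
  running <- cumsum(incr)
  es <- running[which.max(abs(running))]
  structure(list(es = es, running_sum = running,
                 hit_positions = which(hit), p = NA_real_,
                 gene_set_size = n_hits, w = w),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("<gsea_result> ES = %.4f (%d hits, w = %g)%s\n", x$es,
              x$gene_set_size, x$w,
              if (is.na(x$p)) "" else sprintf(", p = %.4g", x$p)))
  invisible(x)
}

#' Gene-set permutation p-value for an enrichment score
#'
#' Draws `n_permutations` random gene sets of the observed size from the
#' ranked list, recomputes the enrichment score for each, and returns
#' `p = (1 + #(|ES_null| >= |ES|)) / (n_permutations + 1)`. Gene-set
#' (not phenotype) permutation keeps the null exact and reproducible at
#' small sample sizes.
#'
#' @param result A [gsea_enrichment_score()] result.
#' @param ranked_symbols The same ranked list the score was computed on.
#' @param weights,w As in [gsea_enrichment_score()].
#' @param n_permutations Number of null draws (default 999).
#' @param seed Integer seed.
#'
#' @return The `gsea_result` with `p` filled in and the null scores attached
#'   as `null_es`.
#' @export
gsea_pvalue <- function(result, ranked_symbols, weights = NULL, w = NULL,
                        n_permutations = 999, seed = 1L) {
  stopifnot(inherits(result, "gsea_result"))
  B <- check_count(n_permutations, "n_permutations")
  ranked_symbols <- normalize_symbols(ranked_symbols)
  L <- length(ranked_symbols)
  m <- result$gene_set_size
  if (m > L) abort("gene set larger than the ranked list")
  w <- w %||% result$w
  withr::local_seed(check_count(seed, "seed", min = 0L))
  null_es <- vapply(seq_len(B), function(b) {
    gsea_enrichment_score(ranked_symbols,
                          sample(ranked_symbols, m),
                          weights = weights, w = w)$es
  }, numeric(1))
  result$p <- (1 + sum(abs(null_es) >= abs(result$es))) / (B + 1)
  result$null_es <- null_es
  result
}

#' @describeIn gsea_enrichment_score Tidy the running sum: one row per
#'   position with the running-sum value and hit flag.
#' @param x A `gsea_result`.
#' @param ... Unused.
#' @export
tidy.gsea_result <- function(x, ...) {
  tibble(position = seq_along(x$running_sum),
         running_sum = x$running_sum,
         hit = seq_along(x$running_sum) %in% x$hit_positions)
}

#' @describeIn gsea_enrichment_score One-row summary (ES, set size, p).
#' @export
glance.gsea_result <- function(x, ...) {
  tibble(es = x$es, gene_set_size = x$gene_set_size, w = x$w, p = x$p)
}
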