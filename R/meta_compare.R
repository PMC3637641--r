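#' Bundle per-study directional gene lists for meta-comparison
#'
#' @param ... Named arguments, one per study, each a list with elements `up`
#'   and `down` holding collapsed [gene_list()]s, or a single named list of
#'   such per-study lists. Within a study the up and down symbol sets must
#'   be disjoint (see [disjoin_directions()]).
#'
#' @return An object of class `study_list_set`.
#' @export
study_list_set <- function(...) {
  dots <- list(...)
  if (length(dots) == 1 && is.null(names(dots)) || (length(dots) == 1 &&
      is.list(dots[[1]]) && !all(c("up", "down") %in% names(dots[[1]])))) {
    dots <- dots[[1]]
  }
  if (is.null(names(dots)) || any(names(dots) == "")) {
    abort("every study must be named")
  }
  for (nm in names(dots)) {
    s <- dots[[nm]]
    if (!is.list(s) || !all(c("up", "down") %in% names(s))) {
      abort(sprintf("study '%s' must have `up` and `down` gene lists", nm))
    }
    for (d in c("up", "down")) {
      if (!inherits(s[[d]], "gene_list")) {
        abort(sprintf("study '%s' %s entry is not a gene_list", nm, d))
      }
      if (!is_collapsed(s[[d]])) {
        abort(sprintf("study '%s' %s list is not collapsed to symbols", nm, d))
      }
    }
    if (length(intersect(s$up$symbol, s$down$symbol)) > 0) {
      abort(sprintf("study '%s' has symbols in both directions; %s", nm,
                    "use disjoin_directions() first"))
    }
  }
  structure(dots, class = "study_list_set")
}

#' @export
print.study_list_set <- function(x, ...) {
  cat(sprintf("<study_list_set> %d studies\n", length(x)))
  for (nm in names(x)) {
    cat(sprintf("  %s: %d up / %d down\n", nm, nrow(x[[nm]]$up),
                nrow(x[[nm]]$down)))
  }
  invisible(x)
}

#' Directional overlap between two gene lists
#'
#' Counts symbols of `list_x` found in `list_y` and expresses the count as a
#' percentage of `list_y`'s size (the column-study convention of the
#' shared/inverted comparison tables). With `opposite = FALSE` the two lists
#' must have the same direction of regulation for the overlap to count as
#' shared; with `opposite = TRUE` they must have opposite directions
#' (inverted expression). If the direction relation does not match the flag,
#' the overlap is 0 by definition.
#'
#' @param list_x,list_y Collapsed [gene_list()]s.
#' @param opposite Count inverted (opposite-direction) overlap instead of
#'   same-direction overlap.
#'
#' @return One-row tibble: `count`, `pct` (full precision, percent of
#'   `list_y`), `pct_display` (half-up rounded to one decimal),
#'   `denominator`.
#' @export
directional_overlap <- function(list_x, list_y, opposite = FALSE) {
  for (l in list(list_x, list_y)) {
    if (!inherits(l, "gene_list")) abort("inputs must be gene_list objects")
    if (!is_collapsed(l)) abort("lists must be collapsed to symbols")
  }
  same_dir <- list_direction(list_x) == list_direction(list_y)
  n <- if (same_dir != opposite) {
    length(intersect(list_x$symbol, list_y$symbol))
  } else 0L
  denom <- nrow(list_y)
  pct <- if (denom > 0) 100 * n / denom else 0
  tibble(count = n, pct = pct, pct_display = round_half_up(pct, 1),
         denominator = denom)
}

#' Pairwise shared and inverted percentage matrices
#'
#' For every ordered study pair (row X, column Y) and each direction,
#' computes the percentage of column study Y's list shared with X in the
#' same direction (`shared`) and present in X's opposite-direction list
#' (`inverted`); percentages are of Y's list size. An `ALL` row gives, per
#' column, the percentage of distinct genes in Y's list that are shared
#' (respectively inverted) with at least one other study.
#'
#' @param set A [study_list_set()] of >= 2 studies.
#'
#' @return An object of class `comparison_matrix`: a tibble with columns
#'   `direction`, `type` (shared/inverted), `row_study` (`"ALL"` for the
#'   summary rows), `col_study`, `count`, `pct`, `pct_display`,
#'   `denominator`.
#' @export
comparison_matrix <- function(set) {
  stopifnot(inherits(set, "study_list_set"))
  if (length(set) < 2) abort("need >= 2 studies")
  studies <- names(set)
  rows <- list()
  for (d in c("up", "down")) {
    for (y in studies) {
      ly <- set[[y]][[d]]
      for (x in setdiff(studies, y)) {
        sh <- directional_overlap(set[[x]][[d]], ly, opposite = FALSE)
        iv <- directional_overlap(set[[x]][[opposite_direction(d)]], ly,
                                  opposite = TRUE)
        rows[[length(rows) + 1]] <- dplyr::bind_rows(
          dplyr::mutate(sh, direction = d, type = "shared",
                        row_study = x, col_study = y),
          dplyr::mutate(iv, direction = d, type = "inverted",
                        row_study = x, col_study = y))
      }
      # ALL rows: distinct genes of Y shared/inverted with >= 1 other study
      others_same <- unique(unlist(lapply(setdiff(studies, y), function(x)
        set[[x]][[d]]$symbol)))
      others_opp <- unique(unlist(lapply(setdiff(studies, y), function(x)
        set[[x]][[opposite_direction(d)]]$symbol)))
      for (ty in c("shared", "inverted")) {
        pool <- if (ty == "shared") others_same else others_opp
        n <- length(intersect(ly$symbol, pool))
        pct <- if (nrow(ly) > 0) 100 * n / nrow(ly) else 0
        rows[[length(rows) + 1]] <- tibble(
          count = n, pct = pct, pct_display = round_half_up(pct, 1),
          denominator = nrow(ly), direction = d, type = ty,
          row_study = "ALL", col_study = y)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- out[, c("direction", "type", "row_study", "col_study",
                 "count", "pct", "pct_display", "denominator")]
  structure(out, class = c("comparison_matrix", class(tibble())))
}

#' Pivot a comparison matrix to the familiar square layout
#'
#' @param cm A [comparison_matrix()].
#' @param direction `"up"` or `"down"`.
#' @param type `"shared"` or `"inverted"`.
#' @return A wide tibble, rows = row studies (plus `ALL`), columns = column
#'   studies, cells = one-decimal percentages.
#' @export
comparison_matrix_wide <- function(cm, direction = "up", type = "shared") {
  stopifnot(inherits(cm, "comparison_matrix"))
  d <- match_direction(direction)
  sub <- cm[cm$direction == d & cm$type == type, ]
  tidyr::pivot_wider(sub[, c("row_study", "col_study", "pct_display")],
                     names_from = "col_study", values_from = "pct_display")
}

#' Cross-study directional intersection signature
#'
#' Intersects the up lists (and, separately, the down lists) of the selected
#' studies: the signature is the set of genes regulated in the same
#' direction in every selected list. Venn region counts over all
#' `2^k - 1` membership patterns per direction are included, along with a
#' per-symbol membership table carrying each list's fold change.
#'
#' @param set A [study_list_set()].
#' @param studies Character vector of study names to intersect (default all).
#'
#' @return An object of class `signature_result` with elements `up_symbols`,
#'   `down_symbols`, `membership` (tibble: direction, symbol, one
#'   logical/fc column pair per study), and `venn_counts` (tibble:
#'   direction, region, count).
#' @export
intersect_signature <- function(set, studies = names(set)) {
  stopifnot(inherits(set, "study_list_set"))
  if (length(studies) < 1) abort("empty study selector")
  if (!all(studies %in% names(set))) {
    abort(sprintf("unknown study: %s",
                  paste(setdiff(studies, names(set)), collapse = ", ")))
  }
  one_direction <- function(d) {
    syms <- lapply(studies, function(s) set[[s]][[d]]$symbol)
    names(syms) <- studies
    universe <- unique(unlist(syms))
    memb <- vapply(syms, function(s) universe %in% s,
                   logical(length(universe)))
    if (length(universe) == 1) memb <- matrix(memb, nrow = 1,
                                              dimnames = list(NULL, studies))
    core <- universe[rowSums(memb) == length(studies)]
    region <- apply(memb, 1, function(r) paste(studies[r], collapse = "&"))
    region_tab <- table(region)
    venn <- tibble(direction = d,
                   region = names(region_tab),
                   count = as.integer(region_tab))
    # all 2^k - 1 regions, zero-filled
    all_regions <- unlist(lapply(seq_along(studies), function(m)
      utils::combn(studies, m, paste, collapse = "&", simplify = TRUE)))
    venn <- dplyr::left_join(tibble(direction = d, region = all_regions),
                             venn, by = c("direction", "region"))
    venn$count[is.na(venn$count)] <- 0L
    mtab <- tibble(direction = d, symbol = universe)
    for (s in studies) {
      mtab[[paste0("in_", s)]] <- memb[, s]
      fc <- set[[s]][[d]]$fc[match(universe, set[[s]][[d]]$symbol)]
      mtab[[paste0("fc_", s)]] <- fc
    }
    list(core = sort(core), venn = venn, membership = mtab)
  }
  up <- one_direction("up")
  down <- one_direction("down")
  structure(
    list(up_symbols = up$core, down_symbols = down$core,
         membership = dplyr::bind_rows(up$membership, down$membership),
         venn_counts = dplyr::bind_rows(up$venn, down$venn),
         studies = studies),
    class = "signature_result"
  )
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("<signature_result> %d lists: %d up + %d down signature genes\n",
              length(x$studies), length(x$up_symbols),
              length(x$down_symbols)))
  invisible(x)
}

#' @describeIn intersect_signature Tidy the signature: one row per signature
#'   gene with its direction.
#' @param x A `signature_result`.
#' @param ... Unused.
#' @export
tidy.signature_result <- function(x, ...) {
  dplyr::bind_rows(
    tibble(direction = "up", symbol = x$up_symbols),
    tibble(direction = "down", symbol = x$down_symbols)
  )
}

#' @describeIn intersect_signature One-row summary with signature sizes.
#' @export
glance.signature_result <- function(x, ...) {
  tibble(n_studies = length(x$studies),
         n_up = length(x$up_symbols), n_down = length(x$down_symbols),
         n_total = length(x$up_symbols) + length(x$down_symbols))
}

#' Genes shared with a reference study, and the combined shared list
#'
#' For each non-reference study, lists the genes shared same-direction with
#' the reference study's lists; additionally returns the union of all genes
#' shared (same direction) between any two or more studies in the set.
#'
#' @param set A [study_list_set()].
#' @param reference_study Name of the reference study.
#'
#' @return List with `per_study` (tibble: study, direction, symbol) and
#'   `combined` (tibble: direction, symbol, n_studies — genes appearing in
#'   >= 2 studies' same-direction lists).
#' @export
shared_gene_table <- function(set, reference_study) {
  stopifnot(inherits(set, "study_list_set"))
  if (!reference_study %in% names(set)) {
    abort(sprintf("unknown reference study '%s'", reference_study))
  }
  per_study <- list()
  for (s in setdiff(names(set), reference_study)) {
    for (d in c("up", "down")) {
      shared <- intersect(set[[s]][[d]]$symbol,
                          set[[reference_study]][[d]]$symbol)
      if (length(shared) > 0) {
        per_study[[length(per_study) + 1]] <-
          tibble(study = s, direction = d, symbol = sort(shared))
      }
    }
  }
  combined <- list()
  for (d in c("up", "down")) {
    syms <- unlist(lapply(names(set), function(s) set[[s]][[d]]$symbol))
    counts <- table(syms)
    keep <- names(counts)[counts >= 2]
    combined[[d]] <- tibble(direction = d, symbol = sort(keep),
                            n_studies = as.integer(counts[sort(keep)]))
  }
  list(per_study = dplyr::bind_rows(per_study),
       combined = dplyr::bind_rows(combined))
}
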