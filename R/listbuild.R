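new_gene_list <- function(entries, study, direction, collapsed,
                          universe_size, shortfall = FALSE) {
  entries <- as_tibble(entries)
  structure(entries,
            class = c("gene_list", class(tibble())),
            study = study, direction = direction,
            collapsed = collapsed, universe_size = universe_size,
            shortfall = shortfall)
}

#' Construct a directional gene list
#'
#' Builds a `gene_list` directly from symbols (e.g. a published list), as an
#' alternative to deriving one from an [rp_analyze()] result via
#' [apply_cutoffs()]. Symbols are normalized (upper case, trimmed) and
#' de-duplicated preserving order.
#'
#' @param symbols Character vector of gene symbols, ordered by rank if known.
#' @param study Study name.
#' @param direction `"up"` or `"down"`.
#' @param fc Optional numeric fold changes parallel to `symbols`.
#' @param collapsed Whether the list is already collapsed to unique symbols
#'   (default `TRUE` for symbol input).
#'
#' @return A `gene_list` tibble (columns `rank, probe_id, symbol, fc, p,
#'   pfp`) with attributes `study`, `direction`, `collapsed`,
#'   `universe_size`.
#' @export
gene_list <- function(symbols, study, direction, fc = NA_real_,
                      collapsed = TRUE) {
  direction <- match_direction(direction)
  symbols <- normalize_symbols(symbols)
  keep <- !duplicated(symbols) & symbols != "" & !is.na(symbols)
  symbols <- symbols[keep]
  fc <- rep_len(fc, length(keep))[keep]
  new_gene_list(
    tibble(rank = seq_along(symbols), probe_id = NA_character_,
           symbol = symbols, fc = fc, p = NA_real_, pfp = NA_real_),
    study = study, direction = direction, collapsed = collapsed,
    universe_size = length(symbols)
  )
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("<gene_list> %s %s: %d entries%s (universe %d)\n",
              attr(x, "study"), toupper(attr(x, "direction")), nrow(x),
              if (isTRUE(attr(x, "collapsed"))) ", collapsed to symbols" else "",
              attr(x, "universe_size")))
  NextMethod()
}

list_direction <- function(x) attr(x, "direction")
list_study <- function(x) attr(x, "study")
is_collapsed <- function(x) isTRUE(attr(x, "collapsed"))

#' Filter probes by detection call before list building
#'
#' Removes probes with insufficient evidence of expression from an
#' [rp_analyze()] result. Two dialects are supported:
#' \describe{
#'   \item{`fraction_present`}{keep probes called Present (`"P"`) in more
#'     than `detection_threshold` of all samples (default > 20%).}
#'   \item{`fraction_detected_p`}{keep probes detected at
#'     `p < detection_p` in more than `detection_threshold` of samples
#'     (default p < 0.01 in > 10%).}
#' }
#'
#' @param result An `rp_result`.
#' @param study The [expression_study()] the result came from (supplies the
#'   detection matrices).
#' @param detection_mode `"fraction_present"` or `"fraction_detected_p"`.
#' @param detection_threshold Fraction of samples that must pass (strict >).
#' @param detection_p Detection p-value threshold for the
#'   `fraction_detected_p` mode.
#'
#' @return A filtered `rp_result` with `universe_size` updated.
#' @export
detection_filter <- function(result, study,
                             detection_mode = c("fraction_present",
                                                "fraction_detected_p"),
                             detection_threshold = 0.2,
                             detection_p = 0.01) {
  stopifnot(inherits(result, "rp_result"), inherits(study, "expression_study"))
  detection_mode <- match.arg(detection_mode)
  detection_threshold <- check_prob(detection_threshold, "detection_threshold")
  frac <- switch(
    detection_mode,
    fraction_present = {
      if (is.null(study$detection_call)) {
        abort("fraction_present filtering requires detection calls")
      }
      rowMeans(study$detection_call == "P")
    },
    fraction_detected_p = {
      if (is.null(study$detection_p)) {
        abort("fraction_detected_p filtering requires detection p-values")
      }
      rowMeans(study$detection_p < check_prob(detection_p, "detection_p"))
    }
  )
  keep_ids <- study$probe_ids[frac > detection_threshold]
  result$table <- result$table[result$table$probe_id %in% keep_ids, ]
  result$universe_size <- nrow(result$table)
  result
}

#' Apply strict significance cutoffs to one direction
#'
#' Keeps probes with `p <= p_max` and `pfp <= pfp_max` in the requested
#' direction (and, optionally, fold change beyond `fc_min` in that
#' direction), ordered by ascending rank product. These are the strict-list
#' settings used for GO/pathway submission (`p <= 1e-4`, `pfp <= 0.05`).
#'
#' @param result An `rp_result` (optionally already detection-filtered).
#' @param direction `"up"` or `"down"`.
#' @param p_max Permutation p-value cutoff.
#' @param pfp_max Percentage-of-false-prediction (FDR) cutoff.
#' @param fc_min Optional linear fold-change cutoff: keep `fc >= fc_min` for
#'   up lists and `fc <= 1/fc_min` for down lists.
#'
#' @return A `gene_list` ordered by RP rank, not yet collapsed.
#' @export
apply_cutoffs <- function(result, direction = c("up", "down"),
                          p_max = 1e-4, pfp_max = 0.05, fc_min = NULL) {
  stopifnot(inherits(result, "rp_result"))
  direction <- match_direction(match.arg(direction))
  tab <- direction_table(result, direction)
  keep <- tab$p <= p_max & tab$pfp <= pfp_max
  if (!is.null(fc_min)) {
    fc_min <- check_positive(fc_min, "fc_min")
    keep <- keep & if (direction == "up") tab$fc >= fc_min else
      tab$fc <= 1 / fc_min
  }
  tab <- tab[keep, ]
  tab <- tab[order(tab$rank), ]
  new_gene_list(tab, study = result$study_name, direction = direction,
                collapsed = FALSE, universe_size = result$universe_size)
}

# One direction's view of the rp_result table with generic column names.
direction_table <- function(result, direction) {
  t <- result$table
  if (direction == "up") {
    tibble(rank = t$rank_up, probe_id = t$probe_id, symbol = t$symbol,
           fc = t$fc, p = t$p_up, pfp = t$pfp_up)
  } else {
    tibble(rank = t$rank_down, probe_id = t$probe_id, symbol = t$symbol,
           fc = t$fc, p = t$p_down, pfp = t$pfp_down)
  }
}

#' Build a length-targeted ("extended") gene list
#'
#' Relaxes the strict p-value/fold-change cutoffs to reach a comparable list
#' length across studies, while still requiring `pfp < pfp_max`: returns the
#' top `target_length` probes by RP rank among those with `pfp < pfp_max`.
#' If fewer probes qualify, all of them are returned and the shortfall is
#' flagged (attribute `shortfall`, plus a warning).
#'
#' @param result An `rp_result`.
#' @param direction `"up"` or `"down"`.
#' @param target_length Desired list length (> 0).
#' @param pfp_max False-prediction cutoff retained while extending
#'   (default 0.05, strict `<`).
#'
#' @return A `gene_list` of at most `target_length` entries.
#' @export
size_targeted_list <- function(result, direction = c("up", "down"),
                               target_length, pfp_max = 0.05) {
  stopifnot(inherits(result, "rp_result"))
  direction <- match_direction(match.arg(direction))
  target_length <- check_count(target_length, "target_length")
  tab <- direction_table(result, direction)
  tab <- tab[tab$pfp < pfp_max, ]
  tab <- tab[order(tab$rank), ]
  shortfall <- nrow(tab) < target_length
  if (shortfall) {
    warn(sprintf(
      "only %d probes have pfp < %g; returning all of them (target %d)",
      nrow(tab), pfp_max, target_length))
  }
  tab <- head(tab, target_length)
  new_gene_list(tab, study = result$study_name, direction = direction,
                collapsed = FALSE, universe_size = result$universe_size,
                shortfall = shortfall)
}

#' Collapse a probeset-level list to unique gene symbols
#'
#' Several probesets can measure one gene; for cross-study comparison each
#' list is collapsed to one entry per official symbol. The probe with the
#' best (lowest) RP rank wins and contributes its statistics; output order
#' is by that rank. Probesets without a symbol (`NA` or empty) are dropped
#' and their count reported via a message.
#'
#' @param x A `gene_list` from [apply_cutoffs()] or [size_targeted_list()].
#' @param mapping Optional two-column data frame (`probe_id`, `symbol`)
#'   overriding the symbols carried in the list.
#'
#' @return A collapsed `gene_list` with unique symbols.
#' @export
collapse_to_symbols <- function(x, mapping = NULL) {
  stopifnot(inherits(x, "gene_list"))
  tab <- as_tibble(x)
  if (!is.null(mapping)) {
    mapping <- as_tibble(mapping)
    stopifnot(all(c("probe_id", "symbol") %in% names(mapping)))
    tab$symbol <- mapping$symbol[match(tab$probe_id, mapping$probe_id)]
  }
  tab$symbol <- normalize_symbols(tab$symbol)
  unmapped <- is.na(tab$symbol) | tab$symbol == "" | tab$symbol == "NA"
  if (any(unmapped)) {
    inform(sprintf("dropping %d un-named probeset(s) at collapse",
                   sum(unmapped)))
    tab <- tab[!unmapped, ]
  }
  tab <- tab[order(tab$rank), ]
  tab <- tab[!duplicated(tab$symbol), ]
  new_gene_list(tab, study = list_study(x), direction = list_direction(x),
                collapsed = TRUE, universe_size = attr(x, "universe_size"))
}

#' Make a study's up and down lists disjoint in symbols
#'
#' After collapsing, a symbol can in principle appear in both directions of
#' one study (different probesets). Directional meta-comparison requires
#' disjoint lists, so the symbol is retained only in the direction where it
#' has the better (lower) RP rank; removals are reported via a message.
#'
#' @param up,down Collapsed `gene_list`s of one study.
#' @return List with elements `up` and `down`, disjoint in symbols.
#' @export
disjoin_directions <- function(up, down) {
  stopifnot(is_collapsed(up), is_collapsed(down))
  both <- intersect(up$symbol, down$symbol)
  if (length(both) > 0) {
    inform(sprintf("%d symbol(s) in both directions; keeping the better rank",
                   length(both)))
    for (s in both) {
      r_up <- up$rank[up$symbol == s]
      r_down <- down$rank[down$symbol == s]
      if (r_up <= r_down) {
        down <- new_gene_list(down[down$symbol != s, ],
                              list_study(down), "down",
                              TRUE, attr(down, "universe_size"))
      } else {
        up <- new_gene_list(up[up$symbol != s, ], list_study(up), "up",
                            TRUE, attr(up, "universe_size"))
      }
    }
  }
  list(up = up, down = down)
}
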