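# Bundled reference tables from six published comparisons of CF
# (F508del-CFTR) vs control airway epithelial transcriptomes: the genes each
# study shares with the reference nasal-brushing study, the published list
# sizes, the 30-gene three-list airway signature, and the qPCR validation
# panel with primer efficiencies.

rpmeta_extdata <- function(file) {
  path <- system.file("extdata", file, package = "rpmeta")
  if (path == "") abort(sprintf("bundled data file not found: %s", file))
  path
}

#' Bundled cross-study reference tables
#'
#' Small plain-text tables shipped with the package, drawn from published
#' comparisons of CF (F508del-CFTR) vs control airway epithelium:
#' \describe{
#'   \item{`cf_shared_genes()`}{genes each of five independent studies
#'     shares, in the same direction, with the reference nasal study
#'     (columns `study`, `direction`, `symbol`).}
#'   \item{`cf_list_sizes()`}{published per-study gene-list sizes
#'     (`study`, `n_up`, `n_down`).}
#'   \item{`cf_signature()`}{the 30-gene (21 up / 9 down) native-airway CF
#'     signature shared by three directional lists.}
#'   \item{`cf_qpcr_panel()`}{the 12-gene qPCR validation panel with array
#'     and qPCR fold changes and primer efficiencies (percent).}
#' }
#'
#' @return A tibble.
#' @name cf_reference_tables
NULL

#' @rdname cf_reference_tables
#' @export
cf_shared_genes <- function() {
  readr::read_tsv(rpmeta_extdata("cf_shared_with_reference.tsv"),
                  show_col_types = FALSE)
}

#' @rdname cf_reference_tables
#' @export
cf_list_sizes <- function() {
  readr::read_tsv(rpmeta_extdata("cf_list_sizes.tsv"),
                  show_col_types = FALSE)
}

#' @rdname cf_reference_tables
#' @export
cf_signature <- function() {
  readr::read_tsv(rpmeta_extdata("cf_signature_genes.tsv"),
                  show_col_types = FALSE)
}

#' @rdname cf_reference_tables
#' @export
cf_qpcr_panel <- function() {
  readr::read_tsv(rpmeta_extdata("cf_qpcr_validation.tsv"),
                  show_col_types = FALSE)
}

#' Reconstruct the six-study list set from the published overlap tables
#'
#' Builds a [study_list_set()] in which every study's directional list has
#' its published size and contains exactly the genes it is recorded to share
#' with the reference study; the remaining positions are filled with
#' synthetic per-study placeholder symbols (`<STUDY>_UP_FILL_001`, ...) that
#' cannot collide across studies. Overlap percentages involving the
#' reference study are therefore exactly recomputable from published data,
#' while cells between two non-reference studies (and inverted overlaps,
#' whose gene identities were not published) are not reproduced.
#'
#' @param reference Name of the reference study (default `"clarke"`).
#'
#' @return A `study_list_set` of six studies.
#' @export
reference_study_set <- function(reference = "clarke") {
  shared <- cf_shared_genes()
  sizes <- cf_list_sizes()
  if (!reference %in% sizes$study) abort("unknown reference study")
  make_list <- function(study, direction, known) {
    n <- sizes[[if (direction == "up") "n_up" else "n_down"]][
      sizes$study == study]
    known <- unique(normalize_symbols(known))
    if (length(known) > n) abort("published overlap exceeds list size")
    fill <- sprintf("%s_%s_FILL_%03d", toupper(study), toupper(direction),
                    seq_len(n - length(known)))
    gene_list(c(known, fill), study = study, direction = direction)
  }
  studies <- list()
  for (s in setdiff(sizes$study, reference)) {
    studies[[s]] <- list(
      up = make_list(s, "up",
                     shared$symbol[shared$study == s & shared$direction == "up"]),
      down = make_list(s, "down",
                       shared$symbol[shared$study == s & shared$direction == "down"])
    )
  }
  # the reference list carries every gene recorded as shared with it
  studies[[reference]] <- list(
    up = make_list(reference, "up",
                   shared$symbol[shared$direction == "up"]),
    down = make_list(reference, "down",
                     shared$symbol[shared$direction == "down"])
  )
  study_list_set(studies[c(setdiff(sizes$study, reference), reference)])
}
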