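#' Construct an expression study
#'
#' Bundles a normalized log2 expression matrix (probes x samples) with its
#' group labels, probe annotation and optional detection calls. This is the
#' unit of input for [rp_analyze()] and downstream list building. Values are
#' expected to be normalized upstream (e.g. quantile/RMA); no normalization
#' is performed here.
#'
#' @param matrix Numeric matrix of log2 intensities, probes in rows, samples
#'   in columns. Column names are sample ids.
#' @param group Character/factor of per-sample labels, values `"case"` or
#'   `"control"`, one per column of `matrix`.
#' @param probe_ids Character vector of unique probe(set) identifiers, one per
#'   row. Defaults to `rownames(matrix)`.
#' @param symbols Character vector of gene symbols parallel to `probe_ids`;
#'   may repeat (several probesets per gene) and may contain `NA` for
#'   un-annotated probesets.
#' @param detection_call Optional character matrix of MAS5-style calls
#'   (`"P"`/`"M"`/`"A"`), same shape as `matrix`.
#' @param detection_p Optional numeric matrix of detection p-values, same
#'   shape as `matrix`.
#' @param study_name Single string naming the study.
#'
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(matrix, group, probe_ids = rownames(matrix),
                             symbols = NULL, detection_call = NULL,
                             detection_p = NULL, study_name = "study") {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    abort("`matrix` must be a numeric matrix (probes x samples)")
  }
  group <- as.character(group)
  if (length(group) != ncol(matrix)) {
    abort("`group` must have one label per sample (matrix column)")
  }
  if (!all(group %in% c("case", "control"))) {
    abort("group labels must be \"case\" or \"control\"")
  }
  if (sum(group == "case") < 1 || sum(group == "control") < 1) {
    abort("need at least one sample in each group")
  }
  if (is.null(probe_ids)) probe_ids <- paste0("probe_", seq_len(nrow(matrix)))
  probe_ids <- as.character(probe_ids)
  if (length(probe_ids) != nrow(matrix)) {
    abort("`probe_ids` must have one id per matrix row")
  }
  if (anyDuplicated(probe_ids)) {
    dup <- probe_ids[duplicated(probe_ids)][1]
    abort(sprintf("duplicated probe id: %s", dup))
  }
  if (!is.null(symbols) && length(symbols) != nrow(matrix)) {
    abort("`symbols` must be parallel to `probe_ids`")
  }
  for (nm in c("detection_call", "detection_p")) {
    d <- get(nm)
    if (!is.null(d) && !identical(dim(d), dim(matrix))) {
      abort(sprintf("`%s` must have the same dimensions as `matrix`", nm))
    }
  }
  if (is.null(colnames(matrix))) {
    colnames(matrix) <- paste0(ifelse(group == "case", "case_", "ctrl_"),
                               seq_along(group))
  }
  rownames(matrix) <- probe_ids
  for (nm in c("detection_call", "detection_p")) {
    if (!is.null(get(nm))) {
      d <- get(nm)
      dimnames(d) <- dimnames(matrix)
      assign(nm, d)
    }
  }
  structure(
    list(matrix = matrix, group = group, probe_ids = probe_ids,
         symbols = if (is.null(symbols)) NULL else as.character(symbols),
         detection_call = detection_call, detection_p = detection_p,
         study_name = as.character(study_name)),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf(
    "<expression_study> %s: %d probes x %d samples (%d case / %d control)\n",
    x$study_name, nrow(x$matrix), ncol(x$matrix),
    sum(x$group == "case"), sum(x$group == "control")))
  cat(sprintf("  detection calls: %s; detection p-values: %s\n",
              if (is.null(x$detection_call)) "absent" else "present",
              if (is.null(x$detection_p)) "absent" else "present"))
  invisible(x)
}

#' @describeIn expression_study Long-format view: one row per probe x sample
#'   with intensity and (if present) detection columns.
#' @param x An `expression_study`.
#' @param ... Unused.
#' @export
tidy.expression_study <- function(x, ...) {
  out <- tibble(
    probe_id = rep(x$probe_ids, times = ncol(x$matrix)),
    symbol = if (is.null(x$symbols)) NA_character_ else
      rep(x$symbols, times = ncol(x$matrix)),
    sample = rep(colnames(x$matrix), each = nrow(x$matrix)),
    group = rep(x$group, each = nrow(x$matrix)),
    log2_intensity = as.vector(x$matrix)
  )
  if (!is.null(x$detection_call)) out$detection_call <- as.vector(x$detection_call)
  if (!is.null(x$detection_p)) out$detection_p <- as.vector(x$detection_p)
  out
}
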