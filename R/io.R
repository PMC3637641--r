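#' Write / read an expression study as delimiter-separated text
#'
#' The matrix file has one header row of sample ids preceded by `probe_id`
#' and `symbol` columns; the groups file is two columns (`sample`, `group`).
#' Detection calls and detection p-values, when present, are written as
#' parallel matrices with the same layout.
#'
#' @param study An [expression_study()].
#' @param path Matrix file path (tab-separated).
#' @param groups_path Companion group-label file (default: `path` with a
#'   `.groups.tsv` suffix).
#' @param detection_path,detection_p_path Optional paths for the detection
#'   call / detection p-value matrices.
#'
#' @return `write_expression_matrix()` returns the paths invisibly;
#'   `read_expression_matrix()` returns an `expression_study`.
#' @export
write_expression_matrix <- function(study, path,
                                    groups_path = paste0(path, ".groups.tsv"),
                                    detection_path = NULL,
                                    detection_p_path = NULL) {
  stopifnot(inherits(study, "expression_study"))
  body <- tibble(probe_id = study$probe_ids,
                 symbol = study$symbols %||% NA_character_)
  mat_df <- cbind(body, as.data.frame(study$matrix))
  readr::write_tsv(mat_df, path)
  readr::write_tsv(tibble(sample = colnames(study$matrix),
                          group = study$group), groups_path)
  if (!is.null(detection_path) && !is.null(study$detection_call)) {
    readr::write_tsv(cbind(body, as.data.frame(study$detection_call)),
                     detection_path)
  }
  if (!is.null(detection_p_path) && !is.null(study$detection_p)) {
    readr::write_tsv(cbind(body, as.data.frame(study$detection_p)),
                     detection_p_path)
  }
  invisible(c(path, groups_path))
}

#' @rdname write_expression_matrix
#' @param study_name Name for the parsed study.
#' @export
read_expression_matrix <- function(path, groups_path = paste0(path, ".groups.tsv"),
                                   detection_path = NULL,
                                   detection_p_path = NULL,
                                   study_name = basename(path)) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (nrow(readr::problems(df)) > 0) {
    pr <- readr::problems(df)
    abort(sprintf("malformed matrix file %s: row %d (%s)", path,
                  pr$row[1], pr$expected[1]))
  }
  if (!all(c("probe_id", "symbol") %in% names(df)[1:2])) {
    abort("first two columns must be `probe_id` and `symbol`")
  }
  if (anyDuplicated(df$probe_id)) {
    abort(sprintf("duplicated probe id: %s",
                  df$probe_id[duplicated(df$probe_id)][1]))
  }
  sample_cols <- setdiff(names(df), c("probe_id", "symbol"))
  vals <- df[sample_cols]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    col <- sample_cols[bad][1]
    row <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
    abort(sprintf("non-numeric cell in column '%s', row %s", col,
                  row %||% "?"))
  }
  mat <- as.matrix(vals)
  rownames(mat) <- df$probe_id
  groups <- readr::read_tsv(groups_path, show_col_types = FALSE)
  if (!all(c("sample", "group") %in% names(groups))) {
    abort("groups file must have `sample` and `group` columns")
  }
  group <- groups$group[match(sample_cols, groups$sample)]
  if (anyNA(group)) {
    abort(sprintf("no group label for sample(s): %s",
                  paste(sample_cols[is.na(group)], collapse = ", ")))
  }
  read_parallel <- function(p) {
    if (is.null(p)) return(NULL)
    d <- readr::read_tsv(p, show_col_types = FALSE)
    m <- as.matrix(d[sample_cols])
    rownames(m) <- d$probe_id
    m[df$probe_id, , drop = FALSE]
  }
  expression_study(mat, group = group, probe_ids = df$probe_id,
                   symbols = df$symbol,
                   detection_call = read_parallel(detection_path),
                   detection_p = read_parallel(detection_p_path),
                   study_name = study_name)
}

#' Write / read a directional gene list
#'
#' Tab-separated with columns `study, direction, rank, probe_id, symbol,
#' fc, p, pfp`. Direction tokens are case-insensitive (`UP`/`up`).
#'
#' @param x A [gene_list()].
#' @param path File path.
#' @return `write_gene_list()` returns `path` invisibly; `read_gene_list()`
#'   returns a `gene_list`.
#' @export
write_gene_list <- function(x, path) {
  stopifnot(inherits(x, "gene_list"))
  out <- as_tibble(x)
  out$study <- list_study(x)
  out$direction <- list_direction(x)
  readr::write_tsv(out[, c("study", "direction", "rank", "probe_id",
                           "symbol", "fc", "p", "pfp")], path)
  invisible(path)
}

#' @rdname write_gene_list
#' @param collapsed Whether the stored list is collapsed to unique symbols
#'   (default: inferred from symbol uniqueness).
#' @export
read_gene_list <- function(path, collapsed = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("study", "direction", "rank", "symbol")
  if (!all(need %in% names(df))) {
    abort(paste("gene list file needs columns:", paste(need, collapse = ", ")))
  }
  dirs <- unique(tolower(df$direction))
  if (length(dirs) != 1 || !dirs %in% c("up", "down")) {
    abort(sprintf("unknown or mixed direction token: %s",
                  paste(unique(df$direction), collapse = ", ")))
  }
  df <- df[order(df$rank), ]
  collapsed <- collapsed %||% !anyDuplicated(normalize_symbols(df$symbol))
  new_gene_list(
    tibble(rank = df$rank,
           probe_id = if ("probe_id" %in% names(df))
             as.character(df$probe_id) else NA_character_,
           symbol = normalize_symbols(df$symbol),
           fc = if ("fc" %in% names(df)) df$fc else NA_real_,
           p = if ("p" %in% names(df)) df$p else NA_real_,
           pfp = if ("pfp" %in% names(df)) df$pfp else NA_real_),
    study = df$study[1], direction = dirs, collapsed = collapsed,
    universe_size = nrow(df))
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated, `term <tab> description
#' <tab> member1 <tab> member2 ...`.
#'
#' @param path GMT file path.
#' @param category Category label attached to every term (enrichment FDR is
#'   computed within category).
#'
#' @return Long tibble: `term_id`, `term_name`, `category`, `symbol`.
#' @export
read_gmt <- function(path, category = "gene_set") {
  lines <- readLines(path)
  lines <- lines[nzchar(stringr::str_trim(lines))]
  purrr::imap_dfr(lines, function(line, i) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort(sprintf("malformed GMT line %d: need term, description, >= 1 member",
                    i))
    }
    members <- unique(normalize_symbols(parts[-(1:2)]))
    members <- members[members != ""]
    if (length(members) == 0) abort(sprintf("empty member list at line %d", i))
    tibble(term_id = parts[1], term_name = parts[2], category = category,
           symbol = members)
  })
}

#' @rdname read_gmt
#' @param annotation Long-format annotation tibble (`term_id`, `term_name`,
#'   `symbol`).
#' @export
write_gmt <- function(annotation, path) {
  annotation <- as_tibble(annotation)
  lines <- annotation |>
    dplyr::group_by(.data$term_id, .data$term_name) |>
    dplyr::summarise(line = paste(c(.data$term_id[1], .data$term_name[1],
                                    .data$symbol), collapse = "\t"),
                     .groups = "drop")
  writeLines(lines$line, path)
  invisible(path)
}
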