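#' Cluster samples by centred correlation with average linkage
#'
#' QC dendrogram of the array samples: the distance between two samples is
#' `1 - r`, where `r` is the Pearson correlation of their (mean-centred)
#' expression vectors; agglomeration uses average linkage (UPGMA). With
#' well-separated groups the two main branches recover the case/control
#' phenotype split.
#'
#' @param study An [expression_study()] with >= 3 samples.
#'
#' @return An object of class `sample_dendrogram` wrapping the `hclust` tree
#'   (element `hclust`) and the per-sample group labels (`group`).
#' @seealso [dendrogram_newick()], [cut_dendrogram()]
#' @export
cluster_samples <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  if (ncol(study$matrix) < 3) abort("need >= 3 samples to cluster")
  sds <- apply(study$matrix, 2, stats::sd)
  if (any(sds == 0)) {
    abort(sprintf("constant expression vector for sample(s): %s",
                  paste(colnames(study$matrix)[sds == 0], collapse = ", ")))
  }
  cc <- cor(study$matrix)  # Pearson correlation mean-centres internally
  hc <- hclust(as.dist(1 - cc), method = "average")
  structure(list(hclust = hc, group = setNames(study$group,
                                               colnames(study$matrix)),
                 study_name = study$study_name),
            class = "sample_dendrogram")
}

#' @export
print.sample_dendrogram <- function(x, ...) {
  cat(sprintf("<sample_dendrogram> %s: %d samples, average linkage on 1 - r\n",
              x$study_name, length(x$group)))
  invisible(x)
}

#' Serialize a sample dendrogram as newick
#'
#' @param dend A [cluster_samples()] result.
#' @param file Optional path; if given the newick string is also written.
#' @return The newick string (invisibly if `file` is given).
#' @export
dendrogram_newick <- function(dend, file = NULL) {
  stopifnot(inherits(dend, "sample_dendrogram"))
  phy <- ape::as.phylo(dend$hclust)
  nwk <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(nwk, file)
    return(invisible(nwk))
  }
  nwk
}

#' Cut a sample dendrogram into k clusters
#'
#' @param dend A [cluster_samples()] result.
#' @param k Number of clusters.
#' @return Tibble with `sample`, `group` (true label) and `cluster`
#'   (assigned cluster id).
#' @export
cut_dendrogram <- function(dend, k = 2) {
  stopifnot(inherits(dend, "sample_dendrogram"))
  cl <- stats::cutree(dend$hclust, k = k)
  tibble(sample = names(cl), group = unname(dend$group[names(cl)]),
         cluster = unname(cl))
}
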