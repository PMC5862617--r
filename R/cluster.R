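#' Select loci for unsupervised clustering
#'
#' Keeps probes whose differential-methylation p-value is below the
#' threshold (default 0.01, the conventional choice for clustering on
#' relevant loci).
#'
#' @param records output of [probe_diffmeth()].
#' @param p_threshold p-value cutoff (strict: p < threshold).
#' @return Character vector of probe ids.
#' @export
select_clustering_loci <- function(records, p_threshold = 0.01) {
  sel <- records$probe_id[records$p_value < p_threshold]
  if (length(sel) == 0)
    stop("no loci pass p < ", p_threshold,
         "; consider relaxing the threshold")
  sel
}

#' Unsupervised hierarchical clustering of samples on selected loci
#'
#' Clusters the samples of a beta matrix (restricted to the supplied
#' loci) by agglomerative hierarchical clustering — Euclidean distance
#' and average linkage by default — and cuts the tree into `k` clusters.
#' When a priori labels are supplied, agreement is quantified by the
#' adjusted Rand index and by the misplaced-sample count (the minimum
#' number of discordant samples over the two cluster-to-label
#' assignments, for k = 2).
#'
#' @param m a [BetaMatrix].
#' @param loci optional character vector of probe ids to cluster on
#'   (default: all probes in `m`).
#' @param k number of clusters to cut (default 2).
#' @param labels optional vector of a priori group labels, named by
#'   sample id or aligned to the sample order.
#' @param dist_method distance measure passed to [stats::dist()].
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return Object of class `cluster_result`: list with `tree` (hclust),
#'   `cluster_labels` (named integer vector), `n_loci_used`, and
#'   `agreement` (list with `misplaced_count` and `adjusted_rand`, NULL
#'   without labels).
#' @export
hierarchical_cluster <- function(m, loci = NULL, k = 2, labels = NULL,
                                 dist_method = "euclidean",
                                 linkage = "average") {
  stopifnot(inherits(m, "BetaMatrix"))
  if (!is.null(loci)) {
    missing <- setdiff(loci, probe_ids(m))
    if (length(missing) > 0)
      stop("loci absent from matrix: ", paste(utils::head(missing, 5), collapse = ", "))
    m <- m[loci, ]
  }
  if (ncol(m$beta) < k) stop("fewer samples than clusters requested")
  if (nrow(m$beta) < 1) stop("no loci to cluster on")
  d <- stats::dist(t(m$beta), method = dist_method)
  tree <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(tree, k = k)

  agreement <- NULL
  if (!is.null(labels)) {
    lab <- if (!is.null(names(labels))) labels[sample_ids(m)] else labels
    if (length(lab) != ncol(m$beta) || any(is.na(lab)))
      stop("labels must cover every sample")
    lab <- as.integer(factor(lab))
    mis <- if (k == 2 && length(unique(lab)) == 2) {
      min(sum(cl != lab), sum(cl != (3L - lab)))
    } else NA_integer_
    agreement <- list(misplaced_count = mis,
                      adjusted_rand = mclust::adjustedRandIndex(cl, lab))
  }
  structure(list(tree = tree, cluster_labels = cl,
                 n_loci_used = nrow(m$beta), agreement = agreement),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("hierarchical clustering on %d loci, %d samples, %d clusters\n",
              x$n_loci_used, length(x$cluster_labels),
              length(unique(x$cluster_labels))))
  if (!is.null(x$agreement))
    cat(sprintf("  agreement: %d misplaced, adjusted Rand %.3f\n",
                x$agreement$misplaced_count, x$agreement$adjusted_rand))
  invisible(x)
}
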