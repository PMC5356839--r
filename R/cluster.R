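# Two-way unsupervised hierarchical clustering on Pearson-correlation
# distance (d = 1 - r). The agglomeration is written out explicitly rather
# than delegated to stats::hclust so that merge ties are broken
# lexicographically by member label, making trees exactly invariant to the
# input order of items.

# items in columns, features in rows; zero-variance items get r = 0
# (distance 1) against everything, which is logged via a warning.
correlation_distance <- function(mat) {
  sds <- apply(mat, 2, stats::sd)
  flat <- sds == 0
  if (any(flat)) {
    warning("zero-variance item(s) assigned distance 1 to all others: ",
            paste(colnames(mat)[flat], collapse = ", "), call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(mat))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  1 - r
}

# deterministic agglomeration on a distance matrix; returns an hclust object
agglomerate <- function(d, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  labels <- colnames(d)
  ord <- order(labels)
  d <- d[ord, ord, drop = FALSE]
  labels <- labels[ord]
  n <- length(labels)
  if (n < 2) stop("need at least 2 items to cluster", call. = FALSE)
  active <- seq_len(n)
  size <- rep(1L, n)
  id <- -seq_len(n)           # hclust coding: negatives = singletons
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  D <- d
  diag(D) <- Inf
  for (step in seq_len(n - 1L)) {
    sub <- D[active, active, drop = FALSE]
    best <- min(sub)
    hits <- which(sub == best, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    # ties: smallest (first, second) position = lexicographically smallest
    # member labels, since items are sorted by label
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- active[hits[1, 1]]; j <- active[hits[1, 2]]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- best
    # Lance-Williams update into slot i (the lower index, i.e. the
    # lexicographically smallest member of the merged cluster)
    others <- setdiff(active, c(i, j))
    new_d <- switch(linkage,
      average = (size[i] * D[i, others] + size[j] * D[j, others]) /
        (size[i] + size[j]),
      complete = pmax(D[i, others], D[j, others]),
      single = pmin(D[i, others], D[j, others]))
    D[i, others] <- new_d
    D[others, i] <- new_d
    size[i] <- size[i] + size[j]
    id[i] <- step
    active <- setdiff(active, j)
  }
  tree <- list(merge = merge, height = height,
               order = leaf_order(merge), labels = labels,
               method = linkage, dist.method = "1 - pearson",
               call = match.call())
  class(tree) <- "hclust"
  tree
}

# leaf order for plotting/heatmaps: standard recursive unfolding
leaf_order <- function(merge) {
  unfold <- function(k) {
    if (k < 0) return(-k)
    c(unfold(merge[k, 1]), unfold(merge[k, 2]))
  }
  unfold(nrow(merge))
}

# endogenous expression with per-gene centering, as clustered
cluster_input <- function(m, center = c("mean", "none", "median")) {
  center <- match.arg(center)
  expr <- class_counts(m, "Endogenous")
  mid <- switch(center, none = 0, mean = rowMeans(expr),
                median = apply(expr, 1, stats::median))
  expr - mid
}

#' Hierarchical clustering of samples or genes on correlation distance
#'
#' Agglomerative clustering under `d = 1 - r_Pearson`, average linkage by
#' default, computed on per-gene centered normalized counts. Merge ties are
#' broken by lexicographic member label, so the tree does not depend on the
#' input order of samples or genes.
#'
#' @param m a [count_matrix] at stage `"bio_normalized"`.
#' @param axis cluster the samples (default) or the genes.
#' @param linkage agglomeration rule.
#' @param center per-gene centering applied before correlating.
#' @return an object of class `hclust` (usable with [stats::cutree],
#'   [ape::as.phylo], etc.).
#' @export
hca <- function(m, axis = c("samples", "genes"),
                linkage = c("average", "complete", "single"),
                center = c("mean", "none", "median")) {
  require_stage(m, "bio_normalized")
  axis <- match.arg(axis)
  x <- cluster_input(m, center)
  mat <- if (axis == "samples") x else t(x)
  if (ncol(mat) < 2) stop("need at least 2 ", axis, call. = FALSE)
  agglomerate(correlation_distance(mat), linkage = match.arg(linkage))
}

#' Two-cluster cut of the sample tree
#'
#' Cuts the sample dendrogram into two clusters and summarizes each by the
#' mean pairwise Pearson correlation of its members, plus a cluster-by-label
#' cross-tabulation.
#'
#' @inheritParams hca
#' @param tree optional precomputed sample tree from [hca]; built if absent.
#' @return list with `assignments` (named cluster label 1/2 per sample),
#'   `within_cluster_correlation` (mean pairwise r per cluster; 1 for
#'   singletons), `crosstab` (cluster x label), and `cut_height`.
#' @export
cut_two <- function(m, tree = NULL, linkage = "average", center = "mean") {
  require_stage(m, "bio_normalized")
  if (ncol(m$counts) < 2) stop("need at least 2 samples", call. = FALSE)
  if (is.null(tree)) tree <- hca(m, "samples", linkage, center)
  k2 <- stats::cutree(tree, k = 2)
  x <- cluster_input(m, center)
  r <- suppressWarnings(stats::cor(x))
  r[!is.finite(r)] <- 0
  wcc <- vapply(1:2, function(k) {
    ids <- names(k2)[k2 == k]
    if (length(ids) < 2) return(1)
    sub <- r[ids, ids]
    mean(sub[upper.tri(sub)])
  }, 0)
  labels <- m$samples$label[match(names(k2), m$samples$sample_id)]
  list(assignments = k2,
       within_cluster_correlation = wcc,
       crosstab = table(cluster = k2, label = labels),
       cut_height = tree$height[length(tree$height) - 1L])
}

#' Export a dendrogram in Newick format
#'
#' @param tree an `hclust` object from [hca].
#' @param path optional output file; if `NULL` the Newick string is
#'   returned.
#' @return the Newick string, invisibly when written to `path`.
#' @export
tree_to_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
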