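#' Euclidean median-linkage (WPGMC) hierarchical clustering
#'
#' Agglomerative clustering used to explore per-droplet composition
#' heterogeneity. Works on squared Euclidean distances with the median
#' (weighted centroid) Lance-Williams update
#' \deqn{d^2(k, i \cup j) = \tfrac12 d^2(k,i) + \tfrac12 d^2(k,j) - \tfrac14 d^2(i,j)}
#' so that each merged cluster is represented by the midpoint of its two
#' parents. Merge heights are reported as the square root of the merged
#' squared distance. Ties are broken by the lowest pair index (clusters
#' numbered leaves first, then merges in creation order). Median linkage
#' can produce inversions (non-monotone heights); the tree remains
#' well-formed and no monotonicity is assumed anywhere.
#'
#' @param points samples x d numeric matrix of per-sample compositions (or
#'   any feature vectors).
#' @param labels leaf labels (default rownames or indices).
#' @return object of class `"linkage_tree"`: `merge` (hclust-style matrix:
#'   negative entries are leaves, positive entries earlier merges),
#'   `height`, `labels`, `n`.
#' @export
hca_median <- function(points, labels = NULL) {
  p <- as.matrix(points)
  if (ncol(p) < 1L) stop("points need at least one dimension", call. = FALSE)
  n <- nrow(p)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  if (is.null(labels))
    labels <- if (!is.null(rownames(p))) rownames(p) else as.character(seq_len(n))
  d2 <- as.matrix(stats::dist(p))^2
  # cluster book-keeping: ids 1..n are leaves, n+m is merge m
  active <- seq_len(n)                    # current cluster ids, creation order
  code <- -seq_len(n)                     # hclust merge codes for each active
  rowof <- seq_len(n)                     # row in d2 for each active cluster
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (m in seq_len(n - 1L)) {
    na <- length(active)
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(na - 1L)) for (j in (i + 1L):na) {
      v <- d2[rowof[i], rowof[j]]
      if (v < best) { best <- v; bi <- i; bj <- j }
    }
    merge[m, ] <- c(code[bi], code[bj])
    height[m] <- sqrt(max(best, 0))
    # Lance-Williams median update, written into row bi
    ri <- rowof[bi]; rj <- rowof[bj]
    others <- rowof[-c(bi, bj)]
    newd <- 0.5 * d2[ri, others] + 0.5 * d2[rj, others] - 0.25 * best
    d2[ri, others] <- newd; d2[others, ri] <- newd
    code[bi] <- m
    active[bi] <- n + m
    code <- code[-bj]; active <- active[-bj]; rowof <- rowof[-bj]
  }
  structure(list(merge = merge, height = height, labels = labels, n = n),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("<linkage_tree: %d leaves, %d merges, heights %.3g-%.3g>\n",
              x$n, length(x$height), min(x$height), max(x$height)))
  invisible(x)
}

#' Convert to a base-R hclust object
#'
#' @param x a `"linkage_tree"`.
#' @param ... unused.
#' @return an object of class `"hclust"` (usable with [stats::cutree()] and
#'   `plot()`; note median-linkage heights may be non-monotone).
#' @export
as.hclust.linkage_tree <- function(x, ...) {
  ord <- integer(0)
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(x$merge[node, 1L]), expand(x$merge[node, 2L]))
  }
  ord <- expand(nrow(x$merge))
  structure(list(merge = x$merge, height = x$height, order = ord,
                 labels = x$labels, method = "median",
                 dist.method = "euclidean"),
            class = "hclust")
}

#' Cut a linkage tree into k clusters
#'
#' Undoes the last `k - 1` merges in agglomeration order, which for
#' monotone trees coincides with cutting the `k - 1` highest merges, and for
#' non-monotone (inverted) median-linkage trees still yields exactly `k`
#' clusters.
#'
#' @param tree a `"linkage_tree"`.
#' @param k number of clusters, `1 <= k <= n` leaves.
#' @return integer cluster memberships (1..k, numbered by first appearance),
#'   named by leaf label.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "linkage_tree"))
  n <- tree$n
  if (k < 1 || k > n) stop("k must be between 1 and the number of leaves", call. = FALSE)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i] <- parent[parent[i]]; i }
  leaves_of <- vector("list", n - 1L)
  keep <- seq_len(max(0L, n - k))
  for (m in seq_len(n - 1L))
    leaves_of[[m]] <- c(
      if (tree$merge[m, 1L] < 0) -tree$merge[m, 1L] else leaves_of[[tree$merge[m, 1L]]],
      if (tree$merge[m, 2L] < 0) -tree$merge[m, 2L] else leaves_of[[tree$merge[m, 2L]]])
  for (m in keep) {
    l <- leaves_of[[m]]
    r <- find(l[1L])
    for (q in l[-1L]) parent[find(q)] <- r
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  cl <- match(roots, unique(roots))
  names(cl) <- tree$labels
  cl
}

#' Export a linkage tree as a merge-matrix CSV
#'
#' Standard R-style representation: one row per merge with the two merged
#' node codes (negative = leaf) and the merge height.
#'
#' @param tree a `"linkage_tree"`.
#' @param path file path.
#' @export
save_linkage <- function(tree, path) {
  df <- data.frame(node_a = tree$merge[, 1L], node_b = tree$merge[, 2L],
                   height = format(tree$height, digits = 15, trim = TRUE),
                   size = vapply(seq_len(nrow(tree$merge)), function(m) {
                     count <- function(node)
                       if (node < 0) 1L else count(tree$merge[node, 1L]) +
                         count(tree$merge[node, 2L])
                     count(m)
                   }, integer(1L)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
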