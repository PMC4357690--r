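# DBSCAN over genomic intervals.
#
# Arms are clustered on the 2-D point (product start, product end) with the
# Chebyshev metric: two arms are neighbours iff both endpoints differ by at
# most eps. With min_pts = 1 every point is a core point, so no noise exists
# and clusters are the connected components of the eps-neighbourhood graph.

#' DBSCAN cluster labels
#'
#' Standard DBSCAN semantics: points with at least \code{min_pts} neighbours
#' (within \code{eps}, the point itself included) are core points; clusters
#' are maximal sets of density-reachable points; non-core points unreachable
#' from any core point are noise (label 0). Seeds are processed in
#' lexicographic point order, so labels are independent of input order.
#'
#' @param points numeric matrix (n x d); distances are Chebyshev
#'   (coordinate-wise maximum).
#' @param eps neighbourhood radius (closed ball).
#' @param min_pts minimum neighbourhood size for a core point.
#' @return integer vector of labels (0 = noise, clusters numbered from 1 in
#'   seed order).
#' @examples
#' dbscan_labels(cbind(c(0, 10, 1000)), eps = 50, min_pts = 1)
#' @export
dbscan_labels <- function(points, eps, min_pts = 1L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (!n) return(integer(0))
  stopifnot(eps > 0, min_pts >= 1)
  ord <- do.call(order, c(lapply(seq_len(ncol(points)), function(j) points[, j]),
                          list(seq_len(n))))
  # neighbourhood query; x-sorted prefilter keeps it near-linear for arms
  x <- points[, 1]
  ox <- order(x)
  xs <- x[ox]
  neighbours <- function(i) {
    lo <- findInterval(x[i] - eps, xs, left.open = TRUE) + 1L
    hi <- findInterval(x[i] + eps, xs)
    if (hi < lo) return(integer(0))
    cand <- ox[lo:hi]
    if (ncol(points) > 1) {
      for (j in 2:ncol(points)) {
        cand <- cand[abs(points[cand, j] - points[i, j]) <= eps]
      }
    }
    cand
  }
  labels <- rep(NA_integer_, n)   # NA = unvisited, 0 = noise
  cl <- 0L
  for (i in ord) {
    if (!is.na(labels[i])) next
    nb <- neighbours(i)
    if (length(nb) < min_pts) { labels[i] <- 0L; next }
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      if (!is.na(labels[q]) && labels[q] != 0L) next
      labels[q] <- cl
      nbq <- neighbours(q)
      if (length(nbq) >= min_pts) {            # q is core: expand
        new <- nbq[is.na(labels[nbq]) | labels[nbq] == 0L]
        queue <- c(queue, setdiff(new, queue))
      }
    }
  }
  labels
}

#' Cluster homology arms by genomic position
#'
#' DBSCAN on (product start, product end) with the Chebyshev metric, so two
#' arms cluster together (at \code{min_pts = 1}) when a chain of arms each
#' differing by at most \code{eps} at both ends connects them. Cluster ids
#' are relabelled deterministically by representative extent (min start, max
#' end), then first arm id.
#'
#' @param arms an arm data frame (\code{start}, \code{end} columns).
#' @param role role label recorded on the result (\code{"span"},
#'   \code{"left"}, \code{"right"}, ...).
#' @param eps neighbourhood radius (nt).
#' @param min_pts DBSCAN core threshold; the default 1 discards no arm.
#' @return the arm data frame with a \code{cluster} column, ordered by
#'   cluster then interval; cluster extents in
#'   \code{attr(, "clusters")}.
#' @export
cluster_arms <- function(arms, role = "span", eps = 50, min_pts = 1L) {
  if (!nrow(arms)) {
    out <- arms
    out$cluster <- integer(0)
    attr(out, "clusters") <- data.frame(cluster = integer(), role = character(),
                                        start = integer(), end = integer(),
                                        n = integer())
    return(out)
  }
  lab <- dbscan_labels(cbind(arms$start, arms$end), eps, min_pts)
  # deterministic relabel by extent, noise (0) kept as singleton clusters
  if (any(lab == 0L)) lab[lab == 0L] <- max(lab) + seq_len(sum(lab == 0L))
  ext <- data.frame(cluster = sort(unique(lab)))
  ext$start <- vapply(ext$cluster, function(cl) min(arms$start[lab == cl]), 0)
  ext$end <- vapply(ext$cluster, function(cl) max(arms$end[lab == cl]), 0)
  ord <- order(ext$start, ext$end, ext$cluster)
  relabel <- integer(max(ext$cluster))
  relabel[ext$cluster[ord]] <- seq_along(ord)
  arms$cluster <- relabel[lab]
  out <- arms[order(arms$cluster, arms$start, arms$end), , drop = FALSE]
  rownames(out) <- NULL
  cls <- ext[ord, ]
  cls$cluster <- seq_along(ord)
  cls$role <- role
  cls$n <- as.integer(table(factor(arms$cluster, levels = cls$cluster)))
  attr(out, "clusters") <- cls[, c("cluster", "role", "start", "end", "n")]
  out
}
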