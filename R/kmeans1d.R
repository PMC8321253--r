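## Scalar k-means engine used by the iterative segmentation.  Clustering is
## performed on element values only (spatial structure enters through masks),
## with k-means++ seeding, Lloyd refinement, and multiple restarts from which
## the smallest within-cluster sum of squares is kept.

# k-means++ seeding: first centre uniform, subsequent centres sampled with
# probability proportional to the squared distance to the nearest centre.
kmeanspp_init <- function(x, k) {
  n <- length(x)
  centers <- numeric(k)
  centers[1L] <- x[sample.int(n, 1L)]
  d2 <- (x - centers[1L])^2
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      ## fewer distinct remaining values than centres; duplicates are later
      ## resolved by the empty-cluster policy
      centers[j:k] <- centers[1L]
      break
    }
    centers[j] <- x[sample.int(n, 1L, prob = d2)]
    d2 <- pmin(d2, (x - centers[j])^2)
  }
  centers
}

# Lloyd's algorithm on scalar data.  Empty clusters are re-seeded at the
# point currently farthest from its assigned centre, so every label stays
# occupied (required by the cluster-to-tissue mapping).
lloyd_1d <- function(x, centers, max_iter = 200L) {
  k <- length(centers)
  labels <- integer(length(x))
  for (it in seq_len(max_iter)) {
    D <- abs(outer(x, centers, "-"))
    new_labels <- max.col(-D, ties.method = "first")
    sizes <- tabulate(new_labels, k)
    while (any(sizes == 0L)) {
      resid <- D[cbind(seq_along(x), new_labels)]
      far <- which.max(resid)
      j <- which(sizes == 0L)[1L]
      centers[j] <- x[far]
      sizes[new_labels[far]] <- sizes[new_labels[far]] - 1L
      new_labels[far] <- j
      sizes[j] <- 1L
      D[, j] <- abs(x - centers[j])
    }
    centers <- as.vector(rowsum(x, new_labels)) / sizes
    if (identical(new_labels, labels)) break
    labels <- new_labels
  }
  list(labels = labels,
       centers = centers,
       objective = sum((x - centers[labels])^2),
       iterations = it)
}

#' Cluster a prepared field once at a fixed number of clusters
#'
#' Runs Lloyd's k-means on the scalar element values of a prepared field,
#' with k-means++ initialization, `restarts` independent runs from
#' deterministic sub-seeds, keeping the run with the smallest within-cluster
#' sum of squares.  Labels are renumbered so that centroids ascend: label 1
#' is the lowest-valued cluster (the sentinel background), label `k` the
#' highest-valued one.  Ties between identical centroids keep their
#' first-occurrence order.
#'
#' @param field a [prepare_field] result (or any numeric matrix).
#' @param k number of clusters (>= 3).
#' @param restarts number of independent k-means++/Lloyd runs (>= 1).
#' @param seed master seed; sub-seeds for the restarts are drawn from it.
#' @return an object of class `"cluster_labeling"`: list with `labels`
#'   (integer matrix, values 1..k), `centroids` (ascending), `k`,
#'   `objective`, and `restart_objectives` (per-restart objectives, in run
#'   order).
#' @export
cluster_once <- function(field, k, restarts = 10L, seed = 1L) {
  vals <- if (inherits(field, "prepared_field")) field$values else field
  if (!is.matrix(vals) || !is.numeric(vals))
    stop("'field' must be a prepared_field or numeric matrix", call. = FALSE)
  if (k < 3L) stop("'k' must be at least 3", call. = FALSE)
  if (restarts < 1L) stop("'restarts' must be at least 1", call. = FALSE)
  x <- as.vector(vals)
  if (length(unique(x)) < k)
    stop("unclusterable: k = ", k, " exceeds the number of distinct values (",
         length(unique(x)), ")", call. = FALSE)
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max, restarts)
  best <- NULL
  objs <- numeric(restarts)
  for (r in seq_len(restarts)) {
    set.seed(subseeds[r])
    fit <- lloyd_1d(x, kmeanspp_init(x, k))
    objs[r] <- fit$objective
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  ## relabel so centroids ascend (stable under ties)
  ord <- order(best$centers)
  relab <- match(seq_len(k), ord)
  labels <- matrix(relab[best$labels], nrow(vals), ncol(vals))
  structure(list(labels = labels,
                 centroids = best$centers[ord],
                 k = k,
                 objective = best$objective,
                 restart_objectives = objs),
            class = "cluster_labeling")
}

#' @export
print.cluster_labeling <- function(x, ...) {
  cat(sprintf("k-means labeling: k = %d, objective = %.6g\n", x$k,
              x$objective))
  cat("  centroids:", paste(format(x$centroids, digits = 4), collapse = ", "),
      "\n")
  invisible(x)
}
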