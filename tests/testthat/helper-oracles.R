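# Independent brute-force oracles used to check the package's operations.

# two-sample KS statistic as the sup of |ECDF_a - ECDF_b| evaluated by
# direct counting over the pooled support
ks_stat_bruteforce <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  max(abs(vapply(xs, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}

# exact 1-D k-means objective by exhaustive enumeration of contiguous
# partitions of the sorted values (optimal 1-D clusters are contiguous)
kmeans1d_exact_objective <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  wcss_seg <- function(seg) sum((seg - mean(seg))^2)
  best <- Inf
  cuts <- utils::combn(n - 1L, k - 1L)
  for (j in seq_len(ncol(cuts))) {
    bounds <- c(0L, cuts[, j], n)
    obj <- sum(vapply(seq_len(k), function(i)
      wcss_seg(x[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1)))
    if (obj < best) best <- obj
  }
  best
}

# erosion by a disk of radius r pixels (pixel centres within the radius),
# checked pixel by pixel
erode_bruteforce <- function(mask, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- expand.grid(dr = -ceiling(r):ceiling(r), dc = -ceiling(r):ceiling(r))
  offs <- offs[offs$dr^2 + offs$dc^2 <= r^2, ]
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    rr <- i + offs$dr; cc <- j + offs$dc
    inside <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    out[i, j] <- all(inside) && all(mask[cbind(rr, cc)])
  }
  out
}

# direct masked, normalized Gaussian convolution (quadratic loop; use on
# small grids only)
blur_bruteforce <- function(v, support, sigma_px) {
  rad <- max(1L, ceiling(3.5 * sigma_px))
  ax <- (-rad):rad
  K <- outer(exp(-ax^2 / (2 * sigma_px^2)), exp(-ax^2 / (2 * sigma_px^2)))
  K <- K / sum(K)
  nr <- nrow(v); nc <- ncol(v)
  out <- v
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!support[i, j]) next
    num <- 0; den <- 0
    for (a in seq_along(ax)) for (b in seq_along(ax)) {
      ii <- i + ax[a]; jj <- j + ax[b]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && support[ii, jj]) {
        num <- num + K[a, b] * v[ii, jj]
        den <- den + K[a, b]
      }
    }
    out[i, j] <- num / den
  }
  out
}

# circular mask helper (centre in pixel units, radius in pixels)
disk_mask <- function(nr, nc, r_px, ctr = c((nr + 1) / 2, (nc + 1) / 2)) {
  (row(matrix(0, nr, nc)) - ctr[1])^2 +
    (col(matrix(0, nr, nc)) - ctr[2])^2 <= r_px^2
}

# prepared field with three constant plateaus inside a rectangular ROI
plateau_field <- function(values = c(5, 20, 60), reps = c(400, 400, 200)) {
  v <- rep(values, reps)
  m <- matrix(v, nrow = 20)
  roi <- matrix(TRUE, nrow(m), ncol(m))
  full <- matrix(-100, nrow(m) + 2, ncol(m) + 2)
  full[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  roi_full <- matrix(FALSE, nrow(full), ncol(full))
  roi_full[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- TRUE
  prepare_field(full, roi_full, sentinel = -100)
}
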