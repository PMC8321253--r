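## Region-of-interest construction: the imaging-domain boundary is contracted
## uniformly inward (e.g. by 3.5 mm) so that spurious artefacts on the
## periphery of the reconstruction are excluded from the tissue analysis.

## ---- low-level mask utilities ----

# 8-connected component labelling by flood fill.  Masks here are a few
# thousand pixels, so a plain R queue is adequate.
label_components <- function(mask) {
  mask <- as_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nlab <- 0L
  offs <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  idx <- which(mask)
  for (p in idx) {
    if (lab[p] != 0L) next
    nlab <- nlab + 1L
    queue <- p
    lab[p] <- nlab
    while (length(queue)) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((q - 1L) %% nr) + 1L
      c <- ((q - 1L) %/% nr) + 1L
      nb_r <- r + offs[, "dr"]
      nb_c <- c + offs[, "dc"]
      ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
      nb <- (nb_c[ok] - 1L) * nr + nb_r[ok]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- nlab
        queue <- c(queue, nb)
      }
    }
  }
  lab
}

# Ordered boundary pixels (row, col) of a connected mask, traced clockwise
# with Moore-neighbour tracing; the trace starts at the topmost-leftmost
# foreground pixel and stops on first return to it.  A single-pixel mask
# returns that pixel.
trace_boundary <- function(mask) {
  mask <- as_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- function(q) q[1L] >= 1L && q[1L] <= nr && q[2L] >= 1L &&
    q[2L] <= nc && mask[q[1L], q[2L]]
  rows <- row(mask)[mask]; cols <- col(mask)[mask]
  ord <- order(rows, cols)
  s <- c(rows[ord[1L]], cols[ord[1L]])
  if (length(rows) == 1L)
    return(matrix(s, ncol = 2L, dimnames = list(NULL, c("row", "col"))))
  ## clockwise neighbourhood starting west: W NW N NE E SE S SW (dr, dc)
  nb <- cbind(c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
              c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L))
  path <- vector("list", 4L * length(rows))
  npts <- 1L
  path[[1L]] <- s
  p <- s
  b_idx <- 1L  # ring index of the backtrack (background) neighbour of p
  repeat {
    found <- FALSE
    last_bg <- b_idx
    for (j in 1:8) {
      d <- ((b_idx - 1L + j) %% 8L) + 1L
      q <- p + nb[d, ]
      if (fg(q)) { found <- TRUE; break }
      last_bg <- d
    }
    if (!found) break                    # isolated pixel; cannot occur here
    if (all(q == s)) break               # closed the contour
    npts <- npts + 1L
    if (npts > length(path)) break       # safety cap for degenerate masks
    path[[npts]] <- q
    ## backtrack for the next step: last background cell examined, as seen
    ## from q (consecutive ring positions are always mutually adjacent)
    rel <- p + nb[last_bg, ] - q
    b_idx <- which(nb[, 1L] == rel[1L] & nb[, 2L] == rel[2L])
    p <- q
  }
  pts <- do.call(rbind, path[seq_len(npts)])
  colnames(pts) <- c("row", "col")
  unique_consecutive(pts)
}

unique_consecutive <- function(pts) {
  if (nrow(pts) < 2L) return(pts)
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
  pts[keep, , drop = FALSE]
}

# pixel (row, col) centres -> physical mm coordinates
px_to_mm <- function(pts, spacing_mm) {
  data.frame(x_mm = (pts[, "col"] - 1) * spacing_mm,
             y_mm = (pts[, "row"] - 1) * spacing_mm)
}

## ---- exported operations ----

#' Trace the boundary of the imaging domain
#'
#' Produces the ordered closed contour of the outer boundary of a connected
#' image support, in physical millimetre coordinates
#' (`x = (col-1) * spacing`, `y = (row-1) * spacing`).
#'
#' @param support binary matrix marking the imaging-domain support.
#' @param spacing_mm pixel spacing in millimetres.
#' @return data frame with columns `x_mm`, `y_mm`; attribute `closed = TRUE`.
#' @export
domain_boundary <- function(support, spacing_mm = 1) {
  stop_if_not_mask(support, "support")
  check_positive_scalar(spacing_mm, "spacing_mm")
  support <- as_mask(support)
  if (!any(support)) stop("imaging-domain support is empty", call. = FALSE)
  lab <- label_components(support)
  if (max(lab) > 1L)
    stop("imaging-domain support is disconnected (", max(lab),
         " components); expected a single connected region", call. = FALSE)
  pts <- trace_boundary(support)
  out <- px_to_mm(pts, spacing_mm)
  attr(out, "closed") <- TRUE
  out
}

#' Contract a region mask uniformly inward
#'
#' Erodes a binary mask by a disk structuring element whose radius is
#' `round(distance_mm / spacing_mm)` pixels (pixel centres within the
#' radius), implemented through the Euclidean distance transform.  Used to
#' pull the region of interest away from the imaging-domain boundary so that
#' peripheral reconstruction artefacts are excluded.
#'
#' @param mask binary matrix (the imaging-domain mask).
#' @param distance_mm contraction distance in millimetres (>= 0).
#' @param spacing_mm pixel spacing in millimetres.
#' @return logical matrix, a subset of `mask`.
#' @export
contract_roi <- function(mask, distance_mm, spacing_mm = 1) {
  stop_if_not_mask(mask)
  check_positive_scalar(spacing_mm, "spacing_mm")
  if (!is.numeric(distance_mm) || length(distance_mm) != 1L || distance_mm < 0)
    stop("'distance_mm' must be a nonnegative scalar", call. = FALSE)
  mask <- as_mask(mask)
  r_px <- round(distance_mm / spacing_mm)
  if (r_px == 0) return(mask)
  ## pad with a background ring so the image border counts as background
  padded <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  padded[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  d <- EBImage::distmap(padded)
  eroded <- d[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] > r_px
  if (!any(eroded))
    stop("ROI vanished: contraction by ", distance_mm,
         " mm removed the entire mask", call. = FALSE)
  eroded
}

#' Prepare a component image for clustering
#'
#' Copies the component image inside the region of interest and assigns a
#' sentinel value (default -100) to every element outside it, so that the
#' background always forms the lowest-valued cluster.  The sentinel must lie
#' strictly below the minimum value inside the ROI; this is validated rather
#' than assumed, since sign conventions for the imaginary component could
#' otherwise break the guarantee.
#'
#' @param values numeric matrix, one scalar component image.
#' @param roi_mask binary matrix, the region of interest.
#' @param sentinel background fill value.
#' @param spacing_mm pixel spacing in millimetres (carried for plotting and
#'   metric computations downstream).
#' @return an object of class `"prepared_field"`: list with `values` (the
#'   sentinel-filled matrix), `roi_mask`, `sentinel`, `spacing_mm`.
#' @export
prepare_field <- function(values, roi_mask, sentinel = -100, spacing_mm = 1) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  stop_if_not_mask(roi_mask, "roi_mask")
  check_same_shape(values, roi_mask, "'values' and 'roi_mask'")
  roi_mask <- as_mask(roi_mask)
  if (!any(roi_mask)) stop("ROI mask is empty", call. = FALSE)
  interior_min <- min(values[roi_mask])
  if (sentinel >= interior_min)
    stop(sprintf(paste0("sentinel (%g) must be strictly below the minimum ",
                        "value inside the ROI (%g); choose a lower sentinel"),
                 sentinel, interior_min), call. = FALSE)
  out <- values
  out[!roi_mask] <- sentinel
  structure(list(values = out, roi_mask = roi_mask, sentinel = sentinel,
                 spacing_mm = spacing_mm),
            class = "prepared_field")
}

#' @export
print.prepared_field <- function(x, ...) {
  cat(sprintf(paste0("Prepared clustering field: %d x %d, %d ROI pixels,",
                     " sentinel %g\n"),
              nrow(x$values), ncol(x$values), sum(x$roi_mask), x$sentinel))
  invisible(x)
}
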