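## Region- and distance-based segmentation quality metrics.  Region metrics
## compare binary masks (or masked dielectric values) from a reference and a
## reconstructed segmentation; the average Hausdorff distance compares the
## shapes of centroid-aligned interface contours.

#' Mask fidelity (normalized cross-correlation of binary masks)
#'
#' The dot product of the vectorized masks divided by the product of their
#' Euclidean norms.  1 means perfect agreement, 0 no overlap; structural
#' distortion and artefacts both lower it.
#'
#' @param ref,rec binary matrices of the same shape, each nonempty.
#' @return a number in \[0, 1\].
#' @export
mask_fidelity <- function(ref, rec) {
  stop_if_not_mask(ref, "ref"); stop_if_not_mask(rec, "rec")
  check_same_shape(ref, rec, "masks")
  a <- as.numeric(as_mask(ref)); b <- as.numeric(as_mask(rec))
  if (sum(a) == 0 || sum(b) == 0)
    stop("fidelity is undefined for an empty mask", call. = FALSE)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Dielectric cross-correlation of masked tissue values
#'
#' The mask-fidelity correlation applied to masked property values instead
#' of binary masks: values are zero outside each mask.  Sensitive to both
#' geometric distortion and errors in the reconstructed dielectric values;
#' invariant under positive scaling of either input.
#'
#' @param ref_values,rec_values numeric matrices of masked values (zero
#'   outside the respective masks), same shape, nonzero norms.
#' @return a number in \[-1, 1\] (\[0, 1\] for nonnegative values).
#' @export
xcorr_diel <- function(ref_values, rec_values) {
  check_same_shape(ref_values, rec_values, "value images")
  na2 <- sum(ref_values^2); nb2 <- sum(rec_values^2)
  if (na2 == 0 || nb2 == 0)
    stop("dielectric cross-correlation is undefined for a zero-norm input",
         call. = FALSE)
  sum(ref_values * rec_values) / sqrt(na2 * nb2)
}

#' Dice similarity coefficient
#'
#' Spatial overlap: `2 |ref & rec| / (|ref| + |rec|)`, cardinalities counting
#' nonzero elements.
#'
#' @param ref,rec binary matrices of the same shape (not both empty).
#' @return a number in \[0, 1\].
#' @export
dice <- function(ref, rec) {
  stop_if_not_mask(ref, "ref"); stop_if_not_mask(rec, "rec")
  check_same_shape(ref, rec, "masks")
  a <- as_mask(ref); b <- as_mask(rec)
  denom <- sum(a) + sum(b)
  if (denom == 0) stop("Dice is undefined for two empty masks", call. = FALSE)
  2 * sum(a & b) / denom
}

#' Ratio of tumor detected (sensitivity proxy)
#'
#' The fraction of the reference region captured by the reconstructed
#' region: `|ref & rec| / |ref|`.
#'
#' @param ref binary reference mask (nonempty).
#' @param rec binary reconstructed mask.
#' @return a number in \[0, 1\].
#' @export
ratio_detected <- function(ref, rec) {
  stop_if_not_mask(ref, "ref"); stop_if_not_mask(rec, "rec")
  check_same_shape(ref, rec, "masks")
  a <- as_mask(ref); b <- as_mask(rec)
  if (sum(a) == 0)
    stop("ratio detected is undefined for an empty reference", call. = FALSE)
  sum(a & b) / sum(a)
}

#' Artefact rejection (specificity proxy)
#'
#' `1 - (|rec| - |ref & rec|) / |ref|`: one minus the false-positive area
#' normalized by the reference area.  1 means no tissue was reconstructed as
#' tumor outside the reference region; the value goes negative when the
#' false-positive area exceeds the reference area.
#'
#' @inheritParams ratio_detected
#' @return a number <= 1 (possibly negative).
#' @export
artefact_rejection <- function(ref, rec) {
  stop_if_not_mask(ref, "ref"); stop_if_not_mask(rec, "rec")
  check_same_shape(ref, rec, "masks")
  a <- as_mask(ref); b <- as_mask(rec)
  if (sum(a) == 0)
    stop("artefact rejection is undefined for an empty reference",
         call. = FALSE)
  1 - (sum(b) - sum(a & b)) / sum(a)
}

#' Extract interface contours from a mask
#'
#' One closed contour per 8-connected component, as boundary pixel centres
#' in millimetre coordinates ordered along the interface.  A single-pixel
#' component is represented by the four corner points of that pixel so that
#' its centroid and distances stay well defined.
#'
#' @param mask binary matrix (nonempty).
#' @param spacing_mm pixel spacing in millimetres.
#' @return list of data frames with columns `x_mm`, `y_mm`
#'   (attribute `closed = TRUE`).
#' @export
extract_contours <- function(mask, spacing_mm = 1) {
  stop_if_not_mask(mask)
  check_positive_scalar(spacing_mm, "spacing_mm")
  mask <- as_mask(mask)
  if (!any(mask)) stop("cannot extract contours from an empty mask",
                       call. = FALSE)
  lab <- label_components(mask)
  lapply(seq_len(max(lab)), function(i) {
    comp <- lab == i
    if (sum(comp) == 1L) {
      r <- row(comp)[comp]; c <- col(comp)[comp]
      h <- spacing_mm / 2
      out <- data.frame(x_mm = (c - 1) * spacing_mm + c(-h, h, h, -h),
                        y_mm = (r - 1) * spacing_mm + c(-h, -h, h, h))
    } else {
      out <- px_to_mm(trace_boundary(comp), spacing_mm)
    }
    attr(out, "closed") <- TRUE
    out
  })
}

# centroid of the region enclosed by a contour: polygon (shoelace) centroid
# when the contour encloses area, mean of the points otherwise
contour_centroid <- function(pts) {
  x <- pts$x_mm; y <- pts$y_mm
  n <- length(x)
  if (n >= 3L) {
    xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
    cross <- x * yn - xn * y
    area <- sum(cross) / 2
    if (abs(area) > sqrt(.Machine$double.eps))
      return(c(sum((x + xn) * cross), sum((y + yn) * cross)) / (6 * area))
  }
  c(mean(x), mean(y))
}

# directed average distance: mean over points of A of the distance to the
# nearest point of B
directed_avg_dist <- function(A, B) {
  d2 <- outer(A[, 1L], B[, 1L], "-")^2 + outer(A[, 2L], B[, 2L], "-")^2
  mean(sqrt(apply(d2, 1L, min)))
}

#' Average Hausdorff distance between two contours
#'
#' Each point set is first translated so the centroid of its enclosed region
#' sits at the origin (shape comparison, insensitive to placement).  The
#' result is the larger of the two directed average distances, where the
#' directed distance from A to B is the mean over points of A of the
#' distance to the nearest point of B.
#'
#' @param ref,rec contour data frames (`x_mm`, `y_mm`), nonempty.
#' @return distance in millimetres (>= 0).
#' @export
average_hausdorff <- function(ref, rec) {
  if (NROW(ref) == 0L || NROW(rec) == 0L)
    stop("average Hausdorff distance requires nonempty point sets",
         call. = FALSE)
  A <- cbind(ref$x_mm, ref$y_mm)
  B <- cbind(rec$x_mm, rec$y_mm)
  A <- sweep(A, 2L, contour_centroid(ref))
  B <- sweep(B, 2L, contour_centroid(rec))
  max(directed_avg_dist(A, B), directed_avg_dist(B, A))
}

# average Hausdorff between two masks: all boundary points per mask, each
# set centred at the centroid of the mask's pixel support
hausdorff_masks <- function(ref_mask, rec_mask, spacing_mm) {
  bpts <- function(m) {
    cc <- extract_contours(m, spacing_mm)
    pts <- do.call(rbind, cc)
    ctr <- c(mean((col(m)[m] - 1) * spacing_mm),
             mean((row(m)[m] - 1) * spacing_mm))
    sweep(cbind(pts$x_mm, pts$y_mm), 2L, ctr)
  }
  A <- bpts(as_mask(ref_mask)); B <- bpts(as_mask(rec_mask))
  max(directed_avg_dist(A, B), directed_avg_dist(B, A))
}

## ---- report assembly ----

# match 8-connected components of the reconstructed tumor mask to reference
# tumor components by nearest centroid; returns a list of rec masks, one per
# reference component
match_tumor_components <- function(ref_mask, rec_mask) {
  ref_lab <- label_components(ref_mask)
  n_ref <- max(ref_lab)
  ref_ctr <- lapply(seq_len(n_ref), function(i) {
    m <- ref_lab == i
    c(mean(row(m)[m]), mean(col(m)[m]))
  })
  out <- replicate(n_ref, matrix(FALSE, nrow(ref_mask), ncol(ref_mask)),
                   simplify = FALSE)
  if (any(rec_mask)) {
    rec_lab <- label_components(rec_mask)
    for (j in seq_len(max(rec_lab))) {
      m <- rec_lab == j
      ctr <- c(mean(row(m)[m]), mean(col(m)[m]))
      d <- vapply(ref_ctr, function(rc) sum((rc - ctr)^2), numeric(1))
      i <- which.min(d)
      out[[i]] <- out[[i]] | m
    }
  }
  out
}

# one metric row; masked-value metrics use the component images when given
metric_row <- function(region, ref_mask, rec_mask, ref_img, rec_img,
                       spacing_mm) {
  if (!any(ref_mask))
    return(data.frame(region = region, fidelity = NA_real_,
                      xcorr_diel = NA_real_, dice = NA_real_, rd = NA_real_,
                      ar = NA_real_, hausdorff_mm = NA_real_))
  rec_empty <- !any(rec_mask)
  xc <- NA_real_
  if (!rec_empty && !is.null(ref_img) && !is.null(rec_img)) {
    rt <- ref_img * ref_mask
    ct <- rec_img * rec_mask
    if (sum(rt^2) > 0 && sum(ct^2) > 0) xc <- xcorr_diel(rt, ct)
  }
  data.frame(region = region,
             fidelity = if (rec_empty) 0 else mask_fidelity(ref_mask, rec_mask),
             xcorr_diel = xc,
             dice = if (rec_empty) 0 else dice(ref_mask, rec_mask),
             rd = ratio_detected(ref_mask, rec_mask),
             ar = artefact_rejection(ref_mask, rec_mask),
             hausdorff_mm = if (rec_empty) NA_real_
                            else hausdorff_masks(ref_mask, rec_mask,
                                                 spacing_mm))
}

#' Evaluate a reconstructed segmentation against a reference
#'
#' Computes the full metric set for the glandular region (the fibroglandular
#' mask only) and for each 8-connected component of the reference malignant
#' mask.  Reconstructed malignant components are matched to the reference
#' tumor whose centroid is nearest; a reference tumor with no matched
#' reconstruction is scored as undetected (RD = 0, AR = 1, Dice = 0, no
#' Hausdorff distance).  A region absent from the reference is reported as a
#' row of `NA`s rather than an error.
#'
#' @param ref_seg,rec_seg `"tissue_segmentation"` objects on the same grid.
#' @param ref_img,rec_img optional numeric matrices of the component values
#'   the segmentations came from; needed for the dielectric
#'   cross-correlation column.
#' @param spacing_mm pixel spacing in millimetres.
#' @return data frame with one row per region (`glandular`, `tumor_1`, ...)
#'   and columns `fidelity`, `xcorr_diel`, `dice`, `rd`, `ar`,
#'   `hausdorff_mm`.
#' @export
evaluate_segmentation <- function(ref_seg, rec_seg, ref_img = NULL,
                                  rec_img = NULL, spacing_mm = 1) {
  stopifnot(inherits(ref_seg, "tissue_segmentation"),
            inherits(rec_seg, "tissue_segmentation"))
  check_same_shape(ref_seg$labels, rec_seg$labels, "segmentations")
  ref_m <- tissue_masks(ref_seg)
  rec_m <- tissue_masks(rec_seg)
  rows <- list(metric_row("glandular", ref_m$fibroglandular,
                          rec_m$fibroglandular, ref_img, rec_img, spacing_mm))
  if (any(ref_m$malignant)) {
    matched <- match_tumor_components(ref_m$malignant, rec_m$malignant)
    ref_lab <- label_components(ref_m$malignant)
    for (i in seq_along(matched))
      rows[[length(rows) + 1L]] <-
        metric_row(sprintf("tumor_%d", i), ref_lab == i, matched[[i]],
                   ref_img, rec_img, spacing_mm)
  } else {
    rows[[length(rows) + 1L]] <-
      metric_row("tumor_1", matrix(FALSE, nrow(ref_seg$labels),
                                   ncol(ref_seg$labels)),
                 rec_m$malignant, ref_img, rec_img, spacing_mm)
  }
  do.call(rbind, rows)
}

#' Per-component metric report for two fitted segmentations
#'
#' Applies [evaluate_segmentation] to every component shared by a reference
#' and a reconstructed [mwiseg] fit, mirroring the layout of a per-region,
#' per-component results table.
#'
#' @param ref_fit,rec_fit [mwiseg] objects fitted to the reference (forward
#'   model) and reconstructed images.
#' @return data frame with columns `region`, `component`, and the six
#'   metrics.
#' @export
evaluate_report <- function(ref_fit, rec_fit) {
  stopifnot(inherits(ref_fit, "mwiseg"), inherits(rec_fit, "mwiseg"))
  comps <- intersect(names(ref_fit$components), names(rec_fit$components))
  ref_imgs <- component_images(ref_fit$image)
  rec_imgs <- component_images(rec_fit$image)
  out <- do.call(rbind, lapply(comps, function(nm) {
    tab <- evaluate_segmentation(ref_fit$components[[nm]]$tissue,
                                 rec_fit$components[[nm]]$tissue,
                                 ref_imgs[[nm]], rec_imgs[[nm]],
                                 ref_fit$image$spacing_mm)
    tab$component <- nm
    tab
  }))
  out[, c("region", "component", "fidelity", "xcorr_diel", "dice", "rd",
          "ar", "hausdorff_mm")]
}
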