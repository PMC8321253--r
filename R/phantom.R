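## Synthetic dielectric breast phantom generator.  Ground-truth phantoms are
## piecewise tissue regions (immersion background, skin ring, fatty interior,
## transition shell, fibroglandular blobs, malignant disks) with per-pixel
## values drawn from ordered, adjoining tissue value ranges; a separate
## degradation step emulates the range of reconstruction quality the
## segmentation has to cope with (blurred interfaces, noise, smooth bias,
## peripheral artefacts).

default_value_ranges <- function() {
  real <- list(background = c(2, 3),
               skin = c(30, 40),
               fatty = c(4, 10),
               transition = c(10, 25),
               fibroglandular = c(25, 45),
               malignant = c(50, 60))
  list(real = real, imaginary = lapply(real, function(r) r / 4))
}

#' Specify a synthetic breast phantom
#'
#' Collects and validates the geometric and dielectric parameters of a
#' ground-truth phantom.  Tumor centres are given in millimetres relative to
#' the breast centre; each tumor disk must lie inside the breast interior.
#' The real-part value ranges must be ordered fatty < transition <
#' fibroglandular < malignant, with at most `overlap_fraction` of each
#' range's width overlapping the next (imaginary ranges are checked the same
#' way).
#'
#' @param grid_shape integer `(rows, cols)` of the image grid.
#' @param pixel_spacing_mm pixel spacing in millimetres.
#' @param breast_radius_mm outer breast (skin) radius in millimetres.
#' @param skin_thickness_mm thickness of the skin ring in millimetres.
#' @param gland_blob_count number of Gaussian bumps forming the
#'   fibroglandular region (0 for a purely fatty interior).
#' @param gland_fraction target fibroglandular fraction of the breast
#'   interior, in (0, 1).
#' @param tumor_centers_mm list of `(x, y)` tumor centres in millimetres
#'   relative to the breast centre.
#' @param tumor_radii_mm vector of tumor radii, one per centre.
#' @param transition_width_mm width of the transition shell surrounding the
#'   fibroglandular region.
#' @param tissue_value_ranges list with `real` and `imaginary` sub-lists of
#'   `(low, high)` ranges per tissue (see `mwiseg:::default_value_ranges`).
#' @param overlap_fraction maximum allowed fractional overlap between
#'   consecutive tissue ranges.
#' @param seed integer seed making the phantom reproducible.
#' @return an object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(grid_shape = c(101L, 101L),
                         pixel_spacing_mm = 1,
                         breast_radius_mm = 45,
                         skin_thickness_mm = 2,
                         gland_blob_count = 5L,
                         gland_fraction = 0.5,
                         tumor_centers_mm = list(c(8, 4)),
                         tumor_radii_mm = 5,
                         transition_width_mm = 6,
                         tissue_value_ranges = default_value_ranges(),
                         overlap_fraction = 0,
                         seed = 1L) {
  if (length(grid_shape) != 2L || any(grid_shape < 8) ||
      any(grid_shape != round(grid_shape)))
    stop("'grid_shape' must be two positive integers", call. = FALSE)
  check_positive_scalar(pixel_spacing_mm, "pixel_spacing_mm")
  check_positive_scalar(breast_radius_mm, "breast_radius_mm")
  check_positive_scalar(skin_thickness_mm, "skin_thickness_mm")
  if (gland_blob_count < 0 || gland_blob_count != round(gland_blob_count))
    stop("'gland_blob_count' must be a nonnegative integer", call. = FALSE)
  if (gland_fraction <= 0 || gland_fraction >= 1)
    stop("'gland_fraction' must lie in (0, 1)", call. = FALSE)
  if (!is.list(tumor_centers_mm))
    tumor_centers_mm <- if (length(tumor_centers_mm))
      list(tumor_centers_mm) else list()
  if (length(tumor_centers_mm) != length(tumor_radii_mm))
    stop("one radius is required per tumor centre", call. = FALSE)
  if (length(tumor_radii_mm) && any(tumor_radii_mm <= 0))
    stop("tumor radii must be positive", call. = FALSE)
  for (comp in c("real", "imaginary")) {
    rg <- tissue_value_ranges[[comp]]
    chain <- c("fatty", "transition", "fibroglandular", "malignant")
    for (i in seq_len(length(chain) - 1L)) {
      a <- rg[[chain[i]]]; b <- rg[[chain[i + 1L]]]
      if (a[2L] > b[1L] + overlap_fraction * diff(a))
        stop(sprintf("%s ranges out of order: %s [%g, %g] overlaps %s [%g, %g] beyond the allowed fraction",
                     comp, chain[i], a[1L], a[2L], chain[i + 1L], b[1L],
                     b[2L]), call. = FALSE)
    }
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 pixel_spacing_mm = pixel_spacing_mm,
                 breast_radius_mm = breast_radius_mm,
                 skin_thickness_mm = skin_thickness_mm,
                 gland_blob_count = as.integer(gland_blob_count),
                 gland_fraction = gland_fraction,
                 tumor_centers_mm = tumor_centers_mm,
                 tumor_radii_mm = tumor_radii_mm,
                 transition_width_mm = transition_width_mm,
                 tissue_value_ranges = tissue_value_ranges,
                 overlap_fraction = overlap_fraction,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a ground-truth phantom
#'
#' Builds the tissue geometry (skin ring, fatty interior, fibroglandular
#' region as a union of thresholded Gaussian bumps, transition shell, tumor
#' disks embedded in the gland) and draws each pixel's real/imaginary
#' permittivity independently and uniformly from its tissue's value range.
#' Deterministic given the spec's seed.
#'
#' @param spec a [phantom_spec].
#' @return an object of class `"ground_truth"`: list with `image` (a
#'   [permittivity_image]), `tissue_map` (a `"tissue_segmentation"` whose
#'   levels include `"skin"`), `domain_mask` (the breast support, whose
#'   boundary is the skin/immersion interface), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  nr <- spec$grid_shape[1L]; nc <- spec$grid_shape[2L]
  sp <- spec$pixel_spacing_mm
  R <- spec$breast_radius_mm
  Ri <- R - spec$skin_thickness_mm
  xmm <- (col(matrix(0, nr, nc)) - (nc + 1) / 2) * sp
  ymm <- (row(matrix(0, nr, nc)) - (nr + 1) / 2) * sp
  rr <- sqrt(xmm^2 + ymm^2)
  breast <- rr <= R
  interior <- rr <= Ri
  skin <- breast & !interior

  ## tumors must fit inside the breast interior
  for (i in seq_along(spec$tumor_centers_mm)) {
    ctr <- spec$tumor_centers_mm[[i]]
    if (sqrt(sum(ctr^2)) + spec$tumor_radii_mm[i] > Ri)
      stop(sprintf("tumor %d (centre %g, %g mm; radius %g mm) extends outside the breast interior",
                   i, ctr[1L], ctr[2L], spec$tumor_radii_mm[i]),
           call. = FALSE)
  }
  tumor <- matrix(FALSE, nr, nc)
  for (i in seq_along(spec$tumor_centers_mm)) {
    ctr <- spec$tumor_centers_mm[[i]]
    tumor <- tumor |
      ((xmm - ctr[1L])^2 + (ymm - ctr[2L])^2 <= spec$tumor_radii_mm[i]^2)
  }

  ## fibroglandular region: union of Gaussian bumps thresholded to hit the
  ## target interior fraction, kept clear of the skin by the transition width
  gland <- matrix(FALSE, nr, nc)
  Rg <- Ri - spec$transition_width_mm - 1
  if (spec$gland_blob_count > 0L) {
    g <- matrix(0, nr, nc)
    for (b in seq_len(spec$gland_blob_count)) {
      rad <- 0.55 * Rg * sqrt(runif(1))
      th <- runif(1, 0, 2 * pi)
      sigma <- runif(1, 0.18, 0.35) * Rg
      g <- g + exp(-((xmm - rad * cos(th))^2 + (ymm - rad * sin(th))^2) /
                     (2 * sigma^2))
    }
    elig <- rr <= Rg
    target <- spec$gland_fraction * sum(interior)
    thr <- quantile(g[elig], pmax(0, 1 - target / sum(elig)), names = FALSE)
    gland <- elig & g >= thr
  }
  gland <- gland | tumor
  transition <- matrix(FALSE, nr, nc)
  if (any(gland)) {
    dist_to_gland <- EBImage::distmap(!gland) * sp
    transition <- interior & !gland & dist_to_gland <= spec$transition_width_mm
  }

  codes <- matrix(match("background", TISSUE_LEVELS), nr, nc)
  codes[interior] <- match("fatty", TISSUE_LEVELS)
  codes[skin] <- match("skin", TISSUE_LEVELS)
  codes[transition] <- match("transition", TISSUE_LEVELS)
  codes[gland] <- match("fibroglandular", TISSUE_LEVELS)
  codes[tumor] <- match("malignant", TISSUE_LEVELS)

  ## Within-tissue heterogeneity: one latent severity value per element,
  ## mapped into both component ranges (storage and loss properties of
  ## tissue are strongly coupled -- both track water content).  The latent
  ## field is spatially smooth (tissue texture is correlated over a few
  ## millimetres, not white), rank-mapped within each tissue so the value
  ## distribution over a tissue stays uniform on its range.
  tex <- masked_gaussian_blur(matrix(rnorm(nr * nc), nr, nc),
                              matrix(TRUE, nr, nc), 2 / sp)
  rg_re <- spec$tissue_value_ranges$real
  rg_im <- spec$tissue_value_ranges$imaginary
  re <- matrix(0, nr, nc)
  im <- matrix(0, nr, nc)
  for (tl in TISSUE_LEVELS) {
    m <- codes == match(tl, TISSUE_LEVELS)
    n <- sum(m)
    if (n > 0L) {
      u <- (rank(tex[m], ties.method = "first") - 0.5) / n
      re[m] <- rg_re[[tl]][1L] + u * diff(rg_re[[tl]])
      im[m] <- rg_im[[tl]][1L] + u * diff(rg_im[[tl]])
    }
  }

  structure(list(image = permittivity_image(re, im, sp),
                 tissue_map = new_tissue_segmentation(codes),
                 domain_mask = breast,
                 spec = spec),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground-truth breast phantom\n")
  print(x$image)
  print(x$tissue_map)
  invisible(x)
}

#' Specify image degradations
#'
#' Parameters of the degradation applied to a ground-truth phantom to
#' emulate reconstruction defects: Gaussian blurring of tissue interfaces
#' (inside the breast support only), additive per-pixel noise, a smooth
#' multiplicative bias field, and high-valued artefact blobs near the
#' periphery (the kind the ROI contraction is designed to exclude).  All
#' parameters zero means the identity transform.
#'
#' @param blur_sigma_mm Gaussian blur standard deviation in millimetres.
#' @param noise_sd additive Gaussian noise standard deviation; a scalar
#'   (both components) or a length-2 vector `(real, imaginary)`.
#' @param bias_amplitude peak relative amplitude of the smooth
#'   multiplicative bias field.
#' @param artefact_count number of peripheral high-value blobs.
#' @param seed integer seed for the noise, bias, and artefact draws.
#' @return an object of class `"degradation_spec"`.
#' @export
degradation_spec <- function(blur_sigma_mm = 0, noise_sd = 0,
                             bias_amplitude = 0, artefact_count = 0L,
                             seed = 1L) {
  vals <- c(blur_sigma_mm, noise_sd, bias_amplitude, artefact_count)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("degradation parameters must be nonnegative", call. = FALSE)
  if (!length(noise_sd) %in% 1:2)
    stop("'noise_sd' must have length 1 or 2", call. = FALSE)
  if (artefact_count != round(artefact_count))
    stop("'artefact_count' must be an integer", call. = FALSE)
  structure(list(blur_sigma_mm = blur_sigma_mm,
                 noise_sd = rep(noise_sd, length.out = 2L),
                 bias_amplitude = bias_amplitude,
                 artefact_count = as.integer(artefact_count),
                 seed = as.integer(seed)),
            class = "degradation_spec")
}

# masked, normalized Gaussian blur: values outside 'support' neither
# contribute nor change
masked_gaussian_blur <- function(v, support, sigma_px) {
  rad <- max(1L, ceiling(3.5 * sigma_px))
  ax <- (-rad):rad
  k1 <- exp(-ax^2 / (2 * sigma_px^2))
  K <- outer(k1, k1)
  K <- K / sum(K)
  num <- EBImage::filter2(v * support, K, boundary = 0)
  den <- EBImage::filter2(support * 1, K, boundary = 0)
  out <- v
  out[support] <- num[support] / den[support]
  out
}

#' Degrade a ground-truth phantom
#'
#' Applies, in order: masked Gaussian blur of the tissue values inside the
#' breast support (immersion background untouched), a smooth multiplicative
#' bias field, additive Gaussian noise, and peripheral artefact blobs with
#' malignant-range values.  The ground-truth tissue map is not modified.
#' Deterministic given the degradation seed.
#'
#' @param truth a [generate_phantom] result.
#' @param deg a [degradation_spec].
#' @return a [permittivity_image] of the degraded field.
#' @export
degrade <- function(truth, deg) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(deg, "degradation_spec"))
  sp <- truth$image$spacing_mm
  support <- truth$domain_mask
  comps <- list(re = truth$image$re, im = truth$image$im)
  if (deg$blur_sigma_mm == 0 && all(deg$noise_sd == 0) &&
      deg$bias_amplitude == 0 && deg$artefact_count == 0L)
    return(permittivity_image(comps$re, comps$im, sp))
  set.seed(deg$seed)
  nr <- nrow(support); nc <- ncol(support)
  xmm <- (col(support) - (nc + 1) / 2) * sp
  ymm <- (row(support) - (nr + 1) / 2) * sp
  n_sup <- sum(support)
  if (deg$blur_sigma_mm > 0)
    comps <- lapply(comps, masked_gaussian_blur, support = support,
                    sigma_px = deg$blur_sigma_mm / sp)
  if (deg$bias_amplitude > 0) {
    R <- truth$spec$breast_radius_mm
    comps <- lapply(comps, function(v) {
      s <- matrix(0, nr, nc)
      for (b in 1:3) {
        cx <- runif(1, -0.6, 0.6) * R; cy <- runif(1, -0.6, 0.6) * R
        sg <- runif(1, 0.5, 0.9) * R
        s <- s + sample(c(-1, 1), 1) *
          exp(-((xmm - cx)^2 + (ymm - cy)^2) / (2 * sg^2))
      }
      s <- s / max(abs(s))
      v[support] <- v[support] * (1 + deg$bias_amplitude * s[support])
      v
    })
  }
  if (any(deg$noise_sd > 0)) {
    comps$re[support] <- comps$re[support] + rnorm(n_sup, 0, deg$noise_sd[1L])
    comps$im[support] <- comps$im[support] + rnorm(n_sup, 0, deg$noise_sd[2L])
  }
  if (deg$artefact_count > 0L) {
    Ri <- truth$spec$breast_radius_mm - truth$spec$skin_thickness_mm
    rg <- truth$spec$tissue_value_ranges
    for (a in seq_len(deg$artefact_count)) {
      rad_pos <- runif(1, max(0, Ri - 5), Ri)
      th <- runif(1, 0, 2 * pi)
      blob_r <- runif(1, 1.5, 3)
      blob <- support &
        ((xmm - rad_pos * cos(th))^2 + (ymm - rad_pos * sin(th))^2 <= blob_r^2)
      nb <- sum(blob)
      if (nb > 0L) {
        comps$re[blob] <- runif(nb, rg$real$malignant[1L],
                                rg$real$malignant[2L])
        comps$im[blob] <- runif(nb, rg$imaginary$malignant[1L],
                                rg$imaginary$malignant[2L])
      }
    }
  }
  permittivity_image(comps$re, comps$im, sp)
}
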