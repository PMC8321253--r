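#' Complex permittivity image
#'
#' Container for a 2D reconstructed complex-permittivity field on a regular
#' pixel grid.  The real part describes the tissue's ability to store
#' microwave energy, the imaginary part its ability to absorb it.
#'
#' @param re real-part matrix.
#' @param im imaginary-part matrix (same shape); defaults to all zeros.
#' @param spacing_mm pixel spacing in millimetres (isotropic).
#' @return an object of class `"permittivity_image"` with fields `re`, `im`,
#'   `spacing_mm`.
#' @export
permittivity_image <- function(re, im = NULL, spacing_mm = 1) {
  if (!is.matrix(re) || !is.numeric(re))
    stop("'re' must be a numeric matrix", call. = FALSE)
  if (is.null(im)) im <- matrix(0, nrow(re), ncol(re))
  check_same_shape(re, im, "real and imaginary components")
  check_positive_scalar(spacing_mm, "spacing_mm")
  structure(list(re = re, im = im, spacing_mm = spacing_mm),
            class = "permittivity_image")
}

#' @export
print.permittivity_image <- function(x, ...) {
  cat(sprintf("Complex permittivity image: %d x %d pixels, %.3g mm spacing\n",
              nrow(x$re), ncol(x$re), x$spacing_mm))
  cat(sprintf("  Re range [%.3g, %.3g], Im range [%.3g, %.3g]\n",
              min(x$re), max(x$re), min(x$im), max(x$im)))
  invisible(x)
}

#' @export
dim.permittivity_image <- function(x) dim(x$re)

#' Recover permittivity from a contrast profile
#'
#' Inverse solvers reconstruct a contrast profile chi relative to an assumed
#' background permittivity eps_b over the imaging domain.  The complex
#' permittivity is recovered elementwise as `eps = eps_b * (chi + 1)` inside
#' the domain; outside the domain the background is returned unchanged
#' (the contrast is zero there by definition).
#'
#' @param chi complex matrix, the contrast profile (zero outside `domain`).
#' @param eps_b complex matrix, the background permittivity profile.
#' @param domain binary matrix marking the imaging domain.
#' @param spacing_mm pixel spacing in millimetres.
#' @return a [permittivity_image].
#' @export
contrast_to_permittivity <- function(chi, eps_b, domain, spacing_mm = 1) {
  check_same_shape(chi, eps_b, "'chi' and 'eps_b'")
  stop_if_not_mask(domain, "domain")
  check_same_shape(chi, domain, "'chi' and 'domain'")
  d <- as_mask(domain)
  if (any(Mod(eps_b[d]) == 0))
    stop("background permittivity is zero inside the imaging domain",
         call. = FALSE)
  eps <- eps_b
  eps[d] <- eps_b[d] * (chi[d] + 1)
  permittivity_image(Re(eps), Im(eps), spacing_mm)
}

#' Compute permittivity from a recovered image (inverse of the conversion)
#'
#' Returns the contrast profile implied by a permittivity image and a
#' background profile; zero outside the imaging domain.
#'
#' @inheritParams contrast_to_permittivity
#' @param img a [permittivity_image].
#' @return complex matrix of contrasts.
#' @export
permittivity_to_contrast <- function(img, eps_b, domain) {
  stopifnot(inherits(img, "permittivity_image"))
  d <- as_mask(domain)
  if (any(Mod(eps_b[d]) == 0))
    stop("background permittivity is zero inside the imaging domain",
         call. = FALSE)
  eps <- complex(real = img$re, imaginary = img$im)
  dim(eps) <- dim(img$re)
  chi <- matrix(0 + 0i, nrow(img$re), ncol(img$re))
  chi[d] <- eps[d] / eps_b[d] - 1
  chi
}

#' Component images of a complex permittivity field
#'
#' The segmentation pipeline is applied independently to three scalar images
#' derived from the complex permittivity: the real component, the loss
#' magnitude `|Im|` (so that lossy malignant tissue is highest-valued under
#' either time-harmonic sign convention), and the magnitude
#' `sqrt(Re^2 + Im^2)`.
#'
#' @param img a [permittivity_image].
#' @return named list of numeric matrices: `real`, `imaginary`, `magnitude`.
#' @export
component_images <- function(img) {
  stopifnot(inherits(img, "permittivity_image"))
  list(real = img$re,
       imaginary = abs(img$im),
       magnitude = sqrt(img$re^2 + img$im^2))
}

## ---- plain-text matrix I/O ----

#' Read and write numeric matrices as comma-separated text
#'
#' Matrices are stored one row per line, values comma-separated at full
#' decimal precision, optionally preceded by `# key=value` header lines
#' (typically `# spacing_mm=...`).  The round trip is lossless.
#'
#' @param x numeric matrix to write.
#' @param path file path.
#' @param header named list/vector of scalar header fields to record.
#' @return `read_matrix_csv` returns the matrix with any header fields
#'   attached as a `"header"` attribute; `write_matrix_csv` returns `path`
#'   invisibly.
#' @export
write_matrix_csv <- function(x, path, header = NULL) {
  if (!is.matrix(x)) stop("'x' must be a matrix", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(header))
    writeLines(sprintf("# %s=%s", nm, format(header[[nm]], digits = 17)), con)
  writeLines(apply(x, 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = TRUE),
          collapse = ",")), con)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grepl("^#", lines)
  header <- list()
  for (h in lines[hdr_idx]) {
    kv <- sub("^#\\s*", "", h)
    parts <- strsplit(kv, "=", fixed = TRUE)[[1L]]
    if (length(parts) == 2L)
      header[[trimws(parts[1L])]] <- as.numeric(parts[2L])
  }
  body <- lines[!hdr_idx & nzchar(lines)]
  if (length(body) == 0L) stop("no matrix rows found in ", path, call. = FALSE)
  rows <- strsplit(body, ",", fixed = TRUE)
  ncol <- length(rows[[1L]])
  if (any(lengths(rows) != ncol))
    stop("malformed matrix file (ragged rows): ", path, call. = FALSE)
  m <- do.call(rbind, lapply(rows, as.numeric))
  if (anyNA(m)) stop("non-numeric entries in matrix file: ", path, call. = FALSE)
  attr(m, "header") <- header
  m
}

## ---- mask PNG I/O ----

#' Read and write binary masks as 8-bit PNG
#'
#' Masks are written as single-channel PNG with foreground 255 and
#' background 0; reading maps any nonzero pixel back to `TRUE`.
#'
#' @param mask logical (or 0/1) matrix.
#' @param path file path.
#' @return `read_mask_png` returns a logical matrix; `write_mask_png`
#'   returns `path` invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stop_if_not_mask(mask)
  png::writePNG(ifelse(as_mask(mask), 1, 0), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  a > 0
}

## ---- report / contour output ----

#' Write a metric report as JSON
#'
#' Serializes a metric report (see [evaluate_segmentation]) keyed
#' region -> component -> metric, with a schema version field.
#'
#' @param report data frame with columns `region`, `component` and metric
#'   columns, as produced by [evaluate_report].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  metric_cols <- setdiff(names(report), c("region", "component"))
  out <- list(schema = "mwiseg-report/1")
  for (rg in unique(report$region)) {
    sub <- report[report$region == rg, , drop = FALSE]
    comp <- list()
    for (i in seq_len(nrow(sub))) {
      vals <- as.list(sub[i, metric_cols])
      comp[[sub$component[i]]] <- vals
    }
    out[[rg]] <- comp
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Write contours as CSV
#'
#' One file with columns `x_mm,y_mm` (and a `contour` index column when
#' several contours are supplied).
#'
#' @param contours a data frame with `x_mm`, `y_mm`, or a list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contours_csv <- function(contours, path) {
  if (is.data.frame(contours)) contours <- list(contours)
  tab <- do.call(rbind, lapply(seq_along(contours), function(i) {
    data.frame(contour = i,
               x_mm = contours[[i]]$x_mm,
               y_mm = contours[[i]]$y_mm)
  }))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write a contour overlay image
#'
#' Renders a scalar image to grayscale, paints contour points on top in
#' color, and writes the result as RGB PNG.  Used to superimpose reference
#' and reconstructed tissue interfaces on a permittivity component image.
#'
#' @param values numeric matrix rendered as the grayscale backdrop.
#' @param contours list of contour data frames (`x_mm`, `y_mm`).
#' @param path output PNG path.
#' @param spacing_mm pixel spacing used to map mm coordinates to pixels.
#' @param colors vector of RGB triplets (each length 3, in \[0,1\]) recycled
#'   over contours.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(values, contours, path, spacing_mm = 1,
                              colors = list(c(1, 0, 0), c(0, 0, 0),
                                            c(0, 0.8, 0))) {
  g <- values - min(values)
  if (max(g) > 0) g <- g / max(g)
  rgb <- array(rep(g, 3L), dim = c(dim(values), 3L))
  if (is.data.frame(contours)) contours <- list(contours)
  for (i in seq_along(contours)) {
    cc <- contours[[i]]
    col <- colors[[(i - 1L) %% length(colors) + 1L]]
    r <- round(cc$y_mm / spacing_mm) + 1L
    c <- round(cc$x_mm / spacing_mm) + 1L
    ok <- r >= 1L & r <= nrow(values) & c >= 1L & c <= ncol(values)
    for (ch in 1:3) rgb[cbind(r[ok], c[ok], ch)] <- col[ch]
  }
  png::writePNG(rgb, path)
  invisible(path)
}
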