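## Iterative k-means segmentation with statistical termination.
##
## The cluster count k starts at 3 (background / breast interior split in
## two).  At each iteration k is incremented and the field re-clustered; the
## highest-valued cluster is the running tumor estimate T and the union of
## the intermediate clusters its complement Tc within the ROI.  For k > 3,
## two-sample Kolmogorov-Smirnov tests compare the value samples drawn over
## T and Tc with the samples from the previous iteration; the refinement
## stops once neither test rejects (at significance alpha), i.e. once both
## distributions have stabilized.

#' Empirical distribution function of a sample
#'
#' Returns the ECDF as its sorted support together with the cumulative
#' fractions at each support point (right-continuous, nondecreasing,
#' reaching 1 at the maximum), plus the step function itself.
#'
#' @param sample numeric vector (nonempty).
#' @return list with `x` (sorted unique values), `p` (cumulative fractions),
#'   and `fun` (the step function, from [stats::ecdf]).
#' @export
ecdf_points <- function(sample) {
  if (length(sample) == 0L) stop("empty sample", call. = FALSE)
  f <- stats::ecdf(sample)
  x <- stats::knots(f)
  list(x = x, p = f(x), fun = f)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes the KS statistic, the supremum over x of the absolute difference
#' between the two empirical distribution functions, and the asymptotic
#' p-value with effective sample size `n1 * n2 / (n1 + n2)`.  Samples here
#' are pixel values over masks, so ties across iterations are expected; the
#' asymptotic p-value is used throughout (sample sizes are typically in the
#' thousands).
#'
#' @param a,b numeric samples (nonempty).
#' @param alpha significance level for the rejection decision.
#' @return object of class `"ks_result"`: list with `statistic`, `p_value`,
#'   `rejected`, `alpha`, `n1`, `n2`.
#' @export
ks_two_sample <- function(a, b, alpha = 0.01) {
  if (length(a) == 0L || length(b) == 0L)
    stop("KS test requires two nonempty samples", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  p <- as.numeric(kt$p.value)
  structure(list(statistic = as.numeric(kt$statistic),
                 p_value = p,
                 rejected = p < alpha,
                 alpha = alpha,
                 n1 = length(a),
                 n2 = length(b)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("two-sample KS: D = %.4f, p = %.4g (n1 = %d, n2 = %d) -> %s\n",
              x$statistic, x$p_value, x$n1, x$n2,
              if (x$rejected) sprintf("reject at alpha = %g", x$alpha)
              else "not rejected"))
  invisible(x)
}

#' Iteratively refine the cluster count with KS termination
#'
#' Runs the iterative clustering scheme on a prepared field: clustering at
#' k = 3, 4, ... with [cluster_once], extracting the tumor-estimate sample
#' (highest cluster) and its complement sample (clusters 2..k-1) at each
#' step, and stopping as soon as neither of the two KS tests against the
#' previous iteration's samples rejects.
#'
#' @param field a [prepare_field] result.
#' @param alpha KS significance level (default 0.01).
#' @param restarts k-means restarts per clustering (default 10).
#' @param seed master seed; per-k sub-seeds are derived from it.
#' @param k_max bound on the cluster count; reaching it without the tests
#'   stabilizing raises an error of class `"mwiseg_no_convergence"` that
#'   carries the history in its `history` field.
#' @return list with `labeling` (the final [cluster_once] result) and
#'   `history` (class `"segmentation_history"`).
#' @export
iterate_segmentation <- function(field, alpha = 0.01, restarts = 10L,
                                 seed = 1L, k_max = 20L) {
  if (!inherits(field, "prepared_field"))
    stop("'field' must be a prepared_field", call. = FALSE)
  if (k_max < 4L) stop("'k_max' must be at least 4", call. = FALSE)
  set.seed(seed)
  kseeds <- sample.int(.Machine$integer.max, k_max)
  records <- list()
  prev_vt <- prev_vc <- NULL
  mk_history <- function(converged, final_k) {
    structure(list(records = records, alpha = alpha, converged = converged,
                   final_k = final_k),
              class = "segmentation_history")
  }
  for (k in 3:k_max) {
    lab <- cluster_once(field, k, restarts = restarts, seed = kseeds[k])
    tumor_mask <- lab$labels == k
    comp_mask <- lab$labels >= 2L & lab$labels <= k - 1L
    if (!any(tumor_mask) || !any(comp_mask))
      stop(errorCondition(
        sprintf("empty tumor estimate or complement at k = %d", k),
        history = mk_history(FALSE, k), class = "mwiseg_degenerate"))
    vt <- field$values[tumor_mask]
    vc <- field$values[comp_mask]
    rec <- list(k = k, tumor_mask = tumor_mask, comp_mask = comp_mask,
                n_tumor = length(vt), n_comp = length(vc),
                centroids = lab$centroids, objective = lab$objective,
                ks_tumor = NULL, ks_comp = NULL)
    if (k > 3L) {
      rec$ks_tumor <- ks_two_sample(vt, prev_vt, alpha)
      rec$ks_comp <- ks_two_sample(vc, prev_vc, alpha)
    }
    records[[length(records) + 1L]] <- rec
    if (k > 3L && !rec$ks_tumor$rejected && !rec$ks_comp$rejected)
      return(list(labeling = lab, history = mk_history(TRUE, k)))
    prev_vt <- vt
    prev_vc <- vc
  }
  stop(errorCondition(
    sprintf("segmentation did not converge within k_max = %d clusters", k_max),
    history = mk_history(FALSE, k_max), class = "mwiseg_no_convergence"))
}

#' @export
print.segmentation_history <- function(x, ...) {
  cat(sprintf("Segmentation history: k = 3..%d, %s (alpha = %g)\n",
              x$final_k,
              if (x$converged) "converged" else "NOT converged", x$alpha))
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' @export
as.data.frame.segmentation_history <- function(x, ...) {
  do.call(rbind, lapply(x$records, function(r) {
    data.frame(k = r$k, n_tumor = r$n_tumor, n_comp = r$n_comp,
               ks_tumor_D = if (is.null(r$ks_tumor)) NA else r$ks_tumor$statistic,
               ks_tumor_p = if (is.null(r$ks_tumor)) NA else r$ks_tumor$p_value,
               ks_comp_D = if (is.null(r$ks_comp)) NA else r$ks_comp$statistic,
               ks_comp_p = if (is.null(r$ks_comp)) NA else r$ks_comp$p_value)
  }))
}

## ---- tissue segmentation container ----

new_tissue_segmentation <- function(codes, component = NA_character_) {
  structure(list(labels = codes, levels = TISSUE_LEVELS,
                 source_component = component),
            class = "tissue_segmentation")
}

#' Binary masks of a tissue segmentation
#'
#' @param seg a `"tissue_segmentation"` object.
#' @return named list of logical matrices, one per tissue level (levels with
#'   no pixels give all-`FALSE` masks).
#' @export
tissue_masks <- function(seg) {
  stopifnot(inherits(seg, "tissue_segmentation"))
  out <- lapply(seq_along(seg$levels), function(i) seg$labels == i)
  names(out) <- seg$levels
  out
}

#' @export
print.tissue_segmentation <- function(x, ...) {
  counts <- tabulate(x$labels, length(x$levels))
  cat(sprintf("Tissue segmentation (%d x %d%s)\n", nrow(x$labels),
              ncol(x$labels),
              if (is.na(x$source_component)) ""
              else paste0(", ", x$source_component, " component")))
  present <- counts > 0
  print(setNames(counts[present], x$levels[present]))
  invisible(x)
}

#' @export
plot.tissue_segmentation <- function(x, main = NULL, ...) {
  cols <- c(background = "#d8e6f2", skin = "#c8a27d", fatty = "#f6e8b1",
            transition = "#e8b04b", fibroglandular = "#c0504d",
            malignant = "#5b1a18")
  present <- sort(unique(as.vector(x$labels)))
  image(t(x$labels)[, nrow(x$labels):1], col = cols[x$levels[present]],
        axes = FALSE, main = main %||% "tissue segmentation", ...)
  legend("topright", legend = x$levels[present], fill = cols[x$levels[present]],
         cex = 0.7, bg = "white")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map ascending clusters to tissue types
#'
#' Translates a final cluster labeling into tissue categories: cluster 1 is
#' background, cluster 2 fatty, clusters 3-4 transition, the intermediate
#' clusters 5..max(k)-1 fibroglandular, and the top cluster malignant.  When
#' the refinement stopped after a single iteration (max(k) = 4) the
#' special-case mapping is used instead: clusters 2, 3, 4 become fatty,
#' fibroglandular, and malignant.
#'
#' With max(k) = 5 the fibroglandular range `4 < k < 5` is empty; the mapping
#' is applied literally and a warning is raised, since no cluster is then
#' attributed to fibroglandular tissue.
#'
#' @param labeling a [cluster_once] result (final `k` must be >= 4).
#' @param component optional name of the source component image.
#' @return object of class `"tissue_segmentation"`.
#' @export
map_clusters <- function(labeling, component = NA_character_) {
  stopifnot(inherits(labeling, "cluster_labeling"))
  kmax <- labeling$k
  if (kmax < 4L)
    stop("cluster-to-tissue mapping requires at least 4 clusters ",
         "(the refinement never returns k = 3)", call. = FALSE)
  map <- character(kmax)
  map[1L] <- "background"
  if (kmax == 4L) {
    map[2:4] <- c("fatty", "fibroglandular", "malignant")
  } else {
    map[2L] <- "fatty"
    map[3:4] <- "transition"
    if (kmax > 5L) map[5:(kmax - 1L)] <- "fibroglandular"
    else warning("final cluster count is 5: no cluster maps to ",
                 "fibroglandular tissue", call. = FALSE)
    map[kmax] <- "malignant"
  }
  codes <- matrix(match(map, TISSUE_LEVELS)[labeling$labels],
                  nrow(labeling$labels), ncol(labeling$labels))
  new_tissue_segmentation(codes, component)
}

#' Segment the component images of a permittivity image
#'
#' Runs the full pipeline (sentinel preparation, iterative clustering, KS
#' termination, tissue mapping) independently on the requested component
#' images of a complex permittivity field.
#'
#' @param image a [permittivity_image].
#' @param roi binary region-of-interest mask (see [contract_roi]).
#' @param components subset of `c("real", "imaginary", "magnitude")`.
#' @param alpha,restarts,seed,k_max passed to [iterate_segmentation];
#'   per-component sub-seeds are derived deterministically from `seed`.
#' @param sentinel background fill value (see [prepare_field]).
#' @return named list, one entry per component, each a list with `tissue`
#'   (the [map_clusters] result), `history`, and `labeling`.
#' @export
segment_components <- function(image, roi,
                               components = c("real", "imaginary",
                                              "magnitude"),
                               alpha = 0.01, restarts = 10L, seed = 1L,
                               k_max = 20L, sentinel = -100) {
  stopifnot(inherits(image, "permittivity_image"))
  components <- match.arg(components, several.ok = TRUE)
  check_same_shape(image$re, roi, "image and ROI")
  comps <- component_images(image)
  out <- list()
  ## every component is refined from the same master seed, so components
  ## with identical values (e.g. |eps| = Re{eps} for a lossless image)
  ## produce identical segmentations
  for (nm in components) {
    field <- prepare_field(comps[[nm]], roi, sentinel = sentinel,
                           spacing_mm = image$spacing_mm)
    res <- iterate_segmentation(field, alpha = alpha, restarts = restarts,
                                seed = seed, k_max = k_max)
    out[[nm]] <- list(tissue = map_clusters(res$labeling, component = nm),
                      history = res$history,
                      labeling = res$labeling)
  }
  out
}

## ---- model-style front end ----

#' Fit an unsupervised tissue segmentation to a microwave breast image
#'
#' The main entry point.  Builds the region of interest by contracting the
#' imaging-domain mask inward (excluding peripheral artefacts), then
#' segments each requested component image with iterative k-means clustering
#' terminated by two-sample KS tests, and maps the final clusters to tissue
#' types.
#'
#' @param image a [permittivity_image].
#' @param domain binary mask of the imaging domain (e.g. the support inside
#'   the skin surface).  Defaults to the full grid.
#' @param roi optional explicit region-of-interest mask; when supplied,
#'   `domain` and `contract_mm` are ignored.
#' @param contract_mm inward contraction of the domain boundary in mm
#'   (default 3.5).
#' @param components which component images to segment.
#' @param alpha KS significance level (default 0.01).
#' @param restarts k-means restarts per clustering (default 10).
#' @param seed master seed controlling all randomness of the fit.
#' @param k_max cluster-count cap (default 20).
#' @param sentinel background fill value (default -100).
#' @return an object of class `"mwiseg"`: list with `components` (per
#'   component: `tissue`, `history`, `labeling`), `roi`, `domain`, `image`,
#'   `params`, `call`.  Methods: `print`, `summary`, `coef` (cluster
#'   centroids), `plot`.
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 7))
#' fit <- mwiseg(ph$image, domain = ph$domain_mask,
#'               components = "real", seed = 7)
#' summary(fit)
#' @export
mwiseg <- function(image, domain = NULL, roi = NULL, contract_mm = 3.5,
                   components = c("real", "imaginary", "magnitude"),
                   alpha = 0.01, restarts = 10L, seed = 1L, k_max = 20L,
                   sentinel = -100) {
  stopifnot(inherits(image, "permittivity_image"))
  if (is.null(roi)) {
    if (is.null(domain))
      domain <- matrix(TRUE, nrow(image$re), ncol(image$re))
    roi <- contract_roi(domain, contract_mm, image$spacing_mm)
  }
  comps <- segment_components(image, roi, components = components,
                              alpha = alpha, restarts = restarts,
                              seed = seed, k_max = k_max, sentinel = sentinel)
  structure(list(components = comps, roi = as_mask(roi), domain = domain,
                 image = image,
                 params = list(contract_mm = contract_mm, alpha = alpha,
                               restarts = restarts, seed = seed,
                               k_max = k_max, sentinel = sentinel),
                 call = match.call()),
            class = "mwiseg")
}

#' @export
print.mwiseg <- function(x, ...) {
  cat("Unsupervised tissue segmentation of a microwave breast image\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  for (nm in names(x$components)) {
    h <- x$components[[nm]]$history
    cat(sprintf("  %-10s final k = %d after %d refinement iteration(s)\n",
                nm, h$final_k, h$final_k - 3L))
  }
  invisible(x)
}

#' @export
summary.mwiseg <- function(object, ...) {
  sp <- object$image$spacing_mm
  tabs <- lapply(names(object$components), function(nm) {
    seg <- object$components[[nm]]$tissue
    counts <- tabulate(seg$labels, length(seg$levels))
    data.frame(component = nm, tissue = seg$levels, pixels = counts,
               area_mm2 = counts * sp^2)
  })
  out <- list(call = object$call,
              areas = do.call(rbind, tabs),
              final_k = vapply(object$components,
                               function(cc) cc$history$final_k, integer(1)),
              alpha = object$params$alpha)
  class(out) <- "summary.mwiseg"
  out
}

#' @export
print.summary.mwiseg <- function(x, ...) {
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat("Final cluster counts:",
      paste(sprintf("%s = %d", names(x$final_k), x$final_k),
            collapse = ", "),
      sprintf("(KS alpha = %g)\n", x$alpha))
  areas <- x$areas[x$areas$pixels > 0, ]
  print(areas, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.mwiseg <- function(object, ...) {
  lapply(object$components, function(cc) cc$labeling$centroids)
}

#' @export
plot.mwiseg <- function(x, component = names(x$components)[1L], ...) {
  plot(x$components[[component]]$tissue,
       main = paste("tissue segmentation,", component, "component"), ...)
}
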