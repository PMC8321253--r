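mk <- function(idx, nr = 6, nc = 6) {
  m <- matrix(FALSE, nr, nc)
  m[idx] <- TRUE
  m
}

test_that("region metrics reproduce hand-computed toy values", {
  ref <- mk(1:4)
  rec <- mk(3:6)
  expect_equal(mask_fidelity(ref, rec), 2 / sqrt(4 * 4))        # 0.5
  expect_equal(dice(ref, rec), 0.5)
  expect_equal(ratio_detected(mk(1:4), mk(2:4)), 0.75)
  expect_equal(artefact_rejection(mk(1:4), mk(2:11)), 1 - 7 / 4)  # -0.75
  v_ref <- matrix(0, 2, 2); v_ref[1:2] <- c(1, 2)
  v_rec <- matrix(0, 2, 2); v_rec[1:2] <- c(2, 1)
  expect_equal(xcorr_diel(v_ref, v_rec), 4 / 5)
})

test_that("metric identities and limits hold", {
  m <- mk(c(8, 9, 14, 15))
  expect_equal(mask_fidelity(m, m), 1)
  expect_equal(dice(m, m), 1)
  expect_equal(ratio_detected(m, m), 1)
  expect_equal(artefact_rejection(m, m), 1)
  other <- mk(25:28)
  expect_equal(mask_fidelity(m, other), 0)
  expect_equal(dice(m, other), 0)
  ## insensitivity limit: nothing reconstructed
  none <- mk(integer(0))
  expect_equal(ratio_detected(m, none), 0)
  expect_equal(artefact_rejection(m, none), 1)
  ## superset reconstruction detects everything
  expect_equal(ratio_detected(m, mk(1:36)), 1)
  expect_error(mask_fidelity(m, none), "empty")
  expect_error(dice(none, none), "empty")
  expect_error(ratio_detected(none, m), "empty")
})

test_that("fidelity and dielectric correlation are scale invariant and symmetric", {
  set.seed(40)
  v <- matrix(runif(64, 1, 5) * (runif(64) > 0.4), 8)
  w <- matrix(runif(64, 1, 5) * (runif(64) > 0.4), 8)
  expect_equal(xcorr_diel(v, 2 * v), 1)
  expect_equal(xcorr_diel(v, w), xcorr_diel(w, v))
  expect_equal(xcorr_diel(3.7 * v, w), xcorr_diel(v, w))
  a <- v > 0; b <- w > 0
  expect_equal(mask_fidelity(a, b), mask_fidelity(b, a))
  expect_equal(dice(a, b), dice(b, a))
})

test_that("contour extraction respects components and degenerate masks", {
  one <- mk(15, 6, 6)
  cc <- extract_contours(one, spacing_mm = 2)
  expect_length(cc, 1)
  expect_equal(nrow(cc[[1]]), 4)                       # four pixel corners
  expect_equal(sort(unique(cc[[1]]$x_mm)), c(3, 5))    # centre 4 mm +/- 1
  rect <- matrix(FALSE, 10, 12); rect[3:8, 4:10] <- TRUE
  cr <- extract_contours(rect)
  expect_length(cr, 1)
  on_perim <- cr[[1]]$x_mm %in% c(3, 9) | cr[[1]]$y_mm %in% c(2, 7)
  expect_true(all(on_perim))
  expect_equal(nrow(cr[[1]]), 2 * (6 + 7) - 4)
  two <- matrix(FALSE, 12, 12); two[2:4, 2:4] <- TRUE; two[8:11, 7:10] <- TRUE
  expect_length(extract_contours(two), 2)
  expect_error(extract_contours(matrix(FALSE, 3, 3)), "empty")
})

test_that("average Hausdorff distance is centred, symmetric and exact on toys", {
  ## identical shapes at different locations coincide after centring
  sq <- data.frame(x_mm = c(0, 2, 2, 0), y_mm = c(0, 0, 2, 2))
  sq_far <- data.frame(x_mm = sq$x_mm + 40, y_mm = sq$y_mm - 17)
  expect_equal(average_hausdorff(sq, sq_far), 0)
  a <- data.frame(x_mm = c(0, 2), y_mm = c(0, 0))
  b <- data.frame(x_mm = c(10, 12), y_mm = c(0, 0))
  expect_equal(average_hausdorff(a, b), 0)
  c1 <- data.frame(x_mm = c(-1, 1), y_mm = c(0, 0))
  c2 <- data.frame(x_mm = c(-2, 2), y_mm = c(0, 0))
  expect_equal(average_hausdorff(c1, c2), 1)
  expect_equal(average_hausdorff(c2, c1), 1)
  expect_error(average_hausdorff(sq[0, ], sq), "nonempty")
})

test_that("integer-pixel shifts leave the average Hausdorff distance unchanged", {
  set.seed(50)
  m1 <- disk_mask(40, 40, 7, c(15, 15)) | disk_mask(40, 40, 4, c(24, 22))
  m2 <- disk_mask(40, 40, 8, c(17, 16))
  c1 <- extract_contours(m1)[[1]]
  c2 <- extract_contours(m2)[[1]]
  base <- average_hausdorff(c1, c2)
  for (shift in list(c(7, -13), c(-2, 9), c(100, 41))) {
    moved <- data.frame(x_mm = c2$x_mm + shift[1], y_mm = c2$y_mm + shift[2])
    expect_lt(abs(average_hausdorff(c1, moved) - base), 1e-9)
    moved1 <- data.frame(x_mm = c1$x_mm + shift[2], y_mm = c1$y_mm + shift[1])
    expect_lt(abs(average_hausdorff(moved1, c2) - base), 1e-9)
  }
})

seg_from_codes <- function(codes) {
  structure(list(labels = codes, levels = tissue_levels(include_skin = TRUE),
                 source_component = "real"),
            class = "tissue_segmentation")
}

toy_segmentation <- function(tumors = list(c(10, 10)), radius = 3) {
  codes <- matrix(match("background", tissue_levels(TRUE)), 24, 24)
  codes[3:21, 3:21] <- match("fatty", tissue_levels(TRUE))
  codes[5:12, 5:12] <- match("fibroglandular", tissue_levels(TRUE))
  for (tc in tumors) {
    d <- disk_mask(24, 24, radius, tc)
    codes[d] <- match("malignant", tissue_levels(TRUE))
  }
  seg_from_codes(codes)
}

test_that("a perfect reconstruction scores 1 on all metrics and 0 distance", {
  seg <- toy_segmentation()
  set.seed(60)
  img <- matrix(runif(576, 10, 50), 24)
  rep <- evaluate_segmentation(seg, seg, img, img, spacing_mm = 1)
  expect_setequal(rep$region, c("glandular", "tumor_1"))
  for (col in c("fidelity", "xcorr_diel", "dice", "rd", "ar"))
    expect_equal(rep[[col]], c(1, 1))
  expect_equal(rep$hausdorff_mm, c(0, 0))
})

test_that("multi-tumor references produce per-tumor rows matched by centroid", {
  ref <- toy_segmentation(tumors = list(c(8, 8), c(17, 17)), radius = 2)
  rec <- toy_segmentation(tumors = list(c(9, 8), c(17, 18)), radius = 2)
  rep <- evaluate_segmentation(ref, rec, spacing_mm = 1)
  expect_setequal(rep$region, c("glandular", "tumor_1", "tumor_2"))
  expect_true(all(rep$rd[rep$region != "glandular"] > 0.5))
})

test_that("an empty reconstructed tumor is scored as undetected", {
  ref <- toy_segmentation()
  rec <- toy_segmentation(tumors = list())
  rep <- evaluate_segmentation(ref, rec, spacing_mm = 1)
  t1 <- rep[rep$region == "tumor_1", ]
  expect_equal(t1$rd, 0)
  expect_equal(t1$ar, 1)
  expect_equal(t1$dice, 0)
  expect_true(is.na(t1$hausdorff_mm))
})

test_that("a region absent from the reference is reported as missing", {
  codes <- matrix(match("fatty", tissue_levels(TRUE)), 10, 10)
  ref <- seg_from_codes(codes)
  rec <- toy_segmentation()
  rec$labels <- rec$labels[1:10, 1:10]
  rep <- evaluate_segmentation(ref, rec, spacing_mm = 1)
  expect_true(all(is.na(rep[rep$region == "glandular",
                            c("dice", "rd", "ar")])))
})
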