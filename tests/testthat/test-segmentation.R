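test_that("ECDF evaluation matches direct counting", {
  e <- ecdf_points(c(1, 2, 3, 4))
  expect_equal(e$fun(2.5), 0.5)
  e2 <- ecdf_points(c(7, 7, 7))
  expect_equal(e2$x, 7)
  expect_equal(e2$p, 1)
  expect_equal(e2$fun(6.999), 0)
  set.seed(8)
  s <- runif(50)
  e3 <- ecdf_points(s)
  q <- seq(-0.1, 1.1, length.out = 100)
  expect_equal(e3$fun(q),
               vapply(q, function(x) mean(s <= x), numeric(1)))
  expect_true(all(diff(e3$p) > 0))
  expect_equal(max(e3$p), 1)
  expect_error(ecdf_points(numeric(0)), "empty")
})

test_that("KS statistic and decision behave at the extremes", {
  a <- c(1, 2, 3, 5)
  r <- ks_two_sample(a, a)
  expect_equal(r$statistic, 0)
  expect_false(r$rejected)
  r2 <- ks_two_sample(c(0, 0, 0), c(1, 1, 1))
  expect_equal(r2$statistic, 1)
  expect_error(ks_two_sample(numeric(0), a), "nonempty")
})

test_that("KS statistic equals the brute-force pooled-support supremum", {
  for (i in 1:25) {
    set.seed(300 + i)
    a <- rnorm(sample(5:50, 1))
    b <- rnorm(sample(5:50, 1), mean = runif(1, -1, 1))
    expect_equal(ks_two_sample(a, b)$statistic, ks_stat_bruteforce(a, b),
                 tolerance = 1e-12)
  }
})

test_that("three constant plateaus terminate at the first test opportunity", {
  f <- plateau_field()
  res <- iterate_segmentation(f, restarts = 5, seed = 4)
  h <- res$history
  expect_true(h$converged)
  expect_equal(h$final_k, 4L)                        # one refinement iteration
  expect_equal(vapply(h$records, `[[`, integer(1), "k"), 3:4)
  ## KS on identical re-extractions cannot reject
  expect_equal(h$records[[2]]$ks_tumor$statistic, 0)
  expect_equal(h$records[[2]]$ks_comp$statistic, 0)
  ## single-iteration special mapping: fatty / fibroglandular / malignant
  seg <- map_clusters(res$labeling)
  m <- tissue_masks(seg)
  expect_equal(sum(m$fatty), 400)
  expect_equal(sum(m$fibroglandular), 400)
  expect_equal(sum(m$malignant), 200)
  expect_equal(sum(m$transition), 0)
  expect_true(all(m$background == (f$values == f$sentinel)))
})

test_that("a structureless uniform ROI terminates with its final tests not rejected", {
  set.seed(17)
  v <- matrix(runif(1600, 20, 30), 40)
  roi <- disk_mask(40, 40, 17)
  f <- prepare_field(v, roi)
  res <- iterate_segmentation(f, restarts = 5, seed = 17)
  h <- res$history
  expect_true(h$converged)
  ks <- h$records[[length(h$records)]]
  expect_gte(ks$ks_tumor$p_value, h$alpha)
  expect_gte(ks$ks_comp$p_value, h$alpha)
  ## history bookkeeping: k strictly ascending from 3, background conserved
  kk <- vapply(h$records, `[[`, integer(1), "k")
  expect_equal(kk, seq(3L, h$final_k))
  for (r in h$records)
    expect_true(all((!r$tumor_mask & !r$comp_mask) == !roi))
})

test_that("an unreachable cluster-count cap raises a history-carrying error", {
  ## a heavy-tailed continuum keeps reshaping the top cluster, so a cap of
  ## k_max = 4 cannot satisfy the stopping rule
  set.seed(2)
  v <- matrix(rlnorm(2500, 3, 0.8), 50)
  f <- prepare_field(v, disk_mask(50, 50, 22))
  err <- tryCatch(iterate_segmentation(f, restarts = 3, seed = 2, k_max = 4),
                  error = identity)
  expect_s3_class(err, "mwiseg_no_convergence")
  expect_s3_class(err$history, "segmentation_history")
  expect_false(err$history$converged)
  expect_equal(vapply(err$history$records, `[[`, integer(1), "k"), 3:4)
})

test_that("cluster-to-tissue mapping follows the ascending-label rule", {
  fake <- function(k) {
    structure(list(labels = matrix(rep(1:k, 2), nrow = 2, byrow = TRUE),
                   centroids = seq_len(k), k = k, objective = 0),
              class = "cluster_labeling")
  }
  seg10 <- map_clusters(fake(10))
  lv <- function(seg, lab) seg$levels[seg$labels[1, lab]]
  expect_equal(lv(seg10, 7), "fibroglandular")
  expect_equal(lv(seg10, 1), "background")
  expect_equal(lv(seg10, 2), "fatty")
  expect_equal(lv(seg10, 3), "transition")
  expect_equal(lv(seg10, 4), "transition")
  expect_equal(lv(seg10, 10), "malignant")
  seg4 <- map_clusters(fake(4))
  expect_equal(vapply(2:4, lv, character(1), seg = seg4),
               c("fatty", "fibroglandular", "malignant"))
  expect_warning(seg5 <- map_clusters(fake(5)), "fibroglandular")
  expect_setequal(seg5$levels[unique(as.vector(seg5$labels))],
                  c("background", "fatty", "transition", "malignant"))
  expect_error(map_clusters(fake(3)), "at least 4")
})

test_that("a purely real image gives identical real and magnitude segmentations", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(61, 61),
                                      breast_radius_mm = 27,
                                      tumor_centers_mm = list(c(5, 3)),
                                      tumor_radii_mm = 4, seed = 31))
  img <- permittivity_image(ph$image$re, NULL, 1)   # drop the imaginary part
  roi <- contract_roi(ph$domain_mask, 3.5, 1)
  segs <- segment_components(img, roi, components = c("real", "magnitude"),
                             restarts = 5, seed = 31)
  expect_identical(segs$real$tissue$labels, segs$magnitude$tissue$labels)
  expect_equal(length(segs), 2L)
  expect_s3_class(segs$real$history, "segmentation_history")
})

test_that("the fitted model object exposes centroids, summary and areas", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(61, 61),
                                      breast_radius_mm = 27,
                                      tumor_centers_mm = list(c(5, 3)),
                                      tumor_radii_mm = 4, seed = 13))
  fit <- mwiseg(ph$image, domain = ph$domain_mask, components = "real",
                restarts = 5, seed = 13)
  expect_s3_class(fit, "mwiseg")
  co <- coef(fit)
  expect_true(all(diff(co$real) > 0))
  s <- summary(fit)
  expect_s3_class(s, "summary.mwiseg")
  tot <- sum(s$areas$pixels[s$areas$component == "real"])
  expect_equal(tot, length(ph$image$re))
  expect_output(print(fit), "final k")
})
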