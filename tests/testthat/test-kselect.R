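test_that("the one-standard-deviation drop rule picks the first real drop", {
  curve <- new_csf_curve(1:4, c(5, 4.9, 2, 1.9), rep(0.5, 4), 10L)
  sel <- select_one_sd(curve)
  expect_identical(sel$chosen_k, 3L)
  expect_identical(sel$rule, "one_sd")
  flat <- new_csf_curve(1:5, rep(2, 5), rep(0.3, 5), 10L)
  expect_identical(select_one_sd(flat)$chosen_k, 1L)
  # invariant to adding a constant to all means
  shifted <- new_csf_curve(1:4, c(5, 4.9, 2, 1.9) + 100, rep(0.5, 4), 10L)
  expect_identical(select_one_sd(shifted)$chosen_k, 3L)
})

test_that("uniform references sit at subinterval midpoints", {
  expect_equal(uniform_reference(c(0, 2, 5, 7, 10)), c(1, 3, 5, 7, 9))
  expect_equal(uniform_reference(c(0, 10)), c(2.5, 7.5))
  expect_equal(uniform_reference(c(3, 9, 3)), 3 + 6 / 3 * (1:3 - 0.5))
  expect_warning(ref0 <- uniform_reference(rep(4, 3)), "zero-width")
  expect_equal(ref0, rep(4, 3))
  # midpoint spacing is (max - min) / n exactly and items stay in range
  s <- c(-2, 13, 5, 6, 7, 8, 1)
  r <- uniform_reference(s)
  expect_equal(unique(round(diff(r), 12)), (max(s) - min(s)) / length(s))
  expect_true(all(r >= min(s) & r <= max(s)))
})

test_that("the grid reference extends per dimension over the bounding box", {
  box <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  g <- uniform_reference(box)
  expect_equal(g, rbind(c(0.25, 0.25), c(0.25, 0.75),
                        c(0.75, 0.25), c(0.75, 0.75)))
  # n items always, inside the box
  withr::with_seed(15, pts <- matrix(stats::rnorm(40), ncol = 2))
  g2 <- uniform_reference(pts)
  expect_identical(nrow(g2), 20L)
  expect_true(all(g2[, 1] >= min(pts[, 1]) & g2[, 1] <= max(pts[, 1])))
})

test_that("string references are seeded uniform strings of median length", {
  s <- template_class_strings(2, 5, 300, seed = 77)
  r1 <- uniform_reference(s, seed = 3)
  r2 <- uniform_reference(s, seed = 3)
  expect_identical(length(r1), length(s))
  expect_identical(unclass(r1), unclass(r2))
  expect_identical(length(as_raw <- r1[[1]]), 300L)
})

test_that("log-ratio selection maximizes D over the defined domain", {
  cs <- new_csf_curve(1:2, c(8, 2), c(0, 0), 1L)
  cn <- new_csf_curve(1:2, c(8, 8), c(0, 0), 1L)
  sel <- select_log_ratio(cs, cn)
  expect_identical(sel$chosen_k, 2L)
  expect_equal(sel$diagnostics$d, c(0, 2))
  # ties break to the smallest k
  equal <- select_log_ratio(cn, cn)
  expect_identical(equal$chosen_k, 1L)
  # zeros are excluded from the argmax domain
  cs0 <- new_csf_curve(1:3, c(4, 0, 1), c(0, 0, 0), 1L)
  cn0 <- new_csf_curve(1:3, c(4, 16, 1), c(0, 0, 0), 1L)
  expect_identical(select_log_ratio(cs0, cn0)$chosen_k, 1L)
  allzero <- new_csf_curve(1:2, c(0, 0), c(0, 0), 1L)
  expect_error(select_log_ratio(allzero, cn), "undefined")
  # antisymmetry under swapping the curves
  d1 <- select_log_ratio(cs, cn)$diagnostics$d
  d2 <- select_log_ratio(cn, cs)$diagnostics$d
  expect_equal(d1, -d2)
})

test_that("feature vectors concatenate means then spreads over K = 1..10", {
  curve <- new_csf_curve(1:10, rep(1, 10), rep(0, 10), 5L)
  expect_identical(csf_feature_vector(curve), c(rep(1, 10), rep(0, 10)))
  withr::with_seed(19, {
    c1 <- new_csf_curve(1:10, stats::runif(10), stats::runif(10), 5L)
    c2 <- new_csf_curve(1:10, stats::runif(10), stats::runif(10), 5L)
  })
  expect_length(csf_feature_vector(c1), 20L)
  expect_false(identical(csf_feature_vector(c1), csf_feature_vector(c2)))
  short <- new_csf_curve(1:5, rep(1, 5), rep(0, 5), 5L)
  expect_error(csf_feature_vector(short), "1..10")
})

test_that("gap statistic separates no-structure from well-separated blobs", {
  one <- as.matrix(gaussian_mixture(1, n_per_cluster = 150, seed = 5)[1:2])
  expect_identical(gap_statistic(one, k_max = 5, b = 10, seed = 5)$chosen_k,
                   1L)
  three <- as.matrix(gaussian_mixture(3, spacing = 10, n_per_cluster = 100,
                                      seed = 6)[1:2])
  expect_identical(gap_statistic(three, k_max = 5, b = 10,
                                 seed = 6)$chosen_k, 3L)
  # selection is stable in the number of reference draws
  expect_identical(gap_statistic(three, k_max = 5, b = 1, seed = 7)$chosen_k,
                   gap_statistic(three, k_max = 5, b = 20, seed = 7)$chosen_k)
})

test_that("AIC and BIC pick three well-separated blobs and agree on order", {
  three <- as.matrix(gaussian_mixture(3, spacing = 10, n_per_cluster = 100,
                                      seed = 8)[1:2])
  ab <- aic_bic_select(three, k_max = 6, seed = 8)
  expect_identical(ab$aic$chosen_k, 3L)
  expect_identical(ab$bic$chosen_k, 3L)
  # BIC penalizes harder, so it never selects more clusters than AIC here
  withr::with_seed(9, {
    for (i in 1:4) {
      pts <- as.matrix(gaussian_mixture(sample(1:3, 1), spacing = 4,
                                        n_per_cluster = 60,
                                        seed = 100 + i)[1:2])
      ab <- aic_bic_select(pts, k_max = 5, seed = i)
      expect_lte(ab$bic$chosen_k, ab$aic$chosen_k)
    }
  })
  # determinism for a fixed seed
  expect_identical(aic_bic_select(three, k_max = 4, seed = 2)$aic$chosen_k,
                   aic_bic_select(three, k_max = 4, seed = 2)$aic$chosen_k)
})

test_that("selection objects expose tidy, glance and autoplot", {
  curve <- new_csf_curve(1:4, c(5, 4.9, 2, 1.9), rep(0.5, 4), 10L)
  sel <- select_one_sd(curve)
  expect_identical(glance(sel)$chosen_k, 3L)
  expect_true("k" %in% names(tidy(sel)))
  expect_s3_class(autoplot(sel), "ggplot")
})
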