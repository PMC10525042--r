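test_that("criterion axioms hold for the bandwidth sum", {
  expect_identical(criterion_bandwidth_sum(list(1, 2, 3)), 0) # singletons
  expect_identical(criterion_bandwidth_sum(list(c(1, 3), c(0, 2))), 4)
  withr::with_seed(41, {
    for (i in 1:20) {
      # oracle-generated parts: the best-modeled member of each part sits
      # at deficiency 0, so zeroing the worst member cannot widen the band
      n <- sample(6:9, 1)
      oracle <- delta_stub(stats::runif(n, 0, 10))
      assignment <- sample(1:3, n, replace = TRUE)
      dl <- lapply(split(seq_len(n), assignment), function(p)
        vapply(p, function(j) oracle(p, j), numeric(1)))
      f0 <- criterion_bandwidth_sum(dl)
      p <- sample(seq_along(dl), 1)
      dl2 <- dl
      dl2[[p]][which.max(dl2[[p]])] <- 0
      expect_lte(criterion_bandwidth_sum(dl2), f0)
      expect_identical(criterion_bandwidth_sum(lapply(dl, function(d) d * 0)), 0)
    }
  })
})

test_that("exact structure function vanishes at k = n and at contiguous stubs", {
  oracle <- delta_stub(2 * (1:4))
  expect_identical(csf_exact(4, 4, oracle)$value, 0)
  r <- csf_exact(4, 2, oracle)
  expect_identical(r$value, 4) # contiguous complexity groups attain (n-k)*2
  expect_identical(sort(unique(r$witness)), 1:2)
  # k = 1: the single whole-set partition
  expect_identical(csf_exact(4, 1, oracle)$value,
                   criterion_bandwidth_sum(list(vapply(1:4, function(i)
                     oracle(1:4, i), numeric(1)))))
})

test_that("exact curves are monotone non-increasing and end at zero", {
  withr::with_seed(43, {
    for (i in 1:5) {
      n <- sample(5:7, 1)
      oracle <- delta_stub(stats::runif(n, 0, 20))
      curve <- csf_exact_curve(n, delta_fun = oracle)
      expect_true(all(diff(curve$mean_h) <= 1e-12))
      expect_identical(curve$mean_h[n], 0)
    }
  })
})

test_that("near-duplicate sets have zero structure function at every k", {
  # single-bit-flip construction: equal stub complexities, all bandwidths 0
  s <- bitflip_string_set(strrep("0", 8), 6)
  oracle <- delta_stub(rep(17, length(s)))
  for (k in seq_along(s)) {
    expect_identical(csf_exact(s, k, oracle)$value, 0)
  }
})

test_that("complexity-spread sets stay above m/n until the last k", {
  n <- 6
  m <- 60
  oracle <- delta_stub((1:n) * m / n)
  for (k in seq_len(n - 1)) {
    expect_gte(csf_exact(n, k, oracle)$value, m / n)
  }
  expect_identical(csf_exact(n, n, oracle)$value, 0)
})

test_that("sigma-trimmed structure function never exceeds the plain one", {
  withr::with_seed(47, {
    for (i in 1:4) {
      n <- sample(6:8, 1)
      oracle <- delta_stub(stats::runif(n, 0, 30))
      m <- length(sigma_trim(vapply(seq_len(n), function(j)
        oracle(seq_len(n), j), numeric(1)))$kept_ids)
      for (k in seq_len(m)) {
        expect_lte(csf_sigma(n, k, oracle)$value,
                   csf_exact(n, k, oracle)$value + 1e-12)
      }
      expect_identical(csf_sigma(n, m, oracle)$value, 0)
    }
  })
  # equal deficiencies: trim keeps everything, values coincide
  oracle <- delta_stub(rep(5, 5))
  expect_identical(csf_sigma(5, 2, oracle)$value,
                   csf_exact(5, 2, oracle)$value)
})

test_that("the subsampled structure value follows the log-bandwidth form", {
  expect_identical(log_bandwidth_value(list(c(0, 7)), 10), 0.3)
  expect_identical(log_bandwidth_value(list(1, 2, 3), 5), 0) # singletons
  expect_identical(log_bandwidth_value(list(numeric(0), c(2, 2)), 4), 0)
  # invariant under permuting cluster order and member order
  dl <- list(c(1, 5, 2), c(0, 3), 7)
  expect_identical(log_bandwidth_value(dl, 6),
                   log_bandwidth_value(rev(lapply(dl, rev)), 6))
})

test_that("two-class string sets drop from K = 1 to K = 2 empirically", {
  s <- template_class_strings(n_classes = 2, per_class = 25, length = 800,
                              seed = 61)
  curve <- csf_empirical(s, k_max = 3, n_subsamples = 60, seed = 61)
  expect_lt(curve$mean_h[2], curve$mean_h[1])
  expect_identical(curve$n_samples[1], 60L)
  expect_true(all(curve$sd_h >= 0))
  # rerun with the same seed is identical
  curve2 <- csf_empirical(s, k_max = 3, n_subsamples = 60, seed = 61)
  expect_equal(tidy(curve), tidy(curve2))
})

test_that("curve containers expose tidy, glance and autoplot", {
  curve <- new_csf_curve(1:4, c(4, 3, 2, 2), c(0.5, 0.4, 0.2, 0.2), 10L)
  expect_named(tidy(curve), c("k", "mean_h", "sd_h", "n_samples"))
  expect_identical(glance(curve)$k_at_min, 3L)
  p <- autoplot(curve)
  expect_s3_class(p, "ggplot")
})
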