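test_that("convex efficiency is exact for squares and below one for crosses", {
  img <- matrix(0, 40, 40)
  square <- as.vector(outer(6:15, (6:15 - 1) * 40, "+"))
  expect_equal(convex_efficiency(square, img), 1)
  # plus shape of 5 unit squares: hull is the 3x3 square minus 4 corner
  # triangles, area 9 - 4 * 1/2 = 7
  plus <- c(22 + (21:23 - 1) * 40, 21 + (22 - 1) * 40, 23 + (22 - 1) * 40)
  expect_equal(convex_efficiency(plus, img), 5 / 7)
  # a disk is nearly convex at pixel resolution
  yy <- matrix(1:40, 40, 40)
  xx <- t(yy)
  disk <- which((yy - 20.5)^2 + (xx - 20.5)^2 <= 20^2)
  expect_gt(convex_efficiency(disk, img), 0.95)
  # degenerate one-pixel-wide regions floor to 1
  line <- 5 + (10:20 - 1) * 40
  expect_equal(convex_efficiency(line, img), 1)
  expect_error(convex_efficiency(1:3, array(0, c(4, 4, 4))), "2-D")
})

test_that("boundary efficiency is one minus the mean rim excess", {
  img <- matrix(0.5, 20, 20)
  region <- as.vector(outer(5:10, (5:10 - 1) * 20, "+"))
  # threshold equal to the neighborhood maximum everywhere: R - T = 0
  expect_equal(boundary_efficiency(region, img, img), 1)
  # constant excess 0.2 on every boundary pixel
  expect_equal(boundary_efficiency(region, img, img - 0.2), 0.8)
  whole <- seq_along(img)
  expect_error(boundary_efficiency(whole, img, img), "no boundary")
})

test_that("background efficiency is the contrast ratio with a guard", {
  img <- matrix(0.5, 10, 10)
  thr <- matrix(0.1, 10, 10)
  region <- 1:20
  background <- 51:100
  thr[background] <- 0.4 # region I - T = 0.4, background I - T = 0.1
  expect_equal(background_efficiency(region, img, thr, background), 4)
  thr[background] <- 0.1 # equal statistics
  expect_equal(background_efficiency(region, img, thr, background), 1)
  thr[background] <- 0.5 # zero denominator
  expect_warning(
    capped <- background_efficiency(region, img, thr, background),
    "capping")
  expect_equal(capped, 10)
  expect_error(background_efficiency(region, img, thr, integer(0)), "empty")
})

test_that("candidate scores are the sum of the three efficiencies", {
  scene <- cell_image(n_cells = 3, seed = 101)
  sc <- score_candidates(scene$candidates, scene$image)
  expect_equal(sc$score, sc$e_convex + sc$e_boundary + sc$e_background)
  sc2 <- score_candidates(scene$candidates, scene$image)
  expect_equal(sc$score, sc2$score) # deterministic
  expect_true(all(sc$e_convex > 0 & sc$e_convex <= 1))
})

test_that("buckets are the components of the overlap graph", {
  r1 <- 1:10
  r2 <- 8:18 # overlaps r1
  r3 <- 15:25 # overlaps r2, not r1
  r4 <- 100:110 # disjoint
  cands <- tibble::tibble(id = 1:4, region = list(r1, r2, r3, r4),
                          n_px = lengths(list(r1, r2, r3, r4)))
  b <- bucket_overlaps(cands)
  expect_identical(b$bucket[1], b$bucket[2])
  expect_identical(b$bucket[2], b$bucket[3]) # transitive closure
  expect_false(b$bucket[4] == b$bucket[1])
  # 50 random rectangles agree with the brute-force component oracle
  rects <- random_rect_candidates(50, seed = 23)
  got <- bucket_overlaps(rects)$bucket
  want <- brute_overlap_components(rects$region)
  expect_identical(mode_label_accuracy(got, want)$accuracy, 1)
})

test_that("greedy selection is non-overlapping and respects score order", {
  a <- tibble::tibble(id = 1:2, region = list(1:10, 5:14),
                      n_px = c(10L, 10L), score = c(2.5, 2))
  sel <- greedy_select(a)
  expect_identical(sel$id, 1L)
  disjoint <- tibble::tibble(id = 1:3, region = list(1:5, 11:15, 21:25),
                             n_px = rep(5L, 3), score = c(1, 2, 3))
  expect_identical(sort(greedy_select(disjoint)$id), 1:3)
  # pairwise non-overlap always holds
  rects <- random_rect_candidates(30, seed = 31)
  sel <- greedy_select(rects)
  occ <- unlist(sel$region)
  expect_identical(anyDuplicated(occ), 0L)
})

test_that("greedy never beats the exhaustive optimum on small buckets", {
  withr::with_seed(37, {
    for (i in 1:40) {
      cands <- random_rect_candidates(sample(4:9, 1), seed = 400 + i)
      got <- sum(greedy_select(cands)$score)
      best <- brute_best_subset(cands$region, cands$score)
      expect_lte(got, best + 1e-9)
    }
  })
})

test_that("IoU-matched detection scores behave at the threshold", {
  truth <- list(1:100, 201:300)
  expect_equal(detection_f1(truth, truth)$f1, 1)
  expect_equal(detection_f1(list(400:450), truth)$f1, 0)
  # one truth split into two halves, each IoU < 0.5: recall 0
  halves <- list(1:49, 50:98) # each IoU 0.49, below the threshold
  r <- detection_f1(halves, list(1:100))
  expect_equal(r$recall, 0)
  expect_equal(r$tp, 0L)
  # label masks are accepted directly
  m <- matrix(0L, 10, 10)
  m[1:20] <- 1L
  m[51:70] <- 2L
  expect_equal(detection_f1(m, m)$f1, 1)
})

test_that("ensemble selection renders a disjoint label mask and report", {
  scene <- cell_image(n_cells = 4, seed = 55)
  sel <- select_ensemble(scene$candidates, scene$image)
  lab <- sel$mask[sel$mask > 0]
  expect_identical(sort(unique(lab)), seq_len(nrow(sel$selected)))
  occ <- unlist(sel$selected$region)
  expect_identical(anyDuplicated(occ), 0L)
  expect_identical(glance(sel)$n_selected, nrow(sel$selected))
  expect_s3_class(autoplot(sel), "ggplot")
})

test_that("label masks round-trip through 16-bit TIFF", {
  m <- matrix(0L, 12, 9)
  m[3:5, 2:4] <- 7L
  m[8:10, 5:7] <- 301L
  path <- withr::local_tempfile(fileext = ".tif")
  write_label_mask(m, path)
  expect_identical(read_label_mask(path), m)
  cands <- mask_to_candidates(m)
  expect_identical(cands$id, c(7L, 301L))
  expect_identical(cands$n_px, c(9L, 9L))
})
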