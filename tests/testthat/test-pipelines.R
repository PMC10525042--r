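test_that("the curve pipeline writes reproducible artifacts", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- list(input = list(kind = "simulate", n_classes = 2, per_class = 8,
                           length = 400, noise_rate = 0.02),
              k_max = 3, n_subsamples = 20, seed = 7, out_dir = out1)
  res <- run_curve(cfg)
  expect_true(all(file.exists(unlist(res$paths))))
  expect_s3_class(res$curve, "csf_curve")
  # identical config and seed give byte-identical outputs
  cfg$out_dir <- out2
  run_curve(cfg)
  for (f in c("curve.json", "curve.csv")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  sel <- jsonlite::read_json(file.path(out1, "selection.json"))
  expect_true(!is.null(sel$seed) && !is.null(sel$config_hash))
})

test_that("the curve pipeline fails cleanly on missing input", {
  out <- withr::local_tempdir()
  cfg <- list(input = list(kind = "strings_csv", path = "does-not-exist.csv"),
              out_dir = out)
  expect_error(run_curve(cfg), "not found")
  expect_false(file.exists(file.path(out, "curve.json")))
})

test_that("the ensemble pipeline combines masks into a disjoint labelling", {
  dir <- withr::local_tempdir()
  scene <- cell_image(n_cells = 4, seed = 29)
  img_path <- file.path(dir, "image.tif")
  tiff::writeTIFF(scene$image, img_path)
  mask_paths <- list()
  for (r in unique(scene$candidates$radius)) {
    sub <- scene$candidates[scene$candidates$radius == r, ]
    m <- matrix(0L, nrow(scene$image), ncol(scene$image))
    for (i in seq_len(nrow(sub))) m[sub$region[[i]]] <- i
    p <- file.path(dir, sprintf("mask_%s.tif", r))
    write_label_mask(m, p)
    mask_paths[[as.character(r)]] <- p
  }
  out <- file.path(dir, "out")
  res <- run_ensemble(list(image = img_path, candidates = mask_paths,
                           out_dir = out, seed = 29))
  expect_true(file.exists(res$paths$mask))
  final <- read_label_mask(res$paths$mask)
  expect_identical(dim(final), dim(scene$truth))
  labs <- final[final > 0]
  expect_identical(sort(unique(labs)), seq_len(max(final)))
  # rerunning writes identical mask bytes
  out2 <- file.path(dir, "out2")
  res2 <- run_ensemble(list(image = img_path, candidates = mask_paths,
                            out_dir = out2, seed = 29))
  expect_identical(readBin(res$paths$mask, "raw", 1e6),
                   readBin(res2$paths$mask, "raw", 1e6))
})

test_that("an ensemble run without candidates writes an empty mask", {
  dir <- withr::local_tempdir()
  img <- matrix(0.2, 32, 32)
  img_path <- file.path(dir, "img.tif")
  tiff::writeTIFF(img, img_path)
  blank <- file.path(dir, "blank.tif")
  write_label_mask(matrix(0L, 32, 32), blank)
  expect_warning(
    res <- run_ensemble(list(image = img_path,
                             candidates = list(blank),
                             out_dir = file.path(dir, "out"))),
    "no candidate")
  final <- read_label_mask(res$paths$mask)
  expect_identical(max(final), 0L)
})

test_that("shape mismatches between image and masks are rejected by name", {
  dir <- withr::local_tempdir()
  img_path <- file.path(dir, "img.tif")
  tiff::writeTIFF(matrix(0.4, 16, 16), img_path)
  bad <- file.path(dir, "bad.tif")
  write_label_mask(matrix(1L, 8, 8), bad)
  expect_error(run_ensemble(list(image = img_path, candidates = list(bad),
                                 out_dir = file.path(dir, "out"))),
               "bad.tif")
})
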