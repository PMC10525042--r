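#' Synthetic 2-D Gaussian mixtures
#'
#' Draws `k` clusters of standard bivariate normals (identity covariance)
#' with component `i` centered at `((i - 1) * spacing, 0)`, the benchmark
#' layout for cluster-number recovery. Fully determined by the seed.
#'
#' @param k Number of components.
#' @param spacing Center spacing along the x axis.
#' @param n_per_cluster Points per component.
#' @param seed Integer seed.
#' @return A tibble `x`, `y`, `label`.
#' @examples
#' pts <- gaussian_mixture(3, spacing = 1.5, n_per_cluster = 100, seed = 7)
#' dplyr::count(pts, label)
#' @export
gaussian_mixture <- function(k = 3L, spacing = 1, n_per_cluster = 500L,
                             seed = 1L) {
  stopifnot(k >= 1L, spacing > 0 || k == 1L, n_per_cluster >= 1L)
  withr::with_seed(seed, {
    purrr::map(seq_len(k), function(i) {
      tibble::tibble(x = stats::rnorm(n_per_cluster,
                                      mean = (i - 1) * spacing),
                     y = stats::rnorm(n_per_cluster),
                     label = as.integer(i))
    }) |> purrr::list_rbind()
  })
}

#' Single-bit-flip string sets
#'
#' The near-duplicate construction: `n` copies of a template bit string,
#' the `i`-th differing from the template exactly at position `i`. Under an
#' ideal complexity oracle such a set has structure-function value 0 at
#' every `k`; any two members differ in exactly two positions.
#'
#' @param template A bit string over `{0, 1}`.
#' @param n Number of flips (`n <= nchar(template)`).
#' @return An [object_set()] of bit strings.
#' @examples
#' unclass(bitflip_string_set("0000", 4))
#' @export
bitflip_string_set <- function(template, n = nchar(template)) {
  stopifnot(is.character(template), length(template) == 1L,
            !grepl("[^01]", template))
  if (n > nchar(template)) {
    stop("`n` exceeds the template length", call. = FALSE)
  }
  bits <- strsplit(template, "")[[1]]
  objs <- vapply(seq_len(n), function(i) {
    b <- bits
    b[i] <- if (b[i] == "0") "1" else "0"
    paste(b, collapse = "")
  }, character(1))
  object_set(objs, ids = sprintf("flip%02d", seq_len(n)))
}

#' Template-class byte strings
#'
#' A desk-scale analogue of a set of digit images drawn from a few classes:
#' each class has a seeded random byte template, and every object is its
#' class template with each byte independently resampled (from the class
#' alphabet) with probability `noise_rate`. Class templates are drawn over
#' alphabets of increasing size (4 up to 256 symbols across classes), so
#' classes differ in intrinsic compressibility the way real image classes
#' do — that difference is exactly what compression-based deficiencies pick
#' up.
#'
#' @param n_classes Number of classes.
#' @param per_class Objects per class.
#' @param length Template length in bytes.
#' @param noise_rate Per-byte resampling probability in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return An [object_set()] of raw byte strings with true class `labels`.
#' @export
template_class_strings <- function(n_classes = 2L, per_class = 50L,
                                   length = 1000L, noise_rate = 0.02,
                                   seed = 1L) {
  stopifnot(n_classes >= 1L, noise_rate >= 0, noise_rate < 0.5)
  alph <- if (n_classes == 1L) 16L else
    as.integer(round(4 * 64^((seq_len(n_classes) - 1) / (n_classes - 1))))
  alph <- pmin(pmax(alph, 2L), 256L)
  withr::with_seed(seed, {
    templates <- lapply(seq_len(n_classes), function(c) {
      sample.int(alph[c], length, replace = TRUE) - 1L
    })
    objs <- list()
    labels <- integer(0)
    for (c in seq_len(n_classes)) {
      for (j in seq_len(per_class)) {
        b <- templates[[c]]
        flip <- stats::runif(length) < noise_rate
        if (any(flip)) {
          b[flip] <- sample.int(alph[c], sum(flip), replace = TRUE) - 1L
        }
        objs[[base::length(objs) + 1L]] <- as.raw(b)
        labels <- c(labels, c)
      }
    }
  })
  object_set(objs, ids = sprintf("s%03d", seq_along(objs)), labels = labels)
}

#' Synthetic nuclear images with candidate segmentations
#'
#' Renders bright elliptical nuclei on a dark noisy background, with a
#' ground-truth label mask, and generates candidate segmentations per
#' expected-radius parameter the way a single-parameter segmenter would:
#' the image is thresholded, connected foreground components are split into
#' `round(area / (pi r^2))` pieces by seeded k-means on pixel coordinates,
#' so small radii over-segment and large radii merge touching cells.
#'
#' Each nucleus has a bright plateau out to half its semi-axes and a linear
#' intensity falloff to background at the full ellipse — the soft edge that
#' real fluorescence point-spread functions produce, and the gradient the
#' boundary efficiency needs in order to tell a true nuclear rim from a cut
#' through bright interior. The truth mask is the region above half the
#' contrast (the half-maximum footprint); candidate generation thresholds
#' lower (30 % of contrast), so close nuclei can merge into one foreground
#' component and large radius parameters under-segment them.
#'
#' @param n_cells Number of nuclei.
#' @param radius_range Semi-axis range in pixels (uniform draw per cell).
#' @param contrast Interior-minus-background intensity.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param size Image size `c(rows, cols)`.
#' @param seed Integer seed.
#' @param candidate_radii Radii at which candidate sets are generated.
#' @return A list of class `cell_scene`: `image` (matrix in `[0, 1]`),
#'   `truth` (integer label mask), `candidates` (tibble with `id`,
#'   `radius`, `region` list-column of pixel indices, `n_px`), `background`
#'   (background intensity level), `seed`.
#' @export
cell_image <- function(n_cells = 6L, radius_range = c(7, 10),
                       contrast = 0.6, noise_sd = 0.05,
                       size = c(128, 128), seed = 1L,
                       candidate_radii = c(4, 5.5, 7.5, 10, 13)) {
  bg_level <- 0.15
  withr::with_seed(seed, {
    truth <- matrix(0L, size[1], size[2])
    img <- matrix(bg_level, size[1], size[2])
    placed <- 0L
    tries <- 0L
    while (placed < n_cells && tries < 400L) {
      tries <- tries + 1L
      a <- stats::runif(1, radius_range[1], radius_range[2])
      b <- stats::runif(1, radius_range[1], radius_range[2])
      th <- stats::runif(1, 0, pi)
      r_max <- max(a, b)
      cy <- stats::runif(1, r_max + 2, size[1] - r_max - 2)
      cx <- stats::runif(1, r_max + 2, size[2] - r_max - 2)
      ell <- ellipse_profile(cy, cx, a, b, th, size)
      core <- ell$idx[ell$rho <= 0.75] # half-maximum footprint
      if (length(core) == 0L || any(truth[core] > 0L)) next
      placed <- placed + 1L
      truth[core] <- placed
      # plateau to rho = 0.5, linear falloff to background at rho = 1
      s <- pmin(1, pmax(0, (1 - ell$rho) / 0.5))
      img[ell$idx] <- pmax(img[ell$idx], bg_level + contrast * s)
    }
    if (placed < n_cells) {
      stop("could not place all cells without overlap; ",
           "reduce n_cells or radius", call. = FALSE)
    }
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), sd = noise_sd),
                          nrow(img))
    }
    img <- pmin(pmax(img, 0), 1)
    candidates <- candidate_masks(img, bg_level + 0.3 * contrast,
                                  candidate_radii, seed)
  })
  structure(list(image = img, truth = truth, candidates = candidates,
                 background = bg_level, seed = seed),
            class = "cell_scene")
}

ellipse_profile <- function(cy, cx, a, b, theta, size) {
  rr <- ceiling(max(a, b))
  ys <- max(1, floor(cy - rr)):min(size[1], ceiling(cy + rr))
  xs <- max(1, floor(cx - rr)):min(size[2], ceiling(cx + rr))
  grid <- expand.grid(y = ys, x = xs)
  dy <- grid$y - cy
  dx <- grid$x - cx
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  rho <- sqrt((u / a)^2 + (v / b)^2)
  inside <- rho <= 1
  list(idx = (grid$x[inside] - 1L) * size[1] + grid$y[inside],
       rho = rho[inside])
}

# Radius-parameterized candidate generation: denoise, threshold, label
# components, split each component into round(area / (pi r^2)) pieces with
# seeded k-means on pixel coordinates.
candidate_masks <- function(img, threshold, radii, seed) {
  smoothed <- EBImage::gblur(img, sigma = 1)
  fg <- matrix(as.numeric(smoothed), nrow(img)) > threshold
  lab <- EBImage::bwlabel(fg)
  lab <- matrix(as.integer(lab), nrow(img))
  comps <- split(which(lab > 0L), lab[lab > 0L])
  rows <- list()
  next_id <- 1L
  for (r in radii) {
    for (comp in comps) {
      area <- length(comp)
      if (area < 9L) next # specks are not candidate nuclei
      pieces <- max(1L, as.integer(round(area / (pi * r^2))))
      regions <- if (pieces == 1L) list(comp) else {
        coords <- cbind((comp - 1L) %% nrow(img) + 1L,
                        (comp - 1L) %/% nrow(img) + 1L)
        km <- withr::with_seed(seed + next_id, {
          stats::kmeans(coords, centers = min(pieces, area),
                        nstart = 5L, iter.max = 50L)
        })
        split(comp, km$cluster)
      }
      for (reg in regions) {
        if (length(reg) < 9L) next
        rows[[length(rows) + 1L]] <-
          tibble::tibble(id = next_id, radius = r,
                         region = list(sort(unname(reg))),
                         n_px = length(reg))
        next_id <- next_id + 1L
      }
    }
  }
  purrr::list_rbind(rows)
}
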