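#' Adaptive threshold image
#'
#' Local-mean threshold: for each pixel, the mean intensity over a square
#' window centered on it (clamped at the image border) minus a constant
#' offset. This is the `T` image entering the boundary and background
#' efficiencies.
#'
#' @param image Numeric matrix with intensities in `[0, 1]`.
#' @param window Odd window side in pixels.
#' @param offset Constant subtracted from the local mean. The default is
#'   tuned to the high-contrast fluorescence regime the synthetic scenes
#'   emulate (contrast about 0.6 over a 0.15 background); it anchors the
#'   background term of the candidate score so the ratio denominator stays
#'   well away from zero. Lower it for dimmer data.
#' @return A matrix of the same shape.
#' @export
adaptive_threshold <- function(image, window = 31L, offset = 0.4) {
  stopifnot(is.matrix(image), window >= 1L)
  h <- (as.integer(window) - 1L) %/% 2L
  nr <- nrow(image)
  nc <- ncol(image)
  # integral image with a zero top row / left column
  ii <- matrix(0, nr + 1L, nc + 1L)
  ii[-1L, -1L] <- apply(apply(image, 2, cumsum), 1, cumsum) |> t()
  r1 <- pmax(seq_len(nr) - h, 1L)
  r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1L)
  c2 <- pmin(seq_len(nc) + h, nc)
  sums <- ii[r2 + 1L, c2 + 1L] - ii[r1, c2 + 1L] - ii[r2 + 1L, c1] +
    ii[r1, c1]
  counts <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  sums / counts - offset
}

region_mask <- function(region, dims) {
  m <- matrix(FALSE, dims[1], dims[2])
  m[region] <- TRUE
  m
}

# Region pixels 8-adjacent to a non-region pixel inside the image
# (neighbours beyond the image border are ignored, so a region covering the
# whole image has no boundary).
boundary_pixels <- function(region, dims) {
  m <- region_mask(region, dims)
  nr <- dims[1]
  nc <- dims[2]
  inner <- matrix(TRUE, nr, nc)
  for (dy in -1:1) {
    for (dx in -1:1) {
      if (dy == 0L && dx == 0L) next
      ys <- seq_len(nr) + dy
      xs <- seq_len(nc) + dx
      oky <- ys >= 1L & ys <= nr
      okx <- xs >= 1L & xs <= nc
      inner[oky, okx] <- inner[oky, okx] & m[ys[oky], xs[okx]]
    }
  }
  region[!inner[region]]
}

max_filter3 <- function(image) {
  nr <- nrow(image)
  nc <- ncol(image)
  out <- image
  for (dy in -1:1) {
    for (dx in -1:1) {
      if (dy == 0L && dx == 0L) next
      ys <- seq_len(nr) + dy
      xs <- seq_len(nc) + dx
      oky <- ys >= 1L & ys <= nr
      okx <- xs >= 1L & xs <= nc
      out[oky, okx] <- pmax(out[oky, okx], image[ys[oky], xs[okx]])
    }
  }
  out
}

#' Segmentation efficiency terms
#'
#' Three normalized measures of how well a candidate region matches the
#' nuclear appearance model (convex, brighter inside than out, sharp
#' boundary):
#'
#' * `convex_efficiency()`: region area divided by the area of its convex
#'   hull, computed on the unit squares of the region's pixels (hull of the
#'   pixel corners), in `(0, 1]`; degenerate single-pixel-wide regions are
#'   floored to 1.
#' * `boundary_efficiency()`: `1 - mean(R - T)` over the region's boundary
#'   pixels, where `R` is the maximal intensity in the 3x3 neighborhood of
#'   each boundary pixel and `T` the adaptive threshold there. A boundary
#'   sitting exactly on the threshold scores 1; a boundary cutting through
#'   bright interior scores lower.
#' * `background_efficiency()`: `mean(I - T)` over the region divided by
#'   `mean(I - T)` over the image background; near-zero denominators are
#'   capped at `cap` with a warning. Unclamped above by design.
#'
#' @param region Integer vector of pixel (linear) indices.
#' @param image Numeric intensity matrix in `[0, 1]`.
#' @param threshold Adaptive threshold matrix ([adaptive_threshold()]).
#' @param background Integer indices of background pixels (typically the
#'   complement of all candidate supports).
#' @param cap Cap for a degenerate background denominator.
#' @param eps Denominator guard.
#' @return A single number.
#' @name efficiencies
NULL

#' @rdname efficiencies
#' @export
convex_efficiency <- function(region, image) {
  dims <- dim(image)
  if (is.null(dims) || length(dims) != 2L) {
    stop("convex_efficiency() supports 2-D images only", call. = FALSE)
  }
  stopifnot(length(region) >= 1L)
  y <- (region - 1L) %% dims[1] + 1L
  x <- (region - 1L) %/% dims[1] + 1L
  corners <- cbind(c(x - 0.5, x + 0.5, x - 0.5, x + 0.5),
                   c(y - 0.5, y - 0.5, y + 0.5, y + 0.5))
  hull <- grDevices::chull(corners)
  hx <- corners[hull, 1]
  hy <- corners[hull, 2]
  area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  length(region) / max(area, length(region))
}

#' @rdname efficiencies
#' @export
boundary_efficiency <- function(region, image, threshold) {
  dims <- dim(image)
  beta <- boundary_pixels(region, dims)
  if (length(beta) == 0L) {
    stop("region has no boundary (covers the whole image)", call. = FALSE)
  }
  r <- max_filter3(image)
  1 - mean(r[beta] - threshold[beta])
}

#' @rdname efficiencies
#' @export
background_efficiency <- function(region, image, threshold, background,
                                  cap = 10, eps = 1e-3) {
  if (length(background) == 0L) {
    stop("background is empty", call. = FALSE)
  }
  num <- mean(image[region] - threshold[region])
  den <- mean(image[background] - threshold[background])
  if (abs(den) < eps) {
    warning("near-zero background contrast; capping background efficiency",
            call. = FALSE)
    return(cap)
  }
  num / den
}

#' Score candidate segmentations
#'
#' Applies the three efficiency terms to every candidate and records their
#' sum as the candidate score. The background used in the background
#' efficiency is the complement of the union of all candidate supports
#' (unless supplied).
#'
#' @param candidates A tibble with columns `id`, `region` (list of pixel
#'   index vectors), and optionally `radius`; e.g. the `candidates` of a
#'   [cell_image()] scene or [mask_to_candidates()].
#' @param image Intensity matrix in `[0, 1]`.
#' @param threshold Optional precomputed [adaptive_threshold()].
#' @param background Optional background pixel indices.
#' @param cap Background-efficiency cap.
#' @return The candidate tibble with `e_convex`, `e_boundary`,
#'   `e_background` and `score` columns.
#' @export
score_candidates <- function(candidates, image, threshold = NULL,
                             background = NULL, cap = 10) {
  stopifnot(is.matrix(image))
  if (is.null(threshold)) threshold <- adaptive_threshold(image)
  if (is.null(background)) {
    support <- unique(unlist(candidates$region))
    background <- setdiff(seq_along(image), support)
  }
  candidates |>
    dplyr::mutate(
      e_convex = purrr::map_dbl(.data$region, convex_efficiency,
                                image = image),
      e_boundary = purrr::map_dbl(.data$region, boundary_efficiency,
                                  image = image, threshold = threshold),
      e_background = purrr::map_dbl(.data$region, background_efficiency,
                                    image = image, threshold = threshold,
                                    background = background, cap = cap),
      score = .data$e_convex + .data$e_boundary + .data$e_background)
}

#' Bucket overlapping candidates
#'
#' Candidates whose regions share at least one pixel (or at least
#' `min_overlap_frac` of the smaller region) are connected; buckets are the
#' connected components of that overlap graph, so selection can run
#' independently per bucket. Bucket pixel supports are pairwise disjoint.
#'
#' @param candidates Candidate tibble with `id` and `region` columns.
#' @param min_overlap_frac Minimum shared fraction of the smaller region
#'   for an overlap edge (0 means any shared pixel).
#' @return The input tibble with a `bucket` integer column.
#' @export
bucket_overlaps <- function(candidates, min_overlap_frac = 0) {
  n <- nrow(candidates)
  if (n == 0L) return(dplyr::mutate(candidates, bucket = integer(0)))
  edges <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ov <- length(intersect(candidates$region[[i]],
                             candidates$region[[j]]))
      lim <- min_overlap_frac * min(length(candidates$region[[i]]),
                                    length(candidates$region[[j]]))
      if (ov > 0 && ov >= lim) edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  dplyr::mutate(candidates, bucket = as.integer(comp))
}

#' Greedy non-overlapping selection
#'
#' Repeatedly takes the highest-scoring remaining candidate and discards
#' every candidate overlapping it; ties break toward the larger region,
#' then the smaller id. The output is always pairwise non-overlapping, and
#' its total score never exceeds the exhaustive optimum.
#'
#' @param scored A scored candidate tibble ([score_candidates()]); may be a
#'   single bucket or the whole ensemble (equivalent results).
#' @return The selected rows of `scored`.
#' @export
greedy_select <- function(scored) {
  ord <- order(-scored$score, -lengths(scored$region), scored$id)
  taken <- logical(nrow(scored))
  occupied <- integer(0)
  for (i in ord) {
    reg <- scored$region[[i]]
    if (!any(reg %in% occupied)) {
      taken[i] <- TRUE
      occupied <- c(occupied, reg)
    }
  }
  scored[taken, , drop = FALSE]
}

#' Ensemble segmentation selection
#'
#' The full ensemble combination: score all candidates, bucket overlapping
#' ones, greedily select a non-overlapping maximum-score subset per bucket,
#' and render the selection as a label mask.
#'
#' @inheritParams score_candidates
#' @param min_overlap_frac Overlap-edge threshold for bucketing.
#' @return A list of class `ensemble_selection`: `selected` (scored rows
#'   with `bucket`), `candidates` (all scored rows with `bucket`), `mask`
#'   (integer label matrix), `image`.
#' @export
select_ensemble <- function(candidates, image, threshold = NULL,
                            background = NULL, cap = 10,
                            min_overlap_frac = 0) {
  scored <- score_candidates(candidates, image, threshold, background, cap)
  scored <- bucket_overlaps(scored, min_overlap_frac)
  selected <- scored |>
    dplyr::group_by(.data$bucket) |>
    dplyr::group_modify(~ greedy_select(.x)) |>
    dplyr::ungroup()
  mask <- matrix(0L, nrow(image), ncol(image))
  for (i in seq_len(nrow(selected))) {
    mask[selected$region[[i]]] <- i
  }
  structure(list(selected = selected, candidates = scored, mask = mask,
                 image = image),
            class = "ensemble_selection")
}

#' @export
print.ensemble_selection <- function(x, ...) {
  cat(sprintf("<ensemble_selection: %d of %d candidates kept in %d buckets>\n",
              nrow(x$selected), nrow(x$candidates),
              length(unique(x$candidates$bucket))))
  invisible(x)
}

#' @export
tidy.ensemble_selection <- function(x, ...) {
  dplyr::select(x$selected, -"region")
}

#' @export
glance.ensemble_selection <- function(x, ...) {
  tibble::tibble(n_candidates = nrow(x$candidates),
                 n_selected = nrow(x$selected),
                 n_buckets = length(unique(x$candidates$bucket)),
                 total_score = sum(x$selected$score))
}

#' @export
autoplot.ensemble_selection <- function(object, ...) {
  img <- object$image
  df <- tidyr::expand_grid(y = seq_len(nrow(img)), x = seq_len(ncol(img)))
  df$intensity <- as.vector(img)
  sel <- purrr::imap(object$selected$region, function(reg, i) {
    tibble::tibble(cell = i,
                   y = (reg - 1L) %% nrow(img) + 1L,
                   x = (reg - 1L) %/% nrow(img) + 1L)
  }) |> purrr::list_rbind()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::geom_tile(data = sel,
                       ggplot2::aes(colour = factor(.data$cell)),
                       fill = NA, linewidth = 0, alpha = 0.2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(fill = "I")
}

#' IoU-matched detection scores
#'
#' Precision, recall and F1 of a selected region set against ground-truth
#' regions: candidate/truth pairs are matched one-to-one greedily by
#' descending intersection-over-union, a match requiring IoU at or above
#' the threshold.
#'
#' @param selected,truth Lists of pixel-index regions (or label masks,
#'   converted via [mask_to_candidates()]).
#' @param iou_threshold Minimum IoU for a match.
#' @return A tibble `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
detection_f1 <- function(selected, truth, iou_threshold = 0.5) {
  sel <- as_region_list(selected)
  tru <- as_region_list(truth)
  ns <- length(sel)
  nt <- length(tru)
  pairs <- list()
  for (i in seq_len(ns)) {
    for (j in seq_len(nt)) {
      inter <- length(intersect(sel[[i]], tru[[j]]))
      if (inter == 0L) next
      un <- length(sel[[i]]) + length(tru[[j]]) - inter
      iou <- inter / un
      if (iou >= iou_threshold) {
        pairs[[length(pairs) + 1L]] <- c(i, j, iou)
      }
    }
  }
  tp <- 0L
  if (length(pairs)) {
    pm <- do.call(rbind, pairs)
    pm <- pm[order(-pm[, 3]), , drop = FALSE]
    used_s <- logical(ns)
    used_t <- logical(nt)
    for (r in seq_len(nrow(pm))) {
      i <- pm[r, 1]
      j <- pm[r, 2]
      if (!used_s[i] && !used_t[j]) {
        used_s[i] <- TRUE
        used_t[j] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  fp <- ns - tp
  fn <- nt - tp
  precision <- if (ns > 0) tp / ns else 0
  recall <- if (nt > 0) tp / nt else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble::tibble(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1)
}

as_region_list <- function(x) {
  if (is.matrix(x)) return(mask_to_candidates(x)$region)
  if (is.data.frame(x)) return(x$region)
  if (inherits(x, "ensemble_selection")) return(x$selected$region)
  x
}

#' Label masks as candidate tables
#'
#' Converts an integer label mask (0 = background) into a candidate tibble
#' with one region per label, and back.
#'
#' @param mask Integer label matrix.
#' @param radius Optional radius annotation for all regions.
#' @return A tibble `id`, `radius`, `region`, `n_px`.
#' @export
mask_to_candidates <- function(mask, radius = NA_real_) {
  stopifnot(is.matrix(mask))
  labs <- sort(unique(mask[mask > 0]))
  regions <- lapply(labs, function(l) which(mask == l))
  tibble::tibble(id = as.integer(labs), radius = radius, region = regions,
                 n_px = lengths(regions))
}

#' Read and write 16-bit label TIFF masks
#'
#' @param mask Integer label matrix (0 = background, labels < 65536).
#' @param path File path.
#' @return `read_label_mask()` returns an integer matrix.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), max(mask) < 65536L)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}
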