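#' K selection results
#'
#' A `k_selection` couples a chosen number of clusters with the rule that
#' produced it and the per-k diagnostic values of that rule.
#'
#' @param chosen_k Selected number of clusters.
#' @param rule Rule name (`"one_sd"`, `"log_ratio"`, `"gap"`, `"aic"`,
#'   `"bic"`).
#' @param diagnostics A tibble with a `k` column and rule-specific values.
#' @return A `k_selection` object.
#' @export
new_k_selection <- function(chosen_k, rule, diagnostics) {
  structure(list(chosen_k = as.integer(chosen_k), rule = rule,
                 diagnostics = diagnostics),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("K = %d selected by rule '%s'\n", x$chosen_k, x$rule))
  invisible(x)
}

#' @export
tidy.k_selection <- function(x, ...) x$diagnostics

#' @export
glance.k_selection <- function(x, ...) {
  tibble::tibble(chosen_k = x$chosen_k, rule = x$rule)
}

#' @export
autoplot.k_selection <- function(object, ...) {
  d <- object$diagnostics
  ycol <- setdiff(names(d), "k")[1]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data[[ycol]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = 2) +
    ggplot2::labs(x = "number of clusters k", y = ycol,
                  title = sprintf("K = %d (%s)", object$chosen_k,
                                  object$rule))
}

#' One-standard-deviation drop rule
#'
#' Chooses the smallest `K >= 2` at which the curve decreases by more than
#' one standard deviation from its previous value:
#' `mean_h(K-1) - mean_h(K) > sd_h(K-1)`. If no drop qualifies, `K = 1`
#' (no meaningful clusters). The rule is invariant to adding a constant to
#' all means.
#'
#' @param curve A [csf_curve] with at least two rows.
#' @return A [new_k_selection()] with per-k `drop` and `threshold`
#'   diagnostics.
#' @export
select_one_sd <- function(curve) {
  stopifnot(nrow(curve) >= 2L)
  m <- curve$mean_h
  s <- curve$sd_h
  drop <- c(NA_real_, m[-length(m)] - m[-1])
  threshold <- c(NA_real_, s[-length(s)])
  qualifies <- !is.na(drop) & drop > threshold
  chosen <- if (any(qualifies)) curve$k[which(qualifies)[1]] else 1L
  new_k_selection(chosen, "one_sd",
                  tibble::tibble(k = curve$k, mean_h = m, drop = drop,
                                 threshold = threshold,
                                 qualifies = qualifies))
}

#' Uniform reference placement
#'
#' Builds the reference set the log-ratio selection compares against: the
#' same number of items distributed uniformly over the range spanned by the
#' data. For a numeric vector the range `[min, max]` is divided into `n`
#' equal subintervals and item `i` sits at the midpoint of subinterval `i`.
#' For a numeric matrix the construction extends per dimension over the
#' bounding box: the smallest uniform grid with at least `n` cells is laid
#' out and truncated to `n` midpoints in row-major order. For an
#' [object_set()] of byte strings the reference is seeded uniform random
#' strings of the median length (the 1-D interval construction has no
#' string analogue, so uniformity is taken over byte values).
#'
#' @param s A numeric vector, a numeric matrix (rows = points), or an
#'   `object_set` of strings/raw objects.
#' @param seed Seed for the string variant.
#' @return An object of the same kind as `s` with the same number of items.
#' @examples
#' uniform_reference(c(0, 2, 5, 7, 10))  # 1, 3, 5, 7, 9
#' @export
uniform_reference <- function(s, seed = 1L) {
  if (is.matrix(s)) return(uniform_reference_grid(s))
  if (inherits(s, "object_set")) return(uniform_reference_strings(s, seed))
  stopifnot(is.numeric(s), length(s) >= 1L)
  n <- length(s)
  lo <- min(s)
  hi <- max(s)
  if (hi - lo <= 0) {
    warning("zero-width range; all reference items coincide", call. = FALSE)
    return(rep(lo, n))
  }
  w <- (hi - lo) / n
  lo + w * (seq_len(n) - 0.5)
}

uniform_reference_grid <- function(s) {
  n <- nrow(s)
  d <- ncol(s)
  m <- ceiling(n^(1 / d)) # per-dimension cells; smallest grid with >= n
  mids <- lapply(seq_len(d), function(j) {
    lo <- min(s[, j])
    hi <- max(s[, j])
    if (hi - lo <= 0) {
      warning("zero-width range in dimension ", j, call. = FALSE)
      return(rep(lo, m))
    }
    lo + (hi - lo) / m * (seq_len(m) - 0.5)
  })
  grid <- as.matrix(expand.grid(rev(mids)))[, d:1, drop = FALSE] # row-major
  dimnames(grid) <- NULL
  if (!is.null(colnames(s))) colnames(grid) <- colnames(s)
  grid[seq_len(n), , drop = FALSE]
}

uniform_reference_strings <- function(set, seed) {
  lens <- vapply(unclass(set), function(e) length(as_bytes(e)), integer(1))
  len <- as.integer(stats::median(lens))
  withr::with_seed(seed, {
    objs <- lapply(seq_along(set), function(i)
      as.raw(sample.int(256L, len, replace = TRUE) - 1L))
  })
  object_set(objs, ids = paste0("ref", seq_along(set)))
}

#' Uniform-reference log-ratio selection
#'
#' `D(k) = log2 H_N(k) - log2 H_S(k)`, where `H_N` is the structure
#' function of the uniform reference placement and `H_S` that of the data.
#' The number of clusters is the `k` maximizing `D(k)` over the values of
#' `k` at which both curves are strictly positive (the log is undefined at
#' zero); ties break toward the smallest `k`. `D` is antisymmetric under
#' swapping the two curves.
#'
#' @param curve_s Data [csf_curve].
#' @param curve_n Reference [csf_curve] on the same k grid.
#' @return A [new_k_selection()] with per-k `d` diagnostics (NA where
#'   undefined).
#' @export
select_log_ratio <- function(curve_s, curve_n) {
  if (!identical(curve_s$k, curve_n$k)) {
    stop("curves must share the same k grid", call. = FALSE)
  }
  ok <- curve_s$mean_h > 0 & curve_n$mean_h > 0
  d <- ifelse(ok, log2(curve_n$mean_h) - log2(curve_s$mean_h), NA_real_)
  if (!any(ok)) {
    stop("log-ratio selection undefined: no k with both curves positive",
         call. = FALSE)
  }
  chosen <- curve_s$k[ok][which.max(d[ok])] # which.max: smallest on ties
  new_k_selection(chosen, "log_ratio",
                  tibble::tibble(k = curve_s$k, d = d))
}

#' CSF feature vector
#'
#' The 20-component summary used to train a supervised predictor of the
#' number of clusters: the per-k means of the curve over `K = 1..10`
#' followed by the per-k standard deviations, in that order.
#'
#' @param curve A [csf_curve] over exactly `k = 1..10`.
#' @return A numeric vector of length 20.
#' @export
csf_feature_vector <- function(curve) {
  if (!identical(curve$k, 1:10)) {
    stop("the feature vector is defined for curves over K = 1..10",
         call. = FALSE)
  }
  c(curve$mean_h, curve$sd_h)
}

#' Gap statistic baseline
#'
#' Compares the within-cluster dispersion of the data under k-means to that
#' of uniform reference draws over the data's bounding box:
#' `gap(k) = mean_b log(W_k^ref_b) - log(W_k)`, with the usual
#' one-standard-error selection (smallest `k` with
#' `gap(k) >= gap(k+1) - se(k+1)`).
#'
#' @param points Numeric matrix or data frame of points (rows = points).
#' @param k_max Largest `k` scanned.
#' @param b Number of reference draws.
#' @param seed Integer seed.
#' @return A [new_k_selection()] with `gap` and `se` diagnostics.
#' @export
gap_statistic <- function(points, k_max = 10L, b = 20L, seed = 1L) {
  x <- as.matrix(points)
  n <- nrow(x)
  k_max <- as.integer(k_max)
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  withr::with_seed(seed, {
    logw <- vapply(seq_len(k_max), function(k) log(kmeans_wss(x, k)),
                   numeric(1))
    logw_ref <- matrix(NA_real_, b, k_max)
    for (bb in seq_len(b)) {
      ref <- vapply(seq_along(lo), function(j) stats::runif(n, lo[j], hi[j]),
                    numeric(n))
      logw_ref[bb, ] <- vapply(seq_len(k_max), function(k)
        log(kmeans_wss(ref, k)), numeric(1))
    }
  })
  gap <- colMeans(logw_ref) - logw
  se <- if (b > 1L) apply(logw_ref, 2, stats::sd) * sqrt(1 + 1 / b)
        else rep(0, k_max)
  chosen <- k_max
  for (k in seq_len(k_max - 1L)) {
    if (gap[k] >= gap[k + 1L] - se[k + 1L]) {
      chosen <- k
      break
    }
  }
  new_k_selection(chosen, "gap",
                  tibble::tibble(k = seq_len(k_max), gap = gap, se = se))
}

kmeans_wss <- function(x, k) {
  if (k == 1L) {
    return(max(sum(scale(x, scale = FALSE)^2), 1e-12))
  }
  km <- stats::kmeans(x, centers = k, nstart = 10L, iter.max = 200L)
  max(km$tot.withinss, 1e-12)
}

#' AIC and BIC baselines for the number of clusters
#'
#' Fits seeded k-means for each `k` and scores a spherical-Gaussian
#' mixture likelihood with hard assignments: `p = k d + (k - 1) + 1` free
#' parameters (centers, mixing weights, one shared variance),
#' `AIC = 2 p - 2 ln L`, `BIC = p ln n - 2 ln L`; the chosen `k` minimizes
#' the criterion.
#'
#' @inheritParams gap_statistic
#' @return A named list of two [new_k_selection()]s (`aic`, `bic`).
#' @export
aic_bic_select <- function(points, k_max = 10L, seed = 1L) {
  x <- as.matrix(points)
  n <- nrow(x)
  d <- ncol(x)
  k_max <- as.integer(k_max)
  withr::with_seed(seed, {
    fits <- lapply(seq_len(k_max), function(k) {
      if (k == 1L) {
        wss <- sum(scale(x, scale = FALSE)^2)
        list(sizes = n, wss = wss)
      } else {
        km <- stats::kmeans(x, centers = k, nstart = 10L, iter.max = 200L)
        list(sizes = km$size, wss = km$tot.withinss)
      }
    })
  })
  ll <- vapply(seq_len(k_max), function(k) {
    f <- fits[[k]]
    s2 <- max(f$wss / (n * d), 1e-12)
    sum(f$sizes * log(f$sizes / n)) - n * d / 2 * log(2 * pi * s2) -
      n * d / 2
  }, numeric(1))
  p <- seq_len(k_max) * d + (seq_len(k_max) - 1L) + 1L
  aic <- 2 * p - 2 * ll
  bic <- p * log(n) - 2 * ll
  diag_tbl <- tibble::tibble(k = seq_len(k_max), loglik = ll, aic = aic,
                             bic = bic)
  list(aic = new_k_selection(which.min(aic), "aic", diag_tbl[c("k", "aic")]),
       bic = new_k_selection(which.min(bic), "bic", diag_tbl[c("k", "bic")]))
}
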