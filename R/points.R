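#' Euclidean deficiency approximation for numeric points
#'
#' For numeric point data the complexity difference between a cluster and a
#' member is approximated by the Euclidean distance from the point to the
#' cluster centroid. `euclidean_delta()` returns that distance;
#' `trimmed_cluster_value()` aggregates a cluster, averaging only the
#' points within one standard deviation of the centroid — read radially:
#' points whose distance to the centroid is at most the standard deviation
#' of all member distances. A cluster that would lose every point to the
#' trim retains its nearest point as a floor (single-point clusters
#' therefore always contribute 0).
#'
#' @param cluster A numeric matrix of cluster member points (rows).
#' @param x A single point (numeric vector).
#' @return `euclidean_delta()`: the distance to the centroid.
#' @export
euclidean_delta <- function(cluster, x) {
  cluster <- as.matrix(cluster)
  stopifnot(nrow(cluster) >= 1L)
  centroid <- colMeans(cluster)
  sqrt(sum((as.numeric(x) - centroid)^2))
}

#' @rdname euclidean_delta
#' @param distances Member distances to the cluster centroid.
#' @param trim Apply the one-standard-deviation radial trim?
#' @export
trimmed_cluster_value <- function(distances, trim = TRUE) {
  if (length(distances) == 0L) return(0)
  if (!trim) return(mean(distances))
  s <- stats::sd(distances)
  if (is.na(s)) return(distances[1]) # single point: always retained
  kept <- distances[distances <= s]
  if (length(kept) == 0L) kept <- min(distances)
  mean(kept)
}

#' Cluster structure function for numeric points
#'
#' The Euclidean-deficiency variant of the empirical pipeline, for point
#' clouds where compression is replaced by geometry. For each `k` the
#' points are clustered by seeded k-means; each cluster is summarized by
#' its trimmed mean distance to the centroid ([trimmed_cluster_value()]),
#' and the structure-function value is the average across clusters. With
#' `n_subsamples > 0`, cluster assignments are computed once on the full
#' set and the value is recomputed on random subsamples of `5 * k` points
#' to attach a spread to each `k`; otherwise the curve is deterministic
#' with zero spread.
#'
#' @param points Numeric matrix or data frame with one row per point
#'   (a `label` column, if present, is ignored).
#' @param k_max Largest number of clusters scanned.
#' @param seed Integer seed.
#' @param n_subsamples Subsamples per `k` (0 for the deterministic curve).
#' @param trim Apply the radial one-standard-deviation trim.
#' @return A [csf_curve] tibble.
#' @export
csf_points <- function(points, k_max, seed = 1L, n_subsamples = 0L,
                       trim = TRUE) {
  x <- points_matrix(points)
  n <- nrow(x)
  k_max <- as.integer(k_max)
  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(k_max), function(k) {
      labels <- if (k == 1L) rep(1L, n) else
        as.integer(stats::kmeans(x, centers = k, nstart = 10L,
                                 iter.max = 200L)$cluster)
      dist_to_centroid <- numeric(n)
      for (p in split(seq_len(n), labels)) {
        ctr <- colMeans(x[p, , drop = FALSE])
        dist_to_centroid[p] <- sqrt(colSums((t(x[p, , drop = FALSE]) -
                                               ctr)^2))
      }
      value_of <- function(idx) {
        mean(vapply(split(idx, labels[idx]), function(p)
          trimmed_cluster_value(dist_to_centroid[p], trim), numeric(1)))
      }
      if (n_subsamples > 0L) {
        h <- vapply(seq_len(n_subsamples), function(b)
          value_of(sample.int(n, min(5L * k, n))), numeric(1))
        tibble::tibble(k = k, mean_h = mean(h), sd_h = stats::sd(h))
      } else {
        tibble::tibble(k = k, mean_h = value_of(seq_len(n)), sd_h = 0)
      }
    }) |> purrr::list_rbind()
  })
  new_csf_curve(rows$k, rows$mean_h, rows$sd_h,
                n_samples = max(1L, n_subsamples), kind = "points")
}

#' Select the number of clusters for numeric points
#'
#' Runs [csf_points()] on the data and on its [uniform_reference()]
#' placement and selects `k` by the uniform-reference log-ratio
#' ([select_log_ratio()], the default), or by the one-standard-deviation
#' drop rule on the subsampled curve.
#'
#' @inheritParams csf_points
#' @param rule `"log_ratio"` or `"one_sd"`.
#' @param n_subsamples Subsamples per `k` for the `"one_sd"` rule.
#' @return A [new_k_selection()] with the data curve attached as attribute
#'   `curve`.
#' @export
select_k_points <- function(points, k_max = 6L,
                            rule = c("log_ratio", "one_sd"), seed = 1L,
                            n_subsamples = 50L, trim = TRUE) {
  rule <- match.arg(rule)
  x <- points_matrix(points)
  if (rule == "log_ratio") {
    curve_s <- csf_points(x, k_max, seed = seed, trim = trim)
    ref <- uniform_reference(x)
    curve_n <- csf_points(ref, k_max, seed = seed + 1L, trim = trim)
    sel <- select_log_ratio(curve_s, curve_n)
  } else {
    curve_s <- csf_points(x, k_max, seed = seed,
                          n_subsamples = n_subsamples, trim = trim)
    sel <- select_one_sd(curve_s)
  }
  attr(sel, "curve") <- curve_s
  sel
}

points_matrix <- function(points) {
  if (is.data.frame(points)) {
    points <- points[, setdiff(names(points), "label"), drop = FALSE]
  }
  x <- as.matrix(points)
  storage.mode(x) <- "double"
  x
}

#' Cluster-number recovery benchmark on Gaussian mixtures
#'
#' Draws repeated synthetic mixtures ([gaussian_mixture()]) and asks each
#' method for the number of clusters, returning one row per trial and
#' method. Methods: the Euclidean-deficiency cluster structure function
#' (`"csf"`, via [select_k_points()]), `"aic"`, `"bic"` and `"gap"`.
#'
#' @param n_trials Number of independent trials.
#' @param k_true Number of mixture components.
#' @param spacing Component spacing along the x axis.
#' @param n_per_cluster Points per component.
#' @param k_max Largest `k` scanned.
#' @param seed Base seed; trial `i` uses `seed + i`.
#' @param methods Character subset of `c("csf", "aic", "bic", "gap")`.
#' @param rule Selection rule passed to [select_k_points()].
#' @return A tibble `trial`, `method`, `chosen_k`, `correct`.
#' @export
benchmark_k_recovery <- function(n_trials = 100L, k_true = 3L,
                                 spacing = 1.5, n_per_cluster = 500L,
                                 k_max = 6L, seed = 1L,
                                 methods = c("csf", "aic"),
                                 rule = "log_ratio") {
  rows <- purrr::map(seq_len(n_trials), function(tr) {
    pts <- gaussian_mixture(k = k_true, spacing = spacing,
                            n_per_cluster = n_per_cluster,
                            seed = seed + tr)
    x <- points_matrix(pts)
    out <- list()
    if ("csf" %in% methods) {
      out$csf <- select_k_points(x, k_max = k_max, rule = rule,
                                 seed = seed + tr)$chosen_k
    }
    if (any(c("aic", "bic") %in% methods)) {
      ab <- aic_bic_select(x, k_max = k_max, seed = seed + tr)
      if ("aic" %in% methods) out$aic <- ab$aic$chosen_k
      if ("bic" %in% methods) out$bic <- ab$bic$chosen_k
    }
    if ("gap" %in% methods) {
      out$gap <- gap_statistic(x, k_max = k_max, seed = seed + tr)$chosen_k
    }
    tibble::tibble(trial = tr, method = names(out),
                   chosen_k = as.integer(unlist(out)))
  }) |> purrr::list_rbind()
  rows$correct <- rows$chosen_k == k_true
  rows
}
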