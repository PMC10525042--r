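#' CSF curve container
#'
#' A `csf_curve` is a tibble with one row per candidate number of clusters:
#' `k`, `mean_h` (mean structure-function value over subsamples), `sd_h`
#' (standard deviation over subsamples; 0 for exact/deterministic curves)
#' and `n_samples`. [tidy()] returns the rows, [glance()] a one-row summary,
#' and [ggplot2::autoplot()] draws the curve with a one-standard-deviation
#' ribbon.
#'
#' @param k Integer vector of part counts.
#' @param mean_h,sd_h Per-k mean and standard deviation.
#' @param n_samples Number of subsamples behind each row.
#' @param kind Free-text provenance tag (`"exact"`, `"empirical"`,
#'   `"points"`).
#' @return A tibble of class `csf_curve`.
#' @name csf_curve
#' @export
new_csf_curve <- function(k, mean_h, sd_h, n_samples = 1L, kind = "empirical") {
  stopifnot(length(k) == length(mean_h), length(k) == length(sd_h),
            all(sd_h >= 0))
  out <- tibble::tibble(k = as.integer(k), mean_h = as.numeric(mean_h),
                        sd_h = as.numeric(sd_h),
                        n_samples = as.integer(n_samples))
  class(out) <- c("csf_curve", class(out))
  attr(out, "kind") <- kind
  out
}

#' @export
#' @importFrom generics tidy
tidy.csf_curve <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("k", "mean_h", "sd_h", "n_samples")])
}

#' @export
#' @importFrom generics glance
glance.csf_curve <- function(x, ...) {
  tibble::tibble(k_max = max(x$k),
                 n_samples = max(x$n_samples),
                 min_mean_h = min(x$mean_h),
                 k_at_min = x$k[which.min(x$mean_h)],
                 kind = attr(x, "kind") %||% "empirical")
}

#' @export
#' @importFrom ggplot2 autoplot
autoplot.csf_curve <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$k, y = .data$mean_h)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_h - .data$sd_h,
                                      ymax = .data$mean_h + .data$sd_h),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$k) +
    ggplot2::labs(x = "number of clusters k", y = "cluster structure function")
}

#' Subsampled structure-function value of one clustering
#'
#' The empirical structure function of a clustered subsample: for each
#' occupied cluster take the bandwidth of its member deficiencies
#' (max - min; 0 for clusters with at most one subsampled member) and
#' accumulate `log2(bandwidth + 1)`; the sum is divided by `k_max` so curves
#' across different `k` share a scale.
#'
#' @param deltas_by_cluster List of numeric deficiency vectors, one per
#'   occupied cluster (empty vectors allowed, contributing 0).
#' @param k_max The maximum number of clusters scanned.
#' @return A single non-negative number.
#' @examples
#' log_bandwidth_value(list(c(0, 7)), k_max = 10)  # log2(8)/10 = 0.3
#' @export
log_bandwidth_value <- function(deltas_by_cluster, k_max) {
  bw <- vapply(deltas_by_cluster, function(d) {
    if (length(d) <= 1L) 0 else max(d) - min(d)
  }, numeric(1))
  sum(log2(bw + 1)) / k_max
}
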