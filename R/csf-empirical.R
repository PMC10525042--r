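#' Empirical cluster structure function by subsampled clustering
#'
#' The practical pipeline for data where exhaustive partition search is
#' impossible. For each `K` in `1..k_max` the full set is clustered once —
#' by classic spectral clustering on the pairwise NCD matrix — and the
#' cluster assignments are reused across subsamples. Each subsample draws
#' `5 * K` objects uniformly without replacement (clamped to the set size
#' with a warning); optimality deficiencies are computed per cluster
#' restricted to the subsample with the compressed-size estimator, and the
#' subsample's structure-function value is the scaled sum of per-cluster
#' log-bandwidths ([log_bandwidth_value()]). The curve reports the mean and
#' standard deviation over subsamples for each `K`.
#'
#' Empirical curves are not forced monotone: the clustering heuristic, the
#' compressor approximation and the subsampling all perturb the ideal
#' non-increasing shape.
#'
#' With `cluster_method = "exhaustive"` (small sets only) the spectral step
#' is replaced by exhaustive minimization of `criterion` over all
#' partitions, and subsamples default to the full set; this reproduces the
#' exact structure function through the empirical plumbing and exists to
#' validate the pipeline.
#'
#' @param set An [object_set()].
#' @param k_max Largest number of clusters scanned.
#' @param spec A [compressor_spec()].
#' @param n_subsamples Number of random subsamples per `K`.
#' @param seed Integer seed; fully determines the run.
#' @param subsample_size `NULL` for the default `5 * K`, `"full"` for the
#'   whole set, or a function of `K`.
#' @param cluster_method `"spectral"` or `"exhaustive"`.
#' @param criterion Criterion for the exhaustive method.
#' @param dist Optional precomputed distance matrix (skips NCD).
#' @return A [csf_curve] tibble.
#' @export
csf_empirical <- function(set, k_max, spec = compressor_spec("gzip"),
                          n_subsamples = 100L, seed = 1L,
                          subsample_size = NULL,
                          cluster_method = c("spectral", "exhaustive"),
                          criterion = criterion_bandwidth_sum,
                          dist = NULL) {
  stopifnot(inherits(set, "object_set"))
  cluster_method <- match.arg(cluster_method)
  n <- length(set)
  k_max <- as.integer(k_max)
  oracle <- delta_compressor(set, spec)

  if (cluster_method == "spectral") {
    if (is.null(dist)) dist <- ncd_matrix(set, spec)
    labels_by_k <- lapply(seq_len(k_max), function(K)
      spectral_cluster(dist, K, seed = seed + K))
  } else {
    if (n > 12L) stop("exhaustive clustering is guarded at n <= 12",
                      call. = FALSE)
    labels_by_k <- lapply(seq_len(k_max), function(K)
      csf_exact(set, K, oracle, criterion)$witness)
    if (is.null(subsample_size)) subsample_size <- "full"
  }

  size_of <- function(K) {
    s <- if (is.null(subsample_size)) 5L * K
         else if (identical(subsample_size, "full")) n
         else subsample_size(K)
    if (s > n) {
      warning(sprintf("subsample size %d exceeds |S| = %d; clamping", s, n),
              call. = FALSE)
      s <- n
    }
    as.integer(s)
  }

  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(k_max), function(K) {
      labels <- labels_by_k[[K]]
      ssize <- size_of(K)
      h <- vapply(seq_len(n_subsamples), function(b) {
        idx <- sample.int(n, ssize)
        groups <- split(idx, labels[idx])
        if (identical(cluster_method, "exhaustive") &&
            identical(criterion, criterion_bandwidth_sum) && ssize == n) {
          # validation mode: evaluate the same criterion the minimizer used
          criterion(lapply(groups, function(p) part_deltas(oracle, p)))
        } else {
          log_bandwidth_value(lapply(groups, function(p)
            part_deltas(oracle, p)), k_max)
        }
      }, numeric(1))
      tibble::tibble(k = K, mean_h = mean(h),
                     sd_h = if (n_subsamples > 1L) stats::sd(h) else 0,
                     n_samples = n_subsamples)
    }) |> purrr::list_rbind()
  })
  new_csf_curve(rows$k, rows$mean_h, rows$sd_h, rows$n_samples,
                kind = if (cluster_method == "spectral") "empirical"
                       else "exhaustive")
}
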