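#' Criterion functions over a partition's deficiencies
#'
#' A criterion function maps the per-part deficiency vectors of a partition
#' to a single value, subject to two axioms: zeroing any deficiency never
#' increases the value, and the value is 0 when all deficiencies are 0. The
#' default criterion is the bandwidth sum: the sum over parts of
#' (max deficiency - min deficiency), 0 for singleton parts.
#'
#' @param delta_list A list of numeric vectors, one per part.
#' @return A single non-negative number.
#' @export
criterion_bandwidth_sum <- function(delta_list) {
  sum(vapply(delta_list, function(d) {
    if (length(d) <= 1L) 0 else max(d) - min(d)
  }, numeric(1)))
}

#' Exact cluster structure function
#'
#' `csf_exact()` computes `H_S(k)`: the minimum of a criterion function over
#' every partition of the set into exactly `k` non-empty parts, by
#' exhaustive enumeration (guarded at `n <= 12`). The witness partition is
#' the first minimizer in canonical enumeration order. The curve is
#' monotone non-increasing in `k` and reaches exactly 0 at `k = n`, where
#' every part is a singleton with deficiency 0.
#'
#' @param set An [object_set()], or an integer giving the set size when the
#'   oracle does not need the objects themselves (stub oracles).
#' @param k Number of parts.
#' @param delta_fun A delta oracle `f(part, x)` over object indices; see
#'   [delta_compressor()] and [delta_stub()].
#' @param criterion A criterion function over per-part deficiency vectors.
#' @return A list of class `csf_exact` with `value`, `k`, `witness` (integer
#'   assignment vector) and `n`.
#' @examples
#' oracle <- delta_stub(2 * (1:4))
#' csf_exact(4, 2, oracle)$value  # 4: contiguous complexity groups win
#' @export
csf_exact <- function(set, k, delta_fun,
                      criterion = criterion_bandwidth_sum) {
  n <- if (inherits(set, "object_set") || is.list(set)) length(set)
       else as.integer(set)
  parts_stream <- enumerate_partitions(n, k)
  best <- Inf
  witness <- NULL
  for (a in parts_stream) {
    v <- criterion(deltas_by_part(delta_fun, a))
    if (v < best) {
      best <- v
      witness <- a
    }
  }
  structure(list(value = best, k = as.integer(k), witness = witness, n = n),
            class = "csf_exact")
}

#' @export
print.csf_exact <- function(x, ...) {
  cat(sprintf("H_S(%d) = %g over %d objects (witness: %s)\n", x$k, x$value,
              x$n, paste(x$witness, collapse = " ")))
  invisible(x)
}

# Per-part deficiency vectors of one assignment under an oracle.
deltas_by_part <- function(delta_fun, assignment) {
  lapply(split(seq_along(assignment), assignment),
         function(p) part_deltas(delta_fun, p))
}

#' @rdname csf_exact
#' @param ks Integer vector of part counts.
#' @return `csf_exact_curve()`: a [csf_curve] tibble with zero spread.
#' @export
csf_exact_curve <- function(set, ks = NULL, delta_fun,
                            criterion = criterion_bandwidth_sum) {
  n <- if (inherits(set, "object_set") || is.list(set)) length(set)
       else as.integer(set)
  if (is.null(ks)) ks <- seq_len(n)
  vals <- vapply(ks, function(k) csf_exact(set, k, delta_fun,
                                           criterion)$value, numeric(1))
  new_csf_curve(k = as.integer(ks), mean_h = vals, sd_h = rep(0, length(ks)),
                n_samples = 1L, kind = "exact")
}

#' Sigma-trimmed cluster structure function
#'
#' Applies [sigma_trim()] to the whole set first — deficiencies are measured
#' against the set as a single part, and only objects within one population
#' standard deviation of the mean deficiency are retained — then computes
#' the exact structure function on the trimmed set. Trimming discards
#' outliers, so the trimmed value never exceeds the untrimmed one.
#'
#' @inheritParams csf_exact
#' @return A `csf_exact` result with an extra field `kept` (original indices
#'   retained by the trim).
#' @export
csf_sigma <- function(set, k, delta_fun,
                      criterion = criterion_bandwidth_sum) {
  n <- if (inherits(set, "object_set") || is.list(set)) length(set)
       else as.integer(set)
  all_idx <- seq_len(n)
  deltas <- part_deltas(delta_fun, all_idx)
  trim <- sigma_trim(deltas, ids = all_idx)
  kept <- trim$kept_ids
  m <- length(kept)
  if (k > m) {
    stop(sprintf("k = %d exceeds the trimmed set size %d", k, m),
         call. = FALSE)
  }
  best <- Inf
  witness <- NULL
  for (a in enumerate_partitions(m, k)) {
    dl <- lapply(split(kept, a), function(p) part_deltas(delta_fun, p))
    v <- criterion(dl)
    if (v < best) {
      best <- v
      witness <- a
    }
  }
  structure(list(value = best, k = as.integer(k), witness = witness,
                 n = m, kept = kept, mu = trim$mu, sigma = trim$sigma),
            class = "csf_exact")
}
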