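#' Optimality deficiency of a part for one of its members
#'
#' The optimality deficiency measures how far a multiset `A` falls short of
#' being an algorithmic sufficient statistic for a member `x`:
#' `delta(A, x) = K(A) + log2|A| - K(x)`. In practice complexities are
#' replaced by compressed sizes, with a small-cardinality guard:
#' parts with fewer than two members have deficiency 0, otherwise
#' `Z(A) - Z(x) + log2|A|`, where `Z(A)` compresses the concatenation of the
#' part's members. The value is reported in bits alongside byte-valued `Z`,
#' exactly as the practical estimator is written; it is not clamped at zero
#' (real compressors, like the theory, allow negative deficiencies).
#'
#' @param part A list/`object_set` of members forming one part.
#' @param x One member of `part`.
#' @param sizes A [compressor_spec()] used as the size oracle.
#' @return The deficiency in bits.
#' @seealso [delta_from_sizes()] for the pure arithmetic given sizes.
#' @examples
#' s <- list(strrep("ab", 500), strrep("ab", 501))
#' optimality_deficiency(s, s[[1]])
#' @export
optimality_deficiency <- function(part, x, sizes = compressor_spec("gzip")) {
  objs <- if (inherits(part, "object_set")) unclass(part) else part
  if (!is.list(objs)) objs <- list(objs)
  member <- any(vapply(objs, identical, logical(1), y = x))
  if (!member) stop("`x` is not a member of `part`", call. = FALSE)
  if (length(objs) < 2L) return(0)
  delta_from_sizes(compressed_size(objs, sizes), compressed_size(x, sizes),
                   length(objs))
}

#' @rdname optimality_deficiency
#' @param z_part,z_x Sizes (bytes, or exact complexities in a stub oracle)
#'   of the part and the member.
#' @param n_part Cardinality of the part.
#' @export
delta_from_sizes <- function(z_part, z_x, n_part) {
  if (n_part < 2L) return(0)
  z_part - z_x + log2(n_part)
}

#' Delta oracles over an object set
#'
#' The exact cluster structure function needs a function
#' `delta(part, x)` for arbitrary parts; these constructors return closures
#' over integer object indices. `delta_compressor()` evaluates the practical
#' compressed-size estimator (with the part concatenated in index order and
#' sizes cached). `delta_stub()` is an idealized oracle for property tests:
#' given per-object complexities `K(x_i)` it treats each part as a perfect
#' model of its most complex member, `delta(A, x) = max(K[A]) - K[x]`, so
#' the member attaining the part maximum has deficiency exactly 0 and the
#' part bandwidth equals the complexity range, as in the theory's
#' constructions.
#'
#' @param set An [object_set()].
#' @param spec A [compressor_spec()].
#' @return A function `f(part, x)` taking an integer vector of object
#'   indices and a single member index.
#' @export
delta_compressor <- function(set, spec = compressor_spec("gzip")) {
  stopifnot(inherits(set, "object_set"))
  objs <- unclass(set)
  force(spec)
  function(part, x) {
    part <- as.integer(part)
    x <- as.integer(x)
    if (!x %in% part) stop("`x` is not in `part`", call. = FALSE)
    if (length(part) < 2L) return(0)
    delta_from_sizes(compressed_size(objs[sort(part)], spec),
                     compressed_size(objs[[x]], spec), length(part))
  }
}

#' @rdname delta_compressor
#' @param complexities Numeric vector of stub complexities `K(x_i)`.
#' @export
delta_stub <- function(complexities) {
  k <- as.numeric(complexities)
  function(part, x) {
    part <- as.integer(part)
    if (!x %in% part) stop("`x` is not in `part`", call. = FALSE)
    if (length(part) < 2L) return(0)
    max(k[part]) - k[as.integer(x)]
  }
}

# All per-member deficiencies of one part under an oracle.
part_deltas <- function(oracle, part) {
  vapply(part, function(i) oracle(part, i), numeric(1))
}

#' Per-part deficiency summaries
#'
#' Mean and bandwidth (max minus min; 0 for singletons) of the optimality
#' deficiencies inside each part of a partition.
#'
#' @param deltas Numeric vector of per-object deficiencies.
#' @param part Vector assigning each object to a part.
#' @param object_id Optional object ids (carried through).
#' @return A tibble with one row per part: `part`, `n`, `mean_delta`,
#'   `bandwidth`.
#' @examples
#' part_statistics(c(2, 9, 5, 5, 5), c(1, 1, 2, 2, 2))
#' @export
part_statistics <- function(deltas, part, object_id = NULL) {
  if (length(deltas) != length(part)) {
    stop("`deltas` and `part` must have the same length", call. = FALSE)
  }
  if (length(deltas) == 0L) stop("empty partition", call. = FALSE)
  tibble::tibble(part = part, delta = as.numeric(deltas)) |>
    dplyr::group_by(part) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_delta = mean(.data$delta),
                     bandwidth = max(.data$delta) - min(.data$delta),
                     .groups = "drop")
}

#' Sigma trimming of a multiset by whole-set deficiencies
#'
#' Computes the population standard deviation `sigma_S` of the deficiencies
#' of all objects measured against the whole set as a single part, and keeps
#' the objects within one `sigma_S` of the mean. This refinement discards
#' outliers before the structure function is evaluated.
#'
#' @param deltas Per-object deficiencies against the whole set.
#' @param ids Optional ids (defaults to indices).
#' @return A list with `kept_ids`, `kept` (logical), `mu`, `sigma`.
#' @examples
#' sigma_trim(c(0, 10, 20))  # keeps only the middle element
#' @export
sigma_trim <- function(deltas, ids = seq_along(deltas)) {
  stopifnot(length(deltas) >= 1L)
  mu <- mean(deltas)
  sigma <- sqrt(mean((deltas - mu)^2))
  kept <- abs(deltas - mu) <= sigma
  list(kept_ids = ids[kept], kept = kept, mu = mu, sigma = sigma)
}

#' Mean intracluster conditional-probability bound
#'
#' The expected conditional probability between members of a part is
#' bounded below by the empirical mean of `2^-delta` over the part, which by
#' the arithmetic-geometric mean inequality is itself at least
#' `2^-mean(delta)`.
#'
#' @param deltas Deficiencies of one non-empty part.
#' @return A number in `(0, 1]` (for non-negative deficiencies).
#' @export
intracluster_probability_bound <- function(deltas) {
  stopifnot(length(deltas) >= 1L)
  mean(2^(-deltas))
}
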