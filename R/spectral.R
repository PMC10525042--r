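#' Pairwise NCD matrix of an object set
#'
#' Computes the symmetric matrix of normalized compression distances among
#' all pairs of objects. The diagonal is forced to 0 and each off-diagonal
#' entry is the order-symmetrized NCD ([ncd()]). With size caching this
#' costs `n (n - 1) / 2 + n` distinct compressions plus the pairwise
#' concatenations.
#'
#' @param set An [object_set()] with at least two objects.
#' @param spec A [compressor_spec()].
#' @return An `n x n` numeric matrix with object ids as dimnames.
#' @export
ncd_matrix <- function(set, spec = compressor_spec("gzip")) {
  stopifnot(inherits(set, "object_set"), length(set) >= 2L)
  n <- length(set)
  ids <- object_ids(set)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      v <- tryCatch(ncd(set[[i]], set[[j]], spec), error = function(e) {
        stop(sprintf("NCD failed for objects '%s'/'%s': %s", ids[i], ids[j],
                     conditionMessage(e)), call. = FALSE)
      })
      d[i, j] <- v
      d[j, i] <- v
    }
  }
  d
}

#' Classic spectral clustering of a distance matrix
#'
#' The normalized-cuts recipe: a Gaussian affinity
#' `A_ij = exp(-D_ij^2 / (2 sigma^2))` with bandwidth `sigma` equal to the
#' median off-diagonal distance (configurable), the symmetric normalized
#' Laplacian, the eigenvectors of its `k` smallest eigenvalues with rows
#' normalized to unit length, and seeded k-means (10 restarts, best inertia
#' kept) on the embedded rows. All `k` labels are present in the output.
#'
#' @param dist Symmetric non-negative distance matrix with zero diagonal.
#' @param k Number of clusters (`k <= nrow(dist)`).
#' @param seed Integer seed for the k-means restarts.
#' @param sigma Affinity bandwidth; default the median off-diagonal
#'   distance.
#' @return Integer labels in `1..k`.
#' @export
spectral_cluster <- function(dist, k, seed = 1L, sigma = NULL) {
  stopifnot(is.matrix(dist), nrow(dist) == ncol(dist))
  n <- nrow(dist)
  k <- as.integer(k)
  if (k > n) stop("k exceeds the number of objects", call. = FALSE)
  if (k == 1L) return(rep(1L, n))
  if (k == n) return(seq_len(n))
  off <- dist[upper.tri(dist)]
  if (is.null(sigma)) sigma <- stats::median(off)
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  if (max(off) - min(off) < 1e-12) {
    warning("degenerate affinity (all distances identical); ",
            "labels follow object order", call. = FALSE)
    return(as.integer(cut(seq_len(n), breaks = k, labels = FALSE)))
  }
  a <- exp(-dist^2 / (2 * sigma^2))
  diag(a) <- 0
  dg <- pmax(rowSums(a), 1e-12)
  s <- 1 / sqrt(dg)
  lsym <- diag(n) - (s * a) %*% diag(s) # I - D^-1/2 A D^-1/2
  eg <- eigen((lsym + t(lsym)) / 2, symmetric = TRUE)
  u <- eg$vectors[, seq.int(n, n - k + 1L), drop = FALSE] # k smallest
  rn <- sqrt(rowSums(u^2))
  u <- u / pmax(rn, 1e-12)
  kmeans_labels(u, k, seed)
}

# Seeded k-means with multiple restarts; falls back to a deterministic
# quantile split if there are fewer distinct rows than centers.
kmeans_labels <- function(x, k, seed, nstart = 10L) {
  if (nrow(unique(round(x, 12))) < k) {
    ord <- order(x[, 1], seq_len(nrow(x)))
    lab <- integer(nrow(x))
    lab[ord] <- as.integer(cut(seq_len(nrow(x)), breaks = k, labels = FALSE))
    return(lab)
  }
  withr::with_seed(seed, {
    km <- stats::kmeans(x, centers = k, nstart = nstart, iter.max = 200L)
  })
  as.integer(km$cluster)
}

#' Mode-label clustering accuracy
#'
#' Evaluates a clustering against known class labels by mapping every
#' cluster to the mode (most common element) of the true labels it
#' contains — ties broken toward the smallest class label — and scoring the
#' fraction of objects whose mapped label matches the truth.
#'
#' @param labels Cluster labels.
#' @param truth True class labels of the same length.
#' @return A list with `accuracy`, `mapping` (cluster -> class), and
#'   `confusion` (rows = truth, columns = predicted class).
#' @export
mode_label_accuracy <- function(labels, truth) {
  if (length(labels) != length(truth)) {
    stop("`labels` and `truth` must have the same length", call. = FALSE)
  }
  truth <- as.character(truth)
  classes <- sort(unique(truth))
  mapping <- vapply(split(truth, labels), function(tr) {
    tab <- table(tr)
    names(tab)[which.max(tab)] # ties: first in sorted name order
  }, character(1))
  predicted <- unname(mapping[as.character(labels)])
  confusion <- table(factor(truth, levels = classes),
                     factor(predicted, levels = classes))
  names(dimnames(confusion)) <- c("truth", "predicted")
  list(accuracy = mean(predicted == truth), mapping = mapping,
       confusion = confusion)
}
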