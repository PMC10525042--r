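# Independent oracles used across the suite. These deliberately avoid the
# package's own implementations.

# Stirling numbers of the second kind via the explicit inclusion-exclusion
# formula (independent of the package's recurrence).
stirling2_formula <- function(n, k) {
  j <- 0:k
  round(sum((-1)^j * choose(k, j) * (k - j)^n) / factorial(k))
}

# Seeded random byte-string object set.
random_byte_set <- function(n, len = 200L, seed = 1L, alphabet = 64L) {
  withr::with_seed(seed, {
    objs <- lapply(seq_len(n), function(i)
      as.raw(sample.int(alphabet, len, replace = TRUE) - 1L))
  })
  object_set(objs)
}

# Connected components of the pairwise-overlap graph by naive closure.
brute_overlap_components <- function(regions) {
  n <- length(regions)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (comp[i] != comp[j] &&
            length(intersect(regions[[i]], regions[[j]])) > 0) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Exhaustive maximum-score non-overlapping subset (bitmask search over
# precomputed pairwise conflicts).
brute_best_subset <- function(regions, scores) {
  n <- length(regions)
  conflict <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && length(intersect(regions[[i]], regions[[j]])) > 0) {
        conflict[i] <- bitwOr(conflict[i], bitwShiftL(1L, j - 1L))
      }
    }
  }
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) > 0)
    ok <- TRUE
    for (i in idx) {
      if (bitwAnd(mask, conflict[i]) > 0) {
        ok <- FALSE
        break
      }
    }
    if (ok) best <- max(best, sum(scores[idx]))
  }
  best
}

# Candidate stacks: the bucket structure ensemble segmentation produces —
# several overlapping candidates per underlying object, objects disjoint.
stacked_bucket_candidates <- function(seed) {
  withr::with_seed(seed, {
    frame <- c(30L, 30L)
    n_obj <- sample(1:2, 1)
    centers <- cbind(sample(8:22, n_obj), sample(8:22, n_obj))
    regions <- list()
    for (o in seq_len(n_obj)) {
      for (j in seq_len(sample(3:5, 1))) {
        h <- sample(4:10, 1)
        w <- sample(4:10, 1)
        cy <- centers[o, 1] + sample(-1:1, 1)
        cx <- centers[o, 2] + sample(-1:1, 1)
        y0 <- max(1, cy - h %/% 2)
        x0 <- max(1, cx - w %/% 2)
        y1 <- min(frame[1], y0 + h - 1L)
        x1 <- min(frame[2], x0 + w - 1L)
        regions[[length(regions) + 1L]] <-
          as.vector(outer(y0:y1, (x0:x1 - 1L) * frame[1], "+"))
      }
    }
    scores <- round(stats::runif(length(regions), 2, 4), 3)
  })
  tibble::tibble(id = seq_along(regions), region = regions,
                 n_px = lengths(regions), score = scores)
}

# Random rectangle regions in a small frame, for bucket/greedy oracles.
random_rect_candidates <- function(n, frame = c(24L, 24L), seed = 1L) {
  withr::with_seed(seed, {
    regions <- lapply(seq_len(n), function(i) {
      h <- sample(3:8, 1)
      w <- sample(3:8, 1)
      y0 <- sample.int(frame[1] - h, 1)
      x0 <- sample.int(frame[2] - w, 1)
      as.vector(outer(y0:(y0 + h - 1L), (x0:(x0 + w - 1L) - 1L) * frame[1],
                      "+"))
    })
    scores <- round(stats::runif(n, 0.5, 5), 3)
  })
  tibble::tibble(id = seq_len(n), region = regions, n_px = lengths(regions),
                 score = scores)
}
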