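#' Enumerate set partitions into exactly k parts
#'
#' Generates every partition of `{1..n}` into exactly `k` non-empty
#' unlabeled parts, each exactly once, as restricted-growth assignment
#' vectors in canonical order (element 1 is always in part 1, and a new part
#' label is introduced only after all smaller labels). The count equals the
#' Stirling number of the second kind `S(n, k)`. Guarded at `n <= 12`
#' because of Bell-number growth.
#'
#' @param n Set size (`1 <= k <= n <= 12`).
#' @param k Number of parts.
#' @return A list of integer assignment vectors of length `n` with values in
#'   `1..k`.
#' @examples
#' length(enumerate_partitions(4, 2))  # S(4, 2) = 7
#' @export
enumerate_partitions <- function(n, k) {
  n <- as.integer(n)
  k <- as.integer(k)
  if (n < 1L || k < 1L || k > n) {
    stop("need 1 <= k <= n", call. = FALSE)
  }
  if (n > 12L) {
    stop("enumerate_partitions() is guarded at n <= 12 ",
         "(the number of set partitions grows like the Bell numbers)",
         call. = FALSE)
  }
  res <- vector("list", stirling2(n, k))
  cnt <- 0L
  a <- integer(n)
  a[1L] <- 1L
  rec <- function(i, m) {
    if (i > n) {
      if (m == k) {
        cnt <<- cnt + 1L
        res[[cnt]] <<- a
      }
      return(invisible(NULL))
    }
    if (m + (n - i + 1L) < k) return(invisible(NULL)) # cannot reach k parts
    for (j in seq_len(min(m + 1L, k))) {
      a[i] <<- j
      rec(i + 1L, max(m, j))
    }
    invisible(NULL)
  }
  if (n == 1L) return(list(a))
  rec(2L, 1L)
  res[seq_len(cnt)]
}

#' @rdname enumerate_partitions
#' @export
stirling2 <- function(n, k) {
  if (k == 0L) return(as.numeric(n == 0L))
  if (k > n) return(0)
  s <- matrix(0, n + 1L, k + 1L)
  s[1L, 1L] <- 1
  for (i in seq_len(n)) {
    for (j in seq_len(min(i, k))) {
      s[i + 1L, j + 1L] <- j * s[i, j + 1L] + s[i, j]
    }
  }
  s[n + 1L, k + 1L]
}
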