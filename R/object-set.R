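#' Ordered multisets of data objects
#'
#' An `object_set` is the basic container clustered by the cluster structure
#' function: an ordered multiset of objects, each with a stable id. Objects
#' may be raw vectors (byte strings), single character strings (interpreted
#' as their bytes, or as bit strings where a function says so), or numeric
#' matrices in `[0, 1]` (grayscale images).
#'
#' @param x A list of objects, or an atomic character vector (one object per
#'   element).
#' @param ids Optional character vector of unique ids, recycled from names or
#'   generated as `"obj<i>"`.
#' @param labels Optional vector of true class labels, kept as an attribute
#'   for evaluation helpers.
#' @return An `object_set`: a list of objects with attributes `ids` and
#'   (optionally) `labels`.
#' @examples
#' s <- object_set(list("abracadabra", "abracadabra", "zzzzzz"))
#' length(s)
#' object_ids(s)
#' @export
object_set <- function(x, ids = NULL, labels = NULL) {
  if (is.character(x)) x <- as.list(x)
  if (!is.list(x)) stop("`x` must be a list or character vector", call. = FALSE)
  ok <- vapply(x, function(e) is.raw(e) || is.matrix(e) ||
                 (is.character(e) && length(e) == 1L), logical(1))
  if (!all(ok)) {
    stop("object_set elements must be raw vectors, single strings or matrices",
         call. = FALSE)
  }
  if (is.null(ids)) {
    ids <- names(x)
    if (is.null(ids) || anyDuplicated(ids) || any(ids == "")) {
      ids <- sprintf("obj%03d", seq_along(x))
    }
  }
  if (length(ids) != length(x) || anyDuplicated(ids)) {
    stop("`ids` must be unique and match the number of objects", call. = FALSE)
  }
  if (!is.null(labels) && length(labels) != length(x)) {
    stop("`labels` must match the number of objects", call. = FALSE)
  }
  structure(unname(x), ids = as.character(ids), labels = labels,
            class = "object_set")
}

#' @export
print.object_set <- function(x, ...) {
  kinds <- vapply(x, function(e) class(e)[1], character(1))
  cat(sprintf("<object_set of %d objects: %s>\n", length(x),
              paste(unique(kinds), collapse = ", ")))
  invisible(x)
}

#' @export
`[.object_set` <- function(x, i) {
  object_set(unclass(x)[i], ids = attr(x, "ids")[i],
             labels = if (!is.null(attr(x, "labels"))) attr(x, "labels")[i])
}

#' @rdname object_set
#' @param set An `object_set`.
#' @export
object_ids <- function(set) attr(set, "ids")

#' @rdname object_set
#' @export
object_labels <- function(set) attr(set, "labels")

# Bytes of one object for compressor input. Images are quantized to 8-bit
# pixel buffers (column-major); strings use their UTF-8 bytes.
as_bytes <- function(x) {
  if (is.raw(x)) return(x)
  if (is.character(x)) return(charToRaw(x))
  if (is.matrix(x)) {
    px <- pmin(pmax(as.vector(x), 0), 1)
    return(as.raw(as.integer(round(px * 255))))
  }
  stop("cannot interpret object of class ", class(x)[1], " as bytes",
       call. = FALSE)
}

# Concatenate objects for joint compression. Image multisets are joined
# side-by-side (shared height), everything else at the byte level.
concat_objects <- function(objs) {
  if (length(objs) == 0L) return(raw(0))
  if (all(vapply(objs, is.matrix, logical(1)))) {
    hts <- vapply(objs, nrow, integer(1))
    if (length(unique(hts)) == 1L) return(do.call(cbind, objs))
  }
  do.call(c, lapply(objs, as_bytes))
}
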