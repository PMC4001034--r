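#' Sets of non-negative integers as ordered closed intervals
#'
#' An `interval_set` stores a finite set of non-negative integers as a sorted
#' sequence of pairwise disjoint, non-adjacent closed intervals
#' `[lo_k, hi_k]`.  This is the canonical representation of population index
#' windows and of contiguous GID ranges.  The constructor normalizes its
#' input: intervals are sorted and overlapping or adjacent intervals are
#' merged, so equal sets always have equal representations.
#'
#' @param lo,hi integer vectors of equal length: lower and upper closed
#'   bounds.  Both empty gives the empty set, which is permitted (e.g. the
#'   target window of a rank that owns no targets).
#' @return An object of class `interval_set`.
#' @examples
#' interval_set(c(0, 9), c(5, 10))      # {0..5, 9, 10}
#' interval_set(c(0, 3), c(2, 5))       # adjacent runs merge to {0..5}
#' @seealso [interval_set_from_ids()]
#' @export
interval_set <- function(lo = integer(), hi = lo) {
  lo <- as.integer(lo)
  hi <- as.integer(hi)
  if (length(lo) != length(hi)) stop("lo and hi must have equal length")
  if (anyNA(lo) || anyNA(hi)) stop("interval bounds must not be NA")
  if (any(lo < 0L)) stop("interval bounds must be non-negative")
  if (any(hi < lo)) stop("each interval needs hi >= lo")
  if (length(lo) > 1L) {
    o <- order(lo)
    lo <- lo[o]
    hi <- hi[o]
    mlo <- lo[1L]
    mhi <- hi[1L]
    out_lo <- integer()
    out_hi <- integer()
    for (k in seq_along(lo)[-1L]) {
      if (lo[k] <= mhi + 1L) {        # overlapping or adjacent: merge
        mhi <- max(mhi, hi[k])
      } else {
        out_lo <- c(out_lo, mlo)
        out_hi <- c(out_hi, mhi)
        mlo <- lo[k]
        mhi <- hi[k]
      }
    }
    lo <- c(out_lo, mlo)
    hi <- c(out_hi, mhi)
  }
  structure(list(lo = lo, hi = hi), class = "interval_set")
}

#' Compress a list of ids into maximal closed intervals
#'
#' Returns the interval-set covering exactly `ids`, with maximal contiguous
#' runs merged — the operation a simulator kernel performs on a user-supplied
#' GID list before handing windows to a connection generator.
#'
#' @param ids non-empty vector of distinct non-negative integers (any order).
#' @return An [interval_set()] whose members are exactly `ids`.
#' @examples
#' interval_set_from_ids(c(3, 4, 5, 9, 10))  # [3,5] and [9,10]
#' @export
interval_set_from_ids <- function(ids) {
  ids <- as.integer(ids)
  if (length(ids) == 0L) stop("ids must be non-empty")
  if (anyNA(ids)) stop("ids must not contain NA")
  if (any(ids < 0L)) stop("ids must be non-negative")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate id: ", dup[1L])
  ids <- sort(ids)
  starts <- c(TRUE, diff(ids) > 1L)
  run <- cumsum(starts)
  interval_set(lo = ids[starts], hi = vapply(split(ids, run), max, integer(1)))
}

#' @export
print.interval_set <- function(x, ...) {
  if (length(x$lo) == 0L) {
    cat("<interval_set: empty>\n")
  } else {
    cat("<interval_set:",
        paste0("[", x$lo, ",", x$hi, "]", collapse = " "),
        "| size", format(iset_size(x), big.mark = ","), ">\n")
  }
  invisible(x)
}

#' Interval-set queries
#'
#' `iset_size()` returns the number of members, `iset_members()` enumerates
#' them in ascending order, `iset_contains()` tests membership (vectorized),
#' and `iset_intersect()` intersects two interval-sets.
#'
#' @param s,a,b interval-sets.
#' @param x integer vector of candidate members.
#' @return A count, an integer vector, a logical vector, or an interval-set.
#' @export
iset_size <- function(s) {
  if (length(s$lo) == 0L) return(0)
  sum(as.double(s$hi) - as.double(s$lo) + 1)
}

#' @rdname iset_size
#' @export
iset_members <- function(s) {
  if (length(s$lo) == 0L) return(integer())
  unlist(Map(seq.int, s$lo, s$hi), use.names = FALSE)
}

#' @rdname iset_size
#' @export
iset_contains <- function(s, x) {
  x <- as.integer(x)
  if (length(s$lo) == 0L) return(rep(FALSE, length(x)))
  idx <- findInterval(x, s$lo)
  ok <- idx >= 1L
  ok[ok] <- x[ok] <= s$hi[idx[ok]]
  ok
}

#' @rdname iset_size
#' @export
iset_intersect <- function(a, b) {
  ia <- 1L
  ib <- 1L
  lo <- integer()
  hi <- integer()
  while (ia <= length(a$lo) && ib <= length(b$lo)) {
    l <- max(a$lo[ia], b$lo[ib])
    h <- min(a$hi[ia], b$hi[ib])
    if (l <= h) {
      lo <- c(lo, l)
      hi <- c(hi, h)
    }
    if (a$hi[ia] < b$hi[ib]) ia <- ia + 1L else ib <- ib + 1L
  }
  interval_set(lo, hi)
}

#' @rdname iset_size
#' @export
is_interval_set <- function(s) inherits(s, "interval_set")

# coerce user input (interval_set, or a plain id vector) to an interval_set;
# empty vectors give the empty set
as_interval_set <- function(x) {
  if (is_interval_set(x)) return(x)
  if (length(x) == 0L) return(interval_set())
  interval_set_from_ids(x)
}
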