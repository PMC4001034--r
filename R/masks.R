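#' Elementary masks of the connection-set algebra
#'
#' A mask is a connection-set of arity 0: a Boolean indicator over pairs
#' `(i, j)` of non-negative source/target indices, possibly with infinite
#' support.  Masks are lazy expression trees; nothing is materialized until a
#' [connection_generator()] cuts the expression to a finite window.
#'
#' * `delta()` — the one-to-one mask: contains `(i, j)` iff `i == j`.  With a
#'   single population this is self-connectivity; between two populations it
#'   is one-to-one wiring.  Infinite support.
#' * `random_mask(p, seed)` — the random mask: an infinite matrix of
#'   independent Bernoulli(`p`) realizations (Erdős–Rényi connectivity).
#'   Membership of each pair is a pure function of `(seed, i, j)` via a
#'   counter-based hash, so two masks with equal `(p, seed)` are the *same*
#'   fixed set, no matter which rank, window or iteration order queries them.
#' * `cross_mask(sources, targets)` — the Cartesian product of two index
#'   sets: all pairs with `i` in `sources` and `j` in `targets`.
#'   Intersecting an infinite expression with a Cartesian product cuts out
#'   its finite part.
#' * `explicit_mask(pairs)` — exactly the listed `(i, j)` pairs.
#' * `full_mask()` — every pair; the identity of intersection (the Cartesian
#'   product of two unbounded index sets).
#'
#' @param p inclusion probability in `[0, 1]`.
#' @param seed non-negative integer seed of the counter-based hash.
#' @param sources,targets index sets: [interval_set()]s or plain id vectors.
#' @param pairs a two-column matrix or data frame of `(source, target)`
#'   index pairs.
#' @return A mask expression (class `csa_mask`).
#' @examples
#' mask_contains(delta(), 5, 5)                      # TRUE
#' M <- explicit_mask(rbind(c(0, 1), c(1, 1), c(1, 2),
#'                          c(3, 2), c(2, 3), c(0, 4)))
#' mask_contains(M, 0, 0)                            # FALSE
#' er <- csa_difference(random_mask(0.1, seed = 7), delta())
#' @name elementary-masks
NULL

new_mask <- function(kind, ...) {
  structure(list(kind = kind, ...),
            class = c(paste0("csa_", kind), "csa_mask"))
}

#' @rdname elementary-masks
#' @export
delta <- function() new_mask("one_to_one")

#' @rdname elementary-masks
#' @export
random_mask <- function(p, seed = 0L) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must be a probability in [0, 1]")
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0L) stop("seed must be a non-negative integer")
  new_mask("random", p = as.double(p), seed = seed)
}

#' @rdname elementary-masks
#' @export
cross_mask <- function(sources, targets) {
  new_mask("cross",
           sources = as_interval_set(sources),
           targets = as_interval_set(targets))
}

#' @rdname elementary-masks
#' @export
explicit_mask <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (length(pairs) == 0L) pairs <- matrix(integer(), ncol = 2L)
  if (ncol(pairs) != 2L) stop("pairs must have two columns: source, target")
  storage.mode(pairs) <- "integer"
  if (anyNA(pairs)) stop("pairs must not contain NA")
  if (any(pairs < 0L)) stop("indices must be non-negative")
  o <- order(pairs[, 2L], pairs[, 1L])   # target-major, the iteration order
  pairs <- pairs[o, , drop = FALSE]
  if (anyDuplicated(pairs)) pairs <- unique(pairs)
  dimnames(pairs) <- list(NULL, c("i", "j"))
  new_mask("explicit", pairs = pairs)
}

#' @rdname elementary-masks
#' @export
full_mask <- function() new_mask("full")

#' Combine masks with set operators
#'
#' Connection-set expressions are built by pointwise Boolean combination of
#' masks: intersection, union and set difference.  Laziness is preserved —
#' infinite operands are never materialized.  The classic idiom
#' `csa_difference(random_mask(p), delta())` is random connectivity without
#' self-connections.  Operators act on masks only; value sets attach at the
#' top level via [cset()].
#'
#' The `&`, `|` and `-` operators are overloaded for mask expressions as
#' sugar for intersection, union and difference.
#'
#' @param op one of `"intersection"`, `"union"`, `"difference"`.
#' @param A,B mask expressions (arity 0).
#' @return A mask expression.
#' @examples
#' no_self <- csa_difference(random_mask(0.5, seed = 1), delta())
#' cut <- csa_intersect(delta(), cross_mask(0:6, 0:6))   # 7 connections
#' @export
combine <- function(op, A, B) {
  op <- match.arg(op, c("intersection", "union", "difference"))
  for (x in list(A, B)) {
    if (inherits(x, "csa_cset") && csa_arity(x) > 0L)
      stop("operators act on masks; attach value sets at top level")
    if (!inherits(x, "csa_mask"))
      stop("operands must be mask expressions")
  }
  new_mask("operator", op = op, left = A, right = B)
}

#' @rdname combine
#' @export
csa_intersect <- function(A, B) combine("intersection", A, B)

#' @rdname combine
#' @export
csa_union <- function(A, B) combine("union", A, B)

#' @rdname combine
#' @export
csa_difference <- function(A, B) combine("difference", A, B)

#' @export
Ops.csa_mask <- function(e1, e2) {
  if (nargs() == 1L) stop("unary ", .Generic, " is not defined for masks")
  switch(.Generic,
         "&" = combine("intersection", e1, e2),
         "|" = combine("union", e1, e2),
         "-" = combine("difference", e1, e2),
         stop("operator ", .Generic, " is not defined for masks"))
}

#' @export
print.csa_mask <- function(x, ...) {
  cat("<csa mask: ", deparse_mask(x), ">\n", sep = "")
  invisible(x)
}

deparse_mask <- function(m) {
  switch(m$kind,
    one_to_one = "oneToOne",
    random = sprintf("random(p=%g, seed=%d)", m$p, m$seed),
    cross = sprintf("cross(|S|=%g, |T|=%g)",
                    iset_size(m$sources), iset_size(m$targets)),
    explicit = sprintf("explicit(%d pairs)", nrow(m$pairs)),
    full = "full",
    operator = sprintf("(%s %s %s)", deparse_mask(m$left),
                       switch(m$op, intersection = "&",
                              union = "|", difference = "-"),
                       deparse_mask(m$right)),
    stop("unknown mask kind"))
}

#' Mask membership: the Boolean indicator function
#'
#' Tests whether pairs `(i, j)` are connections of the mask.  Pure and
#' vectorized: repeated calls agree, out-of-support queries return `FALSE`.
#'
#' @param M a mask expression (or an arity-0 connection-set).
#' @param i,j non-negative source and target index vectors (equal length, or
#'   either of length 1).
#' @return Logical vector.
#' @export
mask_contains <- function(M, i, j) {
  n <- max(length(i), length(j))
  if (!(length(i) %in% c(1L, n)) || !(length(j) %in% c(1L, n)))
    stop("i and j must have equal length (or length 1)")
  i <- rep_len(as.integer(i), n)
  j <- rep_len(as.integer(j), n)
  if (anyNA(i) || anyNA(j)) stop("indices must not be NA")
  if (any(i < 0L) || any(j < 0L)) stop("indices must be non-negative")
  mask_contains_impl(M, i, j)
}

mask_contains_impl <- function(M, i, j) UseMethod("mask_contains_impl")

#' @export
mask_contains_impl.csa_cset <- function(M, i, j) mask_contains_impl(M$mask, i, j)

#' @export
mask_contains_impl.csa_one_to_one <- function(M, i, j) i == j

#' @export
mask_contains_impl.csa_random <- function(M, i, j) {
  cpp_pair_u01(M$seed, .STREAM_MASK, i, j) < M$p
}

#' @export
mask_contains_impl.csa_cross <- function(M, i, j) {
  iset_contains(M$sources, i) & iset_contains(M$targets, j)
}

#' @export
mask_contains_impl.csa_explicit <- function(M, i, j) {
  if (nrow(M$pairs) == 0L) return(rep(FALSE, length(i)))
  key <- paste(i, j)
  key %in% paste(M$pairs[, "i"], M$pairs[, "j"])
}

#' @export
mask_contains_impl.csa_full <- function(M, i, j) rep(TRUE, length(i))

#' @export
mask_contains_impl.csa_operator <- function(M, i, j) {
  l <- mask_contains_impl(M$left, i, j)
  switch(M$op,
         intersection = l & mask_contains_impl(M$right, i, j),
         union = l | mask_contains_impl(M$right, i, j),
         difference = l & !mask_contains_impl(M$right, i, j))
}

# ---- row evaluation -------------------------------------------------------
# mask_row_sources(M, j, win): the ascending source indices i in the
# interval-set `win` with (i, j) in M.  Generators iterate target-major, one
# row at a time; each elementary mask knows how to produce its row lazily.

mask_row_sources <- function(M, j, win) UseMethod("mask_row_sources")

#' @export
mask_row_sources.csa_cset <- function(M, j, win) mask_row_sources(M$mask, j, win)

#' @export
mask_row_sources.csa_one_to_one <- function(M, j, win) {
  if (iset_contains(win, j)) j else integer()
}

#' @export
mask_row_sources.csa_random <- function(M, j, win) {
  cpp_random_row(M$seed, M$p, win$lo, win$hi, j)
}

#' @export
mask_row_sources.csa_cross <- function(M, j, win) {
  if (!iset_contains(M$targets, j)) return(integer())
  iset_members(iset_intersect(win, M$sources))
}

#' @export
mask_row_sources.csa_explicit <- function(M, j, win) {
  i <- M$pairs[M$pairs[, "j"] == j, "i"]
  i[iset_contains(win, i)]
}

#' @export
mask_row_sources.csa_full <- function(M, j, win) iset_members(win)

#' @export
mask_row_sources.csa_operator <- function(M, j, win) {
  l <- mask_row_sources(M$left, j, win)
  switch(M$op,
         intersection = {
           if (length(l) == 0L) return(integer())
           l[mask_contains_impl(M$right, l, rep_len(as.integer(j), length(l)))]
         },
         union = {
           r <- mask_row_sources(M$right, j, win)
           sort(unique(c(l, r)))
         },
         difference = {
           if (length(l) == 0L) return(integer())
           l[!mask_contains_impl(M$right, l, rep_len(as.integer(j), length(l)))]
         })
}

# ---- exact size -----------------------------------------------------------
# Exact connection count of a mask cut to swin x twin when computable without
# iteration; NA means "unknown a priori" (e.g. any expression involving a
# random mask or an operator node).

mask_size_in <- function(M, swin, twin) UseMethod("mask_size_in")

#' @export
mask_size_in.csa_cset <- function(M, swin, twin) mask_size_in(M$mask, swin, twin)

#' @export
mask_size_in.csa_one_to_one <- function(M, swin, twin) {
  iset_size(iset_intersect(swin, twin))
}

#' @export
mask_size_in.csa_random <- function(M, swin, twin) NA_real_

#' @export
mask_size_in.csa_cross <- function(M, swin, twin) {
  iset_size(iset_intersect(swin, M$sources)) *
    iset_size(iset_intersect(twin, M$targets))
}

#' @export
mask_size_in.csa_explicit <- function(M, swin, twin) {
  if (nrow(M$pairs) == 0L) return(0)
  sum(iset_contains(swin, M$pairs[, "i"]) & iset_contains(twin, M$pairs[, "j"]))
}

#' @export
mask_size_in.csa_full <- function(M, swin, twin) {
  iset_size(swin) * iset_size(twin)
}

#' @export
mask_size_in.csa_operator <- function(M, swin, twin) NA_real_
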