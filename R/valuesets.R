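#' Value sets: per-connection parameter functions
#'
#' A value set is a function `V(i, j) -> real` that assigns a parameter
#' (weight, delay, time constant, ...) to each connection of a mask.  Random
#' value sets are counter-based: the value of a pair is a pure function of
#' `(seed, i, j)`, so two iterations of the same expression — on any rank, in
#' any order — emit identical values.
#'
#' * `vs_constant(value)` — the same value on every connection.
#' * `vs_uniform(lo, hi, seed)` — independent Uniform(`lo`, `hi`) values.
#' * `vs_distance_delay(...)` — distance-dependent delays with clipped
#'   Gaussian noise: `V(i, j) = base + ||pos_s(i) - pos_t(j)|| / velocity +
#'   clip(N(0, sigma), lo, hi)`.
#' * `vs_custom(fn)` — any vectorized `function(i, j)`; not serializable.
#'
#' @param value the constant.
#' @param lo,hi for `vs_uniform`, the range; for `vs_distance_delay`, the
#'   clipping bounds of the noise term (`lo <= hi`; defaults `0, 0` disable
#'   the noise).
#' @param seed non-negative integer seed.
#' @param fn a vectorized `function(i, j)` returning numeric.
#' @return An object of class `csa_value_set`.
#' @examples
#' w <- vs_constant(2.5)
#' d <- vs_uniform(0.1, 1.0, seed = 3)
#' @name value-sets
NULL

new_value_set <- function(kind, fn, params = list(), serializable = TRUE) {
  structure(list(kind = kind, fn = fn, params = params,
                 serializable = serializable),
            class = "csa_value_set")
}

#' @rdname value-sets
#' @export
vs_constant <- function(value) {
  value <- as.double(value)
  if (length(value) != 1L || is.na(value)) stop("value must be a single number")
  new_value_set("constant",
                function(i, j) rep(value, length(i)),
                params = list(value = value))
}

#' @rdname value-sets
#' @export
vs_uniform <- function(lo, hi, seed = 0L) {
  lo <- as.double(lo); hi <- as.double(hi); seed <- as.integer(seed)
  if (hi < lo) stop("hi must be >= lo")
  if (is.na(seed) || seed < 0L) stop("seed must be a non-negative integer")
  new_value_set("uniform",
                function(i, j) lo + (hi - lo) * cpp_pair_u01(seed, .STREAM_UNIFORM, i, j),
                params = list(lo = lo, hi = hi, seed = seed))
}

#' @rdname value-sets
#' @export
vs_custom <- function(fn) {
  if (!is.function(fn)) stop("fn must be a function(i, j)")
  new_value_set("custom", fn, serializable = FALSE)
}

#' @rdname value-sets
#' @param pos_source,pos_target neuron positions: either a position table (a
#'   data frame with columns `id`, `x`, `y` and optionally `z`, ids being
#'   0-based population indices — see [read_positions()]), or a function
#'   mapping an index vector to a coordinate matrix.  Function-backed
#'   positions are not serializable.
#' @param velocity conduction velocity (> 0) converting distance to delay.
#' @param base base delay (>= 0) added to every connection.
#' @param sigma standard deviation (>= 0) of the Gaussian noise term.
#' @export
vs_distance_delay <- function(pos_source, pos_target, velocity,
                              base = 0, sigma = 0, lo = 0, hi = 0,
                              seed = 0L) {
  velocity <- as.double(velocity)
  base <- as.double(base); sigma <- as.double(sigma)
  lo <- as.double(lo); hi <- as.double(hi); seed <- as.integer(seed)
  if (!(velocity > 0)) stop("velocity must be > 0")
  if (base < 0) stop("base must be >= 0")
  if (sigma < 0) stop("sigma must be >= 0")
  if (lo > hi) stop("clipping bounds need lo <= hi")
  if (is.na(seed) || seed < 0L) stop("seed must be a non-negative integer")
  ps <- position_lookup(pos_source)
  pt <- position_lookup(pos_target)
  serializable <- !is.null(ps$table) && !is.null(pt$table)
  fn <- function(i, j) {
    a <- ps$fn(i)
    b <- pt$fn(rep_len(as.integer(j), length(i)))
    if (ncol(a) != ncol(b)) stop("source and target positions differ in dimension")
    d <- sqrt(rowSums((a - b)^2))
    noise <- if (sigma > 0) {
      qnorm(cpp_pair_u01(seed, .STREAM_NORMAL, i, j)) * sigma
    } else {
      rep(0, length(i))
    }
    base + d / velocity + pmin(pmax(noise, lo), hi)
  }
  new_value_set("distance_delay", fn,
                params = list(velocity = velocity, base = base, sigma = sigma,
                              lo = lo, hi = hi, seed = seed,
                              pos_source = ps$table, pos_target = pt$table),
                serializable = serializable)
}

# normalize positions to list(fn = index-vector -> matrix, table = df or NULL)
position_lookup <- function(pos) {
  if (is.function(pos)) {
    return(list(fn = function(idx) {
      out <- pos(idx)
      if (is.null(dim(out))) out <- matrix(out, nrow = length(idx))
      out
    }, table = NULL))
  }
  tab <- validate_positions(pos)
  coords <- as.matrix(tab[, setdiff(names(tab), "id"), drop = FALSE])
  fn <- function(idx) {
    row <- match(as.integer(idx), tab$id)
    if (anyNA(row))
      stop("no position for index ", idx[which(is.na(row))[1L]])
    coords[row, , drop = FALSE]
  }
  list(fn = fn, table = tab)
}

validate_positions <- function(tab) {
  tab <- as.data.frame(tab)
  need <- c("id", "x", "y")
  if (!all(need %in% names(tab)))
    stop("position table needs columns id, x, y (and optionally z)")
  keep <- intersect(c("id", "x", "y", "z"), names(tab))
  tab <- tab[, keep]
  tab$id <- as.integer(tab$id)
  if (anyNA(tab$id) || any(tab$id < 0L)) stop("position ids must be non-negative integers")
  if (anyDuplicated(tab$id)) stop("duplicate position id: ", tab$id[duplicated(tab$id)][1L])
  tab
}

#' Read a neuron position table
#'
#' Positions for geometric value sets are exchanged as tab-separated text
#' with a header line and columns `id`, `x`, `y` and optionally `z`; ids are
#' 0-based population indices.
#'
#' @param path path to the TSV file.
#' @return A data frame with columns `id`, `x`, `y`(, `z`).
#' @export
read_positions <- function(path) {
  validate_positions(read.delim(path, sep = "\t", check.names = TRUE))
}

#' @export
print.csa_value_set <- function(x, ...) {
  cat("<csa value set: ", x$kind, ">\n", sep = "")
  invisible(x)
}
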