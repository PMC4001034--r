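#' The connection-generator iteration protocol
#'
#' A connection generator is the consumer-facing view of a connection-set:
#' a stateful iterator modeled on a projection between a source and a target
#' population.  The consumer (a simulator kernel, or any other software)
#' first announces the available source and target index windows with
#' [cg_set_mask()] (serial) or [cg_set_masks()] (one window per parallel
#' rank), then calls [cg_start()] and repeatedly [cg_next()] until the end
#' signal (`NULL`) is returned.
#'
#' Iteration order is target-major: connections come out strictly ascending
#' in `(target, source)` — all sources are iterated per target.  On a
#' multi-rank layout, iteration is restricted to the local rank's window;
#' because random-mask membership is counter-based, the union of the streams
#' over the ranks equals the serial stream exactly.
#'
#' @param x a mask expression or connection-set ([cset()]).
#' @return `connection_generator()` returns an object of class
#'   `connection_generator` (an environment; protocol calls mutate it and
#'   return the generator invisibly, so it can also be used pipe-style).
#' @examples
#' g <- connection_generator(csa_intersect(delta(), cross_mask(0:6, 0:6)))
#' cg_set_mask(g, mask_spec(0:9, 0:9))
#' cg_size(g)   # -1: exact count unknown without iterating the operator node
#' cg_start(g)
#' cg_next(g)   # list(source = 0, target = 0, values = numeric(0))
#' @export
connection_generator <- function(x) {
  if (!inherits(x, "csa_mask") && !inherits(x, "csa_cset"))
    stop("x must be a mask expression or a connection-set")
  g <- new.env(parent = emptyenv())
  g$expr <- x
  g$masks <- NULL
  g$local <- NA_integer_
  g$started <- FALSE
  g$done <- FALSE
  class(g) <- "connection_generator"
  g
}

#' Source/target index windows for a generator
#'
#' A `mask_spec` tells a generator which source and target indices are
#' available to one consumer (one rank): only pairs `(i, j)` with `i` in
#' `sources` and `j` in `targets` are eligible for iteration.
#'
#' @param sources,targets [interval_set()]s or plain id vectors; empty
#'   vectors are allowed (a rank with no local targets).
#' @return An object of class `mask_spec`.
#' @export
mask_spec <- function(sources, targets) {
  structure(list(sources = as_interval_set(sources),
                 targets = as_interval_set(targets)),
            class = "mask_spec")
}

#' @export
print.mask_spec <- function(x, ...) {
  cat("<mask_spec: |sources| =", iset_size(x$sources),
      "|targets| =", iset_size(x$targets), ">\n")
  invisible(x)
}

#' @export
print.connection_generator <- function(x, ...) {
  cat("<connection_generator over ", deparse_mask(expr_mask(x$expr)),
      ", arity ", csa_arity(x), ", masks ",
      if (is.null(x$masks)) "unset" else
        sprintf("set (%d rank(s), local %d)", length(x$masks), x$local),
      ">\n", sep = "")
  invisible(x)
}

#' @rdname connection_generator
#' @param g a connection generator.
#' @export
cg_arity <- function(g) csa_arity(g$expr)

#' Exact connection count, when knowable without iteration
#'
#' Returns the exact number of connections the generator will yield under
#' its current (local) window when that count is computable directly —
#' explicit lists, and the one-to-one, Cartesian-product and full masks cut
#' by interval windows.  Otherwise returns the sentinel `-1` ("unknown"):
#' stochastic masks and operator expressions require iteration to count.
#' A non-negative return is never wrong.
#'
#' @param g a connection generator with masks set.
#' @return Integer-valued count, or `-1`.
#' @export
cg_size <- function(g) {
  if (is.null(g$masks)) stop("cg_size called before set_mask")
  m <- g$masks[[g$local + 1L]]
  n <- mask_size_in(expr_mask(g$expr), m$sources, m$targets)
  if (is.na(n)) -1 else n
}

#' @rdname connection_generator
#' @param mask a [mask_spec()].
#' @export
cg_set_mask <- function(g, mask) cg_set_masks(g, list(mask), 0L)

#' Set per-rank windows on a generator
#'
#' The parallel form of [cg_set_mask()]: every rank passes the *full* list
#' of windows for all ranks plus its own 0-based rank number, so that a
#' generator may exploit the global layout (e.g. to skip non-local work).
#' Iteration is restricted to `masks[[local + 1]]`.  Target windows of
#' different ranks are typically disjoint; overlap is permitted but flagged
#' with a warning.
#'
#' @param g a connection generator (not mid-iteration).
#' @param masks list of [mask_spec()]s, one per rank.
#' @param local 0-based index of the local rank.
#' @return The generator, invisibly.
#' @export
cg_set_masks <- function(g, masks, local = 0L) {
  if (g$started && !g$done)
    stop("cannot change masks mid-iteration; finish or restart first")
  if (!is.list(masks) || length(masks) == 0L ||
      !all(vapply(masks, inherits, logical(1), what = "mask_spec")))
    stop("masks must be a non-empty list of mask_spec objects")
  local <- as.integer(local)
  if (is.na(local) || local < 0L || local >= length(masks))
    stop("local rank out of range: ", local, " with ", length(masks), " mask(s)")
  if (length(masks) > 1L) {
    # single sorted sweep over all ranks' target intervals; within one rank
    # intervals are disjoint and non-adjacent, so any overlap found is
    # between two different ranks
    lo <- unlist(lapply(masks, function(m) m$targets$lo))
    hi <- unlist(lapply(masks, function(m) m$targets$hi))
    rk <- rep(seq_along(masks) - 1L,
              vapply(masks, function(m) length(m$targets$lo), integer(1)))
    if (length(lo) > 1L) {
      o <- order(lo)
      clash <- which(lo[o][-1L] <= hi[o][-length(o)])
      if (length(clash)) {
        k <- clash[1L]
        warning("target windows of ranks ", rk[o][k], " and ", rk[o][k + 1L],
                " overlap; connections in the overlap will be yielded on both ranks")
      }
    }
  }
  g$masks <- masks
  g$local <- local
  g$started <- FALSE
  g$done <- FALSE
  invisible(g)
}

#' @rdname connection_generator
#' @export
cg_start <- function(g) {
  if (is.null(g$masks)) stop("cg_start called before set_mask")
  local <- g$masks[[g$local + 1L]]
  g$targets <- iset_members(local$targets)
  g$swin <- local$sources
  g$ti <- 0L                  # index of the current target in g$targets
  g$row_src <- integer()
  g$row_vals <- NULL
  g$row_pos <- 0L
  g$started <- TRUE
  g$done <- FALSE
  invisible(g)
}

# materialize the row of target j: sources plus the value matrix
cg_row <- function(g, j) {
  src <- mask_row_sources(expr_mask(g$expr), j, g$swin)
  vals <- expr_values(g$expr)
  vmat <- if (length(vals) && length(src)) {
    vapply(vals, function(v) as.double(v$fn(src, j)), numeric(length(src)))
  } else {
    NULL
  }
  if (!is.null(vmat) && is.null(dim(vmat)))   # single source row
    vmat <- matrix(vmat, nrow = length(src))
  list(src = src, vals = vmat)
}

#' @rdname connection_generator
#' @return `cg_next()` returns the next connection as
#'   `list(source =, target =, values =)` with `values` of length
#'   `cg_arity(g)`, or `NULL` (the end signal) once the stream is exhausted;
#'   further calls keep returning `NULL`.
#' @export
cg_next <- function(g) {
  if (!g$started) stop("cg_next called before cg_start")
  if (g$done) return(NULL)
  while (g$row_pos >= length(g$row_src)) {
    if (g$ti >= length(g$targets)) {
      g$done <- TRUE
      return(NULL)
    }
    g$ti <- g$ti + 1L
    row <- cg_row(g, g$targets[g$ti])
    g$row_src <- row$src
    g$row_vals <- row$vals
    g$row_pos <- 0L
  }
  g$row_pos <- g$row_pos + 1L
  values <- if (is.null(g$row_vals)) numeric() else g$row_vals[g$row_pos, ]
  list(source = g$row_src[g$row_pos],
       target = g$targets[g$ti],
       values = as.double(values))
}

#' Drain a generator into a data frame
#'
#' Restarts the generator and collects its whole stream (row-buffered
#' internally, so large streams avoid per-connection overhead).  Columns are
#' `source`, `target`, then `value_1 ... value_k` for arity `k`, in exact
#' iteration order (ascending `(target, source)`).
#'
#' `cg_count()` does the same traversal but only counts, skipping value
#' evaluation.
#'
#' @param g a connection generator with masks set.
#' @return A data frame (`cg_collect`) or a count (`cg_count`).
#' @export
cg_collect <- function(g) {
  cg_start(g)
  arity <- cg_arity(g)
  srcs <- list(); tgts <- list(); vals <- list()
  k <- 0L
  while (g$ti < length(g$targets)) {
    g$ti <- g$ti + 1L
    j <- g$targets[g$ti]
    row <- cg_row(g, j)
    if (length(row$src)) {
      k <- k + 1L
      srcs[[k]] <- row$src
      tgts[[k]] <- rep.int(j, length(row$src))
      if (arity > 0L) vals[[k]] <- row$vals
    }
  }
  g$done <- TRUE
  out <- data.frame(source = unlist(srcs) %||% integer(),
                    target = unlist(tgts) %||% integer())
  if (arity > 0L) {
    vmat <- if (k > 0L) do.call(rbind, vals) else matrix(0, 0L, arity)
    colnames(vmat) <- paste0("value_", seq_len(arity))
    out <- cbind(out, as.data.frame(vmat))
  }
  rownames(out) <- NULL
  out
}

#' @rdname cg_collect
#' @export
cg_count <- function(g) {
  cg_start(g)
  mask <- expr_mask(g$expr)
  total <- 0
  for (j in g$targets) total <- total + length(mask_row_sources(mask, j, g$swin))
  g$ti <- length(g$targets)
  g$done <- TRUE
  total
}

`%||%` <- function(a, b) if (is.null(a)) b else a
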