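#' Connection-sets: a mask plus value sets
#'
#' A connection-set `C = (M, V0, V1, ...)` couples a mask with zero or more
#' value sets; its *arity* is the number of value sets, i.e. the number of
#' values carried by each connection.  A connection-set of arity 0 is for
#' all purposes equivalent to its mask, and the two are interchangeable
#' throughout the package — `cset(M)` simply returns `M`.
#'
#' @param mask a mask expression (arity 0).
#' @param ... value sets ([vs_constant()], [vs_uniform()],
#'   [vs_distance_delay()], [vs_custom()]), in the order their values should
#'   appear in each connection's value vector.
#' @return A connection-set (class `csa_cset`), or `mask` itself when no
#'   value sets are given.
#' @examples
#' C <- cset(delta(), vs_constant(1.0), vs_constant(0.5))
#' csa_arity(C)   # 2
#' @export
cset <- function(mask, ...) {
  values <- list(...)
  if (inherits(mask, "csa_cset"))
    stop("mask already carries value sets; build from the bare mask instead")
  if (!inherits(mask, "csa_mask")) stop("mask must be a mask expression")
  if (length(values) == 0L) return(mask)
  ok <- vapply(values, inherits, logical(1), what = "csa_value_set")
  if (!all(ok)) stop("all ... arguments must be value sets")
  structure(list(mask = mask, value_sets = values), class = "csa_cset")
}

#' Arity: the number of per-connection values
#'
#' @param x a mask, connection-set, or [connection_generator()].
#' @return Integer count of value sets (0 for a bare mask).
#' @export
csa_arity <- function(x) {
  if (inherits(x, "connection_generator")) return(csa_arity(x$expr))
  if (inherits(x, "csa_cset")) return(length(x$value_sets))
  if (inherits(x, "csa_mask")) return(0L)
  stop("not a connection-set expression")
}

# the mask component of a mask-or-cset
expr_mask <- function(x) if (inherits(x, "csa_cset")) x$mask else x

# the value-set list of a mask-or-cset
expr_values <- function(x) if (inherits(x, "csa_cset")) x$value_sets else list()

#' @export
print.csa_cset <- function(x, ...) {
  cat("<csa connection-set: ", deparse_mask(x$mask),
      " with ", length(x$value_sets), " value set(s): ",
      paste(vapply(x$value_sets, `[[`, "", "kind"), collapse = ", "),
      ">\n", sep = "")
  invisible(x)
}
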