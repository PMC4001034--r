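#' Bijection between 0-based algebra indices and simulator GIDs
#'
#' Simulators identify neurons by global ids (GIDs); the algebra enumerates
#' each population with consecutive indices starting at 0.  `gid_index_map()`
#' fixes the bijection: index `k` maps to the k-th GID in the order the user
#' supplied the list (GIDs need not be contiguous or sorted).
#'
#' @param gids non-empty vector of distinct non-negative integers.
#' @return An object of class `gid_map`.
#' @examples
#' m <- gid_index_map(c(101, 205, 206))
#' gid_of(m, 0:2)      # 101 205 206
#' index_of(m, 206)    # 2
#' @export
gid_index_map <- function(gids) {
  gids <- as.integer(gids)
  if (length(gids) == 0L) stop("gids must be non-empty")
  if (anyNA(gids)) stop("gids must not contain NA")
  if (any(gids < 0L)) stop("gids must be non-negative")
  dup <- gids[duplicated(gids)]
  if (length(dup)) stop("duplicate GID: ", dup[1L])
  structure(list(gids = gids), class = "gid_map")
}

#' @rdname gid_index_map
#' @param m a `gid_map`.
#' @param index 0-based indices to translate to GIDs.
#' @export
gid_of <- function(m, index) {
  index <- as.integer(index)
  if (any(index < 0L | index >= length(m$gids)))
    stop("index out of range for this population")
  m$gids[index + 1L]
}

#' @rdname gid_index_map
#' @param gid GIDs to translate to 0-based indices.
#' @export
index_of <- function(m, gid) {
  pos <- match(as.integer(gid), m$gids)
  if (anyNA(pos)) stop("GID not in this population: ", gid[which(is.na(pos))[1L]])
  pos - 1L
}

#' @export
print.gid_map <- function(x, ...) {
  cat("<gid_map over", length(x$gids), "GIDs>\n")
  invisible(x)
}
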