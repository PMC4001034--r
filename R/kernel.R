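#' Populations and the mock simulator network
#'
#' The kernel is a minimal simulator stand-in that exercises the connect
#' path: populations are ordered lists of unique positive global ids (GIDs),
#' and a `network` accumulates a connection table of
#' `(source GID, target GID, named parameters)`.  Networks have reference
#' semantics (they are environments, like simulator state): [cg_connect()]
#' appends to the table in place and also returns the network.
#'
#' @param gids non-empty vector of unique positive integers.
#' @return `population()` returns a `csa_population`; `network()` an empty
#'   `csa_network`.
#' @examples
#' net <- network()
#' pop <- population(c(11, 12, 13, 14, 15))
#' @export
population <- function(gids) {
  gids <- as.integer(gids)
  if (length(gids) == 0L) stop("a population must be non-empty")
  if (anyNA(gids) || any(gids <= 0L)) stop("GIDs must be positive integers")
  dup <- gids[duplicated(gids)]
  if (length(dup)) stop("duplicate GID: ", dup[1L])
  structure(list(gids = gids), class = "csa_population")
}

#' @rdname population
#' @export
network <- function() {
  net <- new.env(parent = emptyenv())
  net$connections <- data.frame(source_gid = integer(), target_gid = integer())
  class(net) <- "csa_network"
  net
}

#' @export
print.csa_network <- function(x, ...) {
  cat("<csa network:", nrow(x$connections), "connection(s),",
      max(0L, ncol(x$connections) - 2L), "parameter column(s)>\n")
  invisible(x)
}

#' Round-robin assignment of targets to ranks
#'
#' The default distribution of target neurons over parallel ranks: target
#' index `j` lives on rank `j %% n_ranks`.  Deterministic, and partitions
#' the targets disjointly and exhaustively.  [cg_connect()] accepts any
#' other assignment function with the same signature.
#'
#' @param j non-negative target indices.
#' @param n_ranks number of ranks (>= 1).
#' @return Integer rank ids in `0:(n_ranks - 1)`.
#' @export
rank_of_target <- function(j, n_ranks) {
  n_ranks <- as.integer(n_ranks)
  if (is.na(n_ranks) || n_ranks < 1L) stop("n_ranks must be >= 1")
  as.integer(j) %% n_ranks
}

#' Create connections from a generator (CGConnect)
#'
#' Wires `pre` to `post` as prescribed by the rules in the connection
#' generator `g`, emulating a parallel simulator in-process: for each rank
#' `r < n_ranks` the kernel derives that rank's window (all `pre` indices as
#' sources; the `post` indices assigned to `r` as targets), calls
#' [cg_set_masks()] with the full window list, drains the stream, and stores
#' every yielded `(i, j, values)` as `(pre GID, post GID, named parameters)`
#' using `param_map`.  Per-rank streams are concatenated in rank order, so
#' the resulting table is deterministic — and, because membership and values
#' are counter-based, identical for every `n_ranks`.
#'
#' @param net a [network()] (modified in place and returned).
#' @param g a [connection_generator()].
#' @param pre,post source and target [population()]s (or plain GID vectors).
#' @param param_map named vector/list mapping parameter names (e.g.
#'   `"weight"`, `"delay"`) to their 0-based position in the generator's
#'   value vector; `NULL` or empty stores bare edges.
#' @param n_ranks number of emulated ranks.
#' @param rank_fn target-to-rank assignment, by default [rank_of_target()].
#' @param strict_arity if `TRUE`, reject generators whose arity is neither 0
#'   nor 2 — mirroring the restriction of simulator kernels that only accept
#'   (weight, delay) value vectors.  Default `FALSE`: any arity works.
#' @return The network, invisibly.
#' @examples
#' M <- explicit_mask(rbind(c(0, 1), c(1, 1), c(1, 2),
#'                          c(3, 2), c(2, 3), c(0, 4)))
#' net <- network()
#' cg_connect(net, connection_generator(M), population(11:15), population(11:15))
#' network_stats(net)$n_connections   # 6
#' @export
cg_connect <- function(net, g, pre, post, param_map = NULL, n_ranks = 1L,
                       rank_fn = rank_of_target, strict_arity = FALSE) {
  if (!inherits(net, "csa_network")) stop("net must be a csa network")
  if (!inherits(g, "connection_generator"))
    stop("g must be a connection generator")
  if (!inherits(pre, "csa_population")) pre <- population(pre)
  if (!inherits(post, "csa_population")) post <- population(post)
  n_ranks <- as.integer(n_ranks)
  if (is.na(n_ranks) || n_ranks < 1L) stop("n_ranks must be >= 1")

  arity <- cg_arity(g)
  if (strict_arity && !arity %in% c(0L, 2L))
    stop("strict mode supports only arities 0 and 2, got ", arity)
  pm <- validate_param_map(param_map, arity)

  pre_map <- gid_index_map(pre$gids)
  post_map <- gid_index_map(post$gids)
  src_win <- interval_set(0L, length(pre$gids) - 1L)
  post_idx <- seq_along(post$gids) - 1L
  ranks <- rank_fn(post_idx, n_ranks)
  if (!all(ranks %in% 0:(n_ranks - 1L)))
    stop("rank_fn returned rank ids outside 0:(n_ranks - 1)")
  masks <- lapply(0:(n_ranks - 1L), function(r) {
    js <- post_idx[ranks == r]
    mask_spec(src_win, if (length(js)) interval_set_from_ids(js) else interval_set())
  })

  chunks <- vector("list", n_ranks)
  for (r in 0:(n_ranks - 1L)) {
    cg_set_masks(g, masks, local = r)
    stream <- cg_collect(g)
    tab <- data.frame(source_gid = gid_of(pre_map, stream$source),
                      target_gid = gid_of(post_map, stream$target))
    for (name in names(pm))
      tab[[name]] <- stream[[paste0("value_", pm[[name]] + 1L)]]
    chunks[[r + 1L]] <- tab
  }
  new_rows <- do.call(rbind, chunks)

  old <- net$connections
  if (nrow(old) == 0L && ncol(old) == 2L && !identical(names(old), names(new_rows))) {
    net$connections <- new_rows      # first connect fixes the parameter columns
  } else {
    if (!identical(names(old), names(new_rows)))
      stop("parameter columns differ from previously stored connections: ",
           "have (", paste(names(old), collapse = ", "), "), new (",
           paste(names(new_rows), collapse = ", "), ")")
    net$connections <- rbind(old, new_rows)
  }
  rownames(net$connections) <- NULL
  invisible(net)
}

validate_param_map <- function(param_map, arity) {
  if (is.null(param_map) || length(param_map) == 0L) return(integer())
  idx <- unlist(param_map)
  if (is.null(names(param_map)) || !all(nzchar(names(param_map))))
    stop("param_map must be named (parameter name -> value index)")
  idx <- as.integer(idx)
  if (anyNA(idx) || any(idx < 0L)) stop("param_map indices must be non-negative")
  if (anyDuplicated(idx)) stop("param_map indices must be distinct")
  bad <- idx[idx >= arity]
  if (length(bad))
    stop("param_map index ", bad[1L], " >= generator arity ", arity)
  setNames(idx, names(param_map))
}

#' Summarize a network's connection table
#'
#' Pure summary of the stored table: total connection count, in-degree per
#' target GID, out-degree per source GID, the range of every stored
#' parameter, and the number of duplicated (multi-edge) GID pairs — the
#' kernel stores repeated identical pairs as multi-edges and flags them
#' here.
#'
#' @param net a [network()].
#' @return A list with elements `n_connections`, `in_degree`, `out_degree`,
#'   `param_range`, `n_multi_edges`.
#' @export
network_stats <- function(net) {
  tab <- net$connections
  params <- setdiff(names(tab), c("source_gid", "target_gid"))
  list(
    n_connections = nrow(tab),
    in_degree = if (nrow(tab)) table(tab$target_gid) else table(integer()),
    out_degree = if (nrow(tab)) table(tab$source_gid) else table(integer()),
    param_range = lapply(setNames(params, params), function(p) range(tab[[p]])),
    n_multi_edges = sum(duplicated(tab[c("source_gid", "target_gid")]))
  )
}

#' Export a network's connection table
#'
#' `write_network_tsv()` writes the table as tab-separated text with header
#' `source_gid`, `target_gid`, then one column per named parameter.
#' `write_network_mtx()` writes the 0/1 adjacency (duplicates collapsed) in
#' Matrix Market coordinate format; rows are source GIDs, columns target
#' GIDs, with dimensions `max(GID)`.
#'
#' @param net a [network()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  write.table(net$connections, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
write_network_mtx <- function(net, path) {
  tab <- unique(net$connections[c("source_gid", "target_gid")])
  n <- if (nrow(tab)) max(tab$source_gid, tab$target_gid) else 1L
  m <- Matrix::sparseMatrix(i = tab$source_gid, j = tab$target_gid,
                            x = 1, dims = c(n, n))
  Matrix::writeMM(m, path)
  invisible(path)
}
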