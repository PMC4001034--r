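test_that("cg_connect stores GID-translated connections", {
  net <- network()
  g <- connection_generator(fig_mask())
  cg_connect(net, g, population(11:15), population(11:15))
  tab <- net$connections
  expect_equal(nrow(tab), 6L)
  expect_true(any(tab$source_gid == 11 & tab$target_gid == 12))
  expect_true(any(tab$source_gid == 11 & tab$target_gid == 15))
  # the full translated set, regardless of storage order
  got <- sort(paste(tab$source_gid, tab$target_gid))
  want <- sort(paste(11 + c(0, 1, 1, 3, 2, 0), 11 + c(1, 1, 2, 2, 3, 4)))
  expect_equal(got, want)
})

test_that("the stored connection set is independent of n_ranks", {
  ref <- NULL
  for (R in c(1L, 2L, 3L, 7L)) {
    net <- network()
    g <- connection_generator(
      cset(csa_difference(random_mask(0.3, seed = 9), delta()),
           vs_constant(2), vs_uniform(0, 1, seed = 4)))
    cg_connect(net, g, population(101:130), population(201:230),
               param_map = c(weight = 0, delay = 1), n_ranks = R)
    tab <- net$connections
    tab <- tab[order(tab$target_gid, tab$source_gid), ]
    rownames(tab) <- NULL
    if (is.null(ref)) ref <- tab else expect_identical(tab, ref)
  }
  # and under a non-modulo rank assignment
  blocky <- function(j, n_ranks) pmin(as.integer(j) %/% 10L, n_ranks - 1L)
  net <- network()
  g <- connection_generator(
    cset(csa_difference(random_mask(0.3, seed = 9), delta()),
         vs_constant(2), vs_uniform(0, 1, seed = 4)))
  cg_connect(net, g, population(101:130), population(201:230),
             param_map = c(weight = 0, delay = 1), n_ranks = 3L,
             rank_fn = blocky)
  tab <- net$connections
  tab <- tab[order(tab$target_gid, tab$source_gid), ]
  rownames(tab) <- NULL
  expect_identical(tab, ref)
})

test_that("stored GID pairs map back to the generator's index stream", {
  pre <- population(c(40, 2, 17, 90, 3))    # non-contiguous, unsorted GIDs
  post <- population(c(7, 5, 900, 12, 44))
  e <- random_mask(0.5, seed = 12)
  net <- network()
  cg_connect(net, connection_generator(e), pre, post, n_ranks = 2)
  stream <- stream_pairs(e, 0:4, 0:4)
  pm <- gid_index_map(pre$gids); qm <- gid_index_map(post$gids)
  back <- cbind(source = index_of(pm, net$connections$source_gid),
                target = index_of(qm, net$connections$target_gid))
  back <- back[order(back[, "target"], back[, "source"]), , drop = FALSE]
  expect_equal(back, stream)
})

test_that("param_map names the stored parameters, exactly", {
  net <- network()
  g <- connection_generator(cset(fig_mask(), vs_constant(1.5),
                                 vs_uniform(0.1, 0.9, seed = 5)))
  cg_connect(net, g, population(11:15), population(11:15),
             param_map = c(weight = 0, delay = 1))
  expect_equal(names(net$connections),
               c("source_gid", "target_gid", "weight", "delay"))
  expect_true(all(net$connections$weight == 1.5))
  expect_true(all(net$connections$delay >= 0.1 & net$connections$delay <= 0.9))
  # an index beyond the arity is rejected
  net2 <- network()
  g2 <- connection_generator(cset(fig_mask(), vs_constant(1)))
  expect_error(
    cg_connect(net2, g2, population(1:5), population(1:5),
               param_map = c(weight = 0, delay = 1)),
    "param_map index 1 >= generator arity 1")
  expect_error(
    cg_connect(net2, g2, population(1:5), population(1:5),
               param_map = c(weight = 0, delay = 0)),
    "distinct")
})

test_that("strict arity mode reproduces the 0-or-2 kernel restriction", {
  net <- network()
  g1 <- connection_generator(cset(fig_mask(), vs_constant(1)))
  expect_error(cg_connect(net, g1, population(1:5), population(1:5),
                          strict_arity = TRUE),
               "only arities 0 and 2")
  g0 <- connection_generator(fig_mask())
  expect_silent(cg_connect(net, g0, population(1:5), population(1:5),
                           strict_arity = TRUE))
  g2 <- connection_generator(cset(fig_mask(), vs_constant(1), vs_constant(2)))
  net2 <- network()
  expect_silent(cg_connect(net2, g2, population(1:5), population(1:5),
                           param_map = c(weight = 0, delay = 1),
                           strict_arity = TRUE))
})

test_that("rank_of_target partitions targets disjointly and exhaustively", {
  expect_equal(rank_of_target(5, 1), 0L)
  expect_equal(rank_of_target(5, 2), 1L)
  for (R in c(1L, 3L, 7L)) {
    ranks <- rank_of_target(0:99, R)
    expect_setequal(unique(ranks), 0:(R - 1L))
    expect_equal(unname(lengths(split(0:99, ranks))),
                 as.integer(table(0:99 %% R)))
    expect_equal(sort(unlist(split(0:99, ranks))), 0:99, ignore_attr = TRUE)
  }
})

test_that("network_stats agrees with the stored table", {
  net <- network()
  cg_connect(net, connection_generator(fig_mask()),
             population(11:15), population(11:15))
  st <- network_stats(net)
  expect_equal(st$n_connections, 6L)
  # index 2 maps to GID 13 and receives (1,2) and (3,2)
  expect_equal(unname(st$in_degree[["13"]]), 2L)
  expect_equal(st$n_multi_edges, 0L)
  expect_equal(network_stats(network())$n_connections, 0L)
  # delta over 7 neurons
  net7 <- network()
  cg_connect(net7, connection_generator(delta()),
             population(1:7), population(1:7))
  expect_equal(network_stats(net7)$n_connections, 7L)
  # repeated connect stores multi-edges and flags them
  cg_connect(net7, connection_generator(delta()),
             population(1:7), population(1:7))
  expect_equal(network_stats(net7)$n_multi_edges, 7L)
})

test_that("network export writes TSV and Matrix Market adjacency", {
  net <- network()
  g <- connection_generator(cset(fig_mask(), vs_constant(1.5), vs_constant(0.2)))
  cg_connect(net, g, population(11:15), population(11:15),
             param_map = c(weight = 0, delay = 1))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network_tsv(net, tsv)
  back <- read.delim(tsv)
  expect_equal(names(back), c("source_gid", "target_gid", "weight", "delay"))
  expect_equal(nrow(back), 6L)
  mtx <- withr::local_tempfile(fileext = ".mtx")
  write_network_mtx(net, mtx)
  m <- Matrix::readMM(mtx)
  expect_equal(sum(m), 6)
  expect_equal(as.numeric(m[11, 12]), 1)
})

test_that("population and param_map validation reject bad input", {
  expect_error(population(integer()), "non-empty")
  expect_error(population(c(0, 1)), "positive")
  expect_error(population(c(3, 3)), "duplicate GID: 3")
  net <- network()
  g <- connection_generator(cset(fig_mask(), vs_constant(1), vs_constant(2)))
  expect_error(cg_connect(net, g, population(1:5), population(1:5),
                          param_map = c(0, 1)), "named")
})
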