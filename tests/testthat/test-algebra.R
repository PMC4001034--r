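test_that("the one-to-one mask is the infinite diagonal", {
  d <- delta()
  expect_true(mask_contains(d, 5, 5))
  expect_false(mask_contains(d, 5, 6))
  expect_true(mask_contains(d, 123456, 123456))
  cut <- stream_pairs(csa_intersect(cross_mask(0:6, 0:6), d), 0:20, 0:20)
  expect_equal(cut, cbind(source = 0:6, target = 0:6))
})

test_that("random mask degenerate probabilities are empty and full", {
  ii <- rep(0:19, each = 20)
  jj <- rep(0:19, times = 20)
  expect_false(any(mask_contains(random_mask(0, seed = 1), ii, jj)))
  expect_true(all(mask_contains(random_mask(1, seed = 1), ii, jj)))
  expect_error(random_mask(1.2), "probability")
  expect_error(random_mask(-0.1), "probability")
})

test_that("random mask realized density matches the binomial expectation", {
  g <- connection_generator(random_mask(0.1, seed = 7))
  cg_set_mask(g, mask_spec(interval_set(0, 999), interval_set(0, 999)))
  n <- cg_count(g)
  sigma <- sqrt(1e6 * 0.1 * 0.9)
  expect_lt(abs(n - 1e5), 4 * sigma)
})

test_that("random mask densities are stable across disjoint blocks", {
  p <- 0.2
  m <- random_mask(p, seed = 3)
  sigma <- sqrt(1e4 * p * (1 - p))
  for (block in list(c(0, 0), c(100, 0), c(0, 100), c(300, 500))) {
    s <- interval_set(block[1], block[1] + 99)
    t <- interval_set(block[2], block[2] + 99)
    g <- connection_generator(m)
    cg_set_mask(g, mask_spec(s, t))
    expect_lt(abs(cg_count(g) - p * 1e4), 4 * sigma)
  }
})

test_that("random-mask membership is a pure function of (seed, i, j)", {
  a <- random_mask(0.3, seed = 42)
  b <- random_mask(0.3, seed = 42)   # distinct expression objects, same set
  ii <- rep(0:29, each = 30)
  jj <- rep(0:29, times = 30)
  expect_identical(mask_contains(a, ii, jj), mask_contains(b, ii, jj))
  # row evaluation through any window agrees with pointwise membership
  for (j in c(0, 7, 29)) {
    row <- stream_pairs(a, 0:29, j:j)
    expect_equal(row[, "source"], (0:29)[mask_contains(a, 0:29, j)])
  }
  # a different seed gives a different set (with overwhelming probability)
  c2 <- random_mask(0.3, seed = 43)
  expect_false(identical(mask_contains(a, ii, jj), mask_contains(c2, ii, jj)))
})

test_that("set difference with delta removes exactly the diagonal", {
  er <- csa_difference(random_mask(0.5, seed = 0), delta())
  ks <- c(0:20, 999, 12345)
  expect_false(any(mask_contains(er, ks, ks)))
  # off-diagonal membership is untouched
  base <- random_mask(0.5, seed = 0)
  ii <- rep(0:14, each = 15); jj <- rep(0:14, times = 15)
  off <- ii != jj
  expect_identical(mask_contains(er, ii[off], jj[off]),
                   mask_contains(base, ii[off], jj[off]))
})

test_that("operator combinations match brute-force enumeration", {
  M <- fig_mask()
  got <- stream_pairs(csa_intersect(M, cross_mask(0:1, 0:4)), 0:9, 0:9)
  expect_equal(got, cbind(source = c(0L, 1L, 1L, 0L), target = c(1L, 1L, 2L, 4L)))
  # X - X is empty over any finite window
  for (X in list(M, delta(), random_mask(0.6, 5), full_mask())) {
    expect_equal(nrow(stream_pairs(csa_difference(X, X), 0:9, 0:9)), 0L)
  }
})

test_that("operators reject operands that carry value sets", {
  C <- cset(fig_mask(), vs_constant(1))
  expect_error(csa_intersect(C, delta()), "attach value sets at top level")
  expect_error(combine("union", delta(), C), "attach value sets at top level")
})

test_that("oracle equivalence holds for random expressions on 10x10 windows", {
  set.seed(101)
  for (rep in 1:40) {
    e <- rand_expr(depth = 3)
    expect_equal(stream_pairs(e, 0:9, 0:9), oracle_pairs(e, 0:9, 0:9))
  }
})

test_that("algebraic laws hold on finite windows", {
  set.seed(202)
  for (rep in 1:15) {
    A <- rand_expr(2); B <- rand_expr(2); C <- rand_expr(2)
    expect_equal(stream_pairs(csa_union(A, B), 0:9, 0:9),
                 stream_pairs(csa_union(B, A), 0:9, 0:9))
    expect_equal(stream_pairs(csa_intersect(A, csa_union(B, C)), 0:9, 0:9),
                 stream_pairs(csa_union(csa_intersect(A, B),
                                        csa_intersect(A, C)), 0:9, 0:9))
    expect_equal(nrow(stream_pairs(csa_difference(A, A), 0:9, 0:9)), 0L)
    expect_equal(stream_pairs(csa_intersect(A, full_mask()), 0:9, 0:9),
                 stream_pairs(A, 0:9, 0:9))
  }
})

test_that("operator sugar &, |, - builds the same expressions", {
  A <- random_mask(0.4, 1)
  expect_equal(stream_pairs(A - delta(), 0:9, 0:9),
               stream_pairs(csa_difference(A, delta()), 0:9, 0:9))
  expect_equal(stream_pairs(A & full_mask(), 0:9, 0:9),
               stream_pairs(A, 0:9, 0:9))
  expect_equal(stream_pairs(delta() | A, 0:9, 0:9),
               stream_pairs(csa_union(delta(), A), 0:9, 0:9))
})

test_that("connection-sets carry value sets and report their arity", {
  C <- cset(delta(), vs_constant(1.0), vs_constant(0.5))
  expect_equal(csa_arity(C), 2L)
  expect_equal(csa_arity(fig_mask()), 0L)
  expect_equal(csa_arity(cset(fig_mask(), vs_constant(2.0))), 1L)
  # cset with no value sets is the mask itself
  expect_identical(cset(delta()), delta())
  g <- connection_generator(C)
  cg_set_mask(g, mask_spec(0:4, 0:4))
  df <- cg_collect(g)
  expect_equal(nrow(df), 5L)
  expect_true(all(df$value_1 == 1.0))
  expect_true(all(df$value_2 == 0.5))
})

test_that("uniform value sets are deterministic and bounded", {
  C <- cset(full_mask(), vs_uniform(2, 5, seed = 9))
  a <- cg_collect(cg_set_mask(connection_generator(C), mask_spec(0:9, 0:9)))
  b <- cg_collect(cg_set_mask(connection_generator(C), mask_spec(0:9, 0:9)))
  expect_identical(a, b)
  expect_true(all(a$value_1 >= 2 & a$value_1 <= 5))
  expect_gt(length(unique(a$value_1)), 50)   # actually varies per pair
})

test_that("distance-dependent delays follow the closed form", {
  pos <- data.frame(id = 0:3, x = c(0, 3, 0, 1), y = c(0, 4, 2, 1))
  # zero distance, no noise: V = base
  v0 <- vs_distance_delay(pos, pos, velocity = 2, base = 0.7)
  expect_equal(v0$fn(2, 2), 0.7)
  # points at distance 5 (3-4-5 triangle): V = base + d / velocity
  expect_equal(v0$fn(0, 1), 0.7 + 5 / 2)
  # sigma > 0 with lo = hi = 0 clips the noise to a point
  v1 <- vs_distance_delay(pos, pos, velocity = 2, base = 0.7, sigma = 3,
                          lo = 0, hi = 0, seed = 4)
  expect_equal(v1$fn(0:3, 1), v0$fn(0:3, 1))
  expect_error(v0$fn(9, 0), "no position for index 9")
  expect_error(vs_distance_delay(pos, pos, velocity = 0), "velocity")
  expect_error(vs_distance_delay(pos, pos, velocity = 1, lo = 1, hi = 0), "lo <= hi")
})

test_that("clipped noise terms always lie within the clipping bounds", {
  pos <- data.frame(id = 0:9, x = rep(0, 10), y = rep(0, 10))
  v <- vs_distance_delay(pos, pos, velocity = 1, base = 1, sigma = 2,
                         lo = -0.5, hi = 0.25, seed = 8)
  C <- cset(full_mask(), v)
  df <- cg_collect(cg_set_mask(connection_generator(C), mask_spec(0:9, 0:9)))
  noise <- df$value_1 - 1   # distance is zero everywhere
  expect_true(all(noise >= -0.5 & noise <= 0.25))
  expect_gt(max(noise), 0.2)     # clipping actually engages
  expect_lt(min(noise), -0.45)
  # reproducible across independent iterations
  df2 <- cg_collect(cg_set_mask(connection_generator(C), mask_spec(0:9, 0:9)))
  expect_identical(df, df2)
})

test_that("position tables round-trip through TSV", {
  pos <- data.frame(id = 0:2, x = c(0, 1, 2), y = c(5, 4, 3), z = c(1, 1, 2))
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(pos, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_positions(f), pos)
})
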