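# Shared fixtures and independent oracles.

# the worked-example mask M = {(0,1),(1,1),(1,2),(3,2),(2,3),(0,4)}
fig_mask <- function() {
  explicit_mask(rbind(c(0, 1), c(1, 1), c(1, 2), c(3, 2), c(2, 3), c(0, 4)))
}

# brute-force oracle: enumerate every pair of the window with the scalar
# indicator, in target-major order.  Independent of the row iterator.
oracle_pairs <- function(expr, s_ids, t_ids) {
  out <- matrix(integer(), ncol = 2L, dimnames = list(NULL, c("source", "target")))
  for (j in t_ids) {
    for (i in s_ids) {
      if (mask_contains(expr, i, j)) out <- rbind(out, c(i, j))
    }
  }
  out
}

# stream of a generator over a single window, as a 2-column matrix
stream_pairs <- function(expr, s, t) {
  g <- connection_generator(expr)
  cg_set_mask(g, mask_spec(s, t))
  df <- cg_collect(g)
  cbind(source = df$source, target = df$target)
}

# random serializable expression for property tests (driven by R's RNG; the
# caller sets the seed)
rand_leaf <- function(max_idx = 9L) {
  switch(sample.int(5L, 1L),
         delta(),
         random_mask(stats::runif(1), sample.int(1000L, 1L)),
         cross_mask(sort(sample(0:max_idx, sample.int(max_idx, 1L))),
                    sort(sample(0:max_idx, sample.int(max_idx, 1L)))),
         explicit_mask(cbind(sample(0:max_idx, 6L, replace = TRUE),
                             sample(0:max_idx, 6L, replace = TRUE))),
         full_mask())
}

rand_expr <- function(depth = 3L, max_idx = 9L) {
  if (depth <= 0L || stats::runif(1) < 0.4) return(rand_leaf(max_idx))
  op <- sample(c("intersection", "union", "difference"), 1L)
  combine(op, rand_expr(depth - 1L, max_idx), rand_expr(depth - 1L, max_idx))
}

# modulo partition of target ids over R ranks, as mask_spec list
modulo_masks <- function(s_win, t_ids, R) {
  lapply(0:(R - 1L), function(r) {
    js <- t_ids[t_ids %% R == r]
    mask_spec(as_iset(s_win),
              if (length(js)) interval_set_from_ids(js) else interval_set())
  })
}

as_iset <- function(x) if (is_interval_set(x)) x else interval_set_from_ids(x)
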