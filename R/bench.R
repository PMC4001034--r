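#' Connection-count scaling benchmarks
#'
#' The benchmarks characterize how the number of generated connections (and,
#' informationally, the wall-clock time) scales with network size and with
#' the number of emulated ranks.  Slopes follow the ratio-of-logarithms
#' convention: `slope = log(y_last / y_first) / log(x_last / x_first)` over
#' the first and last points of a series.  A Bernoulli random mask at fixed
#' `p` creates O(n^2) connections for n neurons (expected count slope 2);
#' the one-to-one mask creates O(n) (slope exactly 1).  Wall-clock times are
#' hardware-dependent and are reported but never asserted.
#'
#' @param mask which elementary mask to benchmark.
#' @param n_values ascending population sizes (at least two); each run cuts
#'   the mask to the square window `{0..n-1} x {0..n-1}`.
#' @param p inclusion probability of the random mask.
#' @param seed non-negative integer seed.
#' @return An object of class `csa_benchmark`: a list with the measurement
#'   series (data frame), the count `slope`, a `time_slope`, and the
#'   parameters used.
#' @examples
#' b <- bench_population_scaling("one_to_one", n_values = c(100, 1000))
#' b$slope   # exactly 1
#' @export
bench_population_scaling <- function(mask = c("random", "one_to_one"),
                                     n_values, p = 0.1, seed = 0L) {
  mask <- match.arg(mask)
  n_values <- as.integer(n_values)
  if (length(n_values) < 2L || is.unsorted(n_values, strictly = TRUE))
    stop("n_values must be at least two ascending sizes")
  expr <- switch(mask,
                 random = random_mask(p, seed),
                 one_to_one = delta())
  count <- numeric(length(n_values))
  secs <- numeric(length(n_values))
  for (k in seq_along(n_values)) {
    n <- n_values[k]
    g <- connection_generator(expr)
    cg_set_mask(g, mask_spec(interval_set(0L, n - 1L), interval_set(0L, n - 1L)))
    secs[k] <- system.time(count[k] <- cg_count(g))[["elapsed"]]
  }
  series <- data.frame(n = n_values, count = count, seconds = secs)
  structure(list(parameter = "n", series = series,
                 slope = loglog_slope(n_values, count),
                 time_slope = loglog_slope(n_values, secs),
                 mask = mask, p = if (mask == "random") p else NA_real_,
                 seed = as.integer(seed)),
            class = "csa_benchmark")
}

#' Strong-scaling benchmark: fixed network, varying rank count
#'
#' Wires a fixed `n`-neuron network with the random mask at probability `p`
#' while varying the number of emulated ranks.  For every rank count the
#' per-rank connection counts are measured and must sum exactly to the
#' serial (1-rank) count — counter-based membership guarantees it.  The
#' report includes per-rank balance; timing is informational only (ranks
#' are emulated sequentially in-process, so wall-clock time does not drop
#' with rank count here).
#'
#' @param n number of neurons (square window `{0..n-1}^2`).
#' @param ranks_list ascending rank counts to test.
#' @inheritParams bench_population_scaling
#' @return A `csa_benchmark` whose series has one row per rank count, with
#'   the total count, timing, and min/max per-rank counts; `per_rank` holds
#'   the individual counts.
#' @export
bench_strong_scaling <- function(n, p = 0.1, ranks_list, seed = 0L) {
  n <- as.integer(n)
  ranks_list <- as.integer(ranks_list)
  if (length(ranks_list) < 1L || is.unsorted(ranks_list, strictly = TRUE))
    stop("ranks_list must be ascending rank counts")
  expr <- random_mask(p, seed)
  win <- interval_set(0L, n - 1L)
  idx <- 0:(n - 1L)
  per_rank <- vector("list", length(ranks_list))
  total <- numeric(length(ranks_list))
  secs <- numeric(length(ranks_list))
  for (k in seq_along(ranks_list)) {
    R <- ranks_list[k]
    ranks <- rank_of_target(idx, R)
    masks <- lapply(0:(R - 1L), function(r) {
      js <- idx[ranks == r]
      mask_spec(win, if (length(js)) interval_set_from_ids(js) else interval_set())
    })
    counts <- numeric(R)
    t0 <- proc.time()[["elapsed"]]
    for (r in 0:(R - 1L)) {
      g <- connection_generator(expr)
      cg_set_masks(g, masks, local = r)
      counts[r + 1L] <- cg_count(g)
    }
    secs[k] <- proc.time()[["elapsed"]] - t0
    per_rank[[k]] <- counts
    total[k] <- sum(counts)
  }
  if (length(unique(total)) != 1L)
    stop("per-rank counts do not sum to the same total across rank counts")
  series <- data.frame(ranks = ranks_list, count = total, seconds = secs,
                       min_per_rank = vapply(per_rank, min, numeric(1)),
                       max_per_rank = vapply(per_rank, max, numeric(1)))
  structure(list(parameter = "ranks", series = series,
                 slope = loglog_slope(ranks_list, total),
                 time_slope = loglog_slope(ranks_list, secs),
                 per_rank = per_rank, n = n, mask = "random", p = p,
                 seed = as.integer(seed)),
            class = "csa_benchmark")
}

# ratio-of-logarithms slope between the last and first point of a series
loglog_slope <- function(x, y) {
  x <- as.double(x); y <- as.double(y)
  first <- 1L; last <- length(x)
  if (last < 2L || x[first] == x[last]) return(NA_real_)
  log(y[last] / y[first]) / log(x[last] / x[first])
}

#' @export
print.csa_benchmark <- function(x, ...) {
  cat("Connection-count benchmark (", x$mask,
      if (!is.na(x$p)) sprintf(", p = %g", x$p), ", seed = ", x$seed, ")\n",
      sep = "")
  print(x$series, row.names = FALSE)
  cat(sprintf("count slope (ratio of logs, last/first): %.4f\n", x$slope))
  if (!is.na(x$time_slope) && all(x$series$seconds > 0))
    cat(sprintf("time slope (informational): %.2f\n", x$time_slope))
  invisible(x)
}
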