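# Shared fixtures. Built once per test run; everything is generated in code.

# default generative parameters (calibration is deterministic, ~20 ms)
default_params <- motility_params()

# one long microtubule: the standard motility geometry
long_mt <- build_network(list(list(c(0, 0), c(60, 0))))

# short microtubule so most runs reach the plus end
short_mt <- build_network(list(list(c(0, 0), c(5, 0))))

# a 20 um spine crossed by 9 perpendicular microtubules (intersection assays)
grid_network <- build_network(c(
  list(list(c(0, 0), c(20, 0))),
  lapply(1:9, function(i) list(c(2 * i, -3), c(2 * i, 3)))))

# modest shared motility ensemble + analysis, reused across test files
shared_ensemble <- simulate_ensemble(default_params, long_mt, 400, seed = 421)
shared_analysis <- analyze_tracks(shared_ensemble, long_mt)

# expand segment labels onto points
frame_labels <- function(seg) {
  lab <- character(nrow(seg$points))
  for (i in seq_len(nrow(seg$segments))) {
    lab[seg$segments$start_idx[i]:seg$segments$end_idx[i]] <-
      seg$segments$state[i]
  }
  lab
}

# brute-force O(n^2) crossing counter based on orientation predicates,
# independent of the parametric solver used by build_network()
ccw <- function(a, b, c) {
  (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
}
segments_cross_bf <- function(p1, p2, q1, q2) {
  d1 <- ccw(q1, q2, p1); d2 <- ccw(q1, q2, p2)
  d3 <- ccw(p1, p2, q1); d4 <- ccw(p1, p2, q2)
  # strict interior crossing: opposite signs on both sides
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

# exhaustive optimal piecewise-constant segmentation by dynamic programming
# (oracle for detect_steps on small traces)
dp_best_rss <- function(y, k, min_size = 2) {
  n <- length(y)
  cy <- c(0, cumsum(y)); cy2 <- c(0, cumsum(y^2))
  cost <- function(a, b) {
    m <- b - a + 1; s <- cy[b + 1] - cy[a]
    max((cy2[b + 1] - cy2[a]) - s^2 / m, 0)
  }
  # dp[j, b] = best RSS of first b samples with j segments
  dp <- matrix(Inf, nrow = k + 1, ncol = n + 1)
  for (b in min_size:n) dp[1, b + 1] <- cost(1, b)
  if (k >= 1) {
    for (j in 2:(k + 1)) {
      for (b in (j * min_size):n) {
        best <- Inf
        for (a in ((j - 1) * min_size):(b - min_size)) {
          v <- dp[j - 1, a + 1] + cost(a + 1, b)
          if (v < best) best <- v
        }
        dp[j, b + 1] <- best
      }
    }
  }
  dp[, n + 1] # best RSS with 1..k+1 segments (0..k change points)
}
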