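# Independent oracles used across the suite.  These deliberately share no
# code with the package implementation.

# brute-force single-molecule transition-probability convolution for the
# lazy nearest-neighbor walk (2D); returns the full distribution on a
# (2*steps+1)^2 support, computed by explicit per-square enumeration
conv_point_source_2d <- function(steps, p) {
  n <- 2 * steps + 3
  f <- matrix(0, n, n)
  mid <- (n + 1) %/% 2
  f[mid, mid] <- 1
  for (s in seq_len(steps)) {
    g <- matrix(0, n, n)
    for (i in 2:(n - 1)) for (j in 2:(n - 1)) if (f[i, j] > 0) {
      g[i, j] <- g[i, j] + (1 - p) * f[i, j]
      g[i - 1, j] <- g[i - 1, j] + p / 4 * f[i, j]
      g[i + 1, j] <- g[i + 1, j] + p / 4 * f[i, j]
      g[i, j - 1] <- g[i, j - 1] + p / 4 * f[i, j]
      g[i, j + 1] <- g[i, j + 1] + p / 4 * f[i, j]
    }
    f <- g
  }
  list(dist = f, mid = mid)
}

# direct summation of binomial pmf terms (no pbinom)
binom_cdf_direct <- function(k, n, p) {
  sum(choose(n, 0:k) * p^(0:k) * (1 - p)^(n - (0:k)))
}

# explicit lazy random walk, one molecule (2D), for displacement-variance
# checks
random_walk_2d <- function(steps, p, n_walkers) {
  x <- numeric(n_walkers); y <- numeric(n_walkers)
  for (s in seq_len(steps)) {
    u <- runif(n_walkers)
    move <- u < p
    dir <- sample.int(4, n_walkers, replace = TRUE)
    x <- x + move * ((dir == 1) - (dir == 2))
    y <- y + move * ((dir == 3) - (dir == 4))
  }
  cbind(x, y)
}

# stationary distribution of a birth-death chain on 0..cap with constant
# birth rate b and linear death rate d*x, by solving the master equation
# (detailed balance) directly
birth_death_stationary <- function(b, d, cap) {
  logw <- c(0, cumsum(log(b / (d * seq_len(cap)))))
  w <- exp(logw - max(logw))
  w / sum(w)
}

# chi-square goodness-of-fit with pooling of bins whose expected count is
# below `min_exp`; returns the p-value
chisq_gof <- function(observed_counts, probs, min_exp = 5) {
  n <- sum(observed_counts)
  exp_counts <- n * probs
  o <- pool <- NULL
  acc_o <- acc_e <- 0
  obs_pooled <- exp_pooled <- numeric(0)
  for (i in seq_along(probs)) {
    acc_o <- acc_o + observed_counts[i]
    acc_e <- acc_e + exp_counts[i]
    if (acc_e >= min_exp) {
      obs_pooled <- c(obs_pooled, acc_o)
      exp_pooled <- c(exp_pooled, acc_e)
      acc_o <- acc_e <- 0
    }
  }
  if (acc_e > 0) {
    obs_pooled[length(obs_pooled)] <- obs_pooled[length(obs_pooled)] + acc_o
    exp_pooled[length(exp_pooled)] <- exp_pooled[length(exp_pooled)] + acc_e
  }
  stat <- sum((obs_pooled - exp_pooled)^2 / exp_pooled)
  stats::pchisq(stat, df = length(obs_pooled) - 1, lower.tail = FALSE)
}

# two-process constant-rate reaction system for SSA validation
two_process_system <- function(r1, r2) {
  reaction_system(c("N1", "N2"), matrix(c(1, 0, 0, 1), 2, 2),
                  function(s) c(r1, r2))
}

mini_culture_config <- function(...) {
  args <- modifyList(list(lattice_shape = c(20, 20), n_cells = 50, moi = 1,
                          t_end = 1800, record_dt = 300, seed = 42),
                     list(...))
  do.call(culture_config, args)
}
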