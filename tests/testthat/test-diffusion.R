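spec2 <- diffusion_spec(D = 50, delta = 20, c = 8, N_max = 256)
tabs2 <- diffusion_tables(spec2)

test_that("diffusion spec enforces the dt = delta^2/(c D) relation", {
  s <- diffusion_spec(D = 50, delta = 20, c = 8)
  expect_equal(s$dt, 1)
  expect_equal(diffusion_spec(D = 50, delta = 20, dt = 1)$c, 8)
  expect_error(diffusion_spec(D = 50, delta = 20, dt = 1, c = 9), "inconsistent")
  expect_error(diffusion_spec(D = 50, delta = 20, c = 8, p_move = 1), "strictly")
  expect_error(diffusion_spec(D = -1, delta = 20, c = 8), "positive")
})

test_that("stochastic 2D step conserves molecules exactly and leaves empty grids empty", {
  g0 <- molecule_grid(matrix(0, 6, 6), 20)
  expect_identical(diffusion_step(g0, spec2, tabs2)$counts, g0$counts)
  set.seed(11)
  m <- matrix(rpois(64, 40), 8, 8)
  g <- molecule_grid(m, 20)
  for (i in 1:50) g <- diffusion_step(g, spec2, tabs2)
  expect_identical(total_count(g), as.numeric(sum(m)))
  expect_true(all(g$counts >= 0))
  expect_true(all(g$counts == floor(g$counts)))
})

test_that("point-mass marginals match Binomial(n, p/4) per direction", {
  # each neighbor receives Binomial(1e6, 1/8): mean 125000, sd ~ 330
  set.seed(12)
  spec_big <- diffusion_spec(D = 50, delta = 20, c = 8, N_max = 64,
                             normal_fallback = TRUE)
  tabs_big <- diffusion_tables(spec_big)
  m <- matrix(0, 5, 5); m[3, 3] <- 1e6
  g1 <- diffusion_step(molecule_grid(m, 20), spec_big, tabs_big)
  nb <- c(g1$counts[2, 3], g1$counts[4, 3], g1$counts[3, 2], g1$counts[3, 4])
  sd_dir <- sqrt(1e6 * (1 / 8) * (7 / 8))
  expect_true(all(abs(nb - 125000) < 5 * sd_dir))
  expect_equal(total_count(g1), 1e6)
})

test_that("3D step conserves molecules and matches Binomial(n, p/6) marginals", {
  set.seed(13)
  spec3 <- diffusion_spec(D = 50, delta = 20, c = 12, dims = 3, N_max = 64)
  tabs3 <- diffusion_tables(spec3)
  a <- array(0, c(5, 5, 5)); a[3, 3, 3] <- 1e6
  g1 <- diffusion_step(molecule_grid(a, 20), spec3, tabs3)
  expect_equal(total_count(g1), 1e6)
  nb <- c(g1$counts[2, 3, 3], g1$counts[4, 3, 3], g1$counts[3, 2, 3],
          g1$counts[3, 4, 3], g1$counts[3, 3, 2], g1$counts[3, 3, 4])
  sd_dir <- sqrt(1e6 * (1 / 12) * (11 / 12))
  expect_true(all(abs(nb - 1e6 / 12) < 5 * sd_dir))
  # all-zero 3D grid stays zero
  gz <- molecule_grid(array(0, c(4, 4, 4)), 20)
  expect_identical(diffusion_step(gz, spec3, tabs3)$counts, gz$counts)
})

test_that("repeat-axis 3D variant conserves mass and has the same direction law", {
  set.seed(14)
  spec3 <- diffusion_spec(D = 50, delta = 20, c = 12, dims = 3, N_max = 8192)
  tabs3 <- diffusion_tables(spec3)
  a <- array(0, c(3, 3, 3)); a[2, 2, 2] <- 6000
  tot_dir <- numeric(6)
  reps <- 40
  for (r in seq_len(reps)) {
    g <- diffusion_step_3d_repeat(molecule_grid(a, 20), spec3, tabs3)
    expect_equal(total_count(g), 6000)
    tot_dir <- tot_dir + c(g$counts[1, 2, 2], g$counts[3, 2, 2],
                           g$counts[2, 1, 2], g$counts[2, 3, 2],
                           g$counts[2, 2, 1], g$counts[2, 2, 3])
  }
  # per-direction marginal Binomial(6000, 1/12) over 40 replicates
  mu <- reps * 6000 / 12
  sd_tot <- sqrt(reps * 6000 * (1 / 12) * (11 / 12))
  expect_true(all(abs(tot_dir - mu) < 5 * sd_tot))
})

test_that("optimized 2D step consumes exactly 4 variates per occupied square", {
  draws <- 0L
  counting_rng <- function(n) { draws <<- draws + n; runif(n) }
  set.seed(15)
  m <- matrix(rpois(144, 5), 12, 12)
  m[1, 1] <- 0  # leave at least one empty square
  n_occ <- sum(m > 0)
  invisible(diffusion_step(molecule_grid(m, 20), spec2, tabs2,
                           rng = counting_rng))
  expect_identical(draws, 4L * n_occ)
})

test_that("counts above N_max fall back to the normal approximation or error", {
  g <- molecule_grid(matrix(c(1000, rep(0, 15)), 4, 4), 20)
  spec_small <- diffusion_spec(D = 50, delta = 20, c = 8, N_max = 16,
                               normal_fallback = FALSE)
  tabs_small <- diffusion_tables(spec_small)
  set.seed(16)
  expect_error(diffusion_step(g, spec_small, tabs_small), "N_max")
  spec_fb <- diffusion_spec(D = 50, delta = 20, c = 8, N_max = 16,
                            normal_fallback = TRUE)
  g2 <- diffusion_step(g, spec_fb, diffusion_tables(spec_fb))
  expect_equal(total_count(g2), 1000)
})

test_that("deterministic step follows the retain/spread rule and conserves mass", {
  m <- matrix(0, 5, 5); m[3, 3] <- 8
  m1 <- deterministic_diffusion_step(m, 0.5)
  expect_equal(m1[3, 3], 4)
  expect_equal(c(m1[2, 3], m1[4, 3], m1[3, 2], m1[3, 4]), rep(1, 4))
  expect_equal(sum(m1), 8)
  # two steps against the brute-force convolution oracle
  or <- conv_point_source_2d(2, 0.5)
  m2 <- deterministic_diffusion_step(m1, 0.5)
  expect_equal(m2[3, 3], 8 * or$dist[or$mid, or$mid])
  expect_equal(m2[3, 3], 8 * 0.3125)
  # uniform grid is a fixed point
  u <- matrix(7.5, 6, 6)
  expect_equal(deterministic_diffusion_step(u, 0.3), u)
  # periodic wrap: corner mass reappears on opposite edges
  e <- matrix(0, 4, 4); e[1, 1] <- 4
  e1 <- deterministic_diffusion_step(e, 1)
  expect_equal(e1[4, 1], 1)
  expect_equal(e1[1, 4], 1)
})

test_that("stochastic mean over many runs agrees with the deterministic profile", {
  set.seed(17)
  spec_fb <- diffusion_spec(D = 50, delta = 20, c = 8, N_max = 512,
                            normal_fallback = TRUE)
  tabs_fb <- diffusion_tables(spec_fb)
  L <- 15; N0 <- 1e4; steps <- 10; n_runs <- 120
  m0 <- matrix(0, L, L); m0[8, 8] <- N0
  acc <- matrix(0, L, L); acc2 <- matrix(0, L, L)
  for (r in seq_len(n_runs)) {
    g <- molecule_grid(m0, 20)
    for (s in seq_len(steps)) g <- diffusion_step(g, spec_fb, tabs_fb)
    acc <- acc + g$counts
    acc2 <- acc2 + g$counts^2
  }
  mean_g <- acc / n_runs
  se <- sqrt(pmax(acc2 / n_runs - mean_g^2, 0) / n_runs)
  det <- m0
  for (s in seq_len(steps)) det <- deterministic_diffusion_step(det, 0.5)
  dev <- abs(mean_g - det)
  expect_true(all(dev <= 3 * se + 1e-9 | det < 0.5))
})

test_that("single molecule performs a lazy random walk with variance p/2 per axis per step", {
  set.seed(18)
  steps <- 100; n_rep <- 400; p <- 0.5
  spec_fb <- spec2
  disp <- matrix(0, n_rep, 2)
  L <- 41
  for (r in seq_len(n_rep)) {
    m <- matrix(0, L, L); m[21, 21] <- 1
    g <- molecule_grid(m, 20)
    for (s in seq_len(steps)) g <- diffusion_step(g, spec_fb, tabs2)
    pos <- which(g$counts == 1, arr.ind = TRUE)
    disp[r, ] <- pos - 21
  }
  v <- mean(c(disp[, 1]^2, disp[, 2]^2)) / steps
  # independent random-walk oracle for the same variance
  set.seed(19)
  w <- random_walk_2d(steps, p, n_rep)
  v_oracle <- mean(c(w[, 1]^2, w[, 2]^2)) / steps
  expect_equal(v, p / 2, tolerance = 0.15)
  expect_equal(v_oracle, p / 2, tolerance = 0.15)
})

test_that("molecule_grid validates its counts", {
  expect_error(molecule_grid(matrix(-1, 2, 2)), "non-negative")
  expect_error(molecule_grid(matrix(0.5, 2, 2)), "whole numbers")
  expect_error(molecule_grid(1:4), "matrix")
})
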