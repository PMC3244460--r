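params <- dc_rate_params()

test_that("initialization places cells on distinct squares and infects by Poisson adsorption", {
  cfg <- mini_culture_config(moi = 0)
  st <- initialize_culture(cfg, params)
  expect_false(any(st$cells$infected))
  expect_identical(anyDuplicated(st$cells$sq), 0L)
  expect_true(all(st$cells$F == params$F0))
  expect_true(all(st$cells$B == 0))
  expect_identical(sum(st$grid$counts), 0)
  # infected count within 5 sigma of n (1 - exp(-moi))
  cfg5 <- culture_config(lattice_shape = c(30, 30), n_cells = 400, moi = 5,
                         t_end = 0, seed = 7)
  st5 <- initialize_culture(cfg5, params)
  p_inf <- 1 - exp(-5)
  expect_lt(abs(sum(st5$cells$infected) - 400 * p_inf),
            5 * sqrt(400 * p_inf * (1 - p_inf)) + 1e-9)
  # determinism under the seed
  st_a <- initialize_culture(cfg5, params)
  expect_identical(st_a$cells, st5$cells)
})

test_that("early responders start above the interferon induction half-level", {
  cfg <- culture_config(lattice_shape = c(40, 40), n_cells = 800, moi = 1,
                        early_responder_fraction = 0.05, t_end = 0, seed = 9)
  st <- initialize_culture(cfg, params)
  frac_hi <- mean(st$cells$P_R > params$K_P)
  expect_lt(abs(frac_hi - 0.05), 5 * sqrt(0.05 * 0.95 / 800))
  # lognormal option targets the same exceedance fraction
  cfgl <- culture_config(lattice_shape = c(40, 40), n_cells = 800, moi = 1,
                         early_responder_fraction = 0.05,
                         pr_distribution = "lognormal", t_end = 0, seed = 9)
  stl <- initialize_culture(cfgl, params)
  frac_l <- mean(stl$cells$P_R > params$K_P)
  expect_lt(abs(frac_l - 0.05), 5 * sqrt(0.05 * 0.95 / 800) + 0.01)
})

test_that("stepping keeps the global interferon audit exact", {
  cfg <- mini_culture_config(moi = 2, seed = 13)
  st <- initialize_culture(cfg, params)
  # give the infected cells transcripts so secretion starts immediately
  st$cells$M_I <- ifelse(st$cells$infected, 40, 0)
  tabs <- diffusion_tables(st$spec)
  for (i in 1:60) {
    st <- step_culture(st, tabs)
    expect_true(culture_audit_ok(st))
  }
  expect_gt(st$audit$secreted, 0)
  # receptor conservation per cell
  expect_true(all(st$cells$F + st$cells$B == params$F0))
  expect_true(all(st$grid$counts >= 0))
})

test_that("an uninfected culture never produces interferon", {
  cfg <- mini_culture_config(moi = 0, t_end = 900, seed = 17)
  tr <- run_culture(cfg, params)
  expect_true(all(tr$pop$free_ifn == 0))
  expect_true(all(tr$pop$mean_MI_infected == 0))
  expect_true(all(tr$pop$mean_B == 0))
  # Rig-I stays at its constitutive stationary mean (linear birth-death):
  # population mean over 50 cells, SE = sqrt(mean/n)
  mr_mean <- params$k_MR_basal / params$d_MR
  se <- sqrt(mr_mean / 50)
  expect_true(all(abs(tr$pop$mean_MR - mr_mean) < 5 * se))
})

test_that("per-cell RNG streams make the result independent of iteration order", {
  cfg <- mini_culture_config(moi = 1, seed = 19)
  st1 <- initialize_culture(cfg, params)
  st2 <- initialize_culture(cfg, params)
  tabs <- diffusion_tables(st1$spec)
  for (i in 1:10) {
    st1 <- step_culture(st1, tabs)
    st2 <- step_culture(st2, tabs, cell_order = rev(seq_len(cfg$n_cells)))
  }
  expect_identical(st1$cells, st2$cells)
  expect_identical(st1$grid$counts, st2$grid$counts)
})

test_that("identical seeds give bit-identical trajectories", {
  cfg <- mini_culture_config(moi = 1, t_end = 600, seed = 23)
  tr1 <- run_culture(cfg, params)
  tr2 <- run_culture(cfg, params)
  expect_identical(tr1$pop, tr2$pop)
  expect_identical(tr1$cells, tr2$cells)
})

test_that("a zero horizon records only the initial state", {
  cfg <- mini_culture_config(t_end = 0, seed = 29)
  tr <- run_culture(cfg, params)
  expect_identical(nrow(tr$pop), 1L)
  expect_identical(tr$pop$t, 0)
})

test_that("interferon spreads outward from a secreting cell", {
  # one infected cell with many transcripts: interferon appears in its
  # square and reaches the neighbors through diffusion
  cfg <- culture_config(lattice_shape = c(15, 15), n_cells = 1, moi = 5,
                        t_end = 0, seed = 31)
  st <- initialize_culture(cfg, params)
  st$cells$infected <- TRUE
  st$cells$M_I <- 400
  tabs <- diffusion_tables(st$spec)
  st1 <- step_culture(st, tabs)
  r <- st$cells$row; cc <- st$cells$col
  expect_gt(st1$grid$counts[r, cc], 0)
  for (i in 1:10) st1 <- step_culture(st1, tabs)
  nb <- c(st1$grid$counts[r %% 15 + 1, cc],
          st1$grid$counts[(r - 2) %% 15 + 1, cc],
          st1$grid$counts[r, cc %% 15 + 1],
          st1$grid$counts[r, (cc - 2) %% 15 + 1])
  expect_true(all(nb > 0))
  expect_true(culture_audit_ok(st1))
})

test_that("half-max induction interpolates the first crossing", {
  expect_equal(half_max_induction(c(0, 1), c(0, 10)),
               c(t_half = 0.5, v_half = 5))
  t <- seq(0, 8, by = 0.05)
  hm <- half_max_induction(t, 100 * (1 - exp(-t)))
  # the sampled maximum sets v_half slightly below the asymptote
  expect_equal(unname(hm["t_half"]), log(2), tolerance = 0.02)
  expect_true(all(is.na(half_max_induction(t, rep(0, length(t))))))
  expect_error(half_max_induction(1, 1), "at least 2")
})

test_that("a single-MOI sweep reports one entry and no pairwise scores", {
  cfg <- mini_culture_config(t_end = 600, seed = 37)
  sw <- moi_sweep(cfg, 1, n_replicates = 2, params = params)
  expect_identical(nrow(sw$t_half), 1L)
  expect_null(sw$dist)
  expect_identical(ncol(sw$ifn_curves), 1L)
  # moi = 0 gives an identically zero interferon curve
  sw0 <- moi_sweep(cfg, c(0, 1), n_replicates = 2, params = params)
  expect_true(all(sw0$ifn_curves[, "moi_0"] == 0))
  expect_true(is.na(sw0$t_half$t_half_ifn[1]))
})
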