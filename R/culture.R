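#' Culture-level configuration
#'
#' Describes the simulated dish: lattice extents, number of cells,
#' multiplicity of infection, the initial Rig-I protein distribution that
#' realizes the early-responder subpopulation, horizon and recording
#' cadence.
#'
#' Early responders are the small fraction of cells whose constitutive Rig-I
#' protein level already exceeds the interferon-induction half-level, so
#' that (if infected) they start transcribing interferon almost immediately.
#' With the `"two_point"` law each cell independently starts at
#' `pr_elevated` with probability `early_responder_fraction` and at
#' `pr_baseline` otherwise; the `"lognormal"` option draws from a log-normal
#' centered at `pr_baseline` whose spread is solved so the same fraction
#' exceeds the induction half-level `K_P` on average.
#'
#' @param lattice_shape integer 2-vector of lattice extents (squares).
#' @param n_cells number of cells, at most the number of squares.
#' @param moi multiplicity of infection (viruses per cell), >= 0.
#' @param early_responder_fraction target fraction of high-basal-Rig-I
#'   cells.
#' @param pr_baseline,pr_elevated the two levels of the two-point initial
#'   Rig-I protein law.
#' @param pr_distribution `"two_point"` or `"lognormal"`.
#' @param t_end horizon (s).
#' @param record_dt recording cadence (s).
#' @param seed master seed; per-cell substreams are split from it.
#' @return object of class `culture_config`.
#' @export
culture_config <- function(lattice_shape = c(40, 40), n_cells = 200,
                           moi = 1, early_responder_fraction = 0.01,
                           pr_baseline = 1000, pr_elevated = 20000,
                           pr_distribution = c("two_point", "lognormal"),
                           t_end = 36000, record_dt = 600, seed = 1) {
  pr_distribution <- match.arg(pr_distribution)
  lattice_shape <- as.integer(lattice_shape)
  if (length(lattice_shape) != 2L || any(lattice_shape < 1))
    stop("`lattice_shape` must be two positive integers", call. = FALSE)
  if (n_cells < 1 || n_cells > prod(lattice_shape))
    stop(sprintf("`n_cells` must be between 1 and the %d lattice squares",
                 prod(lattice_shape)), call. = FALSE)
  if (moi < 0) stop("`moi` must be non-negative", call. = FALSE)
  if (early_responder_fraction < 0 || early_responder_fraction > 1)
    stop("`early_responder_fraction` must lie in [0, 1]", call. = FALSE)
  if (t_end < 0) stop("`t_end` must be non-negative", call. = FALSE)
  if (record_dt <= 0) stop("`record_dt` must be positive", call. = FALSE)
  structure(list(lattice_shape = lattice_shape, n_cells = as.integer(n_cells),
                 moi = moi,
                 early_responder_fraction = early_responder_fraction,
                 pr_baseline = pr_baseline, pr_elevated = pr_elevated,
                 pr_distribution = pr_distribution, t_end = t_end,
                 record_dt = record_dt, seed = as.integer(seed)),
            class = "culture_config")
}

# --- RNG stream plumbing -----------------------------------------------------
# One L'Ecuyer-CMRG substream per cell plus one "environment" stream for
# secretion, binding and diffusion, all split deterministically from the
# master seed, so per-cell trajectories do not depend on the order in which
# cells are advanced and adding cells does not perturb existing streams.

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

set_rng_state <- function(s) {
  if (is.null(s)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", s, envir = globalenv())
}

make_streams <- function(seed, n_cells) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  suppressWarnings(set.seed(seed, kind = "L'Ecuyer-CMRG"))
  base <- get_rng_state()
  env_stream <- parallel::nextRNGStream(base)
  cells <- vector("list", n_cells)
  s <- env_stream
  for (i in seq_len(n_cells)) {
    s <- parallel::nextRNGStream(s)
    cells[[i]] <- s
  }
  list(env = env_stream, cells = cells)
}

# --- initialization ----------------------------------------------------------

#' Initialize a culture
#'
#' Places cells uniformly at random on distinct lattice squares, infects
#' each independently with probability `1 - exp(-moi)` (Poisson viral
#' adsorption: a cell is infected when at least one virion lands on it), and
#' draws initial Rig-I protein from the configured early-responder law.
#' Rig-I transcripts start at their constitutive stationary mean, all
#' interferon counts at zero, and receptors all free (`F = F0`, `B = 0`).
#'
#' @param config a [culture_config()].
#' @param params a [dc_rate_params()].
#' @param spec a [diffusion_spec()]; `NULL` uses [default_diffusion_spec()].
#' @return list of class `culture_state` with the molecule grid, the cell
#'   table (parallel vectors), RNG streams, clock and audit counters.
#' @export
initialize_culture <- function(config, params, spec = NULL) {
  stopifnot(inherits(config, "culture_config"), inherits(params, "dc_rate_params"))
  if (is.null(spec)) spec <- default_diffusion_spec()
  streams <- make_streams(config$seed, config$n_cells)
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set_rng_state(streams$env)
  n <- config$n_cells
  sq <- sample.int(prod(config$lattice_shape), n)   # distinct squares
  infected <- runif(n) < 1 - exp(-config$moi)
  P_R <- switch(config$pr_distribution,
    two_point = ifelse(runif(n) < config$early_responder_fraction,
                       config$pr_elevated, config$pr_baseline),
    lognormal = {
      eps <- config$early_responder_fraction
      sdlog <- if (eps <= 0 || eps >= 1) 0 else
        (log(params$K_P) - log(config$pr_baseline)) / stats::qnorm(1 - eps)
      stats::rlnorm(n, meanlog = log(config$pr_baseline), sdlog = max(sdlog, 0))
    })
  P_R <- round(P_R)
  streams$env <- get_rng_state()
  cells <- list(
    id = seq_len(n),
    sq = sq,
    row = (sq - 1L) %% config$lattice_shape[1] + 1L,
    col = (sq - 1L) %/% config$lattice_shape[1] + 1L,
    infected = infected,
    M_I = rep(0, n),
    M_R = rep(round(params$k_MR_basal / max(params$d_MR, 1e-300)), n),
    P_R = P_R,
    F = rep(params$F0, n),
    B = rep(0, n))
  grid <- molecule_grid(matrix(0, config$lattice_shape[1],
                               config$lattice_shape[2]),
                        square_side = spec$delta)
  structure(list(grid = grid, cells = cells, streams = streams,
                 t = 0, spec = spec,
                 audit = list(secreted = 0, net_bound = 0),
                 config = config, params = params),
            class = "culture_state")
}

#' Default diffusion parameters of the culture application
#'
#' 2D lattice with the spacing set to the cell diameter (20 µm), an
#' emigration probability of 1/2 and the matching calibrated time-step
#' constant c = 8, so `dt = delta^2/(8 D)`; with the default
#' `D = 50` µm²/s this gives a 1 s step.
#'
#' @param N_max lookup-table capacity.
#' @return a [diffusion_spec()].
#' @export
default_diffusion_spec <- function(N_max = 1024L) {
  diffusion_spec(D = 50, delta = 20, p_move = 0.5, c = 8, dims = 2,
                 N_max = N_max, normal_fallback = TRUE)
}

# advance every cell's synchronized SSA by one diffusion step; the bound
# receptor count B is an external condition frozen for the step, exactly as
# in the synchronized Gillespie scheme.  Each cell runs on its own RNG
# substream, so `order` (test hook) must not change the outcome.
advance_cells_ssa <- function(cells, streams, params, dt, order = NULL) {
  n <- length(cells$id)
  if (is.null(order)) order <- seq_len(n)
  k1 <- params$k_MI_max; KP <- params$K_P; hP <- params$h_P
  ktl <- params$k_tl; dMI <- params$d_MI; dMR <- params$d_MR; dPR <- params$d_PR
  hb <- (cells$B / params$K_B)^params$h_B
  a2v <- params$k_MR_basal * (1 + (params$fold_f - 1) * hb / (1 + hb))
  genv <- globalenv()
  for (i in order) {
    assign(".Random.seed", streams[[i]], envir = genv)
    MI <- cells$M_I[i]; MR <- cells$M_R[i]; PR <- cells$P_R[i]
    inf <- cells$infected[i]; a2 <- a2v[i]
    t_loc <- 0
    repeat {
      a1 <- if (inf) { ph <- (PR / KP)^hP; k1 * ph / (1 + ph) } else 0
      a3 <- ktl * MR; a4 <- dMI * MI; a5 <- dMR * MR; a6 <- dPR * PR
      R <- a1 + a2 + a3 + a4 + a5 + a6
      if (R <= 0) break
      tau <- rexp(1, R)
      if (t_loc + tau >= dt) break      # overshoot: discard and resync
      t_loc <- t_loc + tau
      x <- runif(1) * R
      if (x < a1) MI <- MI + 1
      else if (x < a1 + a2) MR <- MR + 1
      else if (x < a1 + a2 + a3) PR <- PR + 1
      else if (x < a1 + a2 + a3 + a4) MI <- MI - 1
      else if (x < a1 + a2 + a3 + a4 + a5) MR <- MR - 1
      else PR <- PR - 1
    }
    cells$M_I[i] <- MI; cells$M_R[i] <- MR; cells$P_R[i] <- PR
    streams[[i]] <- get(".Random.seed", envir = genv)
  }
  list(cells = cells, streams = streams)
}

#' Advance a culture by one diffusion step
#'
#' Executes, in order: (1) each cell's synchronized SSA from `t` to
#' `t + dt` with the bound-receptor count frozen; (2) secretion of
#' Poisson(`M_I * k_sec`) interferon into each cell's square; (3) receptor
#' binding/unbinding in occupied squares; (4) one stochastic diffusion step.
#' Newly secreted molecules can therefore bind locally before diffusing,
#' which is what creates the locally high concentrations around secreting
#' cells.  The global bookkeeping identity
#' `sum(grid) == total secreted - net bound` holds exactly after every step.
#'
#' @param state a `culture_state` from [initialize_culture()].
#' @param tables lookup tables from [diffusion_tables()]; built once by the
#'   caller for speed.
#' @param cell_order internal test hook: permutation in which to advance the
#'   per-cell SSAs (must not affect the result).
#' @return the updated `culture_state` (clock advanced by `spec$dt`).
#' @export
step_culture <- function(state, tables = NULL, cell_order = NULL) {
  stopifnot(inherits(state, "culture_state"))
  spec <- state$spec
  params <- state$params
  if (is.null(tables)) tables <- diffusion_tables(spec)
  dt <- spec$dt
  adv <- advance_cells_ssa(state$cells, state$streams$cells, params, dt,
                           cell_order)
  state$cells <- adv$cells
  state$streams$cells <- adv$streams
  old <- get_rng_state()
  set_rng_state(state$streams$env)
  # secretion (cell id order, independent of storage order)
  n_new <- rpois(length(state$cells$id), state$cells$M_I * params$k_sec)
  state$grid$counts[state$cells$sq] <- state$grid$counts[state$cells$sq] + n_new
  state$audit$secreted <- state$audit$secreted + sum(n_new)
  # receptor exchange in occupied squares
  ex <- receptor_exchange_core(state$grid$counts[state$cells$sq],
                               state$cells$F, state$cells$B, dt,
                               params$k_on, params$k_off)
  state$grid$counts[state$cells$sq] <- ex$ifn
  state$cells$F <- ex$F
  state$cells$B <- ex$B
  state$audit$net_bound <- state$audit$net_bound + sum(ex$n_bind - ex$n_unbind)
  # diffusion
  state$grid <- diffusion_step(state$grid, spec, tables)
  state$streams$env <- get_rng_state()
  set_rng_state(old)
  state$t <- state$t + dt
  state
}

#' Audit the global interferon bookkeeping of a culture state
#'
#' @param state a `culture_state`.
#' @return `TRUE` when `sum(grid) == secreted - net bound` exactly.
#' @export
culture_audit_ok <- function(state) {
  sum(state$grid$counts) == state$audit$secreted - state$audit$net_bound
}

#' Run a culture simulation
#'
#' Advances the culture from time 0 to `config$t_end` in diffusion steps of
#' `spec$dt`, recording per-cell and population summaries every
#' `config$record_dt` seconds (and always at time 0).
#'
#' @param config a [culture_config()].
#' @param params a [dc_rate_params()].
#' @param spec a [diffusion_spec()]; `NULL` uses [default_diffusion_spec()].
#' @param record_cells keep per-cell time series (default `TRUE`).
#' @return object of class `culture_trajectory`: `times` (s), `pop` (a data
#'   frame of population summaries per record time), `cells` (array
#'   `time x cell x (M_I, M_R, P_R, B)` when recorded), `infected` mask, and
#'   the final `state`.
#' @export
run_culture <- function(config, params = dc_rate_params(), spec = NULL,
                        record_cells = TRUE) {
  if (is.null(spec)) spec <- default_diffusion_spec()
  state <- initialize_culture(config, params, spec)
  tables <- diffusion_tables(spec)
  n_steps <- round(config$t_end / spec$dt)
  rec_every <- max(1L, as.integer(round(config$record_dt / spec$dt)))
  rec_steps <- unique(c(0L, seq(0L, n_steps, by = rec_every), n_steps))
  rec_steps <- sort(rec_steps)
  n_rec <- length(rec_steps)
  n <- config$n_cells
  pop <- data.frame(t = rec_steps * spec$dt,
                    mean_MI_infected = numeric(n_rec),
                    mean_MR = numeric(n_rec), mean_PR = numeric(n_rec),
                    mean_B = numeric(n_rec), free_ifn = numeric(n_rec),
                    secreted = numeric(n_rec), net_bound = numeric(n_rec))
  cells_ts <- if (record_cells)
    array(0, dim = c(n_rec, n, 4),
          dimnames = list(NULL, NULL, c("M_I", "M_R", "P_R", "B"))) else NULL
  snap <- function(k) {
    cl <- state$cells
    inf <- cl$infected
    pop$mean_MI_infected[k] <<- if (any(inf)) mean(cl$M_I[inf]) else 0
    pop$mean_MR[k] <<- mean(cl$M_R)
    pop$mean_PR[k] <<- mean(cl$P_R)
    pop$mean_B[k] <<- mean(cl$B)
    pop$free_ifn[k] <<- sum(state$grid$counts)
    pop$secreted[k] <<- state$audit$secreted
    pop$net_bound[k] <<- state$audit$net_bound
    if (record_cells)
      cells_ts[k, , ] <<- cbind(cl$M_I, cl$M_R, cl$P_R, cl$B)
  }
  snap(1L)
  k_rec <- 2L
  if (n_steps > 0) for (s in seq_len(n_steps)) {
    state <- step_culture(state, tables)
    if (k_rec <= n_rec && s == rec_steps[k_rec]) {
      snap(k_rec)
      k_rec <- k_rec + 1L
    }
  }
  structure(list(times = pop$t, pop = pop, cells = cells_ts,
                 infected = state$cells$infected, state = state,
                 config = config, params = params, spec = spec),
            class = "culture_trajectory")
}

#' @export
print.culture_trajectory <- function(x, ...) {
  cat(sprintf(paste0("<culture_trajectory> %d cells (%d infected), ",
                     "%.1f h horizon, %d records\n"),
              length(x$infected), sum(x$infected),
              max(x$times) / 3600, length(x$times)))
  invisible(x)
}
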