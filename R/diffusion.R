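#' Build the lookup tables a diffusion spec needs
#'
#' The two-stage draw scheme reuses a single table at p = 1/2 for the
#' directional splits; when `p_move` is 1/2 the same table also serves the
#' emigration draw, otherwise a second table keyed by `p_move` is built.  A
#' 3D spec additionally gets a p = 1/3 table for the axis split.
#'
#' @param spec a [diffusion_spec()].
#' @return A named list of [build_cumulative_binomial_table()] objects:
#'   `emig`, `half`, and (3D only) `third`.
#' @export
diffusion_tables <- function(spec) {
  stopifnot(inherits(spec, "diffusion_spec"))
  half <- build_cumulative_binomial_table(spec$N_max, 0.5)
  emig <- if (spec$p_move == 0.5) half else
    build_cumulative_binomial_table(spec$N_max, spec$p_move)
  out <- list(emig = emig, half = half)
  if (spec$dims == 3L)
    out$third <- build_cumulative_binomial_table(spec$N_max, 1 / 3)
  out
}

#' One stochastic diffusion step on a periodic lattice
#'
#' Performs one synchronous update: per occupied square the emigrant count is
#' drawn as Binomial(n, p_move) and split among the neighbor directions by
#' successive Binomial(., 1/2) draws (plus a Binomial(., 1/3) axis split in
#' 3D), so each direction receives a Binomial(n, p_move/2d) marginal.
#' Emigrants are computed from the frozen pre-step counts and deposited into
#' a fresh accumulator, making the within-step square order irrelevant.  The
#' total molecule count is conserved exactly.  Empty squares consume no
#' variates; occupied squares consume exactly 4 (2D) or 6 (3D) uniforms from
#' `rng`, which allows an instrumented generator to audit the draw budget.
#'
#' @param grid a [molecule_grid()].
#' @param spec a [diffusion_spec()] with matching `dims`.
#' @param tables lookup tables from [diffusion_tables()]; built on the fly
#'   when `NULL` (wasteful inside loops).
#' @param rng function `n -> n` uniforms on `[0, 1)`; defaults to
#'   [stats::runif()].  Replace with a counting wrapper to instrument draws.
#' @return The updated `molecule_grid`.
#' @examples
#' spec <- diffusion_spec(D = 50, delta = 20, c = 8, N_max = 64)
#' g <- molecule_grid(matrix(10, 4, 4), square_side = 20)
#' set.seed(1)
#' total_count(diffusion_step(g, spec))  # 160, conserved
#' @export
diffusion_step <- function(grid, spec, tables = NULL, rng = stats::runif) {
  stopifnot(inherits(grid, "molecule_grid"), inherits(spec, "diffusion_spec"))
  if (grid$dims != spec$dims)
    stop(sprintf("grid is %dD but spec is %dD", grid$dims, spec$dims), call. = FALSE)
  if (is.null(tables)) tables <- diffusion_tables(spec)
  occ <- which(grid$counts > 0)
  if (length(occ) == 0L) return(grid)
  if (grid$dims == 2L) {
    u <- rng(4L * length(occ))
    grid$counts <- cpp_diffusion_step_2d(
      grid$counts,
      tables$emig$cdf, tables$emig$offsets, tables$emig$N_max, spec$p_move,
      tables$half$cdf, tables$half$offsets, tables$half$N_max,
      as.integer(occ - 1L), u, spec$normal_fallback)
  } else {
    u <- rng(6L * length(occ))
    counts <- cpp_diffusion_step_3d(
      as.vector(grid$counts), dim(grid$counts),
      tables$emig$cdf, tables$emig$offsets, tables$emig$N_max, spec$p_move,
      tables$third$cdf, tables$third$offsets, tables$third$N_max,
      tables$half$cdf, tables$half$offsets, tables$half$N_max,
      as.integer(occ - 1L), u, spec$normal_fallback)
    grid$counts <- array(counts, dim = grid$shape)
  }
  grid
}

#' @rdname diffusion_step
#' @details `diffusion_step_2d()` and `diffusion_step_3d()` are thin
#'   dimension-checked wrappers around `diffusion_step()`.
#' @export
diffusion_step_2d <- function(grid, spec, tables = NULL, rng = stats::runif) {
  if (grid$dims != 2L) stop("`diffusion_step_2d()` requires a 2D grid", call. = FALSE)
  diffusion_step(grid, spec, tables, rng)
}

#' @rdname diffusion_step
#' @export
diffusion_step_3d <- function(grid, spec, tables = NULL, rng = stats::runif) {
  if (grid$dims != 3L) stop("`diffusion_step_3d()` requires a 3D grid", call. = FALSE)
  diffusion_step(grid, spec, tables, rng)
}

#' One 3D diffusion step using the iterative repeat-axis variant
#'
#' Alternative 3D scheme that needs only the p = 1/2 table: emigrants are
#' split by repeated halving into X, Y, Z and a "repeat" pool R (1/4 each),
#' and the R pool is re-split until empty, so each axis ends up with
#' probability 1/3 and the per-direction marginal is again
#' Binomial(n, p_move/6).  The variate budget is random (about 7 per occupied
#' voxel on average); the scheme exists as a memory-lean reference and for
#' distributional cross-checks against the two-table step.
#'
#' @inheritParams diffusion_step
#' @export
diffusion_step_3d_repeat <- function(grid, spec, tables = NULL,
                                     rng = stats::runif) {
  stopifnot(inherits(grid, "molecule_grid"), grid$dims == 3L)
  if (is.null(tables)) tables <- diffusion_tables(spec)
  cnt <- grid$counts
  out <- cnt
  dims <- dim(cnt)
  occ <- which(cnt > 0)
  half <- tables$half
  draw_half <- function(n) {
    if (n == 0) return(0)
    if (n <= half$N_max)
      sample_binomial(n, half, rng(1L))
    else
      sample_binomial_normal_approx(n, 0.5, qnorm(rng(1L)))
  }
  draw_emig <- function(n) {
    if (n <= tables$emig$N_max)
      sample_binomial(n, tables$emig, rng(1L))
    else
      sample_binomial_normal_approx(n, spec$p_move, qnorm(rng(1L)))
  }
  for (idx in occ) {
    pos <- arrayInd(idx, dims)
    nd <- draw_emig(cnt[idx])
    ax <- c(0, 0, 0)
    # split nd into X, Y, Z, R quarters; re-split R until it empties
    while (nd > 0) {
      n_xy <- draw_half(nd)
      nx <- draw_half(n_xy)
      nzr <- nd - n_xy
      nz <- draw_half(nzr)
      ax <- ax + c(nx, n_xy - nx, nz)
      nd <- nzr - nz                    # the repeat pool
    }
    out[idx] <- out[idx] - sum(ax)
    for (a in 1:3) {
      np <- draw_half(ax[a])
      for (sgn in c(1, -1)) {
        nb <- pos
        nb[a] <- (pos[a] - 1 + sgn + dims[a]) %% dims[a] + 1
        out[nb[1], nb[2], nb[3]] <- out[nb[1], nb[2], nb[3]] +
          if (sgn == 1) np else ax[a] - np
      }
    }
  }
  grid$counts <- out
  grid
}

# torus shift of a matrix or 3D array by one lattice unit along `axis`
shift_periodic <- function(a, axis, by) {
  d <- dim(a)
  idx <- lapply(seq_along(d), function(k) seq_len(d[k]))
  idx[[axis]] <- ((idx[[axis]] - 1 - by) %% d[axis]) + 1
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

#' Deterministic (mean-field) diffusion step
#'
#' The noiseless counterpart of [diffusion_step()] used for calibration: each
#' square retains a fraction `1 - p` of its content and sends `p/4` (2D) or
#' `p/6` (3D) to each periodic neighbor.  Values may be real; mass is
#' conserved to floating-point accuracy.
#'
#' @param counts numeric matrix (2D) or 3D array of (possibly real-valued)
#'   local masses, or a [molecule_grid()].
#' @param p fraction of mass leaving a square per step, in `[0, 1]`.
#' @return Object of the same shape/class as `counts`.
#' @examples
#' m <- matrix(0, 5, 5); m[3, 3] <- 8
#' deterministic_diffusion_step(m, 0.5)[3, 3]   # 4
#' @export
deterministic_diffusion_step <- function(counts, p) {
  if (inherits(counts, "molecule_grid")) {
    counts$counts <- deterministic_diffusion_step(counts$counts, p)
    return(counts)
  }
  if (!is.numeric(p) || p < 0 || p > 1)
    stop("`p` must lie in [0, 1]", call. = FALSE)
  nd <- length(dim(counts))
  if (!nd %in% c(2L, 3L))
    stop("`counts` must be a matrix or a 3D array", call. = FALSE)
  acc <- (1 - p) * counts
  share <- p / (2 * nd)
  for (axis in seq_len(nd)) {
    acc <- acc + share * (shift_periodic(counts, axis, 1) +
                          shift_periodic(counts, axis, -1))
  }
  acc
}
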