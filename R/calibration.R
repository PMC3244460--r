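#' Deterministic point-source run
#'
#' Places `N0` units of mass at the center of an odd-sided periodic lattice
#' and applies [deterministic_diffusion_step()] `steps` times, recording the
#' center value after every step together with the final central cross
#' section.  This mimics the delta-function initial condition of the
#' diffusion equation; the center series should follow \eqn{a / t^{d/2}} and
#' the cross-section a Gaussian.
#'
#' @param L odd lattice side (squares); choose `L` large enough that mass
#'   does not wrap around within `steps`.
#' @param N0 initial mass at the center.
#' @param steps number of deterministic steps.
#' @param p fraction of mass leaving a square per step.
#' @param dims 2 or 3.
#' @return list with `center` (length `steps + 1`, entry `k + 1` is the
#'   center value after `k` steps), `profile` (the central row after the
#'   final step), and the run parameters.
#' @export
run_point_source <- function(L, N0, steps, p = 0.5, dims = 2) {
  if (L %% 2 == 0) stop("`L` must be odd so a unique center square exists",
                        call. = FALSE)
  if (!dims %in% c(2, 3)) stop("`dims` must be 2 or 3", call. = FALSE)
  mid <- (L + 1) %/% 2
  cnt <- array(0, dim = rep(L, dims))
  center_idx <- if (dims == 2) cbind(mid, mid) else cbind(mid, mid, mid)
  cnt[center_idx] <- N0
  center <- numeric(steps + 1)
  center[1] <- N0
  for (s in seq_len(steps)) {
    cnt <- deterministic_diffusion_step(cnt, p)
    center[s + 1] <- cnt[center_idx]
  }
  profile <- if (dims == 2) cnt[mid, ] else cnt[mid, mid, ]
  list(center = center, profile = profile, L = L, N0 = N0, steps = steps,
       p = p, dims = dims)
}

#' Fit the inverse-time law to a point-source center series
#'
#' Fits \eqn{u(t) = a / t^m} to the center-concentration series of a
#' point-source run, with the exponent fixed at `m = dims/2` (1 in 2D).  The
#' fit is linear least squares of \eqn{\log u} versus \eqn{\log t} with the
#' slope fixed at \eqn{-m}, i.e. \eqn{\log a = \mathrm{mean}(\log u + m \log
#' t)}: weighting each step equally on the log scale lets the late-time
#' power law dominate instead of the first few (transient) steps, which
#' deviate from the continuum solution.  \eqn{r^2} is reported as
#' \eqn{1 - SS_{res}/SS_{tot}} on the untransformed values (defined as 0 for
#' a constant series).  The default window starts at step 10 to skip the
#' worst of the transient.
#'
#' @param series center values indexed by step: `series[k + 1]` is the value
#'   after `k` steps (as returned in `run_point_source()$center`).
#' @param window integer vector of step numbers to fit (default
#'   `10:(length(series) - 1)`).
#' @param dims spatial dimensionality; the fitted exponent is `dims/2`.
#' @return list with `a`, `r2`, `window` and `exponent`.
#' @export
fit_inverse_time <- function(series, window = NULL, dims = 2) {
  if (is.null(window)) window <- 10:(length(series) - 1)
  window <- as.integer(window)
  if (any(window < 1) || any(window > length(series) - 1))
    stop("`window` must index steps 1..length(series)-1", call. = FALSE)
  if (length(window) < 3)
    stop("insufficient data: fit window must contain at least 3 points",
         call. = FALSE)
  m <- dims / 2
  u <- series[window + 1]
  if (any(u <= 0))
    stop("center series must be positive over the fit window", call. = FALSE)
  x <- window^(-m)
  a <- exp(mean(log(u) + m * log(window)))
  ss_res <- sum((u - a * x)^2)
  ss_tot <- sum((u - mean(u))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  list(a = a, r2 = r2, window = window, exponent = m)
}

#' Free-exponent power-law diagnostic fit
#'
#' Ordinary log-log regression `log u ~ log t` over the same window as
#' [fit_inverse_time()], as a diagnostic that the decay exponent is indeed
#' close to `-dims/2`.  Not used for calibration.
#'
#' @inheritParams fit_inverse_time
#' @return list with `exponent`, `amplitude` and `r2` (of the log-log fit).
#' @export
fit_power_law <- function(series, window = NULL) {
  if (is.null(window)) window <- 10:(length(series) - 1)
  u <- series[window + 1]
  if (any(u <= 0)) stop("power-law diagnostic needs positive values", call. = FALSE)
  fit <- stats::lm(log(u) ~ log(window))
  list(exponent = unname(stats::coef(fit)[2]),
       amplitude = exp(unname(stats::coef(fit)[1])),
       r2 = summary(fit)$r.squared)
}

#' Fit a centered Gaussian to a point-source cross-section
#'
#' Nonlinear least-squares fit of \eqn{g(x) = A \exp(-x^2 / (2\sigma^2))}
#' to a cross-section through the source, with `x` measured in lattice units
#' from the source column.  Start values come from the profile's zeroth and
#' second moments.
#'
#' @param profile numeric cross-section (e.g. `run_point_source()$profile`);
#'   the source is assumed at the middle index.
#' @return list with `A`, `sigma2`, `r2`.
#' @export
fit_gaussian_profile <- function(profile) {
  if (all(profile == 0))
    stop("degenerate input: profile is identically zero", call. = FALSE)
  x <- seq_along(profile) - (length(profile) + 1) / 2
  w <- pmax(profile, 0)
  s2_0 <- sum(w * x^2) / sum(w)
  if (!is.finite(s2_0) || s2_0 <= 0) s2_0 <- 1
  df <- data.frame(x = x, y = profile)
  fit <- minpack.lm::nlsLM(y ~ A * exp(-x^2 / (2 * s2)), data = df,
                           start = list(A = max(profile), s2 = s2_0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  pr <- stats::predict(fit)
  ss_tot <- sum((profile - mean(profile))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum((profile - pr)^2) / ss_tot
  est <- stats::coef(fit)
  list(A = unname(est["A"]), sigma2 = unname(est["s2"]), r2 = r2)
}

#' Derive the time-step constant c from a point-source fit
#'
#' Matches the fitted simulation center law \eqn{u = a / n^{d/2}} (with `n`
#' the step number) to the continuum point-source solution
#' \eqn{u(t) = N \delta^d / (4 \pi D t)^{d/2}} evaluated at
#' \eqn{t = n \Delta t}, \eqn{\Delta t = \delta^2 / (c D)}.  The lattice
#' spacing and diffusion coefficient cancel, leaving
#' \eqn{c = 4\pi a / N} in 2D and \eqn{c = 4\pi (a/N)^{2/3}} in 3D.
#'
#' @param a amplitude from [fit_inverse_time()].
#' @param N_total total mass of the point-source run.
#' @param dims 2 or 3.
#' @return the dimensionless constant `c` of `dt = delta^2/(c*D)`.
#' @export
derive_c <- function(a, N_total, dims = 2) {
  if (!is.numeric(a) || a <= 0)
    stop("invalid fit: amplitude `a` must be positive", call. = FALSE)
  if (dims == 2) 4 * pi * a / N_total
  else if (dims == 3) 4 * pi * (a / N_total)^(2 / 3)
  else stop("`dims` must be 2 or 3", call. = FALSE)
}

#' @rdname derive_c
#' @param delta lattice spacing (µm).
#' @param c time-step constant.
#' @param D diffusion coefficient (µm²/s).
#' @export
dt_from_c <- function(delta, c, D) delta^2 / (c * D)

#' Full point-source calibration at a given emigration fraction
#'
#' Runs the deterministic point source, fits the inverse-time center law and
#' the final Gaussian cross-section, and derives the time-step constant `c`.
#'
#' @inheritParams run_point_source
#' @param profile_steps steps for the cross-section run; `NULL` reuses the
#'   final profile of the center run.
#' @param window fit window for [fit_inverse_time()].
#' @return list of class `calibration_result` with `a`, `c`, `r2_center`,
#'   `r2_profile`, `sigma2_profile`, `steps_used`, `p`, `dims`.
#' @export
calibrate_diffusion <- function(p = 0.5, dims = 2, L = 201, steps = 1000,
                                profile_steps = NULL, N0 = 1e6, window = NULL) {
  run <- run_point_source(L, N0, steps, p, dims)
  fit_c <- fit_inverse_time(run$center, window, dims)
  profile <- if (is.null(profile_steps) || profile_steps == steps) {
    run$profile
  } else {
    run_point_source(L, N0, profile_steps, p, dims)$profile
  }
  fit_g <- fit_gaussian_profile(profile)
  structure(
    list(a = fit_c$a, c = derive_c(fit_c$a, N0, dims),
         r2_center = fit_c$r2, r2_profile = fit_g$r2,
         sigma2_profile = fit_g$sigma2,
         steps_used = range(fit_c$window), p = p, dims = dims),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(paste0("<calibration_result> %dD, p = %g: a = %.6g, c = %.4f ",
                     "(r2 center %.6f, r2 profile %.6f, sigma2 %.3f)\n"),
              x$dims, x$p, x$a, x$c, x$r2_center, x$r2_profile,
              x$sigma2_profile))
  invisible(x)
}

#' Emigration probability from the error-function mass balance
#'
#' Approximates the fraction of molecules leaving a lattice square in one
#' time step by integrating the continuum point-source Gaussian over the
#' central square: the retained fraction per axis is
#' \eqn{\mathrm{erf}(\delta / (2\sqrt{4 D \Delta t}))}, so
#' \eqn{p = 1 - \mathrm{erf}(\delta/(2\sqrt{4 D \Delta t}))^d}.  The two
#' approximations involved (mass concentrated at the square center rather
#' than well mixed, and nearest-neighbor-only moves) make this value differ
#' slightly from the simulation-calibrated `p`.
#'
#' @param delta lattice spacing (µm).
#' @param dt time step (s).
#' @param D diffusion coefficient (µm²/s).
#' @param dims 2 or 3.
#' @return emigration probability in (0, 1).
#' @examples
#' solve_p_mass_balance(20, 1, 50)   # approximately 0.534 at dt = delta^2/(8 D)
#' @export
solve_p_mass_balance <- function(delta, dt, D, dims = 2) {
  stopifnot(delta > 0, dt > 0, D > 0)
  1 - pracma::erf(delta / (2 * sqrt(4 * D * dt)))^dims
}

#' Half-interval search for the emigration probability hitting a target dt
#'
#' Bisects the emigration fraction `p` so the calibrated time step
#' \eqn{\Delta t(p) = \delta^2 / (c(p) D)} matches `dt_target`, where `c(p)`
#' comes from a deterministic point-source calibration at each trial `p`
#' ([calibrate_diffusion()]).  \eqn{\Delta t(p)} increases monotonically with
#' `p` (more emigration per step means each step covers more physical time).
#'
#' @param dt_target desired time step (s).
#' @param delta lattice spacing (µm).
#' @param D diffusion coefficient (µm²/s).
#' @param tol relative tolerance on `|dt(p) - dt_target| / dt_target`.
#' @param bracket search interval for `p`.
#' @param dims 2 or 3.
#' @param L,steps size of the calibration runs per bisection step (smaller
#'   than the headline calibration for speed; accuracy is set by `tol`).
#' @param max_iter bisection iteration cap.
#' @return list with `p`, `dt`, `c`, `iterations`.
#' @export
bisect_p_for_target <- function(dt_target, delta, D, tol = 1e-3,
                                bracket = c(0.05, 0.95), dims = 2,
                                L = 101, steps = 300, max_iter = 60) {
  stopifnot(dt_target > 0, delta > 0, D > 0, tol > 0)
  dt_of_p <- function(p)
    dt_from_c(delta, calibrate_diffusion(p, dims, L, steps)$c, D)
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- dt_of_p(lo) - dt_target
  f_hi <- dt_of_p(hi) - dt_target
  if (f_lo > 0 || f_hi < 0)
    stop(sprintf("target dt = %g not achievable for p in [%g, %g]",
                 dt_target, lo, hi), call. = FALSE)
  p <- NA_real_; dt_p <- NA_real_
  for (it in seq_len(max_iter)) {
    p <- (lo + hi) / 2
    dt_p <- dt_of_p(p)
    if (abs(dt_p - dt_target) / dt_target < tol) break
    if (dt_p < dt_target) lo <- p else hi <- p
  }
  list(p = p, dt = dt_p, c = delta^2 / (dt_p * D), iterations = it)
}
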