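#' Time and value of half-maximal induction
#'
#' The half-max value is `max(values)/2`; the crossing time is linearly
#' interpolated between the record times bracketing the first up-crossing.
#' A series that never rises above zero has no defined induction and is
#' reported as missing (`NA`), not as an error.
#'
#' @param times record times (s), increasing; at least 2 points.
#' @param values population-mean series at `times`.
#' @return named numeric `c(t_half, v_half)`; both `NA` for an identically
#'   zero series.
#' @examples
#' half_max_induction(c(0, 1), c(0, 10))   # t_half 0.5, v_half 5
#' @export
half_max_induction <- function(times, values) {
  if (length(times) < 2 || length(times) != length(values))
    stop("need matching `times` and `values` with at least 2 points",
         call. = FALSE)
  if (all(values == 0)) return(c(t_half = NA_real_, v_half = NA_real_))
  v_half <- max(values) / 2
  i <- which(values >= v_half)[1]
  t_half <- if (i == 1L) times[1] else {
    dv <- values[i] - values[i - 1]
    times[i - 1] + if (dv > 0) (v_half - values[i - 1]) / dv *
      (times[i] - times[i - 1]) else 0
  }
  c(t_half = t_half, v_half = v_half)
}

# normalized root-mean-square distance between two curves: each is scaled to
# peak 1 (an all-zero curve stays zero) before the pointwise comparison
trajectory_distance <- function(f, g) {
  nf <- if (max(f) > 0) f / max(f) else f
  ng <- if (max(g) > 0) g / max(g) else g
  sqrt(mean((nf - ng)^2))
}

#' Sweep the multiplicity of infection
#'
#' Runs `n_replicates` cultures per MOI value (with distinct seeds split
#' from `config$seed`), averages the population curves across replicates,
#' and summarizes: interferon transcripts per infected cell versus time,
#' Rig-I transcripts per cell versus time, half-max induction markers for
#' both, and pairwise trajectory-similarity scores.  The pairwise score is
#' the normalized root-mean-square distance between peak-normalized mean
#' curves, averaged over the interferon and Rig-I curves.
#'
#' @param config_base a [culture_config()]; its `moi` and `seed` fields are
#'   overridden per run.
#' @param moi_values numeric vector of MOI values (non-empty).
#' @param n_replicates replicate cultures per MOI.
#' @param params a [dc_rate_params()].
#' @param spec a [diffusion_spec()] or `NULL` for the default.
#' @return object of class `moi_sweep`: `moi`, `times`, `ifn_curves` and
#'   `rigi_curves` (matrices, one column per MOI), `t_half` (data frame with
#'   both markers per MOI), and `dist` (pairwise distance matrix; `NULL`
#'   for a single MOI).
#' @export
moi_sweep <- function(config_base, moi_values, n_replicates = 5,
                      params = dc_rate_params(), spec = NULL) {
  if (length(moi_values) == 0) stop("`moi_values` must be non-empty", call. = FALSE)
  stopifnot(inherits(config_base, "culture_config"))
  n_moi <- length(moi_values)
  ifn <- rigi <- NULL
  times <- NULL
  for (m in seq_len(n_moi)) {
    acc_i <- acc_r <- NULL
    for (r in seq_len(n_replicates)) {
      cfg <- config_base
      cfg$moi <- moi_values[m]
      cfg$seed <- (config_base$seed + 7919L * m + 104729L * r) %% 2147483647L
      traj <- run_culture(cfg, params, spec, record_cells = FALSE)
      if (is.null(times)) times <- traj$times
      acc_i <- if (is.null(acc_i)) traj$pop$mean_MI_infected else
        acc_i + traj$pop$mean_MI_infected
      acc_r <- if (is.null(acc_r)) traj$pop$mean_MR else
        acc_r + traj$pop$mean_MR
    }
    ifn <- cbind(ifn, acc_i / n_replicates)
    rigi <- cbind(rigi, acc_r / n_replicates)
  }
  colnames(ifn) <- colnames(rigi) <- paste0("moi_", moi_values)
  t_half <- data.frame(
    moi = moi_values,
    t_half_ifn = apply(ifn, 2, function(v) half_max_induction(times, v)["t_half"]),
    v_half_ifn = apply(ifn, 2, function(v) half_max_induction(times, v)["v_half"]),
    t_half_rigi = apply(rigi, 2, function(v) half_max_induction(times, v)["t_half"]),
    v_half_rigi = apply(rigi, 2, function(v) half_max_induction(times, v)["v_half"]),
    row.names = NULL)
  dist <- NULL
  if (n_moi > 1) {
    dist <- matrix(0, n_moi, n_moi,
                   dimnames = list(colnames(ifn), colnames(ifn)))
    for (a in seq_len(n_moi - 1)) for (b in (a + 1):n_moi) {
      d <- (trajectory_distance(ifn[, a], ifn[, b]) +
              trajectory_distance(rigi[, a], rigi[, b])) / 2
      dist[a, b] <- dist[b, a] <- d
    }
  }
  structure(list(moi = moi_values, times = times, ifn_curves = ifn,
                 rigi_curves = rigi, t_half = t_half, dist = dist,
                 n_replicates = n_replicates),
            class = "moi_sweep")
}

#' @export
print.moi_sweep <- function(x, ...) {
  cat(sprintf("<moi_sweep> MOI {%s}, %d replicates each\n",
              paste(x$moi, collapse = ", "), x$n_replicates))
  print(x$t_half)
  if (!is.null(x$dist)) {
    cat("pairwise normalized trajectory distances:\n")
    print(round(x$dist, 4))
  }
  invisible(x)
}
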