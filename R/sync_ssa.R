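#' Define a Markovian reaction system
#'
#' @param species character vector of species names (length `N`).
#' @param stoich integer matrix (`N` x `M`): column `j` is the state change
#'   applied when reaction `j` fires.
#' @param propensity function `state -> numeric(M)` of non-negative reaction
#'   rates; may close over external signals that only change at
#'   synchronization times.
#' @return object of class `reaction_system`.
#' @examples
#' sys <- reaction_system("X", matrix(-1, 1, 1), function(x) 0.1 * x)
#' @export
reaction_system <- function(species, stoich, propensity) {
  stoich <- as.matrix(stoich)
  if (nrow(stoich) != length(species))
    stop("`stoich` must have one row per species", call. = FALSE)
  if (!is.function(propensity))
    stop("`propensity` must be a function of the state", call. = FALSE)
  structure(list(species = species, stoich = stoich, propensity = propensity,
                 n_species = length(species), n_reactions = ncol(stoich)),
            class = "reaction_system")
}

#' Synchronization schedule for the modified Gillespie algorithm
#'
#' @param dt_sync interval between external state updates (s); must be > 0.
#' @param t_end simulation horizon (s).
#' @return object of class `sync_schedule`.
#' @export
sync_schedule <- function(dt_sync, t_end) {
  if (!is.numeric(dt_sync) || dt_sync <= 0)
    stop("`dt_sync` must be positive", call. = FALSE)
  if (!is.numeric(t_end) || t_end < 0)
    stop("`t_end` must be non-negative", call. = FALSE)
  structure(list(dt_sync = dt_sync, t_end = t_end), class = "sync_schedule")
}

#' Exponential waiting time of the next reaction
#'
#' Inverse-transform draw \eqn{\tau = -\ln(u) / R} from the exponential
#' distribution with mean `1/R_total`.
#'
#' @param R_total total propensity (sum of all reaction rates); must be > 0
#'   (a zero total means no event can occur before the horizon, which the
#'   caller handles by advancing to the next synchronization time).
#' @param u uniform variate in (0, 1).
#' @return waiting time in seconds.
#' @export
draw_waiting_time <- function(R_total, u) {
  if (R_total <= 0)
    stop("R_total must be positive; with zero total propensity advance to the next sync",
         call. = FALSE)
  -log(u) / R_total
}

#' Select which reaction fires
#'
#' Returns the index `j` whose cumulative-propensity interval contains
#' `u * sum(a)` (smallest `j` with `cumsum(a)[j] > u * sum(a)`), so each
#' reaction fires with probability proportional to its rate.
#'
#' @param a non-negative propensity vector with positive sum.
#' @param u uniform variate in `[0, 1)`.
#' @return reaction index in `1..length(a)`.
#' @export
select_reaction <- function(a, u) {
  if (any(a < 0)) stop("negative propensity", call. = FALSE)
  total <- sum(a)
  if (total <= 0) stop("all propensities are zero", call. = FALSE)
  findInterval(u * total, cumsum(a), left.open = FALSE) + 1L
}

#' One step of the synchronized Gillespie algorithm
#'
#' Draws a candidate waiting time from the current total propensity.  If the
#' candidate event time exceeds (or exactly hits) the next synchronization
#' time, the state is returned unchanged at `t_sync_next` flagged `"synced"`
#' and the drawn waiting time is discarded: by the memoryless property the
#' post-update waiting time must be redrawn from the updated rates, so no
#' residual is carried over.  Otherwise one reaction fires.
#'
#' @param state named non-negative integer state vector.
#' @param t_now current time; must be `< t_sync_next`.
#' @param t_sync_next next external-update time.
#' @param system a [reaction_system()].
#' @return list with `state`, `t`, `event` (`"fired"` or `"synced"`) and
#'   `reaction` (index, or `NA` on sync).
#' @export
step_synchronized <- function(state, t_now, t_sync_next, system) {
  stopifnot(t_now < t_sync_next)
  a <- system$propensity(state)
  if (any(a < 0))
    stop(sprintf("model error: negative propensity for reaction %d",
                 which(a < 0)[1]), call. = FALSE)
  total <- sum(a)
  if (total <= 0)
    return(list(state = state, t = t_sync_next, event = "synced",
                reaction = NA_integer_))
  tau <- draw_waiting_time(total, runif(1))
  if (t_now + tau >= t_sync_next)       # ties resolve to the sync
    return(list(state = state, t = t_sync_next, event = "synced",
                reaction = NA_integer_))
  j <- select_reaction(a, runif(1))
  list(state = state + system$stoich[, j], t = t_now + tau,
       event = "fired", reaction = j)
}

#' Run the synchronized Gillespie algorithm
#'
#' Simulates the reaction system to `schedule$t_end`, pausing at every
#' multiple of `schedule$dt_sync` to apply `external_update` (a function
#' `(state, t) -> state`) and then continuing with freshly drawn waiting
#' times.  Between synchronizations the dynamics are exactly the classical
#' Gillespie algorithm for the current rates; with a no-op hook the
#' trajectory statistics are indistinguishable from the classical algorithm
#' at any synchronization frequency.
#'
#' @param system a [reaction_system()].
#' @param state0 initial state vector.
#' @param schedule a [sync_schedule()].
#' @param external_update hook applied at each sync time, or `NULL` for the
#'   identity; must return non-negative counts.
#' @param record `"events"` records every fired event and sync;
#'   `"times"` records event/sync times and types but no states (cheapest);
#'   `"none"` returns only the final state.
#' @return object of class `ssa_trajectory`: list with `times`, `types`
#'   (reaction index, or 0 for a sync), `states` (matrix, if recorded) and
#'   `final_state`.
#' @export
run_sync_ssa <- function(system, state0, schedule, external_update = NULL,
                         record = c("events", "times", "none")) {
  record <- match.arg(record)
  stopifnot(inherits(system, "reaction_system"),
            inherits(schedule, "sync_schedule"))
  keep_states <- record == "events"
  keep_times <- record != "none"
  state <- state0
  t <- 0
  cap <- 1024L
  times <- numeric(cap); types <- integer(cap)
  states <- if (keep_states) matrix(0, cap, length(state0)) else NULL
  n_rec <- 0L
  push <- function(tt, ty, st) {
    n_rec <<- n_rec + 1L
    if (n_rec > cap) {
      cap <<- cap * 2L
      length(times) <<- cap; length(types) <<- cap
      if (keep_states) {
        s2 <- matrix(0, cap, length(state0)); s2[seq_len(n_rec - 1L), ] <- states
        states <<- s2
      }
    }
    times[n_rec] <<- tt; types[n_rec] <<- ty
    if (keep_states) states[n_rec, ] <<- st
  }
  stoich <- system$stoich
  prop <- system$propensity
  if (schedule$t_end == 0)
    return(structure(list(times = numeric(0), types = integer(0),
                          states = if (keep_states) {
                            s <- matrix(state0, 1)[0, , drop = FALSE]
                            colnames(s) <- system$species
                            s
                          } else NULL,
                          final_state = state0, t_end = 0),
                     class = "ssa_trajectory"))
  n_sync <- floor(schedule$t_end / schedule$dt_sync + 1e-9)
  sync_times <- seq_len(n_sync) * schedule$dt_sync
  # the hook runs only at true multiples of dt_sync; a trailing partial
  # segment just ends at the horizon
  hook_at <- rep(TRUE, length(sync_times))
  if (n_sync == 0L || sync_times[n_sync] < schedule$t_end - 1e-12) {
    sync_times <- c(sync_times, schedule$t_end)
    hook_at <- c(hook_at, FALSE)
  }
  for (si in seq_along(sync_times)) {
    t_sync <- sync_times[si]
    repeat {
      a <- prop(state)
      if (any(a < 0))
        stop(sprintf("model error: negative propensity for reaction %d",
                     which(a < 0)[1]), call. = FALSE)
      total <- sum(a)
      if (total <= 0) { t <- t_sync; break }
      tau <- -log(runif(1)) / total
      if (t + tau >= t_sync) { t <- t_sync; break }
      t <- t + tau
      j <- findInterval(runif(1) * total, cumsum(a)) + 1L
      state <- state + stoich[, j]
      if (keep_times) push(t, j, state)
    }
    if (!is.null(external_update) && hook_at[si]) {
      state <- external_update(state, t_sync)
      if (any(state < 0))
        stop("external-update error: hook returned negative counts",
             call. = FALSE)
    }
    if (keep_times) push(t_sync, 0L, state)
  }
  structure(
    list(times = if (keep_times) times[seq_len(n_rec)] else numeric(0),
         types = if (keep_times) types[seq_len(n_rec)] else integer(0),
         states = if (keep_states) {
           s <- states[seq_len(n_rec), , drop = FALSE]
           colnames(s) <- system$species
           s
         } else NULL,
         final_state = state, t_end = schedule$t_end),
    class = "ssa_trajectory")
}

#' Inter-event times of fired reactions in a trajectory
#'
#' Differences between successive firing times (synchronization pauses are
#' transparent: they do not break an interval), optionally restricted to one
#' reaction type.
#'
#' @param traj an `ssa_trajectory` recorded with `record != "none"`.
#' @param reaction reaction index to filter on, or `NULL` for all reactions.
#' @return numeric vector of waiting times.
#' @export
inter_event_times <- function(traj, reaction = NULL) {
  stopifnot(inherits(traj, "ssa_trajectory"))
  keep <- if (is.null(reaction)) traj$types > 0L else traj$types == reaction
  diff(c(0, traj$times[keep]))
}
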