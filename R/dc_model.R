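#' Hill (Michaelis-Menten) induction function
#'
#' Saturating rate law \eqn{x^h / (K^h + x^h)}: 0 at `x = 0`, 1/2 at the
#' half-induction level `x = K`, approaching 1 for large `x`; monotone
#' non-decreasing in `x`.
#'
#' @param x inducer amount (count).
#' @param K half-induction level, > 0.
#' @param h Hill coefficient, >= 1.
#' @return fraction in `[0, 1)`.
#' @examples
#' hill(4000, 4000, 4)   # 0.5
#' @export
hill <- function(x, K, h) {
  stopifnot(K > 0, h >= 1, all(x >= 0))
  xh <- (x / K)^h
  xh / (1 + xh)
}

#' Rate parameters of the Rig-I / interferon cell model
#'
#' Bundles the rate constants of the six intracellular reactions, the
#' secretion constant and the surface-receptor kinetics.  The defaults are
#' an illustrative, biologically plausible set (units noted per field); they
#' are configuration, not measured truths, and every value can be overridden
#' from the master configuration file.
#'
#' @param k_MI_max maximal interferon transcription rate (1/s).
#' @param K_P,h_P half-induction Rig-I protein level and Hill coefficient of
#'   interferon induction.
#' @param k_MR_basal constitutive Rig-I transcription rate (1/s).
#' @param fold_f ratio of maximal to constitutive Rig-I induction (>= 1).
#' @param K_B,h_B half-induction bound-receptor number and Hill coefficient
#'   of Rig-I induction.
#' @param k_tl Rig-I translation rate constant (1/s per transcript).
#' @param d_MI,d_MR,d_PR first-order degradation rate constants (1/s) of
#'   interferon transcript, Rig-I transcript and Rig-I protein.
#' @param k_sec interferon molecules secreted per transcript per diffusion
#'   step (dimensionless per step).
#' @param k_on receptor binding rate constant (1/(receptor s)).
#' @param k_off receptor unbinding rate constant (1/s).
#' @param F0 initial free surface receptors per cell.
#' @return object of class `dc_rate_params`.
#' @export
dc_rate_params <- function(k_MI_max = 0.1, K_P = 4000, h_P = 4,
                           k_MR_basal = 5e-3, fold_f = 10,
                           K_B = 500, h_B = 2,
                           k_tl = 0.02, d_MI = 5e-4, d_MR = 5e-4,
                           d_PR = 2e-4, k_sec = 0.25,
                           k_on = 1e-5, k_off = 1e-4, F0 = 2000) {
  p <- list(k_MI_max = k_MI_max, K_P = K_P, h_P = h_P,
            k_MR_basal = k_MR_basal, fold_f = fold_f, K_B = K_B, h_B = h_B,
            k_tl = k_tl, d_MI = d_MI, d_MR = d_MR, d_PR = d_PR,
            k_sec = k_sec, k_on = k_on, k_off = k_off, F0 = F0)
  bad <- names(p)[!vapply(p, function(v) is.numeric(v) && length(v) == 1 &&
                            is.finite(v) && v >= 0, logical(1))]
  if (length(bad))
    stop("rate parameters must be non-negative finite scalars: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (fold_f < 1) stop("`fold_f` must be >= 1", call. = FALSE)
  if (h_P < 1 || h_B < 1) stop("Hill coefficients must be >= 1", call. = FALSE)
  if (K_P <= 0 || K_B <= 0)
    stop("half-induction levels must be positive", call. = FALSE)
  structure(p, class = "dc_rate_params")
}

#' Intracellular state of one cell agent
#'
#' @param M_I interferon transcript count.
#' @param M_R Rig-I transcript count.
#' @param P_R Rig-I protein count.
#' @param infected logical; only infected cells transcribe interferon (viral
#'   RNA is what activates the Rig-I sensing pathway).
#' @param F free surface receptors.
#' @param B bound surface receptors; `F + B` is invariant.
#' @param t_local cell-local clock (s).
#' @param position lattice square `(row, col)`.
#' @return object of class `cell_state`.
#' @export
cell_state <- function(M_I = 0, M_R = 0, P_R = 0, infected = FALSE,
                       F = 0, B = 0, t_local = 0, position = c(NA, NA)) {
  counts <- c(M_I = M_I, M_R = M_R, P_R = P_R, F = F, B = B)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  structure(list(M_I = M_I, M_R = M_R, P_R = P_R, infected = isTRUE(infected),
                 F = F, B = B, t_local = t_local, position = position),
            class = "cell_state")
}

#' Propensities of the six intracellular reactions
#'
#' Reaction order: (1) interferon transcription, gated on infection and Hill
#' in Rig-I protein; (2) Rig-I transcription, a constitutive rate scaled up
#' to `fold_f` times by the bound-receptor Hill term,
#' `k_MR_basal * (1 + (fold_f - 1) * hill(B, K_B, h_B))`; (3) translation;
#' (4-6) first-order degradation of the three species.
#'
#' @param cell a [cell_state()].
#' @param params a [dc_rate_params()].
#' @return numeric vector of six non-negative rates (1/s).
#' @export
dc_propensities <- function(cell, params) {
  stopifnot(inherits(cell, "cell_state"), inherits(params, "dc_rate_params"))
  if (cell$M_I < 0 || cell$M_R < 0 || cell$P_R < 0)
    stop("state error: negative counts", call. = FALSE)
  c(ifn_transcription = if (cell$infected)
      params$k_MI_max * hill(cell$P_R, params$K_P, params$h_P) else 0,
    rigi_transcription = params$k_MR_basal *
      (1 + (params$fold_f - 1) * hill(cell$B, params$K_B, params$h_B)),
    translation = params$k_tl * cell$M_R,
    ifn_mrna_degradation = params$d_MI * cell$M_I,
    rigi_mrna_degradation = params$d_MR * cell$M_R,
    rigi_protein_degradation = params$d_PR * cell$P_R)
}

#' Stoichiometry of the six-reaction cell model
#'
#' @return 3 x 6 integer matrix over species `(M_I, M_R, P_R)` matching the
#'   reaction order of [dc_propensities()].
#' @export
dc_stoichiometry <- function() {
  m <- cbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(-1, 0, 0), c(0, -1, 0), c(0, 0, -1))
  rownames(m) <- c("M_I", "M_R", "P_R")
  colnames(m) <- c("ifn_transcription", "rigi_transcription", "translation",
                   "ifn_mrna_degradation", "rigi_mrna_degradation",
                   "rigi_protein_degradation")
  m
}

#' @rdname dc_propensities
#' @details `dc_reaction_system()` packages the model as a
#'   [reaction_system()] over `(M_I, M_R, P_R)` for use with
#'   [run_sync_ssa()]; `infected` and the bound-receptor count `B` enter as
#'   external conditions frozen between synchronizations.
#' @param infected infection flag for the packaged system.
#' @param B_fun function `t -> bound receptors`, or a constant; evaluated
#'   lazily so a sync hook can update it.
#' @export
dc_reaction_system <- function(params, infected = FALSE, B_fun = 0) {
  b_env <- new.env(parent = emptyenv())
  b_env$B <- if (is.function(B_fun)) B_fun(0) else B_fun
  sys <- reaction_system(
    species = c("M_I", "M_R", "P_R"),
    stoich = dc_stoichiometry(),
    propensity = function(state) {
      c(if (infected) params$k_MI_max * hill(state[3], params$K_P, params$h_P) else 0,
        params$k_MR_basal *
          (1 + (params$fold_f - 1) * hill(b_env$B, params$K_B, params$h_B)),
        params$k_tl * state[2],
        params$d_MI * state[1],
        params$d_MR * state[2],
        params$d_PR * state[3])
    })
  sys$set_B <- function(B) b_env$B <- B
  sys
}

# vectorized receptor-ligand exchange core shared by the single-cell surface
# and the culture stepper; exact binomial thinning of pseudo-first-order
# kinetics over one step
receptor_exchange_core <- function(ifn, F, B, dt, k_on, k_off) {
  p_bind <- 1 - exp(-k_on * F * dt)
  n_bind <- pmin(rbinom(length(ifn), ifn, p_bind), F)
  n_unbind <- rbinom(length(B), B, 1 - exp(-k_off * dt))
  list(ifn = ifn - n_bind + n_unbind,
       F = F - n_bind + n_unbind,
       B = B + n_bind - n_unbind,
       n_bind = n_bind, n_unbind = n_unbind)
}

#' Stochastic receptor binding and unbinding over one diffusion step
#'
#' Free interferon in the cell's lattice square binds free surface receptors
#' with per-molecule probability `1 - exp(-k_on F dt)` (binomial thinning,
#' exact for pseudo-first-order kinetics over the step; the draw is capped
#' at `F` so receptors never go negative), while bound receptors unbind with
#' probability `1 - exp(-k_off dt)`.  The receptor total `F + B` and the
#' combined molecule bookkeeping are conserved exactly.
#'
#' @param square_ifn free interferon count in the cell's square.
#' @param cell a [cell_state()].
#' @param dt the diffusion time step (s).
#' @param params a [dc_rate_params()].
#' @return list with updated `square_ifn` and `cell`.
#' @export
receptor_exchange <- function(square_ifn, cell, dt, params) {
  stopifnot(inherits(cell, "cell_state"), square_ifn >= 0)
  r <- receptor_exchange_core(square_ifn, cell$F, cell$B, dt,
                              params$k_on, params$k_off)
  cell$F <- r$F
  cell$B <- r$B
  list(square_ifn = r$ifn, cell = cell)
}

#' Interferon secretion over one diffusion step
#'
#' Every interferon transcript templates translation during the step and all
#' newly synthesized molecules are secreted immediately, so the number of
#' new extracellular molecules is Poisson with mean `M_I * k_sec`
#' (transcripts are templates, not consumed).
#'
#' @param cell a [cell_state()].
#' @param dt the diffusion time step (s); secretion is parameterized per
#'   step, so `dt` only documents the step the caller is taking.
#' @param params a [dc_rate_params()].
#' @return count of newly secreted molecules (to add to the cell's square).
#' @export
secrete <- function(cell, dt, params) {
  stopifnot(inherits(cell, "cell_state"))
  rpois(1, cell$M_I * params$k_sec)
}
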