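## Per-cell intracellular interaction network: the nine-species ODE system
## linking extracellular glucose to the miR-451 / MO25 / LKB1-STRAD / AMPK /
## TSC2 / Rheb / mTORC1 cascade, its integration, steady states, and the
## phenotype decision.

.gs_species <- c("x1", "x2", "x3", "x4", "x5", "x6", "x7", "x8", "x9")

## pool upper bounds per component (Inf where unbounded)
.gs_pools <- function(consts) {
  c(Inf, Inf, Inf, Inf, consts$S_tot, consts$A_tot, consts$T_tot,
    consts$R_tot, consts$M_tot)
}

.check_state <- function(state, consts, what = "state") {
  if (length(state) != 9L)
    stop(what, " must have 9 components")
  bad <- which(!is.finite(state))
  if (length(bad))
    stop("non-finite ", what, " component: ",
         paste(.gs_species[bad], collapse = ", "))
  if (any(state < 0))
    stop(what, " has negative component: ",
         paste(.gs_species[state < 0], collapse = ", "))
  pools <- .gs_pools(consts)
  over <- which(state > pools * (1 + 1e-9))
  if (length(over))
    stop(what, " exceeds its pool bound: ",
         paste(.gs_species[over], collapse = ", "))
  invisible(TRUE)
}

#' Time derivatives of the intracellular network
#'
#' Right-hand side of the nine-species ODE system. Glucose drives saturating
#' miR-451 synthesis (k1, k1_i); miR-451 reversibly binds MO25 mRNA into a
#' decaying complex (k2, k3, k5), realising translational repression; MO25 is
#' translated (k8) and assembles the LKB1-STRAD scaffold (k9, k10); the
#' scaffold phosphorylates AMPK in a Michaelis-Menten
#' phosphorylation/dephosphorylation cycle (k11 pair) with direct
#' glucose-dependent AMPK inactivation (k12, k12_i); AMPK drives the TSC2
#' cycle (k13 pair); TSC2 inactivates Rheb against constitutive reactivation
#' (k14, k15, k15_i); Rheb activates mTORC1 in a further cycle (k17 pair)
#' with direct AMPK inhibition (k18) and first-order decay (k16).
#'
#' @param state Numeric vector of the nine concentrations x1..x9 (pmol/L).
#' @param glucose Local glucose concentration (g/L), >= 0.
#' @param params Reaction parameters, see [reaction_parameters()].
#' @param consts Network constants, see [network_constants()].
#' @return Numeric vector of the nine time derivatives (pmol L^-1 s^-1).
#' @export
molecular_rhs <- function(state, glucose, params = reaction_parameters(),
                          consts = network_constants()) {
  .check_state(state, consts)
  if (!is.finite(glucose) || glucose < 0)
    stop("glucose must be finite and >= 0")
  d <- gs_rhs_cpp(as.numeric(state), glucose, .pack_params(params),
                  .pack_consts(consts))
  names(d) <- .gs_species
  d
}

#' Advance one cell's molecular state by a fixed-step 4th-order scheme
#'
#' Classical Runge-Kutta integration of the intracellular network at constant
#' local glucose, using `n_sub` equal substeps over `dt_macro`. After each
#' substep the state is clamped to `[0, pool]`; the number of clamped
#' components is reported in the `"clamped"` attribute. The explicit scheme
#' requires substeps small compared to the fastest reaction; for macro-step
#' advances at the baseline (stiff) parameter set use [advance_states()].
#'
#' @inheritParams molecular_rhs
#' @param dt_macro Time to advance (s), > 0.
#' @param n_sub Number of substeps, >= 1.
#' @return The advanced state (named numeric, 9 components).
#' @export
integrate_cell <- function(state, glucose, params = reaction_parameters(),
                           consts = network_constants(), dt_macro, n_sub) {
  .check_state(state, consts)
  if (!is.finite(dt_macro) || dt_macro <= 0) stop("dt_macro must be > 0")
  if (n_sub < 1) stop("n_sub must be >= 1")
  h <- dt_macro / n_sub
  p <- .pack_params(params)
  cc <- .pack_consts(consts)
  pools <- .gs_pools(consts)
  x <- as.numeric(state)
  clamped <- 0L
  for (s in seq_len(n_sub)) {
    k1 <- gs_rhs_cpp(x, glucose, p, cc)
    k2 <- gs_rhs_cpp(x + h / 2 * k1, glucose, p, cc)
    k3 <- gs_rhs_cpp(x + h / 2 * k2, glucose, p, cc)
    k4 <- gs_rhs_cpp(x + h * k3, glucose, p, cc)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (anyNA(x) || any(!is.finite(x)))
      stop("integration produced a non-finite value at substep ", s,
           ", component ",
           paste(.gs_species[!is.finite(x)], collapse = ", "))
    lo <- x < 0
    hi <- x > pools
    if (any(lo) || any(hi)) {
      clamped <- clamped + sum(lo) + sum(hi)
      x[lo] <- 0
      x[hi] <- pools[hi]
    }
  }
  names(x) <- .gs_species
  attr(x, "clamped") <- clamped
  x
}

#' Advance many cells over a macro step (stiff path)
#'
#' Advances a matrix of per-cell molecular states over `dt` seconds at
#' per-cell constant glucose with an adaptive backward-Euler scheme. The
#' network couples reactions with rates spanning roughly 5e-3 to 2e5 s^-1;
#' the L-stable implicit scheme takes the hour-long macro step in a few tens
#' of internal steps per cell where an explicit scheme would need billions.
#'
#' @param states Numeric matrix, one row per cell, nine columns.
#' @param glucose Numeric vector of local glucose (g/L), one value per cell.
#' @inheritParams molecular_rhs
#' @param dt Time to advance (s).
#' @param h0 Initial internal step (s).
#' @param hmax Maximal internal step (s).
#' @return Matrix of advanced states with attribute `"clamped"` (count of
#'   clamp events across all cells).
#' @export
advance_states <- function(states, glucose, params = reaction_parameters(),
                           consts = network_constants(), dt,
                           h0 = 1e-3, hmax = dt / 4) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  res <- gs_advance_cpp(states, as.numeric(glucose), .pack_params(params),
                        .pack_consts(consts), dt, h0, hmax)
  out <- res$states
  colnames(out) <- .gs_species
  attr(out, "clamped") <- res$clamped
  out
}

#' Molecular steady state at fixed glucose
#'
#' Relaxes the network from the all-zero state at constant glucose over a
#' fixed deterministic horizon (`t_max` seconds, taken in adaptive implicit
#' steps) and verifies that the scaled residual norm
#' `max_i |x_i'| / (1 + |x_i|)` has fallen below `tol`. The scaled norm is
#' used because MO25 (x4) has no degradation reaction: total MO25 grows
#' slowly without bound while every switch-relevant species converges, so an
#' absolute residual norm has no root. A fixed shared horizon keeps steady
#' states at different glucose levels directly comparable, which the
#' threshold calibration relies on.
#'
#' @inheritParams molecular_rhs
#' @param tol Convergence tolerance on the scaled residual norm.
#' @param t_max Relaxation horizon (s).
#' @return Named steady-state vector with attribute `"residual"`.
#' @export
steady_state <- function(glucose, params = reaction_parameters(),
                         consts = network_constants(), tol = 1e-4,
                         t_max = 2e6) {
  if (!is.finite(glucose) || glucose < 0)
    stop("glucose must be finite and >= 0")
  x <- advance_states(matrix(0, 1, 9), glucose, params, consts,
                      dt = t_max, h0 = 1e-4, hmax = t_max / 64)
  x <- drop(x)
  resid <- max(abs(molecular_rhs(x, glucose, params, consts)) /
                 (1 + abs(x)))
  if (resid >= tol)
    stop("no steady state within t_max = ", format(t_max),
         " s: scaled residual ", format(resid), " >= tol ", format(tol))
  names(x) <- .gs_species
  attr(x, "residual") <- resid
  x
}

#' Calibrate the phenotype thresholds
#'
#' The AMPK threshold `theta_A` and mTORC1 threshold `theta_M` are set to the
#' midpoints of the respective steady-state concentrations at the two extreme
#' initial glucose levels (0.3 and 4.5 g/L by default). By construction the
#' steady state at low glucose (AMPK high, mTORC1 low) then classifies as
#' MIGRATING and the high-glucose steady state as PROLIFERATING. Calibration
#' is performed on the baseline parameter set only; perturbed simulations
#' reuse the baseline thresholds so that the sweep measures network effects
#' rather than threshold drift. Results are cached per parameter set.
#'
#' @inheritParams molecular_rhs
#' @param glucose_lo,glucose_hi The two calibration glucose levels (g/L).
#' @return List of class `gs_thresholds` with `theta_A` and `theta_M`.
#' @export
calibrate_thresholds <- function(params = reaction_parameters(),
                                 consts = network_constants(),
                                 glucose_lo = 0.3, glucose_hi = 4.5) {
  levels <- sort(c(glucose_lo, glucose_hi))
  key <- paste(format(c(unclass(params), unlist(consts), levels),
                      digits = 17), collapse = "|")
  hit <- .gs_cache[[key]]
  if (!is.null(hit)) return(hit)
  s_lo <- steady_state(levels[1], params, consts)
  s_hi <- steady_state(levels[2], params, consts)
  if (abs(s_lo[["x6"]] - s_hi[["x6"]]) < 1e-8 ||
      abs(s_lo[["x9"]] - s_hi[["x9"]]) < 1e-8)
    stop("degenerate steady states: AMPK/mTORC1 do not separate the two ",
         "glucose levels; the network cannot switch")
  thr <- structure(
    list(theta_A = (s_lo[["x6"]] + s_hi[["x6"]]) / 2,
         theta_M = (s_lo[["x9"]] + s_hi[["x9"]]) / 2),
    class = "gs_thresholds")
  .gs_cache[[key]] <- thr
  thr
}

.gs_cache <- new.env(parent = emptyenv())

#' Decide a cell's phenotype from AMPK and mTORC1
#'
#' MIGRATING when phosphorylated AMPK (x6) exceeds `theta_A` while active
#' mTORC1 (x9) does not exceed `theta_M`; PROLIFERATING in the mirrored
#' case; QUIESCENT otherwise, i.e. when both signals are high or both low
#' (conflicting or sub-threshold signals map to rest).
#'
#' @param state Molecular state vector (9 components).
#' @param thr Thresholds from [calibrate_thresholds()].
#' @return One of `phenotypes()`.
#' @export
decide_phenotype <- function(state, thr) {
  decide_phenotypes(state[[6]], state[[9]], thr)
}

#' Vectorised phenotype decision
#'
#' @param x6,x9 Numeric vectors of AMPK and mTORC1 concentrations.
#' @param thr Thresholds from [calibrate_thresholds()].
#' @return Character vector of phenotype labels.
#' @export
decide_phenotypes <- function(x6, x9, thr) {
  if (!inherits(thr, "gs_thresholds")) stop("thr must be gs_thresholds")
  out <- rep(PHENOTYPE_QUIESCENT, length(x6))
  out[x6 > thr$theta_A & x9 <= thr$theta_M] <- PHENOTYPE_MIGRATING
  out[x9 > thr$theta_M & x6 <= thr$theta_A] <- PHENOTYPE_PROLIFERATING
  out
}
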