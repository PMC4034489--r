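## Shared test utilities.

## A non-stiff parameterisation (all rates of order <= 1) on which explicit
## fixed-step integration is stable with modest substeps; used to cross-check
## integrators against deSolve.
toy_params <- function() {
  reaction_parameters(
    k3 = 0.3, k5 = 0.36, k10 = 0.36, k11_c1 = 1.8, k11_c2 = 1.8,
    k12 = 0.6, k13_c1 = 0.6, k13_c2 = 0.6, k14 = 0.36, k15 = 0.36,
    k16 = 0.36, k17_c1 = 0.36, k17_c2 = 0.36, k18_c = 0.5, k2 = 1e-3,
    k9 = 1e-3)
}

## Independent R transcription of the network right-hand side, structured
## differently from the package implementation (dual-route check).
rhs_reference <- function(x, glucose, params, consts) {
  p <- as.list(unclass(params))
  gt <- glucose * consts$kappa
  gh <- glucose / consts$g_ref
  with(p, c(
    k1 * gt / (1 + x[1] / k1_i) - k2 * x[1] * x[2] + k3 * x[3] - k6 * x[1],
    k4 - k2 * x[1] * x[2] + k3 * x[3] - k7 * x[2],
    k2 * x[1] * x[2] - (k3 + k5) * x[3],
    k8 * x[2] - k9 * x[4] * (consts$S_tot - x[5]) + k10 * x[5],
    k9 * x[4] * (consts$S_tot - x[5]) - k10 * x[5],
    k11_c1 * x[5] * (consts$A_tot - x[6]) / (k11_m1 + consts$A_tot - x[6]) -
      k11_c2 * x[6] / (k11_m2 + x[6]) - k12 * x[6] * gh / (k12_i + gh),
    k13_c1 * x[6] * (consts$T_tot - x[7]) / (k13_m1 + consts$T_tot - x[7]) -
      k13_c2 * x[7] / (k13_m2 + x[7]),
    k14 * (consts$R_tot - x[8]) - k15 * x[8] * x[7] / (k15_i + x[7]),
    k17_c1 * x[8] * (consts$M_tot - x[9]) / (k17_m1 + consts$M_tot - x[9]) -
      k17_c2 * x[9] / (k17_m2 + x[9]) -
      k18_c * x[6] * x[9] / (k18_m + x[9]) - k16 * x[9]))
}

## a random valid molecular state
random_state <- function(consts = network_constants()) {
  pools <- c(100, 100, 100, 100, consts$S_tot, consts$A_tot, consts$T_tot,
             consts$R_tot, consts$M_tot)
  runif(9) * pools
}

## hand-built world for agent-level tests: agents at given positions with
## given phenotypes on an n_side lattice with a fixed glucose matrix
make_world <- function(n_side, pos, phen, glucose_values, t_div = 24L,
                       clock = NULL) {
  n <- nrow(pos)
  occ <- matrix(FALSE, n_side, n_side)
  occ[pos] <- TRUE
  agents <- structure(
    list(row = as.integer(pos[, 1]), col = as.integer(pos[, 2]),
         phenotype = phen,
         clock = if (is.null(clock)) rep(0L, n) else as.integer(clock),
         mol = matrix(0, n, 9)),
    class = "gs_agents")
  structure(list(n_side = as.integer(n_side), agents = agents,
                 occupancy = occ,
                 glucose = glucose_field(glucose_values),
                 step = 0L, t_div = as.integer(t_div),
                 thresholds = structure(list(theta_A = 1, theta_M = 1),
                                        class = "gs_thresholds")),
            class = "gs_world")
}

## brute-force count of lattice points in the closed disc of given radius
disc_count <- function(radius) {
  n <- 0L
  for (i in -radius:radius)
    for (j in -radius:radius)
      if (i * i + j * j <= radius * radius) n <- n + 1L
  n
}
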