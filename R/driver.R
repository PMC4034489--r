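## Simulation driver: couples the molecular, cellular and microenvironment
## layers per macro step and runs a simulation to termination.

#' Simulation configuration
#'
#' One macro step represents one hour (3600 s) of molecular and diffusion
#' time; a migrating cell moves one site (15 um) per step, a glioma-typical
#' speed. Division is delayed by `t_div` macro steps. Glucose consumption is
#' referenced to a nutrient reservoir column above the cell monolayer
#' (petri-dish-like geometry): `uptake_scale` is the ratio of cell height to
#' medium depth (15 um / 3 mm = 0.005 by default) and multiplies the
#' consumption time passed to [consume()].
#'
#' @param glucose0 Initial glucose level (g/L).
#' @param glucose_mode `"constant"` or `"random"` initial field.
#' @param n_side Lattice side (sites).
#' @param radius Seed disc radius (sites).
#' @param params Reaction parameters.
#' @param consts Network constants.
#' @param diffusion A [diffusion_config()].
#' @param thresholds Phenotype thresholds; calibrated from the baseline
#'   parameter set when NULL. Perturbed runs must pass the baseline
#'   thresholds explicitly so the phenotype criterion stays fixed.
#' @param max_steps Step cap for degenerate configurations.
#' @param seed Integer seed; fully determines the trajectory.
#' @param dt_macro Macro step duration (s).
#' @param t_div Division delay (macro steps).
#' @param uptake_scale Dimensionless consumption dilution (cell height over
#'   medium depth).
#' @return List of class `gs_config`.
#' @export
simulation_config <- function(glucose0 = 4.5, glucose_mode = "constant",
                              n_side = 200L, radius = 16L,
                              params = reaction_parameters(),
                              consts = network_constants(),
                              diffusion = diffusion_config(),
                              thresholds = NULL,
                              max_steps = 5000L, seed = 1L,
                              dt_macro = 3600, t_div = 24L,
                              uptake_scale = 0.005) {
  if (!is.finite(glucose0) || glucose0 < 0) stop("glucose0 must be >= 0")
  if (max_steps <= 0) stop("max_steps must be > 0")
  structure(list(glucose0 = glucose0, glucose_mode = glucose_mode,
                 n_side = as.integer(n_side), radius = as.integer(radius),
                 params = params, consts = consts, diffusion = diffusion,
                 thresholds = thresholds, max_steps = as.integer(max_steps),
                 seed = as.integer(seed), dt_macro = dt_macro,
                 t_div = as.integer(t_div), uptake_scale = uptake_scale),
            class = "gs_config")
}

#' Build the initial world for a configuration
#'
#' Seeds the circular tumour, initializes the glucose field, sets every
#' seeded cell's molecular state to the steady state at its local glucose
#' (avoiding start-up transients in the time-to-boundary endpoint), decides
#' initial phenotypes, and starts division clocks at the division delay.
#'
#' @param config A [simulation_config()].
#' @return World state of class `gs_world`.
#' @export
init_world <- function(config) {
  field <- init_field(config$glucose_mode, config$glucose0,
                      c(config$n_side, config$n_side),
                      seed = config$seed, dx = config$diffusion$dx)
  seeded <- seed_tumour(config$n_side, config$radius)
  agents <- seeded$agents
  thr <- config$thresholds
  if (is.null(thr)) thr <- calibrate_thresholds(config$params, config$consts)
  g_local <- field$values[cbind(agents$row, agents$col)]
  ## steady states are expensive; compute once per distinct glucose value
  ug <- unique(g_local)
  ss <- vapply(ug, function(g) steady_state(g, config$params, config$consts),
               numeric(9))
  agents$mol <- t(ss)[match(g_local, ug), , drop = FALSE]
  colnames(agents$mol) <- .gs_species
  agents$phenotype <- decide_phenotypes(agents$mol[, 6], agents$mol[, 9], thr)
  agents$clock <- rep(config$t_div, length(agents$row))
  structure(list(n_side = config$n_side, agents = agents,
                 occupancy = seeded$occupancy, glucose = field,
                 step = 0L, t_div = config$t_div, thresholds = thr),
            class = "gs_world")
}

#' Advance the coupled model by one macro step
#'
#' In order: each cell reads its site's glucose and integrates its
#' molecular network over the macro step (stiff implicit path); phenotypes
#' are re-decided from AMPK and mTORC1; consumption is applied; diffusion
#' substeps cover the macro step; agents act in a freshly shuffled order
#' (preventing directional artefacts); the step counter increments.
#' Daughters placed during the action phase act from the next step on.
#'
#' @param world A world state.
#' @param config The run's [simulation_config()].
#' @return The advanced world.
#' @export
sim_step <- function(world, config) {
  a <- world$agents
  n <- length(a$row)
  if (n > 0L) {
    g_local <- world$glucose$values[cbind(a$row, a$col)]
    a$mol <- advance_states(a$mol, g_local, config$params, config$consts,
                            dt = config$dt_macro)
    a$phenotype <- decide_phenotypes(a$mol[, 6], a$mol[, 9],
                                     world$thresholds)
    world$agents <- a
    world$glucose <- consume(world$glucose, a, config$params,
                             dt = config$dt_macro * config$uptake_scale)
  }
  n_sub <- ceiling(config$dt_macro / config$diffusion$dt_diff)
  world$glucose <- diffusion_step(world$glucose, world$occupancy,
                                  config$diffusion, n_steps = n_sub)
  if (n > 0L) {
    for (i in sample.int(n)) world <- act(world, i)
  }
  world$step <- world$step + 1L
  world
}

#' Run a complete simulation
#'
#' Iterates [sim_step()] from the seeded initial world until the first cell
#' reaches the lattice boundary (or the step cap). Records the four
#' cellular-scale endpoints: the number of macro steps executed (expansion
#' velocity measure), and the total, migrating and proliferating cell counts
#' in the final step (tumour volume and build-up measures).
#'
#' @param config A [simulation_config()].
#' @param keep_world Return the final world in attribute `"world"`?
#' @return List of class `gs_endpoints`: `M_time`, `M_total`, `M_mig`,
#'   `M_prolif`, `terminated_by` (`"boundary"` or `"cap"`).
#' @export
run_simulation <- function(config, keep_world = FALSE) {
  rs <- .save_rng()
  on.exit(.restore_rng(rs))
  set.seed(config$seed)
  world <- init_world(config)
  while (!boundary_reached(world) && world$step < config$max_steps) {
    world <- sim_step(world, config)
  }
  terminated <- if (boundary_reached(world)) "boundary" else "cap"
  phen <- world$agents$phenotype
  out <- structure(
    list(M_time = world$step,
         M_total = length(phen),
         M_mig = sum(phen == PHENOTYPE_MIGRATING),
         M_prolif = sum(phen == PHENOTYPE_PROLIFERATING),
         terminated_by = terminated),
    class = "gs_endpoints")
  if (keep_world) attr(out, "world") <- world
  out
}

#' Replicate seeds from a base seed
#'
#' Replicate `i` of a sweep cell uses seed `base + i`; a fixed documented
#' rule so that replicate runs are reproducible and distinct.
#'
#' @param base Base seed.
#' @param n Number of replicates.
#' @return Integer vector of seeds.
#' @export
replicate_seeds <- function(base, n) as.integer(base) + seq_len(n)

#' Simulator engine backed by the full agent-based model
#'
#' Wraps [run_simulation()] in the engine interface used by [run_lsa()]:
#' a function of a named perturbation vector (factors by parameter name),
#' an initial glucose level and a seed, returning the four endpoints.
#' Thresholds are calibrated once from the template's baseline parameters
#' and reused for every perturbed run.
#'
#' @param config_template A [simulation_config()] providing grid size,
#'   baseline parameters and numerics.
#' @return Function `(perturbations, glucose0, seed) -> gs_endpoints`.
#' @export
abm_engine <- function(config_template = simulation_config()) {
  thr <- config_template$thresholds
  if (is.null(thr))
    thr <- calibrate_thresholds(config_template$params,
                                config_template$consts)
  function(perturbations, glucose0, seed) {
    cfg <- config_template
    cfg$thresholds <- thr
    cfg$glucose0 <- glucose0
    cfg$seed <- as.integer(seed)
    if (!is.null(perturbations) && length(perturbations)) {
      for (nm in names(perturbations))
        cfg$params <- scale_parameter(cfg$params, nm, perturbations[[nm]])
    }
    run_simulation(cfg)
  }
}
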