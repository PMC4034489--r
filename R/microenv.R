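## Glucose field on the lattice: initialization, occupancy-modulated
## diffusion with reflecting boundaries, and consumption by tumour cells.

#' Glucose field constructor
#'
#' @param values Numeric matrix of glucose concentrations (g/L), one value
#'   per grid point.
#' @param dx Grid spacing (m).
#' @return Object of class `gs_field`.
#' @export
glucose_field <- function(values, dx = 1.5e-5) {
  if (!is.matrix(values) || any(values < 0) || any(!is.finite(values)))
    stop("field values must be a non-negative finite matrix")
  if (!is.finite(dx) || dx <= 0) stop("dx must be > 0")
  structure(list(values = values, dx = dx), class = "gs_field")
}

#' Diffusion configuration
#'
#' Explicit forward-time centred-space diffusion of glucose with an
#' occupancy slow-down factor. Stability requires
#' `dt_diff <= dx^2 / (4 D)`; the default substep is 90% of that bound.
#'
#' @param D Effective glucose diffusion coefficient (m^2/s). The default
#'   relaxes the field over roughly two cell diameters per one-hour macro
#'   step (`D * 3600 / dx^2` of order 1), the regime in which consumption
#'   maintains chemotactic gradients on the scale the agent rules read. A
#'   physically aqueous diffusivity would flatten the closed-dish field
#'   almost completely within one macro step and leave no usable gradient.
#' @param dx Grid spacing (m); 1.5e-5 m matches the average cell diameter.
#' @param alpha_occ Dimensionless factor in (0, 1] slowing diffusive
#'   exchange through occupied sites (diffusion is slower through
#'   cell-packed regions); applied as a harmonic-mean interface diffusivity
#'   so that every site-pair flux is antisymmetric.
#' @param dt_diff Diffusion substep (s); defaults to 0.9 * dx^2 / (4 D).
#' @return List of class `gs_diffusion`.
#' @export
diffusion_config <- function(D = 1.3e-13, dx = 1.5e-5, alpha_occ = 0.5,
                             dt_diff = NULL) {
  if (!is.finite(D) || D <= 0) stop("D must be > 0")
  if (!is.finite(alpha_occ) || alpha_occ <= 0 || alpha_occ > 1)
    stop("alpha_occ must be in (0, 1]")
  bound <- dx^2 / (4 * D)
  if (is.null(dt_diff)) dt_diff <- 0.9 * bound
  if (dt_diff > bound)
    stop("unstable diffusion substep: dt_diff = ", format(dt_diff),
         " exceeds dx^2/(4D) = ", format(bound))
  structure(list(D = D, dx = dx, alpha_occ = alpha_occ, dt_diff = dt_diff),
            class = "gs_diffusion")
}

#' Initialize the glucose field
#'
#' Constant mode fills the grid uniformly at `level`; random mode draws
#' i.i.d. uniform values on `[0, 2 * level]` (mean `level`) using `seed`.
#'
#' @param mode `"constant"` or `"random"`.
#' @param level Mean glucose concentration (g/L), >= 0.
#' @param shape Integer vector of length 2, the grid shape.
#' @param seed Integer seed for random mode.
#' @param dx Grid spacing (m).
#' @return A [glucose_field()].
#' @export
init_field <- function(mode = c("constant", "random"), level, shape,
                       seed = 1L, dx = 1.5e-5) {
  mode <- match.arg(mode)
  if (!is.finite(level) || level < 0) stop("glucose level must be >= 0")
  if (length(shape) == 1L) shape <- c(shape, shape)
  if (mode == "constant") {
    vals <- matrix(level, shape[1], shape[2])
  } else {
    rs <- .save_rng()
    on.exit(.restore_rng(rs))
    set.seed(seed)
    vals <- matrix(stats::runif(prod(shape), 0, 2 * level),
                   shape[1], shape[2])
  }
  glucose_field(vals, dx)
}

#' One explicit diffusion step
#'
#' Forward-time centred-space update of the glucose field in conservative
#' (finite-volume) form: the flux across each site pair is damped by the
#' harmonic mean of the two sites' occupancy factors, and boundary faces
#' carry no flux (reflecting boundaries). Because every interior flux is
#' antisymmetric, total glucose mass is conserved exactly for any occupancy
#' pattern; a site-wise damping of the whole update would instead create
#' spurious sources around occupied regions strong enough to invert the
#' chemotactic gradient over the thousands of substeps of a macro step.
#'
#' @param field A [glucose_field()].
#' @param occupancy Logical matrix marking occupied sites.
#' @param cfg A [diffusion_config()]; its `dx` is ignored in favour of the
#'   field's own spacing.
#' @param n_steps Number of substeps to apply (default 1).
#' @return The updated field.
#' @export
diffusion_step <- function(field, occupancy, cfg, n_steps = 1L) {
  stopifnot(inherits(field, "gs_field"), inherits(cfg, "gs_diffusion"))
  if (!identical(dim(occupancy), dim(field$values)))
    stop("occupancy shape must equal the field shape")
  bound <- field$dx^2 / (4 * cfg$D)
  if (cfg$dt_diff > bound)
    stop("unstable diffusion substep: dt_diff = ", format(cfg$dt_diff),
         " exceeds dx^2/(4D) = ", format(bound))
  field$values <- gs_diffuse_cpp(field$values, occupancy, cfg$D,
                                 cfg$alpha_occ, field$dx, cfg$dt_diff,
                                 as.integer(n_steps))
  field
}

#' Glucose consumption by tumour cells
#'
#' Each occupied site loses `0.18016 * r * weight * dt` g/L, clamped at
#' zero, where 0.18016 g/mmol converts the molar uptake rate `r` to mass
#' concentration and the dimensionless weight partitions consumption by
#' phenotype: `C1` for proliferating cells and `C2` for migrating and
#' quiescent cells (proliferation is the energetically expensive programme).
#'
#' @param field A [glucose_field()].
#' @param agents Agent set (see [seed_tumour()]) with positions and
#'   phenotypes.
#' @param params Reaction parameters supplying `r`, `C1`, `C2`.
#' @param dt Consumption time (s), > 0.
#' @return The updated field.
#' @export
consume <- function(field, agents, params = reaction_parameters(), dt) {
  stopifnot(inherits(field, "gs_field"))
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  n <- length(agents$row)
  if (n == 0L) return(field)
  weight <- ifelse(agents$phenotype == PHENOTYPE_PROLIFERATING,
                   params[["C1"]], params[["C2"]])
  demand <- params[["r"]] * 0.18016 * weight * dt
  idx <- cbind(agents$row, agents$col)
  field$values[idx] <- pmax(0, field$values[idx] - demand)
  field
}

#' Total glucose mass on the grid
#'
#' @param field A [glucose_field()].
#' @return Sum of all site concentrations (g/L summed over sites).
#' @export
field_mass <- function(field) sum(field$values)

## save/restore the session RNG state so seeded helpers do not disturb the
## caller's random stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}
.restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
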