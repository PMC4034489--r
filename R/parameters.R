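## Reaction parameters of the intracellular interaction network.
##
## 34 named constants: 31 perturbable reaction constants of the nine-species
## ODE system plus the glucose consumption rate r and the two dimensionless
## consumption weights C1, C2 (which the sensitivity sweep never perturbs).

.gs_param_names <- c(
  "k1", "k1_i", "k2", "k3", "k4", "k5", "k6", "k7", "k8", "k9", "k10",
  "k11_m1", "k11_c1", "k11_m2", "k11_c2", "k12_i", "k12",
  "k13_m1", "k13_c1", "k13_m2", "k13_c2", "k14", "k15_i", "k15", "k16",
  "k17_m1", "k17_c1", "k17_m2", "k17_c2", "k18_m", "k18_c",
  "r", "C1", "C2")

.gs_param_values <- c(
  k1 = 1.2e-9, k1_i = 1, k2 = 3e-2, k3 = 3e1, k4 = 1.4583e-2, k5 = 3.6e2,
  k6 = 1.0467e-2, k7 = 5.626e-3, k8 = 6.4167e-3, k9 = 6e-2, k10 = 3.6e2,
  k11_m1 = 5e2, k11_c1 = 1.8e5, k11_m2 = 5e2, k11_c2 = 1.8e6,
  k12_i = 6e-1, k12 = 6e2,
  k13_m1 = 1e2, k13_c1 = 6e2, k13_m2 = 1e2, k13_c2 = 6e4,
  k14 = 3.6e2, k15_i = 5, k15 = 3.6e2, k16 = 3.6e2,
  k17_m1 = 1e2, k17_c1 = 3.6e3, k17_m2 = 1e2, k17_c2 = 3.6e5,
  k18_m = 1.5104e3, k18_c = 4.86e3,
  r = 1.17e-2, C1 = 8.571e-1, C2 = 1.429e-1)

#' Names of the perturbable reaction parameters
#'
#' The 31 reaction constants of the molecular network that the sensitivity
#' sweep multiplies by scaling factors. The consumption rate `r` and the
#' consumption weights `C1`, `C2` are excluded.
#'
#' @return Character vector of length 31.
#' @export
perturbable_parameters <- function() {
  .gs_param_names[seq_len(31)]
}

#' Baseline reaction parameters
#'
#' Returns the full named set of reaction constants of the intracellular
#' miR-451/AMPK/mTORC1 network, the glucose consumption rate `r`
#' (mmol L^-1 s^-1) and the dimensionless consumption weights `C1`, `C2`.
#' Individual values can be overridden by name.
#'
#' @param ... Named overrides, e.g. `reaction_parameters(k2 = 0.06)`.
#' @return Named numeric vector of class `gs_params` with 34 entries.
#' @examples
#' p <- reaction_parameters()
#' p[["k4"]]
#' @export
reaction_parameters <- function(...) {
  p <- .gs_param_values
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("overrides must be named")
    bad <- setdiff(names(dots), .gs_param_names)
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- unlist(dots)
  }
  validate_params(structure(p, class = "gs_params"))
}

#' Validate a reaction-parameter set
#'
#' Checks completeness (all 34 names, no extras), strict positivity, and the
#' partition constraint C1 + C2 = 1 (within 1e-3).
#'
#' @param params Named numeric vector as returned by [reaction_parameters()].
#' @return `params`, invisibly classed as `gs_params`.
#' @export
validate_params <- function(params) {
  nm <- names(params)
  missing <- setdiff(.gs_param_names, nm)
  extra <- setdiff(nm, .gs_param_names)
  if (length(missing) || length(extra))
    stop("parameter set mismatch; missing: [",
         paste(missing, collapse = ", "), "]; extra: [",
         paste(extra, collapse = ", "), "]")
  if (any(!is.finite(params)) || any(params <= 0))
    stop("all reaction parameters must be finite and > 0; offending: ",
         paste(nm[!is.finite(params) | params <= 0], collapse = ", "))
  if (abs(params[["C1"]] + params[["C2"]] - 1) > 1e-3)
    stop("C1 + C2 must equal 1 within 1e-3 (got ",
         format(params[["C1"]] + params[["C2"]]), ")")
  p <- params[.gs_param_names]
  class(p) <- "gs_params"
  invisible(p)
}

#' Multiply one reaction parameter by a scaling factor
#'
#' @param params A `gs_params` vector.
#' @param name Parameter name, one of the 31 perturbable constants.
#' @param factor Positive multiplicative factor.
#' @return Modified `gs_params` vector.
#' @export
scale_parameter <- function(params, name, factor) {
  if (!name %in% perturbable_parameters())
    stop("'", name, "' is not a perturbable reaction parameter")
  if (!is.finite(factor) || factor <= 0)
    stop("factor must be finite and > 0")
  params[[name]] <- params[[name]] * factor
  validate_params(params)
}

#' Conserved pools and unit conversions of the molecular network
#'
#' Houses the conserved protein pool totals (pmol L^-1) of the
#' phosphorylation cycles, the glucose mass-to-molar conversion `kappa`
#' (pmol per g, from the 180.16 g/mol molar mass of glucose) and the glucose
#' normalisation `g_ref` (g L^-1) used by the dimensionless glucose input of
#' the AMPK equation.
#'
#' @param A_tot,T_tot,R_tot,M_tot Total AMPK, TSC2, Rheb and mTORC1 pools
#'   (pmol L^-1).
#' @param S_tot Total LKB1-STRAD scaffold pool (pmol L^-1).
#' @param kappa Glucose conversion, pmol per g.
#' @param g_ref Glucose normalisation, g L^-1.
#' @return List of class `gs_consts`.
#' @export
network_constants <- function(A_tot = 1e3, T_tot = 1e3, R_tot = 1e3,
                              M_tot = 1e3, S_tot = 5e2,
                              kappa = 5.551e9, g_ref = 4.5) {
  x <- list(A_tot = A_tot, T_tot = T_tot, R_tot = R_tot, M_tot = M_tot,
            S_tot = S_tot, kappa = kappa, g_ref = g_ref)
  if (any(!vapply(x, function(v) is.finite(v) && v > 0, logical(1))))
    stop("all network constants must be finite and > 0")
  structure(x, class = "gs_consts")
}

#' Load the packaged reaction-parameter fixture
#'
#' Reads the plain-text key/value table of all 34 reaction constants shipped
#' with the package, checks it against the expected name set, and returns a
#' validated parameter vector. Exactly 31 entries are flagged perturbable.
#'
#' @param path Path to a parameter table; defaults to the packaged fixture.
#' @return `gs_params` vector with attribute `perturbable` (character names).
#' @export
load_parameters <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reaction_parameters.tsv",
                        package = "glioscale", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("name", "value", "unit", "perturbable")
  if (!all(need %in% names(tab)))
    stop("parameter fixture must have columns: ", paste(need, collapse = ", "))
  missing <- setdiff(.gs_param_names, tab$name)
  extra <- setdiff(tab$name, .gs_param_names)
  if (length(missing) || length(extra))
    stop("parameter fixture key mismatch; missing: [",
         paste(missing, collapse = ", "), "]; extra: [",
         paste(extra, collapse = ", "), "]")
  p <- stats::setNames(tab$value, tab$name)[.gs_param_names]
  p <- validate_params(structure(p, class = "gs_params"))
  pert <- tab$name[tab$perturbable]
  if (length(pert) != 31L)
    stop("expected exactly 31 perturbable parameters, found ", length(pert))
  attr(p, "perturbable") <- pert
  p
}

## internal: parameters + constants as plain numeric vectors for the C++ side
.pack_params <- function(params) as.numeric(params[.gs_param_names])
.pack_consts <- function(consts) {
  as.numeric(c(consts$A_tot, consts$T_tot, consts$R_tot, consts$M_tot,
               consts$S_tot, consts$kappa, consts$g_ref))
}
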