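## Log-linear surrogate endpoint generator: emulates the simulator's
## input -> endpoint statistical structure (smooth monotone response to
## log-scaled parameter changes, multiplicative replicate noise) so the
## sensitivity pipeline is testable in seconds.

#' Surrogate specification
#'
#' The surrogate responds log-linearly to parameter scalings: endpoint
#' `e` under perturbations \eqn{(p_i, b_i)} is
#' `baseline_e(glucose) * exp(sum_i w_e(p_i) * log(b_i))` times a
#' multiplicative lognormal replicate noise `exp(sigma * z)`. This is the
#' simplest structure exhibiting the monotone, factor-scale behaviour the
#' sensitivity coefficients presuppose; it makes no claim to match the
#' simulator quantitatively.
#'
#' @param weights Numeric matrix of log-response weights, one row per
#'   parameter (rownames = parameter names), columns `M_time`, `M_total`,
#'   `M_mig`, `M_prolif`.
#' @param baselines Data frame with column `glucose0` and one positive
#'   column per endpoint.
#' @param sigma Replicate noise scale (>= 0).
#' @param seed Integer seed of the surrogate's noise stream.
#' @return List of class `gs_surrogate`.
#' @export
surrogate_spec <- function(weights, baselines, sigma = 0, seed = 1L) {
  if (!is.matrix(weights) || is.null(rownames(weights)))
    stop("weights must be a matrix with parameter rownames")
  if (!identical(colnames(weights), .gs_endpoint_names))
    stop("weights columns must be ",
         paste(.gs_endpoint_names, collapse = ", "))
  need <- c("glucose0", .gs_endpoint_names)
  if (!all(need %in% names(baselines)))
    stop("baselines must have columns ", paste(need, collapse = ", "))
  if (any(as.matrix(baselines[.gs_endpoint_names]) <= 0))
    stop("baseline endpoints must be > 0")
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(weights = weights, baselines = baselines,
                 sigma = sigma, seed = as.integer(seed)),
            class = "gs_surrogate")
}

#' A ready-made surrogate with a planted dominant parameter
#'
#' Weights increase mildly along the parameter list so the induced
#' sensitivity ranking is known, and `dominant` carries a much larger
#' weight on every endpoint, so the pipeline must rank it first. Baselines
#' reflect the qualitative behaviour of the simulator: low-glucose tumours
#' reach the boundary fast with few cells, high-glucose tumours slowly with
#' many.
#'
#' @param params Parameter names covered by the surrogate.
#' @param dominant Name of the dominant parameter (weight 1.5 vs <= 0.45).
#' @param sigma Replicate noise scale.
#' @param seed Noise stream seed.
#' @return A [surrogate_spec()].
#' @export
default_surrogate_spec <- function(params = perturbable_parameters(),
                                   dominant = "k4", sigma = 0, seed = 1L) {
  if (!dominant %in% params) stop("dominant must be one of params")
  n <- length(params)
  w <- 0.05 + 0.4 * (seq_len(n) - 1) / max(1, n - 1)
  weights <- cbind(M_time = 0.8 * w, M_total = w, M_mig = 1.1 * w,
                   M_prolif = 0.9 * w)
  rownames(weights) <- params
  weights[dominant, ] <- 1.5
  baselines <- data.frame(
    glucose0 = c(0.3, 1.125, 2.25, 4.5),
    M_time   = c(40, 160, 360, 640),
    M_total  = c(1200, 8000, 20000, 36000),
    M_mig    = c(800, 2400, 3000, 2000),
    M_prolif = c(100, 2400, 8000, 20000))
  surrogate_spec(weights, baselines, sigma = sigma, seed = seed)
}

## deterministic 31-bit hash of the run identity, so each (seed, replicate,
## perturbation, glucose) cell has its own reproducible noise draw
.surrogate_hash <- function(spec, perturbations, glucose0, replicate_index) {
  pert_key <- if (length(perturbations))
    paste(names(perturbations), format(perturbations, digits = 15),
          collapse = ";")
  else ""
  key <- paste(spec$seed, replicate_index,
               format(glucose0, digits = 15), pert_key, sep = "|")
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483629
  as.integer(h)
}

#' Generate one surrogate simulation outcome
#'
#' @param perturbations Named numeric vector of scaling factors by
#'   parameter name (NULL or empty for the baseline run). All factors must
#'   be > 0; unknown parameter names are an error.
#' @param glucose0 Initial glucose level; must appear in the spec's
#'   baseline table.
#' @param spec A [surrogate_spec()].
#' @param replicate_index Integer replicate label; together with the spec's
#'   seed it fully determines the noise draw.
#' @return List of class `gs_endpoints` with the four (integer-rounded)
#'   endpoints and `terminated_by = "boundary"`.
#' @export
surrogate_run <- function(perturbations, glucose0, spec,
                          replicate_index = 1L) {
  stopifnot(inherits(spec, "gs_surrogate"))
  row <- which(spec$baselines$glucose0 == glucose0)
  if (length(row) != 1L)
    stop("no surrogate baseline for glucose level ", glucose0)
  m <- unlist(spec$baselines[row, .gs_endpoint_names])
  if (!is.null(perturbations) && length(perturbations)) {
    unknown <- setdiff(names(perturbations), rownames(spec$weights))
    if (length(unknown))
      stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
    if (any(perturbations <= 0)) stop("factors must be > 0")
    shift <- colSums(spec$weights[names(perturbations), , drop = FALSE] *
                       log(perturbations))
    m <- m * exp(shift)
  }
  if (spec$sigma > 0) {
    rs <- .save_rng()
    on.exit(.restore_rng(rs))
    set.seed(.surrogate_hash(spec, perturbations, glucose0,
                             replicate_index))
    m <- m * exp(spec$sigma * stats::rnorm(4))
  }
  m <- round(m)
  ## counts of migrating/proliferating cells cannot exceed the total
  m[["M_mig"]] <- min(m[["M_mig"]], m[["M_total"]])
  m[["M_prolif"]] <- min(m[["M_prolif"]], m[["M_total"]] - m[["M_mig"]])
  structure(list(M_time = m[["M_time"]], M_total = m[["M_total"]],
                 M_mig = m[["M_mig"]], M_prolif = m[["M_prolif"]],
                 terminated_by = "boundary"),
            class = "gs_endpoints")
}

#' Surrogate engine for the sweep
#'
#' Adapts [surrogate_run()] to the engine interface of [run_lsa()]; the
#' engine's `seed` argument is used as the replicate index of the noise
#' stream.
#'
#' @param spec A [surrogate_spec()].
#' @return Function `(perturbations, glucose0, seed) -> gs_endpoints`.
#' @export
surrogate_engine <- function(spec) {
  function(perturbations, glucose0, seed) {
    surrogate_run(perturbations, glucose0, spec, replicate_index = seed)
  }
}
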