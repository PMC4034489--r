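## Multiscale sensitivity pipeline: one-at-a-time parameter sweep,
## normalised sensitivity coefficients, relative endpoint changes,
## max-|S| summaries, Factor+/Factor- selection, combined-pair enumeration
## and screening.

.gs_endpoint_names <- c("M_time", "M_total", "M_mig", "M_prolif")

#' The default scaling-factor list of the sweep
#'
#' Twenty multiplicative factors spanning 0.01 to 100, symmetric around 1 in
#' the near-1 range (the factor 1 itself is excluded: a coefficient against
#' an unchanged parameter is undefined).
#'
#' @return Numeric vector of length 20.
#' @export
lsa_factors <- function() {
  c(0.01, 0.1, 0.5, 0.8, 0.9, 0.95, 0.98, 0.99, 1.01, 1.02, 1.05, 1.1,
    1.2, 1.5, 1.9, 1.99, 5, 10, 50, 100)
}

#' The default initial glucose levels of the sweep (g/L)
#'
#' @return Numeric vector `c(0.3, 1.125, 2.25, 4.5)`.
#' @export
default_glucose_levels <- function() c(0.3, 1.125, 2.25, 4.5)

#' Enumerate the one-at-a-time sweep design
#'
#' The full cross of perturbable parameters, scaling factors and initial
#' glucose levels; with the defaults, 31 x 20 x 4 = 2480 settings.
#'
#' @param params Character vector of parameter names.
#' @param factors Numeric vector of scaling factors (1 excluded).
#' @param glucose_levels Numeric vector of initial glucose levels.
#' @return Data frame with columns `param`, `factor`, `glucose0`.
#' @export
lsa_design <- function(params = perturbable_parameters(),
                       factors = lsa_factors(),
                       glucose_levels = default_glucose_levels()) {
  if (any(factors == 1)) stop("the factor 1 is not part of the design")
  expand.grid(param = params, factor = factors, glucose0 = glucose_levels,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Normalised sensitivity coefficient
#'
#' The relative endpoint change divided by the relative parameter change
#' for a parameter multiplied by factor `b`:
#' `S = (M_pert / M_base - 1) / (b - 1)`.
#'
#' @param M_pert Endpoint value under the perturbed parameter.
#' @param M_base Baseline endpoint value (> 0).
#' @param b Scaling factor (> 0, != 1).
#' @return Dimensionless coefficient (vectorised).
#' @export
sensitivity_coefficient <- function(M_pert, M_base, b) {
  if (any(b == 1)) stop("sensitivity coefficient undefined for factor b = 1")
  if (any(b <= 0)) stop("factor b must be > 0")
  if (any(M_base == 0)) stop("baseline endpoint is 0; coefficient undefined")
  (M_pert / M_base - 1) / (b - 1)
}

#' Relative endpoint change
#'
#' `delta_M = M_pert / M_base - 1`; a value `a` translates back into
#' `M_pert = (a + 1) * M_base`.
#'
#' @param M_pert Perturbed endpoint value.
#' @param M_base Baseline endpoint value (> 0).
#' @return Dimensionless relative change (vectorised).
#' @export
delta_M <- function(M_pert, M_base) {
  if (any(M_base == 0)) stop("baseline endpoint is 0; delta undefined")
  M_pert / M_base - 1
}

.endpoints_vec <- function(e) {
  unlist(e[.gs_endpoint_names])
}

#' Run the one-at-a-time sensitivity sweep
#'
#' For every (parameter, factor, glucose) cell, runs `replicates`
#' simulations with the single parameter multiplied by the factor, averages
#' the four endpoints over replicates, and computes the four sensitivity
#' coefficients and the relative changes of the time and total-count
#' endpoints against the baseline mean for that glucose level. One baseline
#' mean per glucose level is computed from the same number of replicates
#' and shared across all parameters. Replicate seeds follow
#' [replicate_seeds()]. A failing simulator call flags the record
#' (`ok = FALSE`) instead of dropping it; an endpoint with zero baseline
#' yields NA coefficients for that endpoint only.
#'
#' @param sim Engine: function `(perturbations, glucose0, seed)` returning
#'   a list with `M_time`, `M_total`, `M_mig`, `M_prolif` (see
#'   [abm_engine()], [surrogate_engine()]).
#' @param params Character vector of parameters to perturb.
#' @param factors Scaling factors (1 excluded).
#' @param glucose_levels Initial glucose levels (g/L).
#' @param replicates Replicate runs per cell.
#' @param base_seed Base seed for [replicate_seeds()].
#' @return Data frame of class `gs_lsa`, one row per design cell, with the
#'   replicate-mean endpoints, `S_*` coefficients, `dM_time`, `dM_total`
#'   and an `ok` flag. The per-level baseline means are stored in the
#'   `"baselines"` attribute.
#' @export
run_lsa <- function(sim, params = perturbable_parameters(),
                    factors = lsa_factors(),
                    glucose_levels = default_glucose_levels(),
                    replicates = 3L, base_seed = 1L) {
  if (any(factors == 1)) stop("the factor 1 is not part of the design")
  if (replicates < 1L) stop("replicates must be >= 1")
  seeds <- replicate_seeds(base_seed, replicates)
  mean_endpoints <- function(perturb, g) {
    vals <- vapply(seeds,
                   function(s) .endpoints_vec(sim(perturb, g, s)),
                   numeric(4))
    rowMeans(vals)
  }
  base <- lapply(glucose_levels, function(g) mean_endpoints(NULL, g))
  names(base) <- as.character(glucose_levels)
  design <- lsa_design(params, factors, glucose_levels)
  n <- nrow(design)
  M <- matrix(NA_real_, n, 4,
              dimnames = list(NULL, .gs_endpoint_names))
  S <- matrix(NA_real_, n, 4,
              dimnames = list(NULL, paste0("S_", c("time", "total", "mig",
                                                   "prolif"))))
  dM <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("dM_time",
                                                       "dM_total")))
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    g <- design$glucose0[i]
    perturb <- stats::setNames(design$factor[i], design$param[i])
    m <- tryCatch(mean_endpoints(perturb, g), error = function(e) NULL)
    if (is.null(m)) {
      ok[i] <- FALSE
      next
    }
    M[i, ] <- m
    b0 <- base[[as.character(g)]]
    pos <- b0 > 0
    S[i, pos] <- sensitivity_coefficient(m[pos], b0[pos],
                                         design$factor[i])
    if (b0[["M_time"]] > 0)
      dM[i, "dM_time"] <- delta_M(m[["M_time"]], b0[["M_time"]])
    if (b0[["M_total"]] > 0)
      dM[i, "dM_total"] <- delta_M(m[["M_total"]], b0[["M_total"]])
  }
  out <- cbind(design, reps = replicates, as.data.frame(M),
               as.data.frame(S), as.data.frame(dM), ok = ok)
  attr(out, "baselines") <- base
  class(out) <- c("gs_lsa", "data.frame")
  out
}

#' Maximal absolute sensitivity coefficients per parameter
#'
#' For each parameter and endpoint, the maximum of |S| over all factors and
#' glucose levels, together with the glucose level at which the maximum is
#' attained.
#'
#' @param records A `gs_lsa` sweep (or compatible data frame).
#' @return Data frame with one row per parameter and columns `m_<e>` and
#'   `g_<e>` for each endpoint e in time, total, mig, prolif.
#' @export
summarize_max <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stop("no sweep records to summarize")
  eps <- c("time", "total", "mig", "prolif")
  params <- unique(records$param)
  rows <- lapply(params, function(p) {
    sub <- records[records$param == p & records$ok, , drop = FALSE]
    if (nrow(sub) == 0L)
      stop("no successful records for parameter ", p)
    out <- list(param = p)
    for (e in eps) {
      s <- abs(sub[[paste0("S_", e)]])
      j <- which.max(s)
      out[[paste0("m_", e)]] <- s[j]
      out[[paste0("g_", e)]] <- sub$glucose0[j]
    }
    as.data.frame(out)
  })
  do.call(rbind, rows)
}

#' Select the Factor+ and Factor- scaling groups
#'
#' Factor+ collects (parameter, factor) settings whose perturbation strongly
#' slowed tumour expansion at low glucose; Factor- those that strongly
#' reduced the final cell count at high glucose. The default rules are
#' `dM_time > 9` at 0.3 g/L and `dM_total < -0.8` at 4.5 g/L.
#'
#' @param records A `gs_lsa` sweep.
#' @param plus_rule List `(endpoint, threshold, glucose)`; settings with
#'   `records[[endpoint]] > threshold` at that glucose join Factor+.
#' @param minus_rule List `(endpoint, threshold, glucose)`; settings with
#'   `records[[endpoint]] < threshold` at that glucose join Factor-.
#' @return Data frame of class `gs_factor_groups` with columns `param`,
#'   `group` (`"plus"`/`"minus"`), `factor`.
#' @export
select_groups <- function(records,
                          plus_rule = list(endpoint = "dM_time",
                                           threshold = 9, glucose = 0.3),
                          minus_rule = list(endpoint = "dM_total",
                                            threshold = -0.8,
                                            glucose = 4.5)) {
  for (rule in list(plus_rule, minus_rule)) {
    if (!any(records$glucose0 == rule$glucose))
      stop("sweep contains no records at glucose level ", rule$glucose)
  }
  pick <- function(rule, upper) {
    sub <- records[records$glucose0 == rule$glucose & records$ok, ,
                   drop = FALSE]
    v <- sub[[rule$endpoint]]
    keep <- if (upper) v > rule$threshold else v < rule$threshold
    keep[is.na(keep)] <- FALSE
    sub[keep, c("param", "factor")]
  }
  plus <- pick(plus_rule, upper = TRUE)
  minus <- pick(minus_rule, upper = FALSE)
  out <- rbind(
    if (nrow(plus)) cbind(plus[1], group = "plus", plus[2]),
    if (nrow(minus)) cbind(minus[1], group = "minus", minus[2]))
  if (is.null(out))
    out <- data.frame(param = character(), group = character(),
                      factor = numeric())
  out <- out[order(out$param, out$group, out$factor), ]
  rownames(out) <- NULL
  class(out) <- c("gs_factor_groups", "data.frame")
  out
}

#' Enumerate all combinable Factor+/Factor- pairs
#'
#' All pairs of one (parameter, factor) setting from the Factor+ group with
#' one from the Factor- group, excluding pairs that would scale the same
#' parameter twice, in deterministic lexicographic order.
#'
#' @param groups A `gs_factor_groups` table (from [select_groups()] or
#'   [load_factor_groups()]).
#' @return Data frame with columns `param1`, `factor1` (Factor+), `param2`,
#'   `factor2` (Factor-).
#' @export
enumerate_pairs <- function(groups) {
  plus <- groups[groups$group == "plus", c("param", "factor")]
  minus <- groups[groups$group == "minus", c("param", "factor")]
  if (nrow(plus) == 0L || nrow(minus) == 0L)
    return(data.frame(param1 = character(), factor1 = numeric(),
                      param2 = character(), factor2 = numeric()))
  out <- merge(stats::setNames(plus, c("param1", "factor1")),
               stats::setNames(minus, c("param2", "factor2")),
               by = NULL)
  out <- out[out$param1 != out$param2, ]
  out <- out[order(out$param1, out$factor1, out$param2, out$factor2), ]
  rownames(out) <- NULL
  out
}

#' Screen combined-pair runs for jointly beneficial perturbations
#'
#' Retains, per glucose level, the pairs whose combined perturbation slowed
#' expansion (`dM_time > margin`) while shrinking the final cell count
#' (`dM_total < -margin`). The margin excludes combinations that influence
#' the output only very slightly. Also reports the pairs retained at every
#' level of `levels`.
#'
#' @param records Data frame of pair-run results with columns `param1`,
#'   `factor1`, `param2`, `factor2`, `glucose0`, `dM_time`, `dM_total`.
#' @param margin Non-negative threshold margin.
#' @param levels Glucose levels for the "retained everywhere" report;
#'   defaults to all levels present in `records`.
#' @return List with `per_level` (the retained subset of `records`) and
#'   `all_levels` (pairs retained at every level of `levels`).
#' @export
screen_pairs <- function(records, margin = 0.01, levels = NULL) {
  if (margin < 0) stop("margin must be >= 0")
  if (is.null(levels)) levels <- sort(unique(records$glucose0))
  keep <- records$dM_time > margin & records$dM_total < -margin
  keep[is.na(keep)] <- FALSE
  retained <- records[keep, , drop = FALSE]
  rownames(retained) <- NULL
  key <- function(d) paste(d$param1, d$factor1, d$param2, d$factor2,
                           sep = "\r")
  everywhere <- Reduce(intersect, lapply(levels, function(g) {
    key(retained[retained$glucose0 == g, , drop = FALSE])
  }))
  all_levels <- unique(retained[key(retained) %in% everywhere,
                                c("param1", "factor1", "param2", "factor2")])
  all_levels <- all_levels[order(all_levels$param1, all_levels$factor1,
                                 all_levels$param2, all_levels$factor2), ]
  rownames(all_levels) <- NULL
  list(per_level = retained, all_levels = all_levels)
}
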