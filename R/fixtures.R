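## Packaged machine-readable transcriptions of the screening results of the
## full-scale sweep, their parsers/validators, and cross-checks.

#' Load the packaged Factor+/Factor- scaling groups
#'
#' The (parameter, factor) settings selected by the single-perturbation
#' screen: Factor+ settings strongly slowed expansion at low glucose,
#' Factor- settings strongly reduced the final cell count at high glucose.
#' The table covers 14 of the 31 perturbable parameters; 9 of them carry
#' entries in both groups.
#'
#' @param path Optional path to an alternative table.
#' @return `gs_factor_groups` data frame (columns `param`, `group`,
#'   `factor`), directly consumable by [enumerate_pairs()].
#' @export
load_factor_groups <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "factor_groups.tsv",
                        package = "glioscale", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  .validate_factor_groups(tab)
}

.validate_factor_groups <- function(tab) {
  need <- c("param", "group", "factor")
  if (!all(need %in% names(tab)))
    stop("factor-group table must have columns ",
         paste(need, collapse = ", "))
  bad <- which(!tab$group %in% c("plus", "minus") |
                 !tab$param %in% perturbable_parameters() |
                 !tab$factor %in% lsa_factors())
  if (length(bad))
    stop("malformed factor-group row(s): ", paste(bad, collapse = ", "))
  class(tab) <- c("gs_factor_groups", "data.frame")
  tab
}

#' Load the packaged combined-scaling screen results
#'
#' For each glucose level, the (param1, factor1) x (param2, factor2)
#' combinations whose joint perturbation slowed tumour expansion while
#' shrinking the final cell count.
#'
#' @param path Optional path to an alternative table.
#' @return Data frame with columns `param1`, `factor1`, `glucose0`,
#'   `param2`, `factor2`.
#' @export
load_combined_scalings <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "combined_scalings.tsv",
                        package = "glioscale", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("param1", "factor1", "glucose0", "param2", "factor2")
  if (!all(need %in% names(tab)))
    stop("combined-scaling table must have columns ",
         paste(need, collapse = ", "))
  bad <- which(!tab$glucose0 %in% c(1.125, 2.25, 4.5) |
                 tab$factor1 <= 0 | tab$factor2 <= 0 |
                 !tab$param1 %in% perturbable_parameters() |
                 !tab$param2 %in% perturbable_parameters())
  if (length(bad))
    stop("malformed combined-scaling row(s): ",
         paste(bad, collapse = ", "))
  tab
}

#' Load the reference maximal-sensitivity summary
#'
#' Per-parameter maxima of the absolute sensitivity coefficients of the
#' full-scale sweep, with the glucose level attaining each maximum.
#' Shipped for comparison and plotting only: these values derive from
#' full-scale stochastic simulations and are never used as a test oracle.
#'
#' @param path Optional path to an alternative table.
#' @return Data frame in the layout of [summarize_max()].
#' @export
load_max_sensitivity <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "max_sensitivity_reference.tsv",
                        package = "glioscale", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("param", paste0("m_", c("time", "total", "mig", "prolif")),
            paste0("g_", c("time", "total", "mig", "prolif")))
  if (!all(need %in% names(tab)))
    stop("summary table must have columns ", paste(need, collapse = ", "))
  tab
}

#' Pairs retained at every glucose level
#'
#' From a combined-scaling table, the (param1, factor1, param2, factor2)
#' combinations listed at every one of the given glucose levels -- the
#' candidate interventions that decelerate expansion and shrink volume
#' robustly across nutrient conditions.
#'
#' @param combined A table from [load_combined_scalings()].
#' @param levels Glucose levels that must all contain the pair.
#' @return Data frame with columns `param1`, `factor1`, `param2`,
#'   `factor2`, ordered lexicographically.
#' @export
common_pairs <- function(combined, levels = c(1.125, 2.25, 4.5)) {
  key <- paste(combined$param1, combined$factor1, combined$param2,
               combined$factor2, sep = "\r")
  everywhere <- Reduce(intersect, lapply(levels, function(g) {
    key[combined$glucose0 == g]
  }))
  out <- unique(combined[key %in% everywhere,
                         c("param1", "factor1", "param2", "factor2")])
  out <- out[order(out$param1, out$factor1, out$param2, out$factor2), ]
  rownames(out) <- NULL
  out
}
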