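## Plain-text interchange: field snapshots, trajectory snapshots, run
## records. Numeric values are written with 17 significant digits so that
## round-trips are bit-exact.

#' Write a glucose field snapshot
#'
#' Delimited numeric grid with a one-line header (`# nrow ncol dx time`).
#' Values are written with full precision and read back bit-exact by
#' [read_field()].
#'
#' @param field A [glucose_field()].
#' @param path Output file.
#' @param time Simulation time attached to the header (s).
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path, time = 0) {
  stopifnot(inherits(field, "gs_field"))
  v <- field$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %d %d %.17g %.17g", nrow(v), ncol(v), field$dx,
                     time), con)
  writeLines(apply(v, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = "\t")), con)
  invisible(path)
}

#' Read a glucose field snapshot
#'
#' @param path File written by [write_field()].
#' @return A [glucose_field()] with attribute `"time"`.
#' @export
read_field <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^# ", "", lines[1]), " ")[[1]]
  nr <- as.integer(hdr[1]); nc <- as.integer(hdr[2])
  vals <- do.call(rbind, lapply(lines[-1], function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])))
  if (!identical(dim(vals), c(nr, nc)))
    stop("field snapshot shape mismatch")
  out <- glucose_field(vals, dx = as.numeric(hdr[3]))
  attr(out, "time") <- as.numeric(hdr[4])
  out
}

#' Write a per-step trajectory snapshot
#'
#' One delimited row per agent: step, row, col and the phenotype encoded as
#' Q/M/P. Appends when `append = TRUE`, so one file can hold a whole
#' trajectory.
#'
#' @param world A world state.
#' @param path Output file.
#' @param append Append to an existing file?
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(world, path, append = FALSE) {
  a <- world$agents
  code <- c(MIGRATING = "M", PROLIFERATING = "P", QUIESCENT = "Q")
  df <- data.frame(step = world$step, row = a$row, col = a$col,
                   phenotype = unname(code[a$phenotype]))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !append,
                     append = append)
  invisible(path)
}

#' One-line run record
#'
#' Serialises a finished run as a single delimited record: a short hash of
#' the configuration, the seed, the initial glucose level, the four
#' endpoints and the termination cause.
#'
#' @param config The run's [simulation_config()].
#' @param endpoints The run's `gs_endpoints`.
#' @return Single-element character vector (tab-delimited fields).
#' @export
run_record <- function(config, endpoints) {
  key <- paste(format(unclass(config$params), digits = 17),
               config$glucose0, config$glucose_mode, config$n_side,
               config$radius, config$max_steps, config$dt_macro,
               config$t_div, config$uptake_scale, collapse = "|")
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483629
  paste(sprintf("%08x", h), config$seed, config$glucose0,
        endpoints$M_time, endpoints$M_total, endpoints$M_mig,
        endpoints$M_prolif, endpoints$terminated_by, sep = "\t")
}

#' Write a configuration as a key/value document
#'
#' Scalar fields of the configuration (and all reaction parameters) as
#' `key<TAB>value` lines; a human-readable, diffable run description.
#'
#' @param config A [simulation_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  scalars <- c(glucose0 = config$glucose0, glucose_mode = config$glucose_mode,
               n_side = config$n_side, radius = config$radius,
               max_steps = config$max_steps, seed = config$seed,
               dt_macro = config$dt_macro, t_div = config$t_div,
               uptake_scale = config$uptake_scale,
               D = config$diffusion$D, dx = config$diffusion$dx,
               alpha_occ = config$diffusion$alpha_occ,
               dt_diff = config$diffusion$dt_diff)
  pars <- unclass(config$params)
  lines <- c(paste(names(scalars), scalars, sep = "\t"),
             paste(paste0("param.", names(pars)),
                   sprintf("%.17g", pars), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
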