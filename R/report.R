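## Report generation for a sensitivity sweep: coefficient-vs-factor plots,
## the delta-correlation scatter, and the max-|S| summary table.

#' Write sweep reports to a directory
#'
#' Emits, for each parameter in the sweep, a plot of the four sensitivity
#' coefficients against the scaling factor restricted to factors in (0, 2)
#' (the near-1 range where relative effects are largest; extreme factors
#' compress the coefficients by construction), one scatter of the relative
#' time change against the relative total-count change across all records
#' coloured by glucose level, and the [summarize_max()] table in delimited
#' form.
#'
#' @param records A `gs_lsa` sweep with at least one record.
#' @param out_dir Output directory (created if absent).
#' @param device `"png"` or `"pdf"` plot device.
#' @return Invisible character vector of the files written.
#' @export
report <- function(records, out_dir, device = c("png", "pdf")) {
  if (is.null(records) || nrow(records) == 0L)
    stop("no sweep records to report")
  device <- match.arg(device)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  open_dev <- function(file) {
    if (device == "png") grDevices::png(file, width = 900, height = 700)
    else grDevices::pdf(sub("\\.png$", ".pdf", file), width = 9, height = 7)
  }
  ext <- if (device == "png") ".png" else ".pdf"
  files <- character()
  eps <- c("time", "total", "mig", "prolif")
  cols <- c("black", "blue", "red", "orange")

  for (p in unique(records$param)) {
    sub <- records[records$param == p & records$factor > 0 &
                     records$factor < 2 & records$ok, , drop = FALSE]
    f <- file.path(out_dir, paste0("coefficients_", p, ext))
    open_dev(f)
    graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
    glv <- sort(unique(records$glucose0))
    for (e in eps) {
      sc <- paste0("S_", e)
      graphics::plot(NA, xlim = c(0, 2),
                     ylim = range(sub[[sc]], 0, na.rm = TRUE),
                     xlab = "scaling factor",
                     ylab = paste0("S_", e),
                     main = paste0(p, ": ", e))
      graphics::abline(h = 0, col = "grey")
      for (i in seq_along(glv)) {
        s2 <- sub[sub$glucose0 == glv[i], ]
        graphics::points(s2$factor, s2[[sc]], pch = i, col = cols[i])
      }
      if (e == eps[1])
        graphics::legend("topright", legend = paste(glv, "g/L"),
                         pch = seq_along(glv), col = cols, cex = 0.7)
    }
    grDevices::dev.off()
    files <- c(files, f)
  }

  f <- file.path(out_dir, paste0("delta_correlation", ext))
  open_dev(f)
  graphics::par(mar = c(4, 4, 2, 1))
  glv <- sort(unique(records$glucose0))
  keep <- records$ok & !is.na(records$dM_time) & !is.na(records$dM_total)
  graphics::plot(NA, xlim = range(records$dM_total[keep], 0),
                 ylim = range(records$dM_time[keep], 0),
                 xlab = "relative change of final cell count",
                 ylab = "relative change of step count",
                 main = "expansion slow-down vs volume change")
  graphics::abline(h = 0, v = 0, col = "grey")
  for (i in seq_along(glv)) {
    s2 <- records[keep & records$glucose0 == glv[i], ]
    graphics::points(s2$dM_total, s2$dM_time, pch = i, col = cols[i])
  }
  graphics::legend("topleft", legend = paste(glv, "g/L"),
                   pch = seq_along(glv), col = cols, cex = 0.8)
  grDevices::dev.off()
  files <- c(files, f)

  f <- file.path(out_dir, "max_sensitivity.tsv")
  utils::write.table(summarize_max(records), f, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  invisible(files)
}
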