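#' @importFrom graphics abline legend lines matplot points par barplot
#' @importFrom grDevices png dev.off
NULL

plotConstancy <- function(report, camId, path) {
  grDevices::png(path, width = 700, height = 500)
  on.exit(grDevices::dev.off())
  cv <- report$constancy$curves
  if (!length(cv)) { graphics::plot.new(); return(invisible(path)) }
  ylim <- range(unlist(lapply(cv, function(d) range(d$fit, d$scaledReference))))
  graphics::plot(NA, xlim = c(0, 1), ylim = ylim, xlab = "normalized position t",
                 ylab = "brightness (counts)",
                 main = sprintf("%s: fits vs scaled duty-100 reference", camId))
  for (nm in names(cv)) {
    lines(cv[[nm]]$t, cv[[nm]]$fit, col = "steelblue")
    bp <- report$constancy$baselinePoints[[nm]]
    points(bp$t, bp$scaledReference, col = "firebrick", pch = 16)
  }
  legend("topleft", legend = c("per-level fit", "scaled reference"),
         col = c("steelblue", "firebrick"), lty = c(1, NA), pch = c(NA, 16))
  invisible(path)
}

plotSlopes <- function(report, camId, path) {
  grDevices::png(path, width = 600, height = 450)
  on.exit(grDevices::dev.off())
  s <- report$slopes
  pw <- as.numeric(names(s$slopes))
  graphics::plot(pw, s$slopes, pch = 16, xlab = "PWM duty",
                 ylab = "first-order slope (counts per unit t)",
                 main = sprintf("%s: slope vs PWM (R^2 = %s)", camId,
                                format(signif(s$slopeR2, 4))))
  abline(stats::lm(s$slopes ~ pw), col = "grey50", lty = 2)
  invisible(path)
}

plotOrderErrors <- function(report, camId, path) {
  grDevices::png(path, width = 600, height = 450)
  on.exit(grDevices::dev.off())
  E <- report$orders$orderErrors
  matplot(seq_len(ncol(E)), t(E), type = "b", pch = 16, lty = 1,
          xlab = "polynomial order", ylab = "residual variance (counts^2)",
          main = sprintf("%s: error vs order", camId))
  legend("topright", legend = paste("PWM", rownames(E)),
         col = seq_len(nrow(E)), lty = 1, pch = 16)
  invisible(path)
}

plotScaling <- function(sc, camId, path) {
  grDevices::png(path, width = 600, height = 450)
  on.exit(grDevices::dev.off())
  graphics::plot(sc@levels, sc@d, pch = 16, xlab = "PWM duty",
                 ylab = "optimal constant d",
                 main = sprintf("%s: d vs PWM (RMSE %.4g)", camId,
                                sc@linearityRMSE))
  lines(sort(sc@levels), sort(sc@levels) / 100, lty = 2, col = "grey50")
  legend("topleft", legend = c("optimal d", "d = PWM/100 baseline"),
         pch = c(16, NA), lty = c(NA, 2), col = c("black", "grey50"))
  invisible(path)
}

plotComparison <- function(cmp, path) {
  grDevices::png(path, width = 650, height = 450)
  on.exit(grDevices::dev.off())
  pe <- cmp$perExperiment
  m <- rbind(pe$flankMeanR2, pe$centerR2)
  barplot(m, beside = TRUE, names.arg = paste("exp", pe$experiment),
          col = c("steelblue", "firebrick"),
          ylab = expression(R^2), ylim = c(0, 1.05),
          main = "flank-mean vs center R^2 per experiment")
  legend("bottomright", legend = c("flank mean", "center"),
         fill = c("steelblue", "firebrick"))
  invisible(path)
}

## regenerate all plots for a finished pipeline run; plots are derived
## artifacts, never inputs
plotPipeline <- function(res, outDir) {
  if (!is.null(res$method1)) {
    for (camId in names(res$method1)) {
      plotConstancy(res$method1[[camId]], camId,
                    file.path(outDir, sprintf("constancy_%s.png", camId)))
      plotSlopes(res$method1[[camId]], camId,
                 file.path(outDir, sprintf("slope_vs_pwm_%s.png", camId)))
      plotOrderErrors(res$method1[[camId]], camId,
                      file.path(outDir, sprintf("order_errors_%s.png", camId)))
    }
  }
  if (!is.null(res$method2)) {
    for (camId in names(res$method2))
      plotScaling(res$method2[[camId]], camId,
                  file.path(outDir, sprintf("scaling_%s.png", camId)))
  }
  if (!is.null(res$comparison))
    plotComparison(res$comparison, file.path(outDir, "experiment_comparison.png"))
  invisible(outDir)
}
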