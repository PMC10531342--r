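#' Plot posterior curves and corrected membership functions
#'
#' Base-graphics QC plot of one marker's posterior ("conditional
#' probability") curves, optionally overlaid with the corrected membership
#' functions (dashed).  When \code{file} ends in \code{.png} or
#' \code{.svg}, the plot is written there instead of the active device.
#'
#' @param lines a [ProbabilityLines-class]
#' @param mfs optional matching [MembershipFunctionSet-class]
#' @param file optional output file (.png or .svg)
#' @param main plot title
#' @return \code{file} (or \code{NULL}), invisibly
#' @export
plotProbabilityLines <- function(lines, mfs = NULL, file = NULL,
                                 main = lines@markerName) {
  stopifnot(is(lines, "ProbabilityLines"))
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           png = grDevices::png(file, width = 900, height = 600, res = 110),
           svg = grDevices::svg(file, width = 8, height = 5.5),
           stopf("unsupported plot format '.%s' (png or svg)", ext))
    on.exit(grDevices::dev.off())
  }
  K <- nrow(lines@P)
  cols <- grDevices::hcl.colors(max(K, 3L), "Dark 3")[seq_len(K)]
  graphics::matplot(lines@grid, t(lines@P), type = "l", lty = 1, lwd = 1.5,
                    col = cols, xlab = "marker value (arcsinh)",
                    ylab = "probability / membership", main = main,
                    ylim = c(0, 1))
  if (!is.null(mfs)) {
    stopifnot(is(mfs, "MembershipFunctionSet"))
    graphics::matlines(mfs@grid, t(mfs@curves), lty = 2, lwd = 2,
                       col = cols[seq_len(nrow(mfs@curves))])
    graphics::legend("right", bty = "n", lty = c(1, 2), lwd = c(1.5, 2),
                     legend = c("posterior", "membership"))
  }
  invisible(file)
}
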