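#' Diagnostic plot: observed outcome versus the composite biomarker
#'
#' Scatter of observed annual eGFR change against the RASi-only model
#' prediction Delta_R, with guide lines at the CD (-5) and UCD (-10)
#' boundaries. Points from add-on arms sitting above the identity line in
#' the low-Delta_R region indicate drug rescue.
#'
#' @param x A \code{"cross_prediction"} from [cross_predict()].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, \code{x}.
#' @export
plot.cross_prediction <- function(x, ...) {
  pp <- x$per_pair
  cols <- c(RASi = "black", GLP1a = "#1b9e77", MCRa = "#d95f02",
            SGLT2i = "#7570b3")
  col <- cols[pp$arm]
  col[is.na(col)] <- "grey40"
  graphics::plot(pp$delta_R, pp$observed, col = col, pch = 16,
                 xlab = expression(Delta[R] ~ "(predicted, %/yr)"),
                 ylab = expression(Delta * "eGFR (observed, %/yr)"), ...)
  graphics::abline(h = c(-5, -10), v = c(-5, -10), lty = c(2, 3),
                   col = "darkgreen")
  graphics::abline(0, 1, col = "grey60")
  present <- intersect(names(cols), unique(pp$arm))
  graphics::legend("topleft", legend = present, col = cols[present],
                   pch = 16, bty = "n")
  invisible(x)
}
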