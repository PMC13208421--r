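# Figure-style visual summaries of spore morphometry (scatter with
# isoprobability ellipses; violin of the depression statistic). These are
# convenience wrappers; all statistics they draw are available from
# isoEllipse(), kde2() and compareGroups().

needGgplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
}

#' Length-width cloud with per-species isoprobability ellipses
#'
#' @param measurements per-spore or per-collection data.frame with
#'   \code{L_um}, \code{W_um} and a grouping column.
#' @param by grouping column name.
#' @param probLevel probability level of the ellipses.
#' @return A ggplot object.
#' @export
plotSizeCloud <- function(measurements, by = "species", probLevel = 0.95) {
  needGgplot()
  ells <- do.call(rbind, lapply(split(measurements, measurements[[by]]),
    function(d) {
      if (nrow(d) < 3L) return(NULL)
      e <- isoEllipse(cbind(d$L_um, d$W_um), probLevel)
      xy <- ellipsePoints(e)
      data.frame(L_um = xy[, 1], W_um = xy[, 2], group = d[[by]][1])
    }))
  ggplot2::ggplot(measurements,
                  ggplot2::aes(x = .data[["L_um"]], y = .data[["W_um"]],
                               colour = .data[[by]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_path(data = ells,
                       ggplot2::aes(colour = .data[["group"]])) +
    ggplot2::labs(x = "Length (µm)", y = "Width (µm)")
}

#' Violin plot of the suprahilar-depression statistic
#'
#' @param measurements data.frame with \code{depression_pct} and a grouping
#'   column.
#' @param by grouping column name.
#' @return A ggplot object.
#' @export
plotDepressionViolin <- function(measurements, by = "species") {
  needGgplot()
  ggplot2::ggplot(measurements,
                  ggplot2::aes(x = .data[[by]],
                               y = .data[["depression_pct"]],
                               fill = .data[[by]])) +
    ggplot2::geom_violin() +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5, size = 0.8) +
    ggplot2::labs(y = "Suprahilar depression (% of hull area)")
}
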