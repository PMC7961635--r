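# Optional ggplot2 helpers for the two result types users plot most:
# predicted ground reaction wrenches and filter tuning surfaces.

#' Plot predicted per-leg ground reaction forces
#'
#' @param pred a [predict_grfm()] result.
#' @param components force components to show.
#' @return a ggplot object.
#' @export
plot_grfm <- function(pred, components = c("x", "y", "z")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_grfm requires ggplot2")
  W <- pred$wrenches
  long <- do.call(rbind, lapply(pred$legs, function(l) {
    do.call(rbind, lapply(components, function(cc) {
      data.frame(time = W$time, leg = l, component = cc,
                 force = W[[paste0(l, "_force_", cc)]])
    }))
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$force,
                                     color = .data$leg)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "ground reaction force (N)")
}

#' Plot a filter tuning RMSE surface
#'
#' @param tuning a [tune_hyperparameters()] result.
#' @param which RMSE surface to show (`"rmse_a"`, `"rmse_u"`, `"rmse_q"`).
#' @return a ggplot object.
#' @export
plot_tuning <- function(tuning, which = "rmse_a") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_tuning requires ggplot2")
  ggplot2::ggplot(tuning$rmse,
                  ggplot2::aes(x = .data$M, y = .data$D,
                               fill = .data[[which]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = data.frame(M = tuning$M, D = tuning$D),
                        ggplot2::aes(x = .data$M, y = .data$D),
                        inherit.aes = FALSE, shape = 4, size = 3) +
    ggplot2::labs(x = "memory M (samples)", y = "lag D (samples)",
                  fill = which)
}
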