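# Minimal plotting layer for the importance ledger.

#' Heatmap of an importance trajectory
#'
#' Draws tasks (x) against importance coordinates (y) — e.g. the rows of
#' per-task [feature_importance()] or [neuron_importance()] — as a base
#' graphics heatmap, optionally written to a PNG.
#'
#' @param trajectory Numeric matrix, rows = tasks, columns = coordinates.
#' @param file Optional PNG path; `NULL` draws on the current device.
#' @param main Plot title.
#' @param names Optional coordinate labels (default column names).
#' @return Invisibly, the trajectory.
#' @export
plot_importance_heatmap <- function(trajectory, file = NULL,
                                    main = "Importance over tasks",
                                    names = NULL) {
  trajectory <- as.matrix(trajectory)
  if (is.null(names))
    names <- colnames(trajectory) %||% paste0("v", seq_len(ncol(trajectory)))
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 500)
    on.exit(grDevices::dev.off())
  }
  old <- graphics::par(mar = c(4, 5, 3, 1))
  on.exit(graphics::par(old), add = TRUE)
  graphics::image(x = seq_len(nrow(trajectory)),
                  y = seq_len(ncol(trajectory)),
                  z = trajectory,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "task", ylab = "", axes = FALSE, main = main)
  graphics::axis(1, at = seq_len(nrow(trajectory)))
  graphics::axis(2, at = seq_len(ncol(trajectory)), labels = names,
                 las = 2, cex.axis = 0.8)
  graphics::box()
  invisible(trajectory)
}
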