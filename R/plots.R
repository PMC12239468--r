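# Overlay plots in the style of the planning figures: contours, guide lines,
# landmarks. Base graphics only.

draw_line_through <- function(l, y_range, col, lty = 1, lwd = 1.5) {
  # draw a directed line clipped to a parameter range centred on its anchor
  t <- seq(-max(abs(y_range)) - 50, max(abs(y_range)) + 50, length.out = 2)
  xs <- l$anchor[1] + t * l$direction[1]
  ys <- l$anchor[2] + t * l$direction[2]
  graphics::lines(xs, ys, col = col, lty = lty, lwd = lwd)
}

#' Plot a femur silhouette with an optional plan overlay
#'
#' @param x A `femur_silhouette`.
#' @param plan Optional `femur_plan` whose Lines A/B/C and entry point are
#'   overlaid.
#' @param ... Passed to `plot`.
#' @export
plot.femur_silhouette <- function(x, plan = NULL, ...) {
  all_pts <- rbind(unclass(x$anterior_cortex), unclass(x$posterior_cortex),
                   unclass(x$groove_curve))
  graphics::plot(all_pts, type = "n", asp = 1, xlab = "anterior (mm)",
                 ylab = "proximal (mm)", main = "Lateral femur", ...)
  for (nm in c("anterior_cortex", "posterior_cortex"))
    graphics::lines(unclass(x[[nm]]), lwd = 2)
  for (nm in c("canal_anterior_wall", "canal_posterior_wall"))
    graphics::lines(unclass(x[[nm]]), col = "grey50")
  graphics::lines(unclass(x$groove_curve), col = "grey30", lwd = 2)
  graphics::points(rbind(x$blumensaat_posterior, x$notch_roof), pch = 19,
                   col = "darkred")
  if (!is.null(plan)) {
    yr <- range(all_pts[, 2])
    draw_line_through(plan$line_a, yr, col = "steelblue", lty = 2)
    draw_line_through(plan$line_b, yr, col = "firebrick")
    draw_line_through(plan$line_c, yr, col = "darkgreen", lty = 3)
    graphics::points(plan$entry_point[1], plan$entry_point[2], pch = 17,
                     col = "firebrick")
    graphics::legend("topright", bty = "n",
                     legend = c("Line A (cortex)", "Line B (IM guide)",
                                "Line C (reference)"),
                     col = c("steelblue", "firebrick", "darkgreen"),
                     lty = c(2, 1, 3))
  }
  invisible(x)
}

#' Plot a tibia silhouette with an optional plan overlay
#'
#' @param x A `tibia_silhouette`.
#' @param plan Optional `tibia_plan` whose FSA, EM-guide and reference lines
#'   are overlaid.
#' @param ... Passed to `plot`.
#' @export
plot.tibia_silhouette <- function(x, plan = NULL, ...) {
  all_pts <- rbind(unclass(x$anterior_cortex), unclass(x$posterior_cortex),
                   unclass(x$skin_anterior))
  graphics::plot(all_pts, type = "n", asp = 1, xlab = "anterior (mm)",
                 ylab = "proximal (mm)", main = "Lateral lower leg", ...)
  for (nm in c("anterior_cortex", "posterior_cortex"))
    graphics::lines(unclass(x[[nm]]), lwd = 2)
  graphics::lines(unclass(x$skin_anterior), col = "grey60", lty = 2)
  graphics::points(rbind(x$tuberosity, x$ankle_concavity), pch = 19,
                   col = "darkred")
  yr <- range(all_pts[, 2])
  draw_line_through(x$plateau_line, c(-40, 40), col = "grey30")
  if (!is.null(plan)) {
    draw_line_through(plan$fsa_line, yr, col = "steelblue", lty = 2)
    draw_line_through(plan$em_line, yr, col = "firebrick")
    draw_line_through(plan$line_c, yr, col = "darkgreen", lty = 3)
    graphics::legend("topright", bty = "n",
                     legend = c("FSA", "EM guide", "reference"),
                     col = c("steelblue", "firebrick", "darkgreen"),
                     lty = c(2, 1, 3))
  }
  invisible(x)
}

#' Write a PNG overlay of a silhouette and its plan
#'
#' @param plan A `femur_plan` or `tibia_plan`.
#' @param sil The matching silhouette.
#' @param path Output PNG path.
#' @param width,height Device size in pixels.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(plan, sil, path, width = 700, height = 900) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  plot(sil, plan = plan)
  invisible(path)
}
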