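# Rendering: tomogram maps on a green(soft) -> red(stiff) scale and the
# correlation heat-map with significance stars.

#' Green-to-red stiffness palette
#'
#' @param n number of colours.
#' @return character vector of colours, green = soft, red = stiff.
#' @export
stiffness_palette <- function(n = 256) {
  grDevices::colorRampPalette(c("#00A000", "#FFE000", "#D00000"))(n)
}

draw_map <- function(map, zlim, main, pitch = 1, mask_col = "grey75") {
  nr <- nrow(map); nc <- ncol(map)
  xs <- (seq_len(nc) - 0.5) * pitch
  ys <- (seq_len(nr) - 0.5) * pitch
  graphics::image(xs, ys, matrix(0, nc, nr), col = mask_col,
                  xlab = "", ylab = "", axes = FALSE, main = main,
                  cex.main = 0.9)
  graphics::image(xs, ys, t(map[nr:1, , drop = FALSE]),
                  col = stiffness_palette(), zlim = zlim, add = TRUE)
  graphics::box()
}

#' Plot a stiffness tomogram map
#'
#' Draws one depth-segment map (or the full-range map) of a tomogram on
#' the green-to-red stiffness scale; masked pixels are grey.
#'
#' @param x a `"stiffness_tomogram"`.
#' @param segment segment index (1-based) or `"full"` (default).
#' @param zlim colour-scale limits in MPa; defaults to the data range.
#' @param ... unused.
#' @export
plot.stiffness_tomogram <- function(x, segment = "full", zlim = NULL, ...) {
  map <- if (identical(segment, "full")) x$fullrange_map
         else x$segment_maps[[segment]]
  label <- if (identical(segment, "full")) "0-50 nm (full range)"
           else paste0(names(x$segment_maps)[segment], " nm")
  if (all(is.na(map)))
    cm_abort("selected map has no unmasked pixels", "cm_data_error")
  if (is.null(zlim)) zlim <- range(map, na.rm = TRUE)
  if (zlim[1] == zlim[2]) zlim <- zlim + c(-0.5, 0.5)
  draw_map(map, zlim, sprintf("%s  Ea, %s", x$cell_id, label),
           pitch = x$pixel_pitch)
  invisible(x)
}

#' Render a tomogram to a PNG file
#'
#' Writes a multi-panel raster: every 5 nm segment map, the full-range
#' map, a row-by-depth cross-section through the middle of the grid, and
#' the colour scale. Green encodes soft, red stiff material; masked pixels
#' are grey.
#'
#' @param tomo a `"stiffness_tomogram"`.
#' @param path output PNG path.
#' @param zlim colour-scale limits in MPa (default: range over all maps).
#' @param width,height device size in pixels.
#' @return `path`, invisibly.
#' @export
render_tomogram <- function(tomo, path, zlim = NULL,
                            width = 1200, height = 900) {
  stopifnot(inherits(tomo, "stiffness_tomogram"))
  vals <- c(unlist(tomo$segment_maps), tomo$fullrange_map)
  if (is.null(zlim)) zlim <- range(vals, na.rm = TRUE)
  if (!all(is.finite(zlim)) || zlim[1] == zlim[2])
    zlim <- c(zlim[1] - 0.5, zlim[1] + 0.5)
  if (!dir.exists(dirname(path)))
    cm_abort(sprintf("cannot write '%s': directory does not exist", path),
             "cm_io_error")
  ok <- tryCatch({
    grDevices::png(path, width = width, height = height)
    TRUE
  }, error = function(e) e)
  if (inherits(ok, "condition"))
    cm_abort(sprintf("cannot open '%s' for writing: %s", path,
                     conditionMessage(ok)), "cm_io_error")
  on.exit(grDevices::dev.off())
  nseg <- length(tomo$segment_maps)
  graphics::par(mfrow = c(3, ceiling((nseg + 3) / 3)),
                mar = c(1.5, 1.5, 2.5, 0.8))
  for (k in seq_len(nseg))
    draw_map(tomo$segment_maps[[k]], zlim,
             paste0(names(tomo$segment_maps)[k], " nm"),
             pitch = tomo$pixel_pitch)
  draw_map(tomo$fullrange_map, zlim, "full range (headline Ea)",
           pitch = tomo$pixel_pitch)
  # cross-section: middle row of the grid, depth on the vertical axis
  mid <- ceiling(tomo$grid_shape[1] / 2)
  cross <- t(vapply(tomo$segment_maps,
                    function(m) m[mid, ], numeric(tomo$grid_shape[2])))
  mids <- (tomo$segment_edges[-1] + tomo$segment_edges[-length(tomo$segment_edges)]) / 2
  graphics::image(seq_len(ncol(cross)) * tomo$pixel_pitch, mids,
                  t(cross)[, nrow(cross):1, drop = FALSE],
                  col = stiffness_palette(), zlim = zlim,
                  xlab = "", ylab = "depth (nm)",
                  main = sprintf("x-depth section (row %d)", mid),
                  cex.main = 0.9)
  graphics::box()
  # colour scale
  sc <- seq(zlim[1], zlim[2], length.out = 128)
  graphics::image(sc, 1, matrix(sc, ncol = 1), col = stiffness_palette(),
                  yaxt = "n", xlab = "Ea (MPa)", ylab = "",
                  main = "soft (green) -> stiff (red)", cex.main = 0.9)
  invisible(path)
}

#' Heat-map of a Spearman correlation matrix
#'
#' Draws the rho matrix with significance stars per cell
#' (`*` p<0.05, `**` p<0.01, `***` p<0.001, `****` p<0.0001).
#'
#' @param x a `"spearman_matrix"` (see [spearman_matrix()]).
#' @param ... unused.
#' @export
plot.spearman_matrix <- function(x, ...) {
  k <- length(x$variables)
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  graphics::image(seq_len(k), seq_len(k), t(x$rho[k:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = pal, axes = FALSE,
                  xlab = "", ylab = "", main = "Spearman correlation")
  graphics::axis(1, at = seq_len(k), labels = x$variables, tick = FALSE)
  graphics::axis(2, at = seq_len(k), labels = rev(x$variables), tick = FALSE,
                 las = 1)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    rho <- x$rho[i, j]; p <- x$p[i, j]
    if (is.na(rho)) next
    lab <- if (i == j) "" else sprintf("%.2f%s", rho, p_stars(p))
    graphics::text(j, k - i + 1, lab, cex = 0.9)
  }
  graphics::box()
  invisible(x)
}

p_stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 1e-4) "****" else if (p < 1e-3) "***"
  else if (p < 1e-2) "**" else if (p < 0.05) "*" else ""
}
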