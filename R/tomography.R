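#' Depth-resolved stiffness analysis of one cell
#'
#' Runs the full per-pixel chain -- baseline correction, contact
#' detection, indentation conversion, 5 nm segment fits over 0--50 nm and
#' the full-range fit -- for every force curve of one cell. Pixels whose
#' chain fails at any stage are masked with the failure reason recorded;
#' they are never imputed.
#'
#' @param curves list of [force_curve()] objects, each carrying its
#'   `(row, col)` pixel index.
#' @param tip a [tip_geometry()].
#' @param config list of analysis settings; recognized entries and their
#'   defaults: `baseline_fraction` (0.3), `noise_sigma` (NULL: estimate
#'   per curve), `spring_constant` (NULL), `max_depth` (50 nm),
#'   `segment_width` (5 nm), `fit_segments` (TRUE), `min_segment_points`
#'   (3), `contact` (NULL: detect; or a numeric vector of known contact z
#'   positions, one per curve, bypassing detection), `cell_id`,
#'   `grid_shape`, `pixel_pitch` (1 um).
#' @return an object of class `"stiffness_tomogram"`: per-segment Ea maps
#'   (`segment_maps`, matrices with NA for masked pixels), the headline
#'   `fullrange_map`, `r2_map`, the `mask_reason` character matrix
#'   (`"ok"` for used pixels), grid metadata and counters.
#' @export
analyze_cell <- function(curves, tip = tip_geometry(), config = list()) {
  if (!is.list(curves) || length(curves) == 0L ||
      !all(vapply(curves, inherits, logical(1), "force_curve")))
    cm_abort("'curves' must be a non-empty list of force_curve objects",
             "cm_data_error")
  known <- c("baseline_fraction", "noise_sigma", "spring_constant",
             "max_depth", "segment_width", "fit_segments",
             "min_segment_points", "contact", "cell_id", "grid_shape",
             "pixel_pitch")
  bad <- setdiff(names(config), known)
  if (length(bad))
    cm_abort(paste("unknown analyze_cell config keys:",
                   paste(bad, collapse = ", ")), "cm_config_error")
  bf <- config$baseline_fraction %||% 0.3
  max_depth <- config$max_depth %||% 50
  seg_w <- config$segment_width %||% 5
  fit_segments <- config$fit_segments %||% TRUE
  min_pts <- config$min_segment_points %||% 3L
  edges <- seq(0, max_depth, by = seg_w)

  px <- t(vapply(curves, function(cu) cu$pixel, integer(2)))
  if (any(is.na(px)))
    cm_abort("every curve must carry a (row, col) pixel index",
             "cm_data_error")
  shape <- config$grid_shape %||% c(max(px[, 1]), max(px[, 2]))
  if (length(curves) > prod(shape))
    cm_abort("more curves than grid pixels", "cm_data_error")
  if (anyDuplicated(px))
    cm_abort("duplicated pixel indices within one cell", "cm_data_error")

  blank <- matrix(NA_real_, shape[1], shape[2])
  seg_maps <- replicate(length(edges) - 1L, blank, simplify = FALSE)
  names(seg_maps) <- sprintf("%g-%g", edges[-length(edges)], edges[-1])
  fullrange <- blank; r2 <- blank
  mask <- matrix(NA_character_, shape[1], shape[2])

  for (i in seq_along(curves)) {
    cu <- curves[[i]]; r <- px[i, 1]; c <- px[i, 2]
    res <- tryCatch({
      cu <- correct_baseline(cu, bf)
      if (!is.null(config$contact)) {
        cz <- config$contact[i]
      } else {
        cz <- detect_contact_point(cu, noise_sigma = config$noise_sigma,
                                   baseline_fraction = bf)$contact_z
      }
      ind <- to_indentation(cu, cz, spring_constant = config$spring_constant)
      full <- fit_apparent_modulus(ind, tip, max_depth = max_depth)
      segs <- NULL
      if (fit_segments) {
        segs <- lapply(seq_len(length(edges) - 1L), function(k) {
          tryCatch(fit_segment(ind, edges[k], edges[k + 1L], tip,
                               min_points = min_pts),
                   corneomech_error = function(e) NULL)
        })
      }
      list(full = full, segs = segs)
    }, corneomech_error = function(e) e)
    if (inherits(res, "condition")) {
      mask[r, c] <- class(res)[1L]
    } else {
      mask[r, c] <- "ok"
      fullrange[r, c] <- res$full$ea
      r2[r, c] <- res$full$fit_r2
      if (fit_segments)
        for (k in seq_along(res$segs))
          if (!is.null(res$segs[[k]]))
            seg_maps[[k]][r, c] <- res$segs[[k]]$ea
    }
  }
  n_used <- sum(mask == "ok", na.rm = TRUE)
  if (n_used == 0L)
    cm_abort(sprintf("all %d pixels of cell '%s' failed",
                     length(curves), config$cell_id %||% "?"),
             "cm_cell_unusable")
  structure(
    list(cell_id = config$cell_id %||% curves[[1]]$meta$cell_id %||% "cell",
         grid_shape = shape,
         pixel_pitch = config$pixel_pitch %||% 1,
         segment_edges = edges,
         segment_maps = seg_maps,
         fullrange_map = fullrange,
         r2_map = r2,
         mask_reason = mask,
         n_curves = length(curves),
         n_used = n_used,
         n_failed = length(curves) - n_used,
         tip = tip),
    class = "stiffness_tomogram")
}

#' @export
print.stiffness_tomogram <- function(x, ...) {
  cat(sprintf(
    "Stiffness tomogram '%s': %dx%d grid (%g um pitch), %d/%d pixels fitted\n",
    x$cell_id, x$grid_shape[1], x$grid_shape[2], x$pixel_pitch,
    x$n_used, x$n_curves))
  if (x$n_used > 0)
    cat(sprintf("  full-range Ea: median %.4g MPa (range %.3g..%.3g)\n",
                stats::median(x$fullrange_map, na.rm = TRUE),
                min(x$fullrange_map, na.rm = TRUE),
                max(x$fullrange_map, na.rm = TRUE)))
  invisible(x)
}

#' Tidy per-pixel, per-segment table of a tomogram
#'
#' @param x a `"stiffness_tomogram"`.
#' @param ... unused.
#' @return data frame with one row per (pixel, segment), segments labelled
#'   by their depth window plus `"full"` for the headline fit.
#' @export
as.data.frame.stiffness_tomogram <- function(x, ...) {
  shape <- x$grid_shape
  grid <- expand.grid(row = seq_len(shape[1]), col = seq_len(shape[2]))
  one <- function(label, lo, hi, map, r2 = NA_real_) {
    data.frame(cell_id = x$cell_id, row = grid$row, col = grid$col,
               segment = label, depth_lo = lo, depth_hi = hi,
               ea = as.vector(map), r2 = as.vector(r2),
               mask_reason = as.vector(x$mask_reason))
  }
  ne <- length(x$segment_edges)
  out <- do.call(rbind, c(
    lapply(seq_len(ne - 1L), function(k)
      one(names(x$segment_maps)[k], x$segment_edges[k], x$segment_edges[k + 1],
          x$segment_maps[[k]])),
    list(one("full", x$segment_edges[1], x$segment_edges[ne],
             x$fullrange_map, x$r2_map))))
  out[!is.na(out$mask_reason), , drop = FALSE]
}

#' Summarize a tomogram to one cell-level modulus
#'
#' The cell aggregate is the median over unmasked full-range pixels
#' (median for robustness to occasional debris/edge pixels); per-segment
#' medians are computed the same way. The aggregator can be switched to
#' the mean.
#'
#' @param tomo a `"stiffness_tomogram"`.
#' @param aggregate `"median"` (default) or `"mean"`.
#' @return an object of class `"cell_summary"` with `ea_cell` (MPa),
#'   `n_pixels_used` and `per_segment_medians` (data frame `depth_lo`,
#'   `depth_mid`, `ea`, `n`).
#' @export
summarize_cell <- function(tomo, aggregate = c("median", "mean")) {
  stopifnot(inherits(tomo, "stiffness_tomogram"))
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "median") {
    function(v) stats::median(v, na.rm = TRUE)
  } else {
    function(v) mean(v, na.rm = TRUE)
  }
  if (tomo$n_used < 1L)
    cm_abort("no unmasked pixels to summarize", "cm_cell_unusable")
  edges <- tomo$segment_edges
  segs <- data.frame(
    depth_lo = edges[-length(edges)],
    depth_mid = (edges[-length(edges)] + edges[-1]) / 2,
    ea = vapply(tomo$segment_maps, agg, numeric(1)),
    n = vapply(tomo$segment_maps, function(m) sum(!is.na(m)), integer(1)),
    row.names = NULL)
  structure(
    list(cell_id = tomo$cell_id,
         ea_cell = agg(tomo$fullrange_map),
         n_pixels_used = tomo$n_used,
         per_segment_medians = segs,
         aggregate = aggregate),
    class = "cell_summary")
}

#' @export
print.cell_summary <- function(x, ...) {
  cat(sprintf("Cell '%s': Ea = %.4g MPa (%s over %d pixels)\n",
              x$cell_id, x$ea_cell, x$aggregate, x$n_pixels_used))
  invisible(x)
}

#' Aggregate cell summaries to one subject-level modulus
#'
#' The subject aggregate is the arithmetic mean of the per-cell moduli
#' (each cell contributes equally, matching acquisition on 9--10 cells per
#' subject); the median is available as an alternative.
#'
#' @param cells list of [summarize_cell()] results.
#' @param aggregate `"mean"` (default) or `"median"`.
#' @return list with `ea_subject` (MPa), `n_cells`, `ea_cells`.
#' @export
summarize_subject <- function(cells, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (!is.list(cells) || length(cells) == 0L ||
      !all(vapply(cells, inherits, logical(1), "cell_summary")))
    cm_abort("'cells' must be a non-empty list of cell_summary objects",
             "cm_data_error")
  ea <- vapply(cells, function(cs) cs$ea_cell, numeric(1))
  est <- if (aggregate == "mean") mean(ea) else stats::median(ea)
  list(ea_subject = est, n_cells = length(ea), ea_cells = ea,
       aggregate = aggregate)
}
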