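# Force-volume container: long-format CSV (cell_id, row, col, z, force)
# with a sidecar YAML file carrying acquisition attributes (setpoint,
# pixel pitch, grid shape). The sidecar lives at "<csv path>.meta.yaml".

meta_path <- function(path) paste0(path, ".meta.yaml")

#' Write force volumes to the CSV container
#'
#' @param volumes a single `"force_volume"` or a list of them (one per
#'   cell); plain lists of [force_curve()] with a `cell_id` name also
#'   work.
#' @param path output CSV path; a `<path>.meta.yaml` sidecar with
#'   setpoint, pixel pitch and grid shapes is written alongside.
#' @param pixel_pitch grid pitch, um.
#' @return `path`, invisibly.
#' @export
write_force_volume <- function(volumes, path, pixel_pitch = 1) {
  if (inherits(volumes, "force_volume")) volumes <- list(volumes)
  rows <- list(); meta_cells <- list(); setpoint <- NULL
  for (v in volumes) {
    stopifnot(inherits(v, "force_volume"))
    for (cu in v$curves) {
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = v$cell_id, row = cu$pixel[1], col = cu$pixel[2],
        z = cu$z, force = cu$force)
      setpoint <- cu$setpoint
    }
    meta_cells[[v$cell_id]] <- list(grid_shape = as.integer(v$grid_shape),
                                    seed = v$seed)
  }
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE)
  yaml::write_yaml(list(setpoint = setpoint, pixel_pitch = pixel_pitch,
                        cells = meta_cells),
                   meta_path(path))
  invisible(path)
}

#' Read force volumes from the CSV container
#'
#' @param path CSV path written by [write_force_volume()] (or an
#'   equivalent long-format file with columns cell_id, row, col, z,
#'   force; without a sidecar the setpoint defaults to 150 nN).
#' @return named list (one entry per cell) of lists of [force_curve()].
#' @export
read_force_volume <- function(path) {
  if (!file.exists(path))
    cm_abort(sprintf("container not found: '%s'", path), "cm_data_error")
  tab <- utils::read.csv(path)
  need <- c("cell_id", "row", "col", "z", "force")
  if (!all(need %in% names(tab)))
    cm_abort(paste("container must have columns:",
                   paste(need, collapse = ", ")), "cm_data_error")
  meta <- if (file.exists(meta_path(path))) yaml::read_yaml(meta_path(path))
          else list()
  setpoint <- meta$setpoint %||% 150
  out <- list()
  for (cid in unique(tab$cell_id)) {
    sub <- tab[tab$cell_id == cid, , drop = FALSE]
    key <- interaction(sub$row, sub$col, drop = TRUE)
    out[[as.character(cid)]] <- lapply(split(sub, key), function(s) {
      force_curve(s$z, s$force, setpoint = setpoint,
                  pixel = c(s$row[1], s$col[1]),
                  meta = list(cell_id = as.character(cid)))
    })
  }
  attr(out, "pixel_pitch") <- meta$pixel_pitch %||% 1
  attr(out, "setpoint") <- setpoint
  out
}

#' Write tidy fitted results for a set of tomograms
#'
#' One row per (subject, cell, pixel, segment), the package's standard
#' results export.
#'
#' @param tomos list of `"stiffness_tomogram"` objects.
#' @param path output CSV path.
#' @param subject_ids optional vector of subject ids, recycled over
#'   `tomos`.
#' @return the written data frame, invisibly.
#' @export
write_results_csv <- function(tomos, path, subject_ids = NA_character_) {
  if (inherits(tomos, "stiffness_tomogram")) tomos <- list(tomos)
  subject_ids <- rep_len(subject_ids, length(tomos))
  tabs <- mapply(function(tm, sid) {
    cbind(subject_id = sid, as.data.frame(tm))
  }, tomos, subject_ids, SIMPLIFY = FALSE)
  out <- do.call(rbind, tabs)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Read a subject table
#'
#' Expects columns subject_id, group, flg, nmf, tewl, scorad, ea (missing
#' values stay `NA`; they are never zero-filled).
#'
#' @param path CSV path.
#' @return data frame of class `"cohort"`.
#' @export
read_subjects_csv <- function(path) {
  if (!file.exists(path))
    cm_abort(sprintf("subject table not found: '%s'", path), "cm_data_error")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "nmf", "tewl", "ea")
  if (!all(need %in% names(tab)))
    cm_abort(paste("subject table must have columns:",
                   paste(need, collapse = ", ")), "cm_data_error")
  if (!"scorad" %in% names(tab)) tab$scorad <- NA_real_
  if (!"flg" %in% names(tab)) tab$flg <- NA_character_
  bad <- !tab$group %in% c("AD", "control")
  if (any(bad))
    cm_abort("'group' must be 'AD' or 'control'", "cm_data_error")
  if (any(stats::na.omit(tab$nmf) < 0) || any(stats::na.omit(tab$tewl) <= 0))
    cm_abort("nmf must be >= 0 and tewl > 0 where present", "cm_data_error")
  sc <- stats::na.omit(tab$scorad)
  if (length(sc) && (any(sc < 0) || any(sc > 103)))
    cm_abort("scorad must lie in [0, 103]", "cm_data_error")
  class(tab) <- c("cohort", "data.frame")
  tab
}
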