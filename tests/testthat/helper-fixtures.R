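# Shared fixtures: all synthetic, built in code at test time.

noiseless_instrument <- function(...) {
  instrument_model(force_noise_sigma = 0, baseline_tilt = 0,
                   contact_offset_jitter = 0, ...)
}

homogeneous_profile <- function(e = 200, pixel_sigma = 0) {
  depth_profile(c(10, 20), c(e, e, e), pixel_sigma = pixel_sigma)
}

# one clean indentation curve of modulus `e` (MPa), depths 0..max nm
clean_indentation <- function(e = 200, tip = tip_geometry(), step = 0.5,
                              max_depth = 60) {
  delta <- seq(0, max_depth, by = step)
  structure(list(delta = delta,
                 force = hertz_pyramid_force(e, delta, tip),
                 contact_z = 0, contact_index = 1L,
                 pixel = c(1L, 1L), setpoint = Inf),
            class = "indentation_curve")
}

# minimal tomogram around a given full-range map (for aggregator tests)
map_tomogram <- function(map, cell_id = "t") {
  map <- as.matrix(map)
  structure(list(cell_id = cell_id, grid_shape = dim(map), pixel_pitch = 1,
                 segment_edges = c(0, 50),
                 segment_maps = list(`0-50` = map),
                 fullrange_map = map, r2_map = map * 0 + 1,
                 mask_reason = ifelse(is.na(map), "cm_fit_failed", "ok"),
                 n_curves = length(map), n_used = sum(!is.na(map)),
                 n_failed = sum(is.na(map)), tip = tip_geometry()),
            class = "stiffness_tomogram")
}

# flat curve with no contact anywhere (fails the pipeline on purpose)
flat_curve <- function(pixel, n = 100) {
  force_curve(z = seq_len(n), force = rep(0, n), setpoint = 150,
              pixel = pixel)
}

# per-pixel zone-mean ordering check used for depth-ordering properties:
# segments 0-10 nm = surface, 10-20 nm = envelope, 20-50 nm = interior
zone_ordered_fraction <- function(tomo) {
  ok <- 0L; n <- 0L
  for (r in seq_len(tomo$grid_shape[1])) for (cc in seq_len(tomo$grid_shape[2])) {
    if (is.na(tomo$mask_reason[r, cc]) || tomo$mask_reason[r, cc] != "ok") next
    segs <- vapply(tomo$segment_maps, function(m) m[r, cc], numeric(1))
    surf <- mean(segs[1:2], na.rm = TRUE)
    env <- mean(segs[3:4], na.rm = TRUE)
    int <- mean(segs[5:10], na.rm = TRUE)
    n <- n + 1L
    if (is.finite(surf) && is.finite(env) && is.finite(int) &&
        surf < env && env < int)
      ok <- ok + 1L
  }
  list(fraction = ok / n, n = n)
}
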