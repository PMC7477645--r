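# Synthetic-data module: layered force-volume generator with embedded
# ground truth, cohort generator with the study's group/genotype structure
# and correlation pattern, and a topography generator.

#' Layered depth profile of a synthetic corneocyte
#'
#' Three mechanical zones under the probe: a soft surface lipid envelope,
#' a cornified envelope of intermediate stiffness, and the stiff
#' keratin-rich interior. Boundaries default to 10 and 20 nm (zones
#' 0--10, 10--20, 20--50 nm). The zone moduli are order-of-magnitude
#' placeholders in the hundreds-of-MPa range; only their ordering
#' (surface <= middle <= deep) is meaningful by default.
#'
#' @param zone_boundaries strictly increasing depths in (0, 50), nm.
#' @param zone_moduli one modulus per zone (length
#'   `length(zone_boundaries) + 1`), MPa.
#' @param pixel_sigma lognormal sigma of the per-pixel modulus scaling
#'   (within-cell heterogeneity).
#' @return an object of class `"depth_profile"`.
#' @export
depth_profile <- function(zone_boundaries = c(10, 20),
                          zone_moduli = c(100, 200, 400),
                          pixel_sigma = 0.1) {
  if (!is.numeric(zone_boundaries) ||
      any(diff(c(0, zone_boundaries, 50)) <= 0))
    cm_abort("'zone_boundaries' must be strictly increasing within (0, 50)",
             "cm_config_error")
  if (!is.numeric(zone_moduli) ||
      length(zone_moduli) != length(zone_boundaries) + 1L ||
      any(zone_moduli <= 0))
    cm_abort("'zone_moduli' needs one positive modulus per zone",
             "cm_config_error")
  stopifnot_scalar(pixel_sigma, "pixel_sigma", 0, Inf)
  structure(list(zone_boundaries = as.numeric(zone_boundaries),
                 zone_moduli = as.numeric(zone_moduli),
                 pixel_sigma = pixel_sigma),
            class = "depth_profile")
}

#' Instrument model for synthetic force curves
#'
#' Acquisition artifacts embedded in generated curves: Gaussian force
#' noise, linear baseline tilt, jitter of the contact position, the piezo
#' sampling step, the force setpoint at which the controller turns
#' around, and optionally a cantilever spring constant (when given, the
#' recorded z axis includes cantilever deflection).
#'
#' @param force_noise_sigma Gaussian force noise SD, nN.
#' @param baseline_tilt linear baseline drift, nN per nm of piezo travel.
#' @param contact_offset_jitter SD of the contact-position jitter, nm.
#' @param sampling_step piezo sampling step, nm.
#' @param setpoint maximum applied force, nN.
#' @param spring_constant cantilever spring constant, nN/nm, or `NULL`
#'   for pre-converted (tip-sample distance) data.
#' @param approach_length pre-contact baseline length, nm.
#' @param max_indentation hard cap on indentation depth, nm.
#' @return an object of class `"instrument_model"`.
#' @export
instrument_model <- function(force_noise_sigma = 0.1, baseline_tilt = 0.002,
                             contact_offset_jitter = 2, sampling_step = 0.1,
                             setpoint = 150, spring_constant = NULL,
                             approach_length = 40, max_indentation = 70) {
  stopifnot_scalar(force_noise_sigma, "force_noise_sigma", 0, Inf)
  stopifnot_scalar(baseline_tilt, "baseline_tilt", -Inf, Inf)
  stopifnot_scalar(contact_offset_jitter, "contact_offset_jitter", 0, Inf)
  stopifnot_scalar(sampling_step, "sampling_step", 0, Inf, open_lower = TRUE)
  stopifnot_scalar(setpoint, "setpoint", 0, Inf, open_lower = TRUE)
  if (!is.null(spring_constant))
    stopifnot_scalar(spring_constant, "spring_constant", 0, Inf,
                     open_lower = TRUE)
  stopifnot_scalar(approach_length, "approach_length", 0, Inf,
                   open_lower = TRUE)
  stopifnot_scalar(max_indentation, "max_indentation", 0, Inf,
                   open_lower = TRUE)
  structure(list(force_noise_sigma = force_noise_sigma,
                 baseline_tilt = baseline_tilt,
                 contact_offset_jitter = contact_offset_jitter,
                 sampling_step = sampling_step, setpoint = setpoint,
                 spring_constant = spring_constant,
                 approach_length = approach_length,
                 max_indentation = max_indentation),
            class = "instrument_model")
}

#' Noise-free force of a layered profile (piecewise C1 forward model)
#'
#' Within each zone the local stiffness acts through
#' \eqn{dF = 2 C \tan\theta \, E(\delta)/(1-\nu^2)\, \delta\, d\delta};
#' integrating across zone boundaries makes \eqn{F(\delta)} continuous
#' with continuous first derivative. A single zone reduces exactly to
#' [hertz_pyramid_force()].
#'
#' @param delta indentation depths, nm (>= 0).
#' @param profile a [depth_profile()].
#' @param tip a [tip_geometry()].
#' @param scale multiplicative factor applied to all zone moduli.
#' @return force in nN.
#' @export
layered_force <- function(delta, profile, tip = tip_geometry(), scale = 1) {
  stopifnot(inherits(profile, "depth_profile"))
  if (any(delta < 0)) cm_abort("'delta' must be >= 0", "cm_domain_error")
  pref <- tip_prefactor(tip)
  lower <- c(0, profile$zone_boundaries)
  upper <- c(profile$zone_boundaries, Inf)
  e <- profile$zone_moduli * scale
  f <- numeric(length(delta))
  for (i in seq_along(e)) {
    hi2 <- pmin(delta, upper[i])^2
    lo2 <- lower[i]^2
    f <- f + pref * e[i] * pmax(hi2 - lo2, 0)
  }
  f
}

# depth at which the noise-free layered force reaches `force`
layered_inverse <- function(force, profile, tip = tip_geometry(), scale = 1) {
  pref <- tip_prefactor(tip)
  lower <- c(0, profile$zone_boundaries)
  e <- profile$zone_moduli * scale
  fb <- layered_force(c(profile$zone_boundaries, Inf), profile, tip, scale)
  fb_lo <- c(0, fb[-length(fb)])
  i <- findInterval(force, c(fb_lo, Inf))
  i <- min(max(i, 1L), length(e))
  sqrt(lower[i]^2 + (force - fb_lo[i]) / (pref * e[i]))
}

#' Generate a synthetic force volume with embedded ground truth
#'
#' Simulates one cell's grid of approach force curves from a layered
#' depth profile and an instrument model: per pixel a lognormal modulus
#' scaling is drawn, the noise-free piecewise force is built, contact
#' offset, baseline tilt and Gaussian noise are embedded, and the curve
#' is truncated where the (noisy) force reaches the setpoint, as a
#' force-triggered controller would.
#'
#' @param profile a [depth_profile()].
#' @param instrument an [instrument_model()].
#' @param grid_shape integer `(rows, cols)`; default 10x10 = 100 curves
#'   (a 10x10 um area at 1 um steps).
#' @param seed integer seed (mandatory; generation is bit-reproducible).
#' @param tip a [tip_geometry()].
#' @param cell_id label stored with the curves.
#' @return an object of class `"force_volume"`: `curves` (list of
#'   [force_curve()]), `truth` (data frame with per-pixel contact_z,
#'   scale and true zone moduli), and the full parameterization
#'   (`profile`, `instrument`, `tip`, `grid_shape`, `seed`) so the
#'   dataset can be regenerated bit-identically from its own metadata.
#' @export
generate_force_volume <- function(profile, instrument = instrument_model(),
                                  grid_shape = c(10, 10), seed,
                                  tip = tip_geometry(), cell_id = "cell") {
  stopifnot(inherits(profile, "depth_profile"),
            inherits(instrument, "instrument_model"))
  if (length(grid_shape) != 2L || any(grid_shape < 1))
    cm_abort("'grid_shape' must be (rows, cols) >= 1", "cm_config_error")
  grid_shape <- as.integer(grid_shape)
  if (missing(seed)) cm_abort("'seed' is mandatory", "cm_config_error")
  step <- instrument$sampling_step
  with_seed(seed, {
    curves <- vector("list", prod(grid_shape))
    truth <- vector("list", prod(grid_shape))
    k <- 0L
    for (r in seq_len(grid_shape[1])) for (cc in seq_len(grid_shape[2])) {
      k <- k + 1L
      scale <- stats::rlnorm(1, 0, profile$pixel_sigma)
      z0 <- instrument$approach_length +
        stats::rnorm(1, 0, instrument$contact_offset_jitter)
      z0 <- max(z0, step * 8)
      d_end <- min(layered_inverse(instrument$setpoint, profile, tip, scale),
                   instrument$max_indentation)
      delta <- seq(0, d_end, by = step)
      f_clean <- layered_force(delta, profile, tip, scale)
      z_pre <- seq(0, z0 - step, by = step)
      z_post <- z0 + delta
      if (!is.null(instrument$spring_constant))
        z_post <- z_post + f_clean / instrument$spring_constant
      z <- c(z_pre, z_post)
      f <- c(numeric(length(z_pre)), f_clean) +
        instrument$baseline_tilt * z +
        stats::rnorm(length(z), 0, instrument$force_noise_sigma)
      # force-triggered turnaround: stop at the first noisy exceedance
      trig <- which(f >= instrument$setpoint)
      if (length(trig)) {
        keep <- trig[1L]
        if (f[keep] > instrument$setpoint * 1.05) keep <- keep - 1L
        z <- z[seq_len(keep)]; f <- f[seq_len(keep)]
      }
      curves[[k]] <- force_curve(z, f, setpoint = instrument$setpoint,
                                 pixel = c(r, cc),
                                 meta = list(cell_id = cell_id))
      truth[[k]] <- data.frame(
        row = r, col = cc, scale = scale, contact_z = z0,
        t(stats::setNames(profile$zone_moduli * scale,
                          paste0("zone", seq_along(profile$zone_moduli)))),
        delta_max = d_end)
    }
    structure(list(curves = curves, truth = do.call(rbind, truth),
                   profile = profile, instrument = instrument, tip = tip,
                   grid_shape = grid_shape, seed = as.integer(seed),
                   cell_id = cell_id),
              class = "force_volume")
  })
}

#' @export
print.force_volume <- function(x, ...) {
  cat(sprintf(
    "Synthetic force volume '%s': %dx%d curves, zones %s MPa, seed %d\n",
    x$cell_id, x$grid_shape[1], x$grid_shape[2],
    paste(x$profile$zone_moduli, collapse = "/"), x$seed))
  invisible(x)
}

#' Effective full-range modulus of a layered profile
#'
#' The apparent modulus the full-range estimator reports on a noise-free
#' curve from this profile (computed by generating a dense noiseless
#' curve and fitting it). Used to scale per-subject profiles so that a
#' subject's target Ea is what the pipeline would measure.
#'
#' @param profile a [depth_profile()].
#' @param tip a [tip_geometry()].
#' @param max_depth fit range, nm.
#' @param step depth sampling, nm.
#' @return effective apparent modulus, MPa.
#' @export
effective_fullrange_modulus <- function(profile, tip = tip_geometry(),
                                        max_depth = 50, step = 0.1) {
  delta <- seq(0, max_depth, by = step)
  ind <- structure(list(delta = delta,
                        force = layered_force(delta, profile, tip),
                        contact_z = 0, contact_index = 1L,
                        pixel = c(1L, 1L), setpoint = Inf),
                   class = "indentation_curve")
  fit_apparent_modulus(ind, tip, max_depth = max_depth)$ea
}

#' Scale a base profile to a target apparent modulus
#'
#' @param ea target full-range apparent modulus, MPa.
#' @param base base [depth_profile()] whose zone ratios are kept.
#' @param tip a [tip_geometry()].
#' @return a [depth_profile()] whose noise-free full-range fit equals `ea`.
#' @export
subject_depth_profile <- function(ea, base = depth_profile(),
                                  tip = tip_geometry()) {
  stopifnot_scalar(ea, "ea", 0, Inf, open_lower = TRUE)
  e0 <- effective_fullrange_modulus(base, tip)
  depth_profile(base$zone_boundaries, base$zone_moduli * ea / e0,
                base$pixel_sigma)
}

#' Configuration of a synthetic study cohort
#'
#' Defaults encode the study design: 20 AD patients (FLG wild-type /
#' heterozygous / homozygous-or-compound = 5/10/5) and 7 healthy controls
#' (5/2/0). NMF is the single latent driver: genotype lowers the NMF mean
#' with allele dose and the patient group carries an additional NMF
#' deficit independent of genotype; corneocyte stiffness rises with NMF
#' (`ea = ea_slope * nmf + noise`) while barrier function deteriorates
#' (`tewl = tewl_intercept - tewl_slope * nmf + noise`); SCORAD is drawn
#' independently of Ea. The TEWL link is calibrated so the default design
#' reproduces group means of 24.7 (patients) and 9.6 (controls)
#' g m-2 h-1; SCORAD is centred on 47.2. NMF and Ea scales are
#' order-of-magnitude choices (no published values): NMF ~ 0.25--1.0
#' mmol per g protein, Ea ~ hundreds of MPa.
#'
#' @param n_patients,n_controls group sizes.
#' @param patient_flg,control_flg named integer vectors `wt/het/hom`
#'   summing to the group sizes.
#' @param nmf_mean list with `control` and `patient` named vectors of
#'   genotype NMF means (mmol/g protein).
#' @param nmf_sd within-stratum NMF SD.
#' @param ea_slope,ea_sd Ea link: MPa per (mmol/g) and residual SD (MPa).
#' @param tewl_intercept,tewl_slope,tewl_sd TEWL link (g m-2 h-1);
#'   `tewl_slope` > 0 so TEWL falls as NMF rises.
#' @param scorad_mean,scorad_sd SCORAD distribution (patients only),
#'   truncated to the scale bound `[0, 103]`.
#' @param scale integer multiplier of all group sizes (for large-sample
#'   property checks).
#' @param seed integer seed (mandatory).
#' @return an object of class `"cohort_sim_config"`.
#' @export
cohort_sim_config <- function(n_patients = 20, n_controls = 7,
                              patient_flg = c(wt = 5, het = 10, hom = 5),
                              control_flg = c(wt = 5, het = 2, hom = 0),
                              nmf_mean = list(
                                control = c(wt = 1.0, het = 0.8, hom = 0.6),
                                patient = c(wt = 0.6, het = 0.45, hom = 0.25)),
                              nmf_sd = 0.15,
                              ea_slope = 400, ea_sd = 40,
                              tewl_intercept = 37.8, tewl_slope = 29.9,
                              tewl_sd = 3,
                              scorad_mean = 47.2, scorad_sd = 15,
                              scale = 1, seed) {
  if (missing(seed)) cm_abort("'seed' is mandatory", "cm_config_error")
  scale <- as.integer(scale)
  stopifnot_scalar(scale, "scale", 1, Inf)
  if (sum(patient_flg) != n_patients || sum(control_flg) != n_controls)
    cm_abort(sprintf(
      "genotype counts must sum to group sizes (patients %d vs %d, controls %d vs %d)",
      sum(patient_flg), n_patients, sum(control_flg), n_controls),
      "cm_config_error")
  if (!all(c("wt", "het", "hom") %in% names(patient_flg)) ||
      !all(c("wt", "het", "hom") %in% names(control_flg)))
    cm_abort("genotype counts need names wt/het/hom", "cm_config_error")
  stopifnot_scalar(ea_slope, "ea_slope", 0, Inf, open_lower = TRUE)
  stopifnot_scalar(tewl_slope, "tewl_slope", 0, Inf, open_lower = TRUE)
  structure(list(n_patients = n_patients, n_controls = n_controls,
                 patient_flg = patient_flg, control_flg = control_flg,
                 nmf_mean = nmf_mean, nmf_sd = nmf_sd,
                 ea_slope = ea_slope, ea_sd = ea_sd,
                 tewl_intercept = tewl_intercept, tewl_slope = tewl_slope,
                 tewl_sd = tewl_sd,
                 scorad_mean = scorad_mean, scorad_sd = scorad_sd,
                 scale = scale, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Generate a synthetic subject cohort
#'
#' One row per subject with group, FLG genotype, NMF, TEWL, SCORAD
#' (patients only; `NA` for controls) and the latent true apparent
#' modulus `ea`. The full configuration (including the seed) is attached
#' as attribute `"config"`, so the table regenerates bit-identically.
#'
#' @param config a [cohort_sim_config()].
#' @return data frame of class `"cohort"`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  flg_levels <- c("WT", "het", "hom_or_compound")
  rows <- rbind(
    data.frame(group = "AD",
               flg = rep(flg_levels,
                         times = config$patient_flg[c("wt", "het", "hom")] *
                           config$scale)),
    data.frame(group = "control",
               flg = rep(flg_levels,
                         times = config$control_flg[c("wt", "het", "hom")] *
                           config$scale)))
  n <- nrow(rows)
  with_seed(config$seed, {
    key <- ifelse(rows$group == "AD", "patient", "control")
    gkey <- c(WT = "wt", het = "het", hom_or_compound = "hom")[rows$flg]
    mu <- mapply(function(g, f) config$nmf_mean[[g]][[f]], key, gkey)
    nmf <- pmax(stats::rnorm(n, mu, config$nmf_sd), 0)
    ea <- pmax(config$ea_slope * nmf + stats::rnorm(n, 0, config$ea_sd), 1)
    tewl <- pmax(config$tewl_intercept - config$tewl_slope * nmf +
                   stats::rnorm(n, 0, config$tewl_sd), 1)
    scorad <- ifelse(rows$group == "AD",
                     pmin(pmax(stats::rnorm(n, config$scorad_mean,
                                            config$scorad_sd), 0), 103),
                     NA_real_)
    id <- character(n)
    id[rows$group == "AD"] <- sprintf("AD%03d", seq_len(sum(rows$group == "AD")))
    id[rows$group == "control"] <-
      sprintf("C%03d", seq_len(sum(rows$group == "control")))
    out <- data.frame(subject_id = id, group = rows$group, flg = rows$flg,
                      nmf = nmf, tewl = tewl, scorad = scorad, ea = ea,
                      stringsAsFactors = FALSE)
    attr(out, "config") <- config
    class(out) <- c("cohort", "data.frame")
    out
  })
}

#' Generate a synthetic corneocyte surface topography
#'
#' A smooth correlated-noise base surface; for the AD group,
#' Poisson-scattered dome-shaped micro-protrusions are added, emulating
#' the surface alteration seen on patient corneocytes. For rendering and
#' fixtures only; topography is never analysed quantitatively.
#'
#' @param group `"control"` or `"AD"`.
#' @param grid_um image side length, um.
#' @param n samples per side (>= 64).
#' @param seed integer seed.
#' @param protrusion_density protrusions per um^2 (AD default 1.5;
#'   controls 0).
#' @param protrusion_height mean dome height, nm.
#' @param protrusion_radius dome radius, um.
#' @param base_amplitude SD of the base surface, nm.
#' @param base_corr_length correlation length of the base surface, um.
#' @return matrix of heights (nm) with attribute `"params"`.
#' @export
generate_topography <- function(group = c("control", "AD"), grid_um = 10,
                                n = 128, seed,
                                protrusion_density = NULL,
                                protrusion_height = 80,
                                protrusion_radius = 0.25,
                                base_amplitude = 30,
                                base_corr_length = 1) {
  group <- match.arg(group)
  if (n < 64) cm_abort("'n' must be >= 64 samples per side", "cm_config_error")
  if (missing(seed)) cm_abort("'seed' is mandatory", "cm_config_error")
  if (is.null(protrusion_density))
    protrusion_density <- if (group == "AD") 1.5 else 0
  with_seed(seed, {
    # correlated base surface: white noise smoothed by a Gaussian kernel
    # via circular convolution in Fourier space
    w <- matrix(stats::rnorm(n * n), n, n)
    fx <- (seq_len(n) - 1); fx <- pmin(fx, n - fx) / n * grid_um
    d2 <- outer(fx^2, fx^2, "+")
    kern <- exp(-d2 / (2 * (base_corr_length / 2)^2))
    sm <- Re(stats::fft(stats::fft(w) * stats::fft(kern / sum(kern)),
                        inverse = TRUE)) / (n * n)
    base <- sm / stats::sd(sm) * base_amplitude
    h <- base
    n_prot <- stats::rpois(1, protrusion_density * grid_um^2)
    if (n_prot > 0) {
      xs <- stats::runif(n_prot, 0, grid_um)
      ys <- stats::runif(n_prot, 0, grid_um)
      hts <- stats::rlnorm(n_prot, log(protrusion_height), 0.3)
      ax <- (seq_len(n) - 0.5) / n * grid_um
      for (i in seq_len(n_prot)) {
        r2 <- outer((ax - ys[i])^2, (ax - xs[i])^2, "+")
        h <- h + hts[i] * exp(-r2 / (2 * protrusion_radius^2))
      }
    }
    attr(h, "params") <- list(group = group, grid_um = grid_um, n = n,
                              seed = as.integer(seed),
                              protrusion_density = protrusion_density,
                              protrusion_height = protrusion_height,
                              protrusion_radius = protrusion_radius,
                              base_amplitude = base_amplitude,
                              base_corr_length = base_corr_length,
                              n_protrusions = n_prot)
    h
  })
}

#' Count prominent local maxima of a height map
#'
#' Interior samples exceeding all 8 neighbours and lying above the given
#' height quantile; a crude micro-protrusion count for generated maps.
#'
#' @param map height matrix, nm.
#' @param probs height quantile defining "prominent".
#' @return integer count.
#' @export
count_local_maxima <- function(map, probs = 0.99) {
  thr <- stats::quantile(map, probs)
  nr <- nrow(map); nc <- ncol(map)
  inner <- map[2:(nr - 1), 2:(nc - 1)]
  is_max <- inner > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max &
      inner > map[2:(nr - 1) + dr, 2:(nc - 1) + dc]
  }
  sum(is_max)
}
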