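# Synthetic-data module: layered curve generator, cohort generator,
# topography generator.

test_that("a single-zone profile reproduces the closed-form contact law", {
  tip <- tip_geometry()
  prof <- homogeneous_profile(275)
  delta <- seq(0, 60, by = 0.5)
  expect_equal(layered_force(delta, prof, tip),
               hertz_pyramid_force(275, delta, tip), tolerance = 1e-12)
  fv <- generate_force_volume(prof, noiseless_instrument(),
                              grid_shape = c(1, 1), seed = 8, tip = tip)
  cu <- fv$curves[[1]]
  post <- cu$z >= fv$truth$contact_z[1]
  expect_equal(cu$force[post],
               hertz_pyramid_force(275, cu$z[post] - fv$truth$contact_z[1],
                                   tip),
               tolerance = 1e-10)
})

test_that("the layered forward model is continuous with the stated slope", {
  prof <- depth_profile(c(10, 20), c(100, 200, 400))
  tip <- tip_geometry()
  pref <- corneomech:::tip_prefactor(tip)
  h <- 1e-6
  for (b in prof$zone_boundaries) {
    expect_equal(layered_force(b - h, prof, tip),
                 layered_force(b + h, prof, tip), tolerance = 1e-6)
  }
  # within each zone dF/ddelta = 2 * pref * E_zone * delta
  for (d in c(5, 15, 35)) {
    e_zone <- prof$zone_moduli[findInterval(d, c(0, prof$zone_boundaries))]
    num <- (layered_force(d + h, prof, tip) -
              layered_force(d - h, prof, tip)) / (2 * h)
    expect_equal(num, 2 * pref * e_zone * d, tolerance = 1e-6)
  }
})

test_that("generation is bit-identical for a fixed seed and its metadata", {
  fv1 <- generate_force_volume(depth_profile(), instrument_model(),
                               c(3, 3), seed = 123)
  fv2 <- generate_force_volume(depth_profile(), instrument_model(),
                               c(3, 3), seed = 123)
  expect_identical(fv1$curves, fv2$curves)
  expect_identical(fv1$truth, fv2$truth)
  # regeneration purely from the object's own stored parameterization
  fv3 <- generate_force_volume(fv1$profile, fv1$instrument, fv1$grid_shape,
                               seed = fv1$seed, tip = fv1$tip,
                               cell_id = fv1$cell_id)
  expect_identical(fv1$curves, fv3$curves)
  # different seed differs
  fv4 <- generate_force_volume(depth_profile(), instrument_model(),
                               c(3, 3), seed = 124)
  expect_false(identical(fv1$curves, fv4$curves))
})

test_that("generated curves respect the acquisition invariants", {
  fv <- generate_force_volume(depth_profile(), instrument_model(),
                              c(10, 10), seed = 99)
  expect_length(fv$curves, 100)
  for (cu in fv$curves) {
    expect_true(all(diff(cu$z) > 0))
    expect_lte(max(cu$force), cu$setpoint * 1.05)
  }
})

test_that("zone moduli are recovered from noisy pixels via the median", {
  tip <- tip_geometry()
  prof <- depth_profile()  # 100/200/400 MPa
  fv <- generate_force_volume(prof,
                              instrument_model(force_noise_sigma = 3),
                              c(10, 10), seed = 17, tip = tip)
  zones <- rbind(c(0, 10), c(10, 20), c(20, 50))
  est <- vapply(seq_along(fv$curves), function(i) {
    cu <- correct_baseline(fv$curves[[i]])
    ind <- to_indentation(cu, fv$truth$contact_z[i])
    vapply(1:3, function(k)
      tryCatch(fit_segment(ind, zones[k, 1], zones[k, 2], tip)$ea /
                 fv$truth$scale[i],
               corneomech_error = function(e) NA_real_), numeric(1))
  }, numeric(3))
  med <- apply(est, 1, median, na.rm = TRUE)
  expect_lte(max(abs(med - prof$zone_moduli) / prof$zone_moduli), 0.10)
})

test_that("cohort defaults encode the study design", {
  co <- generate_cohort(cohort_sim_config(seed = 1))
  expect_identical(nrow(co), 27L)
  expect_identical(sum(co$group == "AD"), 20L)
  expect_identical(sum(co$group == "control"), 7L)
  tab <- table(co$group, co$flg)
  expect_identical(unname(tab["AD", c("WT", "het", "hom_or_compound")]),
                   c(5L, 10L, 5L))
  expect_identical(unname(tab["control", c("WT", "het", "hom_or_compound")]),
                   c(5L, 2L, 0L))
  # SCORAD only for patients; marginals within physical bounds
  expect_true(all(is.na(co$scorad[co$group == "control"])))
  expect_true(all(!is.na(co$scorad[co$group == "AD"])))
  expect_true(all(co$nmf >= 0))
  expect_true(all(co$tewl > 0))
  expect_true(all(co$scorad[co$group == "AD"] >= 0 &
                    co$scorad[co$group == "AD"] <= 103))
  # reproducible from its attached config
  co2 <- generate_cohort(attr(co, "config"))
  expect_identical(as.data.frame(co), as.data.frame(co2))
  # genotype counts must sum to the group sizes
  expect_error(cohort_sim_config(patient_flg = c(wt = 5, het = 10, hom = 4),
                                 seed = 1),
               class = "cm_config_error")
})

test_that("a x50 cohort shows the designed correlation pattern", {
  co <- generate_cohort(cohort_sim_config(scale = 50, seed = 2))
  expect_identical(nrow(co), 27L * 50L)
  sm <- spearman_matrix(co)
  expect_gt(sm$rho["ea", "nmf"], 0.5)
  expect_lt(sm$rho["ea", "tewl"], -0.5)
  expect_lt(sm$rho["nmf", "tewl"], -0.5)
  expect_lt(abs(sm$rho["ea", "scorad"]), 0.1)
  expect_lt(mean(co$ea[co$group == "AD"]), mean(co$ea[co$group == "control"]))
})

test_that("subject profiles hit a target apparent modulus", {
  tip <- tip_geometry()
  for (target in c(80, 300)) {
    prof <- subject_depth_profile(target, tip = tip)
    expect_equal(effective_fullrange_modulus(prof, tip), target,
                 tolerance = 1e-6)
    # zone ratios preserved
    expect_equal(prof$zone_moduli / prof$zone_moduli[1],
                 c(1, 2, 4), tolerance = 1e-9)
  }
})

test_that("topography maps are seeded and protrusions separate the groups", {
  m1 <- generate_topography("AD", seed = 5)
  m2 <- generate_topography("AD", seed = 5)
  expect_identical(m1, m2)
  expect_identical(dim(m1), c(128L, 128L))
  # zero protrusion density makes the AD surface identical to control
  a0 <- generate_topography("AD", seed = 6, protrusion_density = 0)
  c0 <- generate_topography("control", seed = 6)
  expect_equal(unclass(a0)[, ], unclass(c0)[, ], tolerance = 1e-12)
  # AD maps carry more prominent local maxima across seeds
  wins <- vapply(1:5, function(s) {
    count_local_maxima(generate_topography("AD", seed = s)) >
      count_local_maxima(generate_topography("control", seed = s))
  }, logical(1))
  expect_true(all(wins))
})
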