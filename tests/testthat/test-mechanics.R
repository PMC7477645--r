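# Contact-mechanics core: forward model, preprocessing, contact
# detection, indentation conversion, windowed fits.

test_that("forward model obeys the quadratic contact law", {
  tip <- tip_geometry()
  expect_identical(hertz_pyramid_force(123, 0, tip), 0)
  # doubling depth quadruples force, exactly
  for (d in c(1, 7.5, 33)) {
    expect_equal(hertz_pyramid_force(250, 2 * d, tip) /
                   hertz_pyramid_force(250, d, tip), 4)
  }
  # frozen closed-form evaluation: (2/pi) tan(20 deg) (1000/0.75) 50^2 1e-3
  expect_equal(hertz_pyramid_force(1000, 50, tip_geometry(half_angle = 20,
                                                          poisson_ratio = 0.5,
                                                          geometry_coefficient = 2 / pi)),
               772.3688, tolerance = 1e-6)
  expect_error(hertz_pyramid_force(-1, 10, tip), class = "cm_domain_error")
  expect_error(hertz_pyramid_force(100, -5, tip), class = "cm_domain_error")
})

test_that("forward model is strictly convex in depth", {
  tip <- tip_geometry(half_angle = 35, geometry_coefficient = 0.7453)
  delta <- seq(0.5, 60, by = 0.5)
  f <- hertz_pyramid_force(80, delta, tip)
  d2 <- diff(f, differences = 2)
  expect_true(all(d2 > 0))
})

test_that("baseline correction removes offsets and tilts", {
  z <- seq(0, 99)
  # constant offset, no contact inside the window
  cu <- force_curve(z, rep(0.5, 100), setpoint = 150, pixel = c(1L, 1L))
  cor1 <- correct_baseline(cu, 0.3)
  expect_equal(mean(cor1$force[1:30]), 0, tolerance = 1e-12)
  # linear tilt
  cu2 <- force_curve(z, 0.2 + 0.01 * z, setpoint = 150, pixel = c(1L, 1L))
  cor2 <- correct_baseline(cu2, 0.3)
  slope <- coef(lm(cor2$force[1:30] ~ z[1:30]))[2]
  expect_equal(unname(slope), 0, tolerance = 1e-12)
  # too-short baseline window
  expect_error(correct_baseline(cu, 0.03), class = "cm_data_error")
})

test_that("corrected generator curves match the noise-free forward model", {
  tip <- tip_geometry()
  sigma <- 0.05
  fv <- generate_force_volume(
    homogeneous_profile(200),
    instrument_model(force_noise_sigma = sigma, baseline_tilt = 0.01,
                     contact_offset_jitter = 0),
    grid_shape = c(1, 1), seed = 5, tip = tip)
  cu <- correct_baseline(fv$curves[[1]])
  post <- cu$z >= fv$truth$contact_z[1]
  truth <- hertz_pyramid_force(200, cu$z[post] - fv$truth$contact_z[1], tip)
  rmsd <- sqrt(mean((cu$force[post] - truth)^2))
  expect_lt(rmsd, 2 * sigma)
})

test_that("contact detection finds the generator contact point", {
  fv <- generate_force_volume(homogeneous_profile(200),
                              noiseless_instrument(sampling_step = 1),
                              grid_shape = c(1, 1), seed = 2)
  cu <- correct_baseline(fv$curves[[1]])
  cp <- detect_contact_point(cu, noise_sigma = 1e-9)
  expect_lte(abs(cp$contact_z - fv$truth$contact_z[1]), 1)
  # flat curve: no contact anywhere
  flat <- correct_baseline(flat_curve(c(1L, 1L)))
  expect_error(detect_contact_point(flat, noise_sigma = 0.1),
               class = "cm_no_contact")
})

test_that("contact detection stays within 3 samples at 0.1 nN noise", {
  fv <- generate_force_volume(
    homogeneous_profile(200),
    instrument_model(force_noise_sigma = 0.1, sampling_step = 1,
                     contact_offset_jitter = 2),
    grid_shape = c(10, 20), seed = 19)
  err <- vapply(seq_along(fv$curves), function(i) {
    cu <- correct_baseline(fv$curves[[i]])
    cp <- detect_contact_point(cu, noise_sigma = 0.1)
    abs(cp$contact_z - fv$truth$contact_z[i])
  }, numeric(1))
  expect_gte(mean(err <= 3), 0.95)
  expect_length(err, 200)
})

test_that("indentation conversion handles deflection and recovers depth", {
  # identity mapping without spring constant
  z <- seq(0, 99)
  f <- pmax(z - 40, 0)^2 * 0.001
  cu <- force_curve(z, f, setpoint = 150, pixel = c(1L, 1L))
  ind <- to_indentation(cu, contact_z = 40)
  expect_equal(ind$delta, z[z >= 40] - 40)
  expect_identical(ind$delta[1], 0)
  # finite spring constant shrinks the depth range
  ind_k <- to_indentation(cu, contact_z = 40, spring_constant = 0.1)
  expect_lt(max(ind_k$delta), max(ind$delta))
  # generator with known spring constant: depth recovered within 1%
  k <- 40
  fv <- generate_force_volume(homogeneous_profile(300),
                              noiseless_instrument(spring_constant = k),
                              grid_shape = c(1, 1), seed = 3)
  cu2 <- correct_baseline(fv$curves[[1]])
  ind2 <- to_indentation(cu2, fv$truth$contact_z[1], spring_constant = k)
  d_true <- seq(0, fv$truth$delta_max[1], by = 0.1)
  expect_equal(max(ind2$delta), max(d_true), tolerance = 0.01)
  fit <- fit_apparent_modulus(ind2, tip_geometry())
  expect_equal(fit$ea, 300, tolerance = 0.01)
  # too few post-contact samples
  expect_error(to_indentation(cu, contact_z = 97),
               class = "cm_insufficient_indentation")
})

test_that("windowed fits invert the forward model exactly on clean data", {
  for (e in c(15, 120, 850)) {
    for (tip in list(tip_geometry(),
                     tip_geometry(half_angle = 35, poisson_ratio = 0.3,
                                  geometry_coefficient = 0.7453))) {
      ind <- clean_indentation(e, tip)
      expect_equal(fit_apparent_modulus(ind, tip)$ea, e,
                   tolerance = 1e-6)
      for (lo in c(0, 15, 45))
        expect_equal(fit_segment(ind, lo, lo + 5, tip)$ea, e,
                     tolerance = 1e-6)
    }
  }
})

test_that("fitted modulus scales with force and with 1 - nu^2", {
  tip <- tip_geometry(poisson_ratio = 0)
  ind <- clean_indentation(100, tip)
  base <- fit_apparent_modulus(ind, tip)$ea
  for (s in c(0.25, 3)) {
    ind_s <- ind
    ind_s$force <- ind$force * s
    expect_equal(fit_apparent_modulus(ind_s, tip)$ea, base * s,
                 tolerance = 1e-9)
  }
  # nu = 0.5 divides (1 - nu^2) by 4/3 relative to nu = 0
  tip2 <- tip_geometry(poisson_ratio = 0.5)
  expect_equal(fit_apparent_modulus(ind, tip2)$ea, base * 0.75,
               tolerance = 1e-9)
})

test_that("segment fit reports underfill and failure conditions", {
  ind <- clean_indentation(100, step = 4, max_depth = 60)
  # only two samples fall into [0, 5]
  expect_error(fit_segment(ind, 0, 5, tip_geometry()),
               class = "cm_segment_underfilled")
  # decreasing force gives a non-positive modulus
  bad <- structure(list(delta = seq(0, 50, by = 1),
                        force = seq(10, 0, length.out = 51),
                        contact_z = 0, contact_index = 1L,
                        pixel = c(1L, 1L), setpoint = Inf),
                   class = "indentation_curve")
  expect_error(fit_segment(bad, 0, 50, tip_geometry()),
               class = "cm_fit_failed")
})

test_that("three-zone curves order segment moduli and bound the full fit", {
  tip <- tip_geometry()
  prof <- depth_profile(c(10, 20), c(100, 200, 400), pixel_sigma = 0)
  fv <- generate_force_volume(prof, noiseless_instrument(),
                              grid_shape = c(1, 1), seed = 4, tip = tip)
  cu <- correct_baseline(fv$curves[[1]])
  ind <- to_indentation(cu, fv$truth$contact_z[1])
  e_surface <- fit_segment(ind, 0, 10, tip)$ea
  e_env <- fit_segment(ind, 10, 20, tip)$ea
  e_int <- fit_segment(ind, 20, 50, tip)$ea
  expect_lt(e_surface, e_env)
  expect_lt(e_env, e_int)
  full <- fit_apparent_modulus(ind, tip)$ea
  expect_gt(full, min(prof$zone_moduli))
  expect_lt(full, max(prof$zone_moduli))
})

test_that("truncated curves are fitted over their available range", {
  ind <- clean_indentation(300, max_depth = 30)
  fit <- fit_apparent_modulus(ind, tip_geometry(), max_depth = 50)
  expect_equal(fit$ea, 300, tolerance = 1e-6)
  expect_equal(fit$depth_effective[2], 30)
  expect_identical(fit$depth_hi, 50)
})

test_that("full-range fit is robust to 2% setpoint force noise", {
  tip <- tip_geometry()
  sigma <- 0.02 * 150
  fv <- generate_force_volume(
    homogeneous_profile(150),
    instrument_model(force_noise_sigma = sigma, contact_offset_jitter = 0),
    grid_shape = c(20, 25), seed = 77, tip = tip)
  rel_err <- vapply(seq_along(fv$curves), function(i) {
    cu <- correct_baseline(fv$curves[[i]])
    ind <- to_indentation(cu, fv$truth$contact_z[i])
    abs(fit_apparent_modulus(ind, tip)$ea - 150) / 150
  }, numeric(1))
  expect_length(rel_err, 500)
  expect_lte(median(rel_err), 0.05)
})

test_that("hertz_fit methods are mutually consistent", {
  ind <- clean_indentation(220)
  fit <- fit_apparent_modulus(ind, tip_geometry())
  expect_named(coef(fit), c("ea", "f_offset"))
  expect_equal(unname(coef(fit)["ea"]), 220, tolerance = 1e-6)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-8)
  expect_equal(predict(fit, newdata = data.frame(delta = 50)),
               hertz_pyramid_force(220, 50, tip_geometry()) + fit$f_offset,
               tolerance = 1e-6)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(length(fit$delta), 4L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1))
})
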