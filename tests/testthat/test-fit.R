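test_that("thickness extrapolation reproduces hand arithmetic", {
  seg <- list(slope_m = -0.7096, intercept_c0 = 313.8)
  bulk <- list(c_bulk = 240)
  expect_equal(cbl_thickness(seg, bulk), (240 - 313.8) / (-0.7096))
  expect_equal(cbl_thickness(seg, bulk), 104.0, tolerance = 1e-3)
  # degenerate: intercept at bulk -> zero thickness -> error
  expect_error(cbl_thickness(list(slope_m = -0.5, intercept_c0 = 240),
                             bulk), "inconsistent")
  # slope pointing away from bulk -> negative delta -> error
  expect_error(cbl_thickness(list(slope_m = 0.5, intercept_c0 = 313.8),
                             bulk), "inconsistent")
  expect_error(cbl_thickness(list(slope_m = 0, intercept_c0 = 300),
                             bulk), "zero slope")
})

test_that("Fick flux arithmetic and sign convention", {
  k <- cbl_constants()
  expect_equal(o2_flux(list(slope_m = 0), k), 0)
  expect_equal(o2_flux(list(slope_m = -0.7096), k),
               2.29e-5 * 0.7096 * 3.6e4)
  expect_equal(o2_flux(list(slope_m = -0.7096), k), 0.585,
               tolerance = 1e-3)
  expect_equal(o2_flux(list(slope_m = 0.44), k), -0.363,
               tolerance = 1e-2)
  expect_error(o2_flux(list(slope_m = -0.5), k, analyte = "pH"), "O2")
})

test_that("full pipeline recovers a noiseless simple profile exactly", {
  p <- synth_profile(synth_spec(c_bulk = 240, delta_true = 104,
                                surface_offset = 73.8, noise_sigma = 0))
  fit <- cbl_fit(p)
  expect_equal(fit$profile_class, "simple")
  expect_equal(fit$traits$thickness_um, 104, tolerance = 1e-6)
  expect_equal(fit$traits$surface_delta, 73.8, tolerance = 1e-9)
  expect_equal(fit$traits$flux, 2.29e-5 * (73.8 / 104) * 3.6e4,
               tolerance = 1e-9)
  expect_equal(fit$traits$flux, 0.585, tolerance = 1e-3)
})

test_that("complex profiles take thickness and flux from the upper gradient", {
  spec <- synth_spec(c_bulk = 240, delta_true = 150, surface_offset = 80,
                     profile_class = "complex", upper_fraction = 0.5,
                     lower_slope_ratio = 3, noise_sigma = 0)
  p <- synth_profile(spec)
  truth <- attr(p, "truth")
  fit <- cbl_fit(p)
  expect_equal(fit$profile_class, "complex")
  expect_equal(unname(coef(fit)["slope"]), truth$slope_upper,
               tolerance = 1e-6)
  expect_equal(fit$traits$flux, truth$flux_true, tolerance = 1e-6)
  expect_equal(fit$traits$thickness_um, 150, tolerance = 1)
  # and NOT from the (steeper) lower gradient
  lower_flux <- -cbl_constants()$D_O2 * truth$slope_lower * 3.6e4
  expect_gt(abs(fit$traits$flux - lower_flux), abs(fit$traits$flux))
})

test_that("flat profiles are undetectable with zero surface change", {
  p <- synth_profile(synth_spec(profile_class = "flat", noise_sigma = 0))
  fit <- cbl_fit(p)
  expect_equal(fit$profile_class, "undetectable")
  expect_true(is.na(fit$traits$thickness_um))
  expect_true(is.na(fit$traits$flux))
  expect_equal(fit$traits$surface_delta, 0)
})

test_that("flux-thickness unit identity holds to 1e-9 relative", {
  for (seed in 1:10) {
    p <- synth_profile(synth_spec(c_bulk = 240,
                                  delta_true = 60 + 30 * seed,
                                  surface_offset = 30 + 7 * seed,
                                  noise_sigma = 0.5, seed = seed))
    fit <- cbl_fit(p)
    if (fit$profile_class == "undetectable") next
    d <- fit$traits$thickness_um
    dc <- abs(fit$bulk$c_bulk - fit$chosen_segment$intercept_c0)
    expect_equal(abs(fit$traits$flux),
                 cbl_constants()$D_O2 * dc / d * 3.6e4,
                 tolerance = 1e-9)
  }
})

test_that("scaling O2 values scales flux and delta but not thickness", {
  p <- synth_profile(synth_spec(c_bulk = 200, delta_true = 130,
                                surface_offset = 55, noise_sigma = 0))
  a <- 1.7
  p2 <- cbl_profile(p$z, a * p$value, "O2", p$meta)
  f1 <- cbl_fit(p); f2 <- cbl_fit(p2)
  expect_equal(f2$traits$thickness_um, f1$traits$thickness_um,
               tolerance = 1e-9)
  expect_equal(f2$traits$flux, a * f1$traits$flux, tolerance = 1e-9)
  expect_equal(f2$traits$surface_delta, a * f1$traits$surface_delta,
               tolerance = 1e-9)
})

test_that("light and dark profiles obey the efflux sign convention", {
  for (seed in 1:8) {
    off <- ifelse(seed %% 2 == 0, 1, -1) * (30 + 10 * seed %/% 2)
    p <- synth_profile(synth_spec(c_bulk = 240, delta_true = 150,
                                  surface_offset = off,
                                  noise_sigma = 0.3, seed = seed))
    fit <- cbl_fit(p)
    expect_equal(sign(fit$traits$flux), sign(off))
    expect_equal(sign(fit$traits$surface_delta), sign(off))
  }
})

test_that("batch recovery of thickness is accurate at moderate noise", {
  set.seed(101)
  specs <- lapply(1:50, function(i)
    synth_spec(c_bulk = 240, delta_true = runif(1, 70, 300),
               surface_offset = runif(1, 30, 110), noise_sigma = 0.5,
               seed = 1000 + i))
  err <- vapply(specs, function(s) {
    fit <- cbl_fit(synth_profile(s))
    abs(fit$traits$thickness_um - s$delta_true) / s$delta_true
  }, 0)
  expect_lte(median(err, na.rm = TRUE), 0.05)
})

test_that("pH profiles are fitted on [H+] and report total-scale deltas", {
  # flat pH profile: undetectable, zero delta pH
  zz <- seq(0, 500, 50)
  pf <- cbl_profile(zz, rep(8.05, length(zz)), "pH",
                    meta = list(ph_scale = "total"))
  fit <- cbl_fit(pf)
  expect_equal(fit$profile_class, "undetectable")
  expect_equal(fit$traits$delta_ph, 0)
  # ramped [H+] profile recovers thickness in H+ space
  h_bulk <- 10^-8.0
  spec <- synth_spec(analyte = "pH", c_bulk = 8.0, delta_true = 120,
                     surface_offset = -0.4 * h_bulk, noise_sigma = 0)
  p <- synth_profile(spec)
  fit2 <- cbl_fit(p)
  expect_equal(fit2$traits$thickness_um, 120, tolerance = 1e-3)
  expect_gt(fit2$traits$delta_ph, 0)     # lower [H+] = higher pH
  expect_true(is.na(fit2$traits$flux))   # flux is O2-only
  expect_equal(fit2$traits$delta_h, -0.4 * h_bulk, tolerance = 1e-6)
})

test_that("NBS-scale pH profiles are converted before fitting", {
  h_bulk <- 10^-8.0
  spec <- synth_spec(analyte = "pH", c_bulk = 8.0, delta_true = 120,
                     surface_offset = -0.3 * h_bulk, noise_sigma = 0)
  p_tot <- synth_profile(spec)
  p_nbs <- cbl_profile(p_tot$z,
                       p_tot$value - ph_scale_offset(35, 26),
                       "pH", meta = list(ph_scale = "NBS"))
  f_tot <- cbl_fit(p_tot)
  f_nbs <- cbl_fit(p_nbs)
  # delta pH is scale-robust; thickness matches
  expect_equal(f_nbs$traits$delta_ph, f_tot$traits$delta_ph,
               tolerance = 1e-9)
  expect_equal(f_nbs$traits$thickness_um, f_tot$traits$thickness_um,
               tolerance = 1e-6)
})

test_that("model methods are mutually consistent", {
  p <- synth_profile(synth_spec(c_bulk = 240, delta_true = 150,
                                surface_offset = 70, noise_sigma = 0.5,
                                seed = 3))
  fit <- cbl_fit(p)
  expect_equal(fitted(fit) + residuals(fit), fit$y)
  expect_equal(predict(fit, newdata = 1e4), fit$bulk$c_bulk)
  expect_named(coef(fit), c("intercept", "slope"))
  sims <- simulate(fit, nsim = 3, seed = 9)
  expect_length(sims, 3)
  expect_length(sims[[1]], length(p$z))
  # seeded simulation is reproducible and does not disturb the global RNG
  set.seed(42); before <- runif(1)
  set.seed(42)
  s1 <- simulate(fit, nsim = 1, seed = 7)
  expect_equal(runif(1), before)
  s2 <- simulate(fit, nsim = 1, seed = 7)
  expect_equal(s1, s2)
  expect_output(print(summary(fit)), "segments")
})

test_that("extract_traits returns one metadata-joined row per profile", {
  profiles <- list(make_test_profile("F1", light = "light"),
                   make_test_profile("F2", light = "dark", offset = -40))
  tab <- extract_traits(profiles)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("species", "flow_cm_s", "light", "thickness_um",
                    "flux", "profile_class") %in% names(tab)))
  expect_equal(tab$fragment_id, c("F1", "F2"))
  expect_true(tab$flux[1] > 0 && tab$flux[2] < 0)
})
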