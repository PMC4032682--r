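test_that("doppler velocity follows the frequency-shift relation", {
  cfg <- acoustic_config(
    sound_speed = 1540, center_frequency = 7.5e6,
    doppler_angle = 60
  )
  expect_equal(doppler_velocity(0, cfg), 0)
  expect_equal(doppler_velocity(4870, cfg), 0.9999733, tolerance = 1e-6)
  # linearity in the shift
  expect_equal(doppler_velocity(2 * 4870, cfg), 2 * doppler_velocity(4870, cfg))
  expect_error(acoustic_config(doppler_angle = 90), "90")
})

test_that("resistive index matches direct arithmetic and stays in [0, 1)", {
  expect_equal(resistive_index(50, 50), 0)
  expect_equal(resistive_index(103.20, 37.00), 0.6414729, tolerance = 1e-6)
  expect_equal(resistive_index(25.61, 7.86), 0.6930886, tolerance = 1e-6)
  # unit-free: cm/s and m/s give the same index
  expect_equal(resistive_index(1.032, 0.37), resistive_index(103.2, 37.0))
  expect_error(resistive_index(-1, 0.5))
  expect_error(resistive_index(10, 11), "swapped")
  # property: in [0, 1) for random valid inputs
  set.seed(7)
  v_p <- runif(200, 1, 200)
  v_m <- runif(200) * v_p
  res <- resistive_index(v_p, v_m)
  expect_true(all(res >= 0 & res < 1))
})

test_that("pressure drop reproduces the simplified Bernoulli relation", {
  expect_equal(pressure_drop(0), 0)
  expect_equal(round(pressure_drop(1.0320), 2), 4.26)
  expect_equal(round(pressure_drop(0.7221), 2), 2.09)
  expect_error(pressure_drop(-0.1))
})

test_that("Reynolds, Womersley and Strouhal numbers use the standard forms", {
  thin <- fluid_properties(density = 1055, viscosity = 0.0035)
  expect_equal(reynolds_number(1.0, 0.005, thin), 1507.1429, tolerance = 1e-6)
  # linear in diameter
  expect_equal(
    reynolds_number(1.0, 0.0025, thin),
    reynolds_number(1.0, 0.005, thin) / 2
  )
  expect_equal(womersley_number(0.005, 1.0, thin), 3.4405047,
    tolerance = 1e-6
  )
  # alpha = 1 when the radius is sqrt(nu / (2 pi f))
  r1 <- sqrt(thin$nu / (2 * pi * 1.2))
  expect_equal(womersley_number(2 * r1, 1.2, thin), 1)
  expect_equal(strouhal_number(1, 1, 1), 1)
  expect_equal(strouhal_number(1.25, 0.005, 1.0), 0.00625)
  expect_equal(strouhal_number(1, 0.005, 0.5), 2 * strouhal_number(1, 0.005, 1))
  expect_error(reynolds_number(0, 0.005, thin))
})

test_that("critical peak Reynolds power law has coefficient 169 and the right monotonicity", {
  expect_identical(critical_peak_reynolds(1, 1), 169)
  expect_equal(critical_peak_reynolds(2, 0.5), 362.2594, tolerance = 1e-6)
  st <- c(0.1, 1, 10, 100)
  expect_true(all(diff(critical_peak_reynolds(1, st)) < 0))
  alpha <- c(0.5, 1, 2, 4)
  expect_true(all(diff(critical_peak_reynolds(alpha, 1)) > 0))
})

test_that("supracritical Reynolds number is the absolute transition distance", {
  expect_equal(supracritical_reynolds(169, 169), 0)
  expect_equal(supracritical_reynolds(1507.1, 169), 1338.1)
  expect_equal(supracritical_reynolds(100, 169), 69)
})

test_that("hydraulic diameter recovers known duct identities and converges for polygons", {
  expect_equal(hydraulic_diameter(1, rep(1, 4)), 1) # unit square
  expect_equal(hydraulic_diameter(pi, rep(2 * pi / 64, 64)), 2) # circle D = 2
  # inscribed n-gon converges monotonically to the circle diameter
  dh <- vapply(c(8, 16, 64), function(n) {
    g <- ngon_cross_section(n, diameter = 1)
    hydraulic_diameter(g$area, g$segments)
  }, numeric(1))
  err <- abs(dh - 1)
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.002)
  expect_error(hydraulic_diameter(1, numeric(0)))
})

test_that("degree of stenosis endpoints, inversion and class bands", {
  expect_equal(degree_of_stenosis(5, 5), 0)
  expect_equal(degree_of_stenosis(0, 5), 1)
  expect_equal(degree_of_stenosis(5 / sqrt(2), 5), 0.5)
  expect_error(degree_of_stenosis(6, 5))
  # inverse map d_h = D_h * sqrt(1 - DOS) is the identity on [0, 1]
  dos <- seq(0, 1, by = 0.05)
  expect_equal(degree_of_stenosis(5 * sqrt(1 - dos), 5), dos)
  expect_equal(
    as.character(dos_class(c(0.1, 0.4, 0.9))),
    c("I", "II", "III")
  )
})

test_that("per-unit ratios are loop-normalized and scale invariant", {
  expect_equal(
    supra_ratios(1338.1, 669.05, 1003.575),
    c(ratio_A = 2.0, ratio_L = 1, ratio_V = 1.5)
  )
  expect_equal(unname(supra_ratios(7, 7, 7)), c(1, 1, 1))
  # second component is exactly 1; positive scaling leaves ratios unchanged
  set.seed(11)
  for (i in 1:20) {
    x <- runif(3, 10, 2000)
    s <- runif(1, 0.1, 50)
    r <- supra_ratios(x[1], x[2], x[3])
    expect_identical(unname(r["ratio_L"]), 1)
    expect_equal(supra_ratios(s * x[1], s * x[2], s * x[3]), r)
  }
  expect_error(supra_ratios(10, 0, 10), "per-unit")
})

test_that("hemodynamic profile and feature vector compose the site quantities", {
  m <- data.frame(
    site = c("A", "L", "V"),
    V_p_cm_s = c(103.20, 64.60, 82.56),
    V_m_cm_s = c(37.00, 28.83, 35.43),
    heart_rate_hz = 1,
    D_H_mm = 5
  )
  phi <- build_feature_vector(m)
  expect_named(phi, c(
    "ratio_A", "ratio_L", "ratio_V",
    "res_A", "res_L", "res_V"
  ))
  expect_equal(unname(phi[4:6]), c(0.6414729, 0.5537152, 0.5708576),
    tolerance = 1e-6
  )
  expect_identical(unname(phi["ratio_L"]), 1)
  # three identical sites give unit ratios and equal indices
  phi_id <- build_feature_vector(identical_sites_subject())
  expect_equal(unname(phi_id[1:3]), c(1, 1, 1))
  expect_equal(unname(phi_id[4]), unname(phi_id[5]))
  # missing site
  expect_error(build_feature_vector(m[1:2, ]), "one measurement per site")
  # profile columns are internally consistent
  prof <- hemodynamic_profile(103.2, 37.0, 1.1, 5.0)
  expect_equal(prof$Re_supra, abs(prof$Re - prof$Re_peak))
  expect_equal(prof$delta_P_mmHg, 4 * 1.032^2)
})

test_that("featurize carries subject ids and labels through", {
  cohort <- sample_cohort(cohort_config(), seed = 3)
  feats <- featurize(cohort)
  expect_equal(nrow(feats), 30)
  expect_identical(unique(feats$ratio_L), 1)
  expect_equal(as.vector(table(feats$dos_class)), c(12, 11, 7))
  expect_true(all(feats$subject_id %in% cohort$subject_id))
})
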