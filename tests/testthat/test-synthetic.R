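test_that("default cohort has the reference composition", {
  cohort <- sample_cohort(cohort_config(), seed = 1)
  expect_equal(nrow(cohort), 90) # 30 subjects x 3 sites
  expect_equal(length(unique(cohort$subject_id)), 30)
  expect_equal(
    as.vector(table(cohort$dos_class) / 3),
    c(12, 11, 7)
  )
  expect_true(all(cohort$V_m_cm_s < cohort$V_p_cm_s))
  expect_true(all(cohort$V_m_cm_s > 0))
  expect_true(all(cohort$D_H_mm > 0))
})

test_that("cohort generation is deterministic under a fixed seed", {
  a <- sample_cohort(cohort_config(), seed = 123)
  b <- sample_cohort(cohort_config(), seed = 123)
  expect_identical(a, b)
})

test_that("zero velocity SDs reproduce the configured means exactly", {
  stats <- reference_velocity_stats()
  stats$v_p_sd <- 0
  stats$v_m_sd <- 0
  cohort <- sample_cohort(
    cohort_config(velocity_stats = stats),
    seed = 2
  )
  row <- cohort[cohort$dos_class == "I" & cohort$site == "A", ][1, ]
  expect_equal(row$V_p_cm_s, 103.20)
  expect_equal(row$V_m_cm_s, 37.00)
})

test_that("sample moments match the truncated class-conditional distribution", {
  cohort <- sample_cohort(
    cohort_config(class_sizes = c(I = 1, II = 1, III = 2000)),
    seed = 5
  )
  l3 <- cohort[cohort$dos_class == "III" & cohort$site == "L", ]
  # independent rejection-sampling oracle for the same truncated bivariate
  # normal (Class III loop site: V_p 25.61 +/- 9.62, V_m 7.86 +/- 3.84,
  # correlation 0.7, kept while 0 < V_m < V_p)
  set.seed(987)
  z1 <- rnorm(5e4)
  z2 <- 0.7 * z1 + sqrt(1 - 0.7^2) * rnorm(5e4)
  v_p <- 25.61 + 9.62 * z1
  v_m <- 7.86 + 3.84 * z2
  keep <- v_p > 0 & v_m > 0 & v_m < v_p
  se_p <- 9.62 * sqrt(1 / 2000 + 1 / sum(keep))
  se_m <- 3.84 * sqrt(1 / 2000 + 1 / sum(keep))
  expect_lt(abs(mean(l3$V_p_cm_s) - mean(v_p[keep])), 3 * se_p)
  expect_lt(abs(mean(l3$V_m_cm_s) - mean(v_m[keep])), 3 * se_m)
  # truncation shifts the means only slightly from the configured values
  expect_lt(abs(mean(l3$V_p_cm_s) - 25.61) / 25.61, 0.05)
  expect_lt(abs(mean(l3$V_m_cm_s) - 7.86) / 7.86, 0.05)
})

test_that("degree-of-stenosis labels are consistent with the class bands", {
  cohort <- sample_cohort(cohort_config(), seed = 6)
  per_subject <- cohort[!duplicated(cohort$subject_id), ]
  expect_identical(
    as.character(dos_class(per_subject$dos)),
    as.character(per_subject$dos_class)
  )
  # stenosis is localized at the loop: A and V share the baseline diameter,
  # the loop diameter equals baseline * sqrt(1 - DOS)
  wide <- reshape(cohort[, c("subject_id", "site", "D_H_mm", "dos")],
    idvar = "subject_id", timevar = "site", direction = "wide"
  )
  expect_equal(wide$D_H_mm.A, wide$D_H_mm.V)
  expect_equal(wide$D_H_mm.L, wide$D_H_mm.A * sqrt(1 - wide$dos.A))
})

test_that("large cohorts show the published severity trends", {
  cohort <- sample_cohort(
    cohort_config(class_sizes = c(I = 700, II = 700, III = 600)),
    seed = 7
  )
  feats <- featurize(cohort)
  mean_res <- tapply(
    (feats$res_A + feats$res_L + feats$res_V) / 3,
    feats$dos_class, mean
  )
  expect_true(all(diff(mean_res) > 0)) # resistive index rises I -> III
  loop_vp <- tapply(
    cohort$V_p_cm_s[cohort$site == "L"],
    cohort$dos_class[cohort$site == "L"], mean
  )
  expect_true(all(diff(loop_vp) < 0)) # loop systolic velocity collapses
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(class_sizes = c(1, 1, 0)), "count")
  expect_error(
    cohort_config(dos_ranges = list(
      I = c(0.05, 0.40), # exceeds the Class I band
      II = c(0.30, 0.50), III = c(0.50, 0.95)
    )),
    "band"
  )
  bad_stats <- reference_velocity_stats()
  bad_stats$v_m_mean[1] <- 200 # above v_p: truncation infeasible
  expect_error(cohort_config(velocity_stats = bad_stats), "infeasible")
})

test_that("the full pipeline recovers classes on separable cohorts", {
  # simulate -> featurize -> PSO-train -> classify held-out subjects;
  # median accuracy across seeds should be >= 90% when classes separate
  accs <- vapply(1:10, function(s) {
    train <- featurize(sample_cohort(well_separated_config(), seed = s))
    test <- featurize(sample_cohort(
      well_separated_config(c(I = 4, II = 3, III = 3)),
      seed = s + 1000
    ))
    model <- cra_train(train, seed = s)
    cra_evaluate(model, test)$accuracy
  }, numeric(1))
  expect_gte(median(accs), 0.9)
})
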