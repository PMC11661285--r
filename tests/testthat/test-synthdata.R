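# Phantom atlas and cohort generator: determinism, overlap arithmetic,
# generative-model contracts, ground-truth reconstruction.

test_that("atlas realizes the requested signature sizes and overlap", {
  at <- make_phantom_atlas(c(12, 12, 12), 8, c(60, 60), 0.5, seed = 1)
  expect_equal(sum(at$bmi_signature != 0), 60)
  expect_equal(sum(at$disease_signature != 0), 60)
  expect_lte(abs(length(at$overlap_voxels) - 30), 1)
  # sign mix: 80% of signature voxels negative by default
  expect_equal(sum(at$bmi_signature < 0), 48)
  # signatures live on labelled voxels only (every voxel is labelled)
  expect_true(all(at$region_labels >= 1))
})

test_that("atlas is deterministic and honours overlap 0 and sizing errors", {
  a1 <- make_phantom_atlas(seed = 7)
  a2 <- make_phantom_atlas(seed = 7)
  expect_identical(a1, a2)
  a0 <- make_phantom_atlas(overlap_fraction = 0, seed = 3)
  expect_length(a0$overlap_voxels, 0)
  expect_error(make_phantom_atlas(c(8, 8, 8), 8, c(500, 20), 0.5, seed = 1),
               "capacity")
  expect_error(make_phantom_atlas(c(3, 12, 12)), ">= 4")
  expect_error(make_phantom_atlas(overlap_fraction = 1.2), "overlap_fraction")
})

test_that("null generator produces voxels uncorrelated with BMI", {
  at <- make_phantom_atlas(seed = 1)
  cfg <- cohort_config(groups = c(HC = 300L), beta_bmi = 0, beta_dis = 0,
                       lambda_clin = 0, propensity_sd = 1e-9)
  sim <- simulate_cohort(at, cfg, seed = 4)
  vox <- c(which(at$bmi_signature != 0)[1:10], 1:10)
  rs <- abs(cor(sim$gmv$data[, vox], sim$subjects$bmi))
  expect_lt(max(rs), 3 / sqrt(300))
})

test_that("noiseless single-site generator is exactly linear in BMI on signature voxels", {
  at <- make_phantom_atlas(seed = 1)
  cfg <- cohort_config(groups = c(HC = 50L), noise_sd = 1e-12, n_sites = 1L,
                       site_sd = 0, age_slope_mean = 0, age_slope_sd = 0,
                       sex_effect_sd = 0, propensity_sd = 1e-12,
                       beta_dis = 0, lambda_clin = 0)
  sim <- simulate_cohort(at, cfg, seed = 5)
  v <- which(at$bmi_signature != 0)[1]
  fit <- lm(sim$gmv$data[, v] ~ sim$subjects$bmi)
  expect_lt(max(abs(resid(fit))), 1e-8)
  expect_equal(unname(coef(fit)[2]), cfg$beta_bmi * at$bmi_signature[v],
               tolerance = 1e-6)
})

test_that("simulation is bit-deterministic and the truth record rebuilds the systematic part", {
  at <- make_phantom_atlas(seed = 1)
  cfg <- cohort_config(groups = c(HC = 40L, SCZ = 20L))
  s1 <- simulate_cohort(at, cfg, seed = 6)
  s2 <- simulate_cohort(at, cfg, seed = 6)
  expect_identical(s1$gmv$data, s2$gmv$data)
  expect_identical(s1$subjects, s2$subjects)
  # same seed, noise SD -> 0: matrix equals the reconstruction exactly
  cfg0 <- cohort_config(groups = c(HC = 40L, SCZ = 20L), noise_sd = 1e-15)
  s0 <- simulate_cohort(at, cfg0, seed = 6)
  expect_identical(s0$subjects$bmi, s1$subjects$bmi)
  sys <- reconstruct_systematic(s0$truth, s0$subjects, at)
  expect_lt(max(abs(s0$gmv$data - sys)), 1e-10)
  # residual of the noisy run is the drawn noise (same covariate draws)
  res <- s1$gmv$data - reconstruct_systematic(s1$truth, s1$subjects, at)
  expect_equal(sd(res), cfg$noise_sd, tolerance = 0.01)
  # gap propensity uncorrelated with measured BMI by construction
  big <- simulate_cohort(at, cohort_config(), seed = 7)
  expect_lt(abs(cor(big$truth$propensity, big$subjects$bmi)), 3 / sqrt(600))
})

test_that("mass-univariate regression recovers the seeded signature at default SNR", {
  at <- make_phantom_atlas(seed = 1)
  sim <- simulate_cohort(at, cohort_config(), seed = 2)  # default n = 600
  p <- apply(sim$gmv$data, 2, function(v) cor.test(v, sim$subjects$bmi)$p.value)
  q <- p.adjust(p, "BH")
  sig <- which(at$bmi_signature != 0)
  expect_gte(mean(q[sig] < 0.05), 0.9)
})

test_that("group mix validation and config errors work", {
  expect_error(cohort_config(groups = c(bogus = 10L)), "HC/SCZ/CHR/ROD")
  expect_error(cohort_config(noise_sd = 0), "noise_sd")
  expect_error(longitudinal_config(missing = c(0.2, 1.4)), "missing")
})

test_that("longitudinal coupling behaves as configured", {
  at <- make_phantom_atlas(seed = 1)
  sim <- simulate_cohort(at, cohort_config(groups = c(HC = 400L)), seed = 8)
  # gamma = 0: no propensity coupling
  l0 <- simulate_longitudinal(sim$subjects, sim$truth,
                              longitudinal_config(gamma1 = 0, gamma2 = 0,
                                                  missing = c(0, 0)), seed = 9)
  expect_lt(abs(cor(sim$truth$propensity, l0$weight_t2 - l0$weight_t0)),
            3 / sqrt(400))
  # noise and modifiers off: change is exactly gamma * propensity
  lx <- simulate_longitudinal(sim$subjects, sim$truth,
                              longitudinal_config(gamma1 = 0.5, gamma2 = 1.2,
                                                  drift = c(0, 0), noise_sd = 0,
                                                  missing = c(0, 0)), seed = 10)
  expect_equal(lx$weight_t1 - lx$weight_t0, 0.5 * sim$truth$propensity)
  expect_equal(lx$weight_t2 - lx$weight_t0, 1.2 * sim$truth$propensity)
  # default coupling: positive, significant 2-year correlation
  ld <- simulate_longitudinal(sim$subjects, sim$truth,
                              longitudinal_config(), seed = 11)
  ct <- cor.test(sim$truth$propensity, ld$weight_t2 - ld$weight_t0)
  expect_gt(unname(ct$estimate), 0)
  expect_lt(ct$p.value, 0.05)
  # missing-at-random rates honoured roughly
  expect_equal(mean(is.na(ld$weight_t1)), 0.2, tolerance = 0.08)
})
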