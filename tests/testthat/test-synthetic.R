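# synthetic paired blood/sweat data generation

test_that("generated blood profiles hit the target marginal summaries", {
  sp <- builtin_experiments(seed = 1)$exp1
  blood <- generate_blood_profile(sp)
  expect_equal(nrow(blood), 15)
  expect_lt(abs(mean(blood$values) - 5.6), 0.3)
  expect_lt(abs(sd(blood$values) - 0.9), 0.3)
})

test_that("a zero-SD fasting spec yields a constant profile", {
  sp <- experiment_spec(7, 5.0, 0, 19.3, 12.1, "fasting", seed = 2)
  blood <- generate_blood_profile(sp)
  expect_true(all(blood$values == 5.0))
})

test_that("profiles are deterministic under the spec seed and always positive", {
  for (sp in builtin_experiments(seed = 3)) {
    b1 <- generate_blood_profile(sp)
    b2 <- generate_blood_profile(sp)
    expect_identical(b1$values, b2$values)
    expect_true(all(b1$values > 0))
  }
})

test_that("realised means are unbiased across seeds", {
  means <- vapply(1:50, function(s) {
    mean(generate_blood_profile(meal_spec(s))$values)
  }, numeric(1))
  se <- sd(means) / sqrt(50)
  expect_lt(abs(mean(means) - 5.6), 2 * max(se, 1e-6))
})

test_that("infeasible summaries are rejected", {
  expect_error(experiment_spec(10, 5, 6, 50, 10, "meal"), "SD exceeds")
  expect_error(experiment_spec(0, 5, 1, 50, 10, "meal"), "n_points")
})

test_that("noise-free LDRW-generated sweat equals the forward prediction exactly", {
  pd <- generate_paired(meal_spec(4), "ldrw")
  pred <- predict_sweat(pd$generator_trace$theta_effective, pd$blood_true,
                        pd$blood_true$times)
  expect_equal(pd$sweat_obs$values, pred$values, tolerance = 1e-12)
})

test_that("the realised sweat mean matches the experiment summary", {
  pd <- generate_paired(builtin_experiments(seed = 6)$exp1, "ldrw")
  expect_lt(abs(mean(pd$sweat_obs$values) - 0.0971) / 0.0971, 0.10)
  pdb <- generate_paired(builtin_experiments(seed = 6)$exp2, "biophysical")
  expect_lt(abs(mean(pdb$sweat_obs$values) - 0.0375) / 0.0375, 0.10)
  expect_true(all(pd$sweat_obs$values > 0))
})

test_that("the sweat/blood mean ratio reflects the effective DC gain", {
  sp <- experiment_spec(20, 5.0, 0.3, 42.4, 5, "fasting", noise_rel_sd = 0, seed = 8)
  pd <- generate_paired(sp, "ldrw")
  ratio <- mean(pd$sweat_obs$values) / mean(pd$blood_true$values)
  expect_lt(abs(ratio - pd$generator_trace$theta_effective$A) /
              pd$generator_trace$theta_effective$A, 0.15)
})

test_that("round trip: the inverse estimator recovers the generated truth", {
  pd <- generate_paired(meal_spec(13), "ldrw")
  res <- estimate_blood(pd$sweat_obs,
                        inverse_options(pd$generator_trace$theta_effective))
  expect_lt(rel_rmse(res$blood_est$values, pd$blood_true$values), 0.05)
})
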