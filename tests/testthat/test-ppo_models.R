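test_that("COPD index is the additive composite and rejects bad scales", {
  expect_equal(copd_index(0.92, 0.69), 1.61)
  expect_equal(copd_index(1.00, 1.00), 2.00)
  expect_equal(copd_index(0.50, 0.50), 1.00)
  expect_error(copd_index(0, 0.7), "\\(0, 2\\]")
  expect_error(copd_index(92, 0.7), "\\(0, 2\\]")   # percent scale rejected
})

test_that("5% rule scales the preoperative value by segments removed", {
  expect_equal(five_percent_rule(2.48, 2.5), 2.17)
  expect_equal(round(five_percent_rule(2.48, 2.5), 1), 2.2)
  expect_equal(five_percent_rule(3.1, 0), 3.1)
  expect_equal(five_percent_rule(2.0, 3), 1.70)
  expect_error(five_percent_rule(2, -1), ">= 0")
  expect_error(five_percent_rule(2, 21), "<= 20")
})

test_that("Brunelli FEV1 loss matches hand-computed values to 1e-9", {
  # 21.34 - 0.47*68 + 0.49*16.42 + 17.91*1.61
  expect_equal(brunelli_fev1_loss(68, 16.42, 1.61),
               21.34 - 31.96 + 8.0458 + 28.8351, tolerance = 1e-12)
  expect_equal(brunelli_fev1_loss(68, 16.42, 1.61), 26.2609, tolerance = 1e-9)
  expect_equal(brunelli_fev1_loss(60, 20, 1.5), 29.805, tolerance = 1e-9)
  # coefficient-zero configuration leaves the intercept
  cz <- brunelli_coefficients(fev1 = c(intercept = 21.34, age = 0,
                                       removed_pct = 0, copd_index = 0))
  expect_equal(brunelli_fev1_loss(80, 50, 1.2, cz), 21.34)
  expect_error(brunelli_fev1_loss(-1, 16, 1.6), "positive")
  # 0-1 scale input rejected with a unit hint
  expect_error(brunelli_fev1_loss(68, 0.1642, 1.61), "0-100 percent scale")
})

test_that("Brunelli DLCO loss uses measured-unit DLCO and 0-1 FEV1/FVC", {
  # 35.99 - 0.31*68 - 36.47*0.69 + 0.33*6.27 + 0.54*16.42
  expect_equal(brunelli_dlco_loss(68, 0.69, 6.27, 16.42),
               35.99 - 21.08 - 25.1643 + 2.0691 + 8.8668, tolerance = 1e-12)
  expect_equal(brunelli_dlco_loss(68, 0.69, 6.27, 16.42), 0.6816,
               tolerance = 1e-9)
  # near-zero loss keeps predicted DLCO essentially at the preop value
  loss <- brunelli_dlco_loss(68, 0.69, 6.23, 16.42)
  expect_equal(loss, 0.6684, tolerance = 1e-9)
  expect_equal(round(apply_loss(6.23, loss), 2), 6.19)
  cz <- brunelli_coefficients(dlco = c(intercept = 35.99, age = 0,
                                       fev1_fvc = 0, dlco = 0, removed_pct = 0))
  expect_equal(brunelli_dlco_loss(70, 0.6, 5, 20, cz), 35.99)
  expect_error(brunelli_dlco_loss(68, 69, 6.27, 16.42), "0-1 ratio")
})

test_that("loss application and the volumetric model behave as stated", {
  expect_equal(apply_loss(2.48, 26.26), 2.48 * (1 - 0.2626))
  expect_equal(round(apply_loss(2.48, 26.2609), 1), 1.8)
  expect_equal(apply_loss(3.3, 0), 3.3)
  expect_warning(z <- apply_loss(1.0, 150), "clamped")
  expect_equal(z, 0)
  expect_error(apply_loss(-1, 10), ">= 0")

  expect_equal(volumetric_ppo(2.48, 0.1642), 2.48 * (1 - 0.1642))
  expect_equal(round(volumetric_ppo(2.48, 0.1642), 3), 2.073)
  expect_equal(volumetric_ppo(1.9, 0), 1.9)
  expect_equal(volumetric_ppo(1.9, 1), 0)
  expect_error(volumetric_ppo(1.9, 1.2), "\\[0, 1\\]")
  expect_error(volumetric_ppo(1.9, -0.1), "\\[0, 1\\]")
})

test_that("the three FEV1 predictors coincide in the degenerate configuration", {
  # 5%-per-segment functional resection + loss regression reduced to the
  # removed-percentage term makes all three models identical
  cz <- brunelli_coefficients(fev1 = c(intercept = 0, age = 0,
                                       removed_pct = 1, copd_index = 0))
  for (k in 0:3) {
    frac <- 0.05 * k
    preop <- 2.5
    p5 <- five_percent_rule(preop, k)
    pv <- volumetric_ppo(preop, frac)
    pb <- apply_loss(preop, brunelli_fev1_loss(65, 100 * frac, 1.6, cz))
    expect_equal(p5, pv, tolerance = 1e-12)
    expect_equal(pb, pv, tolerance = 1e-12)
  }
})

test_that("prediction models are monotone in their resection arguments", {
  ks <- seq(0, 19, by = 0.5)
  p <- five_percent_rule(2.48, ks)
  expect_true(all(diff(p) < 0))
  # linearity
  expect_equal(max(abs(diff(p, differences = 2))), 0, tolerance = 1e-12)
  fr <- seq(0, 1, by = 0.05)
  pv <- volumetric_ppo(2.48, fr)
  expect_true(all(diff(pv) < 0))
  expect_equal(max(abs(diff(pv, differences = 2))), 0, tolerance = 1e-12)

  # default-coefficient directions of the FEV1 regression
  l0 <- brunelli_fev1_loss(68, 10, 1.6)
  expect_true(brunelli_fev1_loss(68, 20, 1.6) > l0)   # more resection, more loss
  expect_true(brunelli_fev1_loss(68, 10, 1.8) > l0)   # worse COPD index term
  expect_true(brunelli_fev1_loss(78, 10, 1.6) < l0)   # older, less predicted loss
})

test_that("predict_ppo assembles all models with pre-clamp losses recorded", {
  pred <- predict_ppo(preop_fev1 = 2.48, preop_dlco = 6.27, age = 68,
                      fev1_pct_pred = 0.92, fev1_fvc = 0.69,
                      segments_removed = 3, removed_functional_fraction = 0.1642)
  expect_s3_class(pred, "ppo_prediction")
  expect_equal(pred$ppo_fev1_5pct, 2.48 * 0.85)
  expect_equal(pred$fev1_loss_brunelli_pct, 26.2609, tolerance = 1e-9)
  expect_equal(pred$ppo_fev1_brunelli, 2.48 * (1 - 0.262609), tolerance = 1e-9)
  expect_equal(pred$ppo_fev1_volumetric, 2.48 * (1 - 0.1642))
  expect_equal(pred$ppo_dlco_brunelli,
               6.27 * (1 - brunelli_dlco_loss(68, 0.69, 6.27, 16.42) / 100),
               tolerance = 1e-9)
})
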