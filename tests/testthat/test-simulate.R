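test_that("simulation is deterministic given the seed", {
  a <- fdd11_simulate(500, seed = 99, missing_rate = 0.02)
  b <- fdd11_simulate(500, seed = 99, missing_rate = 0.02)
  expect_identical(a$responses, b$responses)
  expect_identical(a$truth$abilities, b$truth$abilities)
  c <- fdd11_simulate(500, seed = 100, missing_rate = 0.02)
  expect_false(identical(a$responses, c$responses))
})

test_that("simulated scores concentrate on the PCM expected score", {
  ## every person at theta = 0.303: the mean recoded total must approach
  ## the closed-form expected score (~15) by the law of large numbers
  sim <- fdd11_simulate(50000, ability = list(mean = 0.303, sd = 0),
                        seed = 101)
  target <- pcm_expected_score(0.303, published$items)
  expect_equal(mean(rowSums(sim$responses)), target, tolerance = 0.05 / target)
})

test_that("MCAR missingness hits its nominal rate", {
  sim <- fdd11_simulate(50000, missing_rate = 0.02, seed = 102)
  expect_equal(mean(is.na(sim$responses)), 0.02, tolerance = 0.003 / 0.02)
})

test_that("the default ability model is a floor mixture", {
  sim <- fdd11_simulate(20000, seed = 103)
  expect_equal(mean(sim$truth$abilities == -3.5), 0.25, tolerance = 0.05)
  ## right-skew: most of the population reports little difficulty
  sc <- rowSums(sim$responses)
  expect_gt(mean(sc <= 5), 0.5)
})

test_that("twelve-item mode emits a locally dependent emotion pair", {
  sim <- fdd11_simulate(4000, twelve_item = TRUE, seed = 104)
  expect_true(all(c("Q09a", "Q09b") %in% colnames(sim$responses)))
  expect_false("Q09" %in% colnames(sim$responses))
  expect_equal(ncol(sim$responses), 12L)
  ## the simulated pair recodes into 5 categories with max 4
  tl <- emotion_testlet(sim$responses[, "Q09a"], sim$responses[, "Q09b"])
  expect_true(all(tl %in% 0:4))
  expect_equal(max(tl), 4L)

  ## the shared component makes the pair's residual correlation exceed the
  ## dependence-flag threshold after a 12-item calibration
  fit <- pcm_fit(sim$responses)
  fl <- residual_correlation_flags(residuals(fit))
  expect_true(any(fl$flags$item1 == "Q09a" & fl$flags$item2 == "Q09b"))
  expect_gt(fl$correlations["Q09a", "Q09b"], fl$threshold)

  ## with no shared component there is no flag on that pair
  sim0 <- fdd11_simulate(4000, twelve_item = TRUE, testlet_sd = 0, seed = 105)
  fit0 <- pcm_fit(sim0$responses)
  fl0 <- residual_correlation_flags(residuals(fit0))
  expect_false(any(fl0$flags$item1 == "Q09a" & fl0$flags$item2 == "Q09b"))
})

test_that("group-wise DIF shifts act on the shifted group only", {
  props <- c(A = 0.5, B = 0.5)
  sim <- fdd11_simulate(20000, groups = props,
                        dif_shifts = list(B = c(Q11 = 1.0)),
                        ability = list(mean = -0.5, sd = 1), seed = 106)
  mA <- mean(sim$responses[sim$groups == "A", "Q11"])
  mB <- mean(sim$responses[sim$groups == "B", "Q11"])
  expect_gt(mA - mB, 0.2)      # harder thresholds depress the group's scores
  mA3 <- mean(sim$responses[sim$groups == "A", "Q03"])
  mB3 <- mean(sim$responses[sim$groups == "B", "Q03"])
  expect_lt(abs(mA3 - mB3), 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(fdd11_simulate(100, groups = c(A = 0.6, B = 0.6)), "sum")
  expect_error(fdd11_simulate(100, missing_rate = 1), "missing_rate")
  expect_error(fdd11_simulate(100, groups = c(A = 0.5, B = 0.5),
                              dif_shifts = list(Z = c(Q01 = 1))),
               "unknown group")
  expect_error(fdd11_simulate(100, dif_shifts = list(A = c(Q01 = 1))),
               "requires")
  expect_error(fdd11_simulate(0), "positive")
})

test_that("simulate -> calibrate -> score round-trip recovers the truth", {
  sim <- fdd11_simulate(8000, ability = list(mean = -1.2733, sd = 1.0822),
                        seed = 107)
  fit <- pcm_fit(sim$responses)
  truth <- centered(unlist(unclass(published$items)))
  est <- unlist(unclass(fit$items))
  se <- unlist(attr(fit$items, "se"))
  ## family-wise over 30 thresholds: most within 3 SEs, none beyond 4
  z <- abs(est - truth) / se
  expect_gte(mean(z < 3), 0.9)
  expect_lt(max(z), 4)
  ## person-ability errors are consistent with the reported standard errors
  ab <- fit$abilities
  keep <- !ab$extreme
  err <- ab$theta[keep] - (sim$truth$abilities[keep] - mean(sim$truth$abilities[keep]) +
                             mean(ab$theta[keep]))
  ratio <- sqrt(mean(err^2)) / sqrt(mean(ab$se[keep]^2))
  expect_gt(ratio, 0.75)
  expect_lt(ratio, 1.35)
})
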