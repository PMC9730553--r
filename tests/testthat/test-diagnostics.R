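test_that("standardized residuals match hand-computed anchor cases", {
  one <- pcm_items(list(a = 0.4))
  ## dichotomous at theta = tau: P = 0.5, Var = 0.25, so x = 1 gives +1
  ab <- data.frame(theta = 0.4, se = 1, extreme = FALSE)
  z1 <- standardized_residuals(matrix(1L, 1, 1, dimnames = list(NULL, "a")),
                               one, ab)
  expect_equal(as.numeric(z1), 1)
  ## observed equal to expected gives residual 0 (continuous construction)
  it2 <- pcm_items(list(a = c(0, 0)))  # at theta 0, E = 1 exactly
  z0 <- standardized_residuals(matrix(1L, 1, 1, dimnames = list(NULL, "a")),
                               it2, data.frame(theta = 0, se = 1,
                                               extreme = FALSE))
  expect_equal(as.numeric(z0), 0)
})

test_that("residual column means vanish under model-true data", {
  sim <- sim_published(4000, seed = 31)
  truth <- data.frame(theta = sim$truth$abilities, se = NA, extreme = FALSE)
  z <- standardized_residuals(sim$responses, published$items, truth)
  expect_true(all(abs(colMeans(z)) < 0.06))
  ## missing responses stay missing
  X <- sim$responses
  X[1, 3] <- NA
  z2 <- standardized_residuals(X, published$items, truth)
  expect_true(is.na(z2[1, 3]))
})

test_that("item infit is calibrated under the model and flags overfit", {
  sim <- sim_published(5000, seed = 33)
  truth <- data.frame(theta = sim$truth$abilities, se = NA, extreme = FALSE)
  ii <- item_infit(sim$responses, published$items, truth)
  expect_true(all(ii > 0.9 & ii < 1.1))
  expect_length(attr(ii, "flagged"), 0L)

  ## an item generated with doubled discrimination (slope 2 on every step,
  ## as in a generalized PCM) is overdeterministic: its responses track
  ## ability too closely and infit drops below 0.7. Target the population
  ## at the item so the signal is in range.
  sim2 <- sim_published(5000, seed = 36, mean = 0.185, sd = 1.08)
  truth2 <- data.frame(theta = sim2$truth$abilities, se = NA, extreme = FALSE)
  X <- sim2$responses
  tau <- published$items[["Q09"]]
  X[, "Q09"] <- simulate_pcm_matrix(2 * sim2$truth$abilities,
                                    pcm_items(list(Q09 = 2 * tau)))
  ii2 <- item_infit(X, published$items, truth2)
  expect_lt(ii2[["Q09"]], 0.7)
  expect_true("Q09" %in% attr(ii2, "flagged"))
})

test_that("person infit flags erratic response patterns", {
  ## a person answering close to expectation everywhere has tiny infit
  m <- max_categories(published$items)
  th15 <- pcm_ability(15, published$items)$theta
  mom <- fdd11:::pcm_item_moments(th15, published$items)
  nearest <- round(mom$mean)
  X <- rbind(nearest, ifelse(seq_along(m) %% 2 == 0, m, 0L))
  colnames(X) <- names(published$items)
  ab <- abilities_published(X)
  pi <- person_infit(X, published$items, ab)
  expect_lt(pi[1], 0.5)
  ## maximally alternating extreme responses misfit badly
  expect_gt(pi[2], 2)
})

test_that("person misfit rate under the model stays near the tail rate", {
  sim <- sim_published(5000, seed = 34)
  ab <- abilities_published(sim$responses)
  pi <- person_infit(sim$responses, published$items, ab)
  rate <- attr(pi, "misfit_rate")
  expect_gt(rate, 0.001)
  expect_lt(rate, 0.08)
})

test_that("residual correlations flag duplicated items and not independent ones", {
  sim <- sim_published(5000, seed = 35)
  ab <- abilities_published(sim$responses)
  z <- standardized_residuals(sim$responses, published$items, ab)
  fl <- residual_correlation_flags(z)
  expect_equal(nrow(fl$flags), 0L)

  ## duplicating an item produces residual correlation ~1 on that pair
  X <- cbind(sim$responses, Q12 = sim$responses[, "Q11"])
  items2 <- pcm_items(c(unclass(published$items),
                        list(Q12 = published$items[["Q11"]])))
  est <- estimate_persons(X, items2)
  z2 <- standardized_residuals(X, items2, est)
  fl2 <- residual_correlation_flags(z2)
  expect_true(any(fl2$flags$item1 == "Q11" & fl2$flags$item2 == "Q12"))
  expect_gt(fl2$correlations["Q11", "Q12"], 0.9)

  expect_error(residual_correlation_flags(z[, 1:2]), "three items")
})

test_that("the relative flagging rule mirrors the instrument's threshold", {
  ## a pair at r = 0.13 must be flagged when the mean off-diagonal
  ## correlation puts the threshold at exactly 0.11
  off <- c(0.13, rep(((0.11 - 0.2) * 6 - 0.13) / 5, 5))
  M <- diag(4)
  M[upper.tri(M)] <- off
  M <- M + t(M) - diag(4)
  expect_gt(min(eigen(M, symmetric = TRUE)$values), 0)
  ## residual matrix with exactly this sample correlation: orthonormal
  ## zero-mean columns times the Cholesky factor
  set.seed(2)
  U <- qr.Q(qr(scale(matrix(rnorm(400), 100, 4), scale = FALSE)))
  Z <- U %*% chol(M)
  colnames(Z) <- paste0("V", 1:4)
  fl <- residual_correlation_flags(Z)
  expect_equal(fl$threshold, 0.11, tolerance = 1e-10)
  expect_equal(nrow(fl$flags), 1L)
  expect_equal(unname(unlist(fl$flags[1, 1:2])), c("V1", "V2"))
  expect_equal(fl$flags$r, 0.13, tolerance = 1e-10)
})

test_that("threshold ordering checks and collapse proposals work", {
  expect_length(threshold_order_check(published$items), 0L)
  bad <- pcm_items(list(A = c(0.5, -0.2), B = 0.1, C = c(-1, 0, 1)))
  expect_equal(threshold_order_check(bad), "A")

  ## simulate from a disordered item and let the proposal fix it
  dis <- pcm_items(list(A = c(0.8, -0.8), B = c(-1, 0, 1), C = 0.2,
                        D = c(-0.5, 0.5)))
  sim <- fdd11_simulate(3000, items = dis,
                        ability = list(mean = 0, sd = 1.3), seed = 41)
  prop <- suggest_collapse(sim$responses)
  expect_true(prop$ordered)
  expect_gte(nrow(prop$log), 1L)
  expect_equal(prop$log$item[1], "A")
  ## cumulative maps are monotone coarsenings
  for (map in prop$recodes) {
    expect_equal(map[1], 0L)
    expect_true(all(diff(map) %in% 0:1))
  }
  ## data from well-separated thresholds yields an empty proposal
  wide <- pcm_items(list(A = c(-1.5, 0, 1.5), B = c(-1, 1), C = 0.3))
  sim2 <- fdd11_simulate(1500, items = wide,
                         ability = list(mean = 0, sd = 1.3), seed = 42)
  prop2 <- suggest_collapse(sim2$responses)
  expect_equal(nrow(prop2$log), 0L)
  expect_true(prop2$ordered)
})

test_that("PSI has its boundary values and grows with ability spread", {
  expect_equal(person_separation_index(c(-1, 0, 1), se = c(0, 0, 0)), 1)
  th <- c(-1, 0, 1)
  expect_equal(person_separation_index(th, se = rep(sd(th), 3)), 0)
  expect_error(person_separation_index(rep(0.5, 10), se = rep(0.1, 10)),
               "zero variance")
  psis <- vapply(c(0.5, 1.0, 2.0), function(s) {
    sim <- sim_published(3000, seed = 50 + 10 * s, mean = -0.5, sd = s)
    person_separation_index(abilities_published(sim$responses))
  }, numeric(1))
  expect_true(all(diff(psis) > 0))
})

test_that("targeting summary reproduces the published item-location row", {
  sim <- sim_published(2000, seed = 55)
  ab <- abilities_published(sim$responses)
  tg <- targeting_summary(ab, published$items)
  ## published: mean 0.2863, SD 0.7788, range -1.48 to 1.74 over thresholds
  ## (the printed two-decimal thresholds give 0.2867 / 0.7798)
  expect_equal(tg$item_thresholds$mean, 0.2863, tolerance = 0.005)
  expect_equal(tg$item_thresholds$sd, 0.7788, tolerance = 0.005)
  expect_equal(tg$item_thresholds$range, c(-1.48, 1.74))
  ## person distribution recovered within Monte-Carlo error
  expect_equal(tg$persons$mean, mean(ab$theta[!ab$extreme]))
  ## single-threshold SD convention
  tg1 <- targeting_summary(c(-1, 0, 1), pcm_items(list(a = 0.3)))
  expect_equal(tg1$item_thresholds$sd, 0)
  expect_s3_class(tg$map$thresholds, "data.frame")
})

test_that("fit_report aggregates the diagnostics", {
  sim <- sim_published(800, seed = 60)
  fit <- pcm_fit(sim$responses)
  rep <- fit_report(fit)
  expect_s3_class(rep, "fdd11_fit_report")
  expect_length(rep$item_infit, 11L)
  expect_true(rep$psi > 0 && rep$psi < 1)
  expect_output(print(rep), "Person separation index")
  path <- tempfile(fileext = ".json")
  write_fit_report(rep, path)
  parsed <- jsonlite::fromJSON(path)
  expect_equal(length(parsed$item_infit), 11L)
  s <- summary(fit)
  expect_output(print(s), "infit")
})
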