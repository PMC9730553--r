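test_that("the shipped recode maps match the instrument's recoding strategy", {
  maps <- fdd11_recode_map()
  expect_equal(maps$Q02, c(0L, 1L, 1L, 2L, 2L))
  expect_equal(maps$Q11, 0:4)                      # no recoding performed
  expect_equal(maps$Q01, c(0L, 1L, 2L, 3L, 3L))
  expect_equal(fdd11_recode_map(emotion = "testlet")$Q09,
               c(0L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  ## monotone and surjective, for every item
  for (m in maps) {
    expect_equal(m[1], 0L)
    expect_true(all(diff(m) %in% 0:1))
  }
  ## all-maximum original responses reach the recoded maximum sum of 30
  allmax <- matrix(4L, 1, 11, dimnames = list(NULL, names(maps)))
  expect_equal(sum(apply_recodes(allmax, maps)), 30L)
})

test_that("apply_recodes recodes, keeps missing, and validates ranges", {
  maps <- fdd11_recode_map()
  X <- rbind(c(3L, NA, 4L), c(0L, 2L, 1L))
  colnames(X) <- c("Q02", "Q05", "Q11")
  out <- apply_recodes(X, maps[colnames(X)])
  expect_equal(out[1, ], c(Q02 = 2L, Q05 = NA, Q11 = 4L))
  expect_equal(out[2, ], c(Q02 = 0L, Q05 = 1L, Q11 = 1L))
  X[1, 1] <- 7L
  expect_error(apply_recodes(X, maps[colnames(X)]), "out-of-range")
})

test_that("the emotion testlet recodes the two-item sum to five categories", {
  expect_equal(emotion_testlet(4, 4), 4L)
  expect_equal(emotion_testlet(0, 0), 0L)
  expect_equal(emotion_testlet(1, 2), 2L)      # sum 3 -> 2
  expect_true(is.na(emotion_testlet(NA, 3)))
  expect_true(is.na(emotion_testlet(2, NA)))
  expect_error(emotion_testlet(5, 0), "0-4")
})

test_that("missingness filtering retains at most two missing items", {
  X <- matrix(0L, 4, 11, dimnames = list(paste0("p", 1:4), names(published$items)))
  X[2, 1:2] <- NA
  X[3, 1:3] <- NA
  flt <- filter_missingness(X)
  expect_equal(rownames(flt$data), c("p1", "p2", "p4"))
  expect_equal(flt$excluded$person_id, "p3")
  expect_equal(flt$excluded$n_missing, 3)
  ## complete data passes unchanged
  full <- filter_missingness(X[c(1, 4), ])
  expect_equal(nrow(full$data), 2L)
  expect_equal(nrow(full$excluded), 0L)
})

test_that("the 0-100 transform is the published affine map", {
  a <- published$anchors
  expect_equal(transform_to_scale(-3.71, a), 0)
  expect_equal(transform_to_scale(4.18, a), 100)
  ## printed values used rounded anchors/abilities: agreement to ~0.02
  expect_lt(abs(transform_to_scale(0.303, a) - 50.85), 0.02)
  expect_lt(abs(transform_to_scale(-0.31, a) - 43.08), 0.02)
  ## clamped outside the anchors
  expect_equal(transform_to_scale(c(-9, 9), a), c(0, 100))
  ## affine: three collinear thetas stay collinear
  th <- c(-1, 0.5, 2)
  tr <- transform_to_scale(th, a)
  expect_equal(diff(tr)[1] / diff(th)[1], diff(tr)[2] / diff(th)[2])
  expect_error(transform_to_scale(0, c(1, 1)), "theta_min < theta_max")
})

test_that("levels follow the left-closed boundary convention", {
  co <- published$cutoffs
  expect_equal(as.character(assign_level(c(0, 39.39, 41.30, 10.12), co)),
               c("No", "Moderate", "Severe", "Mild"))
  ## scores exactly on a cut-off belong to the higher level
  expect_equal(as.character(assign_level(c(4.3, 22.6, 40.8), co)),
               c("Mild", "Moderate", "Severe"))
  expect_error(assign_level(101, co), "0, 100")
})

test_that("cut-offs are mean +/- one sample SD", {
  expect_equal(as.numeric(derive_cutoffs(c(10, 20, 30))), c(10, 20, 30))
  x <- 50 + c(-1, 1) * 20   # symmetric around 50, sd = 20*sqrt(2), so build exact:
  x <- c(30, 50, 70, 50)    # mean 50
  s <- sd(x)
  expect_equal(as.numeric(derive_cutoffs(x)), c(50 - s, 50, 50 + s))
  expect_error(derive_cutoffs(rep(5, 10)), "degenerate")
  expect_error(derive_cutoffs(c(99, 99.9)), "outside")
  expect_error(fdd11_cutoffs(10, 5, 50))
})

test_that("score_persons reproduces the published conversion", {
  maps <- fdd11_recode_map()
  ## complete patterns with recoded sums 10 and 2
  p10 <- c(Q01 = 2L, Q02 = 1L, Q03 = 1L, Q04 = 1L, Q05 = 0L, Q06 = 1L,
           Q07 = 1L, Q08 = 1L, Q09 = 1L, Q10 = 1L, Q11 = 0L)
  p2 <- c(Q01 = 1L, Q02 = 0L, Q03 = 0L, Q04 = 0L, Q05 = 0L, Q06 = 1L,
          Q07 = 0L, Q08 = 0L, Q09 = 0L, Q10 = 0L, Q11 = 0L)
  X <- rbind(p10, p2)
  sc <- score_persons(X, published)
  expect_equal(sc$sum_score, c(10, 2))
  expect_equal(sc$score_0_100[1], 43.08, tolerance = 1e-2)
  expect_equal(as.character(sc$disability_level), c("Severe", "Mild"))
})

test_that("scoring is sufficient in the sum score and order-invariant", {
  sim <- sim_published(300, seed = 17)
  X <- sim$responses
  sc <- score_persons(X, published)
  ## equal sums -> identical scores
  agg <- tapply(sc$theta, sc$sum_score, function(v) max(v) - min(v))
  expect_true(all(agg < 1e-10))
  ## shuffling persons and columns changes nothing (up to row order)
  set.seed(1)
  X2 <- X[sample(nrow(X)), sample(ncol(X))]
  sc2 <- score_persons(X2, published)
  sc2 <- sc2[match(sc$person_id, sc2$person_id), ]
  expect_equal(sc2$theta, sc$theta)
  expect_equal(sc2$score_0_100, sc$score_0_100)
})

test_that("incomplete persons are scored by ML over answered items", {
  X <- matrix(1L, 2, 11, dimnames = list(NULL, names(published$items)))
  X[2, c("Q05", "Q09")] <- NA
  sc <- score_persons(X, published)
  expect_equal(sc$n_missing, c(0L, 2L))
  ## the answered-subset ML solves the subset expected-score equation
  sub <- pcm_items(unclass(published$items)[setdiff(names(published$items),
                                                    c("Q05", "Q09"))])
  expect_equal(pcm_expected_score(sc$theta[2], sub), sc$sum_score[2],
               tolerance = 1e-6)
  ## fewer answered items -> larger SE
  expect_gt(sc$se[2], sc$se[1])
  ## schema error on wrong items
  bad <- X[, 1:10]
  expect_error(score_persons(bad, published), "do not match")
})

test_that("the shipped score table is internally consistent", {
  st <- published$score_table
  expect_equal(as.character(assign_level(st$score_0_100, published$cutoffs)),
               st$level)
  ## sum-score ranges per level are exactly No {0}, Mild 1-2, Moderate 3-8,
  ## Severe 9-30
  rng <- tapply(st$sum_score, st$level, range)
  expect_equal(rng$No, c(0, 0))
  expect_equal(rng$Mild, c(1, 2))
  expect_equal(rng$Moderate, c(3, 8))
  expect_equal(rng$Severe, c(9, 30))
})
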