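## shared fixtures: all built in code, no stored data

published <- fdd11_calibration()

## small three-item toy instrument for enumeration-based checks
toy_items <- pcm_items(list(
  A = c(-1.0, 0.5),
  B = 0.2,
  C = c(-0.3, 0.1, 0.9)
))

## enumerate every complete response pattern of an instrument
enumerate_patterns <- function(items) {
  grids <- lapply(max_categories(items), function(m) 0:m)
  as.matrix(do.call(expand.grid, grids))
}

## normal-population simulation at the published calibration
sim_published <- function(n, seed, mean = -1.2733, sd = 1.0822, ...) {
  fdd11_simulate(n, items = published$items,
                 ability = list(mean = mean, sd = sd), seed = seed, ...)
}

## abilities data frame for scored persons (complete data, published scale)
abilities_published <- function(X) {
  est <- score_persons(X, published)
  data.frame(theta = est$theta, se = est$se, extreme = est$extreme)
}

centered <- function(x) x - mean(x)
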