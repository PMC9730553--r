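## Synthetic MDS/FDD11-like data with known truth, so every pipeline stage
## can be exercised without the request-only study microdata.

#' Draw a response matrix from the Partial Credit Model
#'
#' Low-level simulator: one row per element of `theta`, one column per item,
#' categories drawn from [pcm_category_probs]. `shift`, when given, is a
#' persons-by-items matrix of threshold shifts (a +d shift of an item's
#' thresholds equals a -d shift of the person's effective ability on that
#' item), used for injecting DIF.
#'
#' @param theta numeric vector of abilities.
#' @param items item parameters.
#' @param shift optional persons-by-items matrix of logit shifts.
#' @return integer response matrix.
#' @export
simulate_pcm_matrix <- function(theta, items, shift = NULL) {
  items <- as_pcm_items(items)
  n <- length(theta)
  X <- matrix(NA_integer_, n, length(items),
              dimnames = list(NULL, names(items)))
  for (i in seq_along(items)) {
    eff <- if (is.null(shift)) theta else theta - shift[, i]
    P <- pcm_category_probs(eff, items[[i]])
    if (n == 1L) P <- matrix(P, nrow = 1L)
    cum <- P
    for (k in 2:ncol(P)) cum[, k] <- cum[, k - 1L] + P[, k]
    u <- stats::runif(n)
    X[, i] <- rowSums(u > cum)           # count of cumulative cells below u
  }
  X
}

#' Simulate FDD11-like response data
#'
#' Generates ordinal response matrices from the Partial Credit Model at a
#' known calibration, emulating the structure of pooled general-population
#' disability survey data: a strongly right-skewed ability distribution
#' (most respondents report no or little difficulty), optional country-like
#' group labels with injected item-level DIF, sparse completely-at-random
#' missingness, and an optional twelve-question variant in which the emotion
#' item is split into two locally dependent source items (Q09a/Q09b).
#'
#' The default ability model is a mixture: a point mass of floor
#' respondents at `theta = -3.5` (weight 0.25) plus a Normal(-1.0, 1.1)
#' bulk. Set `ability = list(mean, sd)` (no `p_floor`) for a plain normal
#' population.
#'
#' @param n_persons number of respondents.
#' @param items item parameters to simulate from; default is the published
#'   FDD11 calibration (responses are then on the recoded category scale).
#' @param ability list describing the ability model: `mean`, `sd`, and
#'   optionally `p_floor` and `floor_theta` for the point-mass component.
#' @param groups optional named numeric vector of group proportions
#'   (must sum to 1).
#' @param dif_shifts optional list: `dif_shifts[[group]][[item]]` is a logit
#'   shift added to that item's thresholds for that group.
#' @param missing_rate per-cell MCAR missingness probability (default 0).
#' @param twelve_item emit `Q09a`/`Q09b` instead of the `Q09` testlet.
#' @param testlet_sd SD of the shared person-level component added to the
#'   two emotion source items in twelve-item mode (controls their residual
#'   correlation; the default targets roughly 0.4).
#' @param seed RNG seed; identical seeds give identical output.
#' @return list of class `fdd11_sim` with `responses` (integer matrix,
#'   person ids as row names), `groups` (factor or `NULL`) and `truth`
#'   (abilities, item parameters, shifts, config).
#' @examples
#' sim <- fdd11_simulate(200, seed = 1)
#' table(rowSums(sim$responses))
#' @export
fdd11_simulate <- function(n_persons,
                           items = fdd11_calibration()$items,
                           ability = list(p_floor = 0.25, floor_theta = -3.5,
                                          mean = -1.0, sd = 1.1),
                           groups = NULL, dif_shifts = NULL,
                           missing_rate = 0, twelve_item = FALSE,
                           testlet_sd = 1.8, seed = NULL) {
  if (n_persons < 1L) stop("'n_persons' must be positive")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("'missing_rate' must lie in [0, 1)")
  if (!is.null(groups)) {
    if (is.null(names(groups)) || abs(sum(groups) - 1) > 1e-8)
      stop("'groups' must be named proportions summing to 1")
  }
  if (!is.null(dif_shifts)) {
    if (is.null(groups)) stop("'dif_shifts' requires 'groups'")
    bad <- setdiff(names(dif_shifts), names(groups))
    if (length(bad)) stop("dif_shifts for unknown group(s): ",
                          paste(bad, collapse = ", "))
    if (any(!is.finite(unlist(dif_shifts)))) stop("DIF shifts must be finite")
  }
  items <- as_pcm_items(items)
  if (!is.null(seed)) set.seed(seed)

  theta <- stats::rnorm(n_persons, ability$mean, ability$sd)
  if (!is.null(ability$p_floor) && ability$p_floor > 0) {
    floor_at <- stats::runif(n_persons) < ability$p_floor
    theta[floor_at] <- ability$floor_theta %||% -3.5
  }

  grp <- NULL
  shift <- NULL
  if (!is.null(groups)) {
    grp <- factor(sample(names(groups), n_persons, replace = TRUE,
                         prob = groups), levels = names(groups))
    if (!is.null(dif_shifts)) {
      shift <- matrix(0, n_persons, length(items),
                      dimnames = list(NULL, names(items)))
      for (g in names(dif_shifts)) {
        s <- dif_shifts[[g]]
        shift[grp == g, names(s)] <-
          matrix(as.numeric(s), sum(grp == g), length(s), byrow = TRUE)
      }
    }
  }

  X <- simulate_pcm_matrix(theta, items, shift)

  if (twelve_item) {
    if (!"Q09" %in% names(items))
      stop("twelve-item mode needs a Q09 testlet item in the calibration")
    u <- stats::rnorm(n_persons, 0, testlet_sd)
    tau9 <- items[["Q09"]]
    sub <- pcm_items(list(Q09a = tau9, Q09b = tau9))
    sh9 <- if (is.null(shift)) NULL else shift[, c("Q09", "Q09"), drop = FALSE]
    XQ <- simulate_pcm_matrix(theta + u, sub, sh9)
    X <- cbind(X[, setdiff(colnames(X), "Q09"), drop = FALSE], XQ)
    X <- X[, order(colnames(X)), drop = FALSE]
  }

  if (missing_rate > 0) {
    drop <- matrix(stats::runif(length(X)) < missing_rate, nrow(X))
    X[drop] <- NA_integer_
  }
  rownames(X) <- sprintf("P%06d", seq_len(n_persons))

  structure(list(
    responses = X,
    groups = grp,
    truth = list(abilities = theta, items = items, dif_shifts = dif_shifts,
                 config = list(n_persons = n_persons, ability = ability,
                               groups = groups, missing_rate = missing_rate,
                               twelve_item = twelve_item,
                               testlet_sd = testlet_sd, seed = seed))
  ), class = "fdd11_sim")
}

#' @export
print.fdd11_sim <- function(x, ...) {
  cat("Synthetic FDD11-style dataset:", nrow(x$responses), "persons x",
      ncol(x$responses), "items\n")
  cat("  missing cells:", sum(is.na(x$responses)),
      sprintf("(%.2f%%)\n", 100 * mean(is.na(x$responses))))
  if (!is.null(x$groups)) {
    cat("  groups:\n")
    print(table(x$groups))
  }
  invisible(x)
}
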