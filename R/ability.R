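#' Maximum likelihood person ability from a sum score
#'
#' Under the Partial Credit Model the recoded sum score is sufficient for the
#' person parameter, so the ML estimate \eqn{\hat\theta(s)} solves
#' \eqn{E(\mathrm{score} \mid \theta) = s}; its standard error is
#' \eqn{I(\hat\theta)^{-1/2}} with \eqn{I} the test information. The
#' likelihood has no maximum at the extreme scores 0 and \eqn{\sum_i m_i};
#' those are returned as the configured anchor abilities (flagged, no SE), or
#' — when no anchors are supplied and `extrapolate = TRUE` — as the ML
#' solution at the fractional score `extreme_adjust` / max−`extreme_adjust`.
#'
#' @param sum_score integer vector of sum scores on the scale of `items`.
#' @param items item parameters ([pcm_items], fitted model or calibration).
#' @param anchors optional numeric `c(theta_min, theta_max)`: abilities
#'   assigned to the extreme scores (the shipped FDD11 calibration uses
#'   −3.71 and 4.18).
#' @param extrapolate if `TRUE` and no anchors are given, extreme scores are
#'   estimated at a fractional score adjustment; if `FALSE`, extreme scores
#'   without anchors are an error.
#' @param extreme_adjust fractional score used for extrapolation (default 0.3).
#' @param interval search interval for the root (logits).
#' @param tol convergence tolerance on the expected score.
#' @return data frame of class `pcm_ability` with columns `sum_score`,
#'   `theta`, `se`, `extreme`.
#' @examples
#' cal <- fdd11_calibration()
#' pcm_ability(15, cal$items)          # theta ~ 0.303, se ~ 0.341
#' pcm_ability(0, cal$items, anchors = cal$anchors)
#' @export
pcm_ability <- function(sum_score, items, anchors = NULL,
                        extrapolate = TRUE, extreme_adjust = 0.3,
                        interval = c(-10, 10), tol = 1e-8) {
  items <- as_pcm_items(items)
  max_score <- sum(max_categories(items))
  sum_score <- as.numeric(sum_score)
  if (any(!is.finite(sum_score)) || any(sum_score < 0) ||
      any(sum_score > max_score))
    stop("sum scores must lie in [0, ", max_score, "]")
  if (!is.null(anchors)) {
    anchors <- as.numeric(anchors)
    if (length(anchors) != 2L || any(!is.finite(anchors)) ||
        anchors[1] >= anchors[2])
      stop("'anchors' must be two finite logits with theta_min < theta_max")
  }

  solve_one <- function(s) {
    th <- theta_root(s, items, interval, tol)
    c(theta = th, se = 1 / sqrt(pcm_information(th, items)))
  }

  out <- data.frame(sum_score = sum_score, theta = NA_real_, se = NA_real_,
                    extreme = sum_score %in% c(0, max_score))
  interior <- !out$extreme
  if (any(interior)) {
    uniq <- unique(sum_score[interior])
    est <- vapply(uniq, solve_one, numeric(2))
    idx <- match(sum_score[interior], uniq)
    out$theta[interior] <- est["theta", idx]
    out$se[interior] <- est["se", idx]
  }
  if (any(out$extreme)) {
    if (!is.null(anchors)) {
      out$theta[out$extreme & sum_score == 0] <- anchors[1]
      out$theta[out$extreme & sum_score == max_score] <- anchors[2]
    } else if (extrapolate) {
      if (extreme_adjust <= 0 || extreme_adjust >= 1)
        stop("'extreme_adjust' must lie in (0, 1)")
      lo <- theta_root(extreme_adjust, items, interval, tol)
      hi <- theta_root(max_score - extreme_adjust, items, interval, tol)
      out$theta[out$extreme & sum_score == 0] <- lo
      out$theta[out$extreme & sum_score == max_score] <- hi
    } else {
      stop("extreme sum score (0 or maximum): no ML estimate exists and no ",
           "anchors are configured")
    }
  }
  class(out) <- c("pcm_ability", "data.frame")
  out
}

## Bisection-bracketed Newton for E(score|theta) = s on `interval`.
theta_root <- function(s, items, interval = c(-10, 10), tol = 1e-8) {
  lo <- interval[1]; hi <- interval[2]
  flo <- pcm_expected_score(lo, items) - s
  fhi <- pcm_expected_score(hi, items) - s
  if (flo > 0 || fhi < 0)
    stop("root not bracketed by the search interval; widen 'interval'")
  th <- 0
  if (th < lo || th > hi) th <- (lo + hi) / 2
  for (iter in 1:100) {
    f <- pcm_expected_score(th, items) - s
    if (abs(f) < tol) return(th)
    if (f > 0) hi <- th else lo <- th
    step <- f / pcm_information(th, items)   # Newton: d E/d theta = information
    th_new <- th - step
    if (!is.finite(th_new) || th_new <= lo || th_new >= hi)
      th_new <- (lo + hi) / 2                # fall back to bisection
    th <- th_new
  }
  th
}

#' @export
print.pcm_ability <- function(x, digits = 3, ...) {
  y <- x
  y$theta <- round(y$theta, digits)
  y$se <- round(y$se, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Full sum-score conversion table
#'
#' Builds the score-to-measure table for an instrument: for every possible
#' recoded sum score, the ML ability and standard error, the transformed
#' 0-100 score (when anchors are supplied) and the disability level (when
#' cut-offs are supplied). With the shipped FDD11 calibration this reproduces
#' the published 31-row conversion table.
#'
#' @param items item parameters, fitted model or calibration artifact (a
#'   calibration artifact contributes its anchors and cut-offs automatically).
#' @param anchors optional `c(theta_min, theta_max)` for the extreme scores
#'   and the 0-100 transform.
#' @param cutoffs optional [fdd11_cutoffs] for level assignment.
#' @param ... passed to [pcm_ability].
#' @return data frame with columns `sum_score`, `theta`, `se`, and, when
#'   available, `score_0_100` and `level`.
#' @examples
#' head(pcm_score_table(fdd11_calibration()))
#' @export
pcm_score_table <- function(items, anchors = NULL, cutoffs = NULL, ...) {
  if (inherits(items, "fdd11_calibration")) {
    if (is.null(anchors)) anchors <- items$anchors
    if (is.null(cutoffs)) cutoffs <- items$cutoffs
    items <- items$items
  }
  items <- as_pcm_items(items)
  max_score <- sum(max_categories(items))
  tab <- pcm_ability(0:max_score, items, anchors = anchors, ...)
  tab <- as.data.frame(unclass(tab))
  if (!is.null(anchors)) {
    tab$score_0_100 <- transform_to_scale(tab$theta, anchors)
    if (!is.null(cutoffs)) tab$level <- assign_level(tab$score_0_100, cutoffs)
  }
  tab
}

## ML abilities for a response matrix (persons x items, NA = missing),
## estimated over each person's answered items only. Persons with identical
## answered-item pattern and score share one root-finding call.
estimate_persons <- function(X, items, anchors = NULL, ...) {
  items <- as_pcm_items(items)
  X <- as.matrix(X)
  if (ncol(X) != length(items))
    stop("response matrix and item parameters disagree on item count")
  n <- nrow(X)
  score <- rowSums(X, na.rm = TRUE)
  answered <- !is.na(X)
  key <- paste(apply(answered, 1L, function(a) paste(which(a), collapse = ",")),
               score, sep = "|")
  out <- data.frame(theta = rep(NA_real_, n), se = NA_real_,
                    sum_score = score, n_missing = rowSums(!answered),
                    extreme = NA)
  for (k in unique(key)) {
    rows <- which(key == k)
    cols <- which(answered[rows[1L], ])
    if (length(cols) == 0L) next
    est <- pcm_ability(score[rows[1L]], pcm_items(unclass(items)[cols]),
                       anchors = anchors, ...)
    out$theta[rows] <- est$theta
    out$se[rows] <- est$se
    out$extreme[rows] <- est$extreme
  }
  out
}
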