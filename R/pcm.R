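#' Partial Credit Model category probabilities
#'
#' Probability of each response category of one item at ability `theta`:
#' \deqn{P(X_i = k \mid \theta) \propto \exp\{\sum_{j \le k} (\theta - \tau_{ij})\},}
#' with the empty sum equal to 0 for \eqn{k = 0}. Computed with a log-space
#' shift, so the vector sums to one to machine precision for any finite
#' ability.
#'
#' @param theta numeric vector of abilities (logits).
#' @param thresholds numeric vector of item thresholds \eqn{\tau_{i1..im}},
#'   or a single-item [pcm_items] object.
#' @return a `length(theta) x (m+1)` matrix of category probabilities
#'   (a plain vector if `theta` has length one).
#' @examples
#' pcm_category_probs(0, c(0, 0))   # 1/3 each
#' pcm_category_probs(0.66, 0.66)   # dichotomous symmetry: 0.5, 0.5
#' @export
pcm_category_probs <- function(theta, thresholds) {
  if (inherits(thresholds, "pcm_items")) {
    if (length(thresholds) != 1L)
      stop("supply a single item's thresholds")
    thresholds <- thresholds[[1L]]
  }
  thresholds <- as.numeric(thresholds)
  if (any(!is.finite(thresholds))) stop("thresholds must be finite")
  if (any(!is.finite(theta))) stop("'theta' must be finite")
  beta <- c(0, cumsum(thresholds))           # cumulative thresholds
  k <- seq_along(beta) - 1L
  lp <- outer(theta, k) - rep(beta, each = length(theta))
  lp <- lp - apply(lp, 1L, max)
  p <- exp(lp)
  p <- p / rowSums(p)
  if (length(theta) == 1L) drop(p) else p
}

## Per-item conditional mean and variance of the category score at theta.
## Returns list(mean, var) as length(theta) x n_items matrices.
pcm_item_moments <- function(theta, items) {
  items <- as_pcm_items(items)
  n <- length(theta)
  E <- V <- matrix(NA_real_, n, length(items),
                   dimnames = list(NULL, names(items)))
  for (i in seq_along(items)) {
    p <- pcm_category_probs(theta, items[[i]])
    if (n == 1L) p <- matrix(p, nrow = 1L)
    k <- 0:(ncol(p) - 1L)
    m1 <- p %*% k
    E[, i] <- m1
    V[, i] <- p %*% k^2 - m1^2
  }
  list(mean = E, var = V)
}

#' Expected total score and Fisher information
#'
#' The model-implied expected sum score \eqn{\sum_i \sum_k k P(X_i=k|\theta)}
#' and the test information \eqn{\sum_i \mathrm{Var}(X_i|\theta)} across a set
#' of items. The expected score is continuous and strictly increasing in
#' `theta`, which makes it the estimating function for maximum likelihood
#' person estimation (the sum score is sufficient for \eqn{\theta} under the
#' PCM); the reciprocal square root of the information is the asymptotic
#' standard error of \eqn{\hat\theta}.
#'
#' @param theta numeric vector of abilities (logits).
#' @param items a [pcm_items] object (or anything coercible: a fitted
#'   [pcm_fit] model or a calibration artifact).
#' @return `pcm_expected_score`: numeric vector of expected sum scores;
#'   `pcm_information`: numeric vector of test information values.
#' @examples
#' it <- pcm_items(list(a = 0))   # one dichotomous item
#' pcm_expected_score(0, it)      # 0.5
#' pcm_information(0, it)         # 0.25
#' @export
pcm_expected_score <- function(theta, items) {
  mom <- pcm_item_moments(theta, items)
  rowSums(mom$mean)
}

#' @rdname pcm_expected_score
#' @export
pcm_information <- function(theta, items) {
  mom <- pcm_item_moments(theta, items)
  rowSums(mom$var)
}
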