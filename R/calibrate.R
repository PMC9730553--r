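## ---- log-space elementary symmetric function machinery ----------------
##
## The conditional likelihood of the Partial Credit Model factors through
## gamma_r, the polytomous elementary symmetric functions: coefficients of
## z^r in prod_i sum_k exp(-beta_ik) z^k, with beta_ik = sum_{j<=k} tau_ij.
## They are computed by the summation recursion (sequential polynomial
## convolution) entirely in log space for numerical stability.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

## convolution of two polynomials given by log-coefficient vectors
log_poly_conv <- function(a, b) {
  na <- length(a); nb <- length(b)
  out <- numeric(na + nb - 1L)
  for (s in seq_along(out)) {
    i <- max(1L, s - nb + 1L):min(na, s)
    out[s] <- logsumexp(a[i] + b[s - i + 1L])
  }
  out
}

## log coefficient vector of item i: (0, -beta_i1, ..., -beta_im)
item_log_poly <- function(tau) c(0, -cumsum(tau))

## log gamma_r, r = 0..sum(m_i), for a list of threshold vectors
log_esf <- function(taus) {
  out <- 0
  for (tau in taus) out <- log_poly_conv(out, item_log_poly(tau))
  out
}

## ---- conditional likelihood on pattern-grouped data -------------------
##
## Persons are grouped by their set of answered items; each group has its
## own ESF. `groups` entries: list(cols, score_counts (named by score),
## cat_counts (list per col of counts for categories 0..m)).

cml_group_data <- function(X, m) {
  answered <- !is.na(X)
  patt <- apply(answered, 1L, function(a) paste(which(a), collapse = ","))
  score <- rowSums(X, na.rm = TRUE)
  groups <- list()
  dropped <- 0L
  for (p in unique(patt)) {
    rows <- which(patt == p)
    cols <- which(answered[rows[1L], ])
    if (length(cols) < 2L) { dropped <- dropped + length(rows); next }
    rmax <- sum(m[cols])
    keep <- rows[score[rows] > 0 & score[rows] < rmax]
    dropped <- dropped + (length(rows) - length(keep))
    if (length(keep) == 0L) next
    sc <- table(score[keep])
    cat_counts <- lapply(cols, function(j)
      tabulate(X[keep, j] + 1L, nbins = m[j] + 1L))
    groups[[length(groups) + 1L]] <- list(
      cols = cols, rmax = rmax,
      scores = as.integer(names(sc)), n_r = as.numeric(sc),
      cat_counts = cat_counts)
  }
  list(groups = groups, n_dropped = dropped)
}

## negative conditional log-likelihood and analytic gradient in tau
cml_nll <- function(par, groups, m) {
  taus <- split_par(par, m)
  nll <- 0
  for (g in groups) {
    lg <- log_esf(taus[g$cols])
    nll <- nll + sum(g$n_r * lg[g$scores + 1L])
    for (t in seq_along(g$cols)) {
      beta <- cumsum(taus[[g$cols[t]]])
      nll <- nll + sum(g$cat_counts[[t]][-1L] * beta)
    }
  }
  nll
}

cml_grad <- function(par, groups, m) {
  taus <- split_par(par, m)
  gbeta <- lapply(m, function(mi) numeric(mi))   # d nll / d beta_ik, k>=1
  for (g in groups) {
    polys <- lapply(taus[g$cols], item_log_poly)
    Tn <- length(polys)
    pre <- vector("list", Tn + 1L); suf <- vector("list", Tn + 1L)
    pre[[1L]] <- 0; suf[[Tn + 1L]] <- 0
    for (t in seq_len(Tn)) pre[[t + 1L]] <- log_poly_conv(pre[[t]], polys[[t]])
    for (t in rev(seq_len(Tn))) suf[[t]] <- log_poly_conv(polys[[t]], suf[[t + 1L]])
    lg <- pre[[Tn + 1L]]
    for (t in seq_len(Tn)) {
      j <- g$cols[t]
      lnoi <- if (Tn == 1L) 0 else log_poly_conv(pre[[t]], suf[[t + 1L]])
      lf <- polys[[t]]
      mk <- m[j]
      ## expected category counts E_k = sum_r n_r P(X=k | score r)
      Ek <- numeric(mk + 1L)
      for (ri in seq_along(g$scores)) {
        r <- g$scores[ri]
        ks <- max(0L, r - (length(lnoi) - 1L)):min(mk, r)
        Ek[ks + 1L] <- Ek[ks + 1L] +
          g$n_r[ri] * exp(lf[ks + 1L] + lnoi[r - ks + 1L] - lg[r + 1L])
      }
      gbeta[[j]] <- gbeta[[j]] + (g$cat_counts[[t]][-1L] - Ek[-1L])
    }
  }
  ## chain rule: d/d tau_ij = sum_{k >= j} d/d beta_ik
  unlist(lapply(gbeta, function(v) rev(cumsum(rev(v)))), use.names = FALSE)
}

split_par <- function(par, m) {
  idx <- rep.int(seq_along(m), m)
  split(par, idx)
}

## ---- category collapsing for never-observed categories ----------------

collapse_structural_zeros <- function(X, action = c("warn", "error")) {
  action <- match.arg(action)
  X <- as.matrix(X)
  maps <- vector("list", ncol(X))
  names(maps) <- colnames(X)
  changed <- FALSE
  for (j in seq_len(ncol(X))) {
    vals <- sort(unique(X[!is.na(X[, j]), j]))
    if (length(vals) < 2L)
      stop("item ", colnames(X)[j] %||% j,
           " has fewer than two observed categories; cannot calibrate")
    full <- 0:max(vals)
    map <- match(full, vals) - 1L          # NA for unobserved categories
    ## unobserved categories merge downward onto the nearest observed one
    map <- cummax_na(map)
    maps[[j]] <- map
    if (!identical(map, full)) {
      changed <- TRUE
      X[, j] <- map[X[, j] + 1L]
    }
  }
  if (changed) {
    msg <- "never-observed categories collapsed onto their lower neighbour"
    if (action == "error") stop(msg) else warning(msg, call. = FALSE)
  }
  list(X = X, maps = if (changed) maps else NULL)
}

cummax_na <- function(x) {
  last <- 0L
  for (i in seq_along(x)) {
    if (is.na(x[i])) x[i] <- last else last <- x[i]
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- the fitting function ---------------------------------------------

#' Fit a Partial Credit Model by conditional maximum likelihood
#'
#' Calibrates item thresholds from a persons-by-items matrix of ordinal
#' responses (integer categories `0..m_i`, `NA` = missing) by maximizing the
#' conditional likelihood given each person's sum score, so no assumption is
#' made about the ability distribution. The conditional likelihood is
#' evaluated through log-space elementary symmetric functions; persons with
#' extreme (zero or maximal) scores carry no information and are dropped
#' internally; persons with missing responses contribute through the
#' conditional likelihood of their answered items. CML identifies thresholds
#' only up to an additive constant: estimates are reported centered
#' (mean threshold 0) and the centering constant is stored as `$shift`.
#'
#' After calibration every person's ML ability and standard error are
#' estimated from their answered items (see [pcm_ability]).
#'
#' @param data matrix or data frame of integer responses, columns = items;
#'   categories must start at 0. Never-observed categories are collapsed
#'   onto their lower neighbour first (with a warning, or an error when
#'   `collapse = "error"`).
#' @param groups optional per-person group labels (kept for DIF screening).
#' @param collapse `"warn"` (default) or `"error"`: what to do when a
#'   never-observed category forces a collapse.
#' @param gtol convergence tolerance on the mean absolute gradient of the
#'   conditional log-likelihood (per retained person).
#' @param max_iter maximum optimizer iterations.
#' @param se compute threshold standard errors from the observed information
#'   (numerical Hessian, Moore-Penrose inverse to respect the identification
#'   constraint)? Default `TRUE`.
#' @return an object of class `pcm_fit` with components `items` (centered
#'   [pcm_items] with SE attribute), `shift`, `logLik_cond`, `convergence`
#'   (`converged`, `iterations`, `gradient_norm`), `abilities` (per-person
#'   data frame), `data`, `groups`, `collapse_maps`, `n_persons`,
#'   `n_dropped_extreme`.
#' @seealso [summary.pcm_fit], [residuals.pcm_fit], [simulate.pcm_fit]
#' @examples
#' sim <- fdd11_simulate(400, seed = 1)
#' fit <- pcm_fit(sim$responses)
#' coef(fit)
#' @export
pcm_fit <- function(data, groups = NULL, collapse = c("warn", "error"),
                    gtol = 1e-8, max_iter = 200, se = TRUE) {
  X <- as.matrix(data)
  storage.mode(X) <- "integer"
  if (is.null(colnames(X))) colnames(X) <- sprintf("I%02d", seq_len(ncol(X)))
  if (ncol(X) < 2L) stop("need at least two items")
  if (any(X < 0, na.rm = TRUE)) stop("categories must be coded 0, 1, 2, ...")
  if (!is.null(groups)) {
    if (length(groups) != nrow(X))
      stop("'groups' must have one label per person")
    groups <- as.factor(groups)
  }

  coll <- collapse_structural_zeros(X, match.arg(collapse))
  X <- coll$X
  m <- apply(X, 2L, max, na.rm = TRUE)

  gd <- cml_group_data(X, m)
  if (length(gd$groups) == 0L)
    stop("no informative persons (all scores extreme or too few answers)")
  n_retained <- sum(vapply(gd$groups, function(g) sum(g$n_r), numeric(1)))

  fn <- function(p) cml_nll(p, gd$groups, m)
  gr <- function(p) cml_grad(p, gd$groups, m)
  par <- numeric(sum(m))
  opt <- stats::optim(par, fn, gr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-13))
  par <- opt$par
  iterations <- opt$counts[["gradient"]]
  ## Newton polish to drive the gradient to the requested tolerance
  for (it in 1:25) {
    g <- gr(par)
    if (mean(abs(g)) / n_retained < gtol) break
    H <- stats::optimHess(par, fn, gr)
    step <- tryCatch(drop(MASS::ginv(H) %*% g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    new <- par - step
    if (fn(new) > fn(par) + 1e-9) break
    par <- new
    iterations <- iterations + 1L
  }
  g <- gr(par)
  grad_norm <- mean(abs(g)) / n_retained
  converged <- grad_norm < gtol
  if (!converged)
    warning("CML estimation did not reach the gradient tolerance (",
            format(grad_norm, digits = 3), " > ", gtol,
            "); returning the last iterate", call. = FALSE)

  shift <- mean(par)
  par_c <- par - shift
  taus <- split_par(par_c, m)
  names(taus) <- colnames(X)

  ses <- NULL
  if (se) {
    H <- stats::optimHess(par, fn, gr)
    V <- MASS::ginv(H)
    P <- length(par)
    C <- diag(P) - matrix(1 / P, P, P)     # centering projection
    Vc <- C %*% V %*% t(C)
    ses <- split_par(sqrt(pmax(diag(Vc), 0)), m)
    names(ses) <- colnames(X)
  }

  items <- pcm_items(taus, ses = ses)
  abilities <- estimate_persons(X, items, anchors = NULL, extrapolate = TRUE)
  if (!is.null(rownames(X))) abilities <- cbind(person_id = rownames(X), abilities)

  structure(list(
    items = items, shift = shift,
    logLik_cond = -fn(par),
    convergence = list(converged = converged, iterations = iterations,
                       gradient_norm = grad_norm),
    abilities = abilities,
    data = X, groups = groups,
    collapse_maps = coll$maps,
    n_persons = nrow(X),
    n_retained = n_retained,
    n_dropped_extreme = gd$n_dropped,
    call = match.call()
  ), class = "pcm_fit")
}

#' @export
print.pcm_fit <- function(x, digits = 3, ...) {
  cat("Partial Credit Model (conditional maximum likelihood)\n")
  cat(sprintf("  %d items, %d persons (%d informative, %d extreme/uninformative dropped)\n",
              length(x$items), x$n_persons, x$n_retained, x$n_dropped_extreme))
  cat(sprintf("  conditional logLik %.2f; %s after %d iterations (mean |grad| %.2e)\n",
              x$logLik_cond,
              if (x$convergence$converged) "converged" else "NOT converged",
              x$convergence$iterations, x$convergence$gradient_norm))
  cat("  thresholds centered at mean 0 (shift ", round(x$shift, digits), ")\n\n",
      sep = "")
  print(x$items, digits = digits)
  invisible(x)
}

#' @export
coef.pcm_fit <- function(object, ...) {
  m <- max(lengths(object$items))
  t(vapply(object$items,
           function(tau) c(tau, rep(NA_real_, m - length(tau))),
           numeric(m)))
}

#' @export
logLik.pcm_fit <- function(object, ...) {
  structure(object$logLik_cond, df = sum(lengths(object$items)) - 1L,
            class = "logLik")
}

#' @export
vcov.pcm_fit <- function(object, ...) {
  ses <- attr(object$items, "se")
  if (is.null(ses)) stop("fit was computed with se = FALSE")
  diag(unlist(ses)^2)
}

#' Standardized response residuals of a fitted PCM
#'
#' @param object a [pcm_fit] object.
#' @param ... unused.
#' @return persons-by-items matrix of standardized residuals (see
#'   [standardized_residuals]).
#' @export
residuals.pcm_fit <- function(object, ...) {
  standardized_residuals(object$data, object$items, object$abilities)
}

#' Person ability estimates from a fitted PCM
#'
#' @param object a [pcm_fit] object.
#' @param newdata optional response matrix on the same items; defaults to the
#'   calibration data (whose estimates are precomputed).
#' @param anchors optional extreme-score anchors.
#' @param ... passed to [pcm_ability].
#' @return data frame with `theta`, `se`, `sum_score`, `n_missing`, `extreme`.
#' @export
predict.pcm_fit <- function(object, newdata = NULL, anchors = NULL, ...) {
  if (is.null(newdata) && is.null(anchors)) return(object$abilities)
  X <- if (is.null(newdata)) object$data else as.matrix(newdata)
  estimate_persons(X, object$items, anchors = anchors, ...)
}

#' Simulate response matrices from a fitted PCM
#'
#' Draws model-true datasets at the fitted thresholds, with abilities
#' resampled from the estimated person abilities (parametric bootstrap of
#' the measurement part, empirical for the ability distribution).
#'
#' @param object a [pcm_fit] object.
#' @param nsim number of datasets.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return list of response matrices.
#' @export
simulate.pcm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  th <- object$abilities$theta
  lapply(seq_len(nsim), function(i)
    simulate_pcm_matrix(sample(th, length(th), replace = TRUE), object$items))
}

#' Person-item map of a fitted PCM
#'
#' Plots the distribution of estimated person abilities above the item
#' threshold locations on the shared logit continuum (the standard targeting
#' display for Rasch-family models).
#'
#' @param x a [pcm_fit] object, a [pcm_items] object, or a calibration
#'   artifact (the latter two require `abilities`).
#' @param abilities optional numeric vector of person abilities; taken from
#'   the fit when `x` is a [pcm_fit].
#' @param main plot title.
#' @param ... passed to [graphics::hist].
#' @return invisibly, the [targeting_summary] of the inputs.
#' @export
plot.pcm_fit <- function(x, abilities = NULL, main = "Person-item map", ...) {
  items <- as_pcm_items(x)
  if (is.null(abilities) && inherits(x, "pcm_fit"))
    abilities <- x$abilities$theta[!x$abilities$extreme]
  if (is.null(abilities)) stop("supply person abilities")
  old <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 3, 1))
  on.exit(graphics::par(old))
  rng <- range(c(abilities, unlist(items)), finite = TRUE)
  graphics::hist(abilities, breaks = 40, xlim = rng, main = main,
                 xlab = "", col = "grey80", border = "white", ...)
  graphics::par(mar = c(4, 4, 1, 1))
  locs <- item_locations(items)
  graphics::plot(NA, xlim = rng, ylim = c(0.5, length(items) + 0.5),
                 yaxt = "n", xlab = "Latent continuum (logits)", ylab = "")
  graphics::axis(2, at = seq_along(items), labels = names(items), las = 1,
                 cex.axis = 0.7)
  for (i in seq_along(items)) {
    graphics::points(items[[i]], rep(i, length(items[[i]])), pch = 1)
    graphics::points(locs[i], i, pch = 16)
  }
  invisible(targeting_summary(abilities, items))
}
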