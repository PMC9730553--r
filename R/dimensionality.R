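## Unidimensionality assessment: polychoric correlations, Horn's parallel
## analysis, and an exploratory bi-factor (Schmid-Leiman) loading
## comparison between the general and the specific factors.

## Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
## construction of the Jacobi matrix.
gauss_legendre <- function(n) {
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1L, ]^2)
}

## Standard bivariate normal CDF Phi2(h, k, rho), vectorized over h and k
## (matrices of equal shape). Uses the identity
##   Phi2(h, k, rho) = Phi(h) Phi(k) + int_0^rho phi2(h, k, t) dt
## with Gauss-Legendre quadrature over the correlation parameter.
pbivnorm <- function(h, k, rho) {
  if (is.null(.fdd11_cache$gl48))
    .fdd11_cache$gl48 <- gauss_legendre(48L)
  gl <- .fdd11_cache$gl48
  out <- stats::pnorm(h) * stats::pnorm(k)
  if (abs(rho) < .Machine$double.eps) return(out)
  t <- rho / 2 * (gl$nodes + 1)          # map [-1,1] -> [0, rho]
  w <- rho / 2 * gl$weights
  acc <- 0
  for (q in seq_along(t)) {
    tq <- t[q]; om <- 1 - tq^2
    dens <- exp(-(h^2 - 2 * tq * h * k + k^2) / (2 * om)) /
      (2 * pi * sqrt(om))
    acc <- acc + w[q] * dens
  }
  out + acc
}

## cell probabilities of a two-way ordinal table under the bivariate normal
## model with thresholds a (rows), b (cols) and latent correlation rho
polychoric_cell_probs <- function(a, b, rho) {
  aa <- c(-Inf, a, Inf); bb <- c(-Inf, b, Inf)
  H <- matrix(aa, length(aa), length(bb))
  K <- matrix(bb, length(aa), length(bb), byrow = TRUE)
  P <- matrix(0, length(aa), length(bb))
  fin <- is.finite(H) & is.finite(K)
  P[fin] <- pbivnorm(H[fin], K[fin], rho)
  P[H == Inf & K == Inf] <- 1
  hi <- H == Inf & is.finite(K); P[hi] <- stats::pnorm(K[hi])
  ki <- K == Inf & is.finite(H); P[ki] <- stats::pnorm(H[ki])
  ## P currently holds the CDF at upper-right corners (-Inf rows/cols are 0)
  cell <- P[-1L, -1L, drop = FALSE] - P[-nrow(P), -1L, drop = FALSE] -
    P[-1L, -ncol(P), drop = FALSE] + P[-nrow(P), -ncol(P), drop = FALSE]
  pmax(cell, 1e-12)
}

## two-step ML polychoric correlation for one item pair
polychoric_pair <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  tab <- table(factor(x, levels = sort(unique(x))),
               factor(y, levels = sort(unique(y))))
  margins <- function(t) {
    p <- cumsum(rowSums(t)) / sum(t)
    stats::qnorm(p[-length(p)])
  }
  a <- margins(tab); b <- margins(t(tab))
  nll <- function(r) -sum(tab * log(polychoric_cell_probs(a, b, r)))
  opt <- stats::optimize(nll, c(-0.999, 0.999))
  opt$minimum
}

#' Polychoric correlation matrix
#'
#' Pairwise two-step maximum likelihood polychoric correlations for
#' ordered-category data: item thresholds from the cumulative margins, then
#' the latent correlation maximizing the bivariate-normal cell likelihood.
#' Items with a single observed category are excluded with a warning. If the
#' resulting matrix is not positive semi-definite it is repaired to the
#' nearest PSD matrix (eigenvalue clipping) with a warning.
#'
#' @param data persons-by-items matrix of ordinal categories (NA allowed;
#'   pairwise-complete observations per pair).
#' @return symmetric correlation matrix.
#' @export
polychoric_matrix <- function(data) {
  X <- as.matrix(data)
  if (is.null(colnames(X))) colnames(X) <- sprintf("I%02d", seq_len(ncol(X)))
  ncat <- apply(X, 2L, function(v) length(unique(v[!is.na(v)])))
  if (any(ncat < 2L)) {
    warning("excluding single-category item(s): ",
            paste(colnames(X)[ncat < 2L], collapse = ", "), call. = FALSE)
    X <- X[, ncat >= 2L, drop = FALSE]
  }
  p <- ncol(X)
  if (p < 2L) stop("need at least two items with two or more categories")
  C <- diag(p)
  dimnames(C) <- list(colnames(X), colnames(X))
  for (i in seq_len(p - 1L))
    for (j in (i + 1L):p)
      C[i, j] <- C[j, i] <- polychoric_pair(X[, i], X[, j])
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    warning("polychoric matrix not positive semi-definite; applying ",
            "nearest-PSD repair", call. = FALSE)
    v <- pmax(ev$values, 1e-8)
    C <- ev$vectors %*% diag(v) %*% t(ev$vectors)
    d <- sqrt(diag(C))
    C <- C / tcrossprod(d)
    dimnames(C) <- list(colnames(X), colnames(X))
  }
  C
}

#' Parallel analysis for the number of factors
#'
#' Horn's parallel analysis: the observed (principal-component) eigenvalues
#' of the correlation matrix are compared with the chosen quantile of
#' eigenvalues of correlation matrices of independent standard-normal data
#' of the same n-by-p shape. Leading factors are retained while their
#' eigenvalue exceeds the reference (counting stops at the first failure,
#' so pure-noise data yields 0).
#'
#' @param corr observed correlation matrix (e.g. from [polychoric_matrix]).
#' @param n sample size behind `corr`.
#' @param reps number of random reference datasets (default 100; fewer than
#'   20 triggers a warning).
#' @param quantile reference quantile (default 0.95).
#' @param seed optional RNG seed for the reference simulation.
#' @return integer number of factors to retain, with attribute
#'   `"eigenvalues"` (observed) and `"reference"` (quantile curve).
#' @export
parallel_analysis <- function(corr, n, reps = 100, quantile = 0.95,
                              seed = NULL) {
  if (reps < 20) warning("fewer than 20 reference replicates", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(corr)
  obs <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  ref <- matrix(NA_real_, reps, p)
  for (r in seq_len(reps)) {
    Z <- matrix(stats::rnorm(n * p), n, p)
    ref[r, ] <- eigen(stats::cor(Z), symmetric = TRUE,
                      only.values = TRUE)$values
  }
  refq <- apply(ref, 2L, stats::quantile, probs = quantile)
  exceeds <- obs > refq
  nf <- if (exceeds[1L]) which.min(c(exceeds, FALSE)) - 1L else 0L
  structure(as.integer(nf), eigenvalues = obs, reference = refq)
}

#' Exploratory bi-factor check of unidimensionality
#'
#' Fits an exploratory factor model with `n_specific` first-order factors
#' (ML via [stats::factanal]), rotates obliquely (promax), factors the
#' factor correlation matrix into one second-order general factor, and
#' applies the Schmid-Leiman orthogonalization. The scale is taken as
#' unidimensional when every item loads higher (in absolute value) on the
#' general factor than on any specific factor.
#'
#' @param corr item correlation matrix (typically polychoric).
#' @param n_specific number of first-order (specific) factors, at least 1.
#'   With 1 the general factor is the single factor and the check is
#'   trivially unidimensional.
#' @param n_obs sample size behind `corr`.
#' @return list of class `fdd11_bifactor`: `n_factors`, `general_loadings`,
#'   `specific_loadings` (per-item max over specific factors),
#'   `unidimensional`, `heywood` (items with near-unit communalities).
#' @export
bifactor_check <- function(corr, n_specific, n_obs) {
  p <- ncol(corr)
  if (p < 3L) stop("need at least three items")
  if (n_specific < 1L) stop("'n_specific' must be at least 1")
  items <- colnames(corr) %||% sprintf("I%02d", seq_len(p))
  if (n_specific == 1L) {
    fa <- stats::factanal(covmat = corr, factors = 1L, n.obs = n_obs)
    g <- as.numeric(fa$loadings)
    out <- list(n_factors = 1L,
                general_loadings = stats::setNames(g, items),
                specific_loadings = stats::setNames(rep(0, p), items),
                unidimensional = TRUE,
                heywood = items[fa$uniquenesses <= 0.005 + 1e-12])
    class(out) <- "fdd11_bifactor"
    return(out)
  }
  fa <- stats::factanal(covmat = corr, factors = n_specific, n.obs = n_obs,
                        rotation = "none")
  rot <- stats::promax(stats::loadings(fa))
  L <- unclass(rot$loadings)
  Phi <- solve(crossprod(rot$rotmat))
  Phi <- stats::cov2cor((Phi + t(Phi)) / 2)
  ## resolve factor sign indeterminacy: reflect factors to positive loading sums
  s <- sign(colSums(L)); s[s == 0] <- 1
  L <- L %*% diag(s, n_specific)
  Phi <- diag(s, n_specific) %*% Phi %*% diag(s, n_specific)
  ## second-order general factor from the factor correlations
  gamma <- second_order_loadings(Phi, n_obs)
  general <- drop(L %*% gamma)
  specific <- L %*% diag(sqrt(pmax(1 - gamma^2, 0)), n_specific)
  spec_max <- apply(abs(specific), 1L, max)
  out <- list(
    n_factors = n_specific,
    general_loadings = stats::setNames(general, items),
    specific_loadings = stats::setNames(spec_max, items),
    unidimensional = all(abs(general) > spec_max),
    heywood = items[fa$uniquenesses <= 0.005 + 1e-12]
  )
  class(out) <- "fdd11_bifactor"
  out
}

second_order_loadings <- function(Phi, n_obs) {
  k <- ncol(Phi)
  if (k == 2L) {
    r <- Phi[1L, 2L]
    if (r <= 0) return(rep(0, 2L))       # no common general factor
    return(rep(sqrt(r), 2L))
  }
  fa2 <- tryCatch(
    stats::factanal(covmat = Phi, factors = 1L, n.obs = n_obs),
    error = function(e) NULL)
  if (is.null(fa2)) {
    ## fall back to the first principal component of Phi, scaled
    e <- eigen(Phi, symmetric = TRUE)
    v <- e$vectors[, 1L] * sqrt(e$values[1L])
    return(pmin(pmax(v * sign(sum(v)), -1), 1))
  }
  as.numeric(fa2$loadings)
}

#' @export
print.fdd11_bifactor <- function(x, digits = 3, ...) {
  cat("Exploratory bi-factor (Schmid-Leiman) check,", x$n_factors,
      "specific factor(s)\n")
  tab <- cbind(general = x$general_loadings,
               max_specific = x$specific_loadings)
  print(round(tab, digits))
  cat("unidimensional:", x$unidimensional, "\n")
  if (length(x$heywood))
    cat("Heywood-boundary items:", paste(x$heywood, collapse = ", "), "\n")
  invisible(x)
}
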