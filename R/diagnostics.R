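## Model-fit machinery: standardized residuals, infit mean squares, local
## dependence screening, threshold ordering, targeting, and the person
## separation index.

## normalise the `abilities` argument: accept the data frame produced by
## pcm_fit()/estimate_persons() or a bare numeric vector of thetas
as_abilities <- function(abilities, n) {
  if (is.numeric(abilities))
    abilities <- data.frame(theta = abilities, se = NA_real_,
                            extreme = FALSE)
  if (!is.data.frame(abilities) || is.null(abilities$theta))
    stop("'abilities' must be a numeric vector or a data frame with $theta")
  if (nrow(abilities) != n)
    stop("abilities and responses disagree on person count")
  if (is.null(abilities$extreme)) abilities$extreme <- FALSE
  abilities
}

## observed responses with conditional moments at each person's theta-hat;
## extreme-score persons are excluded (their extrapolated abilities would
## bias the residual moments)
residual_pieces <- function(data, items, abilities) {
  items <- as_pcm_items(items)
  X <- as.matrix(data)
  ab <- as_abilities(abilities, nrow(X))
  mom <- pcm_item_moments(ab$theta, items)
  E <- mom$mean; V <- mom$var
  E[is.na(X)] <- NA; V[is.na(X)] <- NA
  if (any(ab$extreme)) {
    E[ab$extreme, ] <- NA
    V[ab$extreme, ] <- NA
  }
  degenerate <- !is.na(V) & V < 1e-10
  if (any(degenerate)) {
    warning("zero conditional variance for some responses; residuals set ",
            "missing", call. = FALSE)
    V[degenerate] <- NA
  }
  list(x = X, E = E, V = V)
}

#' Standardized Rasch residuals
#'
#' \eqn{z_{ni} = (x_{ni} - E_{ni}) / \sqrt{\mathrm{Var}_{ni}}} with the
#' conditional PCM moments evaluated at each person's estimated ability.
#' Missing responses stay missing; persons with extreme sum scores are
#' excluded (set missing) because their abilities are anchor/extrapolation
#' values rather than ML estimates.
#'
#' @param data recoded persons-by-items response matrix.
#' @param items item parameters (or fitted model / calibration).
#' @param abilities per-person abilities: the data frame from [pcm_fit] /
#'   [predict.pcm_fit], or a numeric theta vector.
#' @return persons-by-items matrix of standardized residuals.
#' @export
standardized_residuals <- function(data, items, abilities) {
  p <- residual_pieces(data, items, abilities)
  (p$x - p$E) / sqrt(p$V)
}

#' Item infit mean squares
#'
#' Information-weighted mean-square fit statistic per item:
#' \eqn{\mathrm{infit}_i = \sum_n (x_{ni}-E_{ni})^2 / \sum_n \mathrm{Var}_{ni}},
#' with expectation 1 under the model. Items outside `bounds` (the
#' conventional \[0.7, 1.3\] range for good fit) are flagged.
#'
#' @inheritParams standardized_residuals
#' @param bounds acceptable infit range.
#' @return named numeric vector of item infits, with attribute `"flagged"`
#'   (item ids outside `bounds`).
#' @export
item_infit <- function(data, items, abilities, bounds = c(0.7, 1.3)) {
  p <- residual_pieces(data, items, abilities)
  used <- colSums(!is.na(p$V))
  if (any(used < 2L))
    warning("items with fewer than two usable responses have missing infit",
            call. = FALSE)
  num <- colSums((p$x - p$E)^2, na.rm = TRUE)
  den <- colSums(p$V, na.rm = TRUE)
  infit <- ifelse(used >= 2L, num / den, NA_real_)
  names(infit) <- colnames(p$x)
  structure(infit,
            flagged = names(infit)[!is.na(infit) &
                                     (infit < bounds[1] | infit > bounds[2])])
}

#' Person infit mean squares
#'
#' Same statistic computed across items within each person, with the
#' conventional "generous" misfit cut-off of 2. The attribute
#' `"misfit_rate"` is the fraction of assessable persons above `cutoff`.
#'
#' @inheritParams standardized_residuals
#' @param cutoff person misfit threshold (default 2).
#' @return numeric vector of person infits (NA for extreme-score persons),
#'   with attribute `"misfit_rate"`.
#' @export
person_infit <- function(data, items, abilities, cutoff = 2) {
  p <- residual_pieces(data, items, abilities)
  used <- rowSums(!is.na(p$V))
  num <- rowSums((p$x - p$E)^2, na.rm = TRUE)
  den <- rowSums(p$V, na.rm = TRUE)
  infit <- ifelse(used >= 2L, num / den, NA_real_)
  structure(infit, misfit_rate = mean(infit > cutoff, na.rm = TRUE),
            cutoff = cutoff)
}

#' Local dependence screening via residual correlations
#'
#' Pairwise Pearson correlations of the standardized residuals
#' (pairwise-complete observations). Item pairs are flagged when their
#' residual correlation is at least `margin` above the mean of all
#' off-diagonal correlations — the relative rule used for this instrument
#' (0.2 above the mean).
#'
#' @param residuals persons-by-items matrix from [standardized_residuals].
#' @param margin flagging margin above the mean residual correlation.
#' @return list with `correlations` (item matrix), `mean_correlation`,
#'   `threshold`, and `flags` (data frame `item1`, `item2`, `r`).
#' @export
residual_correlation_flags <- function(residuals, margin = 0.2) {
  R <- as.matrix(residuals)
  if (ncol(R) < 3L)
    stop("need at least three items to calibrate the flagging threshold")
  C <- stats::cor(R, use = "pairwise.complete.obs")
  off <- C[upper.tri(C)]
  thr <- margin + mean(off, na.rm = TRUE)
  idx <- which(upper.tri(C) & C >= thr, arr.ind = TRUE)
  flags <- data.frame(item1 = colnames(C)[idx[, 1L]],
                      item2 = colnames(C)[idx[, 2L]],
                      r = C[idx])
  flags <- flags[order(-flags$r), , drop = FALSE]
  rownames(flags) <- NULL
  list(correlations = C, mean_correlation = mean(off, na.rm = TRUE),
       threshold = thr, flags = flags)
}

#' Check threshold ordering
#'
#' An item's thresholds should increase with the category index; a
#' disordered pair means some category is never the most likely response
#' anywhere on the continuum, and suggests collapsing categories.
#'
#' @param items item parameters (or fitted model / calibration).
#' @return character vector of item ids with non-increasing thresholds
#'   (empty when all ordered).
#' @export
threshold_order_check <- function(items) {
  items <- as_pcm_items(items)
  bad <- vapply(items, function(tau)
    length(tau) > 1L && any(diff(tau) <= 0), logical(1))
  names(items)[bad]
}

#' Propose category collapses to restore threshold ordering
#'
#' Iteratively refits the model, and at each round merges — on the item with
#' the worst threshold inversion — the category whose bounding thresholds
#' are inverted into its upper neighbour (the minimal single-category
#' change). Stops when all items are ordered or no further merge is
#' possible.
#'
#' @param data response matrix on the original category scale.
#' @param max_rounds safety limit on refit rounds.
#' @param ... passed to [pcm_fit].
#' @return list with `recodes` (cumulative monotone maps original ->
#'   collapsed, identity where untouched), `log` (one row per merge: round,
#'   item, merged category, inversion size), `fit` (final refit) and
#'   `ordered` (logical).
#' @export
suggest_collapse <- function(data, max_rounds = 10, ...) {
  X <- as.matrix(data)
  storage.mode(X) <- "integer"
  if (is.null(colnames(X))) colnames(X) <- sprintf("I%02d", seq_len(ncol(X)))
  maps <- lapply(apply(X, 2L, max, na.rm = TRUE), function(m) 0:m)
  names(maps) <- colnames(X)
  log <- data.frame(round = integer(), item = character(),
                    merged_category = integer(), inversion = numeric())
  fit <- suppressWarnings(pcm_fit(X, ...))
  for (round in seq_len(max_rounds)) {
    disordered <- threshold_order_check(fit$items)
    if (length(disordered) == 0L) break
    ## worst inversion across disordered items
    inv <- vapply(disordered, function(id) {
      d <- diff(fit$items[[id]]); max(-d)
    }, numeric(1))
    worst <- disordered[which.max(inv)]
    tau <- fit$items[[worst]]
    k <- which.min(diff(tau))          # tau_k > tau_{k+1}: category k misbehaves
    if (max(X[, worst], na.rm = TRUE) < 2L) {
      warning("item ", worst, " cannot be collapsed further but remains ",
              "disordered", call. = FALSE)
      break
    }
    ## merge category k into k+1 on the current (already collapsed) scale
    cur <- X[, worst]
    X[, worst] <- ifelse(!is.na(cur) & cur >= k, cur - 1L, cur)
    maps[[worst]] <- ifelse(maps[[worst]] >= k, maps[[worst]] - 1L,
                            maps[[worst]])
    log <- rbind(log, data.frame(round = round, item = worst,
                                 merged_category = k,
                                 inversion = max(inv)))
    fit <- suppressWarnings(pcm_fit(X, ...))
  }
  list(recodes = maps, log = log, fit = fit,
       ordered = length(threshold_order_check(fit$items)) == 0L)
}

#' Person separation index
#'
#' Reliability-type index of how well the instrument separates persons:
#' \deqn{\mathrm{PSI} = \frac{\mathrm{var}(\hat\theta) - \overline{SE^2}}
#'   {\mathrm{var}(\hat\theta)},}
#' floored at 0, computed over persons with non-extreme scores (extreme
#' scores have no ML estimate). 1 means perfect reproducibility of person
#' placements; values around 0.8 support group-level use with four strata.
#'
#' @param abilities data frame from [pcm_fit]/[predict.pcm_fit] (columns
#'   `theta`, `se`, `extreme`), or a numeric theta vector together with `se`.
#' @param se standard errors when `abilities` is a bare vector.
#' @return a single number in \[0, 1\].
#' @export
person_separation_index <- function(abilities, se = NULL) {
  if (is.numeric(abilities)) {
    theta <- abilities
    if (is.null(se)) stop("supply 'se' with a bare theta vector")
  } else {
    keep <- !abilities$extreme & !is.na(abilities$se)
    theta <- abilities$theta[keep]
    se <- abilities$se[keep]
  }
  if (length(theta) < 2L)
    stop("need at least two non-extreme persons")
  v <- stats::var(theta)
  if (v < .Machine$double.eps)
    stop("undefined PSI: person estimates have zero variance")
  max(0, (v - mean(se^2)) / v)
}

#' Targeting summary
#'
#' Describes how the person ability distribution lines up with the item
#' thresholds on the shared logit continuum, and returns the data behind a
#' person-item map (ability histogram plus threshold/location positions).
#'
#' @param abilities data frame (as from [pcm_fit]) or numeric theta vector;
#'   extreme-score persons are excluded when flagged.
#' @param items item parameters.
#' @return list of class `fdd11_targeting`: `persons` and
#'   `item_thresholds` / `item_locations` (each mean, sd, range), and `map`
#'   (ability histogram breaks/counts plus a threshold data frame). The SD
#'   convention for a single value is 0.
#' @export
targeting_summary <- function(abilities, items) {
  items <- as_pcm_items(items)
  if (is.data.frame(abilities)) {
    keep <- !abilities$extreme
    theta <- abilities$theta[keep]
  } else theta <- as.numeric(abilities)
  msr <- function(x) list(mean = mean(x),
                          sd = if (length(x) > 1L) stats::sd(x) else 0,
                          range = range(x))
  taus <- unlist(unclass(items), use.names = FALSE)
  h <- graphics::hist(theta, breaks = 40, plot = FALSE)
  thr_df <- data.frame(
    item = rep(names(items), lengths(items)),
    threshold = taus)
  structure(list(
    persons = msr(theta),
    item_thresholds = msr(taus),
    item_locations = msr(item_locations(items)),
    map = list(ability_breaks = h$breaks, ability_counts = h$counts,
               thresholds = thr_df,
               locations = item_locations(items))
  ), class = "fdd11_targeting")
}

#' @export
print.fdd11_targeting <- function(x, digits = 3, ...) {
  line <- function(lab, s)
    cat(sprintf("  %-16s mean %8.4f  sd %7.4f  range %s to %s\n", lab,
                s$mean, s$sd, round(s$range[1], digits),
                round(s$range[2], digits)))
  cat("Targeting on the latent continuum (logits)\n")
  line("persons", x$persons)
  line("item thresholds", x$item_thresholds)
  line("item locations", x$item_locations)
  invisible(x)
}

#' Full model-fit report
#'
#' Aggregates the fit diagnostics of a calibrated model: item and person
#' infit, residual-correlation dependence flags, threshold ordering,
#' targeting, person separation index, and (when group labels are present)
#' the DIF screen. Dimensionality checks are included when
#' `dimensionality = TRUE`.
#'
#' @param fit a [pcm_fit] object.
#' @param dimensionality run polychoric parallel analysis + bi-factor check?
#' @param dif_intervals ability class intervals for the DIF screen.
#' @param seed seed for the parallel-analysis reference eigenvalues.
#' @return list of class `fdd11_fit_report`.
#' @export
fit_report <- function(fit, dimensionality = FALSE, dif_intervals = 6,
                       seed = NULL) {
  stopifnot(inherits(fit, "pcm_fit"))
  res <- residuals(fit)
  ii <- item_infit(fit$data, fit$items, fit$abilities)
  pi <- person_infit(fit$data, fit$items, fit$abilities)
  out <- list(
    convergence = fit$convergence,
    item_infit = ii,
    infit_flagged = attr(ii, "flagged"),
    person_misfit_rate = attr(pi, "misfit_rate"),
    residual_dependence = residual_correlation_flags(res),
    disordered_items = threshold_order_check(fit$items),
    psi = person_separation_index(fit$abilities),
    targeting = targeting_summary(fit$abilities, fit$items)
  )
  if (dimensionality) {
    pc <- polychoric_matrix(fit$data)
    nf <- parallel_analysis(pc, n = nrow(fit$data), seed = seed)
    out$dimensionality <- list(
      n_factors = nf,
      bifactor = bifactor_check(pc, n_specific = max(2L, nf),
                                n_obs = nrow(fit$data)))
  }
  if (!is.null(fit$groups))
    out$dif <- dif_test(res, fit$groups, abilities = fit$abilities,
                        n_class_intervals = dif_intervals)
  class(out) <- "fdd11_fit_report"
  out
}

#' @export
print.fdd11_fit_report <- function(x, digits = 3, ...) {
  cat("Model fit report\n----------------\n")
  cat("Item infit mean squares:\n")
  print(round(x$item_infit, digits))
  if (length(x$infit_flagged))
    cat("  outside [0.7, 1.3]:", paste(x$infit_flagged, collapse = ", "), "\n")
  cat(sprintf("Person misfit rate (infit > 2): %.1f%%\n",
              100 * x$person_misfit_rate))
  cat(sprintf("Residual correlation threshold %.3f; %d pair(s) flagged\n",
              x$residual_dependence$threshold,
              nrow(x$residual_dependence$flags)))
  if (nrow(x$residual_dependence$flags))
    print(x$residual_dependence$flags)
  cat("Disordered items:",
      if (length(x$disordered_items))
        paste(x$disordered_items, collapse = ", ") else "none", "\n")
  cat(sprintf("Person separation index: %.3f\n", x$psi))
  print(x$targeting, digits = digits)
  if (!is.null(x$dimensionality)) {
    cat("Parallel analysis factors:", x$dimensionality$n_factors, "\n")
    cat("Bi-factor unidimensional:",
        x$dimensionality$bifactor$unidimensional, "\n")
  }
  if (!is.null(x$dif)) { cat("DIF screen:\n"); print(x$dif) }
  invisible(x)
}

#' Serialize a fit report to JSON
#'
#' @param report an `fdd11_fit_report`.
#' @param path output file.
#' @export
write_fit_report <- function(report, path) {
  x <- unclass(report)
  x$item_infit <- as.list(x$item_infit)
  x$residual_dependence$correlations <-
    as.data.frame(x$residual_dependence$correlations)
  x$targeting <- unclass(x$targeting)
  if (!is.null(x$dif)) x$dif <- as.data.frame(unclass(x$dif))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, na = "null")
  invisible(path)
}

#' Summary of a fitted Partial Credit Model
#'
#' @param object a [pcm_fit].
#' @param ... passed to [fit_report].
#' @return the [fit_report] of the model together with the item table.
#' @export
summary.pcm_fit <- function(object, ...) {
  rep <- fit_report(object, ...)
  items <- data.frame(
    location = item_locations(object$items),
    infit = as.numeric(rep$item_infit))
  structure(list(fit = object, items = items, report = rep),
            class = "summary.pcm_fit")
}

#' @export
print.summary.pcm_fit <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat("\n")
  print(x$report, digits = digits)
  invisible(x)
}
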