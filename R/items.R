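#' Item parameter set for the Partial Credit Model
#'
#' Bundles per-item threshold vectors into a validated object used by all
#' probability, scoring and diagnostic functions. Under the Partial Credit
#' Model an item with \eqn{m_i + 1} ordered categories \eqn{0, \dots, m_i}
#' has \eqn{m_i} thresholds \eqn{\tau_{i1}, \dots, \tau_{im_i}} on the logit
#' scale: the points on the latent continuum where adjacent categories are
#' equally likely. The item location \eqn{\delta_i} is the mean of its
#' thresholds.
#'
#' @param thresholds named list of numeric threshold vectors, one per item,
#'   in category order. Names are the item ids.
#' @param ses optional list of per-threshold standard errors, same shape as
#'   `thresholds`.
#' @return an object of class `pcm_items`: a named list of threshold
#'   vectors with an optional `"se"` attribute.
#' @examples
#' it <- pcm_items(list(Q1 = c(-1, 0, 1), Q2 = 0.5))
#' item_locations(it)
#' @export
pcm_items <- function(thresholds, ses = NULL) {
  if (!is.list(thresholds) || length(thresholds) < 1L)
    stop("'thresholds' must be a non-empty list of numeric vectors")
  if (is.null(names(thresholds)) || anyDuplicated(names(thresholds)) ||
      any(!nzchar(names(thresholds))))
    stop("'thresholds' must have unique, non-empty names (item ids)")
  thresholds <- lapply(thresholds, function(x) {
    x <- as.numeric(x)
    if (length(x) < 1L || any(!is.finite(x)))
      stop("each item needs at least one finite threshold")
    x
  })
  if (!is.null(ses)) {
    if (length(ses) != length(thresholds) ||
        !all(lengths(ses) == lengths(thresholds)))
      stop("'ses' must match 'thresholds' in shape")
    ses <- lapply(ses, as.numeric)
    names(ses) <- names(thresholds)
  }
  structure(thresholds, se = ses, class = "pcm_items")
}

#' @export
print.pcm_items <- function(x, digits = 3, ...) {
  cat("Partial Credit Model item parameters (", length(x), " items, ",
      sum(lengths(x)), " thresholds)\n", sep = "")
  m <- max(lengths(x))
  tab <- t(vapply(x, function(tau) c(tau, rep(NA_real_, m - length(tau))),
                  numeric(m)))
  colnames(tab) <- paste0("tau", seq_len(m))
  tab <- cbind(location = item_locations(x), tab)
  print(round(tab, digits), na.print = "")
  invisible(x)
}

#' Item locations (mean of thresholds)
#'
#' @param items a [pcm_items] object.
#' @return named numeric vector of item locations \eqn{\delta_i}.
#' @export
item_locations <- function(items) {
  vapply(unclass(items), mean, numeric(1))
}

#' Maximum category per item
#' @param items a [pcm_items] object.
#' @return named integer vector \eqn{m_i}.
#' @export
max_categories <- function(items) {
  vapply(unclass(items), length, integer(1))
}

as_pcm_items <- function(x) {
  if (inherits(x, "pcm_items")) return(x)
  if (inherits(x, "fdd11_calibration")) return(x$items)
  if (inherits(x, "pcm_fit")) return(x$items)
  if (is.list(x)) return(pcm_items(x))
  stop("cannot interpret 'items' as PCM item parameters")
}
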