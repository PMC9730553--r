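#' Differential item functioning screen
#'
#' Tests, for each item, whether its standardized residuals differ across
#' groups at comparable ability: a two-way analysis of variance of the
#' residuals on group and ability class interval (quantile bins of the
#' estimated abilities). The reported statistic is the group main effect,
#' with numerator degrees of freedom equal to the number of groups minus
#' one — with 11 country groups, df = 10. The group effect is assessed after
#' the class-interval effect (sequential sums of squares), so ability-level
#' composition differences between groups are absorbed first.
#'
#' @param residuals persons-by-items matrix from [standardized_residuals]
#'   (or [residuals.pcm_fit]).
#' @param groups per-person group labels (at least two groups).
#' @param abilities per-person ability estimates used to form class
#'   intervals: the data frame from [pcm_fit], or a numeric theta vector.
#' @param n_class_intervals number of ability quantile bins (default 6;
#'   reduced automatically when ties leave fewer distinct bin edges).
#' @param min_group_size groups smaller than this are dropped with a warning.
#' @return data frame of class `fdd11_dif` with one row per item: `item`,
#'   `F`, `df1`, `df2`, `p`; attributes `grouping` and `intervals`.
#' @export
dif_test <- function(residuals, groups, abilities, n_class_intervals = 6,
                     min_group_size = 30) {
  Z <- as.matrix(residuals)
  groups <- factor(groups)
  if (length(groups) != nrow(Z))
    stop("'groups' must have one label per person")
  if (nlevels(droplevels(groups)) < 2L)
    stop("need at least two groups for a DIF test")
  theta <- if (is.data.frame(abilities)) abilities$theta else as.numeric(abilities)
  if (length(theta) != nrow(Z))
    stop("'abilities' must cover every person")

  small <- names(which(table(groups) < min_group_size))
  if (length(small)) {
    warning("dropping group(s) below the minimum size: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !(groups %in% small)
    Z <- Z[keep, , drop = FALSE]
    groups <- droplevels(groups[keep])
    theta <- theta[keep]
    if (nlevels(groups) < 2L)
      stop("need at least two groups for a DIF test after dropping ",
           "undersized groups")
  }

  br <- unique(stats::quantile(theta, probs = seq(0, 1,
                                                  length.out = n_class_intervals + 1L),
                               na.rm = TRUE))
  if (length(br) < 3L) stop("ability distribution too degenerate to bin")
  interval <- cut(theta, breaks = br, include.lowest = TRUE)

  ## merge intervals whose group x interval cells are empty
  while (nlevels(interval) > 1L &&
         any(table(groups, interval) == 0L)) {
    tab <- table(groups, interval)
    bad <- which(colSums(tab == 0L) > 0L)[1L]
    lv <- levels(interval)
    into <- if (bad == 1L) 2L else bad - 1L
    levels(interval)[bad] <- lv[into]
    warning("merged an ability class interval with empty group cells",
            call. = FALSE)
  }

  res <- lapply(colnames(Z) %||% seq_len(ncol(Z)), function(it) {
    z <- Z[, it]
    ok <- !is.na(z) & !is.na(interval)
    fit <- stats::aov(z ~ interval + groups + interval:groups,
                      data = data.frame(z = z[ok], interval = interval[ok],
                                        groups = droplevels(groups[ok])))
    a <- stats::anova(fit)
    row <- match("groups", rownames(a))
    data.frame(item = as.character(it), F = a$`F value`[row],
               df1 = a$Df[row], df2 = a$Df[nrow(a)],
               p = a$`Pr(>F)`[row])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "grouping") <- deparse(substitute(groups))
  attr(out, "intervals") <- levels(interval)
  class(out) <- c("fdd11_dif", "data.frame")
  out
}

#' @export
print.fdd11_dif <- function(x, digits = 3, ...) {
  cat("Differential item functioning (group main effect, ANOVA of residuals ",
      "on group x ability class interval)\n", sep = "")
  y <- as.data.frame(x)
  y$F <- round(y$F, 2)
  y$p <- format.pval(y$p, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}
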