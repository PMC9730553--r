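## Calibration artifacts: the JSON container carrying an instrument's item
## thresholds, scale anchors, cut-offs and (optionally) its published
## sum-score conversion table.

.fdd11_cache <- new.env(parent = emptyenv())

#' The published FDD11 calibration
#'
#' Loads the shipped calibration artifact of the WHO Functioning and
#' Disability Disaggregation tool: the 11 recoded items' threshold estimates
#' with standard errors, the extreme-score anchor abilities (−3.71, 4.18)
#' that define the 0-100 transform, the population cut-offs (4.3, 22.6,
#' 40.8) separating no/mild/moderate/severe disability, and the published
#' 31-row sum-score conversion table.
#'
#' @return an object of class `fdd11_calibration`.
#' @examples
#' cal <- fdd11_calibration()
#' cal$anchors
#' @export
fdd11_calibration <- function() {
  if (is.null(.fdd11_cache$published)) {
    path <- system.file("extdata", "fdd11_calibration.json",
                        package = "fdd11", mustWork = TRUE)
    .fdd11_cache$published <- read_calibration(path)
  }
  .fdd11_cache$published
}

#' Read / write calibration artifacts
#'
#' Calibration artifacts are JSON files with fields `instrument`, `items`
#' (id, max_category, thresholds, optional threshold_ses, location),
#' `anchors` (theta_min, theta_max), optional `cutoffs` (c1, c2, c3),
#' optional `score_table`, and a free-text `provenance`. On reading, each
#' item's stated location is checked against the mean of its thresholds
#' (tolerance 0.005, the rounding granularity of published tables).
#'
#' @param path file path.
#' @return `read_calibration`: an `fdd11_calibration` object — a list with
#'   `items` ([pcm_items]), `anchors`, `cutoffs`, `locations`, `infit`,
#'   `score_table`, `instrument`, `provenance`.
#' @export
read_calibration <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  it <- j$items
  if (is.null(it) || is.null(it$id) || is.null(it$thresholds))
    stop("calibration file lacks an items table with id and thresholds")
  thresholds <- it$thresholds
  if (!is.list(thresholds)) thresholds <- as.list(as.data.frame(t(thresholds)))
  names(thresholds) <- it$id
  ses <- NULL
  if (!is.null(it$threshold_ses)) {
    ses <- it$threshold_ses
    if (!is.list(ses)) ses <- as.list(as.data.frame(t(ses)))
    names(ses) <- it$id
  }
  items <- pcm_items(thresholds, ses = ses)
  if (!is.null(it$max_category) &&
      !all(it$max_category == max_categories(items)))
    stop("stated max_category disagrees with threshold counts")
  if (!is.null(it$location)) {
    dev <- abs(it$location - item_locations(items))
    if (any(dev > 0.005 + 1e-9))
      stop("stated item location differs from the threshold mean by more ",
           "than 0.005 (items: ",
           paste(it$id[dev > 0.005 + 1e-9], collapse = ", "), ")")
  }
  anchors <- if (!is.null(j$anchors))
    c(theta_min = j$anchors$theta_min, theta_max = j$anchors$theta_max)
  cutoffs <- if (!is.null(j$cutoffs))
    fdd11_cutoffs(j$cutoffs$c1, j$cutoffs$c2, j$cutoffs$c3)
  structure(list(
    instrument = j$instrument %||% "unnamed",
    items = items,
    anchors = anchors,
    cutoffs = cutoffs,
    locations = if (!is.null(it$location)) stats::setNames(it$location, it$id),
    infit = if (!is.null(it$infit)) stats::setNames(it$infit, it$id),
    score_table = j$score_table,
    provenance = j$provenance %||% ""
  ), class = "fdd11_calibration")
}

#' @param x an `fdd11_calibration` object (for `write_calibration`).
#' @rdname read_calibration
#' @export
write_calibration <- function(x, path) {
  if (!inherits(x, "fdd11_calibration")) stop("'x' must be an fdd11_calibration")
  ses <- attr(x$items, "se")
  items <- data.frame(id = names(x$items),
                      max_category = unname(max_categories(x$items)))
  items$thresholds <- unname(unclass(x$items))
  if (!is.null(ses)) items$threshold_ses <- unname(ses)
  items$location <- unname(item_locations(x$items))
  if (!is.null(x$infit)) items$infit <- unname(x$infit)
  out <- list(instrument = x$instrument,
              provenance = x$provenance,
              items = items)
  if (!is.null(x$anchors))
    out$anchors <- list(theta_min = unname(x$anchors[1]),
                        theta_max = unname(x$anchors[2]))
  if (!is.null(x$cutoffs))
    out$cutoffs <- as.list(stats::setNames(as.numeric(x$cutoffs),
                                           c("c1", "c2", "c3")))
  if (!is.null(x$score_table)) out$score_table <- x$score_table
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Build a calibration artifact from fitted parameters
#'
#' @param items a [pcm_items] object or [pcm_fit].
#' @param anchors,cutoffs scale anchors and level cut-offs (optional).
#' @param instrument,provenance labels stored in the artifact.
#' @param score_table include the computed sum-score conversion table?
#' @return an `fdd11_calibration` object.
#' @export
as_calibration <- function(items, anchors = NULL, cutoffs = NULL,
                           instrument = "custom", provenance = "",
                           score_table = !is.null(anchors)) {
  items <- as_pcm_items(items)
  st <- if (score_table)
    pcm_score_table(items, anchors = anchors, cutoffs = cutoffs)
  structure(list(instrument = instrument, items = items, anchors = anchors,
                 cutoffs = cutoffs, locations = item_locations(items),
                 infit = NULL, score_table = st, provenance = provenance),
            class = "fdd11_calibration")
}

#' @export
print.fdd11_calibration <- function(x, ...) {
  cat("Calibration artifact:", x$instrument, "\n")
  if (nzchar(x$provenance)) cat("  ", x$provenance, "\n", sep = "")
  print(x$items, ...)
  if (!is.null(x$anchors))
    cat("anchors: theta_min ", x$anchors[1], ", theta_max ", x$anchors[2],
        "\n", sep = "")
  if (!is.null(x$cutoffs))
    cat("cut-offs (0-100 scale): ",
        paste(as.numeric(x$cutoffs), collapse = " / "), "\n", sep = "")
  invisible(x)
}
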