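## FDD11 response recoding, testlet construction, missingness filtering,
## 0-100 transformation and disability-level assignment.

## Final recode strategy for the 11 FDD11 questions (original 5-point
## responses coded 0-4). The emotion question Q09 is a testlet built from
## two source items; its 9-point sum recode is `fdd11_testlet_map`.
fdd11_recodes_item <- list(
  Q01 = c(0L, 1L, 2L, 3L, 3L),
  Q02 = c(0L, 1L, 1L, 2L, 2L),
  Q03 = c(0L, 1L, 2L, 3L, 3L),
  Q04 = c(0L, 1L, 2L, 3L, 3L),
  Q05 = c(0L, 1L, 1L, 2L, 2L),
  Q06 = c(0L, 1L, 1L, 2L, 2L),
  Q07 = c(0L, 1L, 1L, 2L, 2L),
  Q08 = c(0L, 1L, 1L, 2L, 2L),
  Q09 = 0:4,                       # already a 5-category testlet response
  Q10 = c(0L, 1L, 2L, 3L, 3L),
  Q11 = 0:4                        # no recoding performed
)

## testlet sum 0-8 -> 5-point scale
fdd11_testlet_map <- c(0L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L)

#' FDD11 recode maps
#'
#' The per-item category recodes of the final FDD11 calibration. Each map is
#' an integer vector indexed by the original category (0-based): element
#' `k + 1` is the recoded category for original response `k`. With
#' `emotion = "item"` (default) the emotion question Q09 is treated as a
#' single 5-category response and recoded by identity; with
#' `emotion = "testlet"` its map is the 9-point testlet-sum recode
#' (sums 0-8 collapsed to 0-4), for data whose Q09 column already holds the
#' sum of the two source items.
#'
#' @param emotion `"item"` or `"testlet"` (see above).
#' @return named list of monotone, surjective integer maps.
#' @examples
#' fdd11_recode_map()$Q02   # 0 1 1 2 2
#' @export
fdd11_recode_map <- function(emotion = c("item", "testlet")) {
  emotion <- match.arg(emotion)
  maps <- fdd11_recodes_item
  if (emotion == "testlet") maps$Q09 <- fdd11_testlet_map
  maps
}

validate_recode_map <- function(map, id = "item") {
  map <- as.integer(map)
  if (map[1L] != 0L || any(diff(map) < 0L) || any(diff(map) > 1L))
    stop("recode map for ", id,
         " must be monotone non-decreasing, start at 0 and be surjective")
  map
}

#' Apply category recodes to a response matrix
#'
#' @param data persons-by-items matrix/data frame of 0-based integer
#'   categories (`NA` = missing). Columns are matched to `recodes` by name
#'   when both are named, by position otherwise.
#' @param recodes named list of recode maps as in [fdd11_recode_map].
#' @return recoded integer matrix; missing entries stay missing.
#' @examples
#' apply_recodes(cbind(Q02 = 0:4), fdd11_recode_map()["Q02"])
#' @export
apply_recodes <- function(data, recodes) {
  X <- as.matrix(data)
  storage.mode(X) <- "integer"
  if (!is.null(colnames(X)) && !is.null(names(recodes))) {
    miss <- setdiff(colnames(X), names(recodes))
    if (length(miss))
      stop("no recode map for column(s): ", paste(miss, collapse = ", "))
    recodes <- recodes[colnames(X)]
  } else if (length(recodes) != ncol(X)) {
    stop("need one recode map per column")
  }
  for (j in seq_len(ncol(X))) {
    map <- validate_recode_map(recodes[[j]], colnames(X)[j] %||% j)
    v <- X[, j]
    bad <- which(!is.na(v) & (v < 0L | v >= length(map)))
    if (length(bad))
      stop("out-of-range categories in column ", colnames(X)[j] %||% j,
           " (rows ", paste(utils::head(bad, 5L), collapse = ", "),
           if (length(bad) > 5L) ", ..." else "", ")")
    X[, j] <- map[v + 1L]
  }
  X
}

#' Combine the two emotion items into the FDD11 testlet
#'
#' The "sad, low or depressed" and "worried, nervous or anxious" questions
#' are locally dependent; the instrument combines them by summing the two
#' 5-point responses and collapsing the 9-point sum back to 5 categories
#' (0 -> 0, 1-2 -> 1, 3-4 -> 2, 5-6 -> 3, 7-8 -> 4).
#'
#' @param q9a,q9b integer vectors of 0-4 responses (`NA` allowed).
#' @return integer vector of testlet categories 0-4; `NA` where either
#'   source response is missing.
#' @examples
#' emotion_testlet(4, 4)  # 4
#' emotion_testlet(1, 2)  # 2
#' @export
emotion_testlet <- function(q9a, q9b) {
  q9a <- as.integer(q9a); q9b <- as.integer(q9b)
  ok <- is.na(q9a) | (q9a >= 0L & q9a <= 4L)
  ok2 <- is.na(q9b) | (q9b >= 0L & q9b <= 4L)
  if (!all(ok) || !all(ok2))
    stop("emotion item responses must be in 0-4 (or NA)")
  s <- q9a + q9b
  out <- rep(NA_integer_, length(s))
  out[!is.na(s)] <- fdd11_testlet_map[s[!is.na(s)] + 1L]
  out
}

#' Filter persons by missingness
#'
#' Retains persons with at most `max_missing` missing item responses (the
#' instrument's rule is two or fewer) and logs the exclusions.
#'
#' @param data persons-by-items response matrix.
#' @param max_missing maximum number of missing items for retention.
#' @return list with `data` (retained rows), `excluded` (data frame of
#'   `person_id`, `n_missing` for dropped persons) and `n_missing` (per
#'   retained person).
#' @export
filter_missingness <- function(data, max_missing = 2) {
  X <- as.matrix(data)
  if (is.null(rownames(X))) rownames(X) <- seq_len(nrow(X))
  nmiss <- rowSums(is.na(X))
  keep <- nmiss <= max_missing
  list(data = X[keep, , drop = FALSE],
       excluded = data.frame(person_id = rownames(X)[!keep],
                             n_missing = nmiss[!keep], row.names = NULL),
       n_missing = nmiss[keep])
}

#' Linear transformation of abilities to the 0-100 disability scale
#'
#' Affine map sending the anchor abilities (the extreme-score abilities of
#' the calibration, −3.71 and 4.18 for the published FDD11 scale) to 0 and
#' 100; values outside are clamped.
#'
#' @param theta numeric vector of abilities (logits).
#' @param anchors numeric `c(theta_min, theta_max)`.
#' @return numeric vector in \[0, 100\].
#' @examples
#' transform_to_scale(0.303, c(-3.71, 4.18))  # 50.85
#' @export
transform_to_scale <- function(theta, anchors) {
  anchors <- as.numeric(anchors)
  if (length(anchors) != 2L || any(!is.finite(anchors)) ||
      anchors[1] >= anchors[2])
    stop("'anchors' must be two finite logits with theta_min < theta_max")
  pmin(pmax(100 * (theta - anchors[1]) / (anchors[2] - anchors[1]), 0), 100)
}

#' Disability-level cut-offs on the 0-100 scale
#'
#' @param c1,c2,c3 increasing cut-offs strictly inside (0, 100). The
#'   published FDD11 values are 4.3, 22.6 and 40.8 (mean of the transformed
#'   score minus one SD, the mean, and the mean plus one SD).
#' @return object of class `fdd11_cutoffs` (named numeric vector).
#' @export
fdd11_cutoffs <- function(c1, c2, c3) {
  x <- c(c1 = as.numeric(c1), c2 = as.numeric(c2), c3 = as.numeric(c3))
  if (any(!is.finite(x)) || x[1] <= 0 || x[3] >= 100 || any(diff(x) <= 0))
    stop("cut-offs must satisfy 0 < c1 < c2 < c3 < 100")
  structure(x, class = "fdd11_cutoffs")
}

#' Assign disability levels from transformed scores
#'
#' Levels are assigned with left-closed, right-open intervals:
#' No `[0, c1)`, Mild `[c1, c2)`, Moderate `[c2, c3)`, Severe `[c3, 100]`.
#'
#' @param transformed numeric scores on the 0-100 scale.
#' @param cutoffs an [fdd11_cutoffs] object (or numeric c1, c2, c3).
#' @return factor with levels `No`, `Mild`, `Moderate`, `Severe`.
#' @examples
#' assign_level(c(0, 39.39, 41.3), fdd11_cutoffs(4.3, 22.6, 40.8))
#' @export
assign_level <- function(transformed, cutoffs) {
  if (!inherits(cutoffs, "fdd11_cutoffs"))
    cutoffs <- do.call(fdd11_cutoffs, as.list(as.numeric(cutoffs)))
  if (any(transformed < 0 | transformed > 100, na.rm = TRUE))
    stop("transformed scores must lie in [0, 100]")
  cut(transformed, breaks = c(-Inf, unclass(cutoffs), Inf), right = FALSE,
      labels = c("No", "Mild", "Moderate", "Severe"))
}

#' Derive mean +/- SD cut-offs from a score distribution
#'
#' The instrument's cut-offs are the mean of the transformed population
#' score minus one standard deviation, the mean, and the mean plus one
#' standard deviation (sample SD, denominator n-1).
#'
#' @param transformed_scores numeric vector of 0-100 scores.
#' @return an [fdd11_cutoffs] object.
#' @examples
#' derive_cutoffs(c(10, 20, 30))  # 10, 20, 30
#' @export
derive_cutoffs <- function(transformed_scores) {
  x <- transformed_scores[is.finite(transformed_scores)]
  if (length(unique(x)) < 2L)
    stop("degenerate score distribution: need at least two distinct scores")
  m <- mean(x); s <- stats::sd(x)
  co <- c(m - s, m, m + s)
  if (co[1] <= 0 || co[3] >= 100)
    stop("derived cut-offs fall outside (0, 100): ",
         paste(round(co, 2), collapse = ", "))
  fdd11_cutoffs(co[1], co[2], co[3])
}

#' Score persons against a calibration
#'
#' Scores a recoded, missingness-filtered response matrix: persons with
#' complete response patterns are scored through the sum-score conversion
#' table (the sum score is sufficient); persons with missing responses get
#' the ML ability over their answered items. Each person receives the logit
#' ability with standard error, the transformed 0-100 score and the
#' disability level.
#'
#' @param data recoded persons-by-items matrix (`NA` = missing). Column
#'   names must match the calibration's item ids (any order).
#' @param calibration an [fdd11_calibration] artifact (or a [pcm_items]
#'   object plus explicit `anchors`/`cutoffs`).
#' @param anchors,cutoffs overrides for the artifact's anchors/cut-offs.
#' @return data frame with `person_id`, `sum_score`, `theta`, `se`,
#'   `score_0_100`, `disability_level`, `n_missing`, `extreme`.
#' @export
score_persons <- function(data, calibration, anchors = NULL, cutoffs = NULL) {
  if (inherits(calibration, "fdd11_calibration")) {
    if (is.null(anchors)) anchors <- calibration$anchors
    if (is.null(cutoffs)) cutoffs <- calibration$cutoffs
    items <- calibration$items
  } else {
    items <- as_pcm_items(calibration)
  }
  if (is.null(anchors)) stop("no anchors available for the 0-100 transform")
  X <- as.matrix(data)
  if (!is.null(colnames(X))) {
    if (!setequal(colnames(X), names(items)))
      stop("response columns do not match the calibration items: expected ",
           paste(names(items), collapse = ", "))
    X <- X[, names(items), drop = FALSE]
  } else if (ncol(X) != length(items)) {
    stop("response matrix and calibration disagree on item count")
  }
  m <- max_categories(items)
  for (j in seq_len(ncol(X))) {
    bad <- which(!is.na(X[, j]) & (X[, j] < 0 | X[, j] > m[j]))
    if (length(bad))
      stop("responses out of range for item ", names(items)[j], " (rows ",
           paste(utils::head(bad, 5L), collapse = ", "), ")")
  }
  est <- estimate_persons(X, items, anchors = anchors)
  out <- data.frame(
    person_id = rownames(X) %||% as.character(seq_len(nrow(X))),
    sum_score = est$sum_score,
    theta = est$theta,
    se = est$se,
    score_0_100 = transform_to_scale(est$theta, anchors),
    n_missing = est$n_missing,
    extreme = est$extreme,
    row.names = NULL
  )
  if (!is.null(cutoffs))
    out$disability_level <- assign_level(out$score_0_100, cutoffs)
  out
}

#' Read a response CSV
#'
#' Reads one-row-per-person response files with item columns `Q01..Q11`
#' (or `Q09a`/`Q09b` for the twelve-question variant, which are combined
#' through [emotion_testlet]). Non-item columns (ids, country, sex, age)
#' are preserved. Responses may be coded 0-4 or 1-5; `coding = "auto"`
#' infers the convention from the observed range.
#'
#' @param file path to a CSV file.
#' @param coding `"auto"`, `"0-4"` or `"1-5"`.
#' @param missing_codes values treated as missing (besides empty cells).
#' @return list with `responses` (0-based integer matrix, emotion testlet
#'   already built), `person_id`, `extra` (data frame of non-item columns)
#'   and `twelve_item` (logical).
#' @export
read_responses <- function(file, coding = c("auto", "0-4", "1-5"),
                           missing_codes = c("", "NA", "-9")) {
  coding <- match.arg(coding)
  raw <- utils::read.csv(file, check.names = FALSE,
                         na.strings = missing_codes,
                         stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) == 0L)
    stop("empty response file: ", file)
  item_cols <- grep("^Q[0-9]{2}[ab]?$", names(raw), value = TRUE)
  if (length(item_cols) == 0L)
    stop("no item columns (Q01..Q11 / Q09a, Q09b) found in ", file)
  twelve <- all(c("Q09a", "Q09b") %in% names(raw))
  M <- as.matrix(raw[item_cols])
  storage.mode(M) <- "integer"
  if (coding == "auto")
    coding <- if (min(M, na.rm = TRUE) >= 1L && max(M, na.rm = TRUE) == 5L)
      "1-5" else "0-4"
  if (coding == "1-5") M <- M - 1L
  if (any(M < 0L | M > 8L, na.rm = TRUE))
    stop("responses outside the supported category range in ", file)
  if (twelve) {
    q9 <- emotion_testlet(M[, "Q09a"], M[, "Q09b"])
    M <- M[, setdiff(colnames(M), c("Q09a", "Q09b")), drop = FALSE]
    M <- cbind(M, Q09 = q9)
    M <- M[, order(colnames(M)), drop = FALSE]
  }
  id_col <- intersect(c("person_id", "id", "ID"), names(raw))[1]
  person_id <- if (!is.na(id_col)) as.character(raw[[id_col]])
               else as.character(seq_len(nrow(raw)))
  rownames(M) <- person_id
  extra <- raw[setdiff(names(raw), c(item_cols, id_col))]
  list(responses = M, person_id = person_id, extra = extra,
       twelve_item = twelve)
}
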