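#' The IKDC Subjective Knee Form instrument definition
#'
#' Builds the instrument specification for the International Knee
#' Documentation Committee (IKDC) Subjective Knee Form: 19 administered
#' items of which 18 are scored. Item 10a (knee function prior to injury)
#' is collected but never enters the total score or any factor model.
#' Items use 2, 5 or 11 ordered response options; codes are stored
#' 0-based, ascending from worst to best, so the raw scored sum ranges
#' from 0 to 87 and the familiar 0-100 score is a linear transform of it.
#'
#' @return An object of class `prom_instrument`: a list with `name`,
#'   `items` (a data frame with columns `item_id`, `description`,
#'   `n_categories`, `scored`), and the raw-score bounds `min_raw`,
#'   `max_raw` over the scored items.
#' @examples
#' ik <- ikdc_instrument()
#' sum(ik$items$scored)   # 18 scored items
#' ik$max_raw             # 87
#' @export
ikdc_instrument <- function() {
  items <- data.frame(
    item_id = c("1", "2", "3", "4", "5", "6", "7", "8",
                paste0("9", letters[1:9]), "10a", "10b"),
    description = c(
      "Activity level without pain",
      "Frequency of pain",
      "Severity of pain",
      "Stiffness/swelling",
      "Activity level without swelling",
      "Locking or catching",
      "Activity level without giving way",
      "Activity level on regular basis",
      "Ascending stairs",
      "Descending stairs",
      "Kneeling",
      "Squatting",
      "Sitting",
      "Rising from chair",
      "Running straight ahead",
      "Jumping/landing on involved leg",
      "Stopping and starting quickly",
      "Knee function prior to injury",
      "Current knee function"),
    n_categories = c(5L, 11L, 11L, 5L, 5L, 2L, 5L, 5L,
                     rep(5L, 9L), 11L, 11L),
    scored = c(rep(TRUE, 17L), FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  new_instrument("IKDC Subjective Knee Form", items)
}

#' Construct an instrument specification
#'
#' @param name Instrument name.
#' @param items Data frame with columns `item_id`, `description`,
#'   `n_categories` and `scored`.
#' @return A `prom_instrument` object.
#' @export
new_instrument <- function(name, items) {
  stopifnot(is.data.frame(items),
            all(c("item_id", "n_categories", "scored") %in% names(items)))
  if (anyDuplicated(items$item_id))
    stop("item_ids must be unique")
  if (any(items$n_categories < 2))
    stop("every item needs at least 2 response categories")
  if (!"description" %in% names(items)) items$description <- items$item_id
  scored <- items$scored
  min_raw <- 0L
  max_raw <- sum(items$n_categories[scored] - 1L)
  if (max_raw <= min_raw) stop("max_raw must exceed min_raw")
  structure(list(name = name, items = items,
                 min_raw = min_raw, max_raw = max_raw),
            class = "prom_instrument")
}

#' @export
print.prom_instrument <- function(x, ...) {
  cat(sprintf("<prom_instrument> %s: %d items (%d scored), raw range %d-%d\n",
              x$name, nrow(x$items), sum(x$items$scored),
              x$min_raw, x$max_raw))
  invisible(x)
}

scored_ids <- function(instrument) {
  instrument$items$item_id[instrument$items$scored]
}

#' Construct a response matrix object
#'
#' Holds integer category codes (0-based, higher = better) for each
#' respondent and item; missing responses are `NA`.
#'
#' @param values Integer matrix (respondents x items) with item ids as
#'   column names; `NA` marks a missing response.
#' @param instrument A `prom_instrument`; codes are validated against
#'   each item's category count.
#' @param respondent_ids Optional respondent identifiers (default
#'   `"r1"..."rN"`).
#' @return A `prom_responses` object.
#' @export
new_responses <- function(values, instrument, respondent_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  ids <- instrument$items$item_id
  if (is.null(colnames(values)))
    stop("response matrix must carry item ids as column names")
  unknown <- setdiff(colnames(values), ids)
  if (length(unknown))
    stop("unknown item column(s): ", paste(unknown, collapse = ", "))
  # reorder/subset to instrument order; absent unscored items tolerated
  present <- ids[ids %in% colnames(values)]
  miss_scored <- setdiff(scored_ids(instrument), present)
  if (length(miss_scored))
    stop("missing scored item column(s): ", paste(miss_scored, collapse = ", "))
  values <- values[, present, drop = FALSE]
  ncat <- instrument$items$n_categories[match(present, ids)]
  for (j in seq_along(present)) {
    v <- values[, j]
    bad <- which(!is.na(v) & (v < 0L | v >= ncat[j]))
    if (length(bad))
      stop(sprintf("out-of-range code %d for item \"%s\" in row %d (valid: 0-%d)",
                   v[bad[1]], present[j], bad[1], ncat[j] - 1L))
  }
  if (is.null(respondent_ids))
    respondent_ids <- paste0("r", seq_len(nrow(values)))
  stopifnot(length(respondent_ids) == nrow(values))
  rownames(values) <- NULL
  structure(list(values = values,
                 respondent_ids = as.character(respondent_ids),
                 instrument = instrument$name,
                 n = nrow(values)),
            class = "prom_responses")
}

#' @export
print.prom_responses <- function(x, ...) {
  nm <- sum(is.na(x$values))
  cat(sprintf("<prom_responses> %d respondents x %d items, %d missing cells\n",
              x$n, ncol(x$values), nm))
  invisible(x)
}

#' Read respondent data from CSV
#'
#' Expects a header row of item ids and one row per respondent; blank
#' cells are treated as missing. Codes may be stored 0-based (default)
#' or 1-based in the file; 1-based input is shifted down on read so the
#' in-memory convention is always 0-based, worst to best.
#'
#' @param path CSV file path.
#' @param instrument A `prom_instrument`.
#' @param coding `"zero"` (default) or `"one"`: the category-code origin
#'   used in the file.
#' @param id_column Optional name of a respondent-id column.
#' @return A `prom_responses` object.
#' @export
read_responses <- function(path, instrument, coding = c("zero", "one"),
                           id_column = NULL) {
  coding <- match.arg(coding)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  rid <- NULL
  if (!is.null(id_column)) {
    if (!id_column %in% names(df)) stop("id column not found: ", id_column)
    rid <- df[[id_column]]
    df[[id_column]] <- NULL
  }
  m <- as.matrix(df)
  m[m == ""] <- NA
  suppressWarnings(storage.mode(m) <- "integer")
  if (coding == "one") m <- m - 1L
  new_responses(m, instrument, respondent_ids = rid)
}

#' Write respondent data to CSV
#'
#' Inverse of [read_responses()]: integer codes round-trip exactly,
#' missing cells are written blank.
#'
#' @param data A `prom_responses` object.
#' @param path Output CSV path.
#' @param coding Code origin to use in the file (see [read_responses()]).
#' @export
write_responses <- function(data, path, coding = c("zero", "one")) {
  coding <- match.arg(coding)
  m <- data$values
  if (coding == "one") m <- m + 1L
  utils::write.csv(as.data.frame(m), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Keep complete cases on the scored items
#'
#' Drops every respondent with at least one missing scored item,
#' mirroring the complete-case treatment used for trial baseline data.
#' Missingness on unscored items (10a) does not remove a row.
#'
#' @param data A `prom_responses` object.
#' @param instrument A `prom_instrument` (default the IKDC).
#' @return A list with `responses` (the filtered `prom_responses`) and
#'   `summary`: `n_total`, `n_complete`, `pct_complete` (exact) and
#'   `pct_complete_rounded` (nearest whole percent).
#' @examples
#' \dontrun{
#' cc <- complete_case_filter(read_responses("ikdc.csv", ikdc_instrument()))
#' cc$summary$pct_complete_rounded
#' }
#' @export
complete_case_filter <- function(data, instrument = ikdc_instrument()) {
  sc <- intersect(colnames(data$values), scored_ids(instrument))
  keep <- rowSums(is.na(data$values[, sc, drop = FALSE])) == 0L
  n_total <- data$n
  n_complete <- sum(keep)
  if (n_complete == 0L)
    stop("no complete cases remain after filtering")
  out <- data
  out$values <- data$values[keep, , drop = FALSE]
  out$respondent_ids <- data$respondent_ids[keep]
  out$n <- n_complete
  summary <- list(n_total = n_total, n_complete = n_complete,
                  pct_complete = 100 * n_complete / n_total,
                  pct_complete_rounded = round(100 * n_complete / n_total))
  list(responses = out, summary = summary)
}

#' IKDC total score on the 0-100 scale
#'
#' Sums the scored-item codes and linearly transforms the raw sum to
#' 0-100 (worst to best): `100 * (raw - min_raw) / (max_raw - min_raw)`.
#' By default only rows complete on all scored items receive a score;
#' incomplete rows are returned as `NA`, never silently imputed. With
#' `allow_partial = TRUE` the conventional mean-substitution rule is
#' applied: for a respondent answering at least `min_answered` (default
#' 16) of the 18 scored items, each missing item is imputed with the
#' mean of that respondent's answered item codes before summing.
#' Because category counts differ across items the imputed sum can
#' overshoot slightly; the final score is truncated into `[0, 100]`.
#'
#' @param data A `prom_responses` object.
#' @param instrument A `prom_instrument`.
#' @param allow_partial Apply the pro-rating rule for near-complete rows.
#' @param min_answered Minimum answered scored items for pro-rating.
#' @return Numeric vector of scores in `[0, 100]`, `NA` where undefined.
#' @export
total_score <- function(data, instrument = ikdc_instrument(),
                        allow_partial = FALSE, min_answered = 16L) {
  sc <- scored_ids(instrument)
  sc <- sc[sc %in% colnames(data$values)]
  v <- data$values[, sc, drop = FALSE]
  maxpts <- instrument$items$n_categories[match(sc, instrument$items$item_id)] - 1L
  n_ans <- rowSums(!is.na(v))
  raw <- rowSums(v, na.rm = TRUE)
  denom_full <- sum(maxpts)
  score <- ifelse(n_ans == length(sc), 100 * raw / denom_full, NA_real_)
  if (allow_partial) {
    partial <- which(n_ans < length(sc) & n_ans >= min_answered)
    for (i in partial) {
      ans <- !is.na(v[i, ])
      imputed <- sum(v[i, ans]) + sum(!ans) * mean(v[i, ans])
      score[i] <- min(100, max(0, 100 * imputed / denom_full))
    }
  }
  score
}

#' Serialize an instrument specification
#'
#' Writes the instrument's item table and raw-score bounds to YAML or
#' JSON so it can travel with exported datasets.
#'
#' @param instrument A `prom_instrument`.
#' @param path Output path; format chosen by extension (`.yaml`/`.yml`
#'   or `.json`).
#' @export
write_instrument <- function(instrument, path) {
  obj <- list(name = instrument$name,
              min_raw = instrument$min_raw, max_raw = instrument$max_raw,
              items = instrument$items)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an instrument specification written by [write_instrument()]
#'
#' @param path YAML or JSON file path.
#' @return A `prom_instrument` object.
#' @export
read_instrument <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  items <- as.data.frame(obj$items, stringsAsFactors = FALSE)
  items$n_categories <- as.integer(items$n_categories)
  items$scored <- as.logical(items$scored)
  new_instrument(obj$name, items)
}
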