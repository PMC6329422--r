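#' Construct and validate a response matrix
#'
#' A response matrix holds one row per respondent and one column per item,
#' with codes 1-5 for the rating categories, the literal 0 for "Does not
#' apply" (only legal on items offering that option), and `NA` for missing.
#' An optional per-person covariate table (demographics, comparator scores,
#' retest totals) travels with the matrix.
#'
#' @param values Numeric matrix, persons x items, with codes in
#'   `{1..n_categories, 0, NA}`. Column names must match the instrument's
#'   item ids (unnamed columns are assigned them positionally).
#' @param instrument The [qol_instrument] the responses belong to.
#' @param person_ids Optional character vector of row identifiers.
#' @param covariates Optional data frame of per-person covariates, one row
#'   per respondent.
#' @return An object of class `qol_responses`.
#' @export
response_matrix <- function(values, instrument, person_ids = NULL,
                            covariates = NULL) {
  stopifnot(inherits(instrument, "qol_instrument"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  ids <- instrument$items$id
  if (is.null(colnames(values))) {
    if (ncol(values) != length(ids)) {
      stop("`values` must have one column per instrument item", call. = FALSE)
    }
    colnames(values) <- ids
  } else {
    unknown <- setdiff(colnames(values), ids)
    if (length(unknown)) {
      stop("unknown item column(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    missing_cols <- setdiff(ids, colnames(values))
    if (length(missing_cols)) {
      stop("missing item column(s): ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    }
    values <- values[, ids, drop = FALSE]
  }
  if (is.null(person_ids)) {
    person_ids <- rownames(values) %||% sprintf("P%04d", seq_len(nrow(values)))
  }
  rownames(values) <- person_ids
  .validate_codes(values, instrument)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(values)) {
      stop("`covariates` must have one row per respondent", call. = FALSE)
    }
  }
  structure(
    list(values = values, person_ids = person_ids,
         item_ids = ids, covariates = covariates,
         instrument = instrument),
    class = "qol_responses"
  )
}

.validate_codes <- function(values, instrument) {
  maxc <- instrument$n_categories
  dna_ok <- instrument$items$has_dna_option
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    bad <- which(!is.na(v) & (v < 0 | v > maxc | v != floor(v)))
    if (length(bad)) {
      stop(sprintf(
        "invalid code %s at row %s, item '%s' (legal codes: 1-%d%s, blank)",
        format(v[bad[1]]), rownames(values)[bad[1]], colnames(values)[j],
        maxc, if (dna_ok[j]) ", 0" else ""
      ), call. = FALSE)
    }
    if (!dna_ok[j]) {
      z <- which(!is.na(v) & v == 0)
      if (length(z)) {
        stop(sprintf(
          "code 0 ('Does not apply') at row %s, item '%s', but this item has no such option",
          rownames(values)[z[1]], colnames(values)[j]
        ), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.qol_responses <- function(x, ...) {
  cat(sprintf(
    "<qol_responses> %d persons x %d items (%d missing, %d 'does not apply')\n",
    nrow(x$values), ncol(x$values), sum(is.na(x$values)),
    sum(x$values == 0, na.rm = TRUE)
  ))
  invisible(x)
}

#' Read and write wide-format response CSV files
#'
#' The interchange format is a UTF-8 CSV with a header of item ids (plus
#' any covariate columns), codes 1-5, the literal 0 for "Does not apply",
#' and empty cells for missing responses.
#'
#' @param path CSV file path.
#' @param instrument The [qol_instrument] describing the expected columns.
#' @return `load_responses()` returns a validated `qol_responses`; rows
#'   with out-of-range codes raise an error naming the offending row and
#'   column. `write_responses()` returns `path` invisibly.
#' @export
load_responses <- function(path, instrument) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- instrument$items$id
  missing_cols <- setdiff(ids, names(df))
  if (length(missing_cols)) {
    stop("response file lacks item column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(df[, ids, drop = FALSE])
  storage.mode(vals) <- "double"
  covar_cols <- setdiff(names(df), c(ids, "person_id"))
  covariates <- if (length(covar_cols)) df[, covar_cols, drop = FALSE] else NULL
  person_ids <- if ("person_id" %in% names(df)) as.character(df$person_id) else NULL
  response_matrix(vals, instrument, person_ids = person_ids,
                  covariates = covariates)
}

#' @rdname load_responses
#' @param responses A `qol_responses` object.
#' @export
write_responses <- function(responses, path) {
  stopifnot(inherits(responses, "qol_responses"))
  df <- as.data.frame(responses$values)
  df <- cbind(person_id = responses$person_ids, df)
  if (!is.null(responses$covariates)) df <- cbind(df, responses$covariates)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Raw total score under the published scoring rules
#'
#' The raw total is the sum of the item codes over all active items, with
#' "Does not apply" scored as 0 and reverse-scored items contributing
#' `6 - code`. Every active item must be answered ("Does not apply" counts
#' as answered); for the 12-item instrument the attainable range is 10-60,
#' with 10 and 11 only reachable through "Does not apply" endorsements.
#'
#' @param responses A `qol_responses` object, or a numeric vector of codes
#'   for a single respondent (in instrument item order).
#' @param instrument The [qol_instrument]; taken from `responses` when
#'   omitted.
#' @return Integer vector of raw totals, one per respondent.
#' @export
raw_total <- function(responses, instrument = NULL) {
  if (inherits(responses, "qol_responses")) {
    instrument <- instrument %||% responses$instrument
    vals <- responses$values
  } else {
    if (is.null(instrument)) stop("`instrument` is required", call. = FALSE)
    vals <- matrix(as.numeric(responses), nrow = 1)
    colnames(vals) <- instrument$items$id
  }
  if (anyNA(vals)) {
    bad <- which(rowSums(is.na(vals)) > 0)[1]
    stop(sprintf(
      "incomplete record (row %s): each of the %d items must be completed",
      bad, ncol(vals)
    ), call. = FALSE)
  }
  rev <- instrument$items$reverse_scored
  maxc <- instrument$n_categories
  contrib <- vals
  if (any(rev)) {
    # reverse only real ratings; a "does not apply" 0 stays 0
    rv <- vals[, rev, drop = FALSE]
    rv[rv > 0] <- (maxc + 1) - rv[rv > 0]
    contrib[, rev] <- rv
  }
  as.integer(rowSums(contrib))
}
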