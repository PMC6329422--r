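# Published raw-to-scaled conversion for the 12-item instrument. Raw totals
# of 10 or 11 (reachable only via "Does not apply" endorsements) score the
# same as 12, and 59 shares the top row with 60.
.published_table3 <- function() {
  scaled <- c(
    62, 74, 80, 84, 87, 89,            # raw 12..17
    91, 93, 94, 96, 97, 98,            # raw 18..23
    100, 101, 102, 103, 104, 105,      # raw 24..29
    106, 107, 108, 109, 110, 111,      # raw 30..35
    112, 113, 114, 115, 116, 117,      # raw 36..41
    118, 119, 120, 121, 123, 124,      # raw 42..47
    125, 126, 128, 129, 131, 133,      # raw 48..53
    135, 137, 139, 143, 147, 154, 154  # raw 54..60
  )
  data.frame(raw = 12:60, scaled = as.integer(scaled))
}

.published_table4 <- function() {
  data.frame(
    lo = c(62L, 91L, 106L, 118L, 135L),
    hi = c(89L, 105L, 117L, 133L, 154L),
    label = c("No to low interference", "Mild interference",
              "Moderate interference", "Substantial interference",
              "Severe interference"),
    stringsAsFactors = FALSE
  )
}

#' Published scoring tables
#'
#' `published_score_table()` returns the raw-to-scaled conversion for the
#' 12-item instrument (scaled scores standardized to mean 100, SD 15 on
#' the development sample); `qualitative_bands()` the five qualitative
#' interpretation bands of the scaled score.
#'
#' @return Data frames (`raw`/`scaled`, and `lo`/`hi`/`label`).
#' @export
published_score_table <- function() .published_table3()

#' @rdname published_score_table
#' @export
qualitative_bands <- function() .published_table4()

#' Qualitative band of a published scaled score
#'
#' Maps an attainable scaled score to its interpretation band. Scaled
#' values the conversion table never produces (e.g. 90 or 134, which fall
#' in the gaps between bands) are rejected rather than guessed at.
#'
#' @param scaled Integer scaled score(s).
#' @return Character vector of band labels.
#' @export
categorize <- function(scaled) {
  t3 <- .published_table3()
  t4 <- .published_table4()
  vapply(scaled, function(s) {
    if (!s %in% t3$scaled) {
      stop("scaled score ", s, " is not attainable from the published table",
           call. = FALSE)
    }
    hit <- which(t4$lo <= s & s <= t4$hi)
    t4$label[hit]
  }, "")
}

#' Score respondents on the published 12-item instrument
#'
#' Computes the raw total under the published rules ("Does not apply"
#' scored 0, reverse-scored items flipped, all 12 items required), looks
#' the scaled score up in the embedded conversion table (raw 10 and 11 are
#' treated as 12), and attaches the qualitative band.
#'
#' @param responses A `qol_responses` on the published instrument, or a
#'   numeric code vector for one respondent.
#' @param instrument Defaults to [published_instrument()] for bare
#'   vectors, or the instrument attached to `responses`.
#' @return Data frame with columns `person_id`, `raw`, `scaled`, `band`.
#' @export
published_score <- function(responses, instrument = NULL) {
  if (!inherits(responses, "qol_responses")) {
    instrument <- instrument %||% published_instrument()
    responses <- response_matrix(matrix(as.numeric(responses), nrow = 1),
                                 instrument)
  }
  instrument <- instrument %||% responses$instrument
  if (nrow(instrument$items) != 12) {
    stop("published scoring is defined for the 12-item instrument",
         call. = FALSE)
  }
  raw <- raw_total(responses, instrument)
  if (any(raw < 10 | raw > 60)) {
    stop("raw total outside the attainable range 10-60", call. = FALSE)
  }
  t3 <- .published_table3()
  scaled <- t3$scaled[match(pmax(raw, 12), t3$raw)]
  data.frame(
    person_id = responses$person_ids,
    raw = raw, scaled = scaled, band = categorize(scaled),
    row.names = NULL
  )
}

#' Build a raw-to-scaled score conversion table from a calibration
#'
#' For every attainable raw total the corresponding person measure is
#' found by solving `expected total score(theta) = raw` (monotone in
#' `theta`; extreme totals are nudged `fit$extreme_adjust` score points
#' inward so the end rows stay finite). Measures are then standardized on
#' the calibration sample's person measures to a scaled metric with mean
#' `mean_target` and SD `sd_target`, and rounded half-up to integers.
#'
#' @param fit A converged `rasch_fit` of the final item set.
#' @param thetas Person measures defining the standardization sample;
#'   defaults to the fit's calibrated persons.
#' @param mean_target,sd_target Scaled-metric mean and SD (100 and 15).
#' @return Object of class `score_table`: a data frame with `raw`,
#'   `measure` (logits) and `scaled`, plus the transform recorded in
#'   attributes (`mean_theta`, `sd_theta`, targets).
#' @export
build_score_table <- function(fit, thetas = NULL, mean_target = 100,
                              sd_target = 15) {
  stopifnot(inherits(fit, "rasch_fit"))
  if (is.null(thetas)) {
    thetas <- fit$theta[names(fit$theta) %in% fit$calibrated_persons]
  }
  thetas <- thetas[!is.na(thetas)]
  ids <- names(fit$delta)[!is.na(fit$delta)]
  idx <- match(ids, names(fit$delta))
  ncat <- vapply(fit$group[idx], function(g) length(fit$tau[[g]]) + 1L, 0L)
  # raw totals on the 1-based response scale
  min_raw <- length(idx)
  max_raw <- sum(ncat)
  exp_total <- function(th) {
    tot <- length(idx)   # the +1 per item for 1-based codes
    for (i in seq_along(idx)) {
      tot <- tot + expected_score(th, fit$delta[idx[i]],
                                  fit$tau[[fit$group[idx[i]]]])
    }
    tot
  }
  solve_theta <- function(target) {
    lo <- -15; hi <- 15
    if (exp_total(lo) > target || exp_total(hi) < target) {
      stop("expected-score function does not bracket the target",
           call. = FALSE)
    }
    for (k in 1:80) {
      mid <- (lo + hi) / 2
      if (exp_total(mid) < target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  raws <- min_raw:max_raw
  adj <- fit$extreme_adjust
  targets <- pmin(pmax(raws, min_raw + adj), max_raw - adj)
  measures <- vapply(targets, solve_theta, 0)
  if (any(diff(measures) < 0)) {
    stop("internal inconsistency: measures not monotone in raw total",
         call. = FALSE)
  }
  m <- mean(thetas); s <- stats::sd(thetas)
  scaled_exact <- mean_target + sd_target * (measures - m) / s
  tab <- data.frame(
    raw = raws, measure = measures,
    scaled = floor(scaled_exact + 0.5)   # round half-up
  )
  structure(tab, class = c("score_table", "data.frame"),
            mean_theta = m, sd_theta = s,
            mean_target = mean_target, sd_target = sd_target)
}

#' Scaled scores of person measures under a score table's transform
#'
#' Applies the standardization recorded in a [build_score_table()] result
#' to person measures, returning exact (unrounded) scaled values.
#'
#' @param table A `score_table`.
#' @param thetas Person measures in logits.
#' @return Numeric vector of scaled scores.
#' @export
scale_measures <- function(table, thetas) {
  attr(table, "mean_target") +
    attr(table, "sd_target") *
      (thetas - attr(table, "mean_theta")) / attr(table, "sd_theta")
}

#' Look a raw total up in a built score table
#'
#' Raw totals below the table's minimum (reachable through "Does not
#' apply" responses) map to the minimum row.
#'
#' @param table A `score_table`.
#' @param raw Integer raw totals.
#' @return Integer scaled scores.
#' @export
lookup_scaled <- function(table, raw) {
  r <- pmax(pmin(raw, max(table$raw)), min(table$raw))
  table$scaled[match(r, table$raw)]
}
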