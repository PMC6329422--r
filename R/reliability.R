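#' Separation reliability of a set of measures
#'
#' The Rasch analogue of a reliability coefficient: the proportion of
#' observed measure variance not attributable to estimation error,
#' `R = (var(measures) - mean(se^2)) / var(measures)`, clamped to
#' `[0, 1]`. Applied to person measures it quantifies how well the
#' instrument separates respondents; applied to item difficulties, how
#' stably the sample locates the items.
#'
#' @param measures Measures in logits (person `theta` or item `delta`).
#' @param ses Their standard errors, same length.
#' @return Reliability in `[0, 1]`.
#' @export
separation_reliability <- function(measures, ses) {
  ok <- !is.na(measures) & !is.na(ses)
  measures <- measures[ok]; ses <- ses[ok]
  if (length(measures) < 2) stop("need at least 2 measures", call. = FALSE)
  v <- stats::var(measures)
  if (v == 0) {
    warning("zero observed variance; reliability undefined, returning 0",
            call. = FALSE)
    return(0)
  }
  min(max((v - mean(ses^2)) / v, 0), 1)
}

#' @rdname separation_reliability
#' @param fit A `rasch_fit`; convenience wrappers applying
#'   `separation_reliability()` to the calibrated person measures or item
#'   difficulties.
#' @export
person_reliability <- function(fit) {
  keep <- names(fit$theta) %in% fit$calibrated_persons
  separation_reliability(fit$theta[keep], fit$theta_se[keep])
}

#' @rdname separation_reliability
#' @export
item_reliability <- function(fit) {
  keep <- names(fit$delta) %in% fit$calibrated_items
  separation_reliability(fit$delta[keep], fit$delta_se[keep])
}

#' Test-retest reliability
#'
#' Pearson correlation between total scores at the two administrations,
#' over the paired complete cases.
#'
#' @param admin1,admin2 Numeric score vectors, paired by position.
#' @return List with `r`, `p` (two-sided) and `n` (pairs used).
#' @export
test_retest <- function(admin1, admin2) {
  if (length(admin1) != length(admin2)) {
    stop("administrations must be paired (equal length)", call. = FALSE)
  }
  ok <- !is.na(admin1) & !is.na(admin2)
  if (sum(ok) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  ct <- stats::cor.test(admin1[ok], admin2[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Convergent and discriminant validity
#'
#' Correlates the instrument score with a convergent comparator (another
#' quality-of-life total) and with a discriminant variable (ordinal
#' disease stage), and tests whether the convergent correlation is
#' significantly larger using Steiger's z for two dependent correlations
#' sharing one variable.
#'
#' @param qol Instrument scores.
#' @param comparator Convergent comparator scores.
#' @param stage Discriminant variable (ordinal integers).
#' @return List with `r_convergent`, `p_convergent`, `r_discriminant`,
#'   `p_discriminant`, `z` (Steiger), `p` (two-sided) and `n`.
#' @export
convergent_discriminant <- function(qol, comparator, stage) {
  ok <- stats::complete.cases(qol, comparator, stage)
  qol <- qol[ok]; comparator <- comparator[ok]; stage <- as.numeric(stage)[ok]
  n <- length(qol)
  if (n < 4) stop("need at least 4 complete triples", call. = FALSE)
  if (stats::sd(qol) == 0 || stats::sd(comparator) == 0 || stats::sd(stage) == 0) {
    stop("a variable is constant; correlation undefined", call. = FALSE)
  }
  c12 <- stats::cor.test(qol, comparator)
  c13 <- stats::cor.test(qol, stage)
  r12 <- unname(c12$estimate); r13 <- unname(c13$estimate)
  r23 <- stats::cor(comparator, stage)
  z <- steiger_z(r12, r13, r23, n)
  list(
    r_convergent = r12, p_convergent = c12$p.value,
    r_discriminant = r13, p_discriminant = c13$p.value,
    z = z, p = 2 * stats::pnorm(-abs(z)), n = n
  )
}

#' Steiger's z for two dependent correlations sharing a variable
#'
#' Compares `cor(x1, x2) = r12` with `cor(x1, x3) = r13` (variable 1
#' shared), given `r23` and the sample size, via Fisher-transformed
#' correlations with Steiger's (1980) covariance correction.
#'
#' @param r12,r13 The two correlations being compared.
#' @param r23 Correlation between the two non-shared variables.
#' @param n Sample size.
#' @return The z statistic (positive when `r12 > r13`).
#' @export
steiger_z <- function(r12, r13, r23, n) {
  rbar <- (r12 + r13) / 2
  # covariance of the Fisher z's for dependent correlations with a shared
  # variable, using the mean correlation in place of the two compared ones
  num <- r23 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r23^2)
  cov_term <- num / (1 - rbar^2)^2
  z12 <- atanh(r12); z13 <- atanh(r13)
  (z12 - z13) * sqrt((n - 3) / (2 - 2 * cov_term))
}
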