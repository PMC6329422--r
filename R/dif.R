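#' Differential item functioning by anchored group calibration
#'
#' Holds the person measures and rating-scale thresholds at their pooled
#' (whole-sample) estimates and re-estimates each item's difficulty
#' separately within each of two covariate groups. The DIF contrast is the
#' difference of the two group difficulties in logits; it is tested with a
#' two-sample t statistic using the joint standard error and a Welch-type
#' degrees-of-freedom approximation. An item is flagged when the absolute
#' contrast exceeds `contrast_cutoff` (1.0 logit) and the test is
#' significant at `alpha` (.05).
#'
#' @param responses The `qol_responses` the pooled fit was computed on.
#' @param fit The pooled `rasch_fit` (anchor).
#' @param grouping Per-person group labels (exactly 2 distinct non-missing
#'   values), or the name of a covariate column. A numeric covariate with
#'   more than 2 values (e.g. age) is dichotomized at the sample median.
#' @param contrast_cutoff Flagging threshold on `|contrast|` in logits.
#' @param alpha Significance level for the flag.
#' @param min_group_size Minimum persons per group (default 20).
#' @return Data frame of class `dif_report`: per item the two group
#'   difficulties and standard errors, `contrast`, `se`, `t`, `df`, `p`
#'   and `flagged`. Items with no score variance in a group are skipped
#'   (`NA` row) with a note.
#' @export
dif <- function(responses, fit, grouping, contrast_cutoff = 1.0,
                alpha = 0.05, min_group_size = 20L) {
  stopifnot(inherits(fit, "rasch_fit"))
  if (is.character(grouping) && length(grouping) == 1) {
    if (is.null(responses$covariates[[grouping]])) {
      stop("covariate not found: ", grouping, call. = FALSE)
    }
    grouping <- responses$covariates[[grouping]]
  }
  if (is.numeric(grouping) && length(unique(stats::na.omit(grouping))) > 2) {
    grouping <- as.integer(grouping > stats::median(grouping, na.rm = TRUE))
  }
  lev <- sort(unique(stats::na.omit(grouping)))
  if (length(lev) != 2) stop("`grouping` must have exactly 2 levels", call. = FALSE)
  gsize <- table(factor(grouping, levels = lev))
  if (any(gsize < min_group_size)) {
    stop(sprintf("each group needs at least %d persons (found %s)",
                 min_group_size, paste(gsize, collapse = "/")), call. = FALSE)
  }

  X0 <- .keyed_codes(fit, responses)
  theta <- unname(fit$theta)
  ids <- responses$item_ids

  est_delta <- function(rows, j) {
    x <- X0[rows, j]
    ok <- !is.na(x) & !is.na(theta[rows])
    x <- x[ok]; th <- theta[rows][ok]
    if (length(x) < 2 || stats::var(x) == 0) return(c(NA, NA, length(x)))
    g <- fit$group[j]
    s <- c(0, cumsum(fit$tau[[g]]))
    de <- unname(fit$delta[j])
    if (is.na(de)) de <- 0
    for (k in 1:100) {
      st <- .cell_stats(th - de, s)
      step <- .clip((sum(st$E) - sum(x)) / max(sum(st$V), 1e-10), 2)
      de <- de + step
      if (abs(step) < 1e-8) break
    }
    st <- .cell_stats(th - de, s)
    c(de, 1 / sqrt(max(sum(st$V), 1e-10)), length(x))
  }

  rows1 <- which(!is.na(grouping) & grouping == lev[1])
  rows2 <- which(!is.na(grouping) & grouping == lev[2])
  out <- lapply(seq_along(ids), function(j) {
    a <- est_delta(rows1, j)
    b <- est_delta(rows2, j)
    if (anyNA(c(a[1], b[1]))) {
      return(data.frame(id = ids[j], delta_1 = a[1], se_1 = a[2],
                        delta_2 = b[1], se_2 = b[2], contrast = NA_real_,
                        se = NA_real_, t = NA_real_, df = NA_real_,
                        p = NA_real_, flagged = NA))
    }
    contrast <- a[1] - b[1]
    se <- sqrt(a[2]^2 + b[2]^2)
    tt <- contrast / se
    df <- (a[2]^2 + b[2]^2)^2 /
      (a[2]^4 / (a[3] - 1) + b[2]^4 / (b[3] - 1))
    p <- 2 * stats::pt(-abs(tt), df)
    data.frame(id = ids[j], delta_1 = a[1], se_1 = a[2],
               delta_2 = b[1], se_2 = b[2], contrast = contrast,
               se = se, t = tt, df = df, p = p,
               flagged = abs(contrast) > contrast_cutoff & p < alpha)
  })
  rep <- do.call(rbind, out)
  attr(rep, "groups") <- lev
  attr(rep, "contrast_cutoff") <- contrast_cutoff
  attr(rep, "alpha") <- alpha
  class(rep) <- c("dif_report", "data.frame")
  rep
}
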