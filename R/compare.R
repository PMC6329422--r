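#' Likelihood-ratio comparison of the grouped vs plain rating scale model
#'
#' The rating scale model (one threshold set for all items) is nested in
#' the grouped rating scale model (one set per scale group), so twice the
#' log-likelihood gain is referred to a chi-square distribution. Under the
#' sum-to-zero threshold identification each group contributes
#' `n_categories - 2` free thresholds, giving
#' `df = (n_groups - 1) * (n_categories - 2)` — 3 for two groups of
#' five-category items. Both fits are joint (unconditional) maximum
#' likelihood, so the chi-square reference is approximate; its size is
#' checked empirically in the package tests.
#'
#' @param grsm A `rasch_fit` with `model = "grsm"`.
#' @param rsm A `rasch_fit` with `model = "rsm"` on the identical data.
#' @return List with `chi2` (clipped at 0), `df` and `p`.
#' @export
lrt_grsm_vs_rsm <- function(grsm, rsm) {
  stopifnot(inherits(grsm, "rasch_fit"), inherits(rsm, "rasch_fit"))
  if (grsm$model != "grsm" || rsm$model != "rsm") {
    stop("arguments must be a grsm fit and an rsm fit, in that order",
         call. = FALSE)
  }
  if (!identical(grsm$fingerprint, rsm$fingerprint)) {
    stop("the two fits were not computed on identical data", call. = FALSE)
  }
  free_thresholds <- function(fit) {
    sum(vapply(fit$tau, function(t) length(t) - 1L, 0L))
  }
  df <- free_thresholds(grsm) - free_thresholds(rsm)
  chi2 <- max(0, 2 * (grsm$loglik - rsm$loglik))
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Item characteristic curve overlay from a partial credit fit
#'
#' Expected-score curves for every item on a common trait grid, grouped by
#' the instrument's scale group, with sup-distance summaries of how alike
#' the curves are within and between groups. Similar within-group curves
#' support pooling the items' thresholds into one rating-scale group.
#'
#' @param pcm_fit A `rasch_fit` with `model = "pcm"`.
#' @param scale_group Character vector of scale-group labels per item (in
#'   item order); defaults to the instrument grouping recorded at fit time
#'   being unavailable for a PCM, so it must be supplied for grouped
#'   summaries, otherwise all items form one group.
#' @param grid Trait grid in logits.
#' @return List with the grid, an items x grid matrix of expected-score
#'   curves, the grouping, and summaries `within_max_dist`,
#'   `within_mean_dist`, `between_max_dist`, `between_mean_dist` (sup
#'   distances between item curves).
#' @export
icc_overlay <- function(pcm_fit, scale_group = NULL,
                        grid = seq(-4, 4, by = 0.1)) {
  stopifnot(inherits(pcm_fit, "rasch_fit"))
  if (pcm_fit$model != "pcm") stop("`pcm_fit` must be a PCM fit", call. = FALSE)
  ids <- names(pcm_fit$delta)
  if (is.null(scale_group)) scale_group <- rep("all", length(ids))
  curves <- matrix(NA_real_, length(ids), length(grid),
                   dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    g <- pcm_fit$group[i]
    curves[i, ] <- expected_score(grid, pcm_fit$delta[i], pcm_fit$tau[[g]])
  }
  supd <- function(i, j) max(abs(curves[i, ] - curves[j, ]))
  within <- c(); between <- c()
  for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
    d <- supd(i, j)
    if (scale_group[i] == scale_group[j]) within <- c(within, d)
    else between <- c(between, d)
  }
  list(
    grid = grid, curves = curves, scale_group = scale_group,
    within_max_dist = if (length(within)) max(within) else 0,
    within_mean_dist = if (length(within)) mean(within) else 0,
    between_max_dist = if (length(between)) max(between) else NA_real_,
    between_mean_dist = if (length(between)) mean(between) else NA_real_
  )
}
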