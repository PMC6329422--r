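#' One-shot psychometric evaluation pipeline
#'
#' Runs the nine-stage evaluation used to develop the instrument, in
#' order: (1) optimal measurement model (partial-credit ICC overlay plus
#' the grouped-vs-plain rating scale likelihood-ratio test); (2) item fit
#' with optional iterative purging; (3) unidimensionality via principal
#' components of standardized residuals; (4) rating scale performance
#' (threshold ordering and category curves); (5) reliability (person,
#' item, and test-retest when retest data are present); (6) test
#' information; (7) person-to-item map; (8) convergent and discriminant
#' validity when comparator data are present; (9) differential item
#' functioning over the configured covariates.
#'
#' @param config A list. Either `config$responses` (a `qol_responses`) or
#'   `config$simulate = TRUE` to generate data from [study_preset()].
#'   Optional fields: `seed` (default 1), `n` (simulated sample size,
#'   default 126), `model` (default `"grsm"`), `purge` (default `TRUE`),
#'   `cutoff` (default 1.33), `dif_covariates` (default
#'   `c("gender", "age", "race")`), `out_dir` (write one JSON artifact per
#'   stage plus `summary.json`).
#' @return List of class `qol_pipeline` with `stages` (nine named
#'   artifacts), `fit` (the final calibration) and `summary`.
#' @export
run_pipeline <- function(config = list()) {
  seed <- config$seed %||% 1L
  model <- config$model %||% "grsm"
  cutoff <- config$cutoff %||% 1.33
  do_purge <- config$purge %||% TRUE
  dif_covs <- config$dif_covariates %||% c("gender", "age", "race")

  retest <- NULL
  comparators <- NULL
  if (!is.null(config$responses)) {
    responses <- config$responses
    retest <- config$retest
    comparators <- config$comparators
  } else {
    preset <- study_preset(seed = seed, n = config$n %||% 126L)
    pair <- simulate_retest(preset$instrument, preset$n, preset$truth)
    responses <- pair$time1
    keep <- seq_len(preset$retest_n)
    retest <- list(time1 = pair$time1, time2 = pair$time2, pairs = keep)
    comparators <- simulate_comparators(responses, seed = seed)
  }
  instrument <- responses$instrument
  stages <- list()

  # (1) optimal measurement model
  pcm <- rasch_fit(responses, instrument, model = "pcm")
  overlay <- icc_overlay(pcm, scale_group = instrument$items$scale_group)
  grsm <- rasch_fit(responses, instrument, model = "grsm")
  rsm <- rasch_fit(responses, instrument, model = "rsm")
  lrt <- lrt_grsm_vs_rsm(grsm, rsm)
  stages$measurement_model <- list(
    lrt = lrt,
    loglik = c(grsm = grsm$loglik, rsm = rsm$loglik, pcm = pcm$loglik),
    icc_within_mean_dist = overlay$within_mean_dist,
    icc_between_mean_dist = overlay$between_mean_dist,
    selected = if (lrt$p < 0.05) "grsm" else "rsm"
  )

  # (2) item fit (with purge)
  if (do_purge) {
    purged <- purge_items(responses, instrument, cutoff = cutoff, model = model)
    fit <- purged$fit
    responses_final <- purged$responses
    stages$item_fit <- list(
      report = item_fit(fit, responses_final)$items,
      removed = purged$removed, retained = purged$retained,
      cutoff = cutoff
    )
  } else {
    fit <- if (model == "grsm") grsm else rasch_fit(responses, instrument, model = model)
    responses_final <- responses
    stages$item_fit <- list(report = item_fit(fit, responses)$items,
                            removed = data.frame(), cutoff = cutoff,
                            retained = instrument$items$id)
  }

  # (3) unidimensionality
  stages$unidimensionality <- pca_first_contrast(fit, responses_final)

  # (4) rating scale performance
  stages$rating_scale <- list(
    thresholds = thresholds_ordered(fit),
    curves = lapply(names(fit$tau), function(g) category_curves(fit, g))
  )

  # (5) reliability
  rel <- list(person = person_reliability(fit), item = item_reliability(fit))
  if (!is.null(retest)) {
    ids <- fit$delta; keep_items <- names(ids)[!is.na(ids)]
    tot <- function(resp) {
      v <- resp$values[, keep_items, drop = FALSE]
      ok <- rowSums(is.na(v)) == 0
      out <- rep(NA_real_, nrow(v)); out[ok] <- rowSums(v[ok, , drop = FALSE])
      out
    }
    p <- retest$pairs
    rel$test_retest <- test_retest(tot(retest$time1)[p], tot(retest$time2)[p])
  }
  stages$reliability <- rel

  # (6) test information
  stages$test_information <- test_information(fit)

  # (7) person-to-item map
  stages$person_item_map <- person_item_map(fit)

  # (8) convergent and discriminant validity
  if (!is.null(comparators)) {
    raw <- rowSums(responses_final$values)
    stages$validity <- convergent_discriminant(raw, comparators$comparator,
                                               comparators$stage)
  } else {
    stages$validity <- list(skipped = "no comparator data supplied")
  }

  # (9) differential item functioning
  covs <- intersect(dif_covs, names(responses_final$covariates %||% list()))
  stages$dif <- lapply(stats::setNames(covs, covs), function(cv) {
    tryCatch(dif(responses_final, fit, cv),
             error = function(e) list(skipped = conditionMessage(e)))
  })

  summary <- list(
    seed = seed, model = model,
    config_hash = {
      cfg <- config[setdiff(names(config), "out_dir")]
      sum(utf8ToInt(paste(deparse(cfg[order(names(cfg))]), collapse = "")))
    },
    n_persons = nrow(responses$values),
    n_items_initial = nrow(instrument$items),
    n_items_final = sum(!is.na(fit$delta)),
    lrt = lrt,
    person_reliability = rel$person,
    item_reliability = rel$item,
    first_contrast_eigenvalue = stages$unidimensionality$first_contrast_eigenvalue,
    variance_explained_pct = stages$unidimensionality$variance_explained_by_measures_pct,
    stage_names = names(stages)
  )

  out <- structure(list(stages = stages, fit = fit, summary = summary,
                        responses = responses_final),
                   class = "qol_pipeline")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(stages)) {
      jsonlite::write_json(.jsonable(stages[[nm]]),
                           file.path(config$out_dir, paste0(nm, ".json")),
                           digits = 10, auto_unbox = TRUE, na = "null",
                           force = TRUE)
    }
    jsonlite::write_json(.jsonable(summary),
                         file.path(config$out_dir, "summary.json"),
                         digits = 10, auto_unbox = TRUE, na = "null",
                         force = TRUE)
  }
  out
}

.jsonable <- function(x) {
  if (inherits(x, "person_item_map")) x <- unclass(x)
  if (is.list(x) && !is.data.frame(x)) return(lapply(x, .jsonable))
  x
}

#' @export
print.qol_pipeline <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<qol_pipeline> %d persons | %d -> %d items | LRT chi2=%.2f (df=%d, p=%.3f)\n",
    s$n_persons, s$n_items_initial, s$n_items_final,
    s$lrt$chi2, s$lrt$df, s$lrt$p
  ))
  cat(sprintf(
    "  person reliability %.3f | item reliability %.3f | first contrast %.2f | %.1f%% variance explained\n",
    s$person_reliability, s$item_reliability,
    s$first_contrast_eigenvalue, s$variance_explained_pct
  ))
  invisible(x)
}
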