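# The calibration view of a response matrix for an existing fit: DNA and
# blanks as NA, reverse-scored items flipped, and the FIT's own category
# collapse applied (never re-derived from the data at hand).
.keyed_codes <- function(fit, responses) {
  instrument <- responses$instrument
  X <- responses$values
  X[X == 0] <- NA
  X0 <- X - 1
  rev <- instrument$items$reverse_scored
  m <- instrument$n_categories - 1L
  if (any(rev)) X0[, rev] <- m - X0[, rev, drop = FALSE]
  if (!is.null(fit$cat_maps)) {
    for (g in names(fit$cat_maps)) {
      obs <- fit$cat_maps[[g]]
      if (length(obs) == m + 1) next
      idx <- which(fit$group == g)
      map <- rep(NA_real_, m + 1)
      map[obs + 1] <- seq_along(obs) - 1
      for (j in idx) X0[, j] <- map[X0[, j] + 1]
    }
  }
  X0
}

# Fitted expectation/variance per observed cell, on the calibration view
# of the data (same keying and category collapse as the fit itself).
.fitted_cells <- function(fit, responses) {
  X0 <- .keyed_codes(fit, responses)
  ev <- .ev_matrices(unname(fit$theta), unname(fit$delta), fit$tau, fit$group)
  list(X0 = X0, E = ev$E, V = ev$V, mask = !is.na(X0))
}

#' Standardized response residuals
#'
#' For every observed cell, `z = (x - E) / sqrt(V)` with `E` and `V` the
#' model expectation and variance of the keyed category score at the
#' calibrated person and item parameters. Missing and "Does not apply"
#' cells are `NA`; cells whose model variance is numerically zero are
#' dropped with a warning.
#'
#' @param fit A `rasch_fit`.
#' @param responses The `qol_responses` the fit was computed on.
#' @return Persons x items matrix of standardized residuals.
#' @export
standardized_residuals <- function(fit, responses) {
  fc <- .fitted_cells(fit, responses)
  Z <- (fc$X0 - fc$E) / sqrt(fc$V)
  degen <- fc$mask & fc$V < 1e-12
  if (any(degen, na.rm = TRUE)) {
    warning(sum(degen), " zero-variance cell(s) excluded from residuals",
            call. = FALSE)
    Z[degen] <- NA
  }
  Z[!fc$mask] <- NA
  dimnames(Z) <- dimnames(responses$values)
  Z
}

#' Infit and outfit mean-square fit statistics
#'
#' Outfit is the unweighted mean of squared standardized residuals;
#' infit weights each squared residual by the cell's model variance
#' (`infit = sum(V * z^2) / sum(V)`). Both are computed per item and per
#' person; values near 1 indicate model-consistent responses and values
#' above about 1.33 conventionally flag misfit.
#'
#' @inheritParams standardized_residuals
#' @return List of class `fit_report` with data frames `items` (id,
#'   infit, outfit, n_obs) and `persons`.
#' @export
item_fit <- function(fit, responses) {
  fc <- .fitted_cells(fit, responses)
  Z2 <- ((fc$X0 - fc$E)^2)
  ok <- fc$mask & fc$V > 1e-12
  Z2[!ok] <- NA
  V <- fc$V; V[!ok] <- NA
  z2std <- Z2 / V

  items <- data.frame(
    id = responses$item_ids,
    infit = colSums(Z2, na.rm = TRUE) / colSums(V, na.rm = TRUE),
    outfit = colMeans(z2std, na.rm = TRUE),
    n_obs = colSums(ok),
    row.names = NULL
  )
  persons <- data.frame(
    id = responses$person_ids,
    infit = rowSums(Z2, na.rm = TRUE) / rowSums(V, na.rm = TRUE),
    outfit = rowMeans(z2std, na.rm = TRUE),
    n_obs = rowSums(ok),
    row.names = NULL
  )
  structure(list(items = items, persons = persons), class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat("<fit_report>\n")
  print(x$items, digits = 3)
  invisible(x)
}

#' Iteratively remove misfitting items
#'
#' Fits the model, computes item infit/outfit mean-squares, and while any
#' item exceeds the cutoff on either statistic removes the single worst
#' offender (largest outfit; ties broken by largest infit, then lowest
#' item position) and refits. Stops when every retained item fits or when
#' a removal would leave fewer than 3 items (in which case it aborts with
#' the partial log attached to the error condition).
#'
#' @param responses A `qol_responses`.
#' @param instrument Instrument; defaults to the one in `responses`.
#' @param cutoff Mean-square cutoff (default 1.33).
#' @param model Model passed to [rasch_fit()].
#' @param ... Further arguments to [rasch_fit()].
#' @return List with `retained` (item ids), `removed` (data frame log:
#'   id, step, infit, outfit), and `fit` (the final calibration).
#' @export
purge_items <- function(responses, instrument = NULL, cutoff = 1.33,
                        model = "grsm", ...) {
  instrument <- instrument %||% responses$instrument
  if (nrow(instrument$items) < 3) stop("need at least 3 items", call. = FALSE)
  current <- instrument
  vals <- responses$values
  log <- data.frame(id = character(), step = integer(),
                    infit = numeric(), outfit = numeric())
  step <- 0L
  repeat {
    rm_obj <- response_matrix(vals[, current$items$id, drop = FALSE],
                              current, person_ids = responses$person_ids,
                              covariates = responses$covariates)
    f <- rasch_fit(rm_obj, current, model = model, ...)
    rep <- item_fit(f, rm_obj)$items
    bad <- rep[rep$infit > cutoff | rep$outfit > cutoff, , drop = FALSE]
    if (!nrow(bad)) {
      return(list(retained = current$items$id, removed = log, fit = f,
                  responses = rm_obj))
    }
    if (nrow(current$items) - 1 < 3) {
      cond <- simpleError("purge would leave fewer than 3 items")
      cond$removed <- log
      stop(cond)
    }
    ord <- order(-bad$outfit, -bad$infit, match(bad$id, current$items$id))
    worst <- bad[ord[1], ]
    step <- step + 1L
    log <- rbind(log, data.frame(id = worst$id, step = step,
                                 infit = worst$infit, outfit = worst$outfit))
    keep <- current$items$id != worst$id
    current <- qol_instrument(current$items[keep, , drop = FALSE],
                              current$n_categories,
                              current$recall_period_days)
  }
}

#' First-contrast principal component of standardized residuals
#'
#' Unrotated principal components analysis of the item-by-item correlation
#' matrix of standardized residuals (missing residuals imputed as 0, with
#' a note in the result). Under a unidimensional model the residuals are
#' near-independent noise and the first eigenvalue stays small (around 2
#' is the conventional concern threshold in this tradition); a structured
#' first contrast signals a second dimension. Also reports the percentage
#' of observation variance explained by the Rasch measures, computed as
#' model sum of squares over model-plus-residual sum of squares.
#'
#' @inheritParams standardized_residuals
#' @return List with `first_contrast_eigenvalue`, `eigenvalues`,
#'   `variance_explained_by_measures_pct`, `n_components_ge_2`,
#'   `loadings` (first contrast), and `n_imputed`.
#' @export
pca_first_contrast <- function(fit, responses) {
  fc <- .fitted_cells(fit, responses)
  Z <- (fc$X0 - fc$E) / sqrt(pmax(fc$V, 1e-12))
  Z[!fc$mask] <- NA
  n_imputed <- sum(is.na(Z))
  Z[is.na(Z)] <- 0
  if (nrow(Z) < ncol(Z)) {
    warning("fewer persons than items: residual correlation is rank-deficient",
            call. = FALSE)
  }
  sdz <- apply(Z, 2, stats::sd)
  keep <- sdz > 0
  R <- stats::cor(Z[, keep, drop = FALSE])
  ev <- eigen(R, symmetric = TRUE)
  SS_model <- sum((fc$E[fc$mask] - mean(fc$E[fc$mask]))^2)
  SS_resid <- sum((fc$X0[fc$mask] - fc$E[fc$mask])^2)
  list(
    first_contrast_eigenvalue = ev$values[1],
    eigenvalues = ev$values,
    variance_explained_by_measures_pct = 100 * SS_model / (SS_model + SS_resid),
    n_components_ge_2 = sum(ev$values >= 2),
    loadings = stats::setNames(ev$vectors[, 1], colnames(R)),
    n_imputed = n_imputed
  )
}

#' Are the Andrich thresholds ordered?
#'
#' Ordered thresholds (`tau_1 < tau_2 < ... `) indicate that successively
#' higher rating categories require successively higher trait levels — the
#' hallmark of a well-functioning rating scale.
#'
#' @param fit A `rasch_fit`.
#' @return Named list per threshold group: `list(ordered = logical, tau)`.
#' @export
thresholds_ordered <- function(fit) {
  lapply(fit$tau, function(t) {
    list(ordered = all(diff(t) > 0), tau = t)
  })
}

#' Category response curves
#'
#' Category probabilities as a function of the person-item offset
#' `theta - delta` for one rating-scale group. Adjacent-category curves
#' cross exactly at the Andrich thresholds; every category has a region
#' where it is modal precisely when the thresholds are ordered.
#'
#' @param fit A `rasch_fit`.
#' @param group Scale-group label (defaults to the first group).
#' @param grid Grid of `theta - delta` offsets.
#' @return List with `grid`, `probs` (categories x grid matrix) and `tau`.
#' @export
category_curves <- function(fit, group = names(fit$tau)[1],
                            grid = seq(-4, 4, by = 0.05)) {
  tau <- fit$tau[[group]]
  if (is.null(tau)) stop("unknown group: ", group, call. = FALSE)
  probs <- vapply(grid, function(phi) category_probs(phi, 0, tau),
                  numeric(length(tau) + 1))
  rownames(probs) <- paste0("cat", 0:length(tau))
  list(grid = grid, probs = probs, tau = tau, group = group)
}

#' Test information and conditional standard error of measurement
#'
#' Information at each trait level is the sum over items of the model
#' variance of the item score; the conditional standard error of
#' measurement is its inverse square root. The instrument measures most
#' precisely where the information curve peaks.
#'
#' @param fit A `rasch_fit`.
#' @param grid Trait grid in logits.
#' @param items Optional subset of item ids.
#' @return Data frame with columns `theta`, `information`, `sem`.
#' @export
test_information <- function(fit, grid = seq(-4, 4, by = 0.1), items = NULL) {
  ids <- items %||% names(fit$delta)
  idx <- match(ids, names(fit$delta))
  info <- rep(0, length(grid))
  for (i in idx) {
    if (is.na(fit$delta[i])) next
    info <- info + item_variance(grid, fit$delta[i], fit$tau[[fit$group[i]]])
  }
  data.frame(theta = grid, information = info, sem = 1 / sqrt(info))
}

#' Person-to-item (Wright) map data
#'
#' Person measures and item difficulties on the shared logit ruler, with a
#' targeting summary: the person-item mean offset, and the proportions of
#' persons located below the easiest and above the hardest item.
#'
#' @param fit A `rasch_fit`.
#' @return List of class `person_item_map` with sorted `persons` and
#'   `items` tables and a `targeting` summary.
#' @export
person_item_map <- function(fit) {
  th <- fit$theta[!is.na(fit$theta)]
  de <- fit$delta[!is.na(fit$delta)]
  persons <- data.frame(id = names(sort(th)), theta = sort(unname(th)))
  items <- data.frame(id = names(sort(de)), delta = sort(unname(de)))
  structure(list(
    persons = persons, items = items,
    targeting = list(
      mean_offset = mean(th) - mean(de),
      sd_theta = stats::sd(th),
      prop_below_items = mean(th < min(de)),
      prop_above_items = mean(th > max(de))
    )
  ), class = "person_item_map")
}

#' @export
print.person_item_map <- function(x, ...) {
  t <- x$targeting
  cat(sprintf(
    "<person_item_map> %d persons, %d items | mean offset %.2f logits | %0.1f%% below easiest item, %0.1f%% above hardest\n",
    nrow(x$persons), nrow(x$items), t$mean_offset,
    100 * t$prop_below_items, 100 * t$prop_above_items
  ))
  invisible(x)
}
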