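# --- data preparation shared by the estimator and the diagnostics ---------

# Returns the calibration view of a response matrix: 0-based keyed codes
# with "Does not apply" (0) and blanks as NA, reverse-scored items flipped
# onto the interference direction, the per-item threshold-group label for
# the requested model, and any adjacent-category collapse applied when a
# group never observes a category.
.prepare_data <- function(responses, instrument, model) {
  X <- responses$values
  X[X == 0] <- NA          # DNA is missing during calibration
  X0 <- X - 1
  rev <- instrument$items$reverse_scored
  m <- instrument$n_categories - 1L
  if (any(rev)) X0[, rev] <- m - X0[, rev, drop = FALSE]

  group <- switch(model,
    grsm = instrument$items$scale_group,
    rsm  = rep("all", nrow(instrument$items)),
    pcm  = instrument$items$id
  )

  if (length(unique(X0[!is.na(X0)])) < 2) {
    stop("need at least 2 distinct observed categories to calibrate",
         call. = FALSE)
  }

  cat_maps <- list()
  collapsed <- character()
  for (g in unique(group)) {
    idx <- which(group == g)
    obs <- sort(unique(as.vector(X0[, idx])))
    obs <- obs[!is.na(obs)]
    full <- 0:m
    if (!all(full %in% obs)) {
      if (length(obs) < 2) {
        stop(sprintf("rating-scale group '%s' has fewer than 2 observed categories", g),
             call. = FALSE)
      }
      map <- rep(NA_real_, m + 1)
      map[obs + 1] <- seq_along(obs) - 1
      for (j in idx) X0[, j] <- map[X0[, j] + 1]
      cat_maps[[g]] <- obs
      collapsed <- c(collapsed, g)
      warning(sprintf(
        "group '%s': categories %s unobserved; adjacent categories collapsed",
        g, paste(setdiff(full, obs), collapse = ",")
      ), call. = FALSE)
    } else {
      cat_maps[[g]] <- full
    }
  }
  K <- vapply(cat_maps, length, 0L)
  list(X0 = X0, group = group, cat_maps = cat_maps, K = K,
       collapsed = collapsed)
}

.fingerprint <- function(values) {
  paste(nrow(values), ncol(values),
        sum(values, na.rm = TRUE), sum(is.na(values)),
        sum(values^2, na.rm = TRUE), sep = ":")
}

# E and V matrices (persons x items) at arbitrary theta for given item
# parameters; used by the fit loop, residuals, information and curves.
.ev_matrices <- function(theta, delta, tau, group) {
  n <- length(theta); I <- length(delta)
  E <- matrix(NA_real_, n, I)
  V <- matrix(NA_real_, n, I)
  for (g in unique(group)) {
    idx <- which(group == g)
    s <- c(0, cumsum(tau[[g]]))
    st <- .cell_stats(as.vector(outer(theta, delta[idx], "-")), s)
    E[, idx] <- st$E
    V[, idx] <- st$V
  }
  list(E = E, V = V)
}

.clip <- function(x, lim = 1) pmin(pmax(x, -lim), lim)

# --- the joint maximum likelihood estimator --------------------------------

#' Fit a polytomous Rasch model by joint maximum likelihood
#'
#' Calibrates a rating scale model (`"rsm"`: one threshold set for all
#' items), grouped rating scale model (`"grsm"`: one threshold set per
#' scale group), or partial credit model (`"pcm"`: one per item) by
#' alternating Newton updates of person measures, item difficulties and
#' Andrich thresholds, in the joint (unconditional) maximum likelihood
#' tradition of the Winsteps software family.
#'
#' Identification: item difficulties are centered to mean 0 and each
#' threshold vector sums to 0 (both applied as likelihood-preserving
#' reparameterizations each cycle). "Does not apply" codes and blanks are
#' skipped (the likelihood runs over observed cells only); reverse-scored
#' items are flipped onto the interference direction before calibration.
#' Persons or items whose observed responses are all-minimum or
#' all-maximum carry no information about their own location; they are
#' excluded from calibration and assigned measures afterwards from their
#' raw score nudged `extreme_adjust` score points inward. A rating-scale
#' group that never observes some category has those categories collapsed
#' into their neighbours, with a warning.
#'
#' @param responses A `qol_responses` object.
#' @param instrument The instrument; defaults to the one attached to
#'   `responses`.
#' @param model `"grsm"`, `"rsm"` or `"pcm"`.
#' @param tol Convergence tolerance: largest absolute parameter change, in
#'   logits, allowed on the final cycle (default 1e-4).
#' @param max_iter Cycle cap; if reached the result is returned with
#'   `converged = FALSE` rather than an error.
#' @param extreme_adjust Score-point nudge used to assign finite measures
#'   to extreme persons and items (default 0.3).
#' @return An object of class `rasch_fit` with person measures (`theta`,
#'   `theta_se`), item difficulties (`delta`, `delta_se`), per-group
#'   thresholds (`tau`, `tau_se`), the joint log-likelihood, the iteration
#'   record, and the ids of persons/items excluded as extreme.
#' @export
rasch_fit <- function(responses, instrument = NULL,
                      model = c("grsm", "rsm", "pcm"),
                      tol = 1e-4, max_iter = 200L, extreme_adjust = 0.3) {
  model <- match.arg(model)
  stopifnot(inherits(responses, "qol_responses"))
  instrument <- instrument %||% responses$instrument
  if (model == "grsm" &&
      length(unique(instrument$items$scale_group)) < 2) {
    stop("grouped rating scale model requires items in both scale groups",
         call. = FALSE)
  }

  prep <- .prepare_data(responses, instrument, model)
  X0 <- prep$X0
  group <- prep$group
  n <- nrow(X0); I <- ncol(X0)
  maxcat <- prep$K[group] - 1   # per item, after any collapse

  mask <- !is.na(X0)
  Xz <- X0; Xz[!mask] <- 0

  r_person <- rowSums(Xz)
  max_person <- as.vector(mask %*% maxcat)
  t_item <- colSums(Xz)
  max_item <- as.vector(t(mask) %*% rep(1, n)) * maxcat

  person_in <- which(mask %*% rep(1, I) > 0 & r_person > 0 & r_person < max_person)
  item_in <- which(colSums(mask) > 0 & t_item > 0 & t_item < max_item)
  extreme_persons <- setdiff(which(rowSums(mask) > 0), person_in)
  extreme_items <- setdiff(seq_len(I), item_in)
  if (length(item_in) < 2) stop("fewer than 2 calibratable items", call. = FALSE)

  Xc <- X0[person_in, item_in, drop = FALSE]
  grp <- group[item_in]
  mk <- mask[person_in, item_in, drop = FALSE]
  Xcz <- Xc; Xcz[!mk] <- 0
  r <- rowSums(Xcz)
  ti <- colSums(Xcz)
  maxr <- as.vector(mk %*% maxcat[item_in])

  theta <- log((r + 0.5) / (maxr - r + 0.5))
  delta <- rep(0, length(item_in))
  taus <- lapply(unique(grp), function(g) rep(0, prep$K[[g]] - 1))
  names(taus) <- unique(grp)

  stats_for <- function(theta, delta, taus) {
    out <- list()
    E <- matrix(NA_real_, length(theta), length(delta))
    V <- matrix(NA_real_, length(theta), length(delta))
    for (g in names(taus)) {
      idx <- which(grp == g)
      s <- c(0, cumsum(taus[[g]]))
      st <- .cell_stats(as.vector(outer(theta, delta[idx], "-")), s)
      E[, idx] <- st$E; V[, idx] <- st$V
      out[[g]] <- st
    }
    list(E = E, V = V, by_group = out)
  }

  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    th_old <- theta; de_old <- delta; ta_old <- unlist(taus)

    st <- stats_for(theta, delta, taus)
    h <- pmax(rowSums(st$V * mk), 1e-10)
    theta <- theta + .clip((r - rowSums(st$E * mk)) / h)

    st <- stats_for(theta, delta, taus)
    hi <- pmax(colSums(st$V * mk), 1e-10)
    delta <- delta + .clip((colSums(st$E * mk) - ti) / hi)

    st <- stats_for(theta, delta, taus)
    for (g in names(taus)) {
      idx <- which(grp == g)
      cells <- which(as.vector(mk[, idx, drop = FALSE]))
      if (!length(cells)) next
      Q <- st$by_group[[g]]$Q[cells, , drop = FALSE]
      x <- as.vector(Xc[, idx, drop = FALSE])[cells]
      mK <- ncol(Q)
      ge <- outer(x, seq_len(mK), ">=")
      gvec <- colSums(Q - ge)
      A <- matrix(0, mK, mK)
      for (j in seq_len(mK)) for (l in j:mK) {
        a <- sum(Q[, max(j, l)]) - sum(Q[, j] * Q[, l])
        A[j, l] <- a; A[l, j] <- a
      }
      stp <- tryCatch(solve(A + diag(1e-8, mK), gvec), error = function(e) gvec / diag(A))
      taus[[g]] <- taus[[g]] + .clip(stp)
      # sum-to-zero recentring, compensated through the group's difficulties
      cg <- mean(taus[[g]])
      taus[[g]] <- taus[[g]] - cg
      delta[idx] <- delta[idx] + cg
    }
    md <- mean(delta)
    delta <- delta - md
    theta <- theta - md

    chg <- max(abs(c(theta - th_old, delta - de_old, unlist(taus) - ta_old)))
    if (chg < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }

  st <- stats_for(theta, delta, taus)
  theta_se <- 1 / sqrt(pmax(rowSums(st$V * mk), 1e-10))
  delta_se <- 1 / sqrt(pmax(colSums(st$V * mk), 1e-10))
  tau_se <- lapply(names(taus), function(g) {
    idx <- which(grp == g)
    cells <- which(as.vector(mk[, idx, drop = FALSE]))
    Q <- st$by_group[[g]]$Q[cells, , drop = FALSE]
    mK <- ncol(Q)
    A <- matrix(0, mK, mK)
    for (j in seq_len(mK)) for (l in j:mK) {
      a <- sum(Q[, max(j, l)]) - sum(Q[, j] * Q[, l])
      A[j, l] <- a; A[l, j] <- a
    }
    sqrt(pmax(diag(tryCatch(solve(A + diag(1e-8, mK)), error = function(e) diag(1 / diag(A)))), 0))
  })
  names(tau_se) <- names(taus)

  loglik <- 0
  for (g in names(taus)) {
    idx <- which(grp == g)
    cells <- which(as.vector(mk[, idx, drop = FALSE]))
    P <- st$by_group[[g]]$P
    x <- as.vector(Xc[, idx, drop = FALSE])[cells]
    loglik <- loglik + sum(log(P[cbind(cells, x + 1)]))
  }

  # full-length parameter vectors, extremes assigned post hoc
  theta_full <- rep(NA_real_, n); theta_se_full <- rep(NA_real_, n)
  theta_full[person_in] <- theta; theta_se_full[person_in] <- theta_se
  delta_full <- rep(NA_real_, I); delta_se_full <- rep(NA_real_, I)
  delta_full[item_in] <- delta; delta_se_full[item_in] <- delta_se
  taus_full <- taus
  for (g in setdiff(unique(group), names(taus))) {
    taus_full[[g]] <- rep(0, prep$K[[g]] - 1)   # group fully extreme (rare)
  }

  solve_theta <- function(target, items_idx) {
    th <- 0
    for (k in 1:100) {
      ev <- .ev_matrices(th, delta_full[items_idx],
                         taus_full[group[items_idx]], group[items_idx])
      g1 <- target - sum(ev$E)
      h1 <- max(sum(ev$V), 1e-10)
      step <- .clip(g1 / h1, 2)
      th <- th + step
      if (abs(step) < 1e-8) break
    }
    ev <- .ev_matrices(th, delta_full[items_idx],
                       taus_full[group[items_idx]], group[items_idx])
    c(th, 1 / sqrt(max(sum(ev$V), 1e-10)))
  }
  for (p in extreme_persons) {
    obs_i <- which(mask[p, ] & !is.na(delta_full))
    if (!length(obs_i)) next
    tot <- sum(X0[p, obs_i])
    mx <- sum(maxcat[obs_i])
    adj <- if (tot <= 0) extreme_adjust else
      if (tot >= mx) mx - extreme_adjust else tot
    est <- solve_theta(adj, obs_i)
    theta_full[p] <- est[1]; theta_se_full[p] <- est[2]
  }
  for (j in extreme_items) {
    obs_p <- which(mask[, j] & !is.na(theta_full))
    if (!length(obs_p)) next
    tot <- sum(X0[obs_p, j])
    mx <- length(obs_p) * maxcat[j]
    adj <- if (tot <= 0) extreme_adjust else
      if (tot >= mx) mx - extreme_adjust else tot
    # solve for delta holding theta: expected item total = adj
    de <- 0
    g <- group[j]
    for (k in 1:100) {
      s <- c(0, cumsum(taus_full[[g]]))
      stc <- .cell_stats(theta_full[obs_p] - de, s)
      step <- .clip((sum(stc$E) - adj) / max(sum(stc$V), 1e-10), 2)
      de <- de + step
      if (abs(step) < 1e-8) break
    }
    delta_full[j] <- de
    s <- c(0, cumsum(taus_full[[g]]))
    stc <- .cell_stats(theta_full[obs_p] - de, s)
    delta_se_full[j] <- 1 / sqrt(max(sum(stc$V), 1e-10))
  }

  structure(
    list(
      model = model,
      theta = stats::setNames(theta_full, responses$person_ids),
      theta_se = stats::setNames(theta_se_full, responses$person_ids),
      delta = stats::setNames(delta_full, responses$item_ids),
      delta_se = stats::setNames(delta_se_full, responses$item_ids),
      tau = taus_full, tau_se = tau_se,
      group = stats::setNames(group, responses$item_ids),
      cat_maps = prep$cat_maps, collapsed = prep$collapsed,
      loglik = loglik, n_iter = it, converged = converged, tol = tol,
      excluded_extreme_persons = responses$person_ids[extreme_persons],
      excluded_extreme_items = responses$item_ids[extreme_items],
      calibrated_persons = responses$person_ids[person_in],
      calibrated_items = responses$item_ids[item_in],
      extreme_adjust = extreme_adjust,
      fingerprint = .fingerprint(responses$values),
      n_persons = n, n_items = I
    ),
    class = "rasch_fit"
  )
}

#' @export
print.rasch_fit <- function(x, ...) {
  cat(sprintf(
    "<rasch_fit:%s> %d persons x %d items | loglik %.2f | %d cycles (%s)\n",
    x$model, x$n_persons, x$n_items, x$loglik, x$n_iter,
    if (x$converged) "converged" else "NOT converged"
  ))
  for (g in names(x$tau)) {
    cat(sprintf("  tau[%s]: %s\n", g,
                paste(sprintf("%.3f", x$tau[[g]]), collapse = " ")))
  }
  invisible(x)
}

#' Serialize a calibration to JSON
#'
#' @param fit A `rasch_fit`.
#' @param path Optional file path; when omitted the JSON string is
#'   returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
calibration_json <- function(fit, path = NULL) {
  payload <- fit[c("model", "theta", "theta_se", "delta", "delta_se",
                   "tau", "tau_se", "loglik", "n_iter", "converged",
                   "excluded_extreme_persons", "excluded_extreme_items")]
  js <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
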