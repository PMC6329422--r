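# Independent substreams derived from one root seed, so that switching one
# generation feature (say, DIF) on or off never perturbs the draws of
# another. Values stay below 2^31 (R integer seeds are 32-bit).
.stream_seed <- function(seed, purpose) {
  u <- utf8ToInt(purpose)
  h <- sum(u * seq_along(u))
  as.integer((as.numeric(seed) %% 65521) * 31627 + h * 1009) %% 2147483629L
}

.with_stream <- function(seed, purpose, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.stream_seed(seed, purpose))
  force(expr)
}

#' Ground truth for response simulation
#'
#' Bundles the generating parameters of a grouped rating scale model plus
#' the off-model features needed to exercise the full pipeline: items that
#' respond uniformly at random (to trigger fit flags), an optional
#' differential-item-functioning contrast, a "Does not apply" endorsement
#' rate for DNA-capable items, and the latent test-retest correlation.
#'
#' @param instrument The [qol_instrument] to simulate for.
#' @param delta Item difficulties in logits; centered to mean 0. Default:
#'   evenly spaced on \[-1, 1\].
#' @param tau Named list of Andrich threshold vectors (one per scale group
#'   present in the instrument), each summing to 0. Defaults to ordered,
#'   moderately spread thresholds that differ slightly between groups.
#' @param misfit_items Ids of items generated uniformly at random over the
#'   categories instead of from the model.
#' @param dif_spec Optional `list(item =, covariate =, contrast =)`: the
#'   named item's difficulty is shifted by `+contrast/2` for covariate
#'   group 1 and `-contrast/2` for group 0 at generation time.
#' @param dna_rate Probability that a DNA-capable item is answered
#'   "Does not apply" (code 0); in `[0, 1)`.
#' @param retest_rho Latent correlation between the two administrations in
#'   [simulate_retest()]; in `[-1, 1]`.
#' @param theta_mean,theta_sd Mean and SD (logits) of the latent trait
#'   distribution (normal).
#' @param seed Root seed; all generation substreams derive from it.
#' @return An object of class `sim_truth`.
#' @export
sim_truth <- function(instrument, delta = NULL, tau = NULL,
                      misfit_items = character(), dif_spec = NULL,
                      dna_rate = 0.1, retest_rho = 0.95,
                      theta_mean = 0, theta_sd = 1, seed = 1L) {
  stopifnot(inherits(instrument, "qol_instrument"))
  I <- nrow(instrument$items)
  if (is.null(delta)) delta <- seq(-1, 1, length.out = I)
  if (length(delta) != I) {
    stop("`delta` must have one value per instrument item", call. = FALSE)
  }
  delta <- delta - mean(delta)
  groups <- unique(instrument$items$scale_group)
  m <- instrument$n_categories - 1L
  if (is.null(tau)) {
    base <- list(
      frequency = c(-1.8, -0.6, 0.6, 1.8),
      intensity = c(-1.2, -0.4, 0.4, 1.2)
    )
    tau <- lapply(groups, function(g) {
      t0 <- base[[g]] %||% seq(-1.5, 1.5, length.out = m)
      if (length(t0) != m) t0 <- seq(-1.5, 1.5, length.out = m)
      t0
    })
    names(tau) <- groups
  }
  for (g in names(tau)) {
    if (length(tau[[g]]) != m) {
      stop(sprintf("threshold vector for group '%s' must have length %d", g, m),
           call. = FALSE)
    }
    if (abs(sum(tau[[g]])) > 1e-8) {
      stop(sprintf("threshold vector for group '%s' must sum to 0", g),
           call. = FALSE)
    }
  }
  if (dna_rate < 0 || dna_rate >= 1) stop("`dna_rate` must be in [0, 1)", call. = FALSE)
  if (abs(retest_rho) > 1) stop("`retest_rho` must be in [-1, 1]", call. = FALSE)
  bad_misfit <- setdiff(misfit_items, instrument$items$id)
  if (length(bad_misfit)) {
    stop("unknown misfit item(s): ", paste(bad_misfit, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(instrument = instrument, delta = delta, tau = tau,
         misfit_items = misfit_items, dif_spec = dif_spec,
         dna_rate = dna_rate, retest_rho = retest_rho,
         theta_mean = theta_mean, theta_sd = theta_sd,
         seed = as.integer(seed)),
    class = "sim_truth"
  )
}

# Draw the standard per-person covariates (binary gender, age, binary race)
.sim_covariates <- function(n, seed) {
  .with_stream(seed, "covariates", {
    data.frame(
      gender = sample(c(0L, 1L), n, replace = TRUE),
      age = pmin(pmax(round(stats::rnorm(n, 59, 13.5)), 22), 86),
      race = stats::rbinom(n, 1L, 0.857)
    )
  })
}

# Map a persons x items grid of uniforms through the model's category CDFs
.draw_codes <- function(theta, delta_eff, tau, instrument, U, misfit) {
  n <- length(theta); I <- length(delta_eff)
  K <- instrument$n_categories
  X <- matrix(NA_real_, n, I)
  grp <- instrument$items$scale_group
  for (g in unique(grp)) {
    idx <- which(grp == g)
    s <- c(0, cumsum(tau[[g]]))
    phi <- outer(theta, delta_eff[idx], "-")
    st <- .cell_stats(as.vector(phi), s)
    cum <- st$P
    for (k in 2:K) cum[, k] <- cum[, k - 1] + cum[, k]
    u <- as.vector(U[, idx])
    code <- rep(1L, length(u))
    for (k in 1:(K - 1)) code <- code + (u > cum[, k])
    X[, idx] <- matrix(code, n, length(idx))
  }
  if (any(misfit)) {
    X[, misfit] <- ceiling(U[, misfit, drop = FALSE] * K)
    X[, misfit][X[, misfit] < 1] <- 1
  }
  X
}

#' Simulate questionnaire responses from the grouped rating scale model
#'
#' Each response is drawn from the grouped-rating-scale category
#' distribution at the person's latent trait and the item's difficulty,
#' using the same probability kernel as the estimator. Items listed in
#' `truth$misfit_items` are instead drawn uniformly over the categories;
#' a DIF item's difficulty is shifted by half the contrast in opposite
#' directions for the two covariate groups; DNA-capable items are replaced
#' by code 0 with probability `truth$dna_rate`; reverse-scored items are
#' recorded on the flipped 1-5 scale. All draws are reproducible from
#' `truth$seed` via independent substreams.
#'
#' @param instrument The [qol_instrument] (must match `truth$instrument`).
#' @param n Number of respondents.
#' @param truth A [sim_truth()] object.
#' @param theta Optional vector of latent trait values to use instead of
#'   drawing them (length `n`).
#' @return A `qol_responses` object with covariates attached and the echoed
#'   generating truth (including the drawn `theta`) in `$truth`.
#' @export
simulate_responses <- function(instrument, n, truth, theta = NULL) {
  stopifnot(inherits(truth, "sim_truth"), n >= 1)
  I <- nrow(instrument$items)
  if (length(truth$delta) != I) {
    stop("`truth$delta` length must equal the number of active items",
         call. = FALSE)
  }
  seed <- truth$seed
  if (is.null(theta)) {
    theta <- .with_stream(seed, "theta",
      stats::rnorm(n, truth$theta_mean, truth$theta_sd))
  }
  covariates <- .sim_covariates(n, seed)
  U <- .with_stream(seed, "responses", matrix(stats::runif(n * I), n, I))

  delta_eff <- matrix(truth$delta, n, I, byrow = TRUE)
  if (!is.null(truth$dif_spec)) {
    ds <- truth$dif_spec
    j <- match(ds$item, instrument$items$id)
    if (is.na(j)) stop("DIF item not in instrument", call. = FALSE)
    gvar <- covariates[[ds$covariate %||% "gender"]]
    delta_eff[, j] <- delta_eff[, j] + ifelse(gvar == 1, ds$contrast / 2,
                                              -ds$contrast / 2)
  }

  misfit <- instrument$items$id %in% truth$misfit_items
  X <- matrix(NA_real_, n, I)
  # DIF shifts the difficulty per person; draw row blocks by group value
  if (is.null(truth$dif_spec)) {
    X <- .draw_codes(theta, truth$delta, truth$tau, instrument, U, misfit)
  } else {
    for (gv in unique(covariates[[truth$dif_spec$covariate %||% "gender"]])) {
      rows <- which(covariates[[truth$dif_spec$covariate %||% "gender"]] == gv)
      X[rows, ] <- .draw_codes(theta[rows], delta_eff[rows[1], ], truth$tau,
                               instrument, U[rows, , drop = FALSE], misfit)
    }
  }

  if (truth$dna_rate > 0 && any(instrument$items$has_dna_option)) {
    dna_idx <- which(instrument$items$has_dna_option)
    Ud <- .with_stream(seed, "dna",
      matrix(stats::runif(n * length(dna_idx)), n, length(dna_idx)))
    X[, dna_idx][Ud < truth$dna_rate] <- 0
  }

  rev <- instrument$items$reverse_scored
  if (any(rev)) {
    rv <- X[, rev, drop = FALSE]
    rv[rv > 0] <- (instrument$n_categories + 1) - rv[rv > 0]
    X[, rev] <- rv
  }

  truth_echo <- truth
  truth_echo$theta <- theta
  out <- response_matrix(X, instrument, covariates = covariates)
  out$truth <- truth_echo
  out
}

#' Simulate a test-retest pair of administrations
#'
#' The second administration shares the item parameters of the first; its
#' latent traits are generated with correlation `truth$retest_rho` to the
#' first administration's (a Gaussian copula on the latent scale, so
#' `retest_rho = 1` copies `theta` exactly).
#'
#' @inheritParams simulate_responses
#' @return A list with `qol_responses` elements `time1` and `time2`.
#' @export
simulate_retest <- function(instrument, n, truth) {
  theta1 <- .with_stream(truth$seed, "theta",
    stats::rnorm(n, truth$theta_mean, truth$theta_sd))
  rho <- truth$retest_rho
  eps <- .with_stream(truth$seed, "retest", stats::rnorm(n))
  theta2 <- truth$theta_mean + rho * (theta1 - truth$theta_mean) +
    truth$theta_sd * sqrt(1 - rho^2) * eps
  truth2 <- truth
  truth2$seed <- .stream_seed(truth$seed, "administration2")
  list(
    time1 = simulate_responses(instrument, n, truth, theta = theta1),
    time2 = simulate_responses(instrument, n, truth2, theta = theta2)
  )
}

#' Simulate comparator variables for validity analyses
#'
#' Generates a continuous convergent comparator (a Skindex-like total) as
#' `loading * z(theta) + noise` and an ordinal disease-stage variable by
#' discretizing a second, weakly loading latent variable into ordered
#' levels.
#'
#' @param theta Latent trait values, or a `qol_responses` carrying an
#'   echoed truth.
#' @param convergent_loading Correlation of the continuous comparator with
#'   the standardized latent trait.
#' @param stage_loading Correlation of the latent stage variable with the
#'   standardized latent trait.
#' @param n_stage_levels Number of ordered stage levels (default 3:
#'   IA / IB / II+).
#' @param seed Seed for the comparator noise streams.
#' @return Data frame with columns `comparator` and `stage`.
#' @export
simulate_comparators <- function(theta, convergent_loading = 0.85,
                                 stage_loading = 0.26, n_stage_levels = 3L,
                                 seed = 1L) {
  if (inherits(theta, "qol_responses")) theta <- theta$truth$theta
  stopifnot(abs(convergent_loading) <= 1, abs(stage_loading) <= 1)
  z <- if (stats::sd(theta) > 0) (theta - mean(theta)) / stats::sd(theta) else theta * 0
  n <- length(theta)
  comparator <- convergent_loading * z +
    sqrt(1 - convergent_loading^2) * .with_stream(seed, "comparator", stats::rnorm(n))
  stage_latent <- stage_loading * z +
    sqrt(1 - stage_loading^2) * .with_stream(seed, "stage", stats::rnorm(n))
  cuts <- stats::quantile(stage_latent,
                          probs = seq_len(n_stage_levels - 1) / n_stage_levels)
  stage <- findInterval(stage_latent, cuts) + 1L
  data.frame(comparator = comparator, stage = stage)
}

#' Study-mimicking simulation preset
#'
#' One-call preset reproducing the development study's structure: 126
#' respondents, 12 items (5 frequency-worded, 7 intensity-worded), 2 items
#' with a "Does not apply" option, a 52.4% retest subsample measured 5 days
#' later, and binary gender plus age and race covariates for DIF.
#'
#' @param seed Root seed.
#' @param n Number of respondents (126 in the study).
#' @param retest_fraction Fraction completing the second administration.
#' @return List with elements `instrument`, `truth`, `n`, `retest_fraction`
#'   and `retest_n`.
#' @export
study_preset <- function(seed = 1L, n = 126L, retest_fraction = 0.524) {
  items <- data.frame(
    id = sprintf("q%02d", 1:12),
    text = sprintf("Synthetic study item %d", 1:12),
    scale_group = rep(c("frequency", "intensity"), times = c(5, 7)),
    has_dna_option = 1:12 %in% c(6, 7),
    reverse_scored = FALSE,
    stringsAsFactors = FALSE
  )
  instrument <- qol_instrument(items)
  truth <- sim_truth(instrument, dna_rate = 0.08, retest_rho = 0.95,
                     seed = seed)
  list(instrument = instrument, truth = truth, n = as.integer(n),
       retest_fraction = retest_fraction,
       retest_n = as.integer(round(n * retest_fraction)))
}
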