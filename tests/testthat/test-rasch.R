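test_that("category probabilities are a proper distribution with the right limits", {
  p <- category_probs(0.3, -0.2, c(-1.5, -0.5, 0.5, 1.5))
  expect_length(p, 5)
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-12)

  # far above the item, the top category dominates
  expect_gt(category_probs(10, 0, c(0, 0, 0, 0))[5], 0.999)
  expect_error(category_probs(Inf, 0, c(0, 0, 0, 0)), "finite")
  expect_error(category_probs(0, 0, c(NA, 0, 0, 0)), "finite")
})

test_that("category probabilities match the brute-force oracle", {
  expect_equal(category_probs(0, 0, c(-2, -1, 1, 2)),
               oracle_probs(0, 0, c(-2, -1, 1, 2)), tolerance = 1e-10)
  set.seed(9)
  for (i in 1:10) {
    th <- rnorm(1, 0, 2); de <- rnorm(1); tau <- rnorm(4)
    expect_equal(category_probs(th, de, tau), oracle_probs(th, de, tau),
                 tolerance = 1e-10)
  }
})

test_that("expected score and variance behave like moments of the category distribution", {
  tau <- c(-2, -1, 1, 2)  # symmetric
  expect_equal(expected_score(0.7, 0.7, tau), 2, tolerance = 1e-10)

  th <- c(-1.3, 0.2, 1.8)
  p <- sapply(th, function(t) category_probs(t, 0.4, tau))
  k <- 0:4
  expect_equal(item_variance(th, 0.4, tau),
               as.vector(k^2 %*% p) - as.vector(k %*% p)^2,
               tolerance = 1e-12)

  # d/dtheta E[X] equals Var[X] (finite differences at 5 points)
  h <- 1e-5
  for (t in c(-2, -1, 0, 1, 2)) {
    fd <- (expected_score(t + h, 0.4, tau) - expected_score(t - h, 0.4, tau)) / (2 * h)
    expect_equal(fd, item_variance(t, 0.4, tau), tolerance = 1e-5)
  }
  expect_true(all(diff(expected_score(seq(-5, 5, 0.25), 0, tau)) > 0))
})

test_that("JMLE recovers generating parameters", {
  s <- sim_fit(1000, seed = 21)
  expect_true(s$fit$converged)
  expect_lt(sqrt(mean((unname(s$fit$delta) - s$truth$delta)^2)), 0.15)
  tau_err <- unlist(s$fit$tau[names(s$truth$tau)]) - unlist(s$truth$tau)
  expect_lt(sqrt(mean(tau_err^2)), 0.20)
  expect_gt(cor(s$fit$theta, s$responses$truth$theta), 0.9)
})

test_that("identification constraints hold at the solution", {
  s <- sim_fit(300, seed = 22)
  keep <- names(s$fit$delta) %in% s$fit$calibrated_items
  expect_equal(mean(s$fit$delta[keep]), 0, tolerance = 1e-6)
  for (g in names(s$fit$tau)) {
    expect_equal(sum(s$fit$tau[[g]]), 0, tolerance = 1e-6)
  }
  expect_true(is.finite(s$fit$loglik))
})

test_that("extreme persons are excluded from calibration but still measured", {
  inst <- make_test_instrument(12)
  tr <- sim_truth(inst, seed = 23)
  r <- simulate_responses(inst, 150, tr)
  r$values[1, ] <- 1   # all-minimum respondent
  r$values[2, ] <- 5   # all-maximum respondent
  r <- response_matrix(r$values, inst, person_ids = r$person_ids)
  f <- rasch_fit(r, inst, model = "grsm")
  expect_true(all(c("P0001", "P0002") %in% f$excluded_extreme_persons))
  expect_true(all(is.finite(f$theta[f$excluded_extreme_persons])))
  expect_lt(f$theta[1], min(f$theta[-(1:2)], na.rm = TRUE) + 0.5)
  expect_gt(f$theta[2], max(f$theta[-(1:2)], na.rm = TRUE) - 0.5)
})

test_that("raw totals are sufficient for the person measure", {
  s <- sim_fit(200, seed = 24)
  totals <- rowSums(s$responses$values)
  th <- unname(s$fit$theta)
  for (tt in unique(totals)) {
    idx <- which(totals == tt)
    if (length(idx) > 1) {
      expect_equal(max(th[idx]) - min(th[idx]), 0, tolerance = 1e-8)
    }
  }
})

test_that("the grouped model never fits worse than the plain rating scale model", {
  inst <- make_test_instrument(12)
  for (seed in 25:27) {
    tr <- sim_truth(inst, seed = seed)
    r <- simulate_responses(inst, 250, tr)
    g <- rasch_fit(r, inst, model = "grsm")
    s <- rasch_fit(r, inst, model = "rsm")
    expect_gte(g$loglik, s$loglik - 1e-6)
  }
})

test_that("likelihood-ratio test has the analytic degrees of freedom", {
  s <- sim_fit(250, seed = 28)
  rsm <- rasch_fit(s$responses, model = "rsm")
  l <- lrt_grsm_vs_rsm(s$fit, rsm)
  expect_equal(l$df, 3)           # two groups, five categories
  expect_gte(l$chi2, 0)
  expect_true(l$p >= 0 && l$p <= 1)

  other <- sim_fit(250, seed = 29)
  expect_error(lrt_grsm_vs_rsm(s$fit, rasch_fit(other$responses, model = "rsm")),
               "identical data")
  expect_error(lrt_grsm_vs_rsm(rsm, rsm), "grsm fit")
})

test_that("fitting the grouped model to plain rating-scale data finds no group difference", {
  inst <- make_test_instrument(12)
  tau0 <- c(-1.5, -0.5, 0.5, 1.5)
  tr <- sim_truth(inst, tau = list(frequency = tau0, intensity = tau0),
                  seed = 77)
  r <- simulate_responses(inst, 1000, tr)
  f <- rasch_fit(r, inst, model = "grsm")
  diff <- abs(f$tau$frequency - f$tau$intensity)
  joint_se <- sqrt(f$tau_se$frequency^2 + f$tau_se$intensity^2)
  expect_true(all(diff <= 2 * joint_se))
})

test_that("estimation bias shrinks with the sample size", {
  inst <- make_test_instrument(12)
  bias_at <- function(n) mean(sapply(1:3, function(s) {
    tr <- sim_truth(inst, seed = s)
    f <- rasch_fit(simulate_responses(inst, n, tr), inst, model = "grsm")
    mean(abs(unname(f$delta) - tr$delta))
  }))
  expect_lt(bias_at(2000), bias_at(200))
})

test_that("partial-credit ICC overlay separates groups with distinct thresholds", {
  inst <- make_test_instrument(12, n_freq = 6)
  tr <- sim_truth(inst,
                  tau = list(frequency = c(-2.4, -0.8, 0.8, 2.4),
                             intensity = c(-0.9, -0.3, 0.3, 0.9)),
                  delta = rep(0, 12), seed = 30)
  r <- simulate_responses(inst, 800, tr)
  pcm <- rasch_fit(r, inst, model = "pcm")
  ov <- icc_overlay(pcm, scale_group = inst$items$scale_group)
  expect_gt(ov$between_mean_dist, ov$within_mean_dist)
  # expected-score curves are monotone at every grid point
  expect_true(all(apply(ov$curves, 1, function(cv) all(diff(cv) > 0))))

  # identical parameters give dissimilarity zero
  f2 <- pcm
  for (g in names(f2$tau)) f2$tau[[g]] <- c(-1, -0.5, 0.5, 1)
  f2$delta[] <- 0
  ov2 <- icc_overlay(f2, scale_group = inst$items$scale_group)
  expect_equal(ov2$within_max_dist, 0, tolerance = 1e-12)
})

test_that("unobserved categories are collapsed with a warning", {
  inst <- make_test_instrument(6, n_freq = 3)
  tr <- sim_truth(inst, seed = 31)
  r <- simulate_responses(inst, 120, tr)
  vals <- r$values
  vals[, 1:3][vals[, 1:3] == 5] <- 4   # frequency group never observes 5
  r2 <- response_matrix(vals, inst)
  expect_warning(f <- rasch_fit(r2, inst, model = "grsm"), "collapsed")
  expect_length(f$tau$frequency, 3)
  expect_length(f$tau$intensity, 4)
  expect_true(f$converged)
})

test_that("calibration serializes to JSON and back", {
  s <- sim_fit(100, seed = 32)
  js <- calibration_json(s$fit)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$loglik, s$fit$loglik, tolerance = 1e-9)
  expect_equal(parsed$model, "grsm")
  expect_equal(unlist(parsed$tau$frequency), unname(s$fit$tau$frequency),
               tolerance = 1e-9)
})
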