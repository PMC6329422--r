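test_that("standardized residuals match direct recomputation", {
  s <- sim_fit(150, seed = 41)
  Z <- standardized_residuals(s$fit, s$responses)
  f <- s$fit
  X <- s$responses$values
  for (cell in list(c(3, 2), c(10, 7), c(99, 12))) {
    i <- cell[1]; j <- cell[2]
    tau <- f$tau[[f$group[j]]]
    p <- oracle_probs(f$theta[i], f$delta[j], tau)
    k <- 0:4
    E <- sum(k * p); V <- sum(k^2 * p) - E^2
    expect_equal(Z[i, j], ((X[i, j] - 1) - E) / sqrt(V), tolerance = 1e-10)
  }
  # missing cells stay missing
  X[5, 1] <- NA
  r2 <- response_matrix(X, s$responses$instrument)
  Z2 <- standardized_residuals(s$fit, r2)
  expect_true(is.na(Z2[5, 1]))
})

test_that("residuals have mean near zero under the generating model", {
  s <- sim_fit(2000, seed = 42)
  Z <- standardized_residuals(s$fit, s$responses)
  expect_lt(abs(mean(Z, na.rm = TRUE)), 0.02)
})

test_that("mean-squares equal hand arithmetic on a 3-person micro grid", {
  inst <- make_test_instrument(2, n_freq = 1)
  X <- matrix(c(2, 3,
                4, 4,
                1, 5), nrow = 3, byrow = TRUE)
  r <- response_matrix(X, inst)
  theta <- c(-0.5, 0.4, 1.1)
  delta <- c(-0.3, 0.3)
  tau <- list(frequency = c(-1.2, -0.4, 0.4, 1.2),
              intensity = c(-0.8, -0.2, 0.2, 0.8))
  fake <- structure(list(
    model = "grsm",
    theta = stats::setNames(theta, r$person_ids),
    delta = stats::setNames(delta, r$item_ids),
    tau = tau, group = stats::setNames(c("frequency", "intensity"), r$item_ids)
  ), class = "rasch_fit")
  rep <- item_fit(fake, r)

  # independent arithmetic from the raw formulae
  k <- 0:4
  E <- matrix(0, 3, 2); V <- matrix(0, 3, 2)
  for (i in 1:3) for (j in 1:2) {
    p <- oracle_probs(theta[i], delta[j], tau[[c("frequency", "intensity")[j]]])
    E[i, j] <- sum(k * p); V[i, j] <- sum(k^2 * p) - E[i, j]^2
  }
  R2 <- ((X - 1) - E)^2
  expect_equal(rep$items$outfit, colMeans(R2 / V), tolerance = 1e-10)
  expect_equal(rep$items$infit, colSums(R2) / colSums(V), tolerance = 1e-10)
  expect_equal(rep$persons$outfit, rowMeans(R2 / V), tolerance = 1e-10)
  expect_equal(rep$persons$infit, rowSums(R2) / rowSums(V), tolerance = 1e-10)
})

test_that("a uniformly random item is caught by outfit", {
  inst <- make_test_instrument(12)
  hits <- sapply(1:5, function(s) {
    tr <- sim_truth(inst, misfit_items = "q04", seed = 500 + s)
    r <- simulate_responses(inst, 400, tr)
    f <- rasch_fit(r, inst, model = "grsm")
    item_fit(f, r)$items$outfit[4] > 1.33
  })
  expect_true(all(hits))
})

test_that("iterative purge removes exactly the off-model items", {
  inst <- make_test_instrument(14, n_freq = 6)
  tr <- sim_truth(inst, misfit_items = c("q05", "q12"), seed = 42)
  r <- simulate_responses(inst, 400, tr)
  pg <- purge_items(r, inst, cutoff = 1.33)
  expect_setequal(pg$removed$id, c("q05", "q12"))
  expect_length(pg$retained, 12)
  expect_equal(pg$removed$step, seq_len(nrow(pg$removed)))

  # deterministic across runs
  pg2 <- purge_items(r, inst, cutoff = 1.33)
  expect_identical(pg$removed$id, pg2$removed$id)

  # idempotent: purging the retained set removes nothing
  pg3 <- purge_items(pg$responses, cutoff = 1.33)
  expect_equal(nrow(pg3$removed), 0)

  # all-model-true data loses nothing
  tr0 <- sim_truth(inst, seed = 43)
  pg0 <- purge_items(simulate_responses(inst, 400, tr0), inst, cutoff = 1.33)
  expect_equal(nrow(pg0$removed), 0)
  expect_length(pg0$retained, 14)
})

test_that("purge aborts rather than dropping below 3 items", {
  inst <- make_test_instrument(3, n_freq = 1)
  tr <- sim_truth(inst, seed = 44)
  r <- simulate_responses(inst, 300, tr)
  v <- r$values
  v[, 3] <- 6 - v[, 1]   # anti-keyed duplicate: gross, removable misfit
  r2 <- response_matrix(v, inst)
  expect_error(purge_items(r2, inst, cutoff = 1.33), "fewer than 3")
  expect_error(purge_items(r2, make_test_instrument(2, n_freq = 1)),
               "at least 3")
})

test_that("first-contrast eigenvalue separates one and two dimensions", {
  inst <- make_test_instrument(12)
  null_ev <- sapply(1:5, function(s) {
    st <- sim_fit(300, seed = 100 + s, instrument = inst)
    pca_first_contrast(st$fit, st$responses)$first_contrast_eigenvalue
  })
  expect_lt(median(null_ev), 2.0)

  two_ev <- sapply(1:5, function(s) {
    tr <- sim_truth(inst, seed = 200 + s)
    set.seed(300 + s)
    th <- rnorm(300); eta <- rnorm(300)
    r1 <- simulate_responses(inst, 300, tr, theta = th)
    r2 <- simulate_responses(inst, 300, tr, theta = 0.6 * th + 0.8 * eta)
    r <- response_matrix(cbind(r1$values[, 1:6], r2$values[, 7:12]), inst)
    f <- rasch_fit(r, inst, model = "grsm")
    pca_first_contrast(f, r)$first_contrast_eigenvalue
  })
  expect_true(all(two_ev > 2.0))
})

test_that("residual PCA conserves the trace and reports explained variance", {
  st <- sim_fit(300, seed = 45)
  pc <- pca_first_contrast(st$fit, st$responses)
  expect_equal(sum(pc$eigenvalues), 12, tolerance = 1e-8)
  expect_true(pc$variance_explained_by_measures_pct > 0 &&
              pc$variance_explained_by_measures_pct < 100)
})

test_that("threshold ordering is detected and recovered", {
  fake <- structure(list(tau = list(a = c(-2, -1, 1, 2),
                                    b = c(-1, -2, 1, 2))),
                    class = "rasch_fit")
  to <- thresholds_ordered(fake)
  expect_true(to$a$ordered)
  expect_false(to$b$ordered)

  ok <- sapply(1:5, function(s) {
    st <- sim_fit(1000, seed = 400 + s)
    all(sapply(thresholds_ordered(st$fit), `[[`, "ordered"))
  })
  expect_true(all(ok))
})

test_that("category curves cross at the Andrich thresholds", {
  st <- sim_fit(300, seed = 46)
  cc <- category_curves(st$fit, "frequency", grid = seq(-4, 4, by = 0.001))
  expect_equal(colSums(cc$probs), rep(1, length(cc$grid)), tolerance = 1e-10)
  # curve values equal category_probs pointwise
  i <- 1500
  expect_equal(unname(cc$probs[, i]), category_probs(cc$grid[i], 0, cc$tau),
               tolerance = 1e-12)
  # adjacent-category crossings: P(k-1) = P(k) at phi = tau_k
  for (k in 1:4) {
    gap <- cc$probs[k, ] - cc$probs[k + 1, ]
    cross <- cc$grid[which(diff(sign(gap)) != 0)[1]]
    expect_equal(cross, cc$tau[k], tolerance = 0.01)
  }
})

test_that("test information is the sum of item variances and symmetric when expected", {
  fake <- structure(list(
    delta = stats::setNames(rep(0, 4), paste0("q", 1:4)),
    tau = list(all = c(-2, -1, 1, 2)),
    group = stats::setNames(rep("all", 4), paste0("q", 1:4))
  ), class = "rasch_fit")
  grid <- seq(-4, 4, by = 0.1)
  ti <- test_information(fake, grid)
  expect_true(all(ti$information >= 0))
  expect_lt(max(abs(ti$information - rev(ti$information))), 1e-9)

  # single item: brute force sum(k^2 p) - sum(k p)^2 at theta = 0
  p <- oracle_probs(0, 0, c(-2, -1, 1, 2))
  k <- 0:4
  one <- test_information(fake, grid = 0, items = "q1")
  expect_equal(one$information, sum(k^2 * p) - sum(k * p)^2, tolerance = 1e-10)
  expect_equal(one$sem, 1 / sqrt(one$information), tolerance = 1e-12)
})

test_that("person-item map orders items by difficulty and flags under-coverage", {
  st <- sim_fit(200, seed = 47)
  pim <- person_item_map(st$fit)
  expect_identical(pim$items$delta, sort(unname(st$fit$delta)))
  expect_identical(pim$persons$theta, sort(unname(st$fit$theta)))

  # a sample shifted half a logit down shows more persons below the items
  inst <- make_test_instrument(12)
  f0 <- rasch_fit(simulate_responses(inst, 126, sim_truth(inst, seed = 55)),
                  inst)
  f1 <- rasch_fit(simulate_responses(inst, 126,
                                     sim_truth(inst, seed = 55,
                                               theta_mean = -0.5)), inst)
  expect_gt(person_item_map(f1)$targeting$prop_below_items,
            person_item_map(f0)$targeting$prop_below_items)

  # serialization round-trip
  js <- jsonlite::toJSON(unclass(pim), digits = NA, auto_unbox = TRUE)
  back <- jsonlite::fromJSON(js)
  expect_equal(back$items$delta, pim$items$delta, tolerance = 1e-12)
})
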