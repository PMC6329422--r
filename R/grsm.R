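#' Category probabilities of the (grouped) rating scale model
#'
#' Probability of each response category for an adjacent-category (Rasch)
#' polytomous item. With person measure `theta`, item difficulty `delta`
#' (both logits) and a vector `tau` of Andrich thresholds shared across the
#' item's rating-scale group, the probability of category `k` (counting from
#' 0) is proportional to `exp(k * (theta - delta) - sum(tau[1:k]))`. The
#' rating scale model uses one `tau` vector for every item, the grouped
#' rating scale model one per item group, and the partial credit model one
#' per item; this kernel is shared by all three.
#'
#' @param theta Person measure in logits (scalar).
#' @param delta Item difficulty in logits (scalar).
#' @param tau Numeric vector of Andrich thresholds (length = number of
#'   categories minus one). For the published instrument this has length 4.
#' @return Numeric vector of `length(tau) + 1` probabilities over categories
#'   `0:length(tau)`, summing to 1.
#' @examples
#' category_probs(0, 0, c(-2, -1, 1, 2))
#' @export
category_probs <- function(theta, delta, tau) {
  if (!all(is.finite(c(theta, delta, tau)))) {
    stop("`theta`, `delta` and `tau` must all be finite", call. = FALSE)
  }
  s <- c(0, cumsum(tau))
  k <- seq_along(s) - 1
  logit <- k * (theta - delta) - s
  w <- exp(logit - max(logit))
  w / sum(w)
}

#' Expected item score and conditional score variance
#'
#' The expected category score (on the 0-based category scale) and its
#' conditional variance under the model of [category_probs()]. The variance
#' is the item's Fisher information about `theta`, and equals the derivative
#' of the expected score with respect to `theta`.
#'
#' @param theta Person measure(s) in logits; may be a vector.
#' @inheritParams category_probs
#' @return Numeric vector, one value per element of `theta`.
#' @export
expected_score <- function(theta, delta, tau) {
  k <- 0:length(tau)
  vapply(theta, function(th) sum(k * category_probs(th, delta, tau)), 0)
}

#' @rdname expected_score
#' @export
item_variance <- function(theta, delta, tau) {
  k <- 0:length(tau)
  vapply(theta, function(th) {
    p <- category_probs(th, delta, tau)
    sum(k^2 * p) - sum(k * p)^2
  }, 0)
}

# Vectorized category-probability engine used by the estimator and the
# simulator (single source of truth for the model kernel).
#
# phi: numeric vector of theta - delta for a set of cells sharing one
# threshold vector; s: cumulative thresholds c(0, cumsum(tau)).
# Returns list(P = cells x K probability matrix, E, V, Q = P(X >= j) for
# j = 1..K-1 as cells x (K-1)).
.cell_stats <- function(phi, s) {
  K <- length(s)
  n <- length(phi)
  M <- matrix(0, n, K)
  for (k in seq_len(K)) M[, k] <- (k - 1) * phi - s[k]
  rmax <- M[, 1]
  for (k in 2:K) rmax <- pmax(rmax, M[, k])
  W <- exp(M - rmax)
  P <- W / rowSums(W)
  kk <- 0:(K - 1)
  E <- as.vector(P %*% kk)
  V <- as.vector(P %*% kk^2) - E^2
  Q <- matrix(0, n, K - 1)
  acc <- rep(0, n)
  for (j in (K - 1):1) {
    acc <- acc + P[, j + 1]
    Q[, j] <- acc
  }
  list(P = P, E = E, V = V, Q = Q)
}
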