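# Shared fixtures: instruments and simulated datasets built in code.

make_test_instrument <- function(I = 12, n_freq = min(5, I - 1),
                                 dna = integer(), rev = integer()) {
  qol_instrument(data.frame(
    id = sprintf("q%02d", seq_len(I)),
    text = sprintf("Test item %d", seq_len(I)),
    scale_group = rep(c("frequency", "intensity"), times = c(n_freq, I - n_freq)),
    has_dna_option = seq_len(I) %in% dna,
    reverse_scored = seq_len(I) %in% rev,
    stringsAsFactors = FALSE
  ))
}

sim_fit <- function(n, seed, instrument = make_test_instrument(),
                    model = "grsm", dna_rate = 0, ...) {
  tr <- sim_truth(instrument, dna_rate = dna_rate, seed = seed, ...)
  r <- simulate_responses(instrument, n, tr)
  list(truth = tr, responses = r,
       fit = rasch_fit(r, instrument, model = model))
}

# Independent brute-force evaluation of the adjacent-category formula,
# written without reference to the package internals: accumulate the
# unnormalized terms exp(k*(theta-delta) - sum(tau[1:k])) directly.
oracle_probs <- function(theta, delta, tau) {
  terms <- numeric(length(tau) + 1)
  for (k in 0:length(tau)) {
    acc <- k * (theta - delta)
    if (k >= 1) for (j in 1:k) acc <- acc - tau[j]
    terms[k + 1] <- exp(acc)
  }
  terms / sum(terms)
}
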