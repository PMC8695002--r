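# Independent oracles used across tests. Everything here is pure R and
# deliberately avoids the package's fitting code paths.

# log-likelihood of the cumulative logit model, straight from the definition
oracle_loglik <- function(y, x, gamma, beta) {
  K <- length(gamma) + 1L
  eta <- if (length(beta)) as.numeric(as.matrix(x) %*% beta) else
    rep(0, length(y))
  sum(vapply(seq_along(y), function(i) {
    k <- y[i]
    A <- if (k < K) plogis(gamma[k] + eta[i]) else 1
    B <- if (k > 1) plogis(gamma[k - 1] + eta[i]) else 0
    log(max(A - B, 1e-300))
  }, numeric(1)))
}

# elastic net objective of the penalized fit, on a given covariate scale
oracle_objective <- function(par, y, x, K, lambda, w) {
  gamma <- par[seq_len(K - 1)]
  beta <- par[-seq_len(K - 1)]
  if (is.unsorted(gamma, strictly = TRUE)) return(1e10)
  -oracle_loglik(y, x, gamma, beta) / length(y) +
    lambda * (w * sum(abs(beta)) + 0.5 * (1 - w) * sum(beta^2))
}

# generic-purpose minimizer of the penalized objective (brute force oracle)
oracle_minimize <- function(y, x, lambda, w, start) {
  K <- length(unique(y))
  optim(start, oracle_objective, y = y, x = x, K = K, lambda = lambda, w = w,
        method = "Nelder-Mead",
        control = list(maxit = 50000, reltol = 1e-13))
}

# relabel outcomes onto 1..K over the observed categories (as the fitters do)
collapse_y <- function(y) match(y, sort(unique(y)))

# small simulated datasets for fitting tests
make_dataset <- function(seed, n = 100, n_items = 5, dif = 0) {
  bank <- sample_item_bank(n_items, 5, seed = seed)
  focal <- if (dif > 0) apply_uniform_dif(bank, 1, dif) else bank
  simulate_responses(bank, focal, ceiling(n / 2), floor(n / 2),
                     seed = seed + 1000L)
}

# design matrices for the studied item
make_design <- function(ds, item = 1) {
  y <- ds$responses[, item]
  sc <- matching_score(ds$responses, item)
  list(y = y,
       x1 = cbind(score = sc),
       x2 = cbind(score = sc, group = as.numeric(ds$group)))
}

# spec tolerance convention for Monte Carlo acceptance comparisons:
# 3 * sqrt(p(1-p)/n) + 0.01, evaluated at the reference proportion
mc_tolerance <- function(p_ref, n) 3 * sqrt(p_ref * (1 - p_ref) / n) + 0.01
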