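test_that("penalty term follows the elastic net mixing formula", {
  expect_equal(penalty_term(c(2, -1), lambda = 0.1, w = 0.5), 0.275)
  expect_equal(penalty_term(c(5, -3), lambda = 0, w = 0.7), 0)
  expect_equal(penalty_term(c(1, 1), lambda = 1, w = 1), 2)    # pure LASSO
  expect_equal(penalty_term(c(2, 0), lambda = 1, w = 0), 2)    # pure ridge
})

test_that("BIC arithmetic is exact", {
  expect_equal(bic_olr(-100, 100, 5), 200 + 5 * log(100))
  expect_equal(bic_olr(-42.5, 10, 0), 85)
  b <- bic_olr(-100, 200, 0:6)
  expect_true(all(diff(b) > 0))  # strictly increasing in the nonzero count
})

test_that("penalized fit at vanishing lambda recovers the ML estimates", {
  for (seed in c(2, 7, 19)) {
    ds <- make_dataset(seed)
    d <- make_design(ds, 1)
    ml <- fit_olr_ml(d$y, d$x2)
    for (w in c(0, 0.5, 1)) {
      pf <- fit_penalized(d$y, d$x2, lambda = 1e-8, w = w)
      expect_true(pf$converged)
      expect_equal(pf$intercepts, ml$intercepts, tolerance = 1e-5)
      expect_equal(unname(pf$slopes), unname(ml$slopes), tolerance = 1e-5)
    }
  }
})

test_that("at lambda_max all slopes are zero and intercepts are the null fit", {
  ds <- make_dataset(4)
  d <- make_design(ds, 1)
  lam <- lambda_sequence(d$y, d$x2, w = 1)
  pf <- fit_penalized(d$y, d$x2, lambda = lam[1], w = 1)
  expect_equal(unname(pf$slopes_std), c(0, 0))
  K <- pf$n_categories
  counts <- as.numeric(table(collapse_y(d$y)))
  expect_equal(pf$intercepts, qlogis(cumsum(counts)[-K] / length(d$y)),
               tolerance = 1e-6)
  expect_equal(pf$n_nonzero, K - 1L)
})

test_that("lambda sequences are geometric and scale-invariant", {
  ds <- make_dataset(8)
  d <- make_design(ds, 1)
  lam <- lambda_sequence(d$y, d$x2, w = 0.5, n_lambda = 20)
  expect_length(lam, 20)
  expect_true(all(diff(lam) < 0))
  expect_lt(sd(diff(log(lam))), 1e-10)
  expect_equal(lam[20] / lam[1], 0.01, tolerance = 1e-10)

  # standardization makes the path invariant to covariate rescaling
  lam2 <- lambda_sequence(d$y, d$x2 %*% diag(c(2, 0.5)), w = 0.5)
  expect_equal(lam, lam2, tolerance = 1e-10)

  # ridge floor: lambda_max uses max(w, 0.01)
  lam_r <- lambda_sequence(d$y, d$x2, w = 0)
  lam_l <- lambda_sequence(d$y, d$x2, w = 1)
  expect_equal(lam_r[1], lam_l[1] / 0.01, tolerance = 1e-10)
})

test_that("coordinate descent matches a brute-force minimizer of the objective", {
  set.seed(77)
  for (i in 1:10) {
    ds <- make_dataset(100 + i, n = 60)
    d <- make_design(ds, 1)
    w <- c(0, 0.5, 1)[(i %% 3) + 1]
    lam <- 0.05 * (1 + (i %% 4))
    pf <- fit_penalized(d$y, d$x2, lambda = lam, w = w, standardize = FALSE)
    K <- pf$n_categories
    start <- c(pf$intercepts + rnorm(K - 1, 0, 0.2), rep(0, 2))
    start[1:(K - 1)] <- sort(start[1:(K - 1)])
    o <- oracle_minimize(collapse_y(d$y), d$x2, lam, w, start)
    expect_lte(pf$objective, o$value + 1e-4)
    expect_equal(pf$objective, min(pf$objective, o$value), tolerance = 1e-4)
  }
})

test_that("objective equals -(1/N) loglik plus penalty at the solution", {
  ds <- make_dataset(23)
  d <- make_design(ds, 1)
  pf <- fit_penalized(d$y, d$x2, lambda = 0.08, w = 0.4, standardize = FALSE)
  expect_equal(pf$objective,
               -pf$loglik_unpenalized / pf$n_obs +
                 penalty_term(unname(pf$slopes), 0.08, 0.4),
               tolerance = 1e-10)
})

test_that("ridge shrinks without zeroing while LASSO produces exact zeros", {
  ds <- make_dataset(15)
  d <- make_design(ds, 1)
  ridge <- fit_penalized(d$y, d$x2, lambda = 5, w = 0)
  expect_true(all(abs(ridge$slopes_std) > 0))
  expect_true(all(abs(ridge$slopes_std) < 0.2))
  lam <- lambda_sequence(d$y, d$x2, w = 1)
  lasso <- fit_penalized(d$y, d$x2, lambda = lam[5], w = 1)
  expect_true(any(lasso$slopes_std == 0))
})

test_that("nonzero count is non-increasing along the LASSO path", {
  violations <- 0
  for (seed in c(3, 14, 31)) {
    ds <- make_dataset(seed, dif = 0.8)
    d <- make_design(ds, 1)
    path <- fit_path(d$y, d$x2, w = 1)
    n_slopes <- path$n_nonzero - (length(unique(d$y)) - 1L)
    violations <- violations + sum(diff(n_slopes) < 0)
    expect_true(all(path$converged))
    expect_lte(sum(diff(n_slopes) < 0), 1)  # single-index discreteness slack
  }
  expect_lte(violations, 2)
})

test_that("BIC selection drops spurious slopes and keeps strong signals", {
  # null outcome: no association with the covariate
  set.seed(5)
  y <- sample(1:4, 150, replace = TRUE)
  x <- cbind(noise = rnorm(150))
  p_null <- fit_path(y, x, w = 1)
  expect_equal(unname(p_null$selected_fit$slopes_std), 0)

  # strong signal: slope 2 at N = 500
  set.seed(6)
  z <- rnorm(500)
  lp <- 2 * z
  u <- runif(500)
  cuts <- c(-1.5, 0, 1.5)
  y2 <- 1L + rowSums(outer(qlogis(u) + lp, cuts, ">"))
  p_sig <- fit_path(as.integer(y2), cbind(signal = z), w = 1)
  expect_gt(abs(p_sig$selected_fit$slopes_std), 0.5)

  expect_equal(p_null$selected_index, which.min(p_null$bic))
})

test_that("a single-lambda path selects that lambda", {
  ds <- make_dataset(10)
  d <- make_design(ds, 1)
  p <- fit_path(d$y, d$x2, w = 0.5, lambdas = 0.1)
  expect_equal(p$selected_index, 1L)
  expect_equal(p$selected_fit$lambda, 0.1)
})

test_that("path reports serialize as TSV", {
  ds <- make_dataset(11)
  d <- make_design(ds, 1)
  p <- fit_path(d$y, d$x2, w = 0.5)
  f <- tempfile(fileext = ".tsv")
  write_path_tsv(p, f)
  tab <- read.delim(f)
  expect_equal(names(tab), c("lambda", "bic", "loglik", "n_nonzero", "selected"))
  expect_equal(nrow(tab), 20)
  expect_equal(sum(tab$selected), 1)
  unlink(f)
})
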