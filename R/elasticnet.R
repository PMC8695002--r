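#' Elastic net penalty term
#'
#' `lambda * (w * sum(|beta_j|) + (1 - w)/2 * sum(beta_j^2))`, mixing the
#' LASSO (`w = 1`) and ridge (`w = 0`) penalties. Intercepts are never
#' penalized and are excluded by construction: `beta` contains slopes only.
#'
#' @param beta Slope vector.
#' @param lambda Regularization strength, `lambda >= 0`.
#' @param w Mixing weight in `[0, 1]`.
#' @return Penalty value.
#' @examples
#' penalty_term(c(2, -1), lambda = 0.1, w = 0.5)  # 0.275
#' @export
penalty_term <- function(beta, lambda, w) {
  stopifnot(lambda >= 0, w >= 0, w <= 1)
  lambda * (w * sum(abs(beta)) + 0.5 * (1 - w) * sum(beta^2))
}

#' BIC for a penalized cumulative logit fit
#'
#' `BIC = -2 logL_lambda + log(N) * N_nonzero`, where `logL_lambda` is the
#' unpenalized log-likelihood evaluated at the penalized estimates and
#' `N_nonzero` counts all nonzero parameters including the intercepts.
#'
#' @param loglik Unpenalized log-likelihood at the penalized solution.
#' @param n_obs Total sample size `N`.
#' @param n_nonzero Number of nonzero parameters, intercepts included.
#' @return BIC value (natural log).
#' @examples
#' bic_olr(-100, 100, 5)   # 200 + 5 * log(100)
#' @export
bic_olr <- function(loglik, n_obs, n_nonzero) {
  stopifnot(n_obs >= 1)
  -2 * loglik + log(n_obs) * n_nonzero
}

# standardize covariate columns to zero mean / unit sample sd for penalized
# fitting; constant columns get scale 1 (their slope stays 0)
standardize_x <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  list(x = xs, center = center, scale = scale)
}

# map standardized-scale (gamma, beta) back to the original covariate scale
unstandardize <- function(gamma, beta, center, scale) {
  b <- beta / scale
  list(gamma = gamma - sum(beta * center / scale), beta = b)
}

#' Automatically generated lambda sequence for the penalized fit
#'
#' The head of the sequence is `lambda_max`, the smallest strength at which
#' every penalized slope is zero; by the subgradient (KKT) condition at the
#' intercept-only fit this is `max_j |score_j| / max(w, 0.01)`, where
#' `score_j` is the gradient of `-(1/N) logL` with respect to slope `j`
#' (on the standardized covariate scale). Pure ridge has no finite
#' all-zero strength, hence the floor on `w` in this formula only. The
#' remaining values are geometrically spaced down to
#' `lambda_max * min_ratio`.
#'
#' @param y Integer outcome vector.
#' @param x Covariate matrix.
#' @param w Elastic net mixing weight.
#' @param n_lambda Sequence length (default 20).
#' @param min_ratio Ratio of smallest to largest lambda (default 0.01).
#' @param standardize Standardize covariates before computing the score
#'   (default TRUE, matching [fit_path()]).
#' @param n_categories Number of nominal categories; defaults to `max(y)`.
#' @return Strictly decreasing numeric vector of length `n_lambda`.
#' @export
lambda_sequence <- function(y, x, w, n_lambda = 20L, min_ratio = 0.01,
                            standardize = TRUE, n_categories = NULL) {
  stopifnot(n_lambda >= 2L, min_ratio > 0, min_ratio < 1)
  d <- olr_design(y, x, n_categories, warn_collapse = FALSE)
  xs <- if (standardize) standardize_x(d$x)$x else d$x
  score <- .olr_null_score_cpp(d$y, xs, d$n_cat)
  lambda_max <- max(abs(score)) / max(w, 0.01)
  if (!is.finite(lambda_max) || lambda_max <= 0) lambda_max <- 1e-3
  exp(seq(log(lambda_max), log(lambda_max * min_ratio),
          length.out = n_lambda))
}

#' Elastic net penalized fit of the cumulative logit model
#'
#' Minimizes `-(1/N) logL + lambda (w sum|beta| + (1-w)/2 sum beta^2)` over
#' intercepts and slopes by cyclic coordinate descent: exact one-dimensional
#' Newton steps on the (unpenalized) intercepts and soft-thresholded proximal
#' Newton steps on the slopes, each safeguarded by a step-halving line search
#' so the objective decreases monotonically. At `lambda = 0` the solution is
#' the ML fit; for `w > 0` exact zeros occur in the slopes.
#'
#' @param y Integer outcome vector, values in `1..n_categories`.
#' @param x Covariate matrix (persons x p).
#' @param lambda Regularization strength `>= 0`.
#' @param w Elastic net mixing weight in `[0, 1]`.
#' @param standardize Scale covariates to unit sample sd (and center) before
#'   fitting; coefficients are returned on the original scale. Default TRUE.
#' @param tol Convergence tolerance on the max coordinate change per cycle.
#' @param max_iter Maximum coordinate descent cycles.
#' @param n_categories Number of nominal categories; defaults to `max(y)`.
#' @return An object of class `penalized_fit`: `intercepts`, `slopes`
#'   (original scale), `slopes_std` (standardized scale, used for the nonzero
#'   count), `loglik_unpenalized`, `objective`, `n_nonzero` (intercepts plus
#'   slopes with `|beta| >` 1e-8 on the standardized scale), `lambda`, `w`,
#'   `converged`, `category_map`.
#' @export
fit_penalized <- function(y, x, lambda, w, standardize = TRUE,
                          tol = 1e-7, max_iter = 200L, n_categories = NULL) {
  stopifnot(lambda >= 0, w >= 0, w <= 1)
  path <- fit_path_internal(y, x, lambdas = lambda, w = w,
                            standardize = standardize, tol = tol,
                            max_iter = max_iter, n_categories = n_categories)
  fit <- path_entry(path, 1L)
  if (!fit$converged)
    warning("coordinate descent did not converge within max_iter cycles")
  fit
}

# shared machinery: fit a whole descending lambda sequence with warm starts
fit_path_internal <- function(y, x, lambdas, w, standardize, tol, max_iter,
                              n_categories = NULL) {
  d <- olr_design(y, x, n_categories, warn_collapse = FALSE)
  std <- if (standardize) standardize_x(d$x)
         else list(x = d$x, center = rep(0, ncol(d$x)),
                   scale = rep(1, ncol(d$x)))
  res <- .olr_cd_path_cpp(d$y, std$x, d$n_cat, as.numeric(lambdas), w,
                          tol, as.integer(max_iter))
  list(cpp = res, lambdas = as.numeric(lambdas), w = w, design = d,
       std = std, n_obs = length(d$y))
}

# materialize one lambda entry of an internal path as a penalized_fit
path_entry <- function(path, i) {
  res <- path$cpp
  gamma_std <- res$gamma[, i]
  beta_std <- res$beta[, i]
  orig <- unstandardize(gamma_std, beta_std, path$std$center, path$std$scale)
  slopes <- orig$beta
  names(slopes) <- colnames(path$design$x)
  n_nonzero <- length(gamma_std) + sum(abs(beta_std) > 1e-8)
  structure(
    list(intercepts = orig$gamma,
         slopes = slopes,
         slopes_std = beta_std,
         loglik_unpenalized = res$loglik[i],
         objective = res$objective[i],
         lambda = path$lambdas[i],
         w = path$w,
         n_nonzero = n_nonzero,
         converged = res$converged[i] == 1L,
         n_iter = res$n_iter[i],
         category_map = path$design$category_map,
         n_obs = path$n_obs,
         n_categories = path$design$n_cat),
    class = "penalized_fit")
}

#' @export
print.penalized_fit <- function(x, ...) {
  cat(sprintf("Elastic net penalized cumulative logit fit (lambda = %.4g, w = %.3g)\n",
              x$lambda, x$w))
  cat("  intercepts:", paste(sprintf("%.4f", x$intercepts), collapse = " "), "\n")
  if (length(x$slopes))
    cat("  slopes:    ",
        paste(sprintf("%s=%.4f", names(x$slopes), x$slopes), collapse = " "), "\n")
  cat(sprintf("  logLik (unpenalized): %.4f  objective: %.6f  nonzero: %d\n",
              x$loglik_unpenalized, x$objective, x$n_nonzero))
  invisible(x)
}

#' Fit a lambda path and select the BIC-minimizing strength
#'
#' Fits every value of an automatically generated descending lambda sequence
#' (see [lambda_sequence()]) by coordinate descent with warm starts from the
#' previous strength, computes the BIC of every converged fit
#' (`-2 logL + log(N) N_nonzero`, intercepts counted), and selects the
#' minimizer, breaking ties toward the larger (more regularized) strength.
#'
#' @inheritParams fit_penalized
#' @param n_lambda Path length (default 20).
#' @param min_ratio Smallest-to-largest lambda ratio (default 0.01).
#' @param lambdas Optional explicit descending lambda vector overriding the
#'   automatic sequence.
#' @return An object of class `olr_path`: `lambdas`, `bic`, `loglik`,
#'   `n_nonzero`, `converged` (per lambda), `selected_index`, and
#'   `selected_fit` (a `penalized_fit`).
#' @examples
#' set.seed(1)
#' y <- sample(1:4, 120, TRUE)
#' x <- cbind(score = rnorm(120))
#' fit_path(y, x, w = 1)
#' @export
fit_path <- function(y, x, w, n_lambda = 20L, min_ratio = 0.01,
                     standardize = TRUE, tol = 1e-7, max_iter = 200L,
                     n_categories = NULL, lambdas = NULL) {
  if (is.null(lambdas))
    lambdas <- lambda_sequence(y, x, w, n_lambda = n_lambda,
                               min_ratio = min_ratio,
                               standardize = standardize,
                               n_categories = n_categories)
  if (length(lambdas) >= 2L && any(diff(lambdas) >= 0))
    stop("lambdas must be strictly decreasing")
  path <- fit_path_internal(y, x, lambdas, w, standardize, tol, max_iter,
                            n_categories = n_categories)
  res <- path$cpp
  n_int <- path$design$n_cat - 1L
  n_nonzero <- n_int + colSums(abs(res$beta) > 1e-8)
  if (ncol(res$beta) == 0L || nrow(res$beta) == 0L)
    n_nonzero <- rep(n_int, length(lambdas))
  bic <- bic_olr(res$loglik, path$n_obs, n_nonzero)
  converged <- res$converged == 1L
  bic_sel <- ifelse(converged, bic, Inf)
  if (all(!is.finite(bic_sel)))
    stop("path failure: no lambda converged")
  selected <- which.min(bic_sel)  # first minimum = largest lambda on ties
  structure(
    list(lambdas = path$lambdas,
         bic = bic,
         loglik = res$loglik,
         objective = res$objective,
         n_nonzero = as.integer(n_nonzero),
         converged = converged,
         selected_index = selected,
         selected_fit = path_entry(path, selected),
         w = w,
         n_obs = path$n_obs),
    class = "olr_path")
}

#' @export
print.olr_path <- function(x, ...) {
  cat(sprintf("Elastic net cumulative logit path (w = %.3g, %d lambdas, N = %d)\n",
              x$w, length(x$lambdas), x$n_obs))
  tab <- data.frame(lambda = signif(x$lambdas, 4),
                    bic = round(x$bic, 3),
                    loglik = round(x$loglik, 3),
                    n_nonzero = x$n_nonzero,
                    selected = as.integer(seq_along(x$lambdas) == x$selected_index))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Serialize a lambda path report as TSV
#'
#' Columns: lambda, bic, loglik, n_nonzero, selected (0/1).
#'
#' @param path An `olr_path`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_path_tsv <- function(path, file) {
  stopifnot(inherits(path, "olr_path"))
  tab <- data.frame(lambda = path$lambdas, bic = path$bic,
                    loglik = path$loglik, n_nonzero = path$n_nonzero,
                    selected = as.integer(seq_along(path$lambdas) ==
                                            path$selected_index))
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
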