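#' Maximum likelihood fit of the proportional-odds cumulative logit model
#'
#' Fits `logit P(Y <= j | x) = gamma_0j + x' beta` by Newton-Raphson with
#' step halving, starting from intercepts at the logits of the empirical
#' cumulative proportions and zero slopes (the log-likelihood is globally
#' concave for the logistic link, so this is reliable). Monotone intercepts
#' are maintained throughout the iteration.
#'
#' Categories that are not observed in `y` are collapsed into the adjacent
#' higher observed category (the model is otherwise unidentifiable); the
#' mapping is recorded in `category_map` and a warning is raised.
#'
#' @param y Integer outcome vector, values in `1..n_categories`.
#' @param x Covariate matrix (persons x p) or `NULL` for an intercept-only
#'   fit. Columns must be linearly independent.
#' @param n_categories Number of nominal categories; defaults to `max(y)`.
#' @param tol Convergence tolerance on the max-norm of the score (default
#'   1e-8); iteration also stops when the relative log-likelihood change
#'   falls below 1e-13.
#' @param max_iter Maximum Newton iterations (default 100).
#' @return An object of class `olr_fit` with elements `intercepts` (strictly
#'   increasing `gamma_0j`), `slopes`, `loglik`, `converged`, `n_iter`,
#'   `separation` (TRUE when any slope exceeds a divergence bound, a symptom
#'   of quasi-complete separation), `category_map` and `n_obs`.
#' @examples
#' y <- rep(1:4, each = 25)
#' fit_olr_ml(y)$intercepts   # logits of 0.25, 0.50, 0.75
#' @export
fit_olr_ml <- function(y, x = NULL, n_categories = NULL,
                       tol = 1e-8, max_iter = 100L) {
  d <- olr_design(y, x, n_categories)
  res <- .olr_newton_cpp(d$y, d$x, d$n_cat, tol, as.integer(max_iter))
  slopes <- as.numeric(res$beta)
  names(slopes) <- colnames(d$x)
  separation <- length(slopes) > 0 && any(abs(slopes) > 20)
  if (separation)
    warning("possible separation: a slope estimate exceeds the divergence bound")
  if (!res$converged)
    warning(sprintf("Newton iteration did not converge in %d iterations (max |score| = %.3g)",
                    max_iter, res$max_grad))
  structure(
    list(intercepts = as.numeric(res$gamma),
         slopes = slopes,
         loglik = res$loglik,
         converged = isTRUE(res$converged),
         n_iter = res$n_iter,
         max_grad = res$max_grad,
         separation = separation,
         category_map = d$category_map,
         n_obs = length(d$y),
         n_categories = d$n_cat),
    class = "olr_fit")
}

#' @export
print.olr_fit <- function(x, ...) {
  cat("Proportional-odds cumulative logit fit (ML)\n")
  cat(sprintf("  observations: %d, observed categories: %d\n",
              x$n_obs, x$n_categories))
  cat("  intercepts:", paste(sprintf("%.4f", x$intercepts), collapse = " "), "\n")
  if (length(x$slopes))
    cat("  slopes:    ",
        paste(sprintf("%s=%.4f", names(x$slopes), x$slopes), collapse = " "), "\n")
  cat(sprintf("  logLik: %.4f  converged: %s (%d iterations)\n",
              x$loglik, x$converged, x$n_iter))
  invisible(x)
}

#' @export
logLik.olr_fit <- function(object, ...) {
  structure(object$loglik,
            df = length(object$intercepts) + length(object$slopes),
            class = "logLik")
}

# validate and pack an ordinal design; collapse unobserved categories
olr_design <- function(y, x, n_categories = NULL, warn_collapse = TRUE) {
  y <- as.integer(y)
  if (anyNA(y)) stop("outcome must not contain missing values")
  if (is.null(n_categories)) n_categories <- max(y)
  if (any(y < 1L) || any(y > n_categories))
    stop("outcome values must lie in 1..n_categories")
  observed <- sort(unique(y))
  if (length(observed) < 2L)
    stop("degenerate outcome: fewer than 2 observed categories")
  category_map <- match(y, observed)   # collapse = relabel onto observed
  if (length(observed) < n_categories && warn_collapse)
    warning(sprintf("collapsed %d unobserved categor%s",
                    n_categories - length(observed),
                    if (n_categories - length(observed) == 1L) "y" else "ies"))
  map <- seq_along(observed)
  names(map) <- observed
  if (is.null(x)) {
    x <- matrix(numeric(0), nrow = length(y), ncol = 0L)
  } else {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    if (nrow(x) != length(y))
      stop("covariate rows must match outcome length")
    if (anyNA(x)) stop("covariates must not contain missing values")
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  list(y = category_map, x = x, n_cat = length(observed), category_map = map)
}

#' Evaluate the cumulative logit log-likelihood of a fit on a design
#'
#' Returns `sum_i log P(Y = y_i | x_i)` under the parameters of `fit`. When
#' evaluated on the fit's own training data this reproduces `fit$loglik`.
#'
#' @param fit An `olr_fit` (or any list with `intercepts` and `slopes`).
#' @param y Integer outcome vector on the fit's collapsed `1..K` scale.
#' @param x Covariate matrix matching `fit$slopes` (or `NULL`).
#' @return Log-likelihood value (<= 0).
#' @export
loglik_olr <- function(fit, y, x = NULL) {
  K <- length(fit$intercepts) + 1L
  y <- as.integer(y)
  if (any(y < 1L) || any(y > K))
    stop("outcome contains categories outside the fit's category map")
  if (is.null(x)) x <- matrix(numeric(0), nrow = length(y), ncol = 0L)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != length(fit$slopes))
    stop("covariate columns must match the fit's slopes")
  .olr_loglik_cpp(y, x, as.numeric(fit$intercepts), as.numeric(fit$slopes))
}

#' Likelihood-ratio test between two nested fits
#'
#' Computes `statistic = 2 (loglik_full - loglik_reduced)` (clipped at zero)
#' and its upper-tail chi-square p-value. For genuinely nested ML fits the
#' statistic cannot be negative beyond numerical slack; a violation beyond
#' `1e-6` signals a fitting failure and raises an error unless
#' `strict = FALSE` (used for penalized fits, where shrinkage breaks the
#' nesting guarantee and the statistic is simply clipped).
#'
#' @param loglik_reduced,loglik_full Log-likelihoods of the reduced and full
#'   model.
#' @param df Degrees of freedom of the test (default 1).
#' @param strict Enforce the ML nesting inequality (default TRUE).
#' @return A list with `statistic` and `p_value`.
#' @examples
#' lr_test(-100, -98.08, df = 1)   # statistic 3.84, p ~ 0.05
#' @export
lr_test <- function(loglik_reduced, loglik_full, df = 1L, strict = TRUE) {
  stat <- 2 * (loglik_full - loglik_reduced)
  if (strict && stat < -1e-6)
    stop(sprintf("nesting violation: full model log-likelihood lower by %.3g (fitting failure?)",
                 -stat / 2))
  stat <- max(stat, 0)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}
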