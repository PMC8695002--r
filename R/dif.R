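#' Configuration for DIF testing
#'
#' @param method `"ml"` for the nonregularized (maximum likelihood) tests or
#'   `"elastic_net"` for the penalized variant.
#' @param w Elastic net mixing weight in `[0, 1]` (ignored for `"ml"`).
#' @param alpha Significance level for flagging (default 0.05).
#' @param score_type Matching criterion: `"total"` (row sum over all items,
#'   the default) or `"rest"` (row sum excluding the studied item).
#' @param lr_loglik Log-likelihood variant entering the penalized
#'   likelihood-ratio comparison: `"unpenalized_at_estimates"` (default; the
#'   plain log-likelihood evaluated at the BIC-selected penalized estimates,
#'   which keeps the statistic on the chi-square scale) or
#'   `"penalized_objective"` (`-2N` times the difference of the penalized
#'   objectives).
#' @param n_lambda,min_ratio,standardize,tol,max_iter Settings forwarded to
#'   [fit_path()].
#' @return A list of class `dif_config`.
#' @export
dif_config <- function(method = c("ml", "elastic_net"), w = 0.5,
                       alpha = 0.05, score_type = c("total", "rest"),
                       lr_loglik = c("unpenalized_at_estimates",
                                     "penalized_objective"),
                       n_lambda = 20L, min_ratio = 0.01,
                       standardize = TRUE, tol = 1e-7, max_iter = 200L) {
  method <- match.arg(method)
  score_type <- match.arg(score_type)
  lr_loglik <- match.arg(lr_loglik)
  stopifnot(alpha > 0, alpha < 1, w >= 0, w <= 1)
  structure(list(method = method, w = w, alpha = alpha,
                 score_type = score_type, lr_loglik = lr_loglik,
                 n_lambda = as.integer(n_lambda), min_ratio = min_ratio,
                 standardize = standardize, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "dif_config")
}

#' Matching score for DIF analysis
#'
#' The observed stand-in for ability: by default the total test score (row
#' sum over all items, including the studied one); `"rest"` excludes the
#' studied item.
#'
#' @param responses Persons x items integer matrix.
#' @param item_index 1-based index of the studied item.
#' @param score_type `"total"` or `"rest"`.
#' @return Numeric per-person score vector.
#' @export
matching_score <- function(responses, item_index,
                           score_type = c("total", "rest")) {
  score_type <- match.arg(score_type)
  s <- rowSums(responses)
  if (score_type == "rest") s <- s - responses[, item_index]
  s
}

# three nested designs for one studied item
nested_designs <- function(score, group) {
  g <- as.numeric(group)
  list(m1 = cbind(score = score),
       m2 = cbind(score = score, group = g),
       m3 = cbind(score = score, group = g, score_x_group = score * g))
}

#' Test one item for uniform and nonuniform DIF
#'
#' Builds the three nested proportional-odds models for the item's responses
#' (model 1: matching score; model 2: score + group; model 3: score + group +
#' score x group interaction). The uniform-DIF statistic compares models 1
#' and 2, the nonuniform-DIF statistic models 2 and 3; both are referred to a
#' chi-square distribution with one degree of freedom.
#'
#' With `method = "ml"` the models are fitted by maximum likelihood and the
#' comparisons are ordinary likelihood-ratio tests. With
#' `method = "elastic_net"` every model is fitted over its own BIC-selected
#' lambda path ([fit_path()]) at the configured mixing weight `w`, and the
#' `-2 delta` comparison uses the log-likelihood variant named by
#' `config$lr_loglik` (clipped at zero: shrinkage breaks the ML nesting
#' guarantee).
#'
#' @param dataset A [response_dataset()].
#' @param item_index 1-based item index.
#' @param config A [dif_config()].
#' @return A one-row data.frame: `item`, `uniform_stat`, `uniform_p`,
#'   `nonuniform_stat`, `nonuniform_p`, `flagged_uniform`,
#'   `flagged_nonuniform`, `converged`, `degenerate`,
#'   `lambda_model1`..`lambda_model3` (NA for ML), `w`, `method`.
#' @export
test_item <- function(dataset, item_index, config = dif_config("ml")) {
  stopifnot(inherits(dataset, "response_dataset"),
            inherits(config, "dif_config"))
  out <- data.frame(item = as.integer(item_index),
                    uniform_stat = NA_real_, uniform_p = NA_real_,
                    nonuniform_stat = NA_real_, nonuniform_p = NA_real_,
                    flagged_uniform = NA, flagged_nonuniform = NA,
                    converged = FALSE, degenerate = FALSE,
                    lambda_model1 = NA_real_, lambda_model2 = NA_real_,
                    lambda_model3 = NA_real_,
                    w = if (config$method == "elastic_net") config$w else NA_real_,
                    method = config$method,
                    stringsAsFactors = FALSE)
  y <- dataset$responses[, item_index]
  if (length(unique(y)) < 2L) {
    out$degenerate <- TRUE
    return(out)
  }
  score <- matching_score(dataset$responses, item_index, config$score_type)
  designs <- nested_designs(score, dataset$group)
  J <- dataset$n_categories
  if (config$method == "ml") {
    fits <- lapply(designs, function(xm)
      suppressWarnings(fit_olr_ml(y, xm, n_categories = J)))
    out$converged <- all(vapply(fits, `[[`, TRUE, "converged"))
    uni <- lr_test(fits$m1$loglik, fits$m2$loglik, df = 1L, strict = FALSE)
    non <- lr_test(fits$m2$loglik, fits$m3$loglik, df = 1L, strict = FALSE)
  } else {
    paths <- lapply(designs, function(xm)
      fit_path(y, xm, w = config$w, n_lambda = config$n_lambda,
               min_ratio = config$min_ratio,
               standardize = config$standardize, tol = config$tol,
               max_iter = config$max_iter, n_categories = J))
    out$converged <- all(vapply(paths, function(p)
      p$selected_fit$converged, TRUE))
    out$lambda_model1 <- paths$m1$selected_fit$lambda
    out$lambda_model2 <- paths$m2$selected_fit$lambda
    out$lambda_model3 <- paths$m3$selected_fit$lambda
    ll <- function(p) {
      if (config$lr_loglik == "unpenalized_at_estimates")
        p$selected_fit$loglik_unpenalized
      else -p$n_obs * p$selected_fit$objective
    }
    uni <- lr_test(ll(paths$m1), ll(paths$m2), df = 1L, strict = FALSE)
    non <- lr_test(ll(paths$m2), ll(paths$m3), df = 1L, strict = FALSE)
  }
  out$uniform_stat <- uni$statistic
  out$uniform_p <- uni$p_value
  out$nonuniform_stat <- non$statistic
  out$nonuniform_p <- non$p_value
  out$flagged_uniform <- uni$p_value < config$alpha
  out$flagged_nonuniform <- non$p_value < config$alpha
  out
}

#' Test every item of a scale for DIF
#'
#' Applies [test_item()] to each item in order with a common matching-score
#' convention. Degenerate items (a single observed category) are reported as
#' flagged entries with `degenerate = TRUE` rather than aborting the sweep.
#'
#' @param dataset A [response_dataset()].
#' @param config A [dif_config()].
#' @return A data.frame of class `dif_results`, one row per item, with a
#'   `n_flagged_uniform` attribute counting uniform-DIF flags.
#' @export
analyze_scale <- function(dataset, config = dif_config("ml")) {
  res <- do.call(rbind, lapply(seq_len(ncol(dataset$responses)),
                               function(i) test_item(dataset, i, config)))
  attr(res, "n_flagged_uniform") <- sum(res$flagged_uniform, na.rm = TRUE)
  attr(res, "alpha") <- config$alpha
  class(res) <- c("dif_results", class(res))
  res
}

#' @export
print.dif_results <- function(x, ...) {
  cat(sprintf("Per-item DIF tests (%s%s, alpha = %g): %d of %d items flagged for uniform DIF\n",
              x$method[1],
              if (x$method[1] == "elastic_net")
                sprintf(", w = %g", x$w[1]) else "",
              attr(x, "alpha"), attr(x, "n_flagged_uniform"), nrow(x)))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write per-item DIF results as TSV
#'
#' Machine-readable per-item report. Header comment lines (prefixed `#`)
#' record the generating configuration so the file can be regenerated.
#'
#' @param results A `dif_results` data.frame from [analyze_scale()].
#' @param file Output path.
#' @param meta Optional named character vector written as `# key: value`
#'   header lines (e.g. seed, input file, config hash).
#' @return `file`, invisibly.
#' @export
write_dif_tsv <- function(results, file, meta = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  utils::write.table(as.data.frame(results), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
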