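#' Define a Monte Carlo simulation condition
#'
#' One cell of the power / type-I-error study design: total sample size,
#' reference-to-focal ratio, scale length, number of categories, uniform DIF
#' magnitude on item 1, the grid of elastic net mixing weights to evaluate
#' alongside the ML test, and the replication count.
#'
#' Group sizes follow the ratio with rounding toward the reference group:
#' `N = 100, R = 2` gives 67/33 and `R = 3` gives 75/25.
#'
#' @param n_total Total sample size `N`.
#' @param ratio Reference-to-focal sample size ratio `R = n_ref / n_focal`.
#' @param n_items Scale length `I`.
#' @param n_categories Response categories per item `J` (default 5).
#' @param dif Uniform DIF magnitude added to item 1's focal thresholds
#'   (0 = null condition).
#' @param w_grid Elastic net mixing weights evaluated per replication (may be
#'   empty for an ML-only study). Default: the 11-point grid
#'   0, 0.01, ..., 0.07, 0.1, 0.5, 1.
#' @param n_reps Number of Monte Carlo replications (default 1000).
#' @param alpha Nominal significance level (default 0.05; rejection when
#'   `p < alpha`, strictly).
#' @param score_type,lr_loglik,n_lambda,min_ratio Forwarded to the tests.
#' @param fixed_bank If TRUE, a single item bank (drawn once from the
#'   condition's seed stream) is reused across replications; by default a
#'   fresh bank is drawn every replication, treating item parameters as
#'   random.
#' @return A list of class `sim_condition`.
#' @export
sim_condition <- function(n_total, ratio = 1, n_items = 5L,
                          n_categories = 5L, dif = 0,
                          w_grid = c(0, 0.01, 0.02, 0.03, 0.04, 0.05,
                                     0.06, 0.07, 0.1, 0.5, 1),
                          n_reps = 1000L, alpha = 0.05,
                          score_type = "total",
                          lr_loglik = "unpenalized_at_estimates",
                          n_lambda = 20L, min_ratio = 0.01,
                          fixed_bank = FALSE) {
  n_focal <- as.integer(round(n_total / (ratio + 1)))
  n_ref <- as.integer(n_total) - n_focal
  stopifnot(n_ref >= 1L, n_focal >= 1L, dif >= 0,
            alpha > 0, alpha < 1, n_reps >= 1L)
  structure(list(n_total = as.integer(n_total), ratio = ratio,
                 n_ref = n_ref, n_focal = n_focal,
                 n_items = as.integer(n_items),
                 n_categories = as.integer(n_categories),
                 dif = dif, w_grid = w_grid,
                 n_reps = as.integer(n_reps), alpha = alpha,
                 score_type = score_type, lr_loglik = lr_loglik,
                 n_lambda = as.integer(n_lambda), min_ratio = min_ratio,
                 fixed_bank = isTRUE(fixed_bank)),
            class = "sim_condition")
}

#' @export
print.sim_condition <- function(x, ...) {
  cat(sprintf(
    "Simulation condition: N = %d (%d/%d), I = %d, J = %d, DIF = %g, %d reps\n",
    x$n_total, x$n_ref, x$n_focal, x$n_items, x$n_categories, x$dif,
    x$n_reps))
  cat("  methods: ML",
      if (length(x$w_grid)) paste0("+ elastic net w = {",
                                   paste(x$w_grid, collapse = ", "), "}"),
      "\n")
  invisible(x)
}

# deterministic per-replication seed stream; stays below 2^31
derive_seed <- function(base_seed, cond_index, rep_index, attempt = 0L) {
  v <- (as.double(base_seed) * 69069 + as.double(cond_index) * 1299709 +
          as.double(rep_index) * 15485863 + as.double(attempt) * 32452843)
  as.integer(v %% 2147483629) + 1L
}

# uniform-DIF rejection indicators for every item and method on one dataset;
# returns matrix (1 + |w_grid|) x I, rownames "ml", "w=..."; NA on failure
uniform_rejections <- function(dataset, cond) {
  I <- cond$n_items
  methods <- c("ml", if (length(cond$w_grid)) paste0("w=", cond$w_grid))
  rej <- matrix(NA, length(methods), I, dimnames = list(methods, NULL))
  J <- dataset$n_categories
  for (it in seq_len(I)) {
    y <- dataset$responses[, it]
    if (length(unique(y)) < 2L) return(NULL)       # degenerate item: redraw
    score <- matching_score(dataset$responses, it, cond$score_type)
    x1 <- cbind(score = score)
    x2 <- cbind(score = score, group = as.numeric(dataset$group))
    f1 <- suppressWarnings(fit_olr_ml(y, x1, n_categories = J))
    f2 <- suppressWarnings(fit_olr_ml(y, x2, n_categories = J))
    if (!f1$converged || !f2$converged) return(NULL)
    p_ml <- lr_test(f1$loglik, f2$loglik, strict = FALSE)$p_value
    rej["ml", it] <- p_ml < cond$alpha
    for (w in cond$w_grid) {
      p1 <- fit_path(y, x1, w = w, n_lambda = cond$n_lambda,
                     min_ratio = cond$min_ratio, n_categories = J)
      p2 <- fit_path(y, x2, w = w, n_lambda = cond$n_lambda,
                     min_ratio = cond$min_ratio, n_categories = J)
      if (!p1$selected_fit$converged || !p2$selected_fit$converged)
        return(NULL)
      ll <- function(p) {
        if (cond$lr_loglik == "unpenalized_at_estimates")
          p$selected_fit$loglik_unpenalized
        else -p$n_obs * p$selected_fit$objective
      }
      pv <- lr_test(ll(p1), ll(p2), strict = FALSE)$p_value
      rej[paste0("w=", w), it] <- pv < cond$alpha
    }
  }
  rej
}

#' Run one Monte Carlo replication
#'
#' Draws a GRM item bank (fresh per replication unless `fixed_bank`), shifts
#' item 1's focal thresholds by the condition's DIF magnitude, simulates a
#' response dataset, and computes uniform-DIF rejection indicators at the
#' condition's alpha for the ML test and every elastic net weight on the
#' same dataset (paired design). Replications in which any required fit
#' fails to converge, or an item is degenerate, are redrawn with a derived
#' seed (up to 10 attempts).
#'
#' @param cond A [sim_condition()].
#' @param rep_index Replication number (enters the seed stream).
#' @param base_seed Integer base seed of the study.
#' @param cond_index Index of the condition within a grid (enters the seed
#'   stream; default 1).
#' @param bank Optional fixed [item_bank()] overriding per-replication
#'   redraws.
#' @return List with `rejections` (methods x items 0/1 matrix) and
#'   `n_attempts`.
#' @export
run_replication <- function(cond, rep_index, base_seed, cond_index = 1L,
                            bank = NULL) {
  for (attempt in 0:9) {
    seed <- derive_seed(base_seed, cond_index, rep_index, attempt)
    rep_bank <- if (is.null(bank))
      sample_item_bank(cond$n_items, cond$n_categories, seed = seed)
    else bank
    focal <- if (cond$dif > 0)
      apply_uniform_dif(rep_bank, 1L, cond$dif) else rep_bank
    dataset <- simulate_responses(rep_bank, focal, cond$n_ref, cond$n_focal,
                                  seed = seed + 1L)
    rej <- tryCatch(uniform_rejections(dataset, cond),
                    error = function(e) NULL)
    if (!is.null(rej))
      return(list(rejections = rej, n_attempts = attempt + 1L))
  }
  stop(sprintf("replication %d: no convergent dataset in 10 attempts",
               rep_index))
}

#' Estimate power and type-I error for one condition
#'
#' Aggregates [run_replication()] over the condition's replication count.
#' Power is the rejection proportion on item 1 (the DIF item); type-I error
#' is the rejection proportion pooled over all non-DIF items and
#' replications. Under a null condition (`dif = 0`) item 1 carries no DIF,
#' so its rejections are pooled into the type-I estimate and power is NA.
#'
#' @param cond A [sim_condition()].
#' @param base_seed Integer base seed.
#' @param cond_index Condition index within a grid (default 1).
#' @param progress Print a progress line every 100 replications.
#' @return A data.frame of class `sim_summary`, one row per (method, metric),
#'   with columns `method`, `metric` (`"power"`/`"type1"`), `estimate`,
#'   `mc_se` (`sqrt(p(1-p)/n)`), `n_effective`, `n_discarded`, plus the
#'   condition descriptors.
#' @export
run_condition <- function(cond, base_seed = 1L, cond_index = 1L,
                          progress = FALSE) {
  bank <- if (cond$fixed_bank)
    sample_item_bank(cond$n_items, cond$n_categories,
                     seed = derive_seed(base_seed, cond_index, 0L))
  else NULL
  methods <- c("ml", if (length(cond$w_grid)) paste0("w=", cond$w_grid))
  acc <- array(NA_real_, c(cond$n_reps, length(methods), cond$n_items),
               dimnames = list(NULL, methods, NULL))
  discarded <- 0L
  for (r in seq_len(cond$n_reps)) {
    rep <- run_replication(cond, r, base_seed, cond_index, bank = bank)
    discarded <- discarded + rep$n_attempts - 1L
    acc[r, , ] <- rep$rejections
    if (progress && r %% 100L == 0L)
      message(sprintf("  replication %d / %d", r, cond$n_reps))
  }
  dif_items <- if (cond$dif > 0) 1L else integer(0)
  null_items <- setdiff(seq_len(cond$n_items), dif_items)
  rows <- do.call(rbind, lapply(methods, function(m) {
    pow <- if (length(dif_items)) mean(acc[, m, dif_items]) else NA_real_
    n_pow <- cond$n_reps * length(dif_items)
    t1 <- mean(acc[, m, null_items])
    n_t1 <- cond$n_reps * length(null_items)
    data.frame(method = m,
               metric = c("power", "type1"),
               estimate = c(pow, t1),
               mc_se = c(if (length(dif_items))
                 sqrt(pow * (1 - pow) / n_pow) else NA_real_,
                 sqrt(t1 * (1 - t1) / n_t1)),
               n_effective = c(n_pow, n_t1),
               stringsAsFactors = FALSE)
  }))
  rows <- rows[!(rows$metric == "power" & is.na(rows$estimate)), ]
  out <- cbind(data.frame(n_total = cond$n_total, ratio = cond$ratio,
                          n_items = cond$n_items,
                          n_categories = cond$n_categories,
                          dif = cond$dif, n_reps = cond$n_reps,
                          stringsAsFactors = FALSE)[rep(1L, nrow(rows)), ],
               rows, n_discarded = discarded)
  rownames(out) <- NULL
  class(out) <- c("sim_summary", class(out))
  out
}

#' Run a grid of simulation conditions
#'
#' Each condition gets an independent seed substream derived from
#' `base_seed` and its index, so results are reproducible condition by
#' condition and independent of the worker count.
#'
#' @param conditions List of [sim_condition()] objects.
#' @param base_seed Integer base seed.
#' @param workers Number of parallel workers (forked; 1 = serial).
#' @param progress Forwarded to [run_condition()].
#' @return Long-format data.frame: one row per (condition, method, metric).
#' @export
run_grid <- function(conditions, base_seed = 1L, workers = 1L,
                     progress = FALSE) {
  stopifnot(length(conditions) >= 1L)
  run_one <- function(ci) {
    tryCatch(run_condition(conditions[[ci]], base_seed, cond_index = ci,
                           progress = progress),
             error = function(e) {
               warning(sprintf("condition %d failed: %s", ci,
                               conditionMessage(e)))
               NULL
             })
  }
  res <- if (workers > 1L && .Platform$OS.type == "unix")
    parallel::mclapply(seq_along(conditions), run_one, mc.cores = workers)
  else lapply(seq_along(conditions), run_one)
  out <- do.call(rbind, Filter(Negate(is.null), res))
  class(out) <- c("sim_summary", class(out))
  out
}

#' Write a simulation summary as TSV
#'
#' @param summary A `sim_summary` data.frame.
#' @param file Output path.
#' @param meta Optional named vector of `# key: value` header lines (seed,
#'   config hash, ...).
#' @return `file`, invisibly.
#' @export
write_summary_tsv <- function(summary, file, meta = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  utils::write.table(as.data.frame(summary), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
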