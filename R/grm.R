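#' Construct an item bank for the graded response model
#'
#' An item bank holds the generating parameters of Samejima's graded response
#' model (GRM): one discrimination `a_i > 0` per item and `J - 1` strictly
#' increasing thresholds `b_i1 < ... < b_i,J-1` per item, all on the latent
#' trait scale.
#'
#' @param discriminations Numeric vector of item discriminations, one per item,
#'   all strictly positive.
#' @param thresholds Numeric matrix (items x `J - 1`) or a list of numeric
#'   vectors, one per item, each strictly increasing.
#' @return An object of class `item_bank` with elements `n_items`,
#'   `n_categories`, `discriminations` and `thresholds` (items x `J - 1`
#'   matrix).
#' @examples
#' item_bank(c(1.2, 1.8), rbind(c(-1, 0, 1, 2), c(-0.5, 0, 0.5, 1)))
#' @export
item_bank <- function(discriminations, thresholds) {
  if (is.list(thresholds)) thresholds <- do.call(rbind, thresholds)
  thresholds <- as.matrix(thresholds)
  discriminations <- as.numeric(discriminations)
  n_items <- length(discriminations)
  if (n_items < 1L) stop("at least one item is required")
  if (nrow(thresholds) != n_items)
    stop("thresholds must have one row per item")
  if (any(!is.finite(discriminations)) || any(discriminations <= 0))
    stop("discriminations must be strictly positive")
  if (any(!is.finite(thresholds)))
    stop("thresholds must be finite")
  if (ncol(thresholds) >= 2L && any(t(apply(thresholds, 1L, diff)) <= 0))
    stop("thresholds must be strictly increasing within each item")
  structure(
    list(n_items = n_items,
         n_categories = ncol(thresholds) + 1L,
         discriminations = discriminations,
         thresholds = thresholds),
    class = "item_bank")
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("GRM item bank: %d items, %d response categories\n",
              x$n_items, x$n_categories))
  tab <- cbind(a = x$discriminations, x$thresholds)
  colnames(tab) <- c("a", paste0("b", seq_len(x$n_categories - 1L)))
  rownames(tab) <- paste0("item_", seq_len(x$n_items))
  print(round(tab, 3), ...)
  invisible(x)
}

#' Draw a random GRM item bank
#'
#' Discriminations are drawn i.i.d. Uniform(1, 2). The `J - 1` thresholds of
#' each item are independent N(0, 1) draws sorted ascending, which guarantees
#' a valid GRM (unsorted thresholds would produce negative category
#' probabilities). Floating-point ties after sorting are perturbed by 1e-9
#' increments to keep the ordering strict.
#'
#' @param n_items Number of items `I >= 1`.
#' @param n_categories Number of response categories `J >= 2`.
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return An [item_bank()].
#' @examples
#' sample_item_bank(5, 5, seed = 7)
#' @export
sample_item_bank <- function(n_items, n_categories, seed = NULL) {
  n_items <- as.integer(n_items)
  n_categories <- as.integer(n_categories)
  if (is.na(n_items) || n_items < 1L)
    stop("n_items must be a positive integer")
  if (is.na(n_categories) || n_categories < 2L)
    stop("n_categories must be an integer >= 2")
  with_seed(seed, {
    a <- stats::runif(n_items, 1, 2)
    b <- t(vapply(seq_len(n_items), function(i) {
      bi <- sort(stats::rnorm(n_categories - 1L))
      tied <- which(diff(bi) <= 0)
      while (length(tied)) {
        bi[tied + 1L] <- bi[tied] + 1e-9
        tied <- which(diff(bi) <= 0)
      }
      bi
    }, numeric(n_categories - 1L)))
    if (n_categories == 2L) b <- matrix(b, ncol = 1L)
    item_bank(a, b)
  })
}

#' Shift one item's thresholds for the focal group (uniform DIF)
#'
#' Returns the focal-group bank: identical to `bank` except that every
#' threshold of `target_item` is shifted by `+magnitude`. The input bank (the
#' reference-group bank) is left unmodified. A magnitude of 0 encodes the
#' null, no-DIF condition.
#'
#' @param bank An [item_bank()].
#' @param target_item 1-based index of the item carrying DIF.
#' @param magnitude Non-negative shift added to the target item's thresholds,
#'   in latent-scale units.
#' @return The focal-group [item_bank()].
#' @examples
#' b <- item_bank(1, matrix(c(-1, 0, 1, 2), 1))
#' apply_uniform_dif(b, 1, 0.4)$thresholds
#' @export
apply_uniform_dif <- function(bank, target_item, magnitude) {
  stopifnot(inherits(bank, "item_bank"))
  target_item <- as.integer(target_item)
  if (is.na(target_item) || target_item < 1L || target_item > bank$n_items)
    stop(sprintf("target_item must be in 1..%d", bank$n_items))
  if (!is.finite(magnitude) || magnitude < 0)
    stop("magnitude must be >= 0")
  focal <- bank
  focal$thresholds[target_item, ] <- focal$thresholds[target_item, ] + magnitude
  focal
}

#' GRM cumulative response probability
#'
#' The probability of responding in or above a category whose threshold is
#' `b`: `P = 1 / (1 + exp(-a (theta - b)))`. Strictly increasing in `theta`,
#' strictly decreasing in `b`; saturates to 0/1 under overflow.
#'
#' @param a Item discrimination, `a > 0`.
#' @param theta Latent trait value(s).
#' @param b Threshold (difficulty) parameter.
#' @return Probability (vectorized over `theta`).
#' @examples
#' grm_cumulative_prob(1, 0, 0)   # 0.5
#' @export
grm_cumulative_prob <- function(a, theta, b) {
  if (any(a <= 0)) stop("discrimination a must be > 0")
  stats::plogis(a * (theta - b))
}

#' GRM category probabilities
#'
#' Category probabilities obtained by differencing adjacent cumulative
#' probabilities: `P(Y = j) = P(Y >= j) - P(Y >= j + 1)` with
#' `P(Y >= 1) = 1` and `P(Y >= J + 1) = 0`. Monotone thresholds guarantee a
#' valid probability simplex.
#'
#' @param a Item discrimination, `a > 0`.
#' @param theta Scalar latent trait value.
#' @param thresholds Strictly increasing threshold vector of length `J - 1`.
#' @return Probability vector of length `J` summing to 1.
#' @examples
#' grm_category_probs(1, 0, c(-1, 0, 1, 2))
#' @export
grm_category_probs <- function(a, theta, thresholds) {
  if (any(a <= 0)) stop("discrimination a must be > 0")
  if (length(thresholds) >= 2L && any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing")
  cum <- c(1, grm_cumulative_prob(a, theta, thresholds), 0)
  pmax(-diff(cum), 0)
}

#' Construct an ordinal response dataset
#'
#' The unit of analysis for DIF detection: a persons x items matrix of
#' integer responses in `1..J` plus a binary group indicator (0 = reference,
#' 1 = focal). The true latent trait can be carried along for diagnostics; it
#' is never used by the detection code, which conditions on the observed
#' total score.
#'
#' @param responses Integer matrix, persons x items, entries in `1..J`, no
#'   missing values.
#' @param group Vector of 0/1 (or `"reference"`/`"focal"`) of length
#'   `nrow(responses)`.
#' @param n_categories Number of response categories `J`; defaults to the
#'   maximum observed response.
#' @param theta_true Optional numeric vector of latent traits (diagnostics
#'   only).
#' @return An object of class `response_dataset`.
#' @export
response_dataset <- function(responses, group, n_categories = NULL,
                             theta_true = NULL) {
  responses <- as.matrix(responses)
  if (is.character(group) || is.factor(group))
    group <- as.integer(as.character(group) == "focal")
  group <- as.integer(group)
  if (anyNA(responses)) stop("responses must not contain missing values")
  if (any(responses != round(responses))) stop("responses must be integers")
  if (is.null(n_categories)) n_categories <- max(responses)
  n_categories <- as.integer(n_categories)
  if (any(responses < 1L) || any(responses > n_categories))
    stop(sprintf("responses must lie in 1..%d", n_categories))
  if (length(group) != nrow(responses))
    stop("group must have one entry per response row")
  if (anyNA(group) || !all(group %in% c(0L, 1L)))
    stop("group must be coded 0 (reference) / 1 (focal)")
  if (!is.null(theta_true) && length(theta_true) != nrow(responses))
    stop("theta_true must have one entry per response row")
  storage.mode(responses) <- "integer"
  colnames(responses) <- paste0("item_", seq_len(ncol(responses)))
  structure(
    list(responses = responses,
         group = group,
         n_categories = n_categories,
         n_ref = sum(group == 0L),
         n_focal = sum(group == 1L),
         theta_true = theta_true),
    class = "response_dataset")
}

#' @export
print.response_dataset <- function(x, ...) {
  cat(sprintf(
    "Ordinal response dataset: %d persons (%d reference / %d focal), %d items, %d categories\n",
    nrow(x$responses), x$n_ref, x$n_focal, ncol(x$responses),
    x$n_categories))
  invisible(x)
}

#' Simulate GRM responses for a reference and a focal group
#'
#' Each person's latent trait is drawn from N(0, 1); each item response is
#' then drawn from the categorical distribution given by
#' [grm_category_probs()] under that person's group bank. Reference rows come
#' first, focal rows after.
#'
#' @param ref_bank Reference-group [item_bank()].
#' @param focal_bank Focal-group [item_bank()]; defaults to `ref_bank` (no
#'   DIF).
#' @param n_ref,n_focal Group sizes, both `>= 1`.
#' @param seed Optional integer seed for reproducibility.
#' @return A [response_dataset()] with `theta_true` attached.
#' @examples
#' b <- sample_item_bank(5, 5, seed = 1)
#' simulate_responses(b, apply_uniform_dif(b, 1, 0.4), 50, 50, seed = 3)
#' @export
simulate_responses <- function(ref_bank, focal_bank = ref_bank,
                               n_ref, n_focal, seed = NULL) {
  stopifnot(inherits(ref_bank, "item_bank"), inherits(focal_bank, "item_bank"))
  if (ref_bank$n_items != focal_bank$n_items ||
      ref_bank$n_categories != focal_bank$n_categories)
    stop("reference and focal banks must share item count and categories")
  n_ref <- as.integer(n_ref); n_focal <- as.integer(n_focal)
  if (is.na(n_ref) || is.na(n_focal) || n_ref < 1L || n_focal < 1L)
    stop("group sizes must be >= 1")
  with_seed(seed, {
    n <- n_ref + n_focal
    group <- c(rep(0L, n_ref), rep(1L, n_focal))
    theta <- stats::rnorm(n)
    I <- ref_bank$n_items
    J <- ref_bank$n_categories
    resp <- matrix(0L, n, I)
    # inverse-CDF draw: Y = 1 + #{j : u < P(Y >= j + 1 | theta)}
    for (it in seq_len(I)) {
      for (g in 0:1) {
        bank <- if (g == 0L) ref_bank else focal_bank
        idx <- which(group == g)
        cum <- stats::plogis(bank$discriminations[it] *
                               outer(theta[idx], bank$thresholds[it, ], "-"))
        u <- stats::runif(length(idx))
        resp[idx, it] <- 1L + as.integer(rowSums(cum > u))
      }
    }
    response_dataset(resp, group, n_categories = J, theta_true = theta)
  })
}

# evaluate expr under a temporary seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
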