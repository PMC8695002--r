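#' Write a response dataset as CSV
#'
#' Columns `item_1..item_I` (integer responses in `1..J`), `group`
#' (0 = reference, 1 = focal) and, when `theta = TRUE` and the dataset
#' carries it, the true latent trait.
#'
#' @param dataset A [response_dataset()].
#' @param file Output path.
#' @param theta Include the `theta` diagnostics column (default FALSE).
#' @return `file`, invisibly.
#' @export
write_response_csv <- function(dataset, file, theta = FALSE) {
  stopifnot(inherits(dataset, "response_dataset"))
  df <- as.data.frame(dataset$responses)
  df$group <- dataset$group
  if (theta && !is.null(dataset$theta_true)) df$theta <- dataset$theta_true
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a response dataset from CSV
#'
#' Expects columns `item_*` and `group` (0 = reference / 1 = focal). Entries
#' must be integers with no missing values; `zero_based = TRUE` accepts
#' `0..J-1` coding (e.g. 5-point Likert items scored 0-4) and shifts it to
#' the internal `1..J` convention. Validation failures name the offending
#' column; missing cells are an error, never silently imputed.
#'
#' @param file CSV path.
#' @param zero_based Input responses are coded from 0 (default FALSE).
#' @param n_categories Number of categories `J`; defaults to the maximum
#'   observed response after shifting.
#' @return A [response_dataset()].
#' @export
read_response_csv <- function(file, zero_based = FALSE, n_categories = NULL) {
  if (!file.exists(file)) stop(sprintf("file not found: %s", file))
  df <- utils::read.csv(file, comment.char = "#")
  item_cols <- grep("^item_", names(df), value = TRUE)
  if (!length(item_cols)) stop("no item_* columns found")
  if (!"group" %in% names(df)) stop("missing required column: group")
  for (cl in c(item_cols, "group")) {
    v <- df[[cl]]
    if (anyNA(v))
      stop(sprintf("missing value in column %s (row %d)", cl,
                   which(is.na(v))[1]))
    if (!is.numeric(v) || any(v != round(v)))
      stop(sprintf("non-integer entries in column %s", cl))
  }
  resp <- as.matrix(df[item_cols])
  if (zero_based) resp <- resp + 1L
  if (any(resp < 1L))
    stop(if (zero_based) "responses below 0 in input"
         else "responses below 1 in input; use zero_based for 0-coded data")
  response_dataset(resp, df$group, n_categories = n_categories,
                   theta_true = if ("theta" %in% names(df)) df$theta)
}

#' Read a simulation grid configuration
#'
#' Parses a YAML condition grid. Top-level keys: `seed`, `conditions` (a
#' list, each entry with keys among `n_total`, `ratio`, `n_items`,
#' `n_categories`, `dif`, `w_grid`, `replications`, `alpha`, `score_type`,
#' `lr_loglik`, `n_lambda`, `min_ratio`, `fixed_bank`). Unknown keys are
#' rejected.
#'
#' @param file YAML path.
#' @return List with `seed` and `conditions` (list of [sim_condition()]).
#' @export
read_grid_config <- function(file) {
  if (!file.exists(file)) stop(sprintf("file not found: %s", file))
  cfg <- yaml::read_yaml(file)
  unknown <- setdiff(names(cfg), c("seed", "conditions"))
  if (length(unknown))
    stop(sprintf("unknown top-level config key(s): %s",
                 paste(unknown, collapse = ", ")))
  if (is.null(cfg$conditions) || !length(cfg$conditions))
    stop("config must list at least one condition")
  allowed <- c("n_total", "ratio", "n_items", "n_categories", "dif",
               "w_grid", "replications", "alpha", "score_type",
               "lr_loglik", "n_lambda", "min_ratio", "fixed_bank")
  conditions <- lapply(cfg$conditions, function(cc) {
    unknown <- setdiff(names(cc), allowed)
    if (length(unknown))
      stop(sprintf("unknown condition key(s): %s",
                   paste(unknown, collapse = ", ")))
    if (is.null(cc$n_total)) stop("condition is missing n_total")
    args <- cc
    names(args)[names(args) == "replications"] <- "n_reps"
    if (!is.null(args$w_grid)) args$w_grid <- unlist(args$w_grid)
    do.call(sim_condition, args)
  })
  list(seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
       conditions = conditions)
}

# short stable hash of a config list, for output headers
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            4294967291)
}

#' Command-line entry point
#'
#' Subcommands:
#' \describe{
#'   \item{simulate}{`difnet simulate --n 100 --ratio 1 --items 5 --dif 0.4
#'     --seed 7 -o data.csv` — write one simulated GRM dataset as CSV.}
#'   \item{dif}{`difnet dif data.csv --method elastic_net --w 0.1 -o out.tsv`
#'     — per-item DIF tests on a response CSV, TSV output.}
#'   \item{power-study}{`difnet power-study grid.yaml -o summary.tsv` — run a
#'     condition grid from a YAML config.}
#' }
#' Every output embeds the resolved seed and config hash as `#` header
#' lines. Returns (and, under `Rscript`, exits with) 0 on success, 1 on
#' validation failure, 2 on usage errors.
#'
#' @param args Character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly.
#' @export
difnet_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: difnet <simulate|dif|power-study> [options]",
    "  simulate    --n N --ratio R --items I [--categories J] [--dif D]",
    "              [--seed S] [--theta] [-o out.csv]",
    "  dif <data.csv> [--method ml|elastic_net] [--w W] [--alpha A]",
    "              [--score total|rest] [--zero-based] [-o out.tsv]",
    "  power-study <grid.yaml> [--workers K] [-o out.tsv]",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(2L)) }
  sub <- args[[1]]
  rest <- args[-1]
  status <- tryCatch({
    switch(sub,
           "simulate" = cli_simulate(rest),
           "dif" = cli_dif(rest),
           "power-study" = cli_power_study(rest),
           { message(sprintf("unknown subcommand: %s\n%s", sub, usage))
             return(invisible(2L)) })
    0L
  }, usage_error = function(e) { message(conditionMessage(e)); 2L },
     error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}

cli_opt <- function(opts, flag, default = NULL, required = FALSE) {
  i <- which(opts == flag)
  if (!length(i)) {
    if (required)
      stop(structure(class = c("usage_error", "error", "condition"),
                     list(message = sprintf("missing required option %s", flag),
                          call = NULL)))
    return(default)
  }
  if (i[1] + 1 > length(opts))
    stop(structure(class = c("usage_error", "error", "condition"),
                   list(message = sprintf("option %s needs a value", flag),
                        call = NULL)))
  opts[i[1] + 1]
}

cli_simulate <- function(opts) {
  n <- as.integer(cli_opt(opts, "--n", required = TRUE))
  ratio <- as.numeric(cli_opt(opts, "--ratio", 1))
  items <- as.integer(cli_opt(opts, "--items", required = TRUE))
  categories <- as.integer(cli_opt(opts, "--categories", 5))
  dif <- as.numeric(cli_opt(opts, "--dif", 0))
  seed <- as.integer(cli_opt(opts, "--seed", 1))
  out <- cli_opt(opts, "-o", "responses.csv")
  keep_theta <- "--theta" %in% opts
  n_focal <- as.integer(round(n / (ratio + 1)))
  n_ref <- n - n_focal
  bank <- sample_item_bank(items, categories, seed = seed)
  focal <- if (dif > 0) apply_uniform_dif(bank, 1L, dif) else bank
  ds <- simulate_responses(bank, focal, n_ref, n_focal, seed = seed + 1L)
  con <- file(out, "w")
  writeLines(sprintf("# seed: %d", seed), con)
  writeLines(sprintf("# config: n=%d ratio=%g items=%d categories=%d dif=%g",
                     n, ratio, items, categories, dif), con)
  close(con)
  df <- as.data.frame(ds$responses)
  df$group <- ds$group
  if (keep_theta) df$theta <- ds$theta_true
  suppressWarnings(utils::write.table(df, out, sep = ",", quote = FALSE,
                                      row.names = FALSE, append = TRUE,
                                      col.names = TRUE))
  message(sprintf("wrote %d x %d dataset to %s", nrow(df), items, out))
  invisible(out)
}

cli_dif <- function(opts) {
  if (!length(opts) || startsWith(opts[[1]], "-"))
    stop(structure(class = c("usage_error", "error", "condition"),
                   list(message = "dif: input CSV must be the first argument",
                        call = NULL)))
  pos <- opts[1]
  ds <- read_response_csv(pos[[1]], zero_based = "--zero-based" %in% opts)
  cfg <- dif_config(method = cli_opt(opts, "--method", "ml"),
                    w = as.numeric(cli_opt(opts, "--w", 0.5)),
                    alpha = as.numeric(cli_opt(opts, "--alpha", 0.05)),
                    score_type = cli_opt(opts, "--score", "total"))
  res <- analyze_scale(ds, cfg)
  out <- cli_opt(opts, "-o", "dif_results.tsv")
  write_dif_tsv(res, out,
                meta = c(input = pos[[1]], method = cfg$method,
                         w = format(cfg$w), alpha = format(cfg$alpha),
                         config = config_hash(unclass(cfg))))
  message(sprintf("wrote per-item DIF results (%d items, %d flagged) to %s",
                  nrow(res), attr(res, "n_flagged_uniform"), out))
  invisible(out)
}

cli_power_study <- function(opts) {
  if (!length(opts) || startsWith(opts[[1]], "-"))
    stop(structure(class = c("usage_error", "error", "condition"),
                   list(message = "power-study: grid YAML must be the first argument",
                        call = NULL)))
  pos <- opts[1]
  cfg <- read_grid_config(pos[[1]])
  workers <- as.integer(cli_opt(opts, "--workers", 1))
  out <- cli_opt(opts, "-o", "power_summary.tsv")
  summary <- run_grid(cfg$conditions, base_seed = cfg$seed,
                      workers = workers)
  write_summary_tsv(summary, out,
                    meta = c(config_file = pos[[1]],
                             seed = format(cfg$seed),
                             config = config_hash(cfg)))
  message(sprintf("wrote %d summary rows to %s", nrow(summary), out))
  invisible(out)
}
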