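#' Specification for the synthetic calibration cohort
#'
#' Defaults emulate a realistic calibration study for a dichotomous
#' knowledge test: 1000 respondents on a standardized trait
#' (theta ~ Normal(0, 1)) answering 22 four-option multiple-choice items.
#' Discriminations are log-normal (location `log(1.2)`, scale 0.35)
#' truncated to `[0.5, 3]` — the range left after screening out weakly
#' discriminating items; difficulties are standard normal truncated to
#' `[-3, 3]`; lower asymptotes are Beta(5, 20), mean 0.2, slightly below
#' the nominal 1-in-4 guessing rate as empirical 3PL calibrations of
#' 4-option items typically are.
#'
#' @param n_respondents,n_items Cohort dimensions.
#' @param theta_mean,theta_sd Latent-trait distribution.
#' @param a_meanlog,a_sdlog,a_bounds Discrimination distribution
#'   (log-normal, truncated).
#' @param b_mean,b_sd,b_bounds Difficulty distribution (normal, truncated).
#' @param c_shape1,c_shape2 Lower-asymptote Beta shapes.
#' @param seed Integer seed recorded in the spec and used by the
#'   generators.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_respondents = 1000L, n_items = 22L,
                           theta_mean = 0, theta_sd = 1,
                           a_meanlog = log(1.2), a_sdlog = 0.35,
                           a_bounds = c(0.5, 3.0),
                           b_mean = 0, b_sd = 1, b_bounds = c(-3, 3),
                           c_shape1 = 5, c_shape2 = 20,
                           seed = 42L) {
  if (n_respondents < 1L || n_items < 1L)
    stop("counts must be >= 1", call. = FALSE)
  if (theta_sd <= 0 || a_sdlog <= 0 || b_sd <= 0)
    stop("scale parameters must be > 0", call. = FALSE)
  if (c_shape1 <= 0 || c_shape2 <= 0)
    stop("Beta shapes must be > 0", call. = FALSE)
  structure(list(n_respondents = as.integer(n_respondents),
                 n_items = as.integer(n_items),
                 theta_mean = theta_mean, theta_sd = theta_sd,
                 a_meanlog = a_meanlog, a_sdlog = a_sdlog,
                 a_bounds = a_bounds,
                 b_mean = b_mean, b_sd = b_sd, b_bounds = b_bounds,
                 c_shape1 = c_shape1, c_shape2 = c_shape2,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Draw n values from `rfun(n)` and resample until all fall inside bounds.
rtrunc <- function(n, rfun, lower, upper) {
  x <- rfun(n)
  bad <- which(x < lower | x > upper)
  while (length(bad) > 0L) {
    x[bad] <- rfun(length(bad))
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Generate a synthetic 3PL item bank
#'
#' Draws item parameters from the distributions in the spec; reproducible
#' for a fixed seed.
#'
#' @param spec A [synthetic_spec()].
#' @return An [item_bank()] with ids `it01`, `it02`, ...
#' @export
generate_item_bank <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_items
  a <- rtrunc(n, function(m) stats::rlnorm(m, spec$a_meanlog, spec$a_sdlog),
              spec$a_bounds[1], spec$a_bounds[2])
  b <- rtrunc(n, function(m) stats::rnorm(m, spec$b_mean, spec$b_sd),
              spec$b_bounds[1], spec$b_bounds[2])
  cc <- stats::rbeta(n, spec$c_shape1, spec$c_shape2)
  item_bank(sprintf("it%02d", seq_len(n)), a, b, cc,
            metadata = sprintf("synthetic bank, seed %d", spec$seed))
}

#' Generate latent-trait values
#'
#' Independent normal draws on the standardized theta scale.
#'
#' @param n Number of respondents.
#' @param mean,sd Normal parameters; `sd > 0`.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
generate_thetas <- function(n, mean = 0, sd = 1, seed = 42L) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (!is.finite(sd) || sd <= 0) stop("sd must be > 0", call. = FALSE)
  set.seed(seed)
  stats::rnorm(n, mean, sd)
}

#' Generate a complete 0/1 response matrix
#'
#' Entry (i, j) is a Bernoulli draw with success probability
#' `prob_correct(item_j, theta_i)`.
#'
#' @param thetas Latent-trait vector (one per respondent).
#' @param bank An [item_bank()].
#' @param seed Integer seed.
#' @return Integer matrix, respondents in rows (named `r0001`, ... unless
#'   `thetas` is named), items in columns (bank ids).
#' @export
generate_response_matrix <- function(thetas, bank, seed = 42L) {
  stopifnot(inherits(bank, "item_bank"))
  set.seed(seed)
  n <- length(thetas)
  m <- nrow(bank)
  P <- vapply(seq_len(m), function(j)
    prob_correct(bank$a[j], bank$b[j], bank$c[j], thetas), numeric(n))
  P <- matrix(P, nrow = n)
  X <- matrix(as.integer(stats::runif(n * m) < P), nrow = n)
  rownames(X) <- if (!is.null(names(thetas))) names(thetas) else
    sprintf("r%04d", seq_len(n))
  colnames(X) <- bank$item_id
  X
}

validate_response_matrix <- function(X, bank) {
  if (is.null(colnames(X)) || !setequal(colnames(X), bank$item_id))
    stop("response matrix columns must exactly match the bank item ids",
         call. = FALSE)
  if (anyNA(X) || !all(X %in% c(0L, 1L)))
    stop("response matrix must be complete 0/1", call. = FALSE)
  if (is.null(rownames(X)) || anyDuplicated(rownames(X)))
    stop("respondent ids must be present and unique", call. = FALSE)
  X[, bank$item_id, drop = FALSE]
}

#' Read / write a response matrix as CSV
#'
#' First column `respondent_id`, remaining columns one per item id,
#' entries 0/1.
#'
#' @param path File path.
#' @return `read_response_matrix()` returns an integer matrix with
#'   respondent row names and item column names.
#' @export
read_response_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = c(respondent_id = "character"))
  if (names(df)[1] != "respondent_id")
    stop("first column must be respondent_id", call. = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(X) <- "integer"
  rownames(X) <- df$respondent_id
  X
}

#' @rdname read_response_matrix
#' @param X Response matrix (respondents x items, dimnames set).
#' @export
write_response_matrix <- function(X, path) {
  df <- data.frame(respondent_id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Post-hoc CAT simulation over a recorded response matrix
#'
#' Replays the adaptive loop for every respondent against their complete
#' recorded response row (no random number generation: the run is fully
#' deterministic), and pairs each session with the full-length EAP score of
#' the same row.
#'
#' @param X Complete 0/1 response matrix (respondents x items).
#' @param bank An [item_bank()].
#' @param config A [cat_config()].
#' @return A list of class `posthoc_run`: `results` (list of
#'   [run_cat()] results), `full_length` (data frame `respondent_id`,
#'   `theta`, `se`), and `config`.
#' @export
run_posthoc_simulation <- function(X, bank, config = cat_config()) {
  stopifnot(inherits(bank, "item_bank"), inherits(config, "cat_config"))
  X <- validate_response_matrix(X, bank)
  pre <- precompute_bank(bank, config_grid(config))
  ids <- rownames(X)
  results <- vector("list", nrow(X))
  fl_theta <- numeric(nrow(X))
  fl_se <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    row <- X[i, ]
    results[[i]] <- run_cat_precomp(ids[i], row, bank, config, pre)
    fl <- full_length_precomp(row, pre)
    fl_theta[i] <- fl$theta
    fl_se[i] <- fl$se
  }
  structure(list(results = results,
                 full_length = data.frame(respondent_id = ids,
                                          theta = fl_theta, se = fl_se,
                                          stringsAsFactors = FALSE),
                 config = config),
            class = "posthoc_run")
}

# Full-length EAP from precomputed probabilities; same sequential update
# (in bank order) as full_length_score().
full_length_precomp <- function(row, pre) {
  w <- pre$grid$prior_weights
  for (i in seq_along(row)) {
    lik <- if (row[[i]] == 1) pre$P[i, ] else 1 - pre$P[i, ]
    w <- w * lik
    w <- w / sum(w)
  }
  th <- sum(pre$grid$points * w)
  list(theta = th, se = sqrt(sum(w * (pre$grid$points - th)^2)))
}

#' @export
print.posthoc_run <- function(x, ...) {
  len <- vapply(x$results, function(r) length(r$administered), integer(1))
  cat(sprintf(
    "Post-hoc CAT run: %d respondents, SE threshold %.2f, cap %d items; mean length %.2f, median %g\n",
    length(x$results), x$config$se_threshold, x$config$max_items,
    mean(len), stats::median(len)))
  invisible(x)
}

#' Flatten session results to per-respondent and per-step tables
#'
#' @param run A [run_posthoc_simulation()] result, or a bare list of
#'   `cat_result` objects.
#' @return `results_to_table()`: one row per respondent (`respondent_id`,
#'   `n_items`, `final_theta`, `final_se`, `stop_reason`, pipe-joined
#'   `administered`). `interim_trace()`: long format, one row per
#'   administered item (`respondent_id`, `step`, `item_id`, `response`,
#'   `theta`, `se`).
#' @export
results_to_table <- function(run) {
  results <- if (inherits(run, "posthoc_run")) run$results else run
  data.frame(
    respondent_id = vapply(results, `[[`, character(1), "respondent_id"),
    n_items = vapply(results, function(r) length(r$administered),
                     integer(1)),
    final_theta = vapply(results, `[[`, numeric(1), "final_theta"),
    final_se = vapply(results, `[[`, numeric(1), "final_se"),
    stop_reason = vapply(results, `[[`, character(1), "stop_reason"),
    administered = vapply(results, function(r)
      paste(r$administered, collapse = "|"), character(1)),
    stringsAsFactors = FALSE)
}

#' @rdname results_to_table
#' @export
interim_trace <- function(run) {
  results <- if (inherits(run, "posthoc_run")) run$results else run
  do.call(rbind, lapply(results, function(r) {
    k <- seq_along(r$administered)
    data.frame(respondent_id = r$respondent_id, step = k,
               item_id = r$administered, response = r$responses,
               theta = r$interim_thetas, se = r$interim_ses,
               stringsAsFactors = FALSE)
  }))
}

#' Run the crossed stopping-rule scenario grid
#'
#' Crosses SE thresholds with maximum-length caps (the canonical design is
#' thresholds {0.50, 0.45} x caps {15, 18, 22}) and produces one post-hoc
#' run plus one summary row per cell.
#'
#' @param X Response matrix.
#' @param bank An [item_bank()].
#' @param thresholds Numeric vector of SE thresholds.
#' @param max_items_list Integer vector of caps.
#' @param base_config A [cat_config()] supplying all other settings.
#' @return A list of class `scenario_grid`: `runs` (named list of
#'   `posthoc_run`, names like `se0.50_max15`) and `summary` (data frame,
#'   one [summarize_scenario()] row per cell).
#' @export
run_scenario_grid <- function(X, bank, thresholds = c(0.50, 0.45),
                              max_items_list = c(15L, 18L, 22L),
                              base_config = cat_config()) {
  cells <- expand.grid(max_items = max_items_list, se = thresholds)
  runs <- list()
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    cfg <- base_config
    cfg$se_threshold <- cells$se[i]
    cfg$max_items <- as.integer(cells$max_items[i])
    label <- sprintf("se%.2f_max%d", cfg$se_threshold, cfg$max_items)
    run <- run_posthoc_simulation(X, bank, cfg)
    runs[[label]] <- run
    rows[[label]] <- summarize_scenario(run, label = label)
  }
  structure(list(runs = runs, summary = do.call(rbind, rows)),
            class = "scenario_grid")
}

#' @export
print.scenario_grid <- function(x, ...) {
  cat(sprintf("CAT scenario grid: %d cells\n", length(x$runs)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
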