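#' Root mean squared error between paired theta vectors
#'
#' @param estimates,reference Equal-length numeric vectors.
#' @return `sqrt(mean((estimates - reference)^2))`.
#' @export
rmse <- function(estimates, reference) {
  if (length(estimates) != length(reference) || length(estimates) == 0L)
    stop("estimates and reference must be nonempty and of equal length",
         call. = FALSE)
  sqrt(mean((estimates - reference)^2))
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Table-style summary of one CAT scenario
#'
#' One row per scenario: administered-length statistics (mean, population
#' SD, range, median, quartile-based IQR with linearly interpolated
#' percentiles), final theta and final SE statistics, and the theta-recovery
#' RMSE against the paired full-length scores.
#'
#' @param run A [run_posthoc_simulation()] result.
#' @param label Scenario label; defaults to `se<threshold>_max<cap>`.
#' @return A one-row data frame.
#' @export
summarize_scenario <- function(run, label = NULL) {
  stopifnot(inherits(run, "posthoc_run"))
  tab <- results_to_table(run)
  if (is.null(label))
    label <- sprintf("se%.2f_max%d", run$config$se_threshold,
                     run$config$max_items)
  len <- tab$n_items
  q <- stats::quantile(len, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(
    scenario = label,
    se_threshold = run$config$se_threshold,
    max_items = run$config$max_items,
    len_mean = mean(len), len_sd = pop_sd(len),
    len_min = min(len), len_max = max(len),
    len_median = q[2], len_q25 = q[1], len_q75 = q[3],
    theta_mean = mean(tab$final_theta), theta_sd = pop_sd(tab$final_theta),
    theta_min = min(tab$final_theta), theta_max = max(tab$final_theta),
    se_mean = mean(tab$final_se), se_sd = pop_sd(tab$final_se),
    se_min = min(tab$final_se), se_max = max(tab$final_se),
    rmse_vs_full_length = rmse(tab$final_theta, run$full_length$theta),
    stringsAsFactors = FALSE)
}

#' Length-distribution summary of a set of sessions
#'
#' @param results List of `cat_result` objects (or a `posthoc_run`).
#' @return List with `mean`, `sd` (population denominator), `min`, `max`,
#'   `median`, `q25`, `q75` of administered item counts.
#' @export
length_summary <- function(results) {
  if (inherits(results, "posthoc_run")) results <- results$results
  if (length(results) == 0L) stop("no results", call. = FALSE)
  len <- vapply(results, function(r) length(r$administered), integer(1))
  q <- stats::quantile(len, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(mean = mean(len), sd = pop_sd(len), min = min(len), max = max(len),
       median = q[2], q25 = q[1], q75 = q[3])
}

#' Correlation between step-k CAT thetas and full-length thetas
#'
#' For each respondent, takes the interim theta after the k-th administered
#' item; a respondent who terminated before step k contributes their final
#' theta (carried forward — the score a capped deployed CAT would report).
#' Pearson correlation with the full-length scores.
#'
#' @param results List of `cat_result` (or a `posthoc_run`).
#' @param full_thetas Full-length theta vector, same respondent order (for
#'   a `posthoc_run` it defaults to the paired full-length scores).
#' @param k Step (>= 1).
#' @param carry_forward If `FALSE`, restrict to respondents still active at
#'   step k instead of carrying final thetas forward.
#' @return Pearson r.
#' @export
correlation_by_length <- function(results, full_thetas = NULL, k,
                                  carry_forward = TRUE) {
  if (inherits(results, "posthoc_run")) {
    if (is.null(full_thetas)) full_thetas <- results$full_length$theta
    results <- results$results
  }
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (length(full_thetas) != length(results))
    stop("full_thetas must pair with results", call. = FALSE)
  if (carry_forward) {
    est <- vapply(results, function(r)
      r$interim_thetas[min(k, length(r$interim_thetas))], numeric(1))
  } else {
    active <- vapply(results, function(r)
      length(r$interim_thetas) >= k, logical(1))
    est <- vapply(results[active], function(r) r$interim_thetas[k],
                  numeric(1))
    full_thetas <- full_thetas[active]
  }
  if (length(est) < 2L || pop_sd(est) == 0 || pop_sd(full_thetas) == 0)
    stop("correlation undefined: fewer than 2 cases or zero variance",
         call. = FALSE)
  stats::cor(est, full_thetas)
}

#' Diagnostics for sessions stopped by the maximum-length rule
#'
#' Counts sessions per stop reason and characterizes the cap-terminated
#' ones: these are expected to sit in the tails of the theta distribution,
#' where item information is low and the SE rule cannot be met.
#'
#' @param results List of `cat_result` (or a `posthoc_run`).
#' @return List: `n_total`, `n_se_reached`, `n_max_items`, and (over the
#'   cap-terminated cases) `prop_theta_below_m1`, `prop_theta_above_p1`,
#'   `se_mean`, `se_min`, `se_max` (`NA` when no such case exists).
#' @export
secondary_rule_diagnostics <- function(results) {
  if (inherits(results, "posthoc_run")) results <- results$results
  if (length(results) == 0L) stop("no results", call. = FALSE)
  reason <- vapply(results, `[[`, character(1), "stop_reason")
  capped <- results[reason == "max_items"]
  out <- list(n_total = length(results),
              n_se_reached = sum(reason == "se_reached"),
              n_max_items = length(capped))
  if (length(capped) == 0L) {
    out[c("prop_theta_below_m1", "prop_theta_above_p1",
          "se_mean", "se_min", "se_max")] <- NA_real_
    return(out)
  }
  th <- vapply(capped, `[[`, numeric(1), "final_theta")
  se <- vapply(capped, `[[`, numeric(1), "final_se")
  out$prop_theta_below_m1 <- mean(th < -1)
  out$prop_theta_above_p1 <- mean(th > 1)
  out$se_mean <- mean(se)
  out$se_min <- min(se)
  out$se_max <- max(se)
  out
}

#' Standard-error reduction from taking one more item
#'
#' For each step k, among respondents who went on to take item k + 1, the
#' proportion whose SE dropped by more than `delta` between steps k and
#' k + 1. Steps nobody continued past are absent from the table rather than
#' reported as zero.
#'
#' @param results List of `cat_result` (or a `posthoc_run`).
#' @param delta Reduction threshold in SE units; default 0.01.
#' @return Data frame with `step`, `n` (denominator: respondents who took
#'   item step + 1) and `prop_reduced` (share with SE drop > `delta`).
#' @export
se_reduction_analysis <- function(results, delta = 0.01) {
  if (inherits(results, "posthoc_run")) results <- results$results
  lens <- vapply(results, function(r) length(r$interim_ses), integer(1))
  steps <- seq_len(max(lens) - 1L)
  rows <- lapply(steps, function(k) {
    took_next <- lens >= k + 1L
    if (!any(took_next)) return(NULL)
    drop <- vapply(results[took_next], function(r)
      r$interim_ses[k] - r$interim_ses[k + 1L], numeric(1))
    data.frame(step = k, n = sum(took_next),
               prop_reduced = mean(drop > delta))
  })
  do.call(rbind, rows)
}

#' Score a fixed static short form and compare it with full-length theta
#'
#' EAP-scores each respondent on the fixed item subset only (the same grid
#' and prior as the full form) and reports the Pearson correlation of the
#' short-form thetas with the full-length thetas.
#'
#' @param X Complete response matrix.
#' @param bank An [item_bank()].
#' @param subset_item_ids Item ids of the static short form.
#' @param config A [cat_config()] (grid settings only).
#' @return List: `thetas` (short-form EAP per respondent), `ses`,
#'   `full_thetas`, and `r` (Pearson correlation).
#' @export
compare_static_short_form <- function(X, bank, subset_item_ids,
                                      config = cat_config()) {
  stopifnot(inherits(bank, "item_bank"))
  unknown <- setdiff(subset_item_ids, bank$item_id)
  if (length(unknown) > 0L)
    stop("unknown item ids: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  X <- validate_response_matrix(X, bank)
  sub_rows <- match(subset_item_ids, bank$item_id)
  sub_bank <- item_bank(bank$item_id[sub_rows], bank$a[sub_rows],
                        bank$b[sub_rows], bank$c[sub_rows],
                        bank$content_domain[sub_rows])
  grid <- config_grid(config)
  pre_sub <- precompute_bank(sub_bank, grid)
  pre_full <- precompute_bank(bank, grid)
  n <- nrow(X)
  short_th <- numeric(n); short_se <- numeric(n); full_th <- numeric(n)
  for (i in seq_len(n)) {
    s <- full_length_precomp(X[i, subset_item_ids], pre_sub)
    short_th[i] <- s$theta; short_se[i] <- s$se
    full_th[i] <- full_length_precomp(X[i, ], pre_full)$theta
  }
  list(thetas = short_th, ses = short_se, full_thetas = full_th,
       r = stats::cor(short_th, full_th))
}

#' Full evaluation report for one scenario
#'
#' Bundles the evaluation battery: correlation-by-length curve (carried
#' forward), termination-class diagnostics, and the per-step SE-reduction
#' table.
#'
#' @param run A [run_posthoc_simulation()] result.
#' @param ks Steps at which to evaluate the correlation curve; defaults to
#'   `1:max_items`.
#' @param delta SE-reduction threshold, see [se_reduction_analysis()].
#' @return A list of class `evaluation_report` with `correlations` (data
#'   frame `k`, `r`), `termination` ([secondary_rule_diagnostics()] list)
#'   and `se_reduction` (data frame).
#' @export
evaluation_report <- function(run, ks = NULL, delta = 0.01) {
  stopifnot(inherits(run, "posthoc_run"))
  if (is.null(ks)) ks <- seq_len(run$config$max_items)
  corr <- data.frame(k = ks, r = vapply(ks, function(k)
    correlation_by_length(run, k = k), numeric(1)))
  structure(list(correlations = corr,
                 termination = secondary_rule_diagnostics(run),
                 se_reduction = se_reduction_analysis(run, delta = delta)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  tr <- x$termination
  cat(sprintf(
    "Evaluation report: %d sessions (%d SE-rule, %d cap-rule terminations)\n",
    tr$n_total, tr$n_se_reached, tr$n_max_items))
  cat(sprintf("  r(CAT, full-length) at k = %d: %.3f\n",
              max(x$correlations$k),
              x$correlations$r[which.max(x$correlations$k)]))
  invisible(x)
}
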