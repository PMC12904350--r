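test_that("rmse matches hand arithmetic and scales linearly", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0.3, -0.4), c(0, 0)), sqrt(0.125))
  x <- c(0.2, -0.7, 1.1); ref <- c(0, 0, 0)
  expect_equal(rmse(2 * x, ref), 2 * rmse(x, ref))
  expect_error(rmse(1:3, 1:2), "equal length")
  expect_error(rmse(numeric(0), numeric(0)), "nonempty")
})

test_that("length summaries use population SD and interpolated quartiles", {
  mk <- function(lens) lapply(seq_along(lens), function(i)
    structure(list(respondent_id = paste0("r", i),
                   administered = paste0("i", seq_len(lens[i])),
                   responses = rep(1L, lens[i]),
                   interim_thetas = rep(0, lens[i]),
                   interim_ses = rep(0.5, lens[i]),
                   final_theta = 0, final_se = 0.5,
                   stop_reason = "se_reached"), class = "cat_result"))
  const <- length_summary(mk(rep(10L, 5)))
  expect_equal(const[c("mean", "sd", "median", "q25", "q75")],
               list(mean = 10, sd = 0, median = 10, q25 = 10, q75 = 10))
  expect_equal(length_summary(mk(c(6L, 8L, 10L, 12L, 14L)))$median, 10)
  set.seed(51)
  lens <- sample(5:22, 1000, replace = TRUE)
  s <- length_summary(mk(lens))
  srt <- sort(lens)
  expect_equal(s$median, unname(quantile(srt, 0.5)))
  expect_equal(s$q25, unname(quantile(srt, 0.25)))
  expect_equal(s$q75, unname(quantile(srt, 0.75)))
  expect_equal(s$sd, sqrt(mean((lens - mean(lens))^2)))
})

test_that("correlation by length carries terminated respondents forward", {
  co <- make_cohort(seed = 14, n_respondents = 50, n_items = 10)
  exhaustive <- run_posthoc_simulation(co$X, co$bank,
                                       cat_config(se_threshold = 0,
                                                  max_items = 10))
  expect_equal(correlation_by_length(exhaustive, k = 10), 1,
               tolerance = 1e-12)
  # hand computation of the Pearson formula at an interior step
  k <- 4L
  est <- vapply(exhaustive$results, function(r) r$interim_thetas[k],
                numeric(1))
  full <- exhaustive$full_length$theta
  hand <- sum((est - mean(est)) * (full - mean(full))) /
    sqrt(sum((est - mean(est))^2) * sum((full - mean(full))^2))
  expect_equal(correlation_by_length(exhaustive, k = k), hand,
               tolerance = 1e-12)
  # carried-forward: k past everyone's length reuses final thetas
  capped <- run_posthoc_simulation(co$X, co$bank,
                                   cat_config(se_threshold = 0.55,
                                              max_items = 6))
  r_beyond <- correlation_by_length(capped, k = 10)
  final <- results_to_table(capped)$final_theta
  expect_equal(r_beyond, cor(final, capped$full_length$theta),
               tolerance = 1e-12)
  # restricted mode drops finished respondents instead
  r_restr <- correlation_by_length(capped, k = 5, carry_forward = FALSE)
  active <- vapply(capped$results, function(r)
    length(r$interim_thetas) >= 5, logical(1))
  expect_equal(r_restr,
               cor(vapply(capped$results[active], function(r)
                 r$interim_thetas[5], numeric(1)),
                 capped$full_length$theta[active]),
               tolerance = 1e-12)
  expect_error(correlation_by_length(list(), numeric(0), k = 1),
               "undefined")
  expect_error(correlation_by_length(exhaustive,
                                     full_thetas = rep(0, 50), k = 2),
               "zero variance")
})

test_that("secondary-rule diagnostics count and characterize capped sessions", {
  mk <- function(theta, se, reason)
    structure(list(respondent_id = "r", administered = "i1",
                   responses = 1L, interim_thetas = theta,
                   interim_ses = se, final_theta = theta, final_se = se,
                   stop_reason = reason), class = "cat_result")
  all_se <- list(mk(0, 0.4, "se_reached"), mk(1, 0.45, "se_reached"))
  d0 <- secondary_rule_diagnostics(all_se)
  expect_equal(d0$n_max_items, 0L)
  expect_true(is.na(d0$prop_theta_below_m1))
  four <- list(mk(-1.5, 0.55, "max_items"), mk(1.5, 0.6, "max_items"),
               mk(0, 0.4, "se_reached"), mk(0.2, 0.4, "se_reached"))
  d <- secondary_rule_diagnostics(four)
  expect_equal(d$n_max_items, 2L)
  expect_equal(d$prop_theta_below_m1, 0.5)
  expect_equal(d$prop_theta_above_p1, 0.5)
  expect_equal(d$se_mean, 0.575)
  expect_equal(c(d$se_min, d$se_max), c(0.55, 0.6))
})

test_that("capped sessions concentrate in the theta tails", {
  co <- make_cohort(seed = 15, n_respondents = 400, n_items = 16)
  run <- run_posthoc_simulation(co$X, co$bank,
                                cat_config(se_threshold = 0.55,
                                           max_items = 12))
  tab <- results_to_table(run)
  capped <- tab$stop_reason == "max_items"
  expect_gt(sum(capped), 0)
  expect_lt(sum(capped), nrow(tab))
  expect_gt(mean(abs(tab$final_theta[capped])),
            mean(abs(tab$final_theta)))
})

test_that("SE-reduction analysis differences interim traces per step", {
  mk <- function(id, ses)
    structure(list(respondent_id = id,
                   administered = paste0("i", seq_along(ses)),
                   responses = rep(1L, length(ses)),
                   interim_thetas = rep(0, length(ses)),
                   interim_ses = ses,
                   final_theta = 0, final_se = ses[length(ses)],
                   stop_reason = "max_items"), class = "cat_result")
  steady <- lapply(1:3, function(i) mk(paste0("s", i),
                                       seq(0.9, by = -0.05,
                                           length.out = 6)))
  a <- se_reduction_analysis(steady)
  expect_equal(a$prop_reduced, rep(1, 5))
  expect_equal(a$n, rep(3L, 5))
  expect_equal(a$step, 1:5)
  # hand-built: drops of (0.10, 0.005) vs (0.02, 0.02) vs length-2 trace
  mixed <- list(mk("a", c(0.9, 0.8, 0.795)),
                mk("b", c(0.9, 0.88, 0.86)),
                mk("c", c(0.9, 0.85)))
  m <- se_reduction_analysis(mixed)
  expect_equal(m$n, c(3L, 2L))
  expect_equal(m$prop_reduced, c(1, 0.5))
  # steps past the longest trace are absent, not zero
  expect_equal(max(m$step), 2L)
  # a delta larger than every drop zeroes the proportions
  expect_equal(se_reduction_analysis(mixed, delta = 0.5)$prop_reduced,
               c(0, 0))
})

test_that("static short forms score on the subset and trail the full form", {
  co <- make_cohort(seed = 16, n_respondents = 120, n_items = 14)
  full <- compare_static_short_form(co$X, co$bank, co$bank$item_id)
  expect_equal(full$r, 1, tolerance = 1e-12)
  # one weakly informative item correlates far worse
  weakest <- co$bank$item_id[which.min(item_information(
    co$bank$a, co$bank$b, co$bank$c, 0))]
  weak <- compare_static_short_form(co$X, co$bank, weakest)
  expect_lt(weak$r, 0.9)
  expect_error(compare_static_short_form(co$X, co$bank, "nope"),
               "unknown")
})

test_that("evaluation reports bundle the battery consistently", {
  co <- make_cohort(seed = 17, n_respondents = 80, n_items = 12)
  run <- run_posthoc_simulation(co$X, co$bank,
                                cat_config(se_threshold = 0.5,
                                           max_items = 10))
  rep <- evaluation_report(run)
  expect_s3_class(rep, "evaluation_report")
  expect_equal(nrow(rep$correlations), 10L)
  expect_true(all(rep$correlations$r >= -1 & rep$correlations$r <= 1))
  tr <- rep$termination
  expect_equal(tr$n_se_reached + tr$n_max_items, 80L)
  expect_true(all(rep$se_reduction$prop_reduced >= 0 &
                    rep$se_reduction$prop_reduced <= 1))
  # the curve recomputes from the raw results
  expect_equal(rep$correlations$r[6],
               correlation_by_length(run, k = 6))
})
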