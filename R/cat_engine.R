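#' Configure a CAT scenario
#'
#' One simulation scenario: the dual stopping rules (standard-error
#' threshold, primary; maximum test length, secondary), the theta prior and
#' quadrature grid, and the item-selection policy. Stopping is evaluated
#' only after a response has been absorbed, and when both rules would fire
#' on the same item the SE rule takes precedence, so every session is
#' classed as exactly one of `se_reached` / `max_items`.
#'
#' @param se_threshold Stop once the posterior SD is at or below this value
#'   (theta units). Default 0.50.
#' @param max_items Hard cap on administered items. Default 22.
#' @param min_items Floor on administered items before stopping is
#'   considered. Default 1 (with a unit-SD prior the first item is always
#'   administered anyway; the floor guards degenerate configurations).
#' @param theta_min,theta_max,n_grid_points,prior_mean,prior_sd Quadrature
#'   grid settings, see [make_grid()].
#' @param policy A [selection_policy()].
#' @return A list of class `cat_config`.
#' @examples
#' cat_config(se_threshold = 0.45, max_items = 15)
#' @export
cat_config <- function(se_threshold = 0.50, max_items = 22L,
                       min_items = 1L, theta_min = -4, theta_max = 4,
                       n_grid_points = 49L, prior_mean = 0, prior_sd = 1,
                       policy = selection_policy()) {
  if (!is.finite(se_threshold) || se_threshold < 0)
    stop("se_threshold must be >= 0", call. = FALSE)
  max_items <- as.integer(max_items)
  min_items <- as.integer(min_items)
  if (min_items < 1L || min_items > max_items)
    stop("need 1 <= min_items <= max_items", call. = FALSE)
  structure(list(se_threshold = se_threshold, max_items = max_items,
                 min_items = min_items, theta_min = theta_min,
                 theta_max = theta_max, n_grid_points = n_grid_points,
                 prior_mean = prior_mean, prior_sd = prior_sd,
                 policy = policy),
            class = "cat_config")
}

#' @export
print.cat_config <- function(x, ...) {
  cat(sprintf(
    "CAT config: stop at SE <= %.2f or %d items (min %d); grid %d pts on [%g, %g]; prior N(%g, %g); selection %s\n",
    x$se_threshold, x$max_items, x$min_items, x$n_grid_points,
    x$theta_min, x$theta_max, x$prior_mean, x$prior_sd^2,
    x$policy$method))
  invisible(x)
}

config_grid <- function(config) {
  make_grid(config$theta_min, config$theta_max, config$n_grid_points,
            config$prior_mean, config$prior_sd)
}

#' Dual stopping rule
#'
#' Continue while fewer than `min_items` responses are in; otherwise stop
#' with reason `"se_reached"` when the current SE is at or below the
#' threshold, else with `"max_items"` when the cap is hit. The SE rule wins
#' when both hold simultaneously.
#'
#' @param current_se Posterior SD after the last absorbed response.
#' @param n_administered Responses absorbed so far.
#' @param config A [cat_config()].
#' @return List with logical `stop` and `reason`
#'   (`"se_reached"`, `"max_items"`, or `NA`).
#' @export
should_stop <- function(current_se, n_administered, config) {
  if (n_administered < config$min_items)
    return(list(stop = FALSE, reason = NA_character_))
  if (current_se <= config$se_threshold)
    return(list(stop = TRUE, reason = "se_reached"))
  if (n_administered >= config$max_items)
    return(list(stop = TRUE, reason = "max_items"))
  list(stop = FALSE, reason = NA_character_)
}

#' Run one adaptive testing session
#'
#' The administration loop: select the next item under the policy, fetch the
#' scored response from `response_oracle`, absorb it into the posterior,
#' record the interim EAP theta and SE, and test the stopping rules.
#'
#' @param respondent_id Identifier recorded in the result.
#' @param response_oracle Either a function `item_id -> 0/1`, or a named
#'   0/1 vector indexed by item id (post-hoc replay of a recorded response
#'   row).
#' @param bank An [item_bank()].
#' @param config A [cat_config()].
#' @return A list of class `cat_result` with fields `respondent_id`,
#'   `administered`, `responses`, `interim_thetas`, `interim_ses`,
#'   `final_theta`, `final_se`, `stop_reason`.
#' @examples
#' bank <- item_bank(paste0("it", 1:5), a = rep(1.5, 5),
#'                   b = c(-2, -1, 0, 1, 2), c = rep(0.2, 5))
#' resp <- stats::setNames(c(1, 1, 0, 0, 0), bank$item_id)
#' run_cat("r1", resp, bank, cat_config(se_threshold = 0, max_items = 5))
#' @export
run_cat <- function(respondent_id, response_oracle, bank, config) {
  pre <- precompute_bank(bank, config_grid(config))
  run_cat_precomp(respondent_id, response_oracle, bank, config, pre)
}

# Per-bank precomputation shared across respondents: likelihood-of-correct
# and Fisher information for every item at every grid point, plus the
# first-item scores at theta 0.
precompute_bank <- function(bank, grid) {
  P <- outer(seq_len(nrow(bank)), seq_along(grid$points),
             function(i, k) prob_correct(bank$a[i], bank$b[i], bank$c[i],
                                         grid$points[k]))
  I <- outer(seq_len(nrow(bank)), seq_along(grid$points),
             function(i, k) item_information(bank$a[i], bank$b[i],
                                             bank$c[i], grid$points[k]))
  list(grid = grid, P = P, I = I,
       info_at_0 = item_information(bank$a, bank$b, bank$c, 0))
}

run_cat_precomp <- function(respondent_id, response_oracle, bank, config,
                            pre) {
  n_items <- nrow(bank)
  if (config$max_items > n_items)
    stop("max_items exceeds bank size", call. = FALSE)
  lookup <- if (is.function(response_oracle)) {
    response_oracle
  } else {
    resp_row <- response_oracle
    function(id) {
      if (!id %in% names(resp_row))
        stop("response matrix has no entry for item ", id, call. = FALSE)
      resp_row[[id]]
    }
  }
  grid <- pre$grid
  w <- grid$prior_weights
  avail <- rep(TRUE, n_items)
  admin <- integer(0)
  responses <- integer(0)
  thetas <- numeric(0)
  ses <- numeric(0)
  reason <- NA_character_
  first <- TRUE
  repeat {
    cand <- which(avail)
    scores <- if (first &&
                  config$policy$first_item_rule == "max_info_at_theta0") {
      pre$info_at_0[cand]
    } else if (!first && config$policy$method == "max_info_at_point") {
      th <- sum(grid$points * w)
      item_information(bank$a[cand], bank$b[cand], bank$c[cand], th)
    } else {
      as.vector(pre$I[cand, , drop = FALSE] %*% w)
    }
    sel <- cand[which.max(scores)]
    first <- FALSE
    avail[sel] <- FALSE
    r <- lookup(bank$item_id[sel])
    if (is.na(r) || !r %in% c(0, 1))
      stop("response oracle returned a non-0/1 value for item ",
           bank$item_id[sel], call. = FALSE)
    lik <- if (r == 1) pre$P[sel, ] else 1 - pre$P[sel, ]
    w <- w * lik
    w <- w / sum(w)
    th <- sum(grid$points * w)
    se <- sqrt(sum(w * (grid$points - th)^2))
    admin <- c(admin, sel)
    responses <- c(responses, as.integer(r))
    thetas <- c(thetas, th)
    ses <- c(ses, se)
    st <- should_stop(se, length(admin), config)
    if (st$stop) { reason <- st$reason; break }
    if (!any(avail))
      stop("bank exhausted before a stopping rule fired", call. = FALSE)
  }
  structure(list(respondent_id = respondent_id,
                 administered = bank$item_id[admin],
                 responses = responses,
                 interim_thetas = thetas,
                 interim_ses = ses,
                 final_theta = thetas[length(thetas)],
                 final_se = ses[length(ses)],
                 stop_reason = reason),
            class = "cat_result")
}

#' @export
print.cat_result <- function(x, ...) {
  cat(sprintf(
    "CAT session %s: %d items, final theta %.3f (SE %.3f), stopped by %s\n",
    x$respondent_id, length(x$administered), x$final_theta, x$final_se,
    x$stop_reason))
  invisible(x)
}

#' Full-length (non-adaptive) EAP score
#'
#' Scores a complete response row by absorbing every bank item into the
#' posterior, using the same EAP machinery as the adaptive loop. The result
#' is order-independent because the Bayes updates commute.
#'
#' @param responses Named 0/1 vector covering every item in the bank.
#' @param bank An [item_bank()].
#' @param config A [cat_config()] (only its grid settings are used).
#' @return List with `theta` and `se`.
#' @export
full_length_score <- function(responses, bank, config = cat_config()) {
  stopifnot(inherits(bank, "item_bank"))
  if (!all(bank$item_id %in% names(responses)))
    stop("responses missing for items: ",
         paste(setdiff(bank$item_id, names(responses)), collapse = ", "),
         call. = FALSE)
  r <- responses[bank$item_id]
  if (anyNA(r) || !all(r %in% c(0, 1)))
    stop("responses must be complete 0/1", call. = FALSE)
  grid <- config_grid(config)
  w <- grid$prior_weights
  for (i in seq_len(nrow(bank))) {
    lik <- response_likelihood(bank$a[i], bank$b[i], bank$c[i], r[[i]],
                               grid$points)
    w <- w * lik
    w <- w / sum(w)
  }
  th <- sum(grid$points * w)
  list(theta = th, se = sqrt(sum(w * (grid$points - th)^2)))
}
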