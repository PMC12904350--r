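#' Build a quadrature grid over theta
#'
#' Equally spaced points on `[theta_min, theta_max]` with prior weights
#' proportional to the normal density times trapezoid-rule quadrature
#' weights (interior points weighted equally, the two endpoints halved),
#' renormalized to sum to one. The trapezoid weighting makes the discrete
#' posterior a proper quadrature of the continuous one, which matters when
#' the posterior piles up against a grid boundary. The grid carries the
#' latent-trait scale: theta is standardized (population mean 0, SD 1) and
#' the default range is -4 to 4. Renormalizing on a finite range truncates
#' the normal prior, so the on-grid prior SD is slightly below the nominal
#' `prior_sd` (about 0.9996 for the defaults).
#'
#' @param theta_min,theta_max Grid range; `theta_min < theta_max`.
#' @param n_points Number of grid points (>= 2). Default 49.
#' @param prior_mean,prior_sd Normal prior parameters; `prior_sd > 0`.
#' @return A list of class `theta_grid` with elements `points` (strictly
#'   increasing numeric) and `prior_weights` (nonnegative, summing to 1).
#' @examples
#' g <- make_grid()
#' sum(g$prior_weights)  # 1
#' @export
make_grid <- function(theta_min = -4, theta_max = 4, n_points = 49,
                      prior_mean = 0, prior_sd = 1) {
  if (!is.finite(theta_min) || !is.finite(theta_max) ||
      theta_min >= theta_max)
    stop("need theta_min < theta_max, both finite", call. = FALSE)
  if (n_points < 2L) stop("n_points must be >= 2", call. = FALSE)
  if (!is.finite(prior_sd) || prior_sd <= 0)
    stop("prior_sd must be > 0", call. = FALSE)
  pts <- seq(theta_min, theta_max, length.out = n_points)
  tw <- rep(1, n_points)
  tw[c(1L, n_points)] <- 0.5
  w <- tw * stats::dnorm(pts, mean = prior_mean, sd = prior_sd)
  w <- w / sum(w)
  structure(list(points = pts, prior_weights = w), class = "theta_grid")
}

#' Initialize the theta posterior at the prior
#'
#' @param grid A [make_grid()] object.
#' @return A list of class `posterior_state` with elements `grid`, `weights`
#'   (equal to the prior weights) and `n_updates = 0`.
#' @export
init_posterior <- function(grid) {
  stopifnot(inherits(grid, "theta_grid"))
  structure(list(grid = grid, weights = grid$prior_weights,
                 n_updates = 0L),
            class = "posterior_state")
}

#' Absorb one scored response into the posterior
#'
#' Bayes step on the quadrature grid: the posterior weight at each point is
#' multiplied by the Bernoulli likelihood of the observed response at that
#' point and renormalized. Updates commute, so the posterior after a set of
#' responses does not depend on administration order (up to floating error).
#'
#' @param state A [init_posterior()] state.
#' @param a,b,c 3PL parameters of the administered item.
#' @param response 0 or 1.
#' @return The updated `posterior_state` (`n_updates` incremented).
#' @export
update_posterior <- function(state, a, b, c, response) {
  stopifnot(inherits(state, "posterior_state"))
  lik <- response_likelihood(a, b, c, response, state$grid$points)
  w <- state$weights * lik
  s <- sum(w)
  if (!is.finite(s) || s <= 0)
    stop("posterior mass vanished during update", call. = FALSE)
  state$weights <- w / s
  state$n_updates <- state$n_updates + 1L
  state
}

#' Expected-a-posteriori (EAP) theta estimate
#'
#' The posterior mean \eqn{\sum_k \theta_k w_k} over the quadrature grid.
#'
#' @param state A `posterior_state`.
#' @return Scalar theta estimate, within the grid range.
#' @export
eap_theta <- function(state) {
  stopifnot(inherits(state, "posterior_state"))
  sum(state$grid$points * state$weights)
}

#' Posterior standard deviation (the EAP standard error)
#'
#' \eqn{\sqrt{\sum_k w_k (\theta_k - \hat\theta)^2}} with \eqn{\hat\theta}
#' the EAP estimate. Used as the reported standard error throughout.
#'
#' @param state A `posterior_state`.
#' @return Nonnegative scalar.
#' @export
posterior_sd <- function(state) {
  stopifnot(inherits(state, "posterior_state"))
  m <- sum(state$grid$points * state$weights)
  sqrt(sum(state$weights * (state$grid$points - m)^2))
}

#' @export
print.posterior_state <- function(x, ...) {
  cat(sprintf(
    "theta posterior on %d-point grid [%g, %g]: EAP %.4f, SD %.4f (%d responses absorbed)\n",
    length(x$grid$points), min(x$grid$points), max(x$grid$points),
    eap_theta(x), posterior_sd(x), x$n_updates))
  invisible(x)
}
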