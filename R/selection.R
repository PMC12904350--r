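#' Item-selection policy
#'
#' Controls how the next item is chosen. `mpwi` (the default and the method
#' with the strongest precision record) scores each candidate by its Fisher
#' information integrated against the current theta posterior;
#' `max_info_at_point` scores by Fisher information at the current EAP point
#' estimate. The first item is chosen before any response exists:
#' `max_info_at_theta0` takes maximum Fisher information at theta = 0 (the
#' conventional first-item location), `mpwi_under_prior` applies MPWI with
#' the prior as posterior — for a symmetric prior centred at 0 the two
#' usually agree. Ties are always broken by lowest bank index, so selection
#' is deterministic.
#'
#' @param method `"mpwi"` or `"max_info_at_point"`.
#' @param first_item_rule `"max_info_at_theta0"` or `"mpwi_under_prior"`.
#' @return A list of class `selection_policy`.
#' @export
selection_policy <- function(method = c("mpwi", "max_info_at_point"),
                             first_item_rule = c("max_info_at_theta0",
                                                 "mpwi_under_prior")) {
  structure(list(method = match.arg(method),
                 first_item_rule = match.arg(first_item_rule),
                 tie_break = "lowest-index"),
            class = "selection_policy")
}

#' Posterior-weighted information score of a candidate item
#'
#' \eqn{\sum_k I(\theta_k) w_k}: the item's Fisher information averaged over
#' the quadrature grid under the current posterior weights.
#'
#' @param state A `posterior_state`.
#' @param a,b,c 3PL parameters of the candidate item.
#' @return Nonnegative scalar score.
#' @export
posterior_weighted_information <- function(state, a, b, c) {
  stopifnot(inherits(state, "posterior_state"))
  sum(item_information(a, b, c, state$grid$points) * state$weights)
}

#' Select the next item to administer
#'
#' Scores every unadministered item in the bank under the policy and returns
#' the id of the maximizer; ties go to the lowest bank index. With
#' `state$n_updates == 0` the policy's first-item rule applies.
#'
#' @param state Current `posterior_state`.
#' @param bank An [item_bank()].
#' @param administered Character vector of item ids already used.
#' @param policy A [selection_policy()].
#' @return The selected `item_id` (length-1 character).
#' @export
select_next_item <- function(state, bank, administered = character(),
                             policy = selection_policy()) {
  stopifnot(inherits(bank, "item_bank"))
  cand <- which(!(bank$item_id %in% administered))
  if (length(cand) == 0L)
    stop("no unadministered items remain", call. = FALSE)
  scores <- candidate_scores(state, bank, cand, policy)
  bank$item_id[cand[which.max(scores)]]
}

# Scores for the candidate rows `cand` of `bank` under `policy`; which.max
# on the result honours the lowest-index tie break because `cand` is in
# bank order.
candidate_scores <- function(state, bank, cand, policy) {
  first <- state$n_updates == 0L
  if (first && policy$first_item_rule == "max_info_at_theta0") {
    return(item_information(bank$a[cand], bank$b[cand], bank$c[cand], 0))
  }
  if (!first && policy$method == "max_info_at_point") {
    th <- eap_theta(state)
    return(item_information(bank$a[cand], bank$b[cand], bank$c[cand], th))
  }
  # MPWI (also the first-item mpwi_under_prior rule, since the initial
  # posterior equals the prior)
  vapply(cand, function(i)
    posterior_weighted_information(state, bank$a[i], bank$b[i], bank$c[i]),
    numeric(1))
}
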