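# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths: probabilities via the raw exp() form,
# posteriors via a dense trapezoid grid, selection via exhaustive scoring.

ref_p3pl <- function(a, b, c, theta) {
  c + (1 - c) / (1 + exp(-a * (theta - b)))
}

ref_info <- function(a, b, c, theta) {
  P <- ref_p3pl(a, b, c, theta)
  Q <- 1 - P
  a^2 * (Q / P) * ((P - c) / (1 - c))^2
}

# EAP / posterior SD on a 10,001-point trapezoid grid over [-4, 4],
# accumulated in log space.
dense_posterior <- function(bank, resp, npts = 10001L,
                            lo = -4, hi = 4) {
  pts <- seq(lo, hi, length.out = npts)
  h <- pts[2] - pts[1]
  tw <- rep(h, npts)
  tw[c(1L, npts)] <- h / 2
  ll <- rep(0, npts)
  for (i in seq_len(nrow(bank))) {
    P <- ref_p3pl(bank$a[i], bank$b[i], bank$c[i], pts)
    ll <- ll + log(if (resp[[bank$item_id[i]]] == 1) P else 1 - P)
  }
  w <- tw * dnorm(pts) * exp(ll - max(ll))
  w <- w / sum(w)
  m <- sum(pts * w)
  list(theta = m, se = sqrt(sum(w * (pts - m)^2)))
}

# Straight-line reimplementation of the adaptive loop (49-point trapezoid
# grid, MPWI selection, first item by Fisher information at theta 0, SE /
# max-length stopping) used as a second-implementation oracle.
ref_cat_trace <- function(resp_row, bank, se_threshold, max_items,
                          n_grid = 49L) {
  pts <- seq(-4, 4, length.out = n_grid)
  tw <- rep(1, n_grid)
  tw[c(1L, n_grid)] <- 0.5
  w <- tw * dnorm(pts)
  w <- w / sum(w)
  avail <- rep(TRUE, nrow(bank))
  admin <- integer(0)
  thetas <- numeric(0)
  ses <- numeric(0)
  first <- TRUE
  reason <- NA_character_
  repeat {
    cand <- which(avail)
    sc <- if (first) {
      ref_info(bank$a[cand], bank$b[cand], bank$c[cand], 0)
    } else {
      vapply(cand, function(i)
        sum(ref_info(bank$a[i], bank$b[i], bank$c[i], pts) * w),
        numeric(1))
    }
    sel <- cand[which.max(sc)]
    first <- FALSE
    avail[sel] <- FALSE
    r <- resp_row[[bank$item_id[sel]]]
    P <- ref_p3pl(bank$a[sel], bank$b[sel], bank$c[sel], pts)
    w <- w * (if (r == 1) P else 1 - P)
    w <- w / sum(w)
    th <- sum(pts * w)
    se <- sqrt(sum(w * (pts - th)^2))
    admin <- c(admin, sel)
    thetas <- c(thetas, th)
    ses <- c(ses, se)
    if (se <= se_threshold) { reason <- "se_reached"; break }
    if (length(admin) >= max_items) { reason <- "max_items"; break }
  }
  list(administered = bank$item_id[admin], thetas = thetas, ses = ses,
       reason = reason)
}

random_bank <- function(n, prefix = "i") {
  item_bank(paste0(prefix, seq_len(n)),
            a = runif(n, 0.5, 3), b = runif(n, -3, 3),
            c = rbeta(n, 5, 20))
}

# Small synthetic cohort built from the generator defaults at reduced size.
make_cohort <- function(seed = 42L, n_respondents = 1000L, n_items = 22L) {
  spec <- synthetic_spec(n_respondents = n_respondents, n_items = n_items,
                         seed = seed)
  bank <- generate_item_bank(spec)
  thetas <- generate_thetas(n_respondents, seed = seed + 1L)
  X <- generate_response_matrix(thetas, bank, seed = seed + 2L)
  list(spec = spec, bank = bank, thetas = thetas, X = X)
}
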