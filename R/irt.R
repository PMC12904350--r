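#' Three-parameter logistic (3PL) response probability
#'
#' Probability of a correct (keyed) response under the Birnbaum 3PL model,
#' \deqn{P(\theta) = c + (1 - c) \, \mathrm{logistic}(a(\theta - b)),}
#' where `a` is the discrimination, `b` the difficulty and `c` the lower
#' asymptote (pseudo-guessing) parameter. The logistic is evaluated through
#' [stats::plogis()], which is overflow-safe for large `|a (theta - b)|`.
#'
#' @param a Discrimination (> 0), on the logit scale per unit of theta.
#' @param b Difficulty, in theta units.
#' @param c Lower asymptote, a probability in `[0, 1)`.
#' @param theta Latent-trait value(s); finite numeric vector.
#' @return Numeric vector of probabilities, `c <= P < 1`, strictly
#'   increasing in `theta`.
#' @examples
#' prob_correct(a = 1, b = 0, c = 0, theta = 0)    # 0.5
#' prob_correct(a = 2, b = 1, c = 0.2, theta = 1)  # 0.6
#' @seealso [item_information()], [response_likelihood()]
#' @export
prob_correct <- function(a, b, c, theta) {
  check_item_params(a, b, c)
  if (!is.numeric(theta) || any(!is.finite(theta)))
    stop("`theta` must be finite numeric", call. = FALSE)
  c + (1 - c) * stats::plogis(a * (theta - b))
}

#' Fisher item information under the 3PL model
#'
#' \deqn{I(\theta) = a^2 \frac{Q(\theta)}{P(\theta)}
#'   \left(\frac{P(\theta) - c}{1 - c}\right)^2,\quad Q = 1 - P.}
#' For `c = 0` this reduces to the 2PL form `a^2 P Q`. Information is
#' nonnegative and vanishes in both tails.
#'
#' @inheritParams prob_correct
#' @return Nonnegative numeric vector, same length as `theta`.
#' @examples
#' item_information(a = 1.5, b = 0, c = 0, theta = 0)  # a^2 / 4 = 0.5625
#' @export
item_information <- function(a, b, c, theta) {
  P <- prob_correct(a, b, c, theta)
  Q <- 1 - P
  a^2 * (Q / P) * ((P - c) / (1 - c))^2
}

#' Bernoulli likelihood of an observed response
#'
#' `P(theta)` for a correct response (`response = 1`), `1 - P(theta)` for an
#' incorrect one. This is the per-item likelihood contribution absorbed by
#' the posterior update in EAP scoring.
#'
#' @inheritParams prob_correct
#' @param response Scalar 0 or 1.
#' @return Numeric vector of likelihood values in `(0, 1)`.
#' @export
response_likelihood <- function(a, b, c, response, theta) {
  if (length(response) != 1L || !response %in% c(0, 1))
    stop("`response` must be a single 0 or 1", call. = FALSE)
  P <- prob_correct(a, b, c, theta)
  if (response == 1) P else 1 - P
}

check_item_params <- function(a, b, c) {
  if (!is.numeric(a) || any(!is.finite(a)) || any(a <= 0))
    stop("discrimination `a` must be finite and > 0", call. = FALSE)
  if (!is.numeric(b) || any(!is.finite(b)))
    stop("difficulty `b` must be finite", call. = FALSE)
  if (!is.numeric(c) || any(!is.finite(c)) || any(c < 0) || any(c >= 1))
    stop("lower asymptote `c` must lie in [0, 1)", call. = FALSE)
  invisible(TRUE)
}

#' Construct an item bank
#'
#' An item bank is a data frame with one row per item and columns
#' `item_id`, `a`, `b`, `c`, `content_domain`. Row order is stable and
#' index-addressable; it defines the tie-break order during item selection.
#'
#' @param item_id Character vector of unique, nonempty item identifiers.
#' @param a,b,c 3PL parameter vectors (see [prob_correct()]).
#' @param content_domain Optional character vector of content labels;
#'   recycled `""` if omitted.
#' @param metadata Optional single string recorded as a provenance
#'   attribute.
#' @return A `data.frame` of class `item_bank`.
#' @examples
#' bank <- item_bank(paste0("it", 1:3), a = c(1, 1.5, 2),
#'                   b = c(-1, 0, 1), c = c(0.2, 0.2, 0.25))
#' bank
#' @export
item_bank <- function(item_id, a, b, c, content_domain = NULL,
                      metadata = "") {
  item_id <- as.character(item_id)
  n <- length(item_id)
  if (n < 1L) stop("an item bank needs at least one item", call. = FALSE)
  if (any(!nzchar(item_id)) || anyNA(item_id))
    stop("item_id values must be nonempty", call. = FALSE)
  if (anyDuplicated(item_id))
    stop("duplicate item_id in bank: ",
         paste(unique(item_id[duplicated(item_id)]), collapse = ", "),
         call. = FALSE)
  if (length(a) != n || length(b) != n || length(c) != n)
    stop("a, b, c must match the number of item ids", call. = FALSE)
  check_item_params(a, b, c)
  if (is.null(content_domain)) content_domain <- rep("", n)
  bank <- data.frame(item_id = item_id, a = as.numeric(a),
                     b = as.numeric(b), c = as.numeric(c),
                     content_domain = as.character(content_domain),
                     stringsAsFactors = FALSE)
  attr(bank, "metadata") <- as.character(metadata)[1L]
  class(bank) <- c("item_bank", "data.frame")
  bank
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("Item bank: %d dichotomous 3PL items\n", nrow(x)))
  cat(sprintf("  a in [%.3f, %.3f]; b in [%.3f, %.3f]; c in [%.3f, %.3f]\n",
              min(x$a), max(x$a), min(x$b), max(x$b), min(x$c), max(x$c)))
  md <- attr(x, "metadata")
  if (!is.null(md) && nzchar(md)) cat("  metadata:", md, "\n")
  NextMethod()
  invisible(x)
}

#' Read / write an item bank as CSV
#'
#' Plain CSV with header columns `item_id,a,b,c,content_domain`. The reader
#' validates the 3PL parameter invariants and rejects duplicate ids.
#'
#' @param path File path.
#' @return `read_item_bank()` returns an [item_bank()]; `write_item_bank()`
#'   returns `path` invisibly.
#' @export
read_item_bank <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(item_id = "character"))
  need <- c("item_id", "a", "b", "c")
  if (!all(need %in% names(df)))
    stop("item bank file must have columns item_id,a,b,c", call. = FALSE)
  item_bank(df$item_id, df$a, df$b, df$c,
            content_domain = if ("content_domain" %in% names(df))
              df$content_domain else NULL)
}

#' @rdname read_item_bank
#' @param bank An [item_bank()].
#' @export
write_item_bank <- function(bank, path) {
  stopifnot(inherits(bank, "item_bank"))
  utils::write.csv(as.data.frame(bank), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
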