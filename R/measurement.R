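#' Item response functions
#'
#' Two-parameter logistic response for binary items and the graded
#' (cumulative-logit) response for ordinal items, in the threshold convention
#' `P(category >= s | f) = logistic(a * f - tau_s)` with strictly increasing
#' thresholds.  Probabilities are clamped to `[1e-12, 1 - 1e-12]` before logs
#' so the conditional log-likelihood stays finite for extreme latent values.
#'
#' @param tau threshold (binary) or increasing threshold vector (ordinal).
#' @param a item loading (discrimination).
#' @param v latent factor value(s); vectorized.
#' @return `binary_item_prob()`: probability of a positive response.
#'   `ordinal_category_probs()`: matrix with one row per latent value and one
#'   column per category, rows summing to 1.
#' @examples
#' binary_item_prob(tau = -2.392, a = 2.104, v = 0) # ~0.916
#' ordinal_category_probs(c(0, 2), a = 0, v = 0)
#' @export
binary_item_prob <- function(tau, a, v) {
  stopifnot(length(tau) == 1, is.finite(tau), is.finite(a))
  stats::plogis(a * v - tau)
}

#' @rdname binary_item_prob
#' @export
ordinal_category_probs <- function(tau, a, v) {
  if (any(diff(tau) <= 0)) stop("thresholds not increasing")
  K <- length(tau) + 1L
  cum <- vapply(tau, function(t) stats::plogis(a * v - t), numeric(length(v)))
  cum <- matrix(cum, nrow = length(v))
  probs <- cbind(1, cum) - cbind(cum, 0)
  colnames(probs) <- paste0("cat", seq_len(K) - 1L)
  probs
}

.clamp <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' Conditional log-likelihood of one factor's item block
#'
#' Sum of log category probabilities of the responses to the items of a single
#' first-order factor, conditional on the factor value.  Missing responses
#' contribute zero (full-information skipping).
#'
#' @param responses integer vector of 0-based category codes (NA = missing),
#'   one per item.
#' @param tau matrix with one row per item and up to two threshold columns
#'   (second column NA for binary items).
#' @param a numeric vector of item loadings.
#' @param v scalar factor value.
#' @return Scalar log-likelihood.
#' @export
item_block_conditional_loglik <- function(responses, tau, a, v) {
  tau <- matrix(tau, ncol = 2)
  stopifnot(length(responses) == nrow(tau), length(a) == nrow(tau),
            length(v) == 1)
  ll <- 0
  for (i in seq_along(responses)) {
    x <- responses[i]
    if (is.na(x)) next
    ti <- tau[i, ][!is.na(tau[i, ])]
    K <- length(ti) + 1L
    if (x < 0 || x >= K) stop(sprintf("out-of-range category code %d for item %d", x, i))
    pr <- unname(ordinal_category_probs(ti, a[i], v)[1, x + 1L])
    ll <- ll + log(.clamp(pr))
  }
  ll
}

#' Standardized loading on the latent-response scale
#'
#' Converts a logit-link item loading `a` on a factor with standard deviation
#' `sigma` to the correlation-scale loading of the underlying continuous
#' response, whose residual is standard logistic with variance `pi^2/3`:
#' `lambda = a * sigma / sqrt((a * sigma)^2 + pi^2 / 3)`.
#'
#' @param a item loading.
#' @param sigma factor standard deviation (> 0).
#' @return Standardized loading in (-1, 1); vectorized over `a`.
#' @export
standardized_loading <- function(a, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  a * sigma / sqrt((a * sigma)^2 + pi^2 / 3)
}
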