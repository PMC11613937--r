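# bivariate-normal cell probabilities for a pair of ordinal items at
# correlation rho, given per-item normal thresholds (two-step ML uses
# thresholds fixed at the margins)
pair_cell_probs <- function(tA, tB, rho) {
  rA <- length(tA) + 1L
  rB <- length(tB) + 1L
  C <- matrix(0, rA + 1L, rB + 1L) # cumulative P(X <= r, Y <= s) incl. margins
  C[rA + 1L, ] <- c(0, stats::pnorm(tB), 1)
  C[, rB + 1L] <- c(0, stats::pnorm(tA), 1)
  corr <- matrix(c(1, rho, rho, 1), 2)
  for (r in seq_len(rA - 1L))
    for (s in seq_len(rB - 1L))
      C[r + 1L, s + 1L] <- mvtnorm::pmvnorm(
        upper = c(tA[r], tB[s]), corr = corr,
        algorithm = mvtnorm::Miwa())[1]
  P <- C[-1, -1, drop = FALSE] - C[-(rA + 1L), -1, drop = FALSE] -
    C[-1, -(rB + 1L), drop = FALSE] + C[-(rA + 1L), -(rB + 1L), drop = FALSE]
  pmax(P, 1e-12)
}

polychoric_rho <- function(tab, tA, tB) {
  nll <- function(rho) -sum(tab * log(pair_cell_probs(tA, tB, rho)))
  stats::optimize(nll, c(-0.999, 0.999), tol = 1e-5)$minimum
}

#' Polychoric / tetrachoric correlation matrix
#'
#' Two-step maximum likelihood: thresholds of an underlying standard normal
#' variable are fixed at the inverse-normal cumulative margins of each item,
#' then each pairwise correlation maximizes the bivariate-normal likelihood of
#' the cross-tabulation (1-D search; bivariate rectangle probabilities from
#' `mvtnorm`).  Items with a single observed category are excluded with a
#' warning.
#'
#' @param X integer matrix of 0-based category codes (NA allowed), columns
#'   named by item.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
polychoric_matrix <- function(X) {
  keep <- vapply(seq_len(ncol(X)), function(j)
    length(unique(X[!is.na(X[, j]), j])) >= 2, logical(1))
  if (!all(keep)) {
    warning(sprintf("excluding single-category item(s): %s",
                    paste(colnames(X)[!keep], collapse = ", ")))
    X <- X[, keep, drop = FALSE]
  }
  p <- ncol(X)
  thr <- lapply(seq_len(p), function(j) {
    x <- X[!is.na(X[, j]), j]
    cums <- cumsum(table(factor(x, levels = sort(unique(x)))))/length(x)
    stats::qnorm(cums[-length(cums)])
  })
  R <- diag(1, p)
  dimnames(R) <- list(colnames(X), colnames(X))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    ok <- !is.na(X[, i]) & !is.na(X[, j])
    tab <- table(factor(X[ok, i], levels = sort(unique(X[!is.na(X[, i]), i]))),
                 factor(X[ok, j], levels = sort(unique(X[!is.na(X[, j]), j]))))
    R[i, j] <- R[j, i] <- polychoric_rho(tab, thr[[i]], thr[[j]])
  }
  R
}

smooth_psd <- function(R, tol = 1e-6) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= tol) return(R)
  warning("correlation matrix not positive definite; eigenvalues clipped")
  v <- pmax(e$values, tol)
  S <- e$vectors %*% diag(v) %*% t(e$vectors)
  D <- diag(1 / sqrt(diag(S)))
  out <- D %*% S %*% D
  dimnames(out) <- dimnames(R)
  out
}

#' Exploratory factor analysis of a correlation matrix
#'
#' Maximum-likelihood factor extraction (`stats::factanal`) followed by an
#' oblique promax rotation by default (the first-order factors are correlated
#' through their second-order trait, so an oblique solution is the natural
#' default).  The solution is canonicalized: columns ordered by explained
#' variance, each column's sign chosen so its largest absolute loading is
#' positive.
#'
#' @param R correlation matrix (smoothed to positive definite if needed).
#' @param n_factors number of factors to extract (< number of items).
#' @param rotation `"promax"`, `"varimax"` or `"none"`.
#' @return Loading matrix (items x factors).
#' @export
efa_extract <- function(R, n_factors, rotation = c("promax", "varimax", "none")) {
  rotation <- match.arg(rotation)
  if (n_factors >= ncol(R)) stop("n_factors must be smaller than the number of items")
  R <- smooth_psd(R)
  fa <- stats::factanal(covmat = R, factors = n_factors, rotation = "none")
  L <- unclass(fa$loadings)
  if (n_factors > 1 && rotation != "none") {
    L <- if (rotation == "promax") unclass(stats::promax(L)$loadings)
      else unclass(stats::varimax(L)$loadings)
  }
  ord <- order(colSums(L^2), decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  for (j in seq_len(ncol(L)))
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  colnames(L) <- paste0("F", seq_len(ncol(L)))
  L
}

#' Suggest the number of factors (Kaiser criterion)
#'
#' Counts the eigenvalues of the correlation matrix exceeding 1; the full
#' eigenvalue list is attached as an attribute so alternative criteria can be
#' eyeballed.
#'
#' @param R correlation matrix.
#' @return Integer count with attribute `eigenvalues`.
#' @export
suggest_nfactors <- function(R) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  structure(sum(ev > 1), eigenvalues = ev)
}

#' Composite reliability and average variance extracted
#'
#' `composite_reliability(lambda) = (sum lambda)^2 / ((sum lambda)^2 +
#' sum(1 - lambda^2))`; `average_variance_extracted(lambda) = mean(lambda^2)`,
#' both on standardized loadings.  The conventional reading is CR >= 0.6 for
#' reliability and AVE >= 0.5 for construct validity.
#'
#' @param lambda numeric vector of standardized loadings in (-1, 1).
#' @return Scalar in `[0, 1]`.
#' @export
composite_reliability <- function(lambda) {
  if (length(lambda) == 0) stop("empty loading list")
  if (any(abs(lambda) >= 1)) stop("standardized loadings must lie in (-1, 1)")
  sum(lambda)^2 / (sum(lambda)^2 + sum(1 - lambda^2))
}

#' @rdname composite_reliability
#' @export
average_variance_extracted <- function(lambda) {
  if (length(lambda) == 0) stop("empty loading list")
  if (any(abs(lambda) >= 1)) stop("standardized loadings must lie in (-1, 1)")
  mean(lambda^2)
}

#' Construct reliability and validity report
#'
#' For every first-order factor, standardizes the item loadings onto the
#' latent-response scale (see [standardized_loading()]) using the factor
#' standard deviation implied by the structural model -- `sqrt(beta^2 + 1)`
#' for a violence-side factor, `sqrt(theta^2 (gamma^2 + 1) + 1)` for a
#' cost-side factor, residual variances being fixed at 1 -- and computes CR
#' and AVE with the conventional 0.6 / 0.5 flags.
#'
#' @param params a `dv_params`.
#' @param spec the matching `dv_spec`.
#' @return Tibble with one row per construct: `construct`, `side`,
#'   `n_items`, `CR`, `AVE`, `cr_ok`, `ave_ok`, and a list-column `lambda` of
#'   standardized loadings.
#' @export
reliability_report <- function(params, spec = default_ecgbvs_spec()) {
  rows <- lapply(seq_len(nrow(spec$factors)), function(i) {
    f <- spec$factors$name[i]
    side <- spec$factors$side[i]
    sigma <- if (side == "violence") sqrt(params$beta[f]^2 + 1)
      else sqrt(params$theta[f]^2 * (params$gamma^2 + 1) + 1)
    it <- spec$items$name[spec$items$factor == f]
    lam <- standardized_loading(params$loadings[it], sigma)
    tibble::tibble(construct = f, side = side, n_items = length(it),
                   CR = composite_reliability(lam),
                   AVE = average_variance_extracted(lam),
                   cr_ok = NA, ave_ok = NA, lambda = list(lam))
  })
  out <- do.call(rbind, rows)
  out$cr_ok <- out$CR >= 0.6
  out$ave_ok <- out$AVE >= 0.5
  out
}
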