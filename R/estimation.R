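#' Gauss-Hermite quadrature grid for standard-normal expectations
#'
#' Nodes and weights (from `statmod::gauss.quad.prob`) such that
#' `sum(w * f(x))` approximates `E[f(Z)]`, `Z ~ N(0,1)`.  The outer grid
#' integrates the two second-order latent dimensions (Violence and the Cost
#' disturbance), the inner grid each first-order factor disturbance.
#'
#' @param n_outer points per outer dimension (default 15).
#' @param n_inner points for each inner factor integral (default 15).
#' @return List of class `dv_grid` with `nodes_out`, `w_out`, `nodes_in`,
#'   `w_in`.
#' @export
quadrature_grid <- function(n_outer = 15, n_inner = 15) {
  go <- statmod::gauss.quad.prob(n_outer, dist = "normal")
  gi <- statmod::gauss.quad.prob(n_inner, dist = "normal")
  structure(list(nodes_out = go$nodes, w_out = go$weights,
                 nodes_in = gi$nodes, w_in = gi$weights),
            class = "dv_grid")
}

# assemble the engine arguments shared by likelihood / gradient calls
engine_args <- function(items, params, spec, covariates = NULL) {
  info <- spec_item_info(spec)
  if (!identical(colnames(items), info$name))
    items <- items[, info$name, drop = FALSE]
  fac <- spec$factors$name
  side <- ifelse(spec$factors$side == "cost", 1L, 0L)
  bstr <- numeric(length(fac))
  names(bstr) <- fac
  bstr[names(params$beta)] <- params$beta
  if (length(params$theta)) bstr[names(params$theta)] <- params$theta
  n <- nrow(items)
  if (!is.null(params$omega)) {
    if (is.null(covariates))
      stop("params include omega but no covariates were supplied")
    Z <- as.matrix(covariates[, names(params$omega), drop = FALSE])
    if (any(!is.finite(Z))) stop("covariates must be complete for analysed rows")
    offset <- as.numeric(Z %*% params$omega)
  } else {
    Z <- matrix(0, n, 0)
    offset <- numeric(0)
  }
  list(X = matrix(as.integer(items), nrow = n,
                  dimnames = dimnames(items)),
       item_fac = match(info$factor, fac) - 1L,
       ncat = info$ncat,
       tau1 = unname(params$tau[info$name, 1]),
       tau2 = {
         t2 <- unname(params$tau[info$name, 2])
         t2[is.na(t2)] <- 0
         t2
       },
       a = unname(params$loadings[info$name]),
       fac_side = side, bstr = unname(bstr),
       gamma = if (is.finite(params$gamma)) params$gamma else 0,
       offset = offset, Z = Z)
}

#' Marginal log-likelihood by nested quadrature
#'
#' Integrates the latent variables out of the joint response distribution:
#' a 2-D outer Gauss-Hermite grid over (Violence, Cost disturbance) and,
#' conditional on the second-order values, one 1-D inner grid per first-order
#' factor disturbance (conditional independence of items makes the inner
#' integrals independent).  Rows with all items missing contribute zero.
#'
#' @param items integer matrix of 0-based category codes (NA = missing),
#'   columns named by item.
#' @param params a `dv_params`.
#' @param spec the matching `dv_spec`.
#' @param grid a [quadrature_grid()].
#' @param covariates covariate data for the Violence regression (iff
#'   `params$omega` present).
#' @param per_subject return the vector of per-subject log-likelihoods
#'   instead of their sum.
#' @return Scalar log-likelihood (or per-subject vector).
#' @export
marginal_loglik <- function(items, params, spec, grid = quadrature_grid(),
                            covariates = NULL, per_subject = FALSE) {
  ea <- engine_args(items, params, spec, covariates)
  out <- loglik_engine(ea$X, ea$item_fac, ea$ncat, ea$tau1, ea$tau2, ea$a,
                       ea$fac_side, ea$bstr, ea$gamma, ea$offset, ea$Z,
                       grid$nodes_out, grid$w_out, grid$nodes_in, grid$w_in,
                       FALSE, per_subject)
  if (per_subject) out$persub else out$loglik
}

marginal_loglik_grad <- function(items, params, spec, grid, covariates = NULL) {
  ea <- engine_args(items, params, spec, covariates)
  loglik_engine(ea$X, ea$item_fac, ea$ncat, ea$tau1, ea$tau2, ea$a,
                ea$fac_side, ea$bstr, ea$gamma, ea$offset, ea$Z,
                grid$nodes_out, grid$w_out, grid$nodes_in, grid$w_in,
                TRUE, FALSE)
}

#' Monte-Carlo likelihood oracle
#'
#' Brute-force marginal likelihood for small models: latent variables are
#' sampled from their generative distributions and the conditional response
#' probability averaged.  The estimate shares one draw set across subjects;
#' the standard error of the total log-likelihood accounts for the induced
#' covariance via the delta method.  Guarded to at most 200 subjects -- this
#' is a testing oracle, not an estimator.
#'
#' @inheritParams marginal_loglik
#' @param n_draws Monte-Carlo sample size.
#' @param seed integer seed.
#' @return List with `loglik`, `se`, `n_draws`.
#' @export
mc_loglik_oracle <- function(items, params, spec, n_draws = 2e5, seed = 1L,
                             covariates = NULL) {
  n <- nrow(items)
  if (n > 200) stop("mc_loglik_oracle is guarded to <= 200 subjects")
  if (as.double(n_draws) * n > 5e7) stop("n_draws * n too large")
  info <- spec_item_info(spec)
  items <- items[, info$name, drop = FALSE]
  lat <- with_local_seed(seed, {
    off <- if (!is.null(params$omega)) {
      Z <- as.matrix(covariates[, names(params$omega), drop = FALSE])
      Z %*% params$omega
    } else matrix(0, n, 1)
    V <- stats::rnorm(n_draws)
    C <- if (length(params$theta)) params$gamma * V + stats::rnorm(n_draws) else NULL
    fnames <- c(names(params$beta), names(params$theta))
    fmat <- matrix(NA_real_, n_draws, length(fnames),
                   dimnames = list(NULL, fnames))
    for (f in names(params$beta)) fmat[, f] <- params$beta[f] * V + stats::rnorm(n_draws)
    for (f in names(params$theta)) fmat[, f] <- params$theta[f] * C + stats::rnorm(n_draws)
    list(V = V, fmat = fmat, off = as.numeric(off))
  })
  # per-subject conditional likelihood across draws
  likmat <- matrix(NA_real_, n_draws, n)
  vio_shift <- !is.null(params$omega)
  for (s in seq_len(n)) {
    lik <- rep(1, n_draws)
    for (i in seq_along(info$name)) {
      x <- items[s, i]
      if (is.na(x)) next
      nm <- info$name[i]
      fcol <- lat$fmat[, info$factor[i]]
      if (vio_shift && info$factor[i] %in% names(params$beta))
        fcol <- fcol + params$beta[info$factor[i]] * lat$off[s]
      if (vio_shift && info$factor[i] %in% names(params$theta))
        fcol <- fcol + params$theta[info$factor[i]] * params$gamma * lat$off[s]
      ti <- params$tau[nm, ][!is.na(params$tau[nm, ])]
      pr <- ordinal_category_probs(ti, params$loadings[nm], fcol)[, x + 1L]
      lik <- lik * pr
    }
    likmat[, s] <- lik
  }
  m <- colMeans(likmat)
  loglik <- sum(log(m))
  r <- as.numeric(likmat %*% (1 / m)) # per-draw influence on the total
  se <- stats::sd(r) / sqrt(n_draws)
  list(loglik = loglik, se = se, n_draws = n_draws)
}

## ---- free-parameter packing -------------------------------------------------

# free vector layout: tau1 (all items), logdtau (ordinal items), a (all items),
# beta (violence factors), theta (cost factors), gamma (if cost side),
# omega (if covariates active)
par_pack <- function(params, spec) {
  info <- spec_item_info(spec)
  ord <- info$name[info$ncat >= 3L]
  v <- c(stats::setNames(params$tau[info$name, 1], paste0("tau1.", info$name)),
         if (length(ord))
           stats::setNames(log(params$tau[ord, 2] - params$tau[ord, 1]),
                           paste0("logdtau.", ord)),
         stats::setNames(params$loadings[info$name], paste0("a.", info$name)),
         stats::setNames(params$beta, paste0("beta.", names(params$beta))))
  if (length(params$theta))
    v <- c(v, stats::setNames(params$theta, paste0("theta.", names(params$theta))),
           gamma = params$gamma)
  if (!is.null(params$omega))
    v <- c(v, stats::setNames(params$omega, paste0("omega.", names(params$omega))))
  v
}

par_unpack <- function(v, spec, template) {
  info <- spec_item_info(spec)
  ord <- info$name[info$ncat >= 3L]
  tau <- matrix(NA_real_, length(info$name), 2,
                dimnames = list(info$name, c("t1", "t2")))
  tau[, 1] <- v[paste0("tau1.", info$name)]
  if (length(ord))
    tau[ord, 2] <- tau[ord, 1] + exp(v[paste0("logdtau.", ord)])
  loadings <- stats::setNames(v[paste0("a.", info$name)], info$name)
  vf <- names(template$beta)
  beta <- stats::setNames(v[paste0("beta.", vf)], vf)
  cf <- names(template$theta)
  theta <- if (length(cf)) stats::setNames(v[paste0("theta.", cf)], cf) else numeric(0)
  gamma <- if (length(cf)) unname(v["gamma"]) else NA_real_
  omega <- if (!is.null(template$omega))
    stats::setNames(v[paste0("omega.", names(template$omega))],
                    names(template$omega)) else NULL
  dv_params(spec, tau, loadings, beta, theta, gamma, omega)
}

# gradient of loglik w.r.t. the free vector, from engine partials
grad_pack <- function(g, v, spec, template) {
  info <- spec_item_info(spec)
  ord <- which(info$ncat >= 3L)
  gt1 <- g$grad_tau1
  out <- c(stats::setNames(gt1 + g$grad_tau2, paste0("tau1.", info$name)),
           if (length(ord))
             stats::setNames(g$grad_tau2[ord] *
                               exp(v[paste0("logdtau.", info$name[ord])]),
                             paste0("logdtau.", info$name[ord])),
           stats::setNames(g$grad_a, paste0("a.", info$name)))
  fac <- spec$factors$name
  gb <- stats::setNames(g$grad_b, fac)
  out <- c(out, stats::setNames(gb[names(template$beta)],
                                paste0("beta.", names(template$beta))))
  if (length(template$theta))
    out <- c(out, stats::setNames(gb[names(template$theta)],
                                  paste0("theta.", names(template$theta))),
             gamma = g$grad_gamma)
  if (!is.null(template$omega))
    out <- c(out, stats::setNames(g$grad_omega,
                                  paste0("omega.", names(template$omega))))
  out
}

## ---- starting values --------------------------------------------------------

start_values <- function(items, spec, include_covariates = FALSE,
                         covariate_names = NULL) {
  info <- spec_item_info(spec)
  n <- nrow(items)
  tau <- matrix(NA_real_, length(info$name), 2,
                dimnames = list(info$name, c("t1", "t2")))
  for (i in seq_along(info$name)) {
    x <- items[, info$name[i]]
    x <- x[!is.na(x)]
    K <- info$ncat[i]
    for (s in seq_len(K - 1L)) {
      r <- mean(x >= s)
      r <- min(max(r, 1 / (2 * n)), 1 - 1 / (2 * n))
      tau[i, s] <- -stats::qlogis(r)
    }
    if (K == 3L && tau[i, 2] <= tau[i, 1]) tau[i, 2] <- tau[i, 1] + 0.5
  }
  loadings <- stats::setNames(rep(1, length(info$name)), info$name)
  vf <- spec$factors$name[spec$factors$side == "violence"]
  cf <- spec$factors$name[spec$factors$side == "cost"]
  dv_params(spec, tau, loadings,
            beta = stats::setNames(rep(0.5, length(vf)), vf),
            theta = if (length(cf)) stats::setNames(rep(0.5, length(cf)), cf)
              else numeric(0),
            gamma = if (length(cf)) 0.5 else NA_real_,
            omega = if (include_covariates)
              stats::setNames(rep(0, length(covariate_names)), covariate_names)
              else NULL)
}

## ---- model fitting ----------------------------------------------------------

#' Fit the latent trait model by marginal maximum likelihood
#'
#' Maximizes the nested-quadrature marginal log-likelihood with analytic
#' gradients using L-BFGS-B.  Threshold ordering of three-category items is
#' enforced by optimizing the log threshold gap.  Rows with all items missing
#' are dropped (with an audit count).  Deterministic given data, starting
#' values and options.
#'
#' @inheritParams marginal_loglik
#' @param start optional `dv_params` of starting values; defaults to logit
#'   thresholds from observed margins, unit loadings, structural coefficients
#'   0.5, zero covariate effects.
#' @param include_covariates fit the Violence-on-covariates regression.
#' @param se compute observed-information standard errors after convergence.
#' @param control list: `maxit` (default 500), `pgtol` (gradient sup-norm
#'   tolerance, default 1e-4), `factr` (L-BFGS-B relative tolerance),
#'   `trace`.
#' @return A `dv_fit`: estimates (`params`), free-parameter vector, standard
#'   errors and Wald p-values (when requested and available), maximized
#'   log-likelihood, AIC/BIC, convergence diagnostics and counts.
#' @export
fit_model <- function(items, spec, grid = quadrature_grid(),
                      covariates = NULL, include_covariates = FALSE,
                      start = NULL, se = FALSE, control = list()) {
  ctl <- utils::modifyList(list(maxit = 500L, pgtol = 1e-4, factr = 1e7,
                                trace = 0L), control)
  info <- spec_item_info(spec)
  items <- items[, info$name, drop = FALSE]
  allmiss <- rowSums(!is.na(items)) == 0
  n_dropped <- sum(allmiss)
  if (n_dropped > 0) {
    items <- items[!allmiss, , drop = FALSE]
    if (!is.null(covariates)) covariates <- covariates[!allmiss, , drop = FALSE]
  }
  n <- nrow(items)
  covnames <- if (include_covariates) spec$covariates$name else NULL
  if (include_covariates) {
    if (is.null(covariates)) stop("include_covariates = TRUE but no covariates given")
    Z <- as.matrix(covariates[, covnames, drop = FALSE])
    kp <- kappa(qr.R(qr(cbind(1, scale(Z, scale = FALSE)))))
    if (!is.finite(kp) || kp > 1e8)
      warning(sprintf("covariates look collinear (condition number %.3g)", kp))
  }
  # optimize with centered, unit-variance covariates: a raw-unit age column
  # makes the mean of omega'Z trade off against every threshold and the
  # search crawls; the reparameterization is exact and undone afterwards
  cov_mu <- NULL
  cov_sd <- NULL
  cov_fit <- covariates
  if (include_covariates) {
    Zr <- as.matrix(covariates[, covnames, drop = FALSE])
    cov_mu <- colMeans(Zr)
    cov_sd <- apply(Zr, 2, stats::sd)
    if (any(cov_sd == 0)) stop("constant covariate column")
    cov_fit <- as.data.frame(scale(Zr, center = cov_mu, scale = cov_sd))
  }
  if (is.null(start))
    start <- start_values(items, spec, include_covariates, covnames)
  template <- start
  v0 <- par_pack(start, spec)

  if (include_covariates && !is.null(start$omega))
    v0 <- par_pack(params_rescale(start, spec, cov_mu, cov_sd,
                                  to_scaled = TRUE), spec)
  negll <- function(v) {
    p <- par_unpack(v, spec, template)
    -marginal_loglik(items, p, spec, grid, cov_fit)
  }
  neggr <- function(v) {
    p <- par_unpack(v, spec, template)
    g <- marginal_loglik_grad(items, p, spec, grid, cov_fit)
    -grad_pack(g, v, spec, template)
  }
  opt <- stats::optim(v0, negll, neggr, method = "L-BFGS-B",
                      control = list(maxit = ctl$maxit, pgtol = ctl$pgtol,
                                     factr = ctl$factr, trace = ctl$trace))
  est_s <- par_unpack(opt$par, spec, template)
  est <- if (include_covariates)
    params_rescale(est_s, spec, cov_mu, cov_sd, to_scaled = FALSE) else est_s
  gfin <- neggr(opt$par)
  grad_norm <- max(abs(gfin))
  converged <- opt$convergence == 0
  # quasi-separation: a loading or threshold running to the boundary (a
  # threshold beyond +-14 puts a category's probability within ~1e-6 of 0/1)
  boundary <- union(names(est$loadings)[abs(est$loadings) > 25],
                    rownames(est$tau)[apply(abs(est$tau) > 14, 1, any,
                                            na.rm = TRUE)])
  k <- length(opt$par)
  ll <- -opt$value
  fit <- structure(list(
    params = est, par = par_pack(est, spec), spec = spec,
    template = template,
    loglik = ll, npar = k, n = n, n_dropped = n_dropped,
    AIC = -2 * ll + 2 * k, BIC = -2 * ll + k * log(n),
    convergence = converged, optim_convergence = opt$convergence,
    message = opt$message, counts = opt$counts, grad_norm = grad_norm,
    boundary_items = boundary, se = NULL, p_value = NULL,
    grid = c(n_outer = length(grid$nodes_out), n_inner = length(grid$nodes_in))),
    class = "dv_fit")
  if (length(boundary))
    warning(sprintf("possible quasi-separation: |loading| > 25 for %s",
                    paste(boundary, collapse = ", ")))
  if (se && converged && length(boundary)) {
    warning("standard errors withheld for a fit with boundary estimates")
    se <- FALSE
  }
  if (se && converged) {
    # information is computed in the well-conditioned scaled space and the
    # covariance mapped back through the exact reparameterization
    ses <- observed_information_se(items, est_s, spec, grid, cov_fit,
                                   template = template)
    if (ses$ok && include_covariates) {
      J <- rescale_jacobian(est_s, spec, cov_mu, cov_sd,
                            names(par_pack(est_s, spec)))
      vc <- J %*% ses$vcov %*% t(J)
      serr <- sqrt(diag(vc))
      names(serr) <- names(fit$par)
      z <- fit$par / serr
      fit$se <- serr
      fit$vcov <- vc
      fit$p_value <- 2 * stats::pnorm(-abs(z))
    } else if (ses$ok) {
      fit$se <- ses$se
      fit$vcov <- ses$vcov
      fit$p_value <- ses$p_value
    }
  }
  fit
}

# per-item multiplier linking a shift of the Violence mean to that item's
# threshold: a_i * beta_j for a violence item, a_i * theta_l * gamma for a
# cost item
item_shift_chain <- function(params, spec) {
  info <- spec_item_info(spec)
  chain <- numeric(length(info$name))
  for (i in seq_along(info$name)) {
    f <- info$factor[i]
    chain[i] <- if (f %in% names(params$beta)) params$beta[f]
      else params$theta[f] * params$gamma
  }
  params$loadings[info$name] * chain
}

# exact reparameterization between raw covariates Z and scaled (Z - mu)/sd:
# omega_scaled = omega_raw * sd, and thresholds shift by the induced change
# of the Violence mean, tau_scaled = tau_raw - a * chain * sum(omega_raw * mu)
params_rescale <- function(params, spec, mu, sd, to_scaled) {
  out <- params
  if (to_scaled) {
    m <- sum(params$omega * mu)
    out$omega <- params$omega * sd
    out$tau <- params$tau - item_shift_chain(params, spec) * m
  } else {
    out$omega <- params$omega / sd
    m <- sum(out$omega * mu)
    out$tau <- params$tau + item_shift_chain(params, spec) * m
  }
  out
}

# Jacobian of the raw free-parameter vector with respect to the scaled one,
# evaluated at the scaled estimate (tau2 enters as log(tau2 - tau1), which
# is invariant to the common shift, so only tau1 rows are non-trivial)
rescale_jacobian <- function(params_s, spec, mu, sd, par_names) {
  info <- spec_item_info(spec)
  k <- length(par_names)
  J <- diag(1, k)
  dimnames(J) <- list(par_names, par_names)
  om_raw <- params_s$omega / sd
  m <- sum(om_raw * mu)
  shift <- item_shift_chain(params_s, spec) # a_i * chain_i at scaled estimate
  for (i in seq_along(info$name)) {
    nm <- info$name[i]
    f <- info$factor[i]
    row <- paste0("tau1.", nm)
    a_i <- params_s$loadings[nm]
    if (f %in% names(params_s$beta)) {
      ch <- params_s$beta[f]
      J[row, paste0("beta.", f)] <- a_i * m
    } else {
      ch <- params_s$theta[f] * params_s$gamma
      J[row, paste0("theta.", f)] <- a_i * params_s$gamma * m
      J[row, "gamma"] <- a_i * params_s$theta[f] * m
    }
    J[row, paste0("a.", nm)] <- ch * m
    J[row, paste0("omega.", names(om_raw))] <- a_i * ch * mu / sd
  }
  for (kk in names(om_raw)) {
    row <- paste0("omega.", kk)
    J[row, row] <- 1 / sd[[kk]]
  }
  J
}

#' Fit the covariate (MIMIC) extension
#'
#' Convenience wrapper around [fit_model()] with the Violence-on-covariates
#' regression active (unit disturbance variance for identification) and
#' standard errors computed, yielding a coefficient / SE / p-value table for
#' the covariate effects.
#'
#' @inheritParams fit_model
#' @return A `dv_fit`; the covariate table is available via
#'   [covariate_table()].
#' @export
fit_covariate_model <- function(items, covariates, spec,
                                grid = quadrature_grid(), start = NULL,
                                se = TRUE, control = list()) {
  if (is.null(spec$covariates) || nrow(spec$covariates) == 0)
    stop("spec declares no covariates")
  fit_model(items, spec, grid, covariates = covariates,
            include_covariates = TRUE, start = start, se = se,
            control = control)
}

#' Covariate effect table of a fitted model
#'
#' @param fit a `dv_fit` from [fit_covariate_model()].
#' @return Tibble with covariate, coefficient, SE, p-value.
#' @export
covariate_table <- function(fit) {
  om <- fit$params$omega
  if (is.null(om)) stop("fit has no covariate effects")
  nm <- paste0("omega.", names(om))
  tibble::tibble(variable = names(om), coefficient = unname(om),
                 se = if (is.null(fit$se)) NA_real_ else unname(fit$se[nm]),
                 p_value = if (is.null(fit$p_value)) NA_real_
                   else unname(fit$p_value[nm]))
}

#' Observed-information standard errors
#'
#' Numerically differentiates the analytic score by central differences
#' (relative step 1e-4) to obtain the observed information at the optimum,
#' inverts it, and reports standard errors and two-sided Wald p-values on the
#' free-parameter scale.  A non-invertible (or not positive-definite)
#' information matrix is flagged and SEs are omitted.
#'
#' @inheritParams marginal_loglik
#' @param params parameter set at the optimum.
#' @param step relative step size.
#' @param template internal: parameter template fixing the free layout.
#' @return List with `se`, `p_value`, `vcov`, `ok`.
#' @export
observed_information_se <- function(items, params, spec,
                                    grid = quadrature_grid(),
                                    covariates = NULL, step = 1e-4,
                                    template = params) {
  v <- par_pack(params, spec)
  k <- length(v)
  gr <- function(x) {
    p <- par_unpack(x, spec, template)
    grad_pack(marginal_loglik_grad(items, p, spec, grid, covariates),
              x, spec, template)
  }
  H <- matrix(NA_real_, k, k, dimnames = list(names(v), names(v)))
  for (j in seq_len(k)) {
    h <- step * max(1, abs(v[j]))
    vp <- v; vp[j] <- v[j] + h
    vm <- v; vm[j] <- v[j] - h
    H[, j] <- (gr(vp) - gr(vm)) / (2 * h)
  }
  I <- -(H + t(H)) / 2 # observed information
  vc <- tryCatch(solve(I), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(diag(vc))) || any(diag(vc) <= 0)) {
    warning("observed information not invertible / not positive definite; SEs omitted")
    return(list(se = NULL, p_value = NULL, vcov = NULL, ok = FALSE))
  }
  se <- sqrt(diag(vc))
  z <- v / se
  list(se = se, p_value = 2 * stats::pnorm(-abs(z)), vcov = vc, ok = TRUE)
}

#' Information criteria
#'
#' `AIC = -2 loglik + 2 k`, `BIC = -2 loglik + k log(n)` with `k` the free
#' parameter count.
#'
#' @param fit a `dv_fit` (or a scalar log-likelihood).
#' @param k,n parameter count and sample size when `fit` is a scalar.
#' @return Named vector `c(AIC, BIC)`.
#' @export
information_criteria <- function(fit, k = NULL, n = NULL) {
  if (inherits(fit, "dv_fit")) {
    ll <- fit$loglik; k <- fit$npar; n <- fit$n
  } else ll <- fit
  c(AIC = -2 * ll + 2 * k, BIC = -2 * ll + k * log(n))
}

#' @export
print.dv_fit <- function(x, ...) {
  cat(sprintf("<dv_fit> loglik = %.3f, k = %d, n = %d, AIC = %.1f, BIC = %.1f\n",
              x$loglik, x$npar, x$n, x$AIC, x$BIC))
  cat(sprintf("  converged: %s (grad max-norm %.2e, %d fn evals)\n",
              x$convergence, x$grad_norm, x$counts[1]))
  if (x$n_dropped > 0)
    cat(sprintf("  dropped %d all-missing rows\n", x$n_dropped))
  invisible(x)
}

#' Text report of a fitted model in the published table layout
#'
#' Renders the estimates grouped into the five panels of the published full
#' model: measurement and structural blocks for Violence, measurement and
#' structural blocks for Cost, and the Cost-on-Violence structural block;
#' plus a covariate panel when present.
#'
#' @param fit a `dv_fit`.
#' @return Character vector of report lines (also printed).
#' @export
fit_report <- function(fit) {
  p <- fit$params
  spec <- fit$spec
  se <- fit$se
  pv <- fit$p_value
  num <- function(x) formatC(x, digits = 3, format = "f")
  getse <- function(nm) if (is.null(se) || !nm %in% names(se)) "-" else num(se[nm])
  getp <- function(nm) if (is.null(pv) || !nm %in% names(pv)) "-" else num(pv[nm])
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))
  panel_items <- function(side, title) {
    add("%s", title)
    for (f in spec$factors$name[spec$factors$side == side]) {
      add("  %s", f)
      for (nm in spec$items$name[spec$items$factor == f]) {
        t2 <- p$tau[nm, 2]
        add("    %-4s %-50s tau1=%8s  tau2=%8s  a=%8s (se %s, p %s)",
            nm, substr(spec$items$label[match(nm, spec$items$name)], 1, 50),
            num(p$tau[nm, 1]), if (is.na(t2)) "   -" else num(t2),
            num(p$loadings[nm]), getse(paste0("a.", nm)), getp(paste0("a.", nm)))
      }
    }
  }
  panel_items("violence", "Measurement Model for Domestic Violence")
  add("Structural Model for Domestic Violence")
  for (f in names(p$beta))
    add("    %-14s beta=%8s (se %s, p %s)", f, num(p$beta[f]),
        getse(paste0("beta.", f)), getp(paste0("beta.", f)))
  if (length(p$theta)) {
    panel_items("cost", "Measurement Model for Cost")
    add("Structural Model for Cost")
    for (f in names(p$theta))
      add("    %-14s theta=%8s (se %s, p %s)", f, num(p$theta[f]),
          getse(paste0("theta.", f)), getp(paste0("theta.", f)))
    add("Structural Model")
    add("    Cost ~ Violence  gamma=%8s (se %s, p %s)", num(p$gamma),
        getse("gamma"), getp("gamma"))
  }
  if (!is.null(p$omega)) {
    add("Covariate Effects on Domestic Violence")
    for (nm in names(p$omega))
      add("    %-22s coef=%8s (se %s, p %s)", nm, num(p$omega[nm]),
          getse(paste0("omega.", nm)), getp(paste0("omega.", nm)))
  }
  add("loglik %.3f  AIC %.1f  BIC %.1f  n %d  k %d", fit$loglik, fit$AIC,
      fit$BIC, fit$n, fit$npar)
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Restrict a specification or parameter set to one side of the model
#'
#' Useful for fitting the violence measurement model alone (no cost items, no
#' Cost-on-Violence regression).
#'
#' @param spec a `dv_spec`.
#' @param side `"violence"` or `"cost"`.
#' @return `subset_spec()`: a `dv_spec`; `subset_params()`: a `dv_params`.
#' @export
subset_spec <- function(spec, side = "violence") {
  stopifnot(side %in% c("violence", "cost"))
  keepf <- spec$factors$side == side
  dv_spec(spec$items[spec$items$factor %in% spec$factors$name[keepf], ],
          {
            f <- spec$factors[keepf, ]
            if (side == "cost") f$side <- "violence" # becomes the top trait
            f
          },
          spec$covariates, include_covariates = spec$include_covariates)
}

#' @rdname subset_spec
#' @param params a `dv_params`.
#' @param spec_sub the restricted spec from `subset_spec()`.
#' @export
subset_params <- function(params, spec_sub) {
  items <- spec_sub$items$name
  vf <- spec_sub$factors$name[spec_sub$factors$side == "violence"]
  str <- c(params$beta, params$theta)[vf]
  dv_params(spec_sub, params$tau[items, , drop = FALSE],
            params$loadings[items], beta = str, theta = numeric(0),
            gamma = NA_real_, omega = params$omega)
}
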