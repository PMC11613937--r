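test_that("quadrature grid integrates standard-normal expectations", {
  g <- quadrature_grid(15, 15)
  expect_equal(sum(g$w_out), 1, tolerance = 1e-12)
  expect_equal(sum(g$w_in), 1, tolerance = 1e-12)
  expect_equal(sum(g$w_out * g$nodes_out^2), 1, tolerance = 1e-10)
  expect_equal(sum(g$w_in * g$nodes_in^4), 3, tolerance = 1e-8)
})

test_that("zero-loading model reduces to independent Bernoulli likelihood", {
  t0 <- toy_violence(n_items = 2)
  t0$params$loadings[] <- 0
  t0$params$tau[, 1] <- c(0.7, -0.3)
  X <- toy_data(t0, 40, seed = 5)
  exact <- sum(dbinom(X[, 1], 1, plogis(-0.7), log = TRUE)) +
    sum(dbinom(X[, 2], 1, plogis(0.3), log = TRUE))
  for (g in list(quadrature_grid(5, 5), quadrature_grid(15, 15)))
    expect_equal(marginal_loglik(X, t0$params, t0$spec, g), exact,
                 tolerance = 1e-10)
  # with zero loadings every draw gives the same conditional likelihood, so
  # the oracle is exact up to floating error
  mc <- mc_loglik_oracle(X, t0$params, t0$spec, n_draws = 5e4, seed = 1)
  expect_lt(abs(mc$loglik - exact), 3 * mc$se + 1e-9)
})

test_that("analytic score matches numerical differentiation", {
  toy <- toy_mixed()
  spec <- toy$spec
  spec$covariates <- data.frame(name = c("z1", "z2"),
                                type = c("continuous", "binary"))
  params <- toy$params
  params$omega <- c(z1 = 0.3, z2 = -0.2)
  set.seed(31)
  Z <- data.frame(z1 = rnorm(40), z2 = rbinom(40, 1, 0.5))
  lat <- generate_latents(params, covariates = Z, seed = 32)
  X <- generate_responses(params, spec, lat, seed = 33)
  grid <- quadrature_grid(9, 9)
  v <- dvcost:::par_pack(params, spec)
  f <- function(x)
    marginal_loglik(X, dvcost:::par_unpack(x, spec, params), spec, grid, Z)
  g_an <- dvcost:::grad_pack(
    dvcost:::marginal_loglik_grad(X, params, spec, grid, Z), v, spec, params)
  g_num <- numDeriv::grad(f, v)
  expect_equal(g_an, g_num, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("monte-carlo oracle behaves like a root-n estimator", {
  toy <- toy_mixed()
  X <- toy_data(toy, 50, seed = 7)
  m1 <- mc_loglik_oracle(X, toy$params, toy$spec, n_draws = 2e4, seed = 1)
  m2 <- mc_loglik_oracle(X, toy$params, toy$spec, n_draws = 8e4, seed = 1)
  # quadrupling draws roughly halves the standard error
  expect_equal(m1$se / m2$se, 2, tolerance = 0.35)
  expect_error(mc_loglik_oracle(matrix(0L, 300, 1), toy$params, toy$spec),
               "200 subjects")
})

test_that("likelihood is invariant to item and subject reordering", {
  toy <- toy_mixed()
  X <- toy_data(toy, 60, seed = 17)
  grid <- quadrature_grid(9, 9)
  ll <- marginal_loglik(X, toy$params, toy$spec, grid)
  # per-subject contributions are permutation-invariant; only the order of
  # the final summation differs
  persub <- marginal_loglik(X, toy$params, toy$spec, grid,
                            per_subject = TRUE)
  perm_s <- sample(nrow(X))
  persub_p <- marginal_loglik(X[perm_s, ], toy$params, toy$spec, grid,
                              per_subject = TRUE)
  expect_identical(persub_p, persub[perm_s])
  perm <- sample(ncol(X))
  expect_equal(marginal_loglik(X[, perm], toy$params, toy$spec, grid), ll,
               tolerance = 1e-12)
})

test_that("fitting a toy model recovers it and is stable to starting values", {
  toy <- toy_four_factor()
  X <- toy_data(toy, 1500, seed = 23)
  grid <- quadrature_grid(15, 15)
  fit <- fit_model(X, toy$spec, grid)
  expect_true(fit$convergence)
  expect_lt(max(abs(fit$params$loadings - toy$params$loadings)), 0.5)
  # multi-start stability: perturbed starts reach the same optimum
  st <- fit$params
  set.seed(41)
  st$loadings <- st$loadings + runif(length(st$loadings), -0.2, 0.2)
  st$beta <- st$beta + runif(length(st$beta), -0.2, 0.2)
  fit2 <- fit_model(X, toy$spec, grid, start = st)
  expect_lt(abs(fit2$loglik - fit$loglik), 1e-3)
  # flipping a response against the factor's prediction lowers the likelihood
  allpos <- which(rowSums(X) == ncol(X))[1]
  persub <- marginal_loglik(X, fit$params, toy$spec, grid, per_subject = TRUE)
  Xf <- X
  Xf[allpos, 1] <- 0L
  persubf <- marginal_loglik(Xf, fit$params, toy$spec, grid,
                             per_subject = TRUE)
  expect_lt(persubf[allpos], persub[allpos])
})

test_that("observed-information standard errors scale and cross-validate", {
  toy <- toy_violence(n_items = 8, n_factors = 2, loads = 1.2, beta = 0.8)
  X1 <- toy_data(toy, 600, seed = 51)
  X2 <- rbind(X1, toy_data(toy, 600, seed = 61))
  grid <- quadrature_grid(9, 9)
  f1 <- fit_model(X1, toy$spec, grid, se = TRUE)
  f2 <- fit_model(X2, toy$spec, grid, se = TRUE)
  expect_true(all(is.finite(f1$se)))
  # doubling n shrinks SEs by about sqrt(2); thresholds are the cleanly
  # identified parameters, loadings also move with their own estimates
  taus <- grep("^tau1", names(f1$se), value = TRUE)
  expect_equal(median(f1$se[taus] / f2$se[taus]), sqrt(2), tolerance = 0.1)
  # central-difference Hessian agrees with an independent differentiator
  v <- dvcost:::par_pack(f1$params, toy$spec)
  H <- numDeriv::hessian(function(x)
    marginal_loglik(X1, dvcost:::par_unpack(x, toy$spec, f1$params),
                    toy$spec, grid), v)
  se_nd <- sqrt(diag(solve(-(H + t(H)) / 2)))
  expect_equal(unname(f1$se), se_nd, tolerance = 1e-3)
})

test_that("zero-loading submodel curvature matches the Bernoulli closed form", {
  # with its loading at 0 an item is Bernoulli(plogis(-tau)); the likelihood
  # curvature in tau at the item MLE must equal n * p * (1 - p)
  t0 <- toy_violence(n_items = 2, n_factors = 1, loads = 0, beta = 0.5)
  t0$params$tau[, 1] <- c(-0.4, 0.2)
  X <- toy_data(t0, 500, seed = 71)
  grid <- quadrature_grid(9, 9)
  phat <- mean(X[, 1])
  p <- t0$params
  p$tau[1, 1] <- -qlogis(phat) # the Bernoulli MLE for item 1
  f <- function(tau1) {
    p$tau[1, 1] <- tau1
    marginal_loglik(X, p, t0$spec, grid)
  }
  info <- -numDeriv::hessian(f, p$tau[1, 1])[1, 1]
  se_model <- 1 / sqrt(info)
  se_closed <- 1 / sqrt(nrow(X) * phat * (1 - phat))
  expect_equal(se_model, se_closed, tolerance = 0.05)
})

test_that("a perfectly separated item is flagged instead of reported", {
  toy <- toy_violence(n_items = 4, n_factors = 1, loads = 1, beta = 0.6)
  X <- toy_data(toy, 150, seed = 81)
  X[, 1] <- 1L # degenerate: always positive
  w <- testthat::capture_warnings(
    fit <- fit_model(X, toy$spec, quadrature_grid(9, 9), se = TRUE,
                     control = list(maxit = 300)))
  expect_match(w, "quasi-separation|withheld|not invertible", all = FALSE)
  expect_true(length(fit$boundary_items) > 0)
  expect_null(fit$se)
})

test_that("information criteria follow their definitions and nesting", {
  expect_equal(unname(information_criteria(-100, k = 5, n = 100)),
               c(210, 200 + 5 * log(100)))
  toy <- toy_four_factor()
  X <- toy_data(toy, 400, seed = 91)
  grid <- quadrature_grid(9, 9)
  fit <- fit_model(X, toy$spec, grid)
  expect_equal(unname(information_criteria(fit)),
               c(fit$AIC, fit$BIC))
  expect_equal(fit$npar,
               n_free_parameters(toy$spec, include_covariates = FALSE))
  # the canonical free-parameter count drives the criteria too
  expect_equal(n_free_parameters(default_ecgbvs_spec()), 90L)
  # the generating parameters lie in the parameter space, so the maximized
  # log-likelihood cannot fall below the likelihood at the truth
  expect_gte(fit$loglik,
             marginal_loglik(X, toy$params, toy$spec, grid))
})

test_that("covariate effects are recovered with their published signs", {
  spec <- default_ecgbvs_spec()
  vspec <- subset_spec(spec, "violence")
  truth <- default_true_params(spec, include_covariates = TRUE)
  vpar <- subset_params(truth, vspec)
  Z <- generate_covariates(4000, seed = 111)
  X <- simulate_canonical(vpar, vspec, 4000, seed = 112, covariates = Z)
  fit <- fit_covariate_model(X, Z, vspec, quadrature_grid(9, 9), se = FALSE)
  expect_true(fit$convergence)
  big <- names(truth$omega)[abs(truth$omega) >= 0.1]
  expect_equal(sign(fit$params$omega[big]), sign(truth$omega[big]))
  # ... and the raw-scale report reproduces the optimized likelihood exactly
  expect_equal(marginal_loglik(X, fit$params, vspec, quadrature_grid(9, 9),
                               covariates = Z),
               fit$loglik, tolerance = 1e-10)
})

test_that("collinear covariates trigger a condition-number warning", {
  spec <- default_ecgbvs_spec()
  vspec <- subset_spec(spec, "violence")
  vpar <- subset_params(default_true_params(spec), vspec)
  X <- simulate_canonical(vpar, vspec, 200, seed = 121)
  Z <- generate_covariates(200, seed = 122)
  Z$husband_age <- 2 * Z$woman_age # exact linear dependence
  expect_warning(
    try(fit_covariate_model(X, Z, vspec, quadrature_grid(5, 5), se = FALSE,
                            control = list(maxit = 2)), silent = TRUE),
    "collinear")
})

test_that("rows with every item missing are dropped with an audit count", {
  toy <- toy_mixed()
  X <- toy_data(toy, 80, seed = 99)
  X[1:3, ] <- NA_integer_
  fit <- fit_model(X, toy$spec, quadrature_grid(7, 7),
                   control = list(maxit = 200))
  expect_equal(fit$n_dropped, 3)
  expect_equal(fit$n, 77)
})
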