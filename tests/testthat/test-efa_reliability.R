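test_that("tetrachoric estimates recover known latent correlations", {
  set.seed(11)
  n <- 5000
  # rho = 0: independent underlying normals, thresholds 0
  X0 <- cbind(A = as.integer(rnorm(n) > 0), B = as.integer(rnorm(n) > 0))
  R0 <- polychoric_matrix(X0)
  expect_lt(abs(R0["A", "B"]), 3 * pi / (2 * sqrt(n)))
  # rho = 0.5 underlying
  z1 <- rnorm(n)
  z2 <- 0.5 * z1 + sqrt(1 - 0.25) * rnorm(n)
  X5 <- cbind(A = as.integer(z1 > 0), B = as.integer(z2 > 0))
  R5 <- polychoric_matrix(X5)
  expect_lt(abs(R5["A", "B"] - 0.5), 3 * pi / (2 * sqrt(n)))
  expect_equal(R5, t(R5))
  expect_equal(diag(R5), c(A = 1, B = 1))
  # polychoric case: a 3-category discretization preserves the correlation
  X3 <- cbind(A = as.integer(cut(z1, c(-Inf, -0.5, 0.7, Inf))) - 1L,
              B = as.integer(cut(z2, c(-Inf, -0.2, 1, Inf))) - 1L)
  R3 <- polychoric_matrix(X3)
  expect_lt(abs(R3["A", "B"] - 0.5), 0.06)
  # single-category items are excluded with a warning
  Xc <- cbind(X0, C = rep(1L, n))
  expect_warning(Rc <- polychoric_matrix(Xc), "single-category")
  expect_equal(colnames(Rc), c("A", "B"))
})

test_that("factor extraction recovers planted structure", {
  set.seed(21)
  # one-factor structure with known standardized loadings
  lam <- c(0.8, 0.7, 0.6, 0.75, 0.65)
  R1 <- tcrossprod(lam) + diag(1 - lam^2)
  L1 <- efa_extract(R1, 1)
  expect_equal(as.numeric(L1), lam, tolerance = 0.1)
  # identity correlation: nothing to extract
  # identity correlation: essentially nothing to extract (the ML surface is
  # flat at zero loadings, so allow the optimizer's small spurious loading)
  Li <- efa_extract(diag(6), 1)
  expect_true(all(rowSums(Li^2) < 0.1))
  expect_lt(mean(rowSums(Li^2)), 0.02)
  expect_error(efa_extract(diag(4), 4), "smaller")
  # two oblique factors: each item's top rotated loading is on its own factor
  L <- rbind(cbind(c(0.8, 0.7, 0.75), 0), cbind(0, c(0.7, 0.8, 0.65)))
  Phi <- matrix(c(1, 0.4, 0.4, 1), 2)
  R2 <- L %*% Phi %*% t(L)
  diag(R2) <- 1
  L2 <- efa_extract(R2, 2)
  top <- apply(abs(L2), 1, which.max)
  expect_equal(length(unique(top[1:3])), 1)
  expect_equal(length(unique(top[4:6])), 1)
  expect_false(top[1] == top[4])
})

test_that("Kaiser criterion counts eigenvalues above one", {
  expect_equal(as.integer(suggest_nfactors(diag(5))), 0L)
  lam <- c(0.8, 0.7, 0.6, 0.75, 0.65)
  R1 <- tcrossprod(lam) + diag(1 - lam^2)
  expect_equal(as.integer(suggest_nfactors(R1)), 1L)
  ev <- attr(suggest_nfactors(R1), "eigenvalues")
  expect_length(ev, 5)
  expect_equal(sum(ev), 5, tolerance = 1e-10)
})

test_that("CR and AVE follow their formulas and invariances", {
  expect_equal(composite_reliability(c(1, 1, 1) - 1e-12), 1, tolerance = 1e-9)
  expect_equal(composite_reliability(0.5), 0.25 / (0.25 + 0.75))
  expect_equal(average_variance_extracted(c(1, 1, 1) - 1e-12), 1,
               tolerance = 1e-9)
  expect_equal(average_variance_extracted(c(0, 0)), 0)
  # published sexual-violence construct from its standardized loadings
  lam_sex <- standardized_loading(c(3.908, 3.069, 1.972), sqrt(0.533^2 + 1))
  expect_lt(abs(composite_reliability(lam_sex) - 0.899992), 0.005)
  expect_lt(abs(average_variance_extracted(lam_sex) - 0.750954), 0.005)
  # children construct AVE from its standardized loadings
  gam <- 1.016
  lam_ch <- standardized_loading(c(3.689, 3.144, 5.533),
                                 sqrt(0.334^2 * (gam^2 + 1) + 1))
  expect_lt(abs(average_variance_extracted(lam_ch) - 0.848483), 0.005)
  # invariant to global sign flips and item order
  lam <- c(0.6, -0.4, 0.8)
  expect_equal(composite_reliability(lam), composite_reliability(-lam))
  expect_equal(average_variance_extracted(lam),
               average_variance_extracted(rev(lam)))
  expect_error(composite_reliability(numeric(0)), "empty")
  expect_error(average_variance_extracted(1.2), "\\(-1, 1\\)")
})

test_that("reliability report covers all constructs with sane flags", {
  spec <- default_ecgbvs_spec()
  rep0 <- reliability_report(default_true_params(spec), spec)
  expect_equal(nrow(rep0), 7)
  expect_true(all(rep0$CR >= 0 & rep0$CR <= 1))
  expect_true(all(rep0$AVE >= 0 & rep0$AVE <= 1))
  expect_true(all(rep0$cr_ok)) # every construct passes the 0.6 rule
  expect_equal(rep0$n_items, c(4L, 6L, 4L, 3L, 8L, 3L, 7L))
  # zero loadings give zero reliability
  p0 <- default_true_params(spec)
  p0$loadings[] <- 0
  rep1 <- reliability_report(p0, spec)
  expect_true(all(rep1$CR == 0))
  expect_true(all(rep1$AVE == 0))
})
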