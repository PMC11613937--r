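spec <- default_ecgbvs_spec()
params <- default_true_params(spec)

test_that("covariate generator is seeded, plausible and respects prevalences", {
  cov1 <- generate_covariates(1000, seed = 7)
  cov2 <- generate_covariates(1000, seed = 7)
  expect_identical(cov1, cov2)
  expect_false(identical(cov1, generate_covariates(1000, seed = 8)))
  expect_true(all(cov1$woman_age >= 18 & cov1$woman_age <= 64))
  expect_true(all(cov1$husband_age >= cov1$woman_age))
  expect_true(all(cov1$husband_salary >= 0))
  # dummies are mutually exclusive within an education variable
  expect_true(all(cov1$woman_edu_uptohs + cov1$woman_edu_abovehs <= 1))
  cov3 <- generate_covariates(10000, seed = 1,
                              prevalences = list(urban = 0.45))
  expect_lt(abs(mean(cov3$urban) - 0.45), 3 * sqrt(0.45 * 0.55 / 10000))
  expect_error(generate_covariates(0), ">= 1")
})

test_that("latent draws satisfy the structural variance algebra", {
  n <- 20000
  lat <- generate_latents(params, n, seed = 42)
  # Var(Cost) = gamma^2 + 1 with the published gamma
  expect_lt(abs(var(lat$cost) - (1.016^2 + 1)),
            3 * (1.016^2 + 1) * sqrt(2 / n))
  # Var(v_Physical) = beta^2 + 1 with the published beta
  expect_lt(abs(var(lat$factors[, "Physical"]) - (1.314^2 + 1)),
            3 * (1.314^2 + 1) * sqrt(2 / n))
  expect_gt(cor(lat$violence, lat$cost), 0.5)
  # gamma = 0 decouples Cost from Violence
  p0 <- params
  p0$gamma <- 0
  lat0 <- generate_latents(p0, n, seed = 43)
  expect_lt(abs(cor(lat0$violence, lat0$cost)), 3 / sqrt(n))
  # covariate shift enters the Violence mean
  pc <- default_true_params(spec, include_covariates = TRUE)
  cov <- generate_covariates(5000, seed = 2)
  latc <- generate_latents(pc, covariates = cov, seed = 3)
  offs <- as.numeric(as.matrix(cov[, names(pc$omega)]) %*% pc$omega)
  expect_lt(abs(mean(latc$violence - offs)), 3 / sqrt(5000))
  expect_error(generate_latents(pc, 100, seed = 1), "no covariates")
  expect_error(generate_latents(params, covariates = cov, seed = 1),
               "no omega")
})

test_that("response sampling matches the item response functions", {
  n <- 20000
  # loading 0, threshold 0: coin flip regardless of the factor
  t0 <- toy_violence(n_items = 2)
  t0$params$loadings[] <- 0
  t0$params$tau[, 1] <- 0
  X0 <- toy_data(t0, n, seed = 5)
  expect_lt(abs(mean(X0[, 1]) - 0.5), 3 * sqrt(0.25 / n))
  # X5 at factor value forced to 0 for all subjects
  lat <- generate_latents(params, n, seed = 6)
  lat$factors[, "Physical"] <- 0
  X <- generate_responses(params, spec, lat, seed = 7)
  p5 <- plogis(2.392)
  expect_lt(abs(mean(X[, "X5"]) - p5), 3 * sqrt(p5 * (1 - p5) / n))
  expect_identical(X, generate_responses(params, spec, lat, seed = 7))
})

test_that("marginal item rates converge to the quadrature closed form", {
  # E[P(x = 1)] = int P(x=1 | v) phi(v; 0, beta^2 + 1) dv for violence items
  n <- 50000
  lat <- generate_latents(params, n, seed = 9)
  X <- generate_responses(params, spec, lat, seed = 10)
  gq <- statmod::gauss.quad.prob(41, dist = "normal")
  for (nm in c("X1", "X5", "X10", "X13", "X15")) {
    f <- spec$items$factor[spec$items$name == nm]
    sigma <- sqrt(params$beta[f]^2 + 1)
    pm <- sum(gq$weights *
                binary_item_prob(params$tau[nm, 1], params$loadings[nm],
                                 sigma * gq$nodes))
    expect_lt(abs(mean(X[, nm]) - pm), 4 * sqrt(pm * (1 - pm) / n))
  }
})

test_that("raw survey generation is deterministic and filter-consistent", {
  s1 <- generate_raw_survey(500, spec, params, seed = 3)
  s2 <- generate_raw_survey(500, spec, params, seed = 3)
  expect_identical(s1$raw, s2$raw)
  expect_identical(s1$items, s2$items)
  # violated share among ever-married rows close to the configured 0.23
  s <- generate_raw_survey(20000, spec, params, seed = 5)
  em <- s$raw$ever_married == 2
  share <- mean(s$raw$ever_violated[em] == 2)
  expect_lt(abs(share - 0.23), 3 * sqrt(0.23 * 0.77 / sum(em)))
  # never-violated rows answer No to all violence items, no cost section
  nv <- s$raw$ever_violated == 1
  expect_true(all(s$raw$X5[nv] == 1))
  expect_true(all(is.na(s$raw$Y1[nv])))
  expect_error(generate_raw_survey(100, spec, params, missingness = 1.5),
               "missingness")
})

test_that("survey files round trip through disk with a provenance sidecar", {
  dir <- withr::local_tempdir()
  s <- generate_raw_survey(200, spec, params, seed = 8)
  paths <- write_survey(s, dir)
  expect_true(all(file.exists(paths)))
  side <- jsonlite::read_json(paths["sidecar"])
  expect_equal(side$seed, 8)
  expect_equal(side$n_eligible, sum(s$eligible))
  raw2 <- utils::read.csv(paths["raw"], check.names = FALSE)
  expect_equal(nrow(raw2), 200)
})
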