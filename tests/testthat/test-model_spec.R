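test_that("canonical spec has the published measurement layout", {
  spec <- default_ecgbvs_spec()
  vi <- spec$items[spec$items$factor %in%
                     spec$factors$name[spec$factors$side == "violence"], ]
  ci <- spec$items[spec$items$factor %in%
                     spec$factors$name[spec$factors$side == "cost"], ]
  expect_equal(nrow(vi), 17)
  expect_equal(length(unique(vi$factor)), 4)
  expect_equal(nrow(ci), 18)
  expect_equal(length(unique(ci$factor)), 3)
  expect_equal(nrow(spec$covariates), 11)
  expect_equal(spec$items$factor[spec$items$name == "X15"], "Sexual")
  expect_equal(spec$link, "logit")
  # three-category items are exactly those with two printed intercepts
  expect_setequal(spec$items$name[spec$items$n_categories == 3],
                  c("Y2", "Y4", "Y5", "Y9", "Y10", "Y11",
                    "Y12", "Y13", "Y15", "Y16", "Y17", "Y18"))
  # factor item counts follow the path diagram
  counts <- table(spec$items$factor)
  expect_equal(unname(c(counts[c("Economic", "Physical", "Psychological",
                                 "Sexual", "QualityOfLife", "Children",
                                 "EconomicCost")])),
               c(4L, 6L, 4L, 3L, 8L, 3L, 7L))
})

test_that("published parameter set is reproduced verbatim and is pure", {
  spec <- default_ecgbvs_spec()
  p <- default_true_params(spec)
  expect_identical(p, default_true_params(spec))
  expect_equal(unname(p$loadings["X15"]), 3.908)
  expect_equal(unname(p$gamma), 1.016)
  expect_equal(unname(p$beta["Physical"]), 1.314)
  expect_equal(unname(p$theta["Children"]), 0.334)
  expect_equal(unname(p$tau["X5", 1]), -2.392)
  expect_equal(unname(p$tau["Y9", ]), c(2.310, 7.177), ignore_attr = TRUE)
  pc <- default_true_params(spec, include_covariates = TRUE)
  expect_equal(length(pc$omega), 11)
  expect_equal(unname(pc$omega["urban"]), 0.108)
  expect_length(validate_spec(spec, p), 0)
  expect_error(default_true_params(dv_spec(
    items = data.frame(name = "A", label = "a", n_categories = 2,
                       factor = "F"),
    factors = data.frame(name = "F", side = "violence"))),
    "canonical")
})

test_that("free-parameter count is the frozen canonical value", {
  spec <- default_ecgbvs_spec()
  # 47 thresholds (17 + 6 binary-cost + 12 * 2) + 35 loadings + 4 beta +
  # 3 theta + 1 gamma
  expect_identical(n_free_parameters(spec), 90L)
  expect_identical(n_free_parameters(spec, include_covariates = TRUE), 101L)
})

test_that("validate_spec reports violated invariants as findings", {
  spec <- default_ecgbvs_spec()
  p <- default_true_params(spec)
  p$tau["Y9", 2] <- p$tau["Y9", 1] - 1
  expect_match(validate_spec(spec, p), "thresholds not increasing",
               all = FALSE)
  spec2 <- spec
  spec2$items <- rbind(spec2$items,
                       tibble::tibble(name = "X1", label = "dup",
                                      n_categories = 2L, factor = "Sexual"))
  expect_match(validate_spec(spec2), "non-simple structure", all = FALSE)
  spec3 <- spec
  spec3$items$factor[1] <- "Nonexistent"
  expect_match(validate_spec(spec3), "unresolved factor", all = FALSE)
})

test_that("YAML round trips preserve specs and parameters exactly", {
  spec <- default_ecgbvs_spec()
  params <- default_true_params(spec)
  fs <- withr::local_tempfile(fileext = ".yaml")
  fp <- withr::local_tempfile(fileext = ".yaml")
  write_spec_yaml(spec, fs)
  spec2 <- read_spec_yaml(fs)
  expect_equal(spec2$items, spec$items)
  expect_equal(spec2$factors, spec$factors)
  expect_equal(spec2$covariates, spec$covariates)
  # irrational values round trip losslessly
  params$loadings["X1"] <- pi
  params$tau["Y9", 2] <- exp(1) + 7
  write_params_yaml(params, fp)
  params2 <- read_params_yaml(fp)
  expect_identical(params2$loadings[["X1"]], pi)
  expect_identical(params2$tau["Y9", 2], exp(1) + 7)
  expect_equal(params2$loadings, params$loadings)
  expect_equal(params2$beta, params$beta)
  expect_equal(params2$gamma, params$gamma)
})
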