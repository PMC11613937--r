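#' Model specification for the two-level violence/cost latent trait model
#'
#' A `dv_spec` object declares the measurement and structural layout: which
#' items load on which first-order factor, which side (violence or cost) each
#' factor belongs to, how many response categories each item has, and which
#' socioeconomic covariates (if any) the Violence trait is regressed on.
#' Simple structure is assumed throughout: every item loads on exactly one
#' first-order factor, the violence-side factors load on a single second-order
#' "Violence" trait and the cost-side factors on a single "Cost" trait.
#'
#' @param items data frame with columns `name`, `label`, `n_categories`,
#'   `factor`.
#' @param factors data frame with columns `name` and `side`
#'   (`"violence"` or `"cost"`).
#' @param covariates data frame with columns `name` and `type`
#'   (`"continuous"`, `"binary"` or `"dummy"`), or `NULL`.
#' @param include_covariates logical; whether the Violence-on-covariates
#'   regression is part of the model.
#' @return An object of class `dv_spec`.
#' @export
dv_spec <- function(items, factors, covariates = NULL,
                    include_covariates = !is.null(covariates)) {
  items <- tibble::as_tibble(items)
  factors <- tibble::as_tibble(factors)
  if (!is.null(covariates)) covariates <- tibble::as_tibble(covariates)
  spec <- structure(
    list(items = items, factors = factors, covariates = covariates,
         include_covariates = isTRUE(include_covariates), link = "logit"),
    class = "dv_spec")
  spec
}

#' @export
print.dv_spec <- function(x, ...) {
  nv <- sum(x$factors$side == "violence")
  nc <- sum(x$factors$side == "cost")
  cat(sprintf("<dv_spec> %d items, %d violence factors, %d cost factors",
              nrow(x$items), nv, nc))
  if (!is.null(x$covariates))
    cat(sprintf(", %d covariates%s", nrow(x$covariates),
                if (x$include_covariates) " (active)" else ""))
  cat("\n")
  invisible(x)
}

#' Canonical survey configuration
#'
#' The shipped configuration of the Egyptian gender-based-violence survey
#' analysis: 17 binary spousal-violence items in four first-order factors
#' (economic, physical, psychological, sexual violence) under a second-order
#' Violence trait; 18 cost items in three factors (quality of life, cost on
#' children, economic cost) under a Cost trait; eleven socioeconomic
#' covariates.  Twelve cost items have three ordered categories (two
#' thresholds); all other items are binary.
#'
#' @return A `dv_spec` describing the canonical model.
#' @export
default_ecgbvs_spec <- function() {
  vi <- c("Preventing from work", "Taking your money", "Refusing to give money",
          "Forcing to participate in home expenses",
          "Slapping or Throwing", "Pushing or Shoving", "Hitting with his fist",
          "Kicking, Dragging or Beating", "Choking or Burning",
          "Threatening using a weapon",
          "Insulting", "Belittling or Humiliating", "Doing things to scare you",
          "Threatened to hurt you",
          "Physical force to have sexual intercourse",
          "Having sexual intercourse against your willing",
          "Forcing to do something sexual that you found degrading or humiliating")
  ci <- c("Having any injury", "Taking time off from work",
          "Stopping to do housework", "Husband taking time off work",
          "Husband stopping or reducing to offer domestic help",
          "Going to police station", "Leaving your home",
          "Case filed in court due to incident",
          "Your children were absent from school",
          "Your children suffered from problems after incident",
          "Your children's educational performance affected",
          "Payments on Health Services", "Days taken off from work were paid",
          "Days your husband took off from work were paid",
          "Payments on renewing possessions", "Payments on Police Services",
          "Payments on Legal Services", "Payments on Accommodation")
  ordinal_cost <- c("Y2", "Y4", "Y5", "Y9", "Y10", "Y11",
                    "Y12", "Y13", "Y15", "Y16", "Y17", "Y18")
  items <- tibble::tibble(
    name = c(paste0("X", 1:17), paste0("Y", 1:18)),
    label = c(vi, ci),
    n_categories = 2L,
    factor = c(rep(c("Economic", "Physical", "Psychological", "Sexual"),
                   c(4L, 6L, 4L, 3L)),
               rep(c("QualityOfLife", "Children", "EconomicCost"),
                   c(8L, 3L, 7L))))
  items$n_categories[items$name %in% ordinal_cost] <- 3L
  factors <- tibble::tibble(
    name = c("Economic", "Physical", "Psychological", "Sexual",
             "QualityOfLife", "Children", "EconomicCost"),
    side = rep(c("violence", "cost"), c(4L, 3L)))
  covariates <- tibble::tibble(
    name = c("woman_age", "husband_age", "husband_works", "husband_salary",
             "woman_edu_uptohs", "woman_edu_abovehs",
             "husband_edu_uptohs", "husband_edu_abovehs",
             "urban", "live_with_inlaws", "family_nearby"),
    type = c("continuous", "continuous", "binary", "continuous",
             "dummy", "dummy", "dummy", "dummy",
             "binary", "binary", "binary"))
  dv_spec(items, factors, covariates, include_covariates = FALSE)
}

#' Parameter set for a model specification
#'
#' Holds every free parameter of the model: item thresholds (one per binary
#' item, two strictly increasing ones per three-category item), item loadings,
#' the structural loadings of the first-order factors on their second-order
#' trait (`beta` for the violence side, `theta` for the cost side), the
#' Cost-on-Violence regression coefficient `gamma`, and optionally the
#' covariate coefficients `omega`.  All residual variances are fixed at 1 for
#' identification (unit Violence variance when no covariates, unit disturbance
#' when covariates are present) and are not free parameters.
#'
#' Item response functions use the threshold convention
#' `P(category >= s | f) = logistic(a * f - tau_s)`.
#'
#' @param spec a `dv_spec`.
#' @param tau matrix with one row per item (rownames = item names) and two
#'   columns; second column `NA` for binary items.
#' @param loadings named numeric vector of item loadings.
#' @param beta named numeric vector over violence-side factors.
#' @param theta named numeric vector over cost-side factors (may be empty).
#' @param gamma scalar Cost-on-Violence coefficient (`NA` if no cost side).
#' @param omega named numeric vector of covariate coefficients, or `NULL`.
#' @return An object of class `dv_params`.
#' @export
dv_params <- function(spec, tau, loadings, beta, theta = numeric(0),
                      gamma = NA_real_, omega = NULL) {
  structure(list(tau = tau, loadings = loadings, beta = beta, theta = theta,
                 gamma = gamma, omega = omega),
            class = "dv_params")
}

#' @export
print.dv_params <- function(x, ...) {
  cat(sprintf("<dv_params> %d items, %d + %d structural loadings, gamma = %s%s\n",
              length(x$loadings), length(x$beta), length(x$theta),
              format(x$gamma),
              if (is.null(x$omega)) "" else
                sprintf(", %d covariate effects", length(x$omega))))
  invisible(x)
}

#' Published full-model estimates as the canonical ground truth
#'
#' Returns the parameter set of the fitted full model reported for the 2015
#' Egyptian survey analysis, used as simulation ground truth and as the input
#' of the reliability reconstruction.  Values are stored verbatim to three
#' decimals as printed.
#'
#' @param spec the canonical spec from [default_ecgbvs_spec()].
#' @param include_covariates logical; attach the published covariate
#'   coefficients as `omega`.
#' @return A `dv_params` object.
#' @export
default_true_params <- function(spec = default_ecgbvs_spec(),
                                include_covariates = FALSE) {
  canon <- default_ecgbvs_spec()
  if (!identical(spec$items[c("name", "n_categories", "factor")],
                 canon$items[c("name", "n_categories", "factor")]))
    stop("default_true_params() is defined only for the canonical spec")
  t1 <- c(X1 = 2.599, X2 = 6.329, X3 = 3.634, X4 = 5.171,
          X5 = -2.392, X6 = -1.426, X7 = 0.142, X8 = 1.710, X9 = 4.732,
          X10 = 3.089,
          X11 = -3.482, X12 = -2.620, X13 = 0.397, X14 = 2.163,
          X15 = 1.574, X16 = 1.493, X17 = 3.581,
          Y1 = -0.385, Y2 = -2.122, Y3 = 2.374, Y4 = 2.708, Y5 = -1.731,
          Y6 = 5.712, Y7 = 1.107, Y8 = 6.711,
          Y9 = 2.310, Y10 = 1.444, Y11 = 2.694,
          Y12 = 2.208, Y13 = 5.374, Y14 = 5.244, Y15 = 3.479, Y16 = 6.851,
          Y17 = 7.711, Y18 = 5.531)
  t2 <- c(Y2 = 4.593, Y4 = 4.822, Y5 = 5.552,
          Y9 = 7.177, Y10 = 4.505, Y11 = 7.852,
          Y12 = 3.471, Y13 = 5.532, Y15 = 4.362, Y16 = 7.859,
          Y17 = 8.593, Y18 = 6.364)
  loadings <- c(X1 = 1.080, X2 = 3.147, X3 = 2.495, X4 = 2.577,
                X5 = 2.104, X6 = 2.851, X7 = 1.752, X8 = 2.010, X9 = 2.066,
                X10 = 0.850,
                X11 = 1.206, X12 = 2.308, X13 = 0.266, X14 = 0.961,
                X15 = 3.908, X16 = 3.069, X17 = 1.972,
                Y1 = 0.524, Y2 = 0.113, Y3 = 1.627, Y4 = 0.133, Y5 = 0.167,
                Y6 = 1.041, Y7 = 1.095, Y8 = 1.192,
                Y9 = 3.689, Y10 = 3.144, Y11 = 5.533,
                Y12 = 1.086, Y13 = 0.778, Y14 = 0.619, Y15 = 0.584,
                Y16 = 1.581, Y17 = 1.700, Y18 = 0.681)
  tau <- matrix(NA_real_, nrow = nrow(canon$items), ncol = 2,
                dimnames = list(canon$items$name, c("t1", "t2")))
  tau[names(t1), 1] <- t1
  tau[names(t2), 2] <- t2
  beta <- c(Economic = 0.677, Physical = 1.314, Psychological = 0.792,
            Sexual = 0.533)
  theta <- c(QualityOfLife = 1.361, Children = 0.334, EconomicCost = 1.176)
  omega <- NULL
  if (include_covariates)
    omega <- c(woman_age = -0.009, husband_age = -0.011,
               husband_works = -0.280, husband_salary = 0.070,
               woman_edu_uptohs = -0.126, woman_edu_abovehs = -0.298,
               husband_edu_uptohs = -0.114, husband_edu_abovehs = -0.291,
               urban = 0.108, live_with_inlaws = 0.226,
               family_nearby = -0.186)
  dv_params(spec, tau, loadings, beta, theta, gamma = 1.016, omega = omega)
}

#' Validate a specification / parameter-set pair
#'
#' Checks the structural invariants (simple structure, resolvable item and
#' factor names, increasing thresholds, category counts) and returns
#' human-readable findings rather than raising.
#'
#' @param spec a `dv_spec`.
#' @param params optional `dv_params` to check against `spec`.
#' @return Character vector of findings; empty when everything holds.
#' @export
validate_spec <- function(spec, params = NULL) {
  findings <- character(0)
  it <- spec$items
  if (anyDuplicated(it$name))
    findings <- c(findings, "non-simple structure: duplicated item names (item assigned to more than one factor)")
  if (!all(it$factor %in% spec$factors$name))
    findings <- c(findings, sprintf("unresolved factor name(s): %s",
      paste(setdiff(unique(it$factor), spec$factors$name), collapse = ", ")))
  if (any(it$n_categories < 2))
    findings <- c(findings, "items with fewer than 2 categories")
  if (!all(spec$factors$side %in% c("violence", "cost")))
    findings <- c(findings, "factor side must be 'violence' or 'cost'")
  empty <- setdiff(spec$factors$name, it$factor)
  if (length(empty))
    findings <- c(findings, sprintf("factor(s) without items: %s",
                                    paste(empty, collapse = ", ")))
  if (!is.null(params)) {
    if (!setequal(rownames(params$tau), it$name) ||
        !setequal(names(params$loadings), it$name))
      findings <- c(findings, "parameter item names do not match the spec")
    ord <- it$name[it$n_categories >= 3]
    ord <- intersect(ord, rownames(params$tau))
    bad <- ord[!is.na(params$tau[ord, 2]) &
                 params$tau[ord, 2] <= params$tau[ord, 1]]
    if (length(bad))
      findings <- c(findings, sprintf("thresholds not increasing for item(s): %s",
                                      paste(bad, collapse = ", ")))
    miss2 <- ord[is.na(params$tau[ord, 2])]
    if (length(miss2))
      findings <- c(findings, sprintf("missing second threshold for 3-category item(s): %s",
                                      paste(miss2, collapse = ", ")))
    vf <- spec$factors$name[spec$factors$side == "violence"]
    cf <- spec$factors$name[spec$factors$side == "cost"]
    if (!setequal(names(params$beta), vf))
      findings <- c(findings, "beta names do not match violence-side factors")
    if (!setequal(names(params$theta), cf))
      findings <- c(findings, "theta names do not match cost-side factors")
    if (length(cf) > 0 && !is.finite(params$gamma))
      findings <- c(findings, "gamma missing although cost side present")
    if (!is.null(params$omega) && !is.null(spec$covariates) &&
        !setequal(names(params$omega), spec$covariates$name))
      findings <- c(findings, "omega names do not match covariates")
  }
  findings
}

#' Number of free parameters of a model
#'
#' Thresholds (one per binary item, two per three-category item), item
#' loadings, structural loadings, `gamma` when a cost side is present, and
#' covariate coefficients when active.  Residual variances are identification
#' constants, not counted.
#'
#' @param spec a `dv_spec`.
#' @param include_covariates count the covariate coefficients too.
#' @return Integer count.
#' @export
n_free_parameters <- function(spec, include_covariates = spec$include_covariates) {
  n_thr <- sum(spec$items$n_categories - 1L)
  n_load <- nrow(spec$items)
  vf <- sum(spec$factors$side == "violence")
  cf <- sum(spec$factors$side == "cost")
  k <- n_thr + n_load + vf + cf + as.integer(cf > 0)
  if (include_covariates && !is.null(spec$covariates))
    k <- k + nrow(spec$covariates)
  as.integer(k)
}
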