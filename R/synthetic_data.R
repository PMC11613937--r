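#' Generate socioeconomic covariates
#'
#' Draws a plausible covariate table for married Egyptian women: woman's age,
#' husband's age (woman's age plus a positive gap), husband's working status,
#' a non-negative salary score, education dummies against a below-high-school
#' reference, urban residence, co-residence with in-laws, and proximity of the
#' woman's own family.  Prevalences are configurable; the urban default of
#' 0.45 mirrors the survey's sampling frame split.
#'
#' @param n number of rows (>= 1).
#' @param seed integer seed; output is a pure function of `(n, seed,
#'   prevalences)`.
#' @param prevalences named list overriding any of `husband_works`, `urban`,
#'   `live_with_inlaws`, `family_nearby` (probabilities) or `woman_edu`,
#'   `husband_edu` (length-3 probability vectors: below / up to / above high
#'   school).
#' @return A tibble with one column per covariate of the canonical spec.
#' @export
generate_covariates <- function(n, seed = 1L, prevalences = list()) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  pv <- utils::modifyList(list(
    husband_works = 0.88, urban = 0.45, live_with_inlaws = 0.30,
    family_nearby = 0.60,
    woman_edu = c(0.35, 0.45, 0.20), husband_edu = c(0.30, 0.45, 0.25)),
    prevalences)
  with_local_seed(seed, {
    woman_age <- round(pmin(pmax(stats::rnorm(n, 33, 8), 18), 64))
    husband_age <- woman_age + round(stats::rgamma(n, shape = 2, scale = 3.5))
    we <- sample.int(3L, n, replace = TRUE, prob = pv$woman_edu)
    he <- sample.int(3L, n, replace = TRUE, prob = pv$husband_edu)
    tibble::tibble(
      woman_age = woman_age,
      husband_age = husband_age,
      husband_works = stats::rbinom(n, 1, pv$husband_works),
      husband_salary = round(stats::rgamma(n, shape = 2, scale = 1.5), 2),
      woman_edu_uptohs = as.integer(we == 2L),
      woman_edu_abovehs = as.integer(we == 3L),
      husband_edu_uptohs = as.integer(he == 2L),
      husband_edu_abovehs = as.integer(he == 3L),
      urban = stats::rbinom(n, 1, pv$urban),
      live_with_inlaws = stats::rbinom(n, 1, pv$live_with_inlaws),
      family_nearby = stats::rbinom(n, 1, pv$family_nearby))
  })
}

#' Draw second-order and first-order latent variables
#'
#' Simulates from the structural part of the model: Violence is standard
#' normal (or `omega'Z + xi` with standard-normal `xi` when `params$omega` is
#' present), Cost equals `gamma * Violence` plus standard-normal noise, and
#' each first-order factor equals its structural loading times its
#' second-order trait plus standard-normal noise.
#'
#' @param params a `dv_params`.
#' @param n number of subjects (ignored when `covariates` is given).
#' @param seed integer seed.
#' @param covariates data frame/matrix with one column per name of
#'   `params$omega`; required iff `params$omega` is non-NULL.
#' @return A list of class `dv_latents`: `violence`, `cost` (NULL when no cost
#'   side) and `factors`, an `n x n_factors` matrix.
#' @export
generate_latents <- function(params, n, seed = 1L, covariates = NULL) {
  has_cov <- !is.null(params$omega)
  if (has_cov && is.null(covariates))
    stop("params include omega but no covariates were supplied")
  if (!has_cov && !is.null(covariates))
    stop("covariates supplied but params include no omega")
  if (has_cov) {
    miss <- setdiff(names(params$omega), colnames(covariates))
    if (length(miss))
      stop(sprintf("covariate column(s) missing: %s", paste(miss, collapse = ", ")))
    n <- nrow(covariates)
  }
  with_local_seed(seed, {
    offset <- if (has_cov)
      as.numeric(as.matrix(covariates[, names(params$omega), drop = FALSE]) %*%
                   params$omega) else 0
    violence <- offset + stats::rnorm(n)
    cost <- NULL
    if (length(params$theta) > 0)
      cost <- params$gamma * violence + stats::rnorm(n)
    fnames <- c(names(params$beta), names(params$theta))
    factors <- matrix(NA_real_, n, length(fnames), dimnames = list(NULL, fnames))
    for (f in names(params$beta))
      factors[, f] <- params$beta[f] * violence + stats::rnorm(n)
    for (f in names(params$theta))
      factors[, f] <- params$theta[f] * cost + stats::rnorm(n)
    structure(list(violence = violence, cost = cost, factors = factors),
              class = "dv_latents")
  })
}

#' Sample item responses given latent factor values
#'
#' Each item is drawn from its categorical response distribution (2PL or
#' graded, see [binary_item_prob()]) given the value of the single first-order
#' factor it loads on.
#'
#' @param params a `dv_params`.
#' @param spec the matching `dv_spec`.
#' @param latents a `dv_latents` from [generate_latents()].
#' @param seed integer seed.
#' @return Integer matrix (subjects x items) of 0-based category codes with
#'   item names as column names.
#' @export
generate_responses <- function(params, spec, latents, seed = 1L) {
  info <- spec_item_info(spec)
  n <- nrow(latents$factors)
  with_local_seed(seed, {
    X <- matrix(NA_integer_, n, length(info$name),
                dimnames = list(NULL, info$name))
    for (i in seq_along(info$name)) {
      nm <- info$name[i]
      f <- latents$factors[, info$factor[i]]
      ti <- params$tau[nm, ][!is.na(params$tau[nm, ])]
      pr <- ordinal_category_probs(ti, params$loadings[nm], f)
      u <- stats::runif(n)
      X[, i] <- as.integer(rowSums(u > t(apply(pr, 1, cumsum))[, -ncol(pr), drop = FALSE]))
    }
    X
  })
}

default_money_cuts <- function()
  c(Y12 = 150, Y16 = 100, Y17 = 500, Y18 = 200)

# component columns behind each derived money item
money_components <- function() list(
  Y12 = c("health_spend", "health_transport", "treatment"),
  Y16 = c("police_transport", "police_station"),
  Y17 = c("lawsuit_filing", "lawyer_fees", "court_transport"))

#' Generate a raw survey table
#'
#' Produces a survey file with the dialect of the emulated questionnaire:
#' binary items coded `1: No, 2: Yes`, three-category items coded 1..3, raw
#' money-amount component columns behind the four derived economic-cost items
#' (health, police, legal, accommodation), covariates, and the marital /
#' violence status columns driving eligibility filtering.  Money components
#' are drawn consistently with the generated item categories given
#' `money_cuts`, so preparing the output with the same cut points reproduces
#' the internally generated item matrix exactly.  Rows for never-violated
#' women carry all-"No" violence items and no cost section.
#'
#' @param n number of raw rows (>= 1).
#' @param spec,params canonical spec and parameter set (defaults shipped).
#' @param seed integer seed.
#' @param violated_share share of ever-married women who ever faced violence
#'   (default 0.23, the emulated survey's reported share).
#' @param ever_married_share,currently_married_share status prevalences.
#' @param missingness MCAR missingness rate applied to item cells of violated
#'   rows, in `[0, 1]`.
#' @param money_cuts named positive-to-high cut points for the four derived
#'   money items.
#' @return A list of class `dv_survey`: `raw` (tibble), `items` (the
#'   model-ready 0-based matrix for eligible rows, before missingness),
#'   `covariates`, `latents`, `eligible` (logical index into `raw`) and
#'   `config` (seed, shares, cuts).
#' @export
generate_raw_survey <- function(n, spec = default_ecgbvs_spec(),
                                params = default_true_params(spec),
                                seed = 1L,
                                violated_share = 0.23,
                                ever_married_share = 0.95,
                                currently_married_share = 0.97,
                                missingness = 0,
                                money_cuts = default_money_cuts()) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("n must be >= 1")
  if (missingness < 0 || missingness > 1) stop("missingness must be in [0, 1]")
  n <- as.integer(n)
  info <- spec_item_info(spec)
  comp <- money_components()

  status <- with_local_seed(seed, {
    ever_married <- stats::rbinom(n, 1, ever_married_share)
    ever_violated <- ifelse(ever_married == 1,
                            stats::rbinom(n, 1, violated_share), 0L)
    currently_married <- ifelse(ever_married == 1,
                                stats::rbinom(n, 1, currently_married_share), 0L)
    cbind(ever_married, ever_violated, currently_married)
  })
  eligible <- status[, "ever_married"] == 1 & status[, "ever_violated"] == 1
  ne <- sum(eligible)

  covariates <- generate_covariates(n, seed = seed + 1L)
  latents <- generate_latents(params, ne, seed = seed + 2L)
  items <- generate_responses(params, spec, latents, seed = seed + 3L)

  raw <- tibble::tibble(id = seq_len(n))
  raw$ever_married <- status[, "ever_married"] + 1L
  raw$currently_married <- status[, "currently_married"] + 1L
  raw$ever_violated <- status[, "ever_violated"] + 1L
  raw <- tibble::as_tibble(cbind(raw, covariates))

  derived <- names(money_cuts)
  survey_items <- setdiff(info$name, derived)
  full <- matrix(NA_integer_, n, length(info$name),
                 dimnames = list(NULL, info$name))
  full[eligible, ] <- items
  viol_names <- info$name[startsWith(info$name, "X")]
  full[!eligible, viol_names] <- 0L

  with_local_seed(seed + 4L, {
    for (nm in survey_items) {
      k <- info$ncat[match(nm, info$name)]
      col <- full[, nm]
      raw[[nm]] <- if (k == 2L) col + 1L else col + 1L # 1/2 dialect or 1..3
    }
    # money components consistent with the generated categories
    amounts <- matrix(0, n, length(derived), dimnames = list(NULL, derived))
    for (nm in derived) {
      cat3 <- full[, nm]
      cut <- money_cuts[[nm]]
      amt <- rep(NA_real_, n)
      amt[!is.na(cat3) & cat3 == 0L] <- 0
      mid <- !is.na(cat3) & cat3 == 1L
      amt[mid] <- round(cut * stats::runif(sum(mid), 0.05, 1), 2)
      hi <- !is.na(cat3) & cat3 == 2L
      amt[hi] <- round(cut * (1 + stats::rlnorm(sum(hi), 0, 0.75)), 2)
      amounts[, nm] <- amt
    }
    split_amount <- function(total, k) {
      # zero-inflated split of a total over k components, at least one positive
      out <- matrix(0, length(total), k)
      pos <- !is.na(total) & total > 0
      if (any(pos)) {
        w <- matrix(stats::rexp(sum(pos) * k), ncol = k)
        keep <- matrix(stats::rbinom(sum(pos) * k, 1, 0.7), ncol = k)
        keep[rowSums(keep) == 0, 1] <- 1L
        w <- w * keep
        out[pos, ] <- round(w / rowSums(w) * total[pos], 4)
      }
      out[is.na(total), ] <- NA_real_
      out
    }
    for (nm in intersect(derived, names(comp))) {
      parts <- split_amount(amounts[, nm], length(comp[[nm]]))
      for (j in seq_along(comp[[nm]])) raw[[comp[[nm]][j]]] <- parts[, j]
    }
    if ("Y18" %in% derived) {
      tot <- amounts[, "Y18"]
      days <- ifelse(!is.na(tot) & tot > 0, sample(1:10, n, replace = TRUE), 0)
      days[is.na(tot)] <- NA_real_
      per_day <- ifelse(!is.na(tot) & tot > 0, round(tot / pmax(days, 1), 4), 0)
      per_day[is.na(tot)] <- NA_real_
      raw$leaving_cost_per_day <- per_day
      raw$days_away <- days
    }
    if (missingness > 0) {
      for (nm in survey_items) {
        hit <- eligible & stats::runif(n) < missingness
        raw[[nm]][hit] <- NA
      }
    }
  })

  structure(list(raw = raw, items = items, covariates = covariates[eligible, ],
                 latents = latents, eligible = eligible,
                 config = list(seed = seed, n = n,
                               violated_share = violated_share,
                               ever_married_share = ever_married_share,
                               currently_married_share = currently_married_share,
                               missingness = missingness,
                               money_cuts = as.list(money_cuts))),
            class = "dv_survey")
}

#' Write a generated survey to disk
#'
#' Writes the raw survey and the model-ready item matrix as headered CSV plus
#' a JSON sidecar recording the seed and generator configuration.
#'
#' @param survey a `dv_survey` from [generate_raw_survey()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_survey <- function(survey, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(raw = file.path(dir, "raw_survey.csv"),
             items = file.path(dir, "item_matrix.csv"),
             sidecar = file.path(dir, "generator.json"))
  utils::write.csv(survey$raw, paths["raw"], row.names = FALSE, na = "")
  utils::write.csv(as.data.frame(survey$items), paths["items"],
                   row.names = FALSE, na = "")
  side <- c(survey$config,
            list(generator_version = as.character(utils::packageVersion("dvcost")),
                 n_eligible = sum(survey$eligible)))
  jsonlite::write_json(side, paths["sidecar"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
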