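#' Preparation configuration
#'
#' Bundles the survey-preparation rules: which raw component columns feed each
#' derived money-cost item, the 3-category cut point of each derived amount
#' (`NULL` = median of the positive amounts), whether partially missing
#' component sets are summed over the observed components (default) or
#' propagated as missing, and which eligibility filters apply.
#'
#' @param money_cuts named numeric vector of positive cut points, or `NULL`
#'   entries / missing names for data-driven medians.
#' @param partial_sum treat missing money components as 0 when at least one
#'   component is observed.
#' @param filter_violated,filter_currently_married eligibility filter flags.
#' @return A list of class `dv_prep_config`.
#' @export
prep_config <- function(money_cuts = NULL, partial_sum = TRUE,
                        filter_violated = TRUE,
                        filter_currently_married = TRUE) {
  if (!is.null(money_cuts) && any(unlist(money_cuts) <= 0))
    stop("money cut points must be positive")
  structure(list(money_cuts = money_cuts, partial_sum = partial_sum,
                 filter_violated = filter_violated,
                 filter_currently_married = filter_currently_married),
            class = "dv_prep_config")
}

#' Recode a 1/2 survey column to 0/1
#'
#' The questionnaire dialect codes binary answers `1: No, 2: Yes`; analysis
#' coding is 1 for a positive ("yes") response and 0 otherwise.  Missing
#' values are preserved.
#'
#' @param x vector with values in `{1, 2, NA}`.
#' @param column column name used in error messages.
#' @return Integer 0/1 vector.
#' @examples
#' recode_binary(c(1, 2, 2, 1)) # 0 1 1 0
#' @export
recode_binary <- function(x, column = deparse(substitute(x))) {
  bad <- setdiff(unique(x[!is.na(x)]), c(1, 2))
  if (length(bad))
    stop(sprintf("unexpected code %s in column '%s'",
                 paste(bad, collapse = ", "), column))
  as.integer(x) - 1L
}

#' Derive money-cost totals from raw components
#'
#' Applies the stated construction rules: money spent on health services is
#' the sum of the health-service, transport and treatment amounts; police is
#' transport plus the amount paid at the station; legal is lawsuit filing plus
#' lawyer fees plus transport to court; accommodation is the per-day cost of
#' staying away times the number of days.  When some but not all components of
#' a sum are missing they are treated as 0 (configurable); a fully missing
#' component set yields a missing total.
#'
#' @param raw data frame holding the component columns.
#' @param config a [prep_config()].
#' @return Tibble with columns `Y12` (health), `Y16` (police), `Y17` (legal),
#'   `Y18` (accommodation).
#' @export
derive_money_totals <- function(raw, config = prep_config()) {
  comp <- money_components()
  for (cols in comp) {
    miss <- setdiff(cols, names(raw))
    if (length(miss)) stop(sprintf("missing component column(s): %s",
                                   paste(miss, collapse = ", ")))
  }
  allcols <- c(unlist(comp), "leaving_cost_per_day", "days_away")
  for (cl in intersect(allcols, names(raw)))
    if (any(raw[[cl]] < 0, na.rm = TRUE))
      stop(sprintf("negative amount in column '%s'", cl))
  sum_rule <- function(m) {
    m <- as.matrix(m)
    allna <- rowSums(!is.na(m)) == 0
    s <- if (config$partial_sum) rowSums(m, na.rm = TRUE) else rowSums(m)
    s[allna] <- NA_real_
    s
  }
  out <- tibble::tibble(
    Y12 = sum_rule(raw[comp$Y12]),
    Y16 = sum_rule(raw[comp$Y16]),
    Y17 = sum_rule(raw[comp$Y17]),
    Y18 = raw$leaving_cost_per_day * raw$days_away)
  out
}

#' Categorize a money amount into three ordered levels
#'
#' Category 0 for a zero amount (no expenditure), category 1 for a positive
#' amount up to the cut point, category 2 above it.  The default cut point is
#' the median of the positive amounts, which is scale-free and reproducible.
#'
#' @param x non-negative amount vector.
#' @param cut positive cut point, or `NULL` for the median of positives.
#' @return Integer vector in `{0, 1, 2}` (NA preserved).
#' @export
categorize_amount <- function(x, cut = NULL) {
  if (any(x < 0, na.rm = TRUE)) stop("amounts must be non-negative")
  pos <- x[!is.na(x) & x > 0]
  if (length(pos) == 0) {
    warning("degenerate amount column: no positive amounts; all category 0")
    return(ifelse(is.na(x), NA_integer_, 0L))
  }
  if (is.null(cut)) cut <- stats::median(pos)
  ifelse(is.na(x), NA_integer_,
         ifelse(x == 0, 0L, ifelse(x <= cut, 1L, 2L)))
}

#' Eligibility filtering with audit counts
#'
#' Keeps ever-married (or engaged) women who ever faced spousal violence and,
#' when configured, restricts further to currently married women.  Status
#' columns use the 1/2 questionnaire dialect.
#'
#' @param raw data frame with `ever_married`, `ever_violated`,
#'   `currently_married` columns.
#' @param config a [prep_config()].
#' @return List with `data` (the filtered table) and `counts`, the audit trail
#'   `c(total, ever_married_violated, currently_married)`.
#' @export
filter_eligible <- function(raw, config = prep_config()) {
  counts <- c(total = nrow(raw))
  out <- raw
  if (config$filter_violated) {
    need <- c("ever_married", "ever_violated")
    miss <- setdiff(need, names(raw))
    if (length(miss)) stop(sprintf("missing status column(s): %s",
                                   paste(miss, collapse = ", ")))
    keep <- !is.na(out$ever_married) & out$ever_married == 2 &
      !is.na(out$ever_violated) & out$ever_violated == 2
    out <- out[keep, , drop = FALSE]
  }
  counts <- c(counts, ever_married_violated = nrow(out))
  if (config$filter_currently_married) {
    if (!"currently_married" %in% names(out))
      stop("missing status column(s): currently_married")
    out <- out[!is.na(out$currently_married) & out$currently_married == 2, ,
               drop = FALSE]
  }
  counts <- c(counts, currently_married = nrow(out))
  list(data = out, counts = counts)
}

#' Survey response rate
#'
#' Completed interviews over eligible respondents, as a percentage rounded to
#' one decimal (the convention of survey audit reports).
#'
#' @param completed,eligible non-negative counts, `completed <= eligible`.
#' @return Percentage.
#' @examples
#' response_rate(20000, 20157) # 99.2
#' @export
response_rate <- function(completed, eligible) {
  stopifnot(completed >= 0, eligible > 0, completed <= eligible)
  round(100 * completed / eligible, 1)
}

#' Prepare a raw survey table for model fitting
#'
#' Runs the full preparation chain: eligibility filtering, 1/2 -> 0/1
#' recoding of binary items, 1..3 -> 0..2 recoding of three-category survey
#' items, derivation and categorization of the four money-cost items, and
#' extraction of the covariate matrix.
#'
#' @param raw raw survey tibble (layout of [generate_raw_survey()]).
#' @param spec a `dv_spec`.
#' @param config a [prep_config()].
#' @return List with `items` (integer matrix of 0-based codes), `covariates`
#'   (tibble or NULL), `counts` (filter audit) and `cuts` (cut points used).
#' @export
prepare_survey <- function(raw, spec, config = prep_config()) {
  flt <- filter_eligible(raw, config)
  dat <- flt$data
  info <- spec_item_info(spec)
  derived <- names(default_money_cuts())
  X <- matrix(NA_integer_, nrow(dat), length(info$name),
              dimnames = list(NULL, info$name))
  for (i in seq_along(info$name)) {
    nm <- info$name[i]
    if (nm %in% derived) next
    if (!nm %in% names(dat)) stop(sprintf("missing item column '%s'", nm))
    X[, i] <- if (info$ncat[i] == 2L) recode_binary(dat[[nm]], nm)
      else as.integer(dat[[nm]]) - 1L
  }
  totals <- derive_money_totals(dat, config)
  cuts_used <- list()
  for (nm in derived) {
    cut <- config$money_cuts[[nm]]
    x <- totals[[nm]]
    pos <- x[!is.na(x) & x > 0]
    if (is.null(cut)) cut <- if (length(pos)) stats::median(pos) else NA_real_
    cuts_used[[nm]] <- cut
    X[, nm] <- suppressWarnings(categorize_amount(x, cut))
  }
  covnames <- if (is.null(spec$covariates)) character(0) else spec$covariates$name
  covariates <- if (length(covnames) && all(covnames %in% names(dat)))
    tibble::as_tibble(dat[covnames]) else NULL
  list(items = X, covariates = covariates, counts = flt$counts,
       cuts = cuts_used)
}
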