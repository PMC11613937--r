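#' Run configuration for the analysis pipeline
#'
#' A single YAML document drives reproducible runs: seed, sample size, output
#' directory, per-stage options.  Unknown keys are rejected so typos fail
#' loudly; the seed is recorded in every artifact.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return Validated config list of class `dv_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  known <- c("seed", "n_rows", "output_dir", "simulate", "prep", "grid", "fit")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  defaults <- list(seed = 1L, n_rows = 500L, output_dir = "dvcost_run",
                   simulate = list(), prep = list(), grid = list(),
                   fit = list())
  cfg <- utils::modifyList(defaults, cfg)
  for (sec in c("simulate", "prep", "grid", "fit")) {
    kn <- switch(sec,
      simulate = c("violated_share", "ever_married_share",
                   "currently_married_share", "missingness"),
      prep = c("money_cuts", "partial_sum", "filter_violated",
               "filter_currently_married"),
      grid = c("n_outer", "n_inner"),
      fit = c("side", "covariates", "maxit", "se"))
    bad <- setdiff(names(cfg[[sec]]), kn)
    if (length(bad))
      stop(sprintf("unknown config key(s) in '%s': %s", sec,
                   paste(bad, collapse = ", ")))
  }
  structure(cfg, class = "dv_run_config")
}

stage_log <- function(stage, t0, files) {
  hashes <- tools::md5sum(files[file.exists(files)])
  message(sprintf("[dvcost] %-10s %6.2fs  %s", stage,
                  as.numeric(Sys.time()) - t0,
                  paste(basename(names(hashes)), substr(hashes, 1, 8),
                        collapse = " ")))
  invisible(hashes)
}

#' Pipeline stages
#'
#' `run_simulate()` writes a synthetic raw survey, its model-ready item
#' matrix and a ground-truth parameter file; `run_fit()` prepares the raw
#' survey and fits the model, writing a JSON fit plus a text report in the
#' published table layout; `run_report()` merges every upstream artifact
#' (with content hashes) into one consolidated JSON report.
#'
#' @param config a `dv_run_config` (or path / list accepted by
#'   [read_run_config()]).
#' @return Invisibly, the paths written.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_simulate <- function(config) {
  cfg <- read_run_config(config)
  t0 <- as.numeric(Sys.time())
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- default_ecgbvs_spec()
  params <- default_true_params(spec)
  sim_args <- c(list(n = cfg$n_rows, spec = spec, params = params, seed = cfg$seed),
                cfg$simulate)
  survey <- do.call(generate_raw_survey, sim_args)
  paths <- write_survey(survey, cfg$output_dir)
  truth <- file.path(cfg$output_dir, "true_params.yaml")
  write_params_yaml(params, truth)
  paths <- c(paths, truth = truth)
  stage_log("simulate", t0, paths)
  invisible(paths)
}

#' @rdname pipeline
#' @export
run_fit <- function(config) {
  cfg <- read_run_config(config)
  t0 <- as.numeric(Sys.time())
  rawpath <- file.path(cfg$output_dir, "raw_survey.csv")
  if (!file.exists(rawpath))
    stop("missing upstream artifact raw_survey.csv; rerun the simulate stage")
  raw <- utils::read.csv(rawpath, check.names = FALSE)
  spec <- default_ecgbvs_spec()
  pc <- do.call(prep_config, cfg$prep)
  prep <- prepare_survey(raw, spec, pc)
  grid <- do.call(quadrature_grid, cfg$grid)
  side <- if (is.null(cfg$fit$side)) "full" else cfg$fit$side
  use_cov <- isTRUE(cfg$fit$covariates)
  ctl <- list()
  if (!is.null(cfg$fit$maxit)) ctl$maxit <- cfg$fit$maxit
  if (use_cov && is.null(prep$covariates))
    stop("covariate stage requested but no covariate columns in the data")
  if (side == "violence") {
    sp <- subset_spec(spec, "violence")
    items <- prep$items[, sp$items$name, drop = FALSE]
  } else {
    sp <- spec
    items <- prep$items
  }
  fit <- fit_model(items, sp, grid, covariates = prep$covariates,
                   include_covariates = use_cov,
                   se = isTRUE(cfg$fit$se), control = ctl)
  fitjson <- file.path(cfg$output_dir, "fit.json")
  report <- file.path(cfg$output_dir, "fit_report.txt")
  audit <- file.path(cfg$output_dir, "prep_audit.json")
  jsonlite::write_json(list(
    seed = cfg$seed, converged = fit$convergence, loglik = fit$loglik,
    npar = fit$npar, n = fit$n, AIC = fit$AIC, BIC = fit$BIC,
    estimates = as.list(fit$par),
    se = if (is.null(fit$se)) NULL else as.list(fit$se),
    p_value = if (is.null(fit$p_value)) NULL else as.list(fit$p_value)),
    fitjson, auto_unbox = TRUE, digits = NA)
  writeLines(utils::capture.output(fit_report(fit)), report)
  jsonlite::write_json(c(list(seed = cfg$seed), as.list(prep$counts),
                         list(cuts = prep$cuts)),
                       audit, auto_unbox = TRUE, digits = NA)
  if (!fit$convergence)
    stop("model fit did not converge; partial diagnostics written to ", fitjson)
  paths <- c(fit = fitjson, report = report, audit = audit)
  stage_log("fit", t0, paths)
  invisible(paths)
}

#' @rdname pipeline
#' @export
run_report <- function(config) {
  cfg <- read_run_config(config)
  t0 <- as.numeric(Sys.time())
  need <- c(raw = "raw_survey.csv", items = "item_matrix.csv",
            sidecar = "generator.json", fit = "fit.json",
            audit = "prep_audit.json")
  paths <- file.path(cfg$output_dir, need)
  names(paths) <- names(need)
  missing <- !file.exists(paths)
  if (any(missing))
    stop(sprintf("missing upstream artifact(s): %s; rerun the %s stage",
                 paste(need[missing], collapse = ", "),
                 if (any(missing[1:3])) "simulate" else "fit"))
  spec <- default_ecgbvs_spec()
  items <- as.matrix(utils::read.csv(paths["items"], check.names = FALSE))
  Rv <- polychoric_matrix(items[, grep("^X", colnames(items)), drop = FALSE])
  nf <- suggest_nfactors(Rv)
  rel <- reliability_report(default_true_params(spec), spec)
  fitdoc <- jsonlite::read_json(paths["fit"])
  audit <- jsonlite::read_json(paths["audit"])
  report <- list(
    provenance = list(
      seed = cfg$seed,
      package_version = as.character(utils::packageVersion("dvcost")),
      config_hash = unname(tools::md5sum(
        {tf <- tempfile(); writeLines(yaml::as.yaml(unclass(cfg)), tf); tf})),
      artifacts = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                          basename(paths)))),
    prep_audit = audit,
    efa = list(n_factors_violence = as.integer(nf),
               eigenvalues_violence = as.numeric(attr(nf, "eigenvalues"))),
    reliability = lapply(seq_len(nrow(rel)), function(i)
      list(construct = rel$construct[i], CR = rel$CR[i], AVE = rel$AVE[i])),
    fit = fitdoc)
  out <- file.path(cfg$output_dir, "run_report.json")
  jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA)
  stage_log("report", t0, c(report = out))
  invisible(c(report = out))
}
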