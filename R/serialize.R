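#' Read and write model specifications and parameter sets as YAML
#'
#' The YAML layout uses item and factor names as stable keys so documents can
#' be edited by hand; numbers are emitted with 17 significant digits so that a
#' write/read round trip reproduces every double bit-for-bit.
#'
#' @param spec a `dv_spec`.
#' @param path file path.
#' @return `write_spec_yaml()` returns `path` invisibly; `read_spec_yaml()`
#'   returns a `dv_spec`.
#' @name spec_yaml
NULL

#' @rdname spec_yaml
#' @export
write_spec_yaml <- function(spec, path) {
  doc <- list(
    link = spec$link,
    include_covariates = spec$include_covariates,
    items = lapply(seq_len(nrow(spec$items)), function(i)
      list(name = spec$items$name[i], label = spec$items$label[i],
           n_categories = spec$items$n_categories[i],
           factor = spec$items$factor[i])),
    factors = lapply(seq_len(nrow(spec$factors)), function(i)
      list(name = spec$factors$name[i], side = spec$factors$side[i])),
    covariates = if (is.null(spec$covariates)) NULL else
      lapply(seq_len(nrow(spec$covariates)), function(i)
        list(name = spec$covariates$name[i], type = spec$covariates$type[i])))
  writeLines(yaml::as.yaml(doc, precision = 17), path)
  invisible(path)
}

#' @rdname spec_yaml
#' @export
read_spec_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  items <- do.call(rbind, lapply(doc$items, function(x)
    data.frame(name = x$name, label = x$label,
               n_categories = as.integer(x$n_categories), factor = x$factor)))
  factors <- do.call(rbind, lapply(doc$factors, function(x)
    data.frame(name = x$name, side = x$side)))
  covariates <- if (is.null(doc$covariates)) NULL else
    do.call(rbind, lapply(doc$covariates, function(x)
      data.frame(name = x$name, type = x$type)))
  dv_spec(items, factors, covariates,
          include_covariates = isTRUE(doc$include_covariates))
}

#' @param params a `dv_params`.
#' @rdname spec_yaml
#' @export
write_params_yaml <- function(params, path) {
  items <- rownames(params$tau)
  doc <- list(
    thresholds = stats::setNames(lapply(items, function(i) {
      v <- params$tau[i, ]
      as.list(v[!is.na(v)])
    }), items),
    loadings = as.list(params$loadings),
    beta = as.list(params$beta),
    theta = as.list(params$theta),
    gamma = params$gamma,
    omega = if (is.null(params$omega)) NULL else as.list(params$omega))
  writeLines(yaml::as.yaml(doc, precision = 17), path)
  invisible(path)
}

#' @rdname spec_yaml
#' @export
read_params_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  items <- names(doc$thresholds)
  tau <- matrix(NA_real_, length(items), 2,
                dimnames = list(items, c("t1", "t2")))
  for (i in items) {
    v <- unlist(doc$thresholds[[i]])
    tau[i, seq_along(v)] <- v
  }
  structure(list(tau = tau,
                 loadings = unlist(doc$loadings),
                 beta = unlist(doc$beta),
                 theta = if (length(doc$theta)) unlist(doc$theta) else numeric(0),
                 gamma = if (is.null(doc$gamma)) NA_real_ else doc$gamma,
                 omega = if (is.null(doc$omega)) NULL else unlist(doc$omega)),
            class = "dv_params")
}
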