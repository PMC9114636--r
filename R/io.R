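#' Read a delimited numeric matrix
#'
#' Rows are instances, columns features. A header line is optional and
#' auto-detected; any delimiter understood by \code{data.table::fread}
#' (comma, tab, whitespace) works.
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_matrix <- function(path) {
  dt <- data.table::fread(path, header = "auto")
  as.matrix(dt)
}

#' Write a numeric matrix as delimited text
#'
#' @param x matrix.
#' @param path output path.
#' @param sep delimiter (default tab).
#' @export
write_matrix <- function(x, path, sep = "\t") {
  data.table::fwrite(data.table::as.data.table(as.matrix(x)), path,
                     sep = sep, col.names = !is.null(colnames(x)))
  invisible(path)
}

#' Read a label vector from text
#'
#' One label per line; empty fields, \code{NA} or \code{?} mark unlabelled
#' instances.
#'
#' @param path file path.
#' @return integer vector with NA for unlabelled instances.
#' @export
read_labels <- function(path) {
  raw <- trimws(readLines(path))
  raw[raw %in% c("", "NA", "?")] <- NA
  as.integer(raw)
}

#' Read a YAML config file
#'
#' Recognised keys mirror the function arguments, e.g. \code{graph.k},
#' \code{graph.tau}, \code{kernel.family}, \code{kernel.sigma},
#' \code{kernel.multi} (list of family/sigma pairs), and any
#' \code{\link{mapca_control}} field under \code{solver.}.
#'
#' @param path YAML file.
#' @return nested list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Resolve kernel and control objects from a config list
#' @param cfg list as returned by \code{\link{read_config}} (may be empty).
#' @return list with \code{kernel}, \code{control}, \code{k}, \code{tau}.
#' @export
config_to_settings <- function(cfg = list()) {
  kern <- if (!is.null(cfg$kernel$multi)) {
    stack_kernels(lapply(cfg$kernel$multi, function(sp)
      kernel_spec(sp$family, sp$sigma)))
  } else {
    kernel_spec(family = cfg$kernel$family %||% "gaussian",
                sigma = cfg$kernel$sigma)
  }
  ctl_args <- cfg$solver %||% list()
  control <- do.call(mapca_control, ctl_args)
  list(kernel = kern, control = control,
       k = cfg$graph$k %||% 5, tau = cfg$graph$tau)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

MAPCA_SCHEMA_VERSION <- "1.0"

kernel_to_list <- function(kern) {
  if (inherits(kern, "mapca_kernel_stack")) {
    list(type = "stack", specs = lapply(kern$specs, kernel_to_list))
  } else {
    out <- list(type = "single", family = kern$family)
    if (!is.null(kern$sigma)) out$sigma <- kern$sigma
    out
  }
}

kernel_from_list <- function(x) {
  if (identical(as.character(x$type), "stack")) {
    stack_kernels(lapply(x$specs, kernel_from_list))
  } else {
    sigma <- x$sigma
    if (length(sigma) != 1L || !is.numeric(sigma)) sigma <- NULL
    kernel_spec(as.character(x$family), sigma)
  }
}

#' Serialise a fitted model to a JSON archive
#'
#' Writes everything needed for out-of-sample prediction (dual coefficients,
#' source weights, kernel spec, graph parameters, class prototypes, training
#' sample and its local weighted means) plus convergence diagnostics, under a
#' versioned schema. Full double precision is retained, so a round trip is
#' lossless.
#'
#' @param fit a \code{mapca_fit}.
#' @param path output path (conventionally \code{.json}).
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "mapca_fit"))
  payload <- list(
    schema = "mapca_fit", schema_version = MAPCA_SCHEMA_VERSION,
    alpha = fit$alpha, gamma = fit$gamma,
    classes = fit$classes, centers = fit$centers,
    kernel = kernel_to_list(fit$kernel),
    graph_k = fit$graph_k, graph_tau = fit$graph_tau,
    X = fit$X, Xhat = fit$Xhat,
    labeled = fit$labeled, y = fit$y, V = fit$V,
    control = unclass(fit$control),
    weighting = fit$weighting, divergence = fit$divergence,
    obj_history = fit$obj_history, iterations = fit$iterations,
    converged = fit$converged, stop_reason = fit$stop_reason)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' Load a fitted model from a JSON archive
#' @param path archive written by \code{\link{write_fit}}.
#' @return a \code{mapca_fit}.
#' @export
read_fit <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  if (!identical(p$schema, "mapca_fit"))
    stop("not a mapca fit archive", call. = FALSE)
  if (!identical(p$schema_version, MAPCA_SCHEMA_VERSION))
    stop("unsupported schema version: ", p$schema_version, call. = FALSE)
  ctl <- do.call(mapca_control, p$control[names(p$control) %in%
    names(formals(mapca_control))])
  structure(list(alpha = as.matrix(p$alpha),
                 gamma = as.numeric(p$gamma %||% numeric(0)),
                 V = as.matrix(p$V), A = NULL,
                 obj_history = as.numeric(p$obj_history),
                 obj_partial = NULL,
                 iterations = p$iterations, converged = p$converged,
                 stop_reason = p$stop_reason,
                 X = as.matrix(p$X), Xhat = as.matrix(p$Xhat),
                 y = as.integer(p$y), classes = p$classes,
                 labeled = as.logical(p$labeled),
                 centers = as.matrix(p$centers),
                 kernel = kernel_from_list(p$kernel),
                 graph_k = p$graph_k, graph_tau = p$graph_tau,
                 control = ctl, weighting = p$weighting,
                 divergence = p$divergence),
            class = "mapca_fit")
}

#' Serialise a source model
#' @param source a \code{mapca_source}.
#' @param path output path.
#' @export
write_source <- function(source, path) {
  stopifnot(inherits(source, "mapca_source"))
  jsonlite::write_json(list(schema = "mapca_source",
                            schema_version = MAPCA_SCHEMA_VERSION,
                            alpha = source$alpha, origin = source$origin,
                            name = source$name),
                       path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' Load a source model
#' @param path archive written by \code{\link{write_source}}.
#' @return a \code{mapca_source}.
#' @export
read_source <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "mapca_source"))
    stop("not a mapca source archive", call. = FALSE)
  mapca_source(as.matrix(p$alpha), origin = p$origin, name = p$name)
}

#' Write a synthetic domain as delimited matrices plus a manifest
#'
#' Writes \code{<stem>_X.tsv} (features), \code{<stem>_y.tsv} (full labels),
#' and \code{<stem>_manifest.json} (labelled/outlier masks and the config).
#'
#' @param domain a \code{mapca_domain}.
#' @param stem path stem.
#' @return the manifest path.
#' @export
write_domain <- function(domain, stem) {
  stopifnot(inherits(domain, "mapca_domain"))
  write_matrix(domain$X, paste0(stem, "_X.tsv"))
  writeLines(as.character(domain$y), paste0(stem, "_y.tsv"))
  cfg <- domain$config
  jsonlite::write_json(list(schema = "mapca_domain",
                            schema_version = MAPCA_SCHEMA_VERSION,
                            labeled = domain$labeled,
                            outlier = domain$outlier,
                            config = unclass(cfg)),
                       paste0(stem, "_manifest.json"),
                       digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor", na = "null")
  invisible(paste0(stem, "_manifest.json"))
}
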