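#' Transductive accuracy of a fit on its unlabelled instances
#'
#' Fraction of unlabelled training instances whose predicted class matches
#' the ground truth. Instances flagged as outliers (which carry arbitrary
#' labels) are excluded when a mask is given.
#'
#' @param fit a \code{mapca_fit}.
#' @param truth ground-truth labels for every training instance.
#' @param exclude optional logical mask of instances to drop (e.g. outliers).
#' @return accuracy in [0, 1].
#' @export
transductive_accuracy <- function(fit, truth, exclude = NULL) {
  pred <- transductive_labels(fit)
  keep <- !fit$labeled
  if (!is.null(exclude)) keep <- keep & !exclude
  mean(pred[keep] == truth[keep])
}

#' Leave-one-domain-out evaluation
#'
#' For each domain in turn: hold it out as the target (keeping only its
#' labelled subset as labels), train source models on every other domain
#' (fully labelled), fit the adaptive classifier, and report the transductive
#' accuracy on the target's unlabelled instances together with the final
#' source weights, iteration count and final objective. Deterministic: a
#' rerun on the same domain objects reproduces the table exactly.
#'
#' @param domains list of at least two \code{mapca_domain} objects sharing M
#'   and d.
#' @param kernel kernel spec or stack.
#' @param control a \code{\link{mapca_control}}.
#' @param weighting source weighting scheme (see \code{\link{mapca}});
#'   \code{"distance"} computes kernel-MMD softmax weights with sharpness
#'   \code{delta} and fixes them.
#' @param delta sharpness of the distance scheme.
#' @param k,tau graph parameters.
#' @return data.frame with one row per held-out domain: accuracy, iterations,
#'   final objective, stop reason, and the gamma vector (list column).
#' @export
leave_one_domain_out <- function(domains, kernel = kernel_spec(),
                                 control = mapca_control(),
                                 weighting = c("optimal", "uniform",
                                               "distance"),
                                 delta = 100, k = 5, tau = NULL) {
  weighting <- match.arg(weighting)
  if (!is.list(domains) || length(domains) < 2L)
    stop("need at least two domains", call. = FALSE)
  stopifnot(all(vapply(domains, inherits, logical(1), "mapca_domain")))

  rows <- lapply(seq_along(domains), function(t) {
    target <- domains[[t]]
    rest <- domains[-t]
    M <- target$config$M
    sources <- lapply(seq_along(rest), function(i)
      train_source(rest[[i]]$X, rest[[i]]$y, target$X,
                   classes = seq_len(M), kernel = kernel,
                   lambda = control$lambda, name = paste0("domain", i)))
    if (weighting == "distance") {
      dists <- vapply(rest, function(dom)
        domain_distance(dom$X, target$X, kernel), numeric(1))
      w <- make_weights("distance", distances = dists, delta = delta)
      fit <- mapca(target$X, partial_labels(target), sources = sources,
                   kernel = kernel, k = k, tau = tau, control = control,
                   weighting = "fixed", fixed_weights = w)
    } else {
      fit <- mapca(target$X, partial_labels(target), sources = sources,
                   kernel = kernel, k = k, tau = tau, control = control,
                   weighting = weighting)
    }
    data.frame(target = t,
               accuracy = transductive_accuracy(fit, target$y,
                                                exclude = target$outlier),
               iterations = fit$iterations,
               objective = utils::tail(fit$obj_history, 1),
               stop_reason = fit$stop_reason,
               gamma = I(list(fit$gamma)))
  })
  do.call(rbind, rows)
}

#' Exhaustive hyperparameter grid search
#'
#' Evaluates every grid row on tasks built by \code{make_task} over the given
#' seeds and returns the configuration with the best mean transductive
#' accuracy. Ties resolve to the lexicographically smallest
#' \code{(lambda, lambda_s, C, beta, eta)}. Cross-validation is not used:
#' under distribution shift a held-out source split is not representative of
#' the target, so the grid is scored directly on the transductive target
#' accuracy of each task.
#'
#' @param grid data.frame whose columns are a subset of
#'   \code{lambda, lambda_s, C, beta, eta}; each row overrides the base
#'   control.
#' @param make_task function(seed) returning a \code{mapca_task}.
#' @param seeds integer vector of task seeds.
#' @param kernel kernel spec or stack.
#' @param control base \code{\link{mapca_control}}.
#' @param weighting source weighting scheme.
#' @return list with \code{best} (the winning grid row, as a one-row
#'   data.frame with its mean accuracy) and \code{results} (the full table).
#' @export
grid_search <- function(grid, make_task, seeds = 1:5,
                        kernel = kernel_spec(), control = mapca_control(),
                        weighting = "optimal") {
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0L) stop("empty grid", call. = FALSE)
  allowed <- c("lambda", "lambda_s", "C", "beta", "eta")
  if (!all(names(grid) %in% allowed))
    stop("grid columns must be among: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  acc <- vapply(seq_len(nrow(grid)), function(r) {
    ctl <- control
    for (nm in names(grid)) ctl[[nm]] <- grid[r, nm]
    mean(vapply(seeds, function(s) {
      task <- make_task(s)
      fit <- mapca(task$target$X, partial_labels(task$target),
                   sources = task$sources, kernel = kernel, control = ctl,
                   weighting = if (ctl$beta > 0 && length(task$sources))
                     weighting else "optimal")
      transductive_accuracy(fit, task$target$y,
                            exclude = task$target$outlier)
    }, numeric(1)))
  }, numeric(1))
  results <- cbind(grid, mean_accuracy = acc)
  full <- results
  for (nm in allowed)
    if (!nm %in% names(full)) full[[nm]] <- control[[nm]]
  ord <- order(-full$mean_accuracy, full$lambda, full$lambda_s, full$C,
               full$beta, full$eta)
  list(best = results[ord[1L], , drop = FALSE], results = results)
}

#' The hyperparameter grid used for empirical tuning
#'
#' Log-spaced candidate values \eqn{10^{-4}, 10^{-3}, \ldots, 10^4} for any
#' of the balance weights.
#'
#' @param params character vector of control names to vary.
#' @return data.frame with the full factorial grid.
#' @export
default_grid <- function(params = c("lambda", "C")) {
  vals <- 10^(-4:4)
  g <- do.call(expand.grid, stats::setNames(rep(list(vals), length(params)),
                                            params))
  as.data.frame(g)
}
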