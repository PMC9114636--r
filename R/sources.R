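#' Source model over the target reference sample
#'
#' A pre-trained source classifier is carried as dual coefficients
#' \code{alpha} over the *target* training sample, so that its decision
#' values on the target are \code{K \%*\% alpha}. Models trained elsewhere are
#' re-expressed in this representation by kernel least-squares projection of
#' their decision values onto the target sample
#' (see \code{\link{train_source}}).
#'
#' @param alpha n x M dual coefficient matrix (n = target sample size).
#' @param origin \code{"trained-here"} or \code{"projected"}.
#' @param name optional domain name.
#' @return object of class \code{mapca_source}.
#' @export
mapca_source <- function(alpha, origin = c("trained-here", "projected"),
                         name = NULL) {
  alpha <- as.matrix(alpha)
  origin <- match.arg(origin)
  if (!all(is.finite(alpha)))
    stop("source coefficients must be finite", call. = FALSE)
  structure(list(alpha = alpha, origin = origin, name = name),
            class = "mapca_source")
}

#' @export
print.mapca_source <- function(x, ...) {
  cat(sprintf("mapca source model%s: %d x %d dual coefficients (%s)\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              nrow(x$alpha), ncol(x$alpha), x$origin))
  invisible(x)
}

# kernel least-squares projection of decision values onto the reference Gram:
# find alpha with K alpha ~= values. Exact solve when K is nonsingular (then
# re-projection is exactly idempotent); tiny ridge fallback otherwise.
project_to_reference <- function(values, K) {
  a <- tryCatch(solve(K, values), error = function(e) NULL)
  if (is.null(a)) {
    jitter <- 1e-10 * sum(diag(K)) / nrow(K)
    a <- solve(K + diag(jitter, nrow(K)), values)
  }
  a
}

#' Train a source classifier and project it onto the target sample
#'
#' Fits a kernel least-squares classifier on a fully labelled source dataset
#' (the unlabelled-free, adaptation-free special case of the decision-model
#' update: minimise \eqn{\|K_s a - Y_s\|_F^2 + \lambda\,\mathrm{tr}(a^T K_s
#' a)}), evaluates its decision values on the target reference sample, and
#' projects them back to dual coefficients over the target Gram matrix.
#'
#' @param X_source fully labelled source feature matrix.
#' @param y_source source labels (no NA), coded on the same classes as the
#'   target; pass \code{classes} to fix the encoding.
#' @param X_target target reference sample (defines the shared
#'   representation).
#' @param classes class levels shared with the target problem (default: the
#'   sorted unique source labels).
#' @param kernel kernel spec or stack (must match the target fit).
#' @param lambda ridge weight of the source fit.
#' @param name optional domain name.
#' @return a \code{\link{mapca_source}} with origin \code{"projected"}.
#' @export
train_source <- function(X_source, y_source, X_target, classes = NULL,
                         kernel = kernel_spec(), lambda = 1, name = NULL) {
  Xs <- as.matrix(X_source)
  if (anyNA(y_source))
    stop("source data must be fully labelled", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(y_source))
  yi <- match(y_source, classes)
  if (anyNA(yi))
    stop("source labels contain classes absent from the target encoding",
         call. = FALSE)
  M <- length(classes)
  Ys <- matrix(0, nrow(Xs), M)
  Ys[cbind(seq_len(nrow(Xs)), yi)] <- 1

  Ks <- gram(Xs, Xs, kernel)
  # (Ks^2 + lambda Ks) a = Ks Ys  <=>  (Ks + lambda I) a = Ys  for Ks > 0
  a_src <- solve(Ks + diag(lambda, nrow(Ks)), Ys)
  Ft <- gram(as.matrix(X_target), Xs, kernel) %*% a_src
  Kt <- gram(as.matrix(X_target), as.matrix(X_target), kernel)
  mapca_source(project_to_reference(Ft, Kt), origin = "projected",
               name = name)
}

#' Kernel maximum-mean-discrepancy between two domains
#'
#' Squared (biased, V-statistic) MMD with the given kernel:
#' \code{mean(K_aa) - 2 mean(K_ab) + mean(K_bb)}. Zero for identical samples
#' and symmetric in its arguments. Used by the distance-based source
#' weighting scheme.
#'
#' @param X_a,X_b feature matrices sharing the feature dimension.
#' @param kernel kernel spec or stack.
#' @return nonnegative scalar.
#' @export
domain_distance <- function(X_a, X_b, kernel = kernel_spec()) {
  X_a <- as.matrix(X_a); X_b <- as.matrix(X_b)
  if (nrow(X_a) == 0L || nrow(X_b) == 0L)
    stop("domains must be non-empty", call. = FALSE)
  if (ncol(X_a) != ncol(X_b))
    stop("domains must share the feature dimension", call. = FALSE)
  max(mean(gram(X_a, X_a, kernel)) - 2 * mean(gram(X_a, X_b, kernel)) +
        mean(gram(X_b, X_b, kernel)), 0)
}

#' Source weights under the ablation weighting schemes
#'
#' Produces a simplex weight vector over q sources:
#' \describe{
#'   \item{uniform}{\eqn{\gamma_i = 1/q} (the NSS ablation: mean fusion).}
#'   \item{distance}{\eqn{\gamma_i \propto \exp(-\delta\,
#'     \mathrm{Dist}(X^s_i, X))} (the NOS ablation; Dist is the kernel MMD of
#'     \code{\link{domain_distance}}), default \eqn{\delta = 100}.}
#'   \item{optimal}{delegates to \code{\link{update_gamma}} on the
#'     adaptation scores A.}
#'   \item{fixed}{validates and passes through user weights.}
#' }
#'
#' @param scheme one of \code{"uniform"}, \code{"distance"},
#'   \code{"optimal"}, \code{"fixed"}.
#' @param q number of sources (required for \code{"uniform"}).
#' @param A adaptation scores (for \code{"optimal"}).
#' @param distances domain distances (for \code{"distance"}).
#' @param eta ridge weight for \code{"optimal"}.
#' @param delta softmax sharpness for \code{"distance"} (default 100).
#' @param weights simplex vector for \code{"fixed"}.
#' @return simplex weight vector.
#' @export
make_weights <- function(scheme = c("uniform", "distance", "optimal",
                                    "fixed"),
                         q = NULL, A = NULL, distances = NULL, eta = 1,
                         delta = 100, weights = NULL) {
  scheme <- match.arg(scheme)
  switch(scheme,
         uniform = {
           if (is.null(q) || q < 1) stop("q required", call. = FALSE)
           rep(1 / q, q)
         },
         distance = {
           if (is.null(distances)) stop("distances required", call. = FALSE)
           e <- exp(-delta * (distances - min(distances)))  # stable softmax
           e / sum(e)
         },
         optimal = {
           if (is.null(A)) stop("A required", call. = FALSE)
           update_gamma(A, eta)
         },
         fixed = {
           if (is.null(weights) || any(weights < 0) ||
               abs(sum(weights) - 1) > 1e-8)
             stop("weights must lie on the probability simplex",
                  call. = FALSE)
           as.numeric(weights)
         })
}

#' No-adaptation fused baseline
#'
#' The comparator without domain adaptation: independently trained
#' classifiers (the target's labelled-data classifier plus each projected
#' source model) have their decision values fused by an unweighted mean, and
#' classes are read off the fused values.
#'
#' @param fit a \code{mapca_fit} trained with \code{beta = 0} (its alpha is
#'   the target-only classifier).
#' @param sources list of \code{mapca_source} over the same reference sample.
#' @return predicted labels for every training instance.
#' @export
fused_baseline_labels <- function(fit, sources) {
  K <- gram(fit$X, fit$X, fit$kernel)
  Fs <- lapply(c(list(fit$alpha), lapply(sources, `[[`, "alpha")),
               function(a) K %*% a)
  F <- Reduce(`+`, Fs) / length(Fs)
  fit$classes[apply(proto_dist2(F), 1L, which.min)]
}
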