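#' Kernel specification
#'
#' The four kernel families used by the solver, all functions of the Euclidean
#' distance \eqn{r = \|a - b\|} with width \eqn{\sigma > 0}:
#' \describe{
#'   \item{gaussian}{\eqn{\exp(-\sigma r^2)} (the default family)}
#'   \item{inverse_square_distance}{\eqn{1 / (1 + \sigma r^2)}}
#'   \item{laplacian}{\eqn{\exp(-\sigma r)}}
#'   \item{inverse_distance}{\eqn{1 / (1 + \sigma r)}}
#' }
#' All take value 1 at zero distance and values in (0, 1].
#'
#' @param family one of \code{"gaussian"}, \code{"inverse_square_distance"},
#'   \code{"laplacian"}, \code{"inverse_distance"}.
#' @param sigma positive width. The default \code{NULL} resolves to
#'   \code{1/d} (the reciprocal feature dimension) when the kernel is first
#'   applied to data.
#' @return object of class \code{mapca_kernel}.
#' @export
kernel_spec <- function(family = c("gaussian", "inverse_square_distance",
                                   "laplacian", "inverse_distance"),
                        sigma = NULL) {
  family <- match.arg(family)
  if (!is.null(sigma)) {
    if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
        sigma <= 0)
      stop("sigma must be a positive finite scalar", call. = FALSE)
  }
  structure(list(family = family, sigma = sigma), class = "mapca_kernel")
}

#' @export
print.mapca_kernel <- function(x, ...) {
  cat(sprintf("mapca kernel: %s, sigma = %s\n", x$family,
              if (is.null(x$sigma)) "1/d (resolved at use)" else
                format(x$sigma)))
  invisible(x)
}

#' Concatenate kernel feature spaces
#'
#' Multi-kernel learning fuses several kernels by concatenating their feature
#' maps \eqn{\tilde\phi = [\phi_1; \ldots; \phi_U]}. The inner product in the
#' concatenated space is additive across blocks, so the effective Gram matrix
#' is the elementwise sum of the per-kernel Gram matrices; all solver shapes
#' are unchanged.
#'
#' @param specs a non-empty list of \code{\link{kernel_spec}} objects
#'   (typically the four families with a shared sigma).
#' @return object of class \code{mapca_kernel_stack}.
#' @export
stack_kernels <- function(specs) {
  if (inherits(specs, "mapca_kernel")) specs <- list(specs)
  if (!is.list(specs) || length(specs) == 0L ||
      !all(vapply(specs, inherits, logical(1), "mapca_kernel")))
    stop("specs must be a non-empty list of kernel_spec objects",
         call. = FALSE)
  structure(list(specs = specs), class = "mapca_kernel_stack")
}

#' Default multi-kernel stack: the four families at a common width
#' @param sigma shared width (NULL = 1/d at use).
#' @return a \code{mapca_kernel_stack} of the four families.
#' @export
default_multikernel <- function(sigma = NULL) {
  stack_kernels(lapply(c("gaussian", "inverse_square_distance",
                         "laplacian", "inverse_distance"),
                       kernel_spec, sigma = sigma))
}

resolve_sigma <- function(spec, d) {
  if (is.null(spec$sigma)) 1 / d else spec$sigma
}

cross_dist2 <- function(A, B) {
  # squared Euclidean distances, p x q
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' Kernel (cross-)Gram matrix
#'
#' Evaluates the kernel between every row of \code{A} and every row of
#' \code{B}. With a \code{mapca_kernel_stack}, returns the sum of the member
#' Gram matrices (the concatenated-feature-space inner product).
#'
#' @param A p x d numeric matrix.
#' @param B q x d numeric matrix (defaults to \code{A}).
#' @param spec a \code{\link{kernel_spec}} or \code{\link{stack_kernels}}
#'   object.
#' @return p x q kernel matrix.
#' @export
gram <- function(A, B = A, spec = kernel_spec()) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(is.finite(A)) || !all(is.finite(B)))
    stop("kernel inputs must be finite", call. = FALSE)
  if (ncol(A) != ncol(B))
    stop("A and B must share the feature dimension", call. = FALSE)
  if (inherits(spec, "mapca_kernel_stack")) {
    return(Reduce(`+`, lapply(spec$specs, function(s) gram(A, B, s))))
  }
  stopifnot(inherits(spec, "mapca_kernel"))
  sigma <- resolve_sigma(spec, ncol(A))
  d2 <- cross_dist2(A, B)
  switch(spec$family,
         gaussian = exp(-sigma * d2),
         inverse_square_distance = 1 / (1 + sigma * d2),
         laplacian = exp(-sigma * sqrt(d2)),
         inverse_distance = 1 / (1 + sigma * sqrt(d2)))
}

#' Gram and cross-Gram pair for a dataset and its local weighted means
#'
#' @param X n x d feature matrix.
#' @param Xhat n x d matrix of local weighted means.
#' @param spec kernel spec or stack.
#' @return list with \code{K} (\code{gram(X, X)}) and \code{Kbar}
#'   (\code{Kbar[j, i] = kernel(xhat_j, x_i)}).
#' @export
gram_pair <- function(X, Xhat, spec = kernel_spec()) {
  list(K = gram(X, X, spec), Kbar = gram(Xhat, X, spec))
}
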