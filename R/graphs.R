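#' k-nearest-neighbour graph with Gaussian edge weights
#'
#' Builds the undirected weighted graph \eqn{G = (X, D)} underlying the local
#' consistency regulariser: each instance is connected to its \code{k} nearest
#' neighbours in Euclidean distance, and an edge carries the Gaussian weight
#' \eqn{D_{ij} = \exp(-\tau \|x_i - x_j\|^2)}. The weight matrix is
#' symmetrised by taking the maximum of the two directed assignments; the
#' directed neighbour sets are kept for the local weighted mean
#' (\code{\link{local_weighted_mean}}), which sums over \eqn{Ks(x_i)} only.
#'
#' Ties at the k-th smallest distance are broken deterministically in favour of
#' the lowest instance index. An instance is never its own neighbour.
#'
#' @param X numeric matrix, rows are instances, columns features. Must be
#'   finite.
#' @param k number of neighbours per instance; requires \code{nrow(X) >= k+1}.
#' @param tau positive Gaussian width parameter. When \code{NULL}, set to
#'   \code{1 / (2 * median pairwise squared distance)}, a scale-robust default.
#' @return an object of class \code{mapca_graph}: a list with elements
#'   \code{n}, \code{k}, \code{tau}, \code{neighbor_index} (n x k matrix of
#'   1-based neighbour indices, ordered by increasing distance) and \code{D}
#'   (symmetric n x n weight matrix).
#' @examples
#' X <- matrix(rnorm(40), 20, 2)
#' g <- knn_graph(X, k = 3)
#' all(g$D == t(g$D))
#' @export
knn_graph <- function(X, k = 5, tau = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(X) || !all(is.finite(X)))
    stop("X must be a finite numeric matrix", call. = FALSE)
  n <- nrow(X)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("k must be a positive integer", call. = FALSE)
  if (k >= n)
    stop("k must be smaller than the number of instances (need n >= k + 1)",
         call. = FALSE)
  d2 <- as.matrix(stats::dist(X))^2
  if (is.null(tau)) {
    off <- d2[upper.tri(d2)]
    med <- stats::median(off)
    if (!is.finite(med) || med <= 0) med <- 1
    tau <- 1 / (2 * med)
  }
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("tau must be a positive finite scalar", call. = FALSE)

  self_excl <- d2
  diag(self_excl) <- Inf
  # order() is stable, so equal distances resolve to the lowest index
  nbr <- t(apply(self_excl, 1L, function(row) order(row)[seq_len(k)]))
  if (k == 1L) nbr <- matrix(nbr, ncol = 1L)

  W <- matrix(0, n, n)
  ii <- rep(seq_len(n), each = k)
  jj <- as.vector(t(nbr))
  W[cbind(ii, jj)] <- exp(-tau * d2[cbind(ii, jj)])
  D <- pmax(W, t(W))

  structure(list(n = n, k = as.integer(k), tau = tau,
                 neighbor_index = nbr, D = D),
            class = "mapca_graph")
}

#' @export
print.mapca_graph <- function(x, ...) {
  cat(sprintf("mapca kNN graph: %d instances, k = %d, tau = %.4g, %d edges\n",
              x$n, x$k, x$tau, sum(x$D > 0) / 2L))
  invisible(x)
}

#' Local weighted mean of every instance
#'
#' Computes, for each instance, the local weighted mean (LWM)
#' \deqn{\hat x_i = \sum_{x_j \in Ks(x_i)} D_{ij} x_j \Big/
#'       \sum_{x_j \in Ks(x_i)} D_{ij},}
#' the Gaussian-weighted average of its k nearest neighbours. The LWM lies in
#' the convex hull of the neighbours; the classifier requires an instance and
#' its LWM to receive consistent labels. The sum runs over the directed
#' neighbour set \eqn{Ks(x_i)} (the instance itself excluded).
#'
#' @param X the feature matrix the graph was built on.
#' @param graph a \code{mapca_graph} from \code{\link{knn_graph}}.
#' @return n x d numeric matrix whose row i is \eqn{\hat x_i}.
#' @export
local_weighted_mean <- function(X, graph) {
  X <- as.matrix(X)
  stopifnot(inherits(graph, "mapca_graph"))
  if (nrow(X) != graph$n)
    stop("X does not match the graph (row count differs)", call. = FALSE)
  n <- graph$n
  Xhat <- matrix(NA_real_, n, ncol(X))
  for (i in seq_len(n)) {
    js <- graph$neighbor_index[i, ]
    w <- exp(-graph$tau * colSums((t(X[js, , drop = FALSE]) - X[i, ])^2))
    sw <- sum(w)
    if (sw <= 0)
      stop("degenerate graph: all neighbour weights underflowed to zero; ",
           "reduce tau", call. = FALSE)
    Xhat[i, ] <- as.vector(w %*% X[js, , drop = FALSE]) / sw
  }
  dimnames(Xhat) <- dimnames(X)
  Xhat
}
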