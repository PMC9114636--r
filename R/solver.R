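#' Solver control parameters
#'
#' Balance weights and iteration controls for the alternating optimisation.
#' The objective combines (i) squared losses of labelled samples and their
#' local weighted means against their labels, (ii) membership-weighted squared
#' losses of unlabelled samples (and LWMs) against the class prototypes,
#' (iii) an RKHS norm penalty, (iv) a fuzzy-entropy regulariser
#' \eqn{C \sum (v^2 \ln v^2 - v^2)} that yields closed-form exponential
#' memberships and damps outliers, and (v) a divergence-weighted discrepancy
#' to pre-trained source models with simplex source weights.
#'
#' @param lambda RKHS norm weight (> 0).
#' @param lambda_s local-weighted-mean consistency weight (>= 0).
#' @param C fuzzy-entropy weight (> 0).
#' @param beta source-adaptation weight (>= 0; 0 disables adaptation and the
#'   fit degenerates to the single-domain semi-supervised model, SSPCA).
#' @param eta ridge weight on the source-weight vector gamma (> 0). Large eta
#'   drives gamma toward uniform weights; small eta lets it concentrate on the
#'   closest sources.
#' @param max_iter maximum number of alternating cycles N.
#' @param window window size (>= 2) for the stopping rule: the fit halts when
#'   the relative spread |max - min| / |max| of the last \code{window}
#'   objective values falls below \code{eps}.
#' @param eps stopping threshold (0 < eps < 1).
#' @param membership_lwm_weighted logical; if \code{TRUE} (default) the
#'   membership update weights the LWM distance by \code{lambda_s}, which is
#'   the stationarity-consistent form of the exponential update; if
#'   \code{FALSE} the LWM distance enters unweighted.
#' @param v_init membership initialisation for the very first decision-model
#'   solve: \code{"zero"} (default: first model fitted from labelled data
#'   only), \code{"one"}, or \code{"random"} (requires a seed for
#'   reproducibility).
#' @return list of class \code{mapca_control}.
#' @export
mapca_control <- function(lambda = 1, lambda_s = 1, C = 1, beta = 1, eta = 1,
                          max_iter = 50, window = 5, eps = 1e-4,
                          membership_lwm_weighted = TRUE,
                          v_init = c("zero", "one", "random")) {
  v_init <- match.arg(v_init)
  stopifnot(is.finite(lambda), lambda > 0,
            is.finite(lambda_s), lambda_s >= 0,
            is.finite(C), C > 0,
            is.finite(beta), beta >= 0,
            is.finite(eta), eta > 0,
            max_iter >= 1, window >= 2,
            is.finite(eps), eps > 0, eps < 1)
  structure(list(lambda = lambda, lambda_s = lambda_s, C = C, beta = beta,
                 eta = eta, max_iter = as.integer(max_iter),
                 window = as.integer(window), eps = eps,
                 membership_lwm_weighted = isTRUE(membership_lwm_weighted),
                 v_init = v_init),
            class = "mapca_control")
}

#' Assemble a training problem
#'
#' Precomputes everything the alternating updates need: the neighbour graph,
#' the local weighted means, the Gram matrix K over samples and the cross-Gram
#' Kbar between LWM points and samples, the one-hot label encoding and the
#' class prototypes (the one-hot basis vectors in label space).
#'
#' @param X n x d feature matrix.
#' @param y length-n label vector (factor or integer); \code{NA} marks
#'   unlabelled instances. Every class must have at least one labelled
#'   instance.
#' @param sources list of \code{mapca_source} objects sharing the reference
#'   sample (may be empty; then adaptation requires \code{beta = 0}).
#' @param kernel a \code{\link{kernel_spec}} or \code{\link{stack_kernels}}.
#' @param k,tau graph parameters passed to \code{\link{knn_graph}}.
#' @return list of class \code{mapca_problem}.
#' @export
mapca_problem <- function(X, y, sources = list(), kernel = kernel_spec(),
                          k = 5, tau = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("y must have one entry per row of X", call. = FALSE)
  if (is.factor(y)) {
    classes <- levels(y)
    yi <- as.integer(y)
  } else {
    classes <- sort(unique(y[!is.na(y)]))
    yi <- match(y, classes)
  }
  M <- length(classes)
  if (M < 2) stop("need at least two classes among the labelled instances",
                  call. = FALSE)
  labeled <- !is.na(yi)
  if (!all(seq_len(M) %in% yi[labeled]))
    stop("every class needs at least one labelled instance", call. = FALSE)

  graph <- knn_graph(X, k = k, tau = tau)
  Xhat <- local_weighted_mean(X, graph)
  gp <- gram_pair(X, Xhat, kernel)

  Ytilde <- matrix(0, n, M)
  Ytilde[cbind(which(labeled), yi[labeled])] <- 1

  if (inherits(sources, "mapca_source")) sources <- list(sources)
  for (s in sources) {
    if (!inherits(s, "mapca_source"))
      stop("sources must be mapca_source objects", call. = FALSE)
    if (!identical(dim(s$alpha), c(n, M)))
      stop("source model does not match the target reference sample ",
           "(expected ", n, " x ", M, " dual coefficients)", call. = FALSE)
  }

  structure(list(X = X, y = yi, classes = classes, M = M, n = n,
                 labeled = labeled, Ytilde = Ytilde,
                 graph = graph, Xhat = Xhat,
                 K = gp$K, Kbar = gp$Kbar,
                 kernel = kernel, sources = sources,
                 centers = diag(M)),
            class = "mapca_problem")
}

# squared distances of decision-value rows to every class prototype e_m:
# out[j, m] = ||F[j, ] - e_m||^2
proto_dist2 <- function(F) {
  n2 <- rowSums(F^2)
  d2 <- matrix(n2, nrow(F), ncol(F)) - 2 * F + 1
  d2[d2 < 0] <- 0
  d2
}

#' Full objective value
#'
#' Evaluates the scalar objective at the given coordinates: labelled losses
#' (sample and LWM, the latter weighted by \code{lambda_s}),
#' membership-squared-weighted unlabelled losses to the class prototypes, the
#' RKHS penalty \eqn{\lambda\,\mathrm{tr}(\alpha^T K \alpha)}, the fuzzy
#' entropy term, and, when \code{beta > 0} and sources are present,
#' \eqn{\beta(\sum_i \gamma_i A_i + \eta \|\gamma\|^2)}. Zero memberships use
#' the continuous limit \eqn{v^2 \ln v^2 \to 0}.
#'
#' @param alpha n x M dual coefficient matrix.
#' @param V n x M membership matrix (rows of labelled instances are ignored).
#' @param gamma simplex weight vector over sources (length 0 when no sources).
#' @param prob a \code{\link{mapca_problem}}.
#' @param control a \code{\link{mapca_control}}.
#' @param A optional precomputed adaptation scores (recomputed if NULL).
#' @return scalar objective value.
#' @export
mapca_objective <- function(alpha, V, gamma, prob, control = mapca_control(),
                            A = NULL) {
  F  <- prob$K %*% alpha
  Fb <- prob$Kbar %*% alpha
  L <- prob$labeled
  Y <- prob$Ytilde
  q_lab <- sum((F[L, , drop = FALSE] - Y[L, , drop = FALSE])^2) +
    control$lambda_s * sum((Fb[L, , drop = FALSE] - Y[L, , drop = FALSE])^2)

  U <- !L
  q_unlab <- 0
  q_ent <- 0
  if (any(U)) {
    d2  <- proto_dist2(F[U, , drop = FALSE])
    d2b <- proto_dist2(Fb[U, , drop = FALSE])
    v2 <- V[U, , drop = FALSE]^2
    q_unlab <- sum(v2 * (d2 + control$lambda_s * d2b))
    ent <- v2 * log(v2) - v2
    ent[v2 == 0] <- 0
    q_ent <- control$C * sum(ent)
  }
  q_rkhs <- control$lambda * sum(alpha * (prob$K %*% alpha))
  q_adapt <- 0
  if (control$beta > 0 && length(prob$sources) > 0) {
    if (is.null(A)) A <- adaptation_scores(alpha, prob)
    q_adapt <- control$beta * (sum(gamma * A) + control$eta * sum(gamma^2))
  }
  q_lab + q_unlab + q_rkhs + q_ent + q_adapt
}

#' Closed-form update of the dual coefficients
#'
#' Solves the normal equations \eqn{H\alpha = B} obtained by setting the
#' objective's gradient in \eqn{\alpha} to zero with memberships and source
#' weights fixed:
#' \deqn{H = K S_L K + \lambda_s \bar K^T S_L \bar K + K \hat V K
#'   + \lambda_s \bar K^T \hat V \bar K + \lambda K
#'   + (\beta/n)(\textstyle\sum_i \gamma_i) K K}
#' \deqn{B = (K + \lambda_s \bar K^T) S_L \tilde Y
#'   + (K + \lambda_s \bar K^T) V_{sq} + (\beta/n) K K \sum_i \gamma_i
#'   \alpha^s_i}
#' where \eqn{S_L} is the labelled-indicator diagonal, \eqn{\hat V} the
#' diagonal of summed squared memberships, and \eqn{V_{sq}} the matrix of
#' squared memberships against one-hot prototypes. A tiny ridge jitter
#' (\code{1e-10 tr(H)/n}) is added only if the plain solve fails.
#'
#' @inheritParams mapca_objective
#' @return n x M matrix of dual coefficients.
#' @export
update_alpha <- function(V, gamma, prob, control = mapca_control()) {
  K <- prob$K; Kb <- prob$Kbar
  n <- prob$n
  sl <- as.numeric(prob$labeled)
  Vsq <- V^2
  Vsq[prob$labeled, ] <- 0
  vhat <- rowSums(Vsq)

  H <- K %*% (sl * K) + control$lambda_s * crossprod(Kb, sl * Kb) +
    K %*% (vhat * K) + control$lambda_s * crossprod(Kb, vhat * Kb) +
    control$lambda * K
  B <- K %*% (sl * prob$Ytilde) +
    control$lambda_s * crossprod(Kb, sl * prob$Ytilde) +
    K %*% Vsq + control$lambda_s * crossprod(Kb, Vsq)

  if (control$beta > 0 && length(prob$sources) > 0) {
    KK <- K %*% K
    H <- H + (control$beta / n) * sum(gamma) * KK
    alpha_mix <- Reduce(`+`, Map(function(g, s) g * s$alpha,
                                 gamma, prob$sources))
    B <- B + (control$beta / n) * KK %*% alpha_mix
  }

  alpha <- tryCatch(solve(H, B), error = function(e) NULL)
  if (is.null(alpha)) {
    jitter <- 1e-10 * sum(diag(H)) / n
    alpha <- tryCatch(solve(H + diag(jitter, n), B), error = function(e) NULL)
    if (is.null(alpha))
      stop("normal-equation matrix is singular; increase lambda",
           call. = FALSE)
  }
  alpha
}

#' Closed-form possibilistic membership update
#'
#' With the decision model fixed, each unlabelled instance j and class m gets
#' the independent (possibilistic) membership
#' \deqn{v_m(x_j) = \exp\!\big(-(\|f(x_j) - c_m\|^2 +
#'   w\,\|f(\hat x_j) - c_m\|^2) / (2C)\big),}
#' with \eqn{w = \lambda_s} when \code{membership_lwm_weighted} and
#' \eqn{w = 1} otherwise. Memberships are not constrained to sum to one across
#' classes, so outliers can hold uniformly low memberships. Values are clamped
#' below at 1e-300 against underflow.
#'
#' @inheritParams mapca_objective
#' @return n x M membership matrix (labelled rows set to 0, unused).
#' @export
update_membership <- function(alpha, prob, control = mapca_control()) {
  F  <- prob$K %*% alpha
  Fb <- prob$Kbar %*% alpha
  w <- if (control$membership_lwm_weighted) control$lambda_s else 1
  V <- matrix(0, prob$n, prob$M)
  U <- !prob$labeled
  if (any(U)) {
    d2 <- proto_dist2(F[U, , drop = FALSE]) +
      w * proto_dist2(Fb[U, , drop = FALSE])
    V[U, ] <- pmax(exp(-d2 / (2 * control$C)), 1e-300)
  }
  V
}

#' Adaptation scores of the source models
#'
#' \eqn{A_i} measures the divergence-weighted discrepancy between the current
#' target model and source model i. With the target-scatter divergence
#' \eqn{S = XX^T} estimated by the empirical sampling frequency \eqn{1/n},
#' \deqn{A_i = \frac{1}{n} \|K(\alpha - \alpha^s_i)\|_F^2
#'     = \frac{1}{n} \sum_j \|f(x_j) - f^s_i(x_j)\|^2.}
#' With \code{divergence = "identity"} (the NTS ablation, S = I) the score is
#' the RKHS discrepancy \eqn{\mathrm{tr}[(\Delta\alpha)^T K \Delta\alpha]}.
#'
#' @param alpha current dual coefficients.
#' @param prob a \code{\link{mapca_problem}} with at least one source.
#' @param divergence \code{"target_scatter"} (default) or \code{"identity"}.
#' @return nonnegative numeric vector of length q.
#' @export
adaptation_scores <- function(alpha, prob,
                              divergence = c("target_scatter", "identity")) {
  divergence <- match.arg(divergence)
  if (length(prob$sources) == 0L)
    stop("no source models in the problem", call. = FALSE)
  vapply(prob$sources, function(s) {
    da <- alpha - s$alpha
    if (divergence == "target_scatter") {
      sum((prob$K %*% da)^2) / prob$n
    } else {
      sum(da * (prob$K %*% da))
    }
  }, numeric(1))
}

#' Simplex-constrained source-weight update
#'
#' Minimises \eqn{\gamma^T A + \eta\|\gamma\|^2} over the probability simplex
#' by sweeps of the pairwise three-case coordinate rule: for a pair (i, j)
#' with mass \eqn{s = \gamma_i + \gamma_j}, the unconstrained optimum
#' \eqn{\gamma_i = s/2 + (A_j - A_i)/(4\eta)} is clamped to \eqn{[0, s]}.
#' Sweeps repeat until no coordinate moves by more than \code{tol}.
#' Smaller scores receive larger weights; with widely separated scores and
#' small eta the solution is sparse, and as eta grows it tends to uniform
#' weights 1/q.
#'
#' @param A nonnegative score vector (length q >= 1).
#' @param eta positive ridge weight.
#' @param gamma0 optional starting point on the simplex (default uniform).
#' @param tol convergence tolerance on the largest coordinate change per
#'   sweep (default 1e-12).
#' @return simplex weight vector of length q.
#' @export
update_gamma <- function(A, eta, gamma0 = NULL, tol = 1e-12) {
  q <- length(A)
  if (q == 0L) stop("A must be non-empty", call. = FALSE)
  stopifnot(is.finite(eta), eta > 0, all(is.finite(A)))
  if (q == 1L) return(1)
  gamma <- if (is.null(gamma0)) rep(1 / q, q) else gamma0
  stopifnot(length(gamma) == q, all(gamma >= 0),
            abs(sum(gamma) - 1) < 1e-8)
  for (sweep in seq_len(100000L)) {
    moved <- 0
    for (i in seq_len(q - 1L)) {
      for (j in seq(i + 1L, q)) {
        s <- gamma[i] + gamma[j]
        if (s == 0) next
        gi <- s / 2 + (A[j] - A[i]) / (4 * eta)
        gi <- min(max(gi, 0), s)
        moved <- max(moved, abs(gamma[i] - gi))
        gamma[i] <- gi
        gamma[j] <- s - gi
      }
    }
    if (moved < tol) break
  }
  gamma
}

#' Fit the multi-source possibilistic semi-supervised classifier
#'
#' Alternating optimisation: initialise source weights uniformly and
#' memberships per \code{control$v_init}, solve the first decision model from
#' the labelled data, compute initial memberships, then cycle closed-form
#' updates of the dual coefficients, the memberships, and (when adaptation is
#' active with the \code{"optimal"} scheme) the simplex source weights. Each
#' partial update globally minimises its coordinate subproblem, so the
#' objective is non-increasing across partial updates and cycles. Iteration
#' stops when the relative spread of the last \code{window} objective values
#' drops below \code{eps}, or after \code{max_iter} cycles.
#'
#' @param X n x d feature matrix (target domain).
#' @param y length-n labels with \code{NA} for unlabelled instances.
#' @param sources list of \code{\link{mapca_source}} models over the target
#'   reference sample (empty list requires \code{beta = 0} in practice; with
#'   no sources the adaptation term is dropped and the fit is the
#'   single-domain semi-supervised model).
#' @param kernel kernel spec or stack.
#' @param k,tau graph parameters.
#' @param control a \code{\link{mapca_control}}.
#' @param weighting source weighting scheme: \code{"optimal"} (updated each
#'   cycle by \code{\link{update_gamma}}), \code{"uniform"} (fixed 1/q), or
#'   \code{"fixed"} (user-supplied simplex vector, e.g. from
#'   \code{\link{make_weights}} in distance mode).
#' @param fixed_weights simplex vector for \code{weighting = "fixed"}.
#' @param divergence divergence used in the adaptation scores (see
#'   \code{\link{adaptation_scores}}); \code{"identity"} gives the NTS
#'   ablation.
#' @param seed optional integer seed, used only by the \code{"random"}
#'   membership initialisation.
#' @param verbose log the per-iteration objective via \code{message()}.
#' @return object of class \code{mapca_fit}: dual coefficients \code{alpha},
#'   source weights \code{gamma}, memberships \code{V}, objective history
#'   (\code{obj_history} per cycle; \code{obj_partial} an iter x 3 matrix of
#'   the objective after the alpha / membership / gamma partial updates),
#'   iteration count, convergence flag and \code{stop_reason}
#'   (\code{"window"} or \code{"max_iter"}), plus everything needed for
#'   out-of-sample prediction.
#' @examples
#' set.seed(1)
#' d <- make_domain(domain_config(n_per_class = 15, seed = 2))
#' y <- ifelse(d$labeled, d$y, NA)
#' fit <- mapca(d$X, y, control = mapca_control(beta = 0))
#' fit$stop_reason
#' @export
mapca <- function(X, y, sources = list(), kernel = kernel_spec(),
                  k = 5, tau = NULL, control = mapca_control(),
                  weighting = c("optimal", "uniform", "fixed"),
                  fixed_weights = NULL,
                  divergence = c("target_scatter", "identity"),
                  seed = NULL, verbose = FALSE) {
  weighting <- match.arg(weighting)
  divergence <- match.arg(divergence)
  prob <- mapca_problem(X, y, sources = sources, kernel = kernel,
                        k = k, tau = tau)
  q <- length(prob$sources)
  adapt <- control$beta > 0 && q > 0

  gamma <- if (q > 0) {
    switch(weighting,
           optimal = rep(1 / q, q),
           uniform = rep(1 / q, q),
           fixed = {
             if (is.null(fixed_weights) || length(fixed_weights) != q ||
                 any(fixed_weights < 0) || abs(sum(fixed_weights) - 1) > 1e-8)
               stop("fixed_weights must be a simplex vector of length q",
                    call. = FALSE)
             as.numeric(fixed_weights)
           })
  } else numeric(0)

  V <- matrix(0, prob$n, prob$M)
  if (control$v_init == "one") {
    V[!prob$labeled, ] <- 1
  } else if (control$v_init == "random") {
    if (!is.null(seed)) set.seed(seed)
    V[!prob$labeled, ] <- stats::runif(sum(!prob$labeled) * prob$M)
  }

  alpha <- update_alpha(V, gamma, prob, control)
  V <- update_membership(alpha, prob, control)
  A <- if (adapt) adaptation_scores(alpha, prob, divergence) else NULL
  obj0 <- mapca_objective(alpha, V, gamma, prob, control, A = A)
  obj_history <- obj0
  obj_partial <- matrix(numeric(0), 0, 3,
                        dimnames = list(NULL, c("alpha", "membership",
                                                "gamma")))
  stop_reason <- "max_iter"
  iter <- 0L
  for (itr in seq_len(control$max_iter)) {
    iter <- itr
    alpha <- update_alpha(V, gamma, prob, control)
    A <- if (adapt) adaptation_scores(alpha, prob, divergence) else NULL
    q1 <- mapca_objective(alpha, V, gamma, prob, control, A = A)
    V <- update_membership(alpha, prob, control)
    q2 <- mapca_objective(alpha, V, gamma, prob, control, A = A)
    if (adapt && weighting == "optimal")
      gamma <- update_gamma(A, control$eta, gamma0 = gamma)
    q3 <- mapca_objective(alpha, V, gamma, prob, control, A = A)
    obj_partial <- rbind(obj_partial, c(q1, q2, q3))
    obj_history <- c(obj_history, q3)
    if (verbose)
      message(sprintf("iter %3d: objective %.8g", itr, q3))
    if (length(obj_history) >= control$window) {
      win <- utils::tail(obj_history, control$window)
      spread <- abs(max(win) - min(win)) / max(abs(max(win)), 1e-300)
      if (spread < control$eps) { stop_reason <- "window"; break }
    }
  }
  if (verbose)
    message(sprintf("stopped after %d iterations (%s)", iter, stop_reason))

  structure(list(alpha = alpha, gamma = gamma, V = V, A = A,
                 obj_history = obj_history, obj_partial = obj_partial,
                 iterations = iter, converged = stop_reason == "window",
                 stop_reason = stop_reason,
                 X = prob$X, Xhat = prob$Xhat, y = prob$y,
                 classes = prob$classes, labeled = prob$labeled,
                 centers = prob$centers, kernel = prob$kernel,
                 graph_k = prob$graph$k, graph_tau = prob$graph$tau,
                 control = control, weighting = weighting,
                 divergence = divergence),
            class = "mapca_fit")
}

#' Single-domain semi-supervised fit (no source adaptation)
#'
#' The degenerate case of \code{\link{mapca}} with the adaptation term
#' removed (beta = 0, no sources): a graph-regularised possibilistic
#' semi-supervised kernel classifier (SSPCA).
#'
#' @inheritParams mapca
#' @return a \code{mapca_fit}.
#' @export
sspca <- function(X, y, kernel = kernel_spec(), k = 5, tau = NULL,
                  control = mapca_control(), seed = NULL, verbose = FALSE) {
  control$beta <- 0
  mapca(X, y, sources = list(), kernel = kernel, k = k, tau = tau,
        control = control, seed = seed, verbose = verbose)
}

#' @export
print.mapca_fit <- function(x, ...) {
  cat(sprintf(paste0("mapca fit: %d instances (%d labelled), %d classes, ",
                     "%d sources\n"),
              nrow(x$X), sum(x$labeled), length(x$classes), length(x$gamma)))
  cat(sprintf("  %d iterations, stop: %s, final objective %.6g\n",
              x$iterations, x$stop_reason, utils::tail(x$obj_history, 1)))
  if (length(x$gamma))
    cat("  gamma:", paste(sprintf("%.3f", x$gamma), collapse = " "), "\n")
  invisible(x)
}

#' Predict classes and memberships for new instances
#'
#' Evaluates the decision function \eqn{f(x) = \alpha^T k(x)} against the
#' training sample, assigns the class whose prototype is nearest (ties to the
#' lowest class index), and computes possibilistic memberships from the
#' distances of \eqn{f(x)} and \eqn{f(\hat x)} to the prototypes, where
#' \eqn{\hat x} is the local weighted mean of x over its k nearest training
#' samples (same Gaussian weights as training).
#'
#' @param object a \code{mapca_fit}.
#' @param newdata matrix of new instances (training feature dimension).
#' @param ... unused.
#' @return list with \code{class} (predicted labels on the original class
#'   scale), \code{decision} (n x M decision values), and \code{membership}
#'   (n x M possibilistic memberships in (0, 1]).
#' @export
predict.mapca_fit <- function(object, newdata, ...) {
  Xn <- as.matrix(newdata)
  if (ncol(Xn) != ncol(object$X))
    stop("newdata must have the training feature dimension", call. = FALSE)
  F <- gram(Xn, object$X, object$kernel) %*% object$alpha
  d2 <- proto_dist2(F)
  cls <- apply(d2, 1L, which.min)  # which.min takes the lowest index on ties

  # LWM of each new point over its k nearest training samples
  k <- object$graph_k
  tau <- object$graph_tau
  dx2 <- cross_dist2(Xn, object$X)
  Xhat <- matrix(NA_real_, nrow(Xn), ncol(Xn))
  for (i in seq_len(nrow(Xn))) {
    js <- order(dx2[i, ])[seq_len(k)]
    w <- exp(-tau * dx2[i, js])
    if (sum(w) <= 0)
      stop("degenerate neighbourhood weights; reduce tau", call. = FALSE)
    Xhat[i, ] <- as.vector(w %*% object$X[js, , drop = FALSE]) / sum(w)
  }
  Fb <- gram(Xhat, object$X, object$kernel) %*% object$alpha
  ctl <- object$control
  w <- if (ctl$membership_lwm_weighted) ctl$lambda_s else 1
  V <- pmax(exp(-(d2 + w * proto_dist2(Fb)) / (2 * ctl$C)), 1e-300)

  list(class = object$classes[cls], decision = F, membership = V)
}

#' Transductive labels of the unlabelled training instances
#'
#' @param fit a \code{mapca_fit}.
#' @return factor/vector of predicted labels for every training instance
#'   (labelled instances included), on the original class scale.
#' @export
transductive_labels <- function(fit) {
  F <- gram(fit$X, fit$X, fit$kernel) %*% fit$alpha
  fit$classes[apply(proto_dist2(F), 1L, which.min)]
}
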