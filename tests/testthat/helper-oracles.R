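# Independent, loop-based oracles. These deliberately avoid the package's
# vectorised code paths.

# brute-force kNN graph: all-pairs distances, lowest-index tie-break
oracle_graph <- function(X, k, tau) {
  n <- nrow(X)
  d2 <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) d2[i, j] <- sum((X[i, ] - X[j, ])^2)
  nbr <- matrix(0L, n, k)
  for (i in 1:n) {
    o <- setdiff(order(d2[i, ]), i)
    nbr[i, ] <- o[1:k]
  }
  W <- matrix(0, n, n)
  for (i in 1:n) for (j in nbr[i, ]) W[i, j] <- exp(-tau * d2[i, j])
  D <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) D[i, j] <- max(W[i, j], W[j, i])
  list(nbr = nbr, W = W, D = D)
}

oracle_lwm <- function(X, k, tau) {
  g <- oracle_graph(X, k, tau)
  n <- nrow(X)
  Xhat <- matrix(0, n, ncol(X))
  for (i in 1:n) {
    num <- rep(0, ncol(X)); den <- 0
    for (j in g$nbr[i, ]) {
      num <- num + g$W[i, j] * X[j, ]
      den <- den + g$W[i, j]
    }
    Xhat[i, ] <- num / den
  }
  Xhat
}

# Euclidean projection onto the probability simplex (sort-based closed form)
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  pmax(v - (css[rho] - 1) / rho, 0)
}

# exact solution of min gamma'A + eta ||gamma||^2 on the simplex
oracle_gamma <- function(A, eta) project_simplex(-A / (2 * eta))

# term-by-term objective summation with explicit loops
oracle_objective <- function(alpha, V, gamma, prob, control) {
  K <- prob$K; Kb <- prob$Kbar
  n <- prob$n; M <- prob$M
  f  <- t(alpha) %*% K        # column j = f(x_j)
  fb <- alpha2fb(alpha, Kb)   # column j = f(xhat_j)
  q <- 0
  for (i in which(prob$labeled)) {
    yi <- prob$Ytilde[i, ]
    q <- q + sum((f[, i] - yi)^2) + control$lambda_s * sum((fb[, i] - yi)^2)
  }
  for (j in which(!prob$labeled)) for (m in 1:M) {
    cm <- prob$centers[m, ]
    v2 <- V[j, m]^2
    q <- q + v2 * sum((f[, j] - cm)^2) +
      control$lambda_s * v2 * sum((fb[, j] - cm)^2)
    q <- q + control$C * (if (v2 > 0) v2 * log(v2) - v2 else 0)
  }
  q <- q + control$lambda * sum(diag(t(alpha) %*% K %*% alpha))
  if (control$beta > 0 && length(prob$sources) > 0) {
    A <- rep(0, length(prob$sources))
    for (i in seq_along(prob$sources)) {
      fs <- t(prob$sources[[i]]$alpha) %*% K
      for (j in 1:n) A[i] <- A[i] + sum((f[, j] - fs[, j])^2) / n
    }
    q <- q + control$beta * (sum(gamma * A) + control$eta * sum(gamma^2))
  }
  q
}

alpha2fb <- function(alpha, Kbar) {
  # f(xhat_j) = alpha' Kbar[j, ]'
  t(Kbar %*% alpha)
}

# normal-equation matrices assembled with explicit diagonal matrices
oracle_HB <- function(V, gamma, prob, control) {
  K <- prob$K; Kb <- prob$Kbar
  n <- prob$n; M <- prob$M
  SL <- diag(as.numeric(prob$labeled))
  Vm <- lapply(1:M, function(m) {
    d <- rep(0, n); d[!prob$labeled] <- V[!prob$labeled, m]^2
    diag(d)
  })
  Vhat <- Reduce(`+`, Vm)
  H <- K %*% SL %*% K + control$lambda_s * t(Kb) %*% SL %*% Kb +
    K %*% Vhat %*% K + control$lambda_s * t(Kb) %*% Vhat %*% Kb +
    control$lambda * K
  B <- K %*% SL %*% prob$Ytilde +
    control$lambda_s * t(Kb) %*% SL %*% prob$Ytilde
  ones <- rep(1, n)
  for (m in 1:M)
    B <- B + (K + control$lambda_s * t(Kb)) %*% Vm[[m]] %*% ones %*%
      t(prob$centers[m, ])
  if (control$beta > 0 && length(prob$sources) > 0) {
    KK <- K %*% K
    H <- H + (control$beta / n) * sum(gamma) * KK
    mix <- matrix(0, n, M)
    for (i in seq_along(gamma))
      mix <- mix + gamma[i] * prob$sources[[i]]$alpha
    B <- B + (control$beta / n) * KK %*% mix
  }
  list(H = H, B = B)
}

# 1-D grid search over v in (0, 1] of the per-entry membership subproblem
oracle_membership_entry <- function(a, b, w, C, step = 2.5e-5) {
  v <- seq(step, 1, by = step)
  g <- v^2 * (a + w * b) + C * (v^2 * log(v^2) - v^2)
  v[which.min(g)]
}

# loop-based biased MMD^2 with a Gaussian kernel
oracle_mmd2 <- function(Xa, Xb, sigma) {
  kf <- function(x, y) exp(-sigma * sum((x - y)^2))
  s1 <- 0
  for (i in 1:nrow(Xa)) for (j in 1:nrow(Xa)) s1 <- s1 + kf(Xa[i, ], Xa[j, ])
  s2 <- 0
  for (i in 1:nrow(Xa)) for (j in 1:nrow(Xb)) s2 <- s2 + kf(Xa[i, ], Xb[j, ])
  s3 <- 0
  for (i in 1:nrow(Xb)) for (j in 1:nrow(Xb)) s3 <- s3 + kf(Xb[i, ], Xb[j, ])
  s1 / nrow(Xa)^2 - 2 * s2 / (nrow(Xa) * nrow(Xb)) + s3 / nrow(Xb)^2
}

# small random labelled/unlabelled instance with random source models
random_instance <- function(seed, n = 12, M = 2, q = 2, d = 3,
                            control = mapca_control()) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  y <- rep(NA_integer_, n)
  y[1:M] <- 1:M
  extra <- sample((M + 1):n, 2)
  y[extra] <- sample(1:M, 2, replace = TRUE)
  sources <- replicate(q, mapca_source(matrix(rnorm(n * M, sd = 0.3), n, M)),
                       simplify = FALSE)
  prob <- mapca_problem(X, y, sources = sources, k = 3)
  V <- matrix(0, n, M)
  V[is.na(y), ] <- matrix(runif(sum(is.na(y)) * M, 0.05, 1),
                          sum(is.na(y)), M)
  gamma <- as.numeric(rexp(q)); gamma <- gamma / sum(gamma)
  list(X = X, y = y, prob = prob, V = V, gamma = gamma, control = control)
}

# study-condition settings of the adaptation experiments (see the methods
# vignette): beta/n ~ 1 so the adaptation term matches the per-instance
# weight of the clustering losses, small eta so source selection can
# concentrate
adaptation_control <- function(...) {
  mapca_control(beta = 100, eta = 0.1, ...)
}
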