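test_that("objective closed forms hold for the zero model", {
  # all labelled, alpha = 0, beta = 0: Q = l (1 + lambda_s) for one-hot labels
  set.seed(21)
  X <- matrix(rnorm(24), 8, 3)
  y <- rep(1:2, 4)
  prob <- mapca_problem(X, y, k = 3)
  ctl <- mapca_control(beta = 0, lambda_s = 0.7)
  a0 <- matrix(0, 8, 2)
  V <- matrix(0, 8, 2)
  expect_equal(mapca_objective(a0, V, numeric(0), prob, ctl), 8 * 1.7)

  # with unlabelled points and all memberships 1, the entropy term is
  # C * M * u * (0 - 1) and each unlabelled point adds (1 + lambda_s) ||c_m||^2
  y2 <- y; y2[5:8] <- NA
  prob2 <- mapca_problem(X, y2, k = 3)
  V1 <- matrix(0, 8, 2); V1[5:8, ] <- 1
  ctl2 <- mapca_control(beta = 0, lambda_s = 1, C = 2)
  # 4 labelled one-hot losses on sample + LWM, 4x2 unit prototype distances
  # at v = 1 (sample + LWM), entropy C (0 - 1) per unlabelled entry
  expect_equal(mapca_objective(a0, V1, numeric(0), prob2, ctl2),
               4 * (1 + 1) + 4 * 2 * (1 + 1) + 2 * (0 - 1) * 2 * 4)
})

test_that("objective matches an independently coded term-by-term sum", {
  for (seed in 1:6) {
    inst <- random_instance(seed, n = 8, M = 2, q = 2)
    alpha <- matrix(rnorm(16, sd = 0.4), 8, 2)
    q_pkg <- mapca_objective(alpha, inst$V, inst$gamma, inst$prob,
                             inst$control)
    q_orc <- oracle_objective(alpha, inst$V, inst$gamma, inst$prob,
                              inst$control)
    expect_equal(q_pkg, q_orc, tolerance = 1e-10)
  }
})

test_that("alpha update solves its normal equations and minimises the objective", {
  for (seed in 1:5) {
    inst <- random_instance(seed, n = 10, M = 2, q = 2)
    alpha <- update_alpha(inst$V, inst$gamma, inst$prob, inst$control)
    hb <- oracle_HB(inst$V, inst$gamma, inst$prob, inst$control)
    expect_lt(norm(hb$H %*% alpha - hb$B, "F") / norm(hb$B, "F"), 1e-8)
    q0 <- mapca_objective(alpha, inst$V, inst$gamma, inst$prob, inst$control)
    set.seed(seed + 500)
    for (p in 1:100) {
      delta <- matrix(rnorm(20, sd = 10^runif(1, -4, 0)), 10, 2)
      expect_gte(mapca_objective(alpha + delta, inst$V, inst$gamma,
                                 inst$prob, inst$control), q0 - 1e-10)
    }
  }
})

test_that("a huge RKHS penalty shrinks alpha toward zero", {
  inst <- random_instance(1, n = 10, M = 2, q = 2)
  ctl <- mapca_control(lambda = 1e8, beta = 1)
  alpha <- update_alpha(inst$V, inst$gamma, inst$prob, ctl)
  expect_lt(norm(alpha, "F"), 1e-5)
})

test_that("alpha update agrees with a generic numerical minimiser", {
  inst <- random_instance(3, n = 10, M = 2, q = 2)
  alpha <- update_alpha(inst$V, inst$gamma, inst$prob, inst$control)
  fn <- function(par) mapca_objective(matrix(par, 10, 2), inst$V,
                                      inst$gamma, inst$prob, inst$control)
  opt <- optim(rep(0, 20), fn, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  expect_equal(as.numeric(alpha), opt$par, tolerance = 1e-4)
  expect_lte(fn(as.numeric(alpha)), opt$value + 1e-8)
})

test_that("membership update has the exponential closed form and its limits", {
  inst <- random_instance(2, n = 12, M = 2, q = 2)
  alpha <- update_alpha(inst$V, inst$gamma, inst$prob, inst$control)
  # grid-search oracle per unlabelled entry
  V <- update_membership(alpha, inst$prob, inst$control)
  F <- inst$prob$K %*% alpha
  Fb <- inst$prob$Kbar %*% alpha
  w <- inst$control$lambda_s
  for (j in which(!inst$prob$labeled)) for (m in 1:2) {
    a <- sum((F[j, ] - inst$prob$centers[m, ])^2)
    b <- sum((Fb[j, ] - inst$prob$centers[m, ])^2)
    expect_lt(abs(V[j, m] -
                    oracle_membership_entry(a, b, w, inst$control$C)), 1e-4)
  }
  # C -> Inf gives v -> 1, C -> 0+ gives v -> 0 at nonzero distance
  big <- update_membership(alpha, inst$prob, mapca_control(C = 1e12))
  expect_true(all(abs(big[!inst$prob$labeled, ] - 1) < 1e-6))
  tiny <- update_membership(alpha, inst$prob, mapca_control(C = 1e-6))
  expect_true(all(tiny[!inst$prob$labeled, ] < 1e-10))
  # memberships never exceed 1 and are positive
  expect_true(all(V[!inst$prob$labeled, ] > 0 &
                    V[!inst$prob$labeled, ] <= 1))
})

test_that("membership decreases as the decision value moves off the prototype", {
  set.seed(10)
  X <- matrix(rnorm(30), 10, 3)
  y <- c(1, 2, rep(NA, 8))
  prob <- mapca_problem(X, y, k = 3)
  ctl <- mapca_control()
  # two alphas whose decision values differ only in distance to prototype 1
  a1 <- matrix(0.01, 10, 2)
  a2 <- matrix(-0.05, 10, 2)
  V1 <- update_membership(a1, prob, ctl)
  V2 <- update_membership(a2, prob, ctl)
  F1 <- prob$K %*% a1; F2 <- prob$K %*% a2
  d1 <- rowSums((F1 - rep(1, 10) %o% prob$centers[1, ])^2)
  d2 <- rowSums((F2 - rep(1, 10) %o% prob$centers[1, ])^2)
  worse <- which(!prob$labeled & d2 > d1)
  expect_true(all(V2[worse, 1] < V1[worse, 1]))
})

test_that("adaptation scores are zero at the source, quadratic, and match a loop", {
  inst <- random_instance(4, n = 10, M = 2, q = 3)
  prob <- inst$prob
  alpha <- prob$sources[[2]]$alpha
  A <- adaptation_scores(alpha, prob)
  expect_equal(A[2], 0)
  # quadratic scaling in the deviation
  base <- prob$sources[[1]]$alpha
  dev <- alpha - base
  A1 <- adaptation_scores(base + dev, prob)[1]
  A2 <- adaptation_scores(base + 3 * dev, prob)[1]
  expect_equal(A2, 9 * A1, tolerance = 1e-10)
  # pointwise-sum oracle
  f <- t(alpha) %*% prob$K
  for (i in 1:3) {
    fs <- t(prob$sources[[i]]$alpha) %*% prob$K
    expect_equal(A[i], sum((f - fs)^2) / prob$n, tolerance = 1e-10)
  }
  # identity divergence is the RKHS discrepancy
  Ai <- adaptation_scores(alpha, prob, divergence = "identity")
  da <- alpha - prob$sources[[1]]$alpha
  expect_equal(Ai[1], sum(diag(t(da) %*% prob$K %*% da)), tolerance = 1e-10)
})

test_that("gamma update solves the simplex QP", {
  expect_equal(update_gamma(c(3.2), eta = 0.5), 1)
  expect_equal(update_gamma(rep(2, 4), eta = 0.3), rep(0.25, 4))
  set.seed(77)
  for (r in 1:10) {
    A <- runif(5, 0, 2)
    g <- update_gamma(A, eta = 0.3)
    expect_lt(max(abs(g - oracle_gamma(A, 0.3))), 1e-8)
    expect_equal(sum(g), 1, tolerance = 1e-12)
    expect_true(all(g >= 0 & g <= 1))
    # smaller score never gets the smaller weight
    o <- order(A)
    expect_true(all(diff(g[o]) <= 1e-12))
  }
  # eta -> infinity tends to uniform weights
  g <- update_gamma(c(0.1, 5, 9), eta = 1e8)
  expect_lt(max(abs(g - 1 / 3)), 1e-4)
  expect_error(update_gamma(numeric(0), 1), "non-empty")
})

test_that("fit descends monotonically and stops by the window rule", {
  for (seed in 1:5) {
    inst <- random_instance(seed + 30, n = 15, M = 2, q = 2)
    fit <- mapca(inst$X, inst$y, sources = inst$prob$sources,
                 k = 3, control = inst$control)
    chain <- c(fit$obj_history[1], as.numeric(t(fit$obj_partial)))
    rel <- diff(chain) / pmax(abs(chain[-length(chain)]), 1e-300)
    expect_true(all(rel <= 1e-9))
    expect_identical(fit$stop_reason, "window")
    expect_lt(fit$iterations, fit$control$max_iter + 1)
  }
})

test_that("beta = 0 ignores sources and equals the adaptation-free path", {
  inst <- random_instance(8, n = 14, M = 2, q = 2)
  ctl <- mapca_control(beta = 0)
  f1 <- mapca(inst$X, inst$y, sources = inst$prob$sources, k = 3,
              control = ctl)
  f2 <- sspca(inst$X, inst$y, k = 3, control = ctl)
  expect_lt(max(abs(f1$alpha - f2$alpha)), 1e-10)
  expect_lt(max(abs(f1$V - f2$V)), 1e-10)
  expect_equal(f1$obj_history, f2$obj_history, tolerance = 1e-12)
  # single source forces gamma = 1
  f3 <- mapca(inst$X, inst$y, sources = inst$prob$sources[1], k = 3,
              control = mapca_control(beta = 1))
  expect_identical(f3$gamma, 1)
})

test_that("per-iteration objective and stopping reason are logged", {
  inst <- random_instance(12, n = 12, M = 2, q = 2)
  msgs <- capture_messages(
    mapca(inst$X, inst$y, sources = inst$prob$sources, k = 3,
          control = inst$control, verbose = TRUE))
  expect_true(any(grepl("objective", msgs)))
  expect_true(any(grepl("stopped after \\d+ iterations \\(window\\)", msgs)))
})

test_that("prediction matches a pointwise scorer and interpolates labels", {
  cfg <- domain_config(M = 3, d = 5, n_per_class = 25, labeled_fraction = 0.2,
                       seed = 6)
  dom <- make_domain(cfg)
  fit <- sspca(dom$X, partial_labels(dom))
  # labelled points of a separable task get their own labels back
  pred_train <- predict(fit, dom$X)
  expect_true(all(pred_train$class[dom$labeled] == dom$y[dom$labeled]))

  # held-out points: loop-based scorer
  new <- make_domain(domain_config(M = 3, d = 5, n_per_class = 10, seed = 999))
  pr <- predict(fit, new$X)
  for (i in seq_len(8)) {
    kx <- sapply(seq_len(nrow(fit$X)), function(j)
      exp(-sum((new$X[i, ] - fit$X[j, ])^2) / 5))
    f <- as.numeric(t(fit$alpha) %*% kx)
    d2 <- sapply(1:3, function(m) sum((f - fit$centers[m, ])^2))
    expect_equal(as.numeric(pr$decision[i, ]), f, tolerance = 1e-10)
    expect_equal(pr$class[i], which.min(d2))
  }
  # membership rows in (0,1]; argmax membership = argmin distance class
  expect_true(all(pr$membership > 0 & pr$membership <= 1))
  expect_equal(apply(pr$membership, 1, which.max), pr$class)
  expect_error(predict(fit, new$X[, 1:3]), "feature dimension")
})

test_that("problem construction validates labels and sources", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(mapca_problem(X, rep(1, 10), k = 2), "two classes")
  expect_error(mapca_problem(X, c(1, rep(NA, 9)), k = 2), "two classes")
  y <- c(1, 2, rep(NA, 8))
  bad <- mapca_source(matrix(0, 9, 2))
  expect_error(mapca_problem(X, y, sources = list(bad), k = 2),
               "reference sample")
})
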