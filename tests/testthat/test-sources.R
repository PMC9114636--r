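test_that("source training reproduces labels and projection is faithful", {
  # well-separated two-class source; target = a fresh draw of the same law
  set.seed(31)
  Xs <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2))
  ys <- rep(1:2, each = 20)
  Xt <- rbind(matrix(rnorm(30, 0), 15, 2), matrix(rnorm(30, 6), 15, 2))
  kern <- kernel_spec("gaussian", 0.5)
  src <- train_source(Xs, ys, Xt, kernel = kern, lambda = 0.1)
  expect_s3_class(src, "mapca_source")
  expect_identical(src$origin, "projected")

  # decision values of the projected model match the original's on the target
  Ks <- gram(Xs, Xs, kern)
  a_src <- solve(Ks + diag(0.1, 40), diag(2)[ys, ])
  F_orig <- gram(Xt, Xs, kern) %*% a_src
  Kt <- gram(Xt, Xt, kern)
  F_proj <- Kt %*% src$alpha
  expect_lt(max(abs(F_proj - F_orig)) / max(abs(F_orig)), 1e-6)

  # predicted classes on the separable source training data are the labels
  F_self <- Ks %*% a_src
  expect_equal(apply(F_self, 1, which.max), ys)

  # projecting twice is idempotent
  a2 <- mapca:::project_to_reference(Kt %*% src$alpha, Kt)
  expect_lt(max(abs(a2 - src$alpha)), 1e-10)
})

test_that("source with target-identical law transfers its labels", {
  dom <- make_domain(domain_config(M = 2, d = 3, n_per_class = 20,
                                   labeled_fraction = 1, seed = 14))
  src <- train_source(dom$X, dom$y, dom$X, lambda = 0.1)
  F <- gram(dom$X, dom$X) %*% src$alpha
  expect_gt(mean(apply(F, 1, which.max) == dom$y), 0.95)
  expect_error(train_source(dom$X, c(dom$y[-1], 7), dom$X, classes = 1:2),
               "absent")
  expect_error(train_source(dom$X, replace(dom$y, 1, NA), dom$X),
               "fully labelled")
})

test_that("domain distance is a kernel MMD: zero, symmetric, loop-checked", {
  set.seed(55)
  Xa <- matrix(rnorm(200), 100, 2)
  Xb <- matrix(rnorm(200, mean = 2), 100, 2)
  kern <- kernel_spec("gaussian", 0.5)
  expect_equal(domain_distance(Xa, Xa, kern), 0, tolerance = 1e-12)
  expect_equal(domain_distance(Xa, Xb, kern), domain_distance(Xb, Xa, kern))
  expect_equal(domain_distance(Xa, Xb, kern), oracle_mmd2(Xa, Xb, 0.5),
               tolerance = 1e-10)
  expect_error(domain_distance(Xa[0, ], Xb, kern), "non-empty")
  expect_error(domain_distance(Xa, Xb[, 1, drop = FALSE], kern),
               "feature dimension")
})

test_that("weighting schemes live on the simplex and match hand values", {
  expect_equal(make_weights("uniform", q = 4), rep(0.25, 4))
  expect_equal(make_weights("distance", distances = c(0.3, 0.3, 0.3)),
               rep(1 / 3, 3))
  # delta = 100, distances (0.01, 0.02): softmax by independent scalar code
  w <- make_weights("distance", distances = c(0.01, 0.02), delta = 100)
  expect_equal(w, c(0.731058578630005, 0.268941421369995), tolerance = 1e-14)
  expect_equal(make_weights("fixed", weights = c(0.2, 0.8)), c(0.2, 0.8))
  expect_error(make_weights("fixed", weights = c(0.5, 0.2)), "simplex")
  A <- c(0.5, 0.1, 2)
  expect_equal(make_weights("optimal", A = A, eta = 0.3),
               update_gamma(A, 0.3))
  for (sch in list(make_weights("uniform", q = 3),
                   make_weights("distance", distances = runif(3)),
                   make_weights("optimal", A = runif(3), eta = 0.2))) {
    expect_equal(sum(sch), 1, tolerance = 1e-12)
    expect_true(all(sch >= 0 & sch <= 1))
  }
})

test_that("relevant sources score lower adaptation divergence after fitting", {
  task <- make_recovery_task(seed = 2)
  fit <- mapca(task$target$X, partial_labels(task$target),
               sources = task$sources, control = adaptation_control())
  expect_lt(fit$A[1], fit$A[2])   # identical-law source is closer
  expect_gte(fit$gamma[1], fit$gamma[2])
})

test_that("weighting-scheme ordering mirrors the ablation ranking", {
  # optimal >= uniform >= irrelevant-only (medians over seeds)
  res <- t(sapply(1:8, function(s) {
    task <- make_recovery_task(seed = 100 + s)
    y <- partial_labels(task$target)
    ctl <- adaptation_control()
    f_opt <- mapca(task$target$X, y, sources = task$sources, control = ctl)
    f_uni <- mapca(task$target$X, y, sources = task$sources,
                   weighting = "uniform", control = ctl)
    f_irr <- mapca(task$target$X, y, sources = task$sources[2],
                   control = ctl)
    c(opt = transductive_accuracy(f_opt, task$target$y),
      uni = transductive_accuracy(f_uni, task$target$y),
      irr = transductive_accuracy(f_irr, task$target$y))
  }))
  expect_gte(median(res[, "opt"]), median(res[, "uni"]))
  expect_gte(median(res[, "uni"]), median(res[, "irr"]))
})
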