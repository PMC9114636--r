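#' Synthetic domain configuration
#'
#' Describes one "domain" as a mixture of Gaussian class blobs with an
#' optional rigid shift (translation plus a rotation in the plane of the
#' first two features), injected box-uniform outliers carrying random labels,
#' and stratified label scarcity. Rotation and translation together emulate
#' the covariate and conditional distribution shift seen across subjects,
#' sessions, and recording devices; features emulate differential-entropy
#' EEG features only in scale (moderate dimension, continuous, roughly
#' Gaussian per class).
#'
#' @param M class count.
#' @param d feature dimension (d >= 2; default means require d >= M).
#' @param n_per_class Gaussian instances per class (>= 2).
#' @param class_means M x d matrix of class means; default places class m at
#'   \code{mean_scale} times the m-th coordinate axis.
#' @param mean_scale scale of the default class means (default 3, i.e. a
#'   3-sigma separation along each axis with unit class sd).
#' @param class_sd common within-class standard deviation (spherical).
#' @param shift length-d translation (scalars are recycled).
#' @param rotation rotation angle in radians applied in the plane of the
#'   first two features (before translation).
#' @param outlier_fraction fraction (of the Gaussian count) of injected
#'   outliers, in [0, 0.5).
#' @param outlier_scale inflation factor of the outlier bounding box.
#' @param labeled_fraction fraction of instances labelled, in (0, 1];
#'   exactly \code{ceiling(labeled_fraction * n)} instances are labelled,
#'   stratified by (assigned) class.
#' @param seed integer seed; identical config + seed reproduce the dataset
#'   exactly.
#' @return object of class \code{mapca_domain_config}.
#' @export
domain_config <- function(M = 3, d = 5, n_per_class = 30, class_means = NULL,
                          mean_scale = 3, class_sd = 1, shift = 0,
                          rotation = 0, outlier_fraction = 0,
                          outlier_scale = 3, labeled_fraction = 0.1,
                          seed = 1) {
  stopifnot(M >= 2, d >= 2, n_per_class >= 2,
            class_sd > 0, outlier_fraction >= 0, outlier_fraction < 0.5,
            outlier_scale > 0, labeled_fraction > 0, labeled_fraction <= 1)
  if (is.null(class_means)) {
    if (d < M) stop("default class means need d >= M", call. = FALSE)
    class_means <- matrix(0, M, d)
    class_means[cbind(seq_len(M), seq_len(M))] <- mean_scale
  }
  class_means <- as.matrix(class_means)
  stopifnot(identical(dim(class_means), c(as.integer(M), as.integer(d))))
  if (length(shift) == 1L) shift <- rep(shift, d)
  stopifnot(length(shift) == d)
  structure(list(M = as.integer(M), d = as.integer(d),
                 n_per_class = as.integer(n_per_class),
                 class_means = class_means, class_sd = class_sd,
                 shift = as.numeric(shift), rotation = rotation,
                 outlier_fraction = outlier_fraction,
                 outlier_scale = outlier_scale,
                 labeled_fraction = labeled_fraction,
                 seed = as.integer(seed)),
            class = "mapca_domain_config")
}

rotation_matrix <- function(d, angle) {
  R <- diag(d)
  R[1, 1] <- cos(angle); R[1, 2] <- -sin(angle)
  R[2, 1] <- sin(angle); R[2, 2] <- cos(angle)
  R
}

#' Generate one synthetic domain
#'
#' Draws Gaussian class blobs, applies the domain's rotation and translation,
#' appends box-uniform outliers with random class labels, and picks a
#' stratified labelled subset. Fully deterministic given the config (which
#' carries the seed).
#'
#' @param config a \code{\link{domain_config}}.
#' @return object of class \code{mapca_domain}: list with \code{X}
#'   (n x d matrix), \code{y} (integer classes 1..M for all instances,
#'   including the arbitrary labels assigned to outliers), \code{labeled}
#'   (logical mask), \code{outlier} (logical ground-truth mask) and
#'   \code{config}.
#' @export
make_domain <- function(config) {
  stopifnot(inherits(config, "mapca_domain_config"))
  set.seed(config$seed)
  M <- config$M; d <- config$d; npc <- config$n_per_class
  n_in <- M * npc
  X <- matrix(stats::rnorm(n_in * d, sd = config$class_sd), n_in, d)
  y <- rep(seq_len(M), each = npc)
  X <- X + config$class_means[y, , drop = FALSE]
  if (config$rotation != 0)
    X <- X %*% t(rotation_matrix(d, config$rotation))
  X <- sweep(X, 2L, config$shift, "+")

  n_out <- round(config$outlier_fraction * n_in)
  outlier <- rep(FALSE, n_in)
  if (n_out > 0) {
    lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
    mid <- (lo + hi) / 2
    half <- (hi - lo) / 2 * config$outlier_scale
    Xo <- sapply(seq_len(d), function(c)
      stats::runif(n_out, mid[c] - half[c], mid[c] + half[c]))
    Xo <- matrix(Xo, n_out, d)
    X <- rbind(X, Xo)
    y <- c(y, sample(seq_len(M), n_out, replace = TRUE))
    outlier <- c(outlier, rep(TRUE, n_out))
  }
  n <- nrow(X)

  n_lab <- ceiling(config$labeled_fraction * n)
  # stratified by assigned class: proportional allocation, at least 1 each
  labeled <- rep(FALSE, n)
  alloc <- pmax(1L, floor(n_lab * tabulate(y, M) / n))
  while (sum(alloc) < n_lab) {
    m <- which.max(tabulate(y, M) - alloc)
    alloc[m] <- alloc[m] + 1L
  }
  for (m in seq_len(M)) {
    idx <- which(y == m)
    labeled[idx[sample.int(length(idx), min(alloc[m], length(idx)))]] <- TRUE
  }

  structure(list(X = X, y = y, labeled = labeled, outlier = outlier,
                 config = config),
            class = "mapca_domain")
}

#' @export
print.mapca_domain <- function(x, ...) {
  cat(sprintf(paste0("mapca synthetic domain: n = %d (%d labelled, ",
                     "%d outliers), %d classes, d = %d\n"),
              nrow(x$X), sum(x$labeled), sum(x$outlier),
              x$config$M, x$config$d))
  invisible(x)
}

#' Partially observed label vector of a domain (NA on unlabelled instances)
#' @param domain a \code{mapca_domain}.
#' @return integer vector with NA for unlabelled instances.
#' @export
partial_labels <- function(domain) {
  ifelse(domain$labeled, domain$y, NA_integer_)
}

#' Build a multi-source task: target domain plus projected source models
#'
#' Generates the target domain and each source domain, trains a kernel
#' least-squares classifier on every (fully labelled) source via
#' \code{\link{train_source}}, projected onto the target reference sample,
#' and records the caller-declared relevance flags for weight-recovery
#' experiments.
#'
#' @param target_config \code{\link{domain_config}} of the target.
#' @param source_configs list of source domain configs (same M and d).
#' @param relevance optional logical vector: is source i drawn from the
#'   target's law?
#' @param kernel kernel spec or stack used for source training/projection.
#' @param lambda ridge weight of the source fits.
#' @return object of class \code{mapca_task}: list with \code{target}
#'   (a \code{mapca_domain}), \code{source_domains}, \code{sources}
#'   (list of \code{mapca_source}), and \code{relevance}.
#' @export
make_multisource_task <- function(target_config, source_configs = list(),
                                  relevance = NULL,
                                  kernel = kernel_spec(), lambda = 1) {
  stopifnot(inherits(target_config, "mapca_domain_config"))
  for (sc in source_configs) {
    stopifnot(inherits(sc, "mapca_domain_config"))
    if (sc$M != target_config$M || sc$d != target_config$d)
      stop("source configs must share M and d with the target",
           call. = FALSE)
  }
  target <- make_domain(target_config)
  source_domains <- lapply(source_configs, make_domain)
  sources <- lapply(seq_along(source_domains), function(i) {
    dom <- source_domains[[i]]
    train_source(dom$X, dom$y, target$X,
                 classes = seq_len(target_config$M),
                 kernel = kernel, lambda = lambda,
                 name = paste0("source", i))
  })
  structure(list(target = target, source_domains = source_domains,
                 sources = sources, relevance = relevance),
            class = "mapca_task")
}

#' Canonical source-relevance recovery task
#'
#' The benchmark used throughout the package's experiments: a 3-class,
#' 5-feature target with 10% labels, one source drawn from the target's own
#' law (different seed), and one irrelevant source whose class means are
#' cyclically permuted (conditional shift) and translated by 0.5 in every
#' coordinate. The permutation makes the irrelevant source confidently wrong
#' on the target, so uniform fusion measurably hurts, while a purely
#' translated far-away source would merely project to near-zero coefficients.
#'
#' @param seed integer seed controlling all three domains.
#' @param n_per_class instances per class per domain.
#' @param labeled_fraction labelled fraction of the target.
#' @param outlier_fraction outlier fraction of the target (default 0).
#' @param kernel kernel used to train/project the sources.
#' @return a \code{mapca_task} with \code{relevance = c(TRUE, FALSE)}.
#' @export
make_recovery_task <- function(seed = 1, n_per_class = 30,
                               labeled_fraction = 0.1,
                               outlier_fraction = 0,
                               kernel = kernel_spec()) {
  base <- domain_config(M = 3, d = 5, n_per_class = n_per_class,
                        labeled_fraction = labeled_fraction,
                        outlier_fraction = outlier_fraction,
                        seed = seed)
  relevant <- domain_config(M = 3, d = 5, n_per_class = n_per_class,
                            labeled_fraction = 1, seed = seed + 100001L)
  permuted_means <- base$class_means[c(2, 3, 1), ]
  irrelevant <- domain_config(M = 3, d = 5, n_per_class = n_per_class,
                              class_means = permuted_means, shift = 0.5,
                              labeled_fraction = 1, seed = seed + 200003L)
  make_multisource_task(base, list(relevant, irrelevant),
                        relevance = c(TRUE, FALSE), kernel = kernel)
}
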