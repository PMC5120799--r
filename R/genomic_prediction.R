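# The four genome-wide prediction models share a fit/predict contract:
# fit_* returns a classed object whose predict() method takes a coded
# genotype matrix for new lines (same marker columns as training).

#' Genomic relationship matrix (VanRaden method 1)
#'
#' On the dosage-equivalent +/-1 coding, columns are centered by their
#' observed means and `G = Z Z' / (2 sum p_k (1 - p_k))` with `p_k` the
#' observed frequency of the +1 allele at marker k.
#'
#' @param coded Imputed coded matrix (lines x markers).
#' @return An n x n `kernel_matrix` with attributes `kind = "additive"`,
#'   `p` (allele frequencies), `denom` (the 2 sum p(1-p) normalizer) and
#'   `centers` (column means).
#' @export
build_grm <- function(coded) {
  if (anyNA(coded)) stop("coded matrix must be imputed before building G")
  p <- (colMeans(coded) + 1) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: G undefined")
  centers <- colMeans(coded)
  Z <- sweep(coded, 2, centers)
  G <- tcrossprod(Z) / denom
  structure(G, kind = "additive", p = p, denom = denom, centers = centers,
            class = c("kernel_matrix", "matrix"))
}

#' Digenic epistatic kernel for EG-BLUP
#'
#' The additive-by-additive relationship is the elementwise (Hadamard)
#' square of the additive kernel, rescaled so its mean diagonal equals the
#' mean diagonal of G. The construction is coding-dependent and is fixed
#' here to the +/-1 parental coding used throughout.
#'
#' @param G Additive kernel from [build_grm()].
#' @return An n x n `kernel_matrix` with `kind = "epistatic"` and attribute
#'   `scale` (the rescaling factor applied to `G * G`).
#' @export
build_epistatic_kernel <- function(G) {
  H0 <- unclass(G) * unclass(G)
  sc <- mean(diag(G)) / mean(diag(H0))
  structure(H0 * sc, kind = "epistatic", scale = sc,
            class = c("kernel_matrix", "matrix"))
}

# REML for y = 1 mu + g + e, g ~ N(0, s2g K): profile log-likelihood over
# delta = s2e / s2g on the eigenbasis of the projected kernel (EMMA-style).
.reml_1k <- function(y, K) {
  n <- length(y)
  X <- matrix(1, n, 1)
  S <- diag(n) - X %*% t(X) / n
  es <- eigen(S %*% K %*% S, symmetric = TRUE)
  keep <- seq_len(n - 1)
  theta <- pmax(es$values[keep], 0)
  eta <- as.vector(crossprod(es$vectors[, keep], y))
  ll <- function(log_delta) {
    d <- exp(log_delta)
    w <- theta + d
    -0.5 * ((n - 1) * log(sum(eta^2 / w)) + sum(log(w)))
  }
  opt <- stats::optimize(ll, interval = c(-25, 25), maximum = TRUE,
                         tol = 1e-10)
  delta <- exp(opt$maximum)
  s2g <- sum(eta^2 / (theta + delta)) / (n - 1)
  s2e <- delta * s2g
  list(s2g = s2g, s2e = s2e, delta = delta, reml = opt$objective)
}

# REML log-likelihood for arbitrary V = s2e (I + sum_r ratio_r K_r),
# used by the two-kernel (EG-BLUP) fit
.reml_ll_multi <- function(log_ratios, y, kernels) {
  n <- length(y)
  V0 <- diag(n)
  for (r in seq_along(kernels))
    V0 <- V0 + exp(log_ratios[r]) * unclass(kernels[[r]])
  ch <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(ch)) return(-1e10)
  X <- matrix(1, n, 1)
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(Vi_X, y))
  r <- y - X %*% beta
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  yPy <- sum(r * Vi_r)
  s2e <- yPy / (n - 1)
  -0.5 * (2 * sum(log(diag(ch))) + log(det(XtViX)) +
            (n - 1) * log(s2e) + (n - 1))
}

#' GBLUP / EG-BLUP mixed-model fit
#'
#' Single kernel: `y = 1 mu + g + e` with `g ~ N(0, s2g K)`, REML by 1-D
#' optimization of the eigen-rotated profile likelihood over the variance
#' ratio. Two kernels (EG-BLUP): `y = 1 mu + g + h + e`, REML by
#' Nelder-Mead over the two log variance ratios. Random effects come from
#' the mixed-model equations at the optimum.
#'
#' @param y Entry-mean vector.
#' @param K Additive `kernel_matrix` (from [build_grm()]).
#' @param K2 Optional second (epistatic) kernel for EG-BLUP.
#' @param coded Optional training coded matrix; stored to enable
#'   [predict()] on new lines via the cross-kernel.
#' @return A `gblup_fit`: `mu`, `s2g`, `s2h` (NA for single kernel),
#'   `s2e`, `g` (additive BLUPs), `h` (epistatic BLUPs or NULL), `fitted`,
#'   plus the training metadata needed for prediction.
#' @export
fit_gblup <- function(y, K, K2 = NULL, coded = NULL) {
  n <- length(y)
  stopifnot(nrow(K) == n)
  if (is.null(K2)) {
    fit <- .reml_1k(y, unclass(K))
    s2g <- fit$s2g; s2e <- fit$s2e; s2h <- NA_real_
    V <- s2g * unclass(K) + diag(s2e + 1e-10, n)
    Vi <- solve(V)
    mu <- as.numeric(sum(Vi %*% y) / sum(Vi))
    g <- as.vector(s2g * unclass(K) %*% Vi %*% (y - mu))
    h <- NULL
  } else {
    stopifnot(nrow(K2) == n)
    kernels <- list(K, K2)
    start <- c(0, -1)
    opt <- stats::optim(start, .reml_ll_multi, y = y, kernels = kernels,
                        method = "Nelder-Mead",
                        control = list(fnscale = -1, maxit = 500,
                                       reltol = 1e-10))
    ratios <- exp(opt$par)
    n1 <- length(y)
    V0 <- diag(n1) + ratios[1] * unclass(K) + ratios[2] * unclass(K2)
    ch <- chol(V0)
    Vi0_y <- backsolve(ch, forwardsolve(t(ch), y))
    one <- rep(1, n1)
    Vi0_1 <- backsolve(ch, forwardsolve(t(ch), one))
    mu <- sum(Vi0_y) / sum(Vi0_1)
    r <- y - mu
    Vi0_r <- backsolve(ch, forwardsolve(t(ch), r))
    s2e <- sum(r * Vi0_r) / (n1 - 1)
    s2g <- ratios[1] * s2e
    s2h <- ratios[2] * s2e
    g <- as.vector(ratios[1] * unclass(K) %*% Vi0_r)
    h <- as.vector(ratios[2] * unclass(K2) %*% Vi0_r)
  }
  fitted <- mu + g + if (is.null(h)) 0 else h
  structure(list(mu = mu, s2g = s2g, s2h = s2h, s2e = s2e, g = g, h = h,
                 fitted = fitted, K = K, K2 = K2, coded = coded,
                 line_ids = names(y)),
            class = "gblup_fit")
}

#' RR-BLUP marker-effect fit
#'
#' Ridge regression on all markers with a common shrinkage. Variance
#' components are taken from the equivalent GBLUP fit with the VanRaden
#' kernel: `s2beta = s2g / (2 sum p(1-p))` and `lambda = s2e / s2beta`.
#' The effects are the BLUPs `beta = s2beta Z' V^-1 (y - mu)`, identical
#' to the ridge solution `(Z'Z + lambda I)^-1 Z'(y - mu)`.
#'
#' @param y Entry-mean vector.
#' @param coded Imputed coded matrix.
#' @param lambda Optional fixed ridge parameter; when supplied the REML
#'   step is skipped and `mu` is the plain mean of `y`.
#' @return An `rrblup_fit`: `mu`, `beta` (named per marker), `s2g`, `s2e`,
#'   `s2beta`, `lambda`, `centers`, `fitted`.
#' @export
fit_rrblup <- function(y, coded, lambda = NULL) {
  G <- build_grm(coded)
  centers <- attr(G, "centers")
  denom <- attr(G, "denom")
  Z <- sweep(coded, 2, centers)
  n <- length(y)
  if (is.null(lambda)) {
    fit <- .reml_1k(y, unclass(G))
    s2g <- fit$s2g; s2e <- fit$s2e
    s2beta <- s2g / denom
    lambda <- s2e / s2beta
    V <- s2g * unclass(G) + diag(s2e + 1e-10, n)
    Vi <- solve(V)
    mu <- as.numeric(sum(Vi %*% y) / sum(Vi))
    beta <- as.vector(s2beta * crossprod(Z, Vi %*% (y - mu)))
  } else {
    s2g <- NA_real_; s2e <- NA_real_; s2beta <- NA_real_
    mu <- mean(y)
    beta <- as.vector(solve(crossprod(Z) + diag(lambda, ncol(Z)),
                            crossprod(Z, y - mu)))
  }
  names(beta) <- colnames(coded)
  structure(list(mu = mu, beta = beta, s2g = s2g, s2e = s2e,
                 s2beta = s2beta, lambda = lambda, centers = centers,
                 fitted = as.vector(mu + Z %*% beta)),
            class = "rrblup_fit")
}

#' BayesCpi marker-effect fit by Gibbs sampling
#'
#' Bayesian variable-selection regression
#' `y = 1 mu + sum_k Z_k beta_k delta_k + e` with
#' `beta_k | delta_k = 1 ~ N(0, s2beta)` (a single common effect
#' variance), `delta_k ~ Bernoulli(1 - pi)`, `pi ~ Uniform(0, 1)`, and
#' scaled-inverse-chi-square priors (4 df) on `s2beta` and `s2e` with
#' scales set from `var(y)` at an assumed initial genomic h2 of 0.5.
#' The sampler is implemented in compiled code and driven by R's RNG, so a
#' fixed seed reproduces the chain exactly. Markers should be pruned to
#' pairwise r^2 <= 0.95 beforehand.
#'
#' @param y Entry-mean vector.
#' @param coded Imputed coded matrix (LD-pruned).
#' @param n_iter Total Gibbs iterations (default 20000).
#' @param burn_in Burn-in iterations discarded (default 6000).
#' @param seed Integer seed.
#' @return A `bayescpi_fit`: `mu`, `beta` (posterior mean of
#'   `beta * delta` per marker), `inclusion_prob`, `pi_mean`, `s2beta`,
#'   `s2e`, `centers`, `fitted`, `settings`.
#' @export
fit_bayescpi <- function(y, coded, n_iter = 20000, burn_in = 6000,
                         seed = 1L) {
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  centers <- colMeans(coded)
  Z <- sweep(coded, 2, centers)
  set.seed(seed)
  res <- bayescpi_gibbs(as.matrix(Z), as.numeric(y), as.integer(n_iter),
                        as.integer(burn_in))
  beta <- as.vector(res$beta_mean)
  names(beta) <- colnames(coded)
  structure(list(mu = res$mu_mean, beta = beta,
                 inclusion_prob = stats::setNames(as.vector(res$incl_prob),
                                                  colnames(coded)),
                 pi_mean = res$pi_mean, s2beta = res$s2beta_mean,
                 s2e = res$s2e_mean, centers = centers,
                 fitted = as.vector(res$mu_mean + Z %*% beta),
                 settings = list(n_iter = n_iter, burn_in = burn_in,
                                 seed = seed)),
            class = "bayescpi_fit")
}

#' Predict new lines from a fitted genome-wide model
#'
#' Marker-effect models (`rrblup_fit`, `bayescpi_fit`) code the new lines
#' with the training centering and return `mu + Z_new beta`. Kernel models
#' (`gblup_fit`) build the cross-kernel between new and training lines
#' with the training allele frequencies and return
#' `mu + G_new,train (G_train + ridge)^-1 g_hat` (plus the analogous
#' epistatic term for EG-BLUP).
#'
#' @param object A fitted model.
#' @param newdata Coded matrix of new lines with the same marker columns
#'   as training.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @name predict_models
NULL

.check_markers <- function(fit_markers, newdata) {
  missing <- setdiff(fit_markers, colnames(newdata))
  if (length(missing) > 0)
    stop(sprintf("markers missing from new data: %s%s",
                 paste(utils::head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) ", ..." else ""))
}

#' @rdname predict_models
#' @export
predict.rrblup_fit <- function(object, newdata, ...) {
  .check_markers(names(object$beta), newdata)
  Z <- sweep(newdata[, names(object$beta), drop = FALSE], 2, object$centers)
  as.vector(object$mu + Z %*% object$beta)
}

#' @rdname predict_models
#' @export
predict.bayescpi_fit <- function(object, newdata, ...) {
  .check_markers(names(object$beta), newdata)
  Z <- sweep(newdata[, names(object$beta), drop = FALSE], 2, object$centers)
  as.vector(object$mu + Z %*% object$beta)
}

#' @rdname predict_models
#' @export
predict.gblup_fit <- function(object, newdata, ...) {
  if (is.null(object$coded))
    stop("fit was built without the training coded matrix; cannot form the cross-kernel")
  .check_markers(colnames(object$coded), newdata)
  centers <- attr(object$K, "centers")
  denom <- attr(object$K, "denom")
  Zt <- sweep(object$coded, 2, centers)
  Zn <- sweep(newdata[, colnames(object$coded), drop = FALSE], 2, centers)
  Gcross <- tcrossprod(Zn, Zt) / denom
  n <- nrow(object$K)
  Gi_g <- solve(unclass(object$K) + diag(1e-8, n), object$g)
  pred <- object$mu + as.vector(Gcross %*% Gi_g)
  if (!is.null(object$K2)) {
    sc <- attr(object$K2, "scale")
    Hcross <- (Gcross * Gcross) * sc
    Hi_h <- solve(unclass(object$K2) + diag(1e-8, n), object$h)
    pred <- pred + as.vector(Hcross %*% Hi_h)
  }
  pred
}
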