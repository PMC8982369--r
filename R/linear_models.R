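# The three linear genomic-prediction models: Bayesian GBLUP (G-side Gibbs),
# BayesB (mixture-prior Gibbs), and the elastic net in the convention where
# alpha = 1 is pure ridge and alpha = 0 pure lasso.

#' GBLUP Gibbs configuration
#'
#' Full-scale defaults (150,000 iterations, 50,000
#' burn-in, thinning 10, i.e. 10,000 posterior samples). Desk-scale runs in
#' this package's tests and evaluation helpers pass shorter chains.
#'
#' @param n_iter,burn_in,thin chain settings.
#' @param df_prior prior degrees of freedom for the variance components.
#' @export
gblup_config <- function(n_iter = 150000, burn_in = 50000, thin = 10,
                         df_prior = 5) {
  stopifnot(n_iter > burn_in, thin >= 1)
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 df_prior = df_prior), class = "gblup_config")
}

#' BayesB configuration
#'
#' Full-scale defaults (120,000 iterations, 20,000
#' burn-in, thinning 100). `pi` is the prior probability of a null marker
#' effect; non-null effects have a scaled-t prior with `nu` degrees of freedom
#' and scale `s2` (`NULL` = solve `s2` so the prior expected marker variance
#' totals half the phenotypic variance given `pi` and standardized genotypes).
#'
#' @param n_iter,burn_in,thin chain settings.
#' @param pi prior null probability (default 0.95).
#' @param nu t-prior degrees of freedom (default 5; must exceed 2).
#' @param s2 t-prior scale, or `NULL` to derive from the data.
#' @export
bayesb_config <- function(n_iter = 120000, burn_in = 20000, thin = 100,
                          pi = 0.95, nu = 5, s2 = NULL) {
  stopifnot(n_iter > burn_in, thin >= 1, pi >= 0, pi < 1, nu > 2)
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 pi = pi, nu = nu, s2 = s2), class = "bayesb_config")
}

#' Elastic-net configuration
#'
#' Uses the convention `alpha = lambda2 / (lambda1 + lambda2)`: `alpha = 1` is
#' pure ridge, `alpha = 0` pure lasso (reversed from glmnet's convention).
#' `lambda_total` scales with sample size: `lambda1 + lambda2 =
#' lambda_total * n`.
#'
#' @param alpha mixing parameter in \[0, 1\].
#' @param lambda_total overall penalty strength.
#' @param standardize standardize predictor columns before fitting.
#' @export
enet_config <- function(alpha = 0.5, lambda_total = 0.1, standardize = TRUE) {
  stopifnot(alpha >= 0, alpha <= 1, lambda_total >= 0)
  structure(list(alpha = alpha, lambda_total = lambda_total,
                 standardize = standardize), class = "enet_config")
}

#' Fit GBLUP by Gibbs sampling and predict unphenotyped animals
#'
#' Samples `y*_ref = 1 mu + a_ref + e`, `a ~ N(0, G_rr sigma_a^2)`, on the
#' reference block of `G`; genetic values of the remaining (validation)
#' animals are predicted as the conditional expectation
#' `g_val = G_vr (G_rr + 1e-8 I)^-1 a_ref` at the posterior means.
#'
#' @param ystar named vector of precorrected phenotypes covering (at least)
#'   the reference animals.
#' @param G additive `relationship_matrix` over reference and validation
#'   animals (dimnames = animal ids).
#' @param reference_ids animals to train on.
#' @param cfg a [gblup_config()].
#' @param seed integer seed.
#' @return object of class `c("gblup_fit", "gp_fit")`: `mu`, `gvalues` (named,
#'   all animals in `G`), `varcomp`, `reference_ids`, `cfg`.
#' @export
fit_gblup <- function(ystar, G, reference_ids, cfg = gblup_config(), seed = 1) {
  ids <- rownames(G)
  stopifnot(!is.null(ids), all(reference_ids %in% ids),
            all(reference_ids %in% names(ystar)))
  y <- ystar[reference_ids]
  stopifnot(!anyNA(y))
  rr <- match(reference_ids, ids)
  G_rr <- unclass(G)[rr, rr, drop = FALSE]
  fit <- .gibbs_mixed(y, list(G_rr), cfg$n_iter, cfg$burn_in, cfg$thin,
                      cfg$df_prior, seed, keep_u = TRUE)
  a_ref <- fit$u_mean[[1]]
  gv <- stats::setNames(rep(NA_real_, length(ids)), ids)
  gv[reference_ids] <- a_ref
  val_ids <- setdiff(ids, reference_ids)
  if (length(val_ids)) {
    sol <- solve(G_rr + diag(1e-8, length(rr)), a_ref)
    gv[val_ids] <- unclass(G)[match(val_ids, ids), rr, drop = FALSE] %*% sol
  }
  structure(list(mu = fit$mu_mean, gvalues = gv,
                 varcomp = c(sigma_a = fit$sigma_g_mean[1],
                             sigma_e = fit$sigma_e_mean),
                 h2 = mean(fit$h2_samples),
                 reference_ids = reference_ids, cfg = cfg, seed = seed),
            class = c("gblup_fit", "gp_fit"))
}

#' @export
predict.gblup_fit <- function(object, ids = names(object$gvalues), ...) {
  stats::setNames(object$mu + object$gvalues[ids], ids)
}

#' Back-solve SNP effects from GBLUP genetic values
#'
#' `beta = Z' (G + jitter I)^-1 a / m`, which satisfies `Z beta = a` (to
#' numerical tolerance) whenever `G = Z Z' / m` and `a` lies in the range of
#' `G`.
#'
#' @param fit a `gblup_fit` (or any named vector of genetic values via
#'   `gvalues`).
#' @param Z centered/standardized genotype matrix used to build `G`.
#' @param G the additive relationship matrix `Z Z' / m`.
#' @param jitter ridge added before inversion (default 1e-8).
#' @return named per-SNP effect vector.
#' @export
backsolve_snp_effects <- function(fit, Z, G, jitter = 1e-8) {
  a <- if (inherits(fit, "gblup_fit")) fit$gvalues else fit
  ids <- rownames(G)
  stopifnot(identical(rownames(Z), ids), all(!is.na(a[ids])))
  m <- ncol(Z)
  sol <- solve(unclass(G) + diag(jitter, nrow(G)), a[ids])
  stats::setNames(as.numeric(crossprod(Z, sol)) / m, colnames(Z))
}

#' Fit BayesB by Gibbs sampling
#'
#' Each marker has a null effect with prior probability `pi`, otherwise a
#' normal effect whose variance has a scaled-inverse-chi-square prior
#' (marginally scaled-t with `nu` df and scale `s2`). Returns posterior-mean
#' effects and per-marker posterior inclusion frequencies.
#'
#' @param ystar named reference phenotype vector.
#' @param Z standardized reference genotype matrix (rows = animals in
#'   `names(ystar)` order).
#' @param cfg a [bayesb_config()].
#' @param seed integer seed.
#' @return object of class `c("bayesb_fit", "gp_fit")`: `mu`, `beta` (named),
#'   `inclusion`, `sigma_e`, `cfg`.
#' @export
fit_bayesb <- function(ystar, Z, cfg = bayesb_config(), seed = 1) {
  stopifnot(nrow(Z) == length(ystar), !anyNA(ystar), !anyNA(Z))
  vy <- stats::var(ystar)
  s2 <- cfg$s2
  if (is.null(s2)) {
    # prior expected total marker variance = 0.5 * var(y):
    # m * (1 - pi) * E[sigma_gk^2] = m (1-pi) nu s2/(nu-2) = 0.5 vy
    s2 <- 0.5 * vy * (cfg$nu - 2) / (cfg$nu * ncol(Z) * max(1 - cfg$pi, 1e-12))
  }
  nu_e <- 5
  s2_e <- 0.5 * vy * (nu_e - 2) / nu_e # prior mean = half the phenotypic variance
  res <- with_seed(seed,
    .bayesb_mcmc(Z, as.numeric(ystar), cfg$n_iter, cfg$burn_in, cfg$thin,
                 cfg$pi, cfg$nu, s2, nu_e, s2_e))
  structure(list(mu = res$mu, beta = stats::setNames(res$beta, colnames(Z)),
                 inclusion = stats::setNames(res$inclusion, colnames(Z)),
                 sigma_e = res$sigma_e, n_samples = res$n_samples,
                 cfg = cfg, seed = seed),
            class = c("bayesb_fit", "gp_fit"))
}

#' @export
predict.bayesb_fit <- function(object, Z, ...) {
  stats::setNames(as.numeric(object$mu + Z[, names(object$beta), drop = FALSE] %*%
                               object$beta), rownames(Z))
}

#' Fit the elastic net by cyclic coordinate descent
#'
#' Minimizes `||y - X b||^2 + lambda2 ||b||^2 + lambda1 ||b||_1` with
#' soft-thresholding updates; the intercept is unpenalized (handled by
#' centering). `lambda2 = alpha * lambda_total * n`,
#' `lambda1 = (1 - alpha) * lambda_total * n`.
#'
#' @param ystar reference phenotype vector.
#' @param Z predictor matrix (rows = animals in `ystar` order).
#' @param cfg an [enet_config()].
#' @param beta_init optional warm start.
#' @return object of class `c("enet_fit", "gp_fit")`: `mu`, `beta` (on the
#'   internally standardized scale when `standardize = TRUE`), column `centers`
#'   and `scales`, convergence info, `cfg`.
#' @export
fit_enet <- function(ystar, Z, cfg = enet_config(), beta_init = NULL) {
  stopifnot(nrow(Z) == length(ystar), !anyNA(ystar), !anyNA(Z))
  n <- length(ystar)
  centers <- colMeans(Z)
  X <- sweep(Z, 2, centers)
  if (isTRUE(cfg$standardize)) {
    scales <- apply(X, 2, sd_pop)
    scales[scales == 0] <- 1
  } else {
    scales <- rep(1, ncol(Z))
  }
  X <- sweep(X, 2, scales, "/")
  mu <- mean(ystar)
  yc <- as.numeric(ystar) - mu
  lambda2 <- cfg$alpha * cfg$lambda_total * n
  lambda1 <- (1 - cfg$alpha) * cfg$lambda_total * n
  if (is.null(beta_init)) beta_init <- numeric(ncol(Z))
  res <- .enet_cd(X, yc, lambda1, lambda2, beta_init)
  if (!res$converged) {
    warning("elastic net did not converge after ", res$sweeps,
            " sweeps; returning best iterate")
  }
  structure(list(mu = mu, beta = stats::setNames(res$beta, colnames(Z)),
                 centers = stats::setNames(centers, colnames(Z)),
                 scales = stats::setNames(scales, colnames(Z)),
                 converged = res$converged, sweeps = res$sweeps, cfg = cfg),
            class = c("enet_fit", "gp_fit"))
}

#' @export
predict.enet_fit <- function(object, Z, ...) {
  X <- sweep(Z[, names(object$beta), drop = FALSE], 2, object$centers)
  X <- sweep(X, 2, object$scales, "/")
  stats::setNames(as.numeric(object$mu + X %*% object$beta), rownames(Z))
}

#' Exponentially decreasing lambda path
#'
#' @param from,to path endpoints (default 1 down to 0.01).
#' @param n_steps at most this many values (default 20), constant ratio.
#' @export
lambda_path <- function(from = 1, to = 0.01, n_steps = 20) {
  stopifnot(from > to, to > 0, n_steps >= 2)
  exp(seq(log(from), log(to), length.out = n_steps))
}

#' Two-step grid search for the elastic net
#'
#' A single seeded 80-20 split of the reference set; for each `alpha` in
#' `alpha_grid` the `lambda` path is traversed (warm starts along the path) and
#' the pair minimizing mean squared error on the held-out 20% wins. Exact MSE
#' ties are broken by smallest `lambda`, then largest `alpha`. The winner is
#' refit on the full reference set.
#'
#' @param ystar named reference phenotype vector.
#' @param Z predictor matrix with rownames = animal ids.
#' @param alpha_grid grid over the mixing parameter (default 0 to 1 by 0.05).
#' @param lambdas penalty path (default [lambda_path()]).
#' @param seed integer seed for the split.
#' @param standardize passed to [enet_config()].
#' @return list with `fit` (refit `enet_fit`), `best` config, and `grid`
#'   (data.frame alpha/lambda/mse).
#' @export
tune_enet <- function(ystar, Z, alpha_grid = seq(0, 1, by = 0.05),
                      lambdas = lambda_path(), seed = 1, standardize = TRUE) {
  ids <- names(ystar)
  stopifnot(!is.null(ids), length(ids) >= 10, identical(rownames(Z), ids))
  sp <- split_80_20(ids, seed = seed)
  tries <- 0
  while (stats::sd(ystar[sp$test]) == 0 && tries < 10) {
    tries <- tries + 1
    message("degenerate split (constant test phenotype); resampling with seed ",
            seed + tries)
    sp <- split_80_20(ids, seed = seed + tries)
  }
  ytr <- ystar[sp$train]; yte <- ystar[sp$test]
  Ztr <- Z[sp$train, , drop = FALSE]; Zte <- Z[sp$test, , drop = FALSE]
  grid <- expand.grid(alpha = alpha_grid, lambda = lambdas)
  grid$mse <- NA_real_
  best <- NULL
  for (a in alpha_grid) {
    warm <- NULL
    for (l in lambdas) {
      cfg <- enet_config(alpha = a, lambda_total = l, standardize = standardize)
      f <- fit_enet(ytr, Ztr, cfg, beta_init = warm)
      warm <- unname(f$beta)
      pred <- predict(f, Zte)
      mse <- mean((yte - pred)^2)
      grid$mse[grid$alpha == a & grid$lambda == l] <- mse
      cand <- list(alpha = a, lambda = l, mse = mse)
      if (is.null(best) || mse < best$mse ||
          (mse == best$mse && (l < best$lambda ||
                               (l == best$lambda && a > best$alpha)))) {
        best <- cand
      }
    }
  }
  cfg <- enet_config(alpha = best$alpha, lambda_total = best$lambda,
                     standardize = standardize)
  list(fit = fit_enet(ystar, Z, cfg), best = cfg, grid = grid,
       split_seed = seed + tries)
}
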