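# Phenotype precorrection, genomic relationship matrices (additive and
# additive-by-additive), and Gibbs-sampling variance components.

#' Precorrect phenotypes for fixed effects
#'
#' Fits, per trait, an ordinary least-squares model of the raw phenotype on the
#' categorical covariates (main effects only, full-rank treatment coding) and
#' stores the residual as the precorrected phenotype `y*` in a new column
#' `<trait>_star`. Covariates with fewer than two observed levels are dropped
#' silently (an intercept-only fit then yields `y* = y - mean(y)`). A
#' rank-deficient covariate design raises an error naming the aliased terms.
#'
#' Precorrection is fitted on the full dataset (reference and validation
#' together), before any split; see the methods vignette for the
#' information-flow caveat.
#'
#' @param traits a `trait_table` (data.frame with a `"traits"` attribute).
#' @param trait_names traits to precorrect (default: all declared).
#' @param covariates covariate column names (default diet, generation, litter,
#'   sex).
#' @return the trait table with `<trait>_star` columns added and a
#'   `"precorrect_fits"` attribute holding per-trait fitted effect tables.
#' @export
precorrect <- function(traits,
                       trait_names = attr(traits, "traits"),
                       covariates = c("diet", "generation", "litter", "sex")) {
  stopifnot(is.data.frame(traits), length(trait_names) >= 1)
  missing_cov <- setdiff(covariates, names(traits))
  if (length(missing_cov)) stop("missing covariate columns: ",
                                paste(missing_cov, collapse = ", "))
  fits <- list()
  for (tr in trait_names) {
    y <- traits[[tr]]
    obs <- which(!is.na(y))
    dat <- traits[obs, covariates, drop = FALSE]
    dat[] <- lapply(dat, function(v) factor(v))
    use <- covariates[vapply(dat, function(f) nlevels(droplevels(f)) >= 2, logical(1))]
    ystar <- rep(NA_real_, nrow(traits))
    if (length(use) == 0) {
      ystar[obs] <- y[obs] - mean(y[obs])
      fits[[tr]] <- data.frame(term = "(Intercept)", estimate = mean(y[obs]))
    } else {
      df <- cbind(data.frame(.y = y[obs]), dat[use])
      fml <- stats::as.formula(paste(".y ~", paste(use, collapse = " + ")))
      fit <- stats::lm(fml, data = df)
      cf <- stats::coef(fit)
      if (anyNA(cf)) {
        stop("confounding error: aliased covariate levels: ",
             paste(names(cf)[is.na(cf)], collapse = ", "))
      }
      res <- stats::residuals(fit)
      ystar[obs] <- res - mean(res)
      fits[[tr]] <- data.frame(term = names(cf), estimate = unname(cf))
    }
    traits[[paste0(tr, "_star")]] <- ystar
  }
  attr(traits, "precorrect_fits") <- fits
  traits
}

#' Centered and standardized genotype matrix Z
#'
#' `z_ik = (x_ik - 2 p_k) / sqrt(2 p_k (1 - p_k))` with `p_k` the sample
#' allele frequency computed over the animals in the matrix. Errors on
#' monomorphic SNPs (divide-by-zero guard) and on missing dosages.
#'
#' @param x a `genotype_panel` or a complete dosage matrix.
#' @return numeric matrix with the same dimnames.
#' @export
standardize_dosages <- function(x) {
  dos <- if (inherits(x, "genotype_panel")) x$dosages else x
  if (anyNA(dos)) stop("dosages must be complete; run impute_mean() first")
  p <- colMeans(dos) / 2
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic SNP(s): ",
         paste(utils::head(colnames(dos)[p <= 0 | p >= 1], 5), collapse = ", "))
  }
  sweep(sweep(dos, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
}

#' Additive genomic relationship matrix (VanRaden, second method)
#'
#' `G = Z Z' / m` with `Z` the centered and standardized genotype matrix and
#' `m` the number of markers.
#'
#' @param x a `genotype_panel` or complete dosage matrix.
#' @return symmetric matrix of class `relationship_matrix`, kind `"additive"`.
#' @export
build_g_additive <- function(x) {
  Z <- standardize_dosages(x)
  G <- tcrossprod(Z) / ncol(Z)
  structure(G, class = c("relationship_matrix", "matrix"), kind = "additive")
}

#' Additive-by-additive relationship matrix
#'
#' The Hadamard (element-wise) square `G # G` of the additive relationship
#' matrix; by the Schur product theorem it is positive semidefinite whenever
#' `G` is.
#'
#' @param G an additive `relationship_matrix`.
#' @return matrix of class `relationship_matrix`, kind
#'   `"additive_by_additive"`.
#' @export
build_g_epistatic <- function(G) {
  stopifnot(inherits(G, "relationship_matrix"))
  GG <- unclass(G) * unclass(G)
  structure(GG, class = c("relationship_matrix", "matrix"),
            kind = "additive_by_additive")
}

# Gibbs sampler for y = 1*mu + sum_j u_j + e with u_j ~ N(0, K_j sigma_j^2).
# Each K_j is eigendecomposed once; the conditional posterior of the
# transformed coordinates alpha_j = U_j' u_j is then diagonal. With a single
# component the whole chain runs in the eigenbasis (orthogonal transforms
# preserve the iid residual), costing O(n) per iteration; with two components
# each update costs two n x n matrix-vector products. Scaled-inverse-chi-square
# priors (df = df_prior) with prior modes of 0.5 var(y)/k per genetic component
# and 0.5 var(y) for the residual. "Prior modes" here are parameterized via the
# prior mean (nu s2 / (nu - 2) = target): matching the mode instead provably
# over-inflates small variance components (see the methods vignette).
.gibbs_mixed <- function(y, Klist, n_iter, burn_in, thin, df_prior = 5,
                         seed = 1, keep_u = FALSE, tol = 1e-8) {
  n <- length(y)
  k <- length(Klist)
  eig <- lapply(Klist, function(K) {
    e <- eigen(unclass(K), symmetric = TRUE)
    if (min(e$values) < -1e-6 * max(abs(e$values))) {
      stop("numerical error: relationship matrix is not PSD")
    }
    e$values[e$values < tol] <- 0
    e
  })
  vy <- stats::var(y)
  nu <- df_prior
  s2g <- (0.5 * vy / k) * (nu - 2) / nu
  s2e <- (0.5 * vy) * (nu - 2) / nu

  if (k == 1) {
    return(.gibbs_single(y, eig[[1]], n_iter, burn_in, thin, nu, s2g, s2e,
                         seed, keep_u))
  }

  with_seed(seed, {
    mu <- mean(y)
    sig_g <- rep(0.5 * vy / k, k)
    sig_e <- 0.5 * vy
    alpha <- lapply(eig, function(e) numeric(n))
    u <- lapply(eig, function(e) numeric(n))
    r <- y - mu
    n_samp <- floor((n_iter - burn_in) / thin)
    samp_g <- matrix(NA_real_, n_samp, k)
    samp_e <- numeric(n_samp)
    samp_mu <- numeric(n_samp)
    u_sum <- if (keep_u) lapply(seq_len(k), function(j) numeric(n)) else NULL
    s <- 0L
    for (it in seq_len(n_iter)) {
      for (j in seq_len(k)) {
        d <- eig[[j]]$values
        U <- eig[[j]]$vectors
        rj <- r + u[[j]]
        rt <- crossprod(U, rj)
        v <- ifelse(d > 0, 1 / (1 / sig_e + 1 / (d * sig_g[j])), 0)
        m_post <- v * rt / sig_e
        a <- m_post + sqrt(v) * stats::rnorm(n)
        unew <- as.numeric(U %*% a)
        r <- rj - unew
        u[[j]] <- unew
        alpha[[j]] <- as.numeric(a)
        npos <- sum(d > 0)
        ss <- sum(a[d > 0]^2 / d[d > 0])
        sig_g[j] <- (nu * s2g + ss) / stats::rchisq(1, nu + npos)
      }
      # intercept
      r <- r + mu
      mu <- stats::rnorm(1, mean(r), sqrt(sig_e / n))
      r <- r - mu
      sig_e <- (nu * s2e + sum(r^2)) / stats::rchisq(1, nu + n)
      if (it > burn_in && (it - burn_in) %% thin == 0) {
        s <- s + 1L
        samp_g[s, ] <- sig_g
        samp_e[s] <- sig_e
        samp_mu[s] <- mu
        if (keep_u) for (j in seq_len(k)) u_sum[[j]] <- u_sum[[j]] + u[[j]]
      }
    }
    list(sigma_g_mean = colMeans(samp_g), sigma_g_sd = apply(samp_g, 2, stats::sd),
         sigma_e_mean = mean(samp_e), sigma_e_sd = stats::sd(samp_e),
         mu_mean = mean(samp_mu),
         h2_samples = rowSums(samp_g) / (rowSums(samp_g) + samp_e),
         samples = list(g = samp_g, e = samp_e),
         u_mean = if (keep_u) lapply(u_sum, function(z) z / s) else NULL,
         n_samples = s)
  })
}

# Single-component fast path: the model is transformed once by U', after
# which every Gibbs update is O(n).
.gibbs_single <- function(y, e, n_iter, burn_in, thin, nu, s2g, s2e,
                          seed, keep_u) {
  n <- length(y)
  d <- e$values
  U <- e$vectors
  yt <- as.numeric(crossprod(U, y))
  onet <- as.numeric(crossprod(U, rep(1, n)))
  pos <- d > 0
  npos <- sum(pos)
  with_seed(seed, {
    vy <- stats::var(y)
    mu <- mean(y)
    sig_g <- 0.5 * vy
    sig_e <- 0.5 * vy
    alpha <- numeric(n)
    n_samp <- floor((n_iter - burn_in) / thin)
    samp_g <- numeric(n_samp); samp_e <- numeric(n_samp); samp_mu <- numeric(n_samp)
    a_sum <- numeric(n)
    s <- 0L
    for (it in seq_len(n_iter)) {
      rt <- yt - mu * onet
      v <- ifelse(pos, 1 / (1 / sig_e + 1 / (d * sig_g)), 0)
      alpha <- v * rt / sig_e + sqrt(v) * stats::rnorm(n)
      ss <- sum(alpha[pos]^2 / d[pos])
      sig_g <- (nu * s2g + ss) / stats::rchisq(1, nu + npos)
      # intercept: 1'(y - U alpha) / n = (onet' (yt - alpha)) / n
      mu <- stats::rnorm(1, sum(onet * (yt - alpha)) / n, sqrt(sig_e / n))
      res2 <- sum((yt - mu * onet - alpha)^2)
      sig_e <- (nu * s2e + res2) / stats::rchisq(1, nu + n)
      if (it > burn_in && (it - burn_in) %% thin == 0) {
        s <- s + 1L
        samp_g[s] <- sig_g; samp_e[s] <- sig_e; samp_mu[s] <- mu
        if (keep_u) a_sum <- a_sum + alpha
      }
    }
    list(sigma_g_mean = mean(samp_g), sigma_g_sd = stats::sd(samp_g),
         sigma_e_mean = mean(samp_e), sigma_e_sd = stats::sd(samp_e),
         mu_mean = mean(samp_mu),
         h2_samples = samp_g / (samp_g + samp_e),
         samples = list(g = matrix(samp_g, ncol = 1), e = samp_e),
         u_mean = if (keep_u) list(as.numeric(U %*% (a_sum / s))) else NULL,
         n_samples = s)
  })
}

#' Estimate variance components by Gibbs sampling
#'
#' Fits `y* = 1 mu + u_1 (+ u_2) + e` with `u_j ~ N(0, K_j sigma_j^2)` for one
#' (additive) or two (additive plus additive-by-additive) relationship
#' matrices, using scaled-inverse-chi-square priors. Heritability is reported
#' as the genetic fraction of the total variance, with the
#' additive-by-additive component included in the denominator when fitted.
#'
#' @param ystar complete numeric vector of precorrected phenotypes.
#' @param K a `relationship_matrix` or list of one or two of them, conformable
#'   with `ystar`.
#' @param n_iter,burn_in,thin Gibbs chain settings (desk-scale defaults).
#' @param df_prior prior degrees of freedom (default 5).
#' @param seed integer seed.
#' @return object of class `varcomp`: posterior means and SDs of each variance,
#'   `h2` (posterior mean and SD), per-component variance fractions, and the
#'   retained samples.
#' @export
estimate_variance_components <- function(ystar, K, n_iter = 15000,
                                         burn_in = 5000, thin = 10,
                                         df_prior = 5, seed = 1) {
  if (inherits(K, "relationship_matrix") || is.matrix(K)) K <- list(K)
  stopifnot(length(K) %in% c(1, 2), !anyNA(ystar))
  stopifnot(all(vapply(K, nrow, 1L) == length(ystar)))
  fit <- .gibbs_mixed(ystar, K, n_iter, burn_in, thin, df_prior, seed)
  kinds <- vapply(seq_along(K), function(j) attr(K[[j]], "kind") %||%
                    paste0("component", j), character(1))
  tot <- sum(fit$sigma_g_mean) + fit$sigma_e_mean
  structure(list(
    sigma = stats::setNames(c(fit$sigma_g_mean, fit$sigma_e_mean),
                            c(kinds, "residual")),
    sigma_sd = stats::setNames(c(fit$sigma_g_sd, fit$sigma_e_sd),
                               c(kinds, "residual")),
    fractions = stats::setNames(c(fit$sigma_g_mean / tot, fit$sigma_e_mean / tot),
                                c(kinds, "residual")),
    h2 = mean(fit$h2_samples), h2_sd = stats::sd(fit$h2_samples),
    n_samples = fit$n_samples,
    settings = c(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 df_prior = df_prior, seed = seed)), class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat("varcomp (Gibbs posterior means +/- SD):\n")
  for (nm in names(x$sigma)) {
    cat(sprintf("  %-22s %8.4f +/- %.4f (fraction %.3f)\n", nm,
                x$sigma[[nm]], x$sigma_sd[[nm]], x$fractions[[nm]]))
  }
  cat(sprintf("  h2 = %.3f +/- %.3f (%d samples)\n", x$h2, x$h2_sd, x$n_samples))
  invisible(x)
}
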