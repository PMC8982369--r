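# GBLUP, BayesB, elastic net: oracle equivalences and contracts.

test_that("GBLUP posterior mean matches the closed-form mixed-model solve", {
  # oracle: a_blup = G (G + lambda I)^-1 (y - mu) at the posterior-mean
  # variance ratio lambda = sigma_e^2 / sigma_a^2
  f <- simulate_founders(n_snps = 300, n_chromosomes = 3, seed = 50)
  d <- population_design(generation_labels = c(1, 2),
                         generation_sizes = c(20, 60))
  pop <- drop_generations(f, d, seed = 51)
  sim <- simulate_trait(pop, trait_architecture(n_additive_qtl = 60,
                                                h2_additive = 0.5,
                                                fixed_effect_sizes = c(diet = 0)),
                        seed = 52)
  ids <- pop$meta$animal_id
  ref <- ids[1:60]
  y <- setNames(sim$traits$y, ids)
  G <- build_g_additive(pop$panel)
  fit <- fit_gblup(y, G, ref, gblup_config(60000, 10000, 5), seed = 53)
  lam <- fit$varcomp["sigma_e"] / fit$varcomp["sigma_a"]
  G_rr <- unclass(G)[ref, ref]
  a_oracle <- G_rr %*% solve(G_rr + diag(lam, 60), y[ref] - fit$mu)
  rms <- sqrt(mean((fit$gvalues[ref] - a_oracle)^2))
  expect_lt(rms, 0.02)
})

test_that("GBLUP approaches interpolation as noise vanishes", {
  pop <- small_pop()
  G <- build_g_additive(pop$panel)
  ids <- pop$meta$animal_id[1:120]
  Gs <- structure(unclass(G)[ids, ids], class = class(G), kind = "additive")
  set.seed(54)
  # a noiseless genetic phenotype drawn from N(0, G)
  e <- eigen(unclass(Gs), symmetric = TRUE)
  y <- setNames(as.numeric(e$vectors %*% (sqrt(pmax(e$values, 0)) * rnorm(120))),
                ids)
  fit <- fit_gblup(y, Gs, ids, gblup_config(8000, 3000, 5), seed = 55)
  expect_gt(cor(fit$gvalues[ids], y - mean(y)), 0.99)
})

test_that("G-side prediction equals SNP-side ridge at a matched variance ratio", {
  panel <- random_panel(40, 100, seed = 56)
  Z <- standardize_dosages(panel)
  G <- build_g_additive(panel)
  set.seed(57)
  y <- rnorm(40)
  yc <- y - mean(y)
  ref <- 1:30; val <- 31:40
  lam <- 1.5
  m <- 100
  a_ref <- unclass(G)[ref, ref] %*% solve(unclass(G)[ref, ref] + diag(lam, 30), yc[ref])
  g_val <- unclass(G)[val, ref] %*% solve(unclass(G)[ref, ref] + diag(1e-8, 30), a_ref)
  beta <- solve(crossprod(Z[ref, ]) + diag(m * lam, m), crossprod(Z[ref, ], yc[ref]))
  expect_lt(max(abs(Z[val, ] %*% beta - g_val)), 1e-6)
})

test_that("backsolved SNP effects reproduce the genetic values", {
  panel <- random_panel(30, 60, seed = 58)
  Z <- standardize_dosages(panel)
  G <- build_g_additive(panel)
  set.seed(59)
  a <- as.numeric(unclass(G) %*% rnorm(30)) # in range(G)
  names(a) <- rownames(Z)
  beta <- backsolve_snp_effects(a, Z, G)
  expect_lt(max(abs(Z %*% beta - a)), 1e-6)
  expect_equal(unname(backsolve_snp_effects(setNames(numeric(30), rownames(Z)),
                                            Z, G)),
               numeric(60))
  # 2-animal toy: G = [[2,-2],[-2,2]]
  dos <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("a1", "a2"), c("s1", "s2")))
  map <- data.frame(snp_id = c("s1", "s2"), chrom = 1, pos_cM = 1:2)
  p2 <- genotype_panel(dos, map)
  Z2 <- standardize_dosages(p2)
  G2 <- build_g_additive(p2)
  a2 <- c(a1 = 1, a2 = -1)
  b2 <- backsolve_snp_effects(a2, Z2, G2)
  expect_equal(as.numeric(Z2 %*% b2), c(1, -1), tolerance = 1e-6)
})

test_that("BayesB with pi near 1 suppresses effects on pure noise", {
  panel <- random_panel(100, 200, seed = 60)
  Z <- standardize_dosages(panel)
  set.seed(61)
  y <- setNames(rnorm(100), rownames(Z))
  fit <- fit_bayesb(y, Z, bayesb_config(3000, 500, 5, pi = 0.999), seed = 62)
  expect_gt(mean(abs(fit$beta) < 0.01 * sd(y)), 0.99)
})

test_that("BayesB concentrates inclusion on a single strong QTL", {
  hits <- 0L
  for (s in 1:20) {
    panel <- random_panel(400, 500, seed = 700 + s)
    Z <- standardize_dosages(panel)
    set.seed(800 + s)
    qtl <- sample(500, 1)
    g <- Z[, qtl] * sqrt(0.3)
    y <- setNames(g + rnorm(400, sd = sqrt(0.7)), rownames(Z))
    fit <- fit_bayesb(y, Z, bayesb_config(2500, 500, 4), seed = 900 + s)
    if (which.max(fit$inclusion) == qtl) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("BayesB with pi = 0 matches an independent BayesA sampler", {
  # oracle: minimal BayesA Gibbs in plain R (every marker always in the model)
  bayesa_oracle <- function(y, Z, n_iter, burn_in, nu, s2, nu_e, s2e, seed) {
    set.seed(seed)
    n <- nrow(Z); m <- ncol(Z)
    zz <- colSums(Z^2)
    beta <- numeric(m); sig_g <- rep(s2, m)
    mu <- mean(y); sig_e <- var(y) / 2
    r <- y - mu
    beta_sum <- numeric(m); kept <- 0
    for (it in seq_len(n_iter)) {
      for (j in seq_len(m)) {
        r <- r + Z[, j] * beta[j]
        c_j <- zz[j]; lamj <- sig_e / sig_g[j]
        v <- sig_e / (c_j + lamj)
        bmean <- sum(Z[, j] * r) / (c_j + lamj)
        beta[j] <- rnorm(1, bmean, sqrt(v))
        r <- r - Z[, j] * beta[j]
        sig_g[j] <- (nu * s2 + beta[j]^2) / rchisq(1, nu + 1)
      }
      mu_new <- rnorm(1, mean(r + mu), sqrt(sig_e / n))
      r <- r + mu - mu_new; mu <- mu_new
      sig_e <- (nu_e * s2e + sum(r^2)) / rchisq(1, nu_e + n)
      if (it > burn_in) {
        beta_sum <- beta_sum + beta; kept <- kept + 1
      }
    }
    beta_sum / kept
  }
  panel <- random_panel(100, 50, seed = 63)
  Z <- standardize_dosages(panel)
  set.seed(64)
  beta_true <- rnorm(50, 0, 0.15)
  y <- setNames(as.numeric(Z %*% beta_true) + rnorm(100, sd = 0.5), rownames(Z))
  vy <- var(y); nu <- 5
  s2 <- 0.5 * vy * (nu - 2) / (nu * 50)
  s2e <- 0.5 * vy * (nu + 2) / nu
  fit <- fit_bayesb(y, Z, bayesb_config(12000, 2000, 5, pi = 0, nu = nu, s2 = s2),
                    seed = 65)
  oracle <- bayesa_oracle(as.numeric(y), Z, 6000, 1000, nu, s2, nu, s2e, seed = 66)
  expect_gt(cor(fit$beta, oracle), 0.98)
})

test_that("elastic net with alpha = 1 matches the ridge closed form", {
  set.seed(67)
  n <- 40; m <- 12
  Z <- matrix(rnorm(n * m), n, m, dimnames = list(sprintf("a%d", 1:n),
                                                  sprintf("s%d", 1:m)))
  Z <- sweep(Z, 2, colMeans(Z))
  y <- setNames(rnorm(n), rownames(Z))
  lt <- 0.05
  fit <- fit_enet(y, Z, enet_config(alpha = 1, lambda_total = lt,
                                    standardize = FALSE))
  lambda2 <- lt * n
  oracle <- solve(crossprod(Z) + diag(lambda2, m), crossprod(Z, y - mean(y)))
  expect_lt(max(abs(fit$beta - oracle)), 1e-6)
})

test_that("elastic net with alpha = 0 soft-thresholds on an orthonormal design", {
  set.seed(68)
  n <- 40; m <- 8
  A <- matrix(rnorm(n * m), n, m)
  A <- sweep(A, 2, colMeans(A))
  Z <- qr.Q(qr(A)) # orthonormal, columns orthogonal to 1
  dimnames(Z) <- list(sprintf("a%d", 1:n), sprintf("s%d", 1:m))
  y <- setNames(rnorm(n), rownames(Z))
  lt <- 0.02
  fit <- fit_enet(y, Z, enet_config(alpha = 0, lambda_total = lt,
                                    standardize = FALSE))
  bols <- crossprod(Z, y - mean(y))
  thr <- lt * n / 2
  soft <- sign(bols) * pmax(abs(bols) - thr, 0)
  expect_lt(max(abs(fit$beta - soft)), 1e-8)
})

test_that("elastic net with zero penalty recovers OLS", {
  set.seed(69)
  n <- 50; m <- 5
  Z <- matrix(rnorm(n * m), n, m, dimnames = list(sprintf("a%d", 1:n),
                                                  sprintf("s%d", 1:m)))
  y <- setNames(Z %*% c(1, -2, 0.5, 0, 3) + rnorm(n, sd = 0.3), rownames(Z))
  fit <- fit_enet(y, Z, enet_config(alpha = 0.5, lambda_total = 0,
                                    standardize = FALSE))
  ols <- lm(y ~ Z)
  expect_equal(unname(fit$beta), unname(coef(ols)[-1]), tolerance = 1e-5)
})

test_that("lambda path honours its endpoint and ratio contract", {
  p <- lambda_path()
  expect_identical(length(p), 20L)
  expect_equal(p[1], 1)
  expect_lte(p[20], 0.01 + 1e-12)
  expect_equal(diff(log(p)), rep(diff(log(p))[1], 19), tolerance = 1e-12)
})

test_that("tune_enet finds a near-unpenalized fit on a noiseless sparse signal", {
  set.seed(70)
  n <- 60; m <- 20
  Z <- matrix(rnorm(n * m), n, m, dimnames = list(sprintf("a%d", 1:n),
                                                  sprintf("s%d", 1:m)))
  y <- setNames(as.numeric(2 * Z[, 1] - Z[, 3]), rownames(Z))
  res <- tune_enet(y, Z, alpha_grid = seq(0, 1, 0.25))
  expect_equal(res$best$lambda_total, 0.01, tolerance = 1e-12)
  expect_lt(min(res$grid$mse), 1e-3)
})

test_that("tune_enet does not fit pure noise", {
  mses <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    n <- 50; m <- 30
    Z <- matrix(rnorm(n * m), n, m, dimnames = list(sprintf("a%d", 1:n),
                                                    sprintf("s%d", 1:m)))
    y <- setNames(rnorm(n), rownames(Z))
    res <- tune_enet(y, Z, alpha_grid = seq(0, 1, 0.25), seed = s)
    sp <- split_80_20(rownames(Z), seed = res$split_seed)
    min(res$grid$mse) / var(y[sp$test])
  }, numeric(1))
  expect_gte(stats::median(mses), 0.9)
})

test_that("all fitters are invariant to constant phenotype shifts", {
  panel <- random_panel(60, 40, seed = 71)
  Z <- standardize_dosages(panel)
  G <- build_g_additive(panel)
  set.seed(72)
  y <- setNames(rnorm(60), rownames(Z))
  ys <- y + 100
  f1 <- fit_enet(y, Z, enet_config(0.5, 0.05))
  f2 <- fit_enet(ys, Z, enet_config(0.5, 0.05))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f2$mu - f1$mu, 100, tolerance = 1e-10)
  b1 <- fit_bayesb(y, Z, bayesb_config(800, 200, 2), seed = 73)
  b2 <- fit_bayesb(ys, Z, bayesb_config(800, 200, 2), seed = 73)
  expect_equal(b1$beta, b2$beta, tolerance = 1e-9)
  g1 <- fit_gblup(y, G, rownames(Z)[1:40], gblup_config(2000, 500, 5), seed = 74)
  g2 <- fit_gblup(ys, G, rownames(Z)[1:40], gblup_config(2000, 500, 5), seed = 74)
  expect_equal(g1$gvalues, g2$gvalues, tolerance = 1e-9)
})

test_that("MCMC fits are deterministic under a fixed seed", {
  panel <- random_panel(50, 30, seed = 75)
  Z <- standardize_dosages(panel)
  G <- build_g_additive(panel)
  set.seed(76)
  y <- setNames(rnorm(50), rownames(Z))
  expect_identical(fit_bayesb(y, Z, bayesb_config(500, 100, 2), seed = 7)$beta,
                   fit_bayesb(y, Z, bayesb_config(500, 100, 2), seed = 7)$beta)
  expect_identical(fit_gblup(y, G, rownames(Z)[1:30], gblup_config(800, 200, 2),
                             seed = 8)$gvalues,
                   fit_gblup(y, G, rownames(Z)[1:30], gblup_config(800, 200, 2),
                             seed = 8)$gvalues)
})
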