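covar_frame <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(q = runif(n), garden = factor(sample(c("f", "s"), n, TRUE)),
             year = factor(sample(2010:2012, n, TRUE)))
}

test_that("covariate adjustment matches the normal equations", {
  set.seed(51)
  n <- 200
  cv <- covar_frame(n)
  X <- stats::model.matrix(~ q + garden + year, cv)
  beta <- c(1, 2, -0.5, 0.3, 0.8)
  y <- as.numeric(X %*% beta) + rnorm(n, 0, 0.7)
  adj <- adjust_phenotype(y, cv)
  # independent oracle: hand-solved least squares
  bh <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(adj$residuals), as.numeric(y - X %*% bh),
               tolerance = 1e-10)
  # residuals orthogonal to every fitted covariate column
  expect_lt(max(abs(crossprod(X, adj$residuals))), 1e-8)
  # exact linear dependence on q leaves zero residuals
  adj2 <- adjust_phenotype(2 + 3 * cv$q, cv["q"])
  expect_lt(max(abs(adj2$residuals)), 1e-10)
  # no covariate effect: residuals are the centered trait, R2 near 0
  y0 <- rnorm(n)
  adj3 <- adjust_phenotype(y0, cv)
  expect_gt(cor(adj3$residuals, y0 - mean(y0)), 0.98)
  expect_lt(adj3$r2_cov, 0.1)
})

test_that("binary traits yield logistic response residuals", {
  set.seed(52)
  n <- 300
  cv <- covar_frame(n, 2)
  eta <- -0.5 + 2 * cv$q
  y <- rbinom(n, 1, plogis(eta))
  adj <- adjust_phenotype(y, cv["q"], family = "binary")
  fit <- stats::glm(y ~ q, data = cv, family = stats::binomial())
  expect_equal(unname(adj$residuals), unname(y - fitted(fit)),
               tolerance = 1e-10)
})

test_that("degenerate covariates are handled with warnings", {
  cv <- data.frame(q = runif(20), flat = rep(1, 20))
  expect_warning(adjust_phenotype(rnorm(20), cv), "constant covariate")
  expect_error(adjust_phenotype(rep(NA_real_, 20), cv), "no non-missing")
})

test_that("kinship is the centered cross-product with PSD repair", {
  dos <- rbind(c(0, 1, 2, 1), c(0, 2, 2, 1), c(2, 1, 0, 0))
  K <- kinship(dos)
  # hand computation (all four columns vary)
  Xc <- scale(dos, center = TRUE, scale = FALSE)
  expect_equal(K$K, tcrossprod(Xc) / 4, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(K$L_eff, 4)
  # centered construction: K 1 = 0
  expect_lt(max(abs(K$K %*% rep(1, 3))), 1e-8)
  expect_lt(max(abs(K$K - t(K$K))), 1e-10)
  # monomorphic markers dropped from L_eff
  K2 <- kinship(cbind(dos, c(1, 1, 1)))
  expect_equal(K2$L_eff, 4)
  expect_equal(K2$K, K$K, tolerance = 1e-12)
  # identical individuals give identical rows
  Kdup <- kinship(rbind(c(0, 1, 2, 1), c(0, 1, 2, 1), c(2, 0, 0, 0)))
  expect_equal(Kdup$K[1, ], Kdup$K[2, ], tolerance = 1e-12)
  expect_error(kinship(matrix(1, 3, 2)), "monomorphic")
})

test_that("per-draw identities hold and runs are reproducible", {
  set.seed(53)
  n <- 80; L <- 60
  X <- matrix(rbinom(n * L, 2, 0.4), n, L)
  y <- X[, 7] * 0.8 + rnorm(n)
  cfg <- bslmm_config(n_chains = 2, n_iter = 5000, seed = 9)
  f1 <- bslmm(y, X, cfg = cfg)
  expect_equal(f1$draws$h2, f1$draws$pve * f1$draws$pge)
  expect_true(all(f1$draws$pve >= 0 & f1$draws$pve <= 1))
  expect_true(all(f1$draws$pge >= 0 & f1$draws$pge <= 1))
  expect_true(all(f1$draws$n_gamma == round(f1$draws$n_gamma)))
  expect_true(all(f1$pip >= 0 & f1$pip <= 1))
  # empty sparse set forces PGE = 0 and n_gamma = 0
  empty <- f1$draws$n_gamma == 0
  if (any(empty)) expect_true(all(f1$draws$pge[empty] == 0))
  # identical inputs + seeds give identical draws
  f2 <- bslmm(y, X, cfg = cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$pip, f2$pip)
})

test_that("marker permutation preserves the association signal", {
  set.seed(54)
  n <- 150; L <- 80
  X <- matrix(rbinom(n * L, 2, 0.5), n, L)
  y <- X[, 40] * 1.0 + rnorm(n)
  cfg <- bslmm_config(n_chains = 2, n_iter = 20000, seed = 4)
  f1 <- bslmm(y, X, cfg = cfg)
  perm <- sample(L)
  f2 <- bslmm(y, X[, perm], cfg = cfg)
  pip_back <- f2$pip[order(perm)]
  expect_equal(which.max(f1$pip), 40)
  expect_equal(which.max(pip_back), 40)
  expect_lt(max(abs(f1$pip - pip_back)), 0.15)  # Monte Carlo tolerance
})

test_that("the kinship-only mode recovers the polygenic fraction", {
  s <- small_sim(seed = 55, n_sites = 150, n_ind = 500)
  ph <- simulate_phenotype(s$ped, phenotype_spec("second", pve = 0.5,
                                                 covar_frac = 0))
  fit <- bslmm(ph$y, s$ped$anc_dosage,
               cfg = bslmm_config(n_chains = 2, n_iter = 20000,
                                  pi_zero = TRUE, seed = 5))
  expect_true(all(fit$draws$pge == 0))
  expect_true(all(fit$draws$n_gamma == 0))
  expect_lt(abs(mean(fit$draws$pve) - 0.5), 0.15)
})

test_that("short and long chains agree within Monte Carlo error", {
  set.seed(56)
  n <- 60; L <- 30
  X <- matrix(rbinom(n * L, 2, 0.5), n, L)
  y <- X[, 1] * 1.2 + rnorm(n)
  f_short <- bslmm(y, X, cfg = bslmm_config(n_chains = 2, n_iter = 20000,
                                            seed = 1))
  f_long <- bslmm(y, X, cfg = bslmm_config(n_chains = 2, n_iter = 200000,
                                           seed = 77))
  se <- mcse(f_short$draws$pve)
  diff <- abs(mean(f_short$draws$pve) - mean(f_long$draws$pve))
  expect_lt(diff, 3 * se + 0.005)
})

test_that("posterior PVE intervals are consistent with the simulated truth", {
  # single ancestry QTL explaining 40% of the variance
  cover <- logical(10)
  for (r in 1:10) {
    s <- small_sim(seed = 700 + r, n_sites = 250, n_ind = 300,
                   chrom_length_bp = 1.25e7)
    ph <- simulate_phenotype(s$ped, phenotype_spec("first", h2 = 0.4,
                                                   pve = 0.4, n_qtl = 1,
                                                   covar_frac = 0))
    fit <- bslmm(ph$y, s$ped$anc_dosage,
                 cfg = bslmm_config(n_chains = 2, n_iter = 30000,
                                    seed = 800 + r))
    ci <- stats::quantile(fit$draws$pve, c(0.05, 0.95))
    cover[r] <- ci[1] <= 0.4 && 0.4 <= ci[2]
  }
  expect_gte(mean(cover), 0.7)
})

test_that("posterior probabilities are draw fractions", {
  df <- data.frame(h2 = c(rep(0.02, 19), 0.001), pve = rep(0.2, 20))
  expect_equal(posterior_prob(df, ~ h2 >= 0.01), 0.95)
  expect_equal(posterior_prob(df, ~ pve >= 0.05), 1)
  expect_equal(posterior_prob(df, ~ h2 > 1), 0)
  expect_error(posterior_prob(df[0, ], ~ h2 > 0), "no retained draws")
})
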