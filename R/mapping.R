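#' Adjust a phenotype for covariates before mapping
#'
#' Quantitative traits: ordinary least-squares residuals after regressing
#' on the declared covariates (genome-wide ancestry q, common garden,
#' planting year, per trait). Binary traits: response residuals
#' (observed - fitted probability) from a binomial logistic fit on the
#' same covariates. Categorical covariates are one-hot encoded with a
#' reference level by the model formula; collinear columns are dropped
#' (with a warning) rather than failing.
#'
#' @param y Trait vector (0/1 for `family = "binary"`). NAs are dropped
#'   together with their covariate rows.
#' @param covariates data.frame of covariate columns (already subset to
#'   the trait's declared list).
#' @param family `"quantitative"` or `"binary"`.
#' @return A list of class `hz_adjusted`: `residuals` (named, NA rows
#'   removed), `fitted`, `family`, `fit` (the lm/glm object), `r2_cov`
#'   (variance fraction explained by covariates, quantitative only).
#' @export
adjust_phenotype <- function(y, covariates,
                             family = c("quantitative", "binary")) {
  family <- match.arg(family)
  stopifnot(is.data.frame(covariates), length(y) == nrow(covariates))
  ok <- !is.na(y) & stats::complete.cases(covariates)
  if (!any(ok)) stop("trait has no non-missing observations")
  dat <- droplevels(data.frame(.y = y[ok], covariates[ok, , drop = FALSE]))
  # drop constant covariates up front (would be collinear with intercept)
  const <- vapply(dat[-1], function(col) length(unique(col)) < 2, logical(1))
  if (any(const)) {
    warning("dropping constant covariate(s): ",
            paste(names(dat)[-1][const], collapse = ", "))
    dat <- dat[c(TRUE, !const)]
  }
  fit <- if (family == "quantitative") {
    stats::lm(.y ~ ., data = dat)
  } else {
    stopifnot(all(dat$.y %in% 0:1))
    stats::glm(.y ~ ., data = dat, family = stats::binomial())
  }
  if (any(is.na(stats::coef(fit))))
    warning("collinear covariate column(s) dropped from the fit")
  res <- if (family == "quantitative") stats::residuals(fit)
         else dat$.y - stats::fitted(fit)
  names(res) <- rownames(covariates)[ok]
  r2 <- if (family == "quantitative")
    1 - stats::var(res) / stats::var(dat$.y) else NA_real_
  structure(list(residuals = res, fitted = stats::fitted(fit),
                 family = family, fit = fit, r2_cov = r2, kept = which(ok)),
            class = "hz_adjusted")
}

#' Ancestry kinship (genomic similarity) matrix
#'
#' Centers each marker column and returns the cross-product scaled by the
#' number of polymorphic markers: `K = Xc Xc' / L_eff`. Monomorphic
#' markers are dropped from `L_eff`. If numerical noise produces negative
#' eigenvalues beyond tolerance they are clipped at zero
#' (smallest-eigenvalue repair).
#'
#' @param dosages Individuals x markers matrix (ancestry dosages in
#'   [0, 2], or any genotype coding).
#' @return A list of class `hz_kinship`: `K` (n x n), `L_eff`, `repaired`.
#' @export
kinship <- function(dosages) {
  stopifnot(nrow(dosages) >= 2)
  sds <- apply(dosages, 2, stats::sd)
  poly <- which(!is.na(sds) & sds > 0)
  if (length(poly) == 0) stop("all markers monomorphic")
  Xc <- scale(dosages[, poly, drop = FALSE], center = TRUE, scale = FALSE)
  K <- tcrossprod(Xc) / length(poly)
  K <- (K + t(K)) / 2
  repaired <- FALSE
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    e <- eigen(K, symmetric = TRUE)
    K <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    K <- (K + t(K)) / 2
    repaired <- TRUE
  }
  dimnames(K) <- list(rownames(dosages), rownames(dosages))
  structure(list(K = K, L_eff = length(poly), repaired = repaired),
            class = "hz_kinship")
}

#' MCMC configuration for the sparse mixed-model sampler
#'
#' The `"desk"` preset (3 chains of 50,000 iterations, 10% burn-in) is
#' the default working scale; `"paper"` names the 10-chain, 12-million
#' iteration, 2-million burn-in setting used for full-size analyses.
#'
#' @param n_chains,n_iter,n_burnin,thin Chain settings; `n_burnin`
#'   defaults to 10% of `n_iter`.
#' @param preset `"desk"`, `"paper"`, or `"custom"` (use the numbers
#'   given).
#' @param s_max Cap on the sparse-set size (default 30; sparse
#'   architectures of interest involve few loci, and the cap mainly binds
#'   for null traits where the set size is prior-driven).
#' @param pi_zero If TRUE the sparse component is switched off (the
#'   kinship-only degenerate model).
#' @param w_h,w_rho,w_pi Random-walk proposal half-widths.
#' @param seed Base seed; chain k uses `seed + k - 1`.
#' @export
bslmm_config <- function(n_chains = 3L, n_iter = 50000L,
                         n_burnin = NULL, thin = 10L,
                         preset = c("desk", "paper", "custom"),
                         s_max = 30L, pi_zero = FALSE,
                         w_h = 0.25, w_rho = 0.25, w_pi = 1,
                         seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    n_chains <- 10L; n_iter <- 12e6; n_burnin <- 2e6
  }
  if (is.null(n_burnin)) n_burnin <- as.integer(round(n_iter * 0.1))
  stopifnot(n_burnin < n_iter, n_chains >= 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 preset = preset, s_max = as.integer(s_max),
                 pi_zero = isTRUE(pi_zero), w_h = w_h, w_rho = w_rho,
                 w_pi = w_pi, seed = as.integer(seed)),
            class = "hz_bslmm_config")
}

#' Fit the Bayesian sparse linear mixed model by MCMC
#'
#' Samples the model `y = X_gamma beta_gamma + u + e`, with
#' `u ~ N(0, sigma_b^2 K)` and spike-and-slab marker effects, by
#' Metropolis-within-Gibbs: add/remove/swap moves on the sparse set,
#' random-walk moves on the heritability hyperparameters
#' (`h ~ U(0,1)`, `rho ~ U(0,1)`, `log pi ~ U(log(1/L), 0)`), with
#' effect sizes and the residual variance integrated out analytically.
#' Per retained draw the effects are sampled back and PVE, PGE (empirical
#' variance fractions of the sampled linear predictors), `h2 = PVE * PGE`
#' and `n_gamma` recorded; chains are pooled after burn-in and per-marker
#' PIPs averaged over pooled draws.
#'
#' The phenotype and marker columns are standardized to unit variance
#' before sampling; K is scaled to mean diagonal 1.
#'
#' @param y Adjusted phenotype (e.g. `adjust_phenotype(...)$residuals`).
#' @param dosages Individuals x markers dosage matrix (monomorphic
#'   markers are carried with PIP 0 but excluded from sampling).
#' @param K Optional `hz_kinship` or matrix; computed from `dosages` if
#'   missing.
#' @param cfg A [bslmm_config()].
#' @return An object of class `hz_draws`: `draws` (pooled data.frame with
#'   h, rho, pi, n_gamma, pve, pge, h2, logml, chain), `pip` (per input
#'   marker), `chains` (per-chain acceptance rates and draw counts),
#'   `n`, `L_used`.
#' @export
bslmm <- function(y, dosages, K = NULL, cfg = bslmm_config()) {
  stopifnot(length(y) == nrow(dosages))
  n <- length(y)
  if (n < 30) warning("n < 30: posterior summaries will be unstable")
  sds <- apply(dosages, 2, stats::sd)
  use <- which(!is.na(sds) & sds > 0)
  X <- scale(dosages[, use, drop = FALSE])
  ys <- as.numeric(scale(y))

  if (is.null(K)) K <- kinship(dosages)
  Km <- if (inherits(K, "hz_kinship")) K$K else as.matrix(K)
  md <- mean(diag(Km))
  if (md > 0) Km <- Km / md
  eg <- eigen(Km, symmetric = TRUE)
  if (min(eg$values) < -1e-6)
    stop("kinship matrix is not positive semidefinite")
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  ytil <- as.numeric(crossprod(U, ys))
  Xtil <- crossprod(U, X)

  pooled <- vector("list", cfg$n_chains)
  pip <- rep(0, ncol(dosages))
  chain_info <- data.frame(chain = seq_len(cfg$n_chains), seed = NA_integer_,
                           accept_gamma = NA_real_, accept_hyper = NA_real_)
  for (k in seq_len(cfg$n_chains)) {
    chain_seed <- cfg$seed + k - 1L
    set.seed(chain_seed)
    res <- .bslmm_chain(X, Xtil, ytil, U, d,
                        cfg$n_iter, cfg$n_burnin, cfg$thin,
                        cfg$s_max, cfg$pi_zero,
                        cfg$w_h, cfg$w_rho, cfg$w_pi)
    dr <- as.data.frame(res$draws)
    names(dr) <- c("h", "rho", "pi", "n_gamma", "pve", "pge", "h2", "logml")
    if (!all(is.finite(dr$logml)))
      stop(sprintf("chain %d diverged: non-finite log-likelihood", k))
    dr$chain <- k
    pooled[[k]] <- dr
    pip[use] <- pip[use] + res$pip
    chain_info$seed[k] <- chain_seed
    chain_info$accept_gamma[k] <- res$accept_gamma
    chain_info$accept_hyper[k] <- res$accept_hyper
  }
  draws <- do.call(rbind, pooled)
  structure(list(draws = draws, pip = pip / cfg$n_chains,
                 chains = chain_info, n = n, L_used = length(use),
                 cfg = cfg),
            class = "hz_draws")
}

#' Posterior probability of a predicate over pooled draws
#'
#' Fraction of pooled post-burn-in draws satisfying `predicate`, e.g.
#' `posterior_prob(fit, ~ h2 >= 0.01)`.
#'
#' @param draws An `hz_draws` or its `draws` data.frame.
#' @param predicate A one-sided formula or function evaluated on the
#'   draws data.frame, returning a logical vector.
#' @export
posterior_prob <- function(draws, predicate) {
  df <- if (inherits(draws, "hz_draws")) draws$draws else as.data.frame(draws)
  if (nrow(df) == 0) stop("no retained draws")
  sat <- if (inherits(predicate, "formula")) {
    eval(predicate[[2]], envir = df)
  } else predicate(df)
  mean(sat)
}

#' @export
print.hz_draws <- function(x, ...) {
  cat("<hz_draws>", nrow(x$draws), "pooled draws,", x$cfg$n_chains,
      "chains | posterior means: PVE",
      sprintf("%.3f, PGE %.3f, h2 %.3f, n_gamma %.1f\n",
              mean(x$draws$pve), mean(x$draws$pge), mean(x$draws$h2),
              mean(x$draws$n_gamma)))
  invisible(x)
}
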