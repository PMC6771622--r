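#' Specification of a simulated trait's genetic architecture
#'
#' Three architecture classes mirror the classes the mapping model is
#' meant to distinguish: `"first"` (sparse QTL on local ancestry plus a
#' polygenic background), `"second"` (polygenic background only), and
#' `"third"` (no genetic variance at all: covariates + noise).
#'
#' Variance targets are fractions of total trait variance. `h2` is the
#' sparse fraction and `pve` the total genetic fraction, both expressed
#' on the post-covariate scale (i.e. among the non-covariate variance),
#' matching how the mapping model sees the trait after covariates are
#' regressed out.
#'
#' @param class Architecture class.
#' @param h2 Sparse-effect variance fraction (first class only).
#' @param pve Total genetic variance fraction (sparse + polygenic).
#' @param n_qtl Number of sparse ancestry QTLs (first class).
#' @param covar_frac Fraction of total variance due to covariates
#'   (genome-wide ancestry q, common garden, planting year).
#' @param zero_fraction If non-NULL, the trait is zero-inflated by
#'   liability thresholding to this target zero fraction (compounds
#'   absent in part of the population).
#' @param covar_effects Relative covariate effect sizes before rescaling.
#' @param name Trait name.
#' @export
phenotype_spec <- function(class = c("first", "second", "third"),
                           h2 = 0.3, pve = 0.6, n_qtl = 3L,
                           covar_frac = 0.2, zero_fraction = NULL,
                           covar_effects = list(q = 1, cg = 0.6,
                                                y = c(0, 0.4, -0.3)),
                           name = "trait") {
  class <- match.arg(class)
  if (class == "second") h2 <- 0
  if (class == "third") { h2 <- 0; pve <- 0 }
  if (h2 > pve) stop("h2 cannot exceed pve")
  if (pve > 1 || pve < 0 || covar_frac < 0 || covar_frac >= 1)
    stop("variance targets must be fractions")
  if (covar_frac + (1 - covar_frac) * pve > 1)
    stop("variance targets sum to more than 1")
  structure(list(class = class, h2 = h2, pve = pve, n_qtl = as.integer(n_qtl),
                 covar_frac = covar_frac, zero_fraction = zero_fraction,
                 covar_effects = covar_effects, name = name),
            class = "hz_phenospec")
}

scale_component <- function(x, target_var) {
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s < 1e-12 || target_var <= 0) return(rep(0, length(x)))
  x * sqrt(target_var) / s
}

#' Simulate a quantitative or zero-inflated trait on a hybrid pedigree
#'
#' Builds the trait as covariate terms (genome-wide ancestry q, common
#' garden, planting year) + sparse ancestry-QTL effects + a polygenic
#' term drawn from a zero-mean multivariate normal with covariance
#' proportional to the ancestry kinship matrix + residual noise. Each
#' component is centered and rescaled so realized sample variance
#' fractions hit the `phenotype_spec` targets (up to the small sample
#' cross-covariances between components). Zero-inflated traits are
#' produced by liability thresholding: abundance = max(liability -
#' threshold, 0) with the threshold set at the liability's normal
#' `zero_fraction` quantile.
#'
#' @param ped An `hz_pedigree`.
#' @param pheno_spec A [phenotype_spec()].
#' @param seed Seed; defaults to `ped$spec$seed + 3`.
#' @param covars Optional data.frame (`id`, `q`, `garden`, `year`) to
#'   reuse the same covariate assignment across traits; sampled afresh
#'   when NULL.
#' @return A list: `y` (named trait vector), `components` (data.frame of
#'   the centered, scaled covariate/sparse/polygenic/residual components),
#'   `covars` (id, q, garden, year), and `truth` (the pedigree's
#'   `hz_truth` updated with `qtl`, `varfrac`, `covars`,
#'   `liability_threshold`).
#' @export
simulate_phenotype <- function(ped, pheno_spec, seed = ped$spec$seed + 3L,
                               covars = NULL) {
  stopifnot(inherits(ped, "hz_pedigree"), inherits(pheno_spec, "hz_phenospec"))
  set.seed(seed)
  n <- length(ped$ids)
  dos <- ped$anc_dosage

  if (is.null(covars)) {
    garden <- factor(sample(c("fribourg", "salerno"), n, replace = TRUE))
    year <- factor(sample(c(2010L, 2011L, 2014L), n, replace = TRUE))
  } else {
    garden <- factor(covars$garden)
    year <- factor(covars$year)
  }
  q <- ped$truth$q_true
  ce <- pheno_spec$covar_effects
  eta_cov <- ce$q * as.numeric(scale(q)) +
    ce$cg * (as.integer(garden) - 1L) +
    ce$y[as.integer(year)]

  cf <- pheno_spec$covar_frac
  rest <- 1 - cf
  v_sparse <- rest * pheno_spec$h2
  v_poly <- rest * (pheno_spec$pve - pheno_spec$h2)
  v_resid <- rest * (1 - pheno_spec$pve)

  qtl <- NULL
  eta_sparse <- rep(0, n)
  if (pheno_spec$class == "first" && pheno_spec$n_qtl > 0L && v_sparse > 0) {
    poly_sites <- which(apply(dos, 2, stats::sd) > 0)
    idx <- sort(sample(poly_sites, min(pheno_spec$n_qtl, length(poly_sites))))
    beta <- stats::rnorm(length(idx))
    eta_sparse <- as.numeric(scale(dos[, idx, drop = FALSE], scale = FALSE) %*% beta)
    qtl <- data.frame(site = idx,
                      chrom = ped$sites$chrom[idx], pos = ped$sites$pos[idx],
                      effect = beta, stringsAsFactors = FALSE)
  }

  eta_poly <- rep(0, n)
  if (v_poly > 0) {
    K <- kinship(dos)$K
    eig <- eigen(K, symmetric = TRUE)
    lam <- pmax(eig$values, 0)
    eta_poly <- as.numeric(eig$vectors %*% (sqrt(lam) * stats::rnorm(n)))
  }

  eps <- stats::rnorm(n)

  comp <- data.frame(
    covar = scale_component(eta_cov, cf),
    sparse = scale_component(eta_sparse, v_sparse),
    poly = scale_component(eta_poly, v_poly),
    resid = scale_component(eps, v_resid)
  )
  y <- rowSums(comp)
  names(y) <- ped$ids

  thr <- NULL
  if (!is.null(pheno_spec$zero_fraction)) {
    zf <- pheno_spec$zero_fraction
    thr <- stats::qnorm(zf, mean = mean(y), sd = stats::sd(y))
    y <- pmax(y - thr, 0)
  }

  truth <- ped$truth
  truth$qtl <- qtl
  truth$varfrac <- list(covar = cf, sparse = v_sparse, poly = v_poly,
                        resid = v_resid)
  truth$covars <- data.frame(id = ped$ids, q = q, garden = garden,
                             year = year, stringsAsFactors = FALSE)
  truth$liability_threshold <- thr

  list(y = y, components = comp, covars = truth$covars, truth = truth)
}
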