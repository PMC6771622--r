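#' Filter sites on minor allele frequency, missingness and depth
#'
#' Keeps biallelic sites with estimated minor allele frequency at least
#' `maf_min`, per-site missingness at most `missing_max`, and mean depth
#' at most the `depth_q` quantile of mean depths across sites (high-depth
#' sites are prone to paralogy). Allele frequency per site is estimated
#' from posterior mean genotypes under a flat prior on the likelihood
#' triples. Site order is preserved.
#'
#' @param gl An `hz_gl`.
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param missing_max Maximum fraction missing (default 0.5).
#' @param depth_q Depth quantile cutoff (default 0.95).
#' @return The filtered `hz_gl`, with attribute `n_dropped`.
#' @export
filter_sites <- function(gl, maf_min = 0.05, missing_max = 0.5,
                         depth_q = 0.95) {
  stopifnot(maf_min >= 0, maf_min <= 1, missing_max >= 0, missing_max <= 1,
            depth_q >= 0, depth_q <= 1)
  miss_frac <- colMeans(gl$missing)
  mean_depth <- colMeans(gl$depth)
  dcut <- stats::quantile(mean_depth, depth_q, names = FALSE, type = 7)

  w <- gl$lik[, , 1] + gl$lik[, , 2] + gl$lik[, , 3]
  pm_geno <- (gl$lik[, , 2] + 2 * gl$lik[, , 3]) / w
  pm_geno[gl$missing] <- NA
  p_alt <- colMeans(pm_geno, na.rm = TRUE) / 2
  p_alt[is.nan(p_alt)] <- 0
  maf <- pmin(p_alt, 1 - p_alt)

  keep <- maf >= maf_min & miss_frac <= missing_max & mean_depth <= dcut
  if (!any(keep)) warning("all sites removed by filters")
  out <- new_hz_gl(gl$ids, gl$sites[keep, , drop = FALSE],
                   gl$lik[, keep, , drop = FALSE],
                   gl$depth[, keep, drop = FALSE],
                   gl$missing[, keep, drop = FALSE])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Hudson's F_ST with finite-sample correction
#'
#' Per site, numerator `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`
#' and denominator `p1(1-p2) + p2(1-p1)`; the genome-wide mean is the
#' ratio of averages (sum of numerators over sum of denominators), the
#' bias-robust convention. Sample sizes are haploid counts; pass `Inf`
#' for known (infinite-sample) frequencies, which drops the correction.
#' Sites with zero denominator (both populations fixed for the same
#' allele) are excluded from the mean.
#'
#' @param p1,p2 Allele frequencies in the two populations.
#' @param n1,n2 Haploid sample sizes (e.g. 102 for 51 diploids), or `Inf`.
#' @return A list of class `hz_fst`: `num`, `den` (per site), `fst_site`,
#'   `fst_mean`, `frac_fixed_diff` (fraction of sites with
#'   `|p1 - p2| > 0.95`), `n_excluded`.
#' @export
hudson_fst <- function(p1, p2, n1, n2) {
  stopifnot(length(p1) == length(p2), all(p1 >= 0 & p1 <= 1, na.rm = TRUE),
            all(p2 >= 0 & p2 <= 1, na.rm = TRUE))
  if (!is.infinite(n1) && n1 < 2 || !is.infinite(n2) && n2 < 2)
    stop("sample sizes must be >= 2 (or Inf)")
  corr1 <- if (is.infinite(n1)) 0 else p1 * (1 - p1) / (n1 - 1)
  corr2 <- if (is.infinite(n2)) 0 else p2 * (1 - p2) / (n2 - 1)
  num <- (p1 - p2)^2 - corr1 - corr2
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- den > 0 & !is.na(den) & !is.na(num)
  structure(list(
    num = num, den = den,
    fst_site = ifelse(ok, num / den, NA_real_),
    fst_mean = sum(num[ok]) / sum(den[ok]),
    frac_fixed_diff = mean(abs(p1 - p2) > 0.95, na.rm = TRUE),
    n_excluded = sum(!ok)
  ), class = "hz_fst")
}

#' Classify individuals as parental or hybrid from genome-wide ancestry
#'
#' `q < 0.05` is called pure tremula (`"T"`), `q > 0.95` pure alba
#' (`"A"`), anything between is a hybrid (`"H"`).
#' @param q Vector of alba-ancestry fractions.
#' @export
species_class <- function(q) {
  ifelse(q < 0.05, "T", ifelse(q > 0.95, "A", "H"))
}

# One EM pass for q given fixed parental frequencies. Returns, for each
# individual, the updated q and the log-likelihood at the *input* q.
# lik: n x L x 3 (normalized), mask: n x L logical, q: length n.
em_q_step <- function(lik, mask, q, p_A, p_T) {
  n <- length(q)
  f <- outer(q, p_A) + outer(1 - q, p_T)        # n x L individual allele freq
  f <- pmin(pmax(f, 1e-9), 1 - 1e-9)
  w0 <- lik[, , 1] * (1 - f)^2
  w1 <- lik[, , 2] * 2 * f * (1 - f)
  w2 <- lik[, , 3] * f^2
  tot <- w0 + w1 + w2
  ll_site <- log(tot)
  ll_site[mask] <- 0
  loglik <- rowSums(ll_site)
  w0 <- w0 / tot; w1 <- w1 / tot; w2 <- w2 / tot
  # posterior that an allele copy is alba, given it is alt / ref
  pA_mat <- matrix(p_A, n, length(p_A), byrow = TRUE)
  pT_mat <- matrix(p_T, n, length(p_T), byrow = TRUE)
  z_alt <- q * pA_mat / f
  z_ref <- q * (1 - pA_mat) / (1 - f)
  exp_alba <- w1 * (z_alt + z_ref) + 2 * w2 * z_alt + 2 * w0 * z_ref
  exp_alba[mask] <- NA
  q_new <- rowMeans(exp_alba, na.rm = TRUE) / 2
  q_new[is.nan(q_new)] <- 0.5
  list(q = pmin(pmax(q_new, 1e-9), 1 - 1e-9), loglik = loglik)
}

#' Estimate genome-wide ancestry by EM from genotype likelihoods
#'
#' Fits the two-ancestry admixture model: at each site, an individual
#' with ancestry fraction q carries alleles that are alternate with
#' probability `q * p_A + (1 - q) * p_T`, and the genotype likelihood
#' triple is integrated over the implied binomial genotype distribution.
#' EM alternates the per-individual q update (expected alba allele
#' copies) with, in unsupervised mode, parental frequency updates from
#' expected ancestry-specific allele counts. With a reference `panel`
#' the parental frequencies are held fixed (supervised mode). The
#' log-likelihood is checked to be non-decreasing at every iteration.
#'
#' If the two parental frequency tracks are (numerically) identical the
#' model is non-identifiable: q is returned as 0.5 with an infinite-width
#' interval and `identifiable = FALSE`.
#'
#' @param gl An `hz_gl` (apply [mask_low_depth()] and [filter_sites()]
#'   first, as appropriate).
#' @param panel Optional list/data.frame with `p_A` and `p_T` per site.
#' @param labels Optional named vector ("A"/"T") of known parentals used
#'   to initialize frequencies in unsupervised mode.
#' @param tol Convergence tolerance on the largest parameter change.
#' @param max_iter Maximum EM iterations.
#' @param n_boot Site-bootstrap replicates for the 95% interval on q
#'   (0 skips the bootstrap).
#' @param seed Seed for the bootstrap.
#' @return A list of class `hz_q`: `q`, `ci95` (2 x n matrix or NULL),
#'   `class` (T/H/A), `p_A`, `p_T`, `loglik`, `identifiable`,
#'   `n_iter`, `supervised`.
#' @export
estimate_q_em <- function(gl, panel = NULL, labels = NULL,
                          tol = 1e-5, max_iter = 200L,
                          n_boot = 0L, seed = 1L) {
  n <- length(gl$ids); L <- nrow(gl$sites)
  lik <- gl$lik; mask <- gl$missing
  supervised <- !is.null(panel)

  if (supervised) {
    p_A <- pmin(pmax(panel$p_A, 1e-6), 1 - 1e-6)
    p_T <- pmin(pmax(panel$p_T, 1e-6), 1 - 1e-6)
    if (max(abs(p_A - p_T)) < 1e-9) {
      warning("parental frequencies identical everywhere: q not identifiable")
      return(structure(list(
        q = rep(0.5, n), ci95 = rbind(lo = rep(0, n), hi = rep(1, n)),
        class = rep("H", n), p_A = p_A, p_T = p_T, loglik = NA_real_,
        identifiable = FALSE, n_iter = 0L, supervised = TRUE
      ), class = "hz_q"))
    }
  } else {
    # initialize frequencies from labeled parentals if given, else from
    # a mild random split of the posterior-mean allele frequencies
    w <- lik[, , 1] + lik[, , 2] + lik[, , 3]
    pm <- (lik[, , 2] + 2 * lik[, , 3]) / w / 2
    pm[mask] <- NA
    if (!is.null(labels)) {
      iA <- which(gl$ids %in% names(labels)[labels == "A"])
      iT <- which(gl$ids %in% names(labels)[labels == "T"])
      p_A <- colMeans(pm[iA, , drop = FALSE], na.rm = TRUE)
      p_T <- colMeans(pm[iT, , drop = FALSE], na.rm = TRUE)
    } else {
      base <- colMeans(pm, na.rm = TRUE)
      set.seed(seed)
      jit <- stats::runif(L, -0.2, 0.2)
      p_A <- pmin(pmax(base + jit, 0.02), 0.98)
      p_T <- pmin(pmax(base - jit, 0.02), 0.98)
    }
    p_A[is.na(p_A)] <- 0.5; p_T[is.na(p_T)] <- 0.5
    p_A <- pmin(pmax(p_A, 1e-6), 1 - 1e-6)
    p_T <- pmin(pmax(p_T, 1e-6), 1 - 1e-6)
  }

  q <- rep(0.5, n)
  ll_prev <- -Inf
  it <- 0L
  repeat {
    it <- it + 1L
    step <- em_q_step(lik, mask, q, p_A, p_T)
    ll <- sum(step$loglik)
    if (ll < ll_prev - 1e-6)
      warning(sprintf("EM log-likelihood decreased at iteration %d", it))
    dq <- max(abs(step$q - q))
    q <- step$q
    dp <- 0
    if (!supervised) {
      upd <- em_freq_update(lik, mask, q, p_A, p_T)
      dp <- max(abs(upd$p_A - p_A), abs(upd$p_T - p_T))
      p_A <- upd$p_A; p_T <- upd$p_T
    }
    ll_prev <- ll
    if ((dq < tol && dp < tol) || it >= max_iter) break
  }

  ci <- NULL
  if (n_boot > 0L) {
    set.seed(seed)
    qb <- matrix(NA_real_, n_boot, n)
    for (b in seq_len(n_boot)) {
      j <- sample.int(L, L, replace = TRUE)
      qq <- q
      for (k in 1:25) {
        st <- em_q_step(lik[, j, , drop = FALSE], mask[, j, drop = FALSE],
                        qq, p_A[j], p_T[j])
        if (max(abs(st$q - qq)) < 1e-4) { qq <- st$q; break }
        qq <- st$q
      }
      qb[b, ] <- qq
    }
    ci <- apply(qb, 2, stats::quantile, probs = c(0.025, 0.975))
    rownames(ci) <- c("lo", "hi")
  }

  structure(list(
    q = stats::setNames(q, gl$ids), ci95 = ci, class = species_class(q),
    p_A = p_A, p_T = p_T, loglik = ll_prev, identifiable = TRUE,
    n_iter = it, supervised = supervised
  ), class = "hz_q")
}

# M-step for parental frequencies in unsupervised mode: expected
# ancestry-specific alt and total allele copies accumulated over
# individuals.
em_freq_update <- function(lik, mask, q, p_A, p_T) {
  n <- length(q); L <- length(p_A)
  f <- outer(q, p_A) + outer(1 - q, p_T)
  f <- pmin(pmax(f, 1e-9), 1 - 1e-9)
  w0 <- lik[, , 1] * (1 - f)^2
  w1 <- lik[, , 2] * 2 * f * (1 - f)
  w2 <- lik[, , 3] * f^2
  tot <- w0 + w1 + w2
  w0 <- w0 / tot; w1 <- w1 / tot; w2 <- w2 / tot
  pA_mat <- matrix(p_A, n, L, byrow = TRUE)
  pT_mat <- matrix(p_T, n, L, byrow = TRUE)
  zA_alt <- q * pA_mat / f            # P(copy alba | alt)
  zA_ref <- q * (1 - pA_mat) / (1 - f)
  # expected alt copies from alba / tremula, expected copies per ancestry
  alt_A <- w1 * zA_alt + 2 * w2 * zA_alt
  alt_T <- w1 * (1 - zA_alt) + 2 * w2 * (1 - zA_alt)
  cnt_A <- alt_A + w1 * zA_ref + 2 * w0 * zA_ref
  cnt_T <- alt_T + w1 * (1 - zA_ref) + 2 * w0 * (1 - zA_ref)
  alt_A[mask] <- 0; alt_T[mask] <- 0; cnt_A[mask] <- 0; cnt_T[mask] <- 0
  pA_new <- colSums(alt_A) / pmax(colSums(cnt_A), 1e-9)
  pT_new <- colSums(alt_T) / pmax(colSums(cnt_T), 1e-9)
  list(p_A = pmin(pmax(pA_new, 1e-6), 1 - 1e-6),
       p_T = pmin(pmax(pT_new, 1e-6), 1 - 1e-6))
}
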