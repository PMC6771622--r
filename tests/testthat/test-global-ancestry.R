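# helper: hz_gl with fully certain genotypes
gl_from_geno <- function(geno, sites, depth = 20L) {
  n <- nrow(geno); L <- ncol(geno)
  lik <- array(1e-12, c(n, L, 3))
  for (g in 0:2) lik[, , g + 1][geno == g] <- 1
  new_hz_gl(paste0("i", seq_len(n)), sites, lik,
            matrix(depth, n, L), matrix(FALSE, n, L))
}

test_that("site filters enforce MAF, missingness and the depth quantile", {
  # 6 sites: site 1 monomorphic, site 2 60% missing, site 3 ultra-deep,
  # sites 4-6 clean
  n <- 10
  geno <- cbind(rep(0, n), rep(1, n), rep(1, n), rep(1, n),
                rep(c(0, 2), 5), rep(c(1, 0), 5))
  sites <- data.frame(chrom = "chr1", pos = 1:6 * 1000)
  gl <- gl_from_geno(geno, sites)
  gl$missing[1:6, 2] <- TRUE
  for (g in 1:3) gl$lik[, , g][gl$missing] <- 1
  gl$depth[, 3] <- 1000L
  out <- filter_sites(gl, maf_min = 0.05, missing_max = 0.5, depth_q = 0.8)
  expect_equal(out$sites$pos, c(4000, 5000, 6000))
  expect_equal(attr(out, "n_dropped"), 3)
  # vacuous thresholds return the input unchanged
  out2 <- filter_sites(gl, maf_min = 0, missing_max = 1, depth_q = 1)
  expect_equal(nrow(out2$sites), 6)
  expect_equal(out2$lik, gl$lik)
  # everything fails -> empty with a warning
  expect_warning(out3 <- filter_sites(gl, maf_min = 0.51, missing_max = 1,
                                      depth_q = 1), "all sites removed")
  expect_equal(nrow(out3$sites), 0)
})

test_that("Hudson's estimator matches hand arithmetic", {
  expect_equal(hudson_fst(0, 1, Inf, Inf)$fst_mean, 1)
  expect_equal(hudson_fst(0.3, 0.3, Inf, Inf)$fst_mean, 0)
  # finite-sample case, 51 diploids = 102 haploid genomes each
  p1 <- 0.2; p2 <- 0.8; nh <- 102
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (nh - 1) - p2 * (1 - p2) / (nh - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  r <- hudson_fst(p1, p2, nh, nh)
  expect_equal(r$fst_site, num / den, tolerance = 1e-15)
  # both fixed for the same allele: excluded from the mean
  r2 <- hudson_fst(c(0, 0.2), c(0, 0.8), Inf, Inf)
  expect_equal(r2$n_excluded, 1)
  expect_equal(r2$fst_mean, hudson_fst(0.2, 0.8, Inf, Inf)$fst_mean)
  # ratio of averages, not average of ratios
  r3 <- hudson_fst(c(0.1, 0.5), c(0.9, 0.5), Inf, Inf)
  expect_equal(r3$fst_mean, sum(r3$num) / sum(r3$den))
  expect_error(hudson_fst(0.5, 0.5, 1, 102), "sample sizes")
})

test_that("fraction of near-fixed allele-frequency differences is reported", {
  r <- hudson_fst(c(0.01, 0.5, 0.02), c(0.99, 0.5, 0.2), Inf, Inf)
  expect_equal(r$frac_fixed_diff, 1 / 3)
})

test_that("EM drives q to the boundary for a pure parental individual", {
  L <- 60
  sites <- data.frame(chrom = "chr1", pos = seq_len(L) * 100)
  geno <- matrix(2L, 1, L)  # hom-alt everywhere
  gl <- gl_from_geno(geno, sites)
  panel <- data.frame(p_A = rep(1 - 1e-9, L), p_T = rep(1e-9, L))
  q <- estimate_q_em(gl, panel = panel)
  expect_gt(q$q[1], 0.999)
  expect_equal(unname(q$class[1]), "A")
})

test_that("EM recovers a hybrid's ancestry fraction from the admixture model", {
  # individual sampled directly from the model at q = 0.3
  set.seed(21)
  L <- 1000
  p_A <- runif(L, 0.05, 0.95); p_T <- runif(L, 0.05, 0.95)
  f <- 0.3 * p_A + 0.7 * p_T
  geno <- matrix(rbinom(L, 2, f), 1, L)
  gl <- gl_from_geno(geno, data.frame(chrom = "chr1", pos = seq_len(L)))
  q <- estimate_q_em(gl, panel = data.frame(p_A = p_A, p_T = p_T))
  expect_lt(abs(q$q[1] - 0.3), 0.05)
  expect_true(q$identifiable)
})

test_that("identical parental frequencies are flagged non-identifiable", {
  L <- 20
  gl <- gl_from_geno(matrix(1L, 2, L),
                     data.frame(chrom = "chr1", pos = seq_len(L)))
  p <- runif(L)
  expect_warning(q <- estimate_q_em(gl, panel = data.frame(p_A = p, p_T = p)),
                 "not identifiable")
  expect_false(q$identifiable)
  expect_equal(unname(q$q), c(0.5, 0.5))
  expect_equal(unname(q$ci95["hi", ] - q$ci95["lo", ]), c(1, 1))
})

test_that("EM log-likelihood never decreases on simulated data", {
  s <- small_sim(seed = 22, n_sites = 150, n_ind = 15)
  gl <- mask_low_depth(s$gl)
  # a decrease raises a warning inside estimate_q_em
  expect_no_warning(estimate_q_em(gl, panel = s$panel))
  expect_no_warning(estimate_q_em(gl, seed = 2))  # unsupervised path
})

test_that("supervised and unsupervised q agree given labeled parents", {
  spec <- sim_spec(n_sites = 300, n_chrom = 2, seed = 5, depth_mean = 10)
  fr <- simulate_parental_frequencies(spec)
  hyb <- simulate_hybrid_pedigree(fr, spec, n_ind = 40, seed = 6)
  pa <- simulate_hybrid_pedigree(fr, spec, n_ind = 50, type = "parental_A",
                                 seed = 7)
  pt <- simulate_hybrid_pedigree(fr, spec, n_ind = 50, type = "parental_T",
                                 seed = 8)
  ids <- c(paste0("h", 1:40), paste0("a", 1:50), paste0("t", 1:50))
  ped <- list(geno = rbind(hyb$geno, pa$geno, pt$geno), ids = ids,
              sites = fr)
  gl <- mask_low_depth(simulate_genotype_likelihoods(ped, spec, seed = 9))
  sup <- estimate_q_em(gl, panel = data.frame(p_A = fr$p_A, p_T = fr$p_T))
  labels <- setNames(c(rep("A", 50), rep("T", 50)),
                     c(paste0("a", 1:50), paste0("t", 1:50)))
  uns <- estimate_q_em(gl, labels = labels)
  expect_lt(max(abs(sup$q - uns$q)), 0.02)
})

test_that("bootstrap intervals on q cover the point estimate", {
  s <- small_sim(seed = 23, n_sites = 120, n_ind = 8)
  q <- estimate_q_em(mask_low_depth(s$gl), panel = s$panel,
                     n_boot = 50, seed = 3)
  expect_true(all(q$ci95["lo", ] <= q$q + 1e-9))
  expect_true(all(q$ci95["hi", ] >= q$q - 1e-9))
})

test_that("species classes follow the 0.05 / 0.95 thresholds", {
  expect_equal(species_class(c(0, 0.049, 0.05, 0.5, 0.95, 0.951, 1)),
               c("T", "T", "H", "H", "H", "A", "A"))
})
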