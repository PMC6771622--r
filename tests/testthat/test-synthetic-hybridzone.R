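test_that("spec validation rejects out-of-range parameters", {
  expect_error(sim_spec(fst_target = 1), "fst_target")
  expect_error(sim_spec(fst_target = -0.1), "fst_target")
  expect_error(sim_spec(chrom_length_bp = 0), "chrom_length_bp")
  expect_error(sim_spec(missing_rate = 1.5), "probabilities")
  expect_error(sim_spec(g_max = 0), "g_max")
  expect_s3_class(sim_spec(fst_target = 0), "hz_spec")
})

test_that("identical spec and seed reproduce all outputs exactly", {
  a <- small_sim(seed = 11)
  b <- small_sim(seed = 11)
  expect_identical(a$freqs$p_A, b$freqs$p_A)
  expect_identical(a$ped$geno, b$ped$geno)
  expect_identical(a$ped$truth$q_true, b$ped$truth$q_true)
  expect_identical(a$gl$lik, b$gl$lik)
  c <- small_sim(seed = 12)
  expect_false(identical(a$gl$lik, c$gl$lik))
})

test_that("zero divergence collapses both species onto the ancestor", {
  spec <- sim_spec(n_sites = 100, n_chrom = 1, fst_target = 0, seed = 2)
  fr <- simulate_parental_frequencies(spec)
  expect_identical(fr$p_A, fr$p_anc)
  expect_identical(fr$p_T, fr$p_anc)
})

test_that("frequency tracks hit the divergence target and report fixed differences", {
  spec <- sim_spec(n_sites = 2500, n_chrom = 2, fst_target = 0.39, seed = 1)
  fr <- simulate_parental_frequencies(spec)
  expect_true(all(fr$p_A >= 0 & fr$p_A <= 1))
  expect_true(all(fr$p_T >= 0 & fr$p_T <= 1))
  # ratio-of-averages F_ST computed directly from the tracks
  num <- (fr$p_A - fr$p_T)^2
  den <- fr$p_A * (1 - fr$p_T) + fr$p_T * (1 - fr$p_A)
  fst_direct <- sum(num) / sum(den)
  expect_lt(abs(fst_direct - 0.39), 0.03)
  expect_equal(attr(fr, "fst_infinite"), fst_direct, tolerance = 1e-12)
  expect_true(is.numeric(attr(fr, "frac_fixed_diff")))
  # diagnostic-site option raises the fixed-difference fraction
  spec2 <- sim_spec(n_sites = 2500, n_chrom = 2, diag_frac = 0.12, seed = 1)
  fr2 <- simulate_parental_frequencies(spec2)
  expect_gt(attr(fr2, "frac_fixed_diff"), 0.1)
})

test_that("F1 and pure parental individuals have forced ancestry", {
  s <- small_sim(seed = 3, n_sites = 50, n_ind = 5)
  f1 <- simulate_hybrid_pedigree(s$freqs, s$spec, n_ind = 5, type = "F1")
  expect_true(all(f1$anc_dosage == 1L))
  expect_equal(unname(f1$truth$q_true), rep(0.5, 5))
  pa <- simulate_hybrid_pedigree(s$freqs, s$spec, n_ind = 3, type = "parental_A")
  expect_true(all(pa$anc_dosage == 2L))
  expect_equal(unname(pa$truth$q_true), rep(1, 3))
  # a pure parental has exactly one tract per chromosome
  tr <- pa$truth$tracts
  expect_equal(nrow(tr), 3 * s$spec$n_chrom)
  expect_error(simulate_hybrid_pedigree(s$freqs, s$spec, g = 0),
               "empty pedigree")
})

test_that("meiosis produces Poisson crossovers at the map length", {
  # 1-Morgan chromosome: 20 Mb at 5 cM/Mb
  set.seed(4)
  L_bp <- 2e7
  h1 <- list(ends = L_bp, anc = 1L)
  h2 <- list(ends = L_bp, anc = 0L)
  ncx <- replicate(500, {
    g <- hybridmap:::sim_meiosis(h1, h2, L_bp, morgan = 1)
    length(g$ends) - 1L  # every crossover switches ancestry (A vs T haps)
  })
  se <- sqrt(1 / 500)   # Poisson(1) mean over 500 draws
  expect_lt(abs(mean(ncx) - 1), 3 * se)
})

test_that("tracts tile chromosomes and q matches alba tract fraction", {
  s <- small_sim(seed = 5, n_ind = 20)
  tr <- s$ped$truth$tracts
  glen <- s$spec$chrom_length_bp
  for (id in unique(tr$id)) {
    for (ch in unique(tr$chrom)) {
      t1 <- tr[tr$id == id & tr$chrom == ch, ]
      expect_equal(t1$start, c(0, utils::head(t1$end, -1)))
      expect_equal(utils::tail(t1$end, 1), glen)
    }
    alba <- sum((tr$end - tr$start)[tr$id == id] * tr$state[tr$id == id])
    q <- alba / (2 * s$spec$n_chrom * glen)
    expect_equal(q, unname(s$ped$truth$q_true[id]), tolerance = 1e-12)
  }
})

test_that("mean tract length decreases with generations since admixture", {
  ml <- vapply(1:5, function(g) {
    spec <- sim_spec(n_sites = 20, n_chrom = 1, chrom_length_bp = 2.5e7,
                     seed = 42)
    fr <- simulate_parental_frequencies(spec)
    ped <- simulate_hybrid_pedigree(fr, spec, n_ind = 150, g = g,
                                    seed = 99 + g)
    tr <- ped$truth$tracts
    mean(tr$end - tr$start)
  }, numeric(1))
  expect_true(all(diff(ml) < 0))
})

test_that("genotype likelihoods follow the binomial read model", {
  # noiseless high-depth limit: all mass on the true genotype
  s <- small_sim(seed = 6, n_sites = 40, n_ind = 8, depth_mean = 200,
                 seq_error = 0, missing_rate = 0)
  called <- apply(s$gl$lik, c(1, 2), which.max) - 1L
  nonmiss <- !s$gl$missing
  expect_true(all(called[nonmiss] == s$ped$geno[nonmiss]))
  off <- apply(s$gl$lik, c(1, 2), function(v) sort(v, decreasing = TRUE)[2])
  expect_true(all(off[nonmiss] < 1e-6))
  # zero depth: missing flag and a flat triple
  expect_true(any(s0 <- small_sim(seed = 7, depth_mean = 0.5)$gl$missing))
  gl0 <- small_sim(seed = 7, depth_mean = 0.5)$gl
  flat <- gl0$lik[, , 1][gl0$missing]
  expect_true(all(flat == 1))
  # hand oracle: het site, depth 10, 6 alt reads, bias 0.6, error 0.01
  lik <- genotype_likelihoods(matrix(6), matrix(10L), seq_error = 0.01,
                              allelic_bias = 0.6)
  p1 <- 0.6 * 0.99 + 0.4 * 0.01
  hand <- c(dbinom(6, 10, 0.01), dbinom(6, 10, p1), dbinom(6, 10, 0.99))
  expect_equal(as.numeric(lik[1, 1, ]), hand / max(hand), tolerance = 1e-12)
})

test_that("low-depth masking flags calls under the read threshold", {
  s <- small_sim(seed = 8, depth_mean = 6)
  gl <- mask_low_depth(s$gl, min_depth = 5)
  expect_true(all(gl$missing[s$gl$depth < 5]))
  expect_true(all(gl$lik[, , 2][gl$depth < 5] == 1))
  expect_false(any(gl$missing[s$gl$depth >= 5] & !s$gl$missing[s$gl$depth >= 5]))
})

test_that("phenotype generator hits its variance-fraction targets", {
  s <- small_sim(seed = 9, n_sites = 250, n_ind = 500)
  ph <- simulate_phenotype(s$ped, phenotype_spec("first", h2 = 0.3,
                                                 pve = 0.6, n_qtl = 3))
  v <- apply(ph$components, 2, stats::var)
  fr <- v / sum(v)
  # targets on the total scale: covar 0.2, sparse 0.24, poly 0.24, resid 0.32
  expect_lt(abs(fr["sparse"] - 0.8 * 0.3), 0.05)
  expect_lt(abs(fr["poly"] - 0.8 * 0.3), 0.05)
  expect_lt(abs(fr["covar"] - 0.2), 0.05)
  expect_equal(nrow(ph$truth$qtl), 3)
  # third class: zero genetic variance by construction
  ph3 <- simulate_phenotype(s$ped, phenotype_spec("third"))
  expect_true(all(ph3$components$sparse == 0))
  expect_true(all(ph3$components$poly == 0))
  expect_null(ph3$truth$qtl)
  # invalid targets
  expect_error(phenotype_spec("first", h2 = 0.7, pve = 0.5), "h2")
  expect_error(phenotype_spec("first", pve = 1.2), "fractions")
})

test_that("zero-inflated traits hit the target zero fraction", {
  s <- small_sim(seed = 10, n_sites = 100, n_ind = 500)
  ph <- simulate_phenotype(s$ped, phenotype_spec("first", zero_fraction = 0.3))
  zf <- mean(ph$y == 0)
  se <- sqrt(0.3 * 0.7 / 500)
  expect_lt(abs(zf - 0.3), 3 * se)
  expect_true(all(ph$y >= 0))
  expect_false(is.null(ph$truth$liability_threshold))
})
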