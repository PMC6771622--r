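test_that("transition kernel has the right limits and hand-checked values", {
  pr <- hmm_params(g = 5, recomb_rate_cM_per_Mb = 5, q = 0.5)
  expect_equal(transition_kernel(0, pr), diag(3), ignore_attr = TRUE)
  # large distance: every row approaches the diploid stationary distribution
  far <- transition_kernel(1e12, pr)
  statn <- c((1 - 0.5)^2, 2 * 0.5 * 0.5, 0.5^2)
  for (i in 1:3) expect_equal(unname(far[i, ]), statn, tolerance = 1e-9)
  # hand arithmetic at d = 1 Mb: s = 1 - exp(-g * rho * d) = 1 - exp(-0.25)
  s <- 1 - exp(-5 * 0.05 * 1)
  stay <- (1 - s) + s * 0.5
  m <- transition_kernel(1e6, pr)
  expect_equal(unname(m["AA", "AA"]), stay^2, tolerance = 1e-12)
  expect_equal(unname(m["TT", "TT"]), stay^2, tolerance = 1e-12)
  # rows are stochastic for asymmetric q too
  m2 <- transition_kernel(2.3e5, hmm_params(q = 0.2))
  expect_equal(unname(rowSums(m2)), rep(1, 3), tolerance = 1e-12)
})

test_that("emission likelihood handles flat, fixed and hand-computed cases", {
  # uninformative likelihoods: equal across states
  em <- emission_likelihood(c(1, 1, 1), p_A = 0.9, p_T = 0.2,
                            miscopy_eps = 0.06)
  expect_equal(unname(em[1, 1]), unname(em[1, 2]))
  expect_equal(unname(em[1, 2]), unname(em[1, 3]))
  # fixed difference, certain hom-alt, no miscopying
  em2 <- emission_likelihood(c(0, 0, 1), p_A = 1, p_T = 0, miscopy_eps = 0)
  expect_equal(unname(em2[1, ]), c(0, 0, 1))
  # hand evaluation with miscopying
  pa <- 0.94 * 0.9 + 0.06 * 0.5
  pt <- 0.94 * 0.1 + 0.06 * 0.5
  hand_het <- pa * (1 - pt) + pt * (1 - pa)
  em3 <- emission_likelihood(c(0, 1, 0), p_A = 0.9, p_T = 0.1,
                             p_mean = 0.5, miscopy_eps = 0.06)
  expect_equal(unname(em3[1, "het"]), hand_het, tolerance = 1e-12)
  expect_equal(unname(em3[1, "AA"]), 2 * pa * (1 - pa), tolerance = 1e-12)
  expect_equal(unname(em3[1, "TT"]), 2 * pt * (1 - pt), tolerance = 1e-12)
})

test_that("forward-backward equals exhaustive path enumeration", {
  set.seed(31)
  for (L in c(1, 4, 5)) {
    pos <- sort(sample.int(5e6, L))
    p_A <- runif(L, 0.1, 0.95); p_T <- runif(L, 0.05, 0.9)
    lik <- matrix(runif(3 * L), L, 3)
    mask <- runif(L) < 0.2
    mask[1] <- FALSE  # keep at least one informative site
    pr <- hmm_params(g = 4, recomb_rate_cM_per_Mb = 5, miscopy_eps = 0.06,
                     q = 0.35)
    fb <- forward_backward(lik, pos, p_A, p_T, pr, mask = mask)
    oracle <- enumerate_posterior(lik, pos, p_A, p_T, pr, mask = mask)
    expect_lt(max(abs(fb$post - oracle$post)), 1e-10)
    expect_equal(fb$loglik, oracle$loglik, tolerance = 1e-10)
  }
})

test_that("single-site posteriors are stationary times emission", {
  pr <- hmm_params(q = 0.3)
  lik <- matrix(c(0.1, 1, 0.4), 1, 3)
  fb <- forward_backward(lik, pos = 1000, p_A = 0.9, p_T = 0.1, pr)
  em <- emission_likelihood(lik, 0.9, 0.1, miscopy_eps = pr$miscopy_eps)
  expect_equal(unname(fb$post[1, ]),
               unname(em[1, ] * c(0.49, 0.42, 0.09)) /
                 sum(em[1, ] * c(0.49, 0.42, 0.09)), tolerance = 1e-12)
})

test_that("fully masked chromosomes fall back to the stationary posterior", {
  pr <- hmm_params(q = 0.3)
  lik <- matrix(runif(9), 3, 3)
  expect_warning(
    fb <- forward_backward(lik, pos = c(1, 2, 3) * 1e5, p_A = rep(0.9, 3),
                           p_T = rep(0.1, 3), pr, mask = rep(TRUE, 3)),
    "stationary")
  statn <- c(0.49, 0.42, 0.09)
  for (t in 1:3) expect_equal(unname(fb$post[t, ]), statn, tolerance = 1e-9)
  expect_equal(unname(fb$dosage), rep(2 * 0.3, 3), tolerance = 1e-9)
})

test_that("posterior rows sum to one and both passes agree on the likelihood", {
  s <- small_sim(seed = 32, n_sites = 150, n_ind = 6)
  gl <- mask_low_depth(s$gl)
  for (i in 1:3) {
    sel <- which(gl$sites$chrom == "chr1")
    fb <- forward_backward(matrix(gl$lik[i, sel, ], length(sel), 3),
                           gl$sites$pos[sel], s$panel$p_A[sel],
                           s$panel$p_T[sel],
                           hmm_params(q = s$ped$truth$q_true[i]),
                           mask = gl$missing[i, sel])
    expect_equal(unname(rowSums(fb$post)), rep(1, length(sel)),
                 tolerance = 1e-9)
    expect_equal(fb$loglik, fb$loglik_backward, tolerance = 1e-8)
  }
})

test_that("expected dosage is the posterior mean alba-allele count", {
  post <- rbind(c(0, 0, 1), c(0.25, 0.5, 0.25), c(1, 0, 0))
  expect_equal(expected_dosage(post), c(2, 1, 0))
})

test_that("dosages track the true diploid ancestry on simulated hybrids", {
  s <- small_sim(seed = 33, n_sites = 300, n_ind = 20, depth_mean = 8)
  gl <- mask_low_depth(s$gl)
  lai <- local_ancestry(gl, s$panel, s$ped$truth$q_true)
  expect_true(all(lai$dosage >= 0 & lai$dosage <= 2))
  expect_lt(mean(abs(lai$dosage - s$ped$anc_dosage)), 0.3)
})

test_that("raising the miscopying rate never adds ancestry switches", {
  s <- small_sim(seed = 34, n_sites = 300, n_chrom = 1, chrom_length_bp = 2e7,
                 n_ind = 10)
  gl <- mask_low_depth(s$gl)
  sw <- vapply(c(0, 0.06, 0.2, 0.4), function(eps) {
    count_switches(local_ancestry(gl, s$panel, s$ped$truth$q_true,
                                  miscopy_eps = eps))
  }, numeric(1))
  expect_true(all(diff(sw) <= 0))
})

test_that("the likelihood scan ranks parameter combinations", {
  s <- small_sim(seed = 35, n_sites = 120, n_ind = 5)
  gl <- mask_low_depth(s$gl)
  sc <- lai_scan(gl, s$panel, s$ped$truth$q_true, g_grid = c(2, 5),
                 eps_grid = c(0.06))
  expect_equal(nrow(sc), 2)
  expect_true(!is.unsorted(rev(sc$loglik)))
})
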