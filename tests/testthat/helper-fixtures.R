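# Shared fixture builders and independent oracles.

# small synthetic hybrid-zone data set built fresh from a seed
small_sim <- function(seed = 1, n_sites = 200, n_chrom = 2,
                      chrom_length_bp = 1e7, n_ind = 30, g = 5,
                      depth_mean = 8, diag_frac = 0, ...) {
  spec <- sim_spec(n_sites = n_sites, n_chrom = n_chrom,
                   chrom_length_bp = chrom_length_bp,
                   depth_mean = depth_mean, diag_frac = diag_frac,
                   seed = seed, ...)
  freqs <- simulate_parental_frequencies(spec)
  ped <- simulate_hybrid_pedigree(freqs, spec, n_ind = n_ind, g = g)
  gl <- simulate_genotype_likelihoods(ped, spec)
  list(spec = spec, freqs = freqs, ped = ped, gl = gl,
       panel = data.frame(p_A = freqs$p_A, p_T = freqs$p_T))
}

# Brute-force HMM posterior by exhaustive enumeration over all 3^L state
# paths; completely independent of the forward-backward implementation.
enumerate_posterior <- function(lik, pos, p_A, p_T, params, mask = NULL) {
  L <- length(pos)
  if (is.null(mask)) mask <- rep(FALSE, L)
  em <- emission_likelihood(lik, p_A, p_T, miscopy_eps = params$miscopy_eps)
  em[mask, ] <- 1
  pi0 <- diploid_stationary_oracle(params$q)
  trans <- lapply(2:max(L, 2), function(t)
    if (t <= L) transition_oracle(pos[t] - pos[t - 1], params) else NULL)
  paths <- as.matrix(expand.grid(rep(list(1:3), L)))
  w <- apply(paths, 1, function(st) {
    p <- pi0[st[1]] * em[1, st[1]]
    if (L > 1) for (t in 2:L) p <- p * trans[[t - 1]][st[t - 1], st[t]] * em[t, st[t]]
    p
  })
  post <- matrix(0, L, 3)
  for (t in 1:L) for (k in 1:3) post[t, k] <- sum(w[paths[, t] == k])
  list(post = post / rowSums(post), loglik = log(sum(w)))
}

# independent re-derivations of the chain ingredients used by the oracle
diploid_stationary_oracle <- function(q) {
  c(TT = (1 - q)^2, het = 2 * q * (1 - q), AA = q^2)
}

transition_oracle <- function(d_bp, params) {
  dM <- params$recomb_rate_cM_per_Mb * d_bp / 1e6 / 100
  s <- 1 - exp(-params$g * dM)
  # haploid chain as explicit 2x2, then collapse the ordered pair
  hap <- matrix(c(1 - s * params$q, s * params$q,
                  s * (1 - params$q), 1 - s * (1 - params$q)),
                2, 2, byrow = TRUE)  # rows/cols: (T, A)
  states <- list(c(1, 1), c(1, 2), c(2, 2))  # TT, het(unordered), AA
  m <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    a <- states[[i]]; b <- states[[j]]
    pr <- hap[a[1], b[1]] * hap[a[2], b[2]]
    if (b[1] != b[2]) pr <- pr + hap[a[1], b[2]] * hap[a[2], b[1]]
    m[i, j] <- pr
  }
  m
}

# batch-means Monte Carlo standard error
mcse <- function(v, n_batch = 40) {
  m <- matrix(v[seq_len(n_batch * (length(v) %/% n_batch))], ncol = n_batch)
  stats::sd(colMeans(m)) / sqrt(n_batch)
}
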