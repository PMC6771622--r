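#' HMM parameters for diploid local-ancestry inference
#'
#' @param g Generations since admixture (>= 1); scales the switch rate.
#' @param recomb_rate_cM_per_Mb Recombination rate prior.
#' @param miscopy_eps Miscopying rate: emission smoothing that lets a
#'   haplotype of one ancestry emit alleles typical of the pooled panel.
#' @param q Individual-specific prior alba-ancestry fraction.
#' @export
hmm_params <- function(g = 5, recomb_rate_cM_per_Mb = 5,
                       miscopy_eps = 0.06, q = 0.5) {
  stopifnot(g >= 1, miscopy_eps >= 0, miscopy_eps < 1, q >= 0, q <= 1,
            recomb_rate_cM_per_Mb >= 0)
  structure(list(g = g, recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
                 miscopy_eps = miscopy_eps, q = q), class = "hz_hmm_params")
}

#' Diploid ancestry stationary distribution (TT, het, AA)
#' @keywords internal
diploid_stationary <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

#' Transition kernel between diploid ancestry states
#'
#' Each haploid ancestry chain switches to its stationary distribution
#' (q for alba, 1-q for tremula) with probability
#' `s = 1 - exp(-g * d_M)`, where `d_M` is the inter-site distance in
#' Morgans under the `recomb_rate_cM_per_Mb` map. The diploid kernel over
#' (TT, het, AA) is the product of the two independent haploid chains
#' collapsed onto the unphased state space.
#'
#' @param d_bp Distance in base pairs (>= 0).
#' @param params An [hmm_params()].
#' @return 3x3 row-stochastic matrix, rows/cols ordered (TT, het, AA).
#' @export
transition_kernel <- function(d_bp, params) {
  stopifnot(d_bp >= 0)
  q <- params$q
  d_M <- params$recomb_rate_cM_per_Mb * (d_bp / 1e6) / 100
  s <- 1 - exp(-params$g * d_M)
  a <- 1 - s * q        # T -> T
  b <- s * q            # T -> A
  ct <- s * (1 - q)     # A -> T
  d <- 1 - s * (1 - q)  # A -> A
  m <- matrix(c(
    a * a,      2 * a * b,         b * b,
    a * ct,     a * d + b * ct,    b * d,
    ct * ct,    2 * ct * d,        d * d
  ), 3, 3, byrow = TRUE)
  dimnames(m) <- list(c("TT", "het", "AA"), c("TT", "het", "AA"))
  m
}

#' Emission likelihood of a genotype-likelihood triple given ancestry state
#'
#' A haplotype of alba ancestry carries the alternate allele with
#' probability `(1 - eps) * p_A + eps * p_mean` (symmetric for tremula):
#' the miscopying rate `eps` shrinks each ancestry's frequency toward the
#' pooled panel frequency `p_mean`. The genotype distribution given the
#' diploid state is the product over the two haplotypes' ancestries, and
#' the emission is the likelihood triple integrated over it.
#'
#' Vectorized over sites: `lik` may be an L x 3 matrix with `p_A`, `p_T`,
#' `p_mean` length-L vectors, giving an L x 3 emission matrix
#' (columns TT, het, AA).
#'
#' @param lik Genotype likelihoods for (0, 1, 2) alternate copies.
#' @param p_A,p_T Parental panel frequencies.
#' @param p_mean Pooled panel frequency (default the average).
#' @param miscopy_eps Miscopying rate.
#' @export
emission_likelihood <- function(lik, p_A, p_T, p_mean = (p_A + p_T) / 2,
                                miscopy_eps = 0.06) {
  if (is.null(dim(lik))) lik <- matrix(lik, 1, 3)
  pa <- (1 - miscopy_eps) * p_A + miscopy_eps * p_mean
  pt <- (1 - miscopy_eps) * p_T + miscopy_eps * p_mean
  g_tt <- cbind((1 - pt)^2, 2 * pt * (1 - pt), pt^2)
  g_het <- cbind((1 - pa) * (1 - pt), pa * (1 - pt) + pt * (1 - pa), pa * pt)
  g_aa <- cbind((1 - pa)^2, 2 * pa * (1 - pa), pa^2)
  em <- cbind(TT = rowSums(lik * g_tt),
              het = rowSums(lik * g_het),
              AA = rowSums(lik * g_aa))
  em
}

#' Forward-backward local-ancestry posteriors for one individual/chromosome
#'
#' Standard scaled forward-backward over the three diploid ancestry
#' states. The chain is initialized at the stationary distribution
#' implied by the individual's genome-wide ancestry prior `params$q`.
#' Masked sites are treated as uninformative emissions. If no usable
#' site remains the posterior is the stationary distribution everywhere
#' (with a warning).
#'
#' @param lik L x 3 genotype-likelihood matrix, sites sorted by position.
#' @param pos 1-based site positions (sorted, same chromosome).
#' @param p_A,p_T Panel frequencies per site.
#' @param params An [hmm_params()].
#' @param mask Optional logical vector of masked sites.
#' @return A list of class `hz_lai`: `post` (L x 3, columns TT/het/AA,
#'   rows summing to 1), `dosage` (expected alba-allele count in [0, 2]),
#'   `state` (max-posterior state index 1..3), `confidence` (its
#'   posterior probability), `loglik`, and `loglik_backward` (independent
#'   recomputation from the backward recursion).
#' @export
forward_backward <- function(lik, pos, p_A, p_T, params, mask = NULL) {
  L <- length(pos)
  stopifnot(nrow(lik) == L, !is.unsorted(pos))
  if (is.null(mask)) mask <- rep(FALSE, L)
  em <- emission_likelihood(lik, p_A, p_T, miscopy_eps = params$miscopy_eps)
  em[mask, ] <- 1
  # guard against all-zero emission rows (numerically impossible sites)
  zero <- rowSums(em) == 0
  em[zero, ] <- 1
  if (all(mask | zero)) warning("no usable sites: posterior is stationary")

  pi0 <- diploid_stationary(params$q)
  P <- vector("list", L)
  if (L > 1) {
    for (t in 2:L) P[[t]] <- transition_kernel(pos[t] - pos[t - 1], params)
  }

  alpha <- matrix(0, L, 3); cvec <- numeric(L)
  a <- pi0 * em[1, ]
  cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
  if (L > 1) for (t in 2:L) {
    a <- as.numeric(alpha[t - 1, ] %*% P[[t]]) * em[t, ]
    cvec[t] <- sum(a)
    alpha[t, ] <- a / cvec[t]
  }

  beta <- matrix(0, L, 3)
  beta[L, ] <- 1
  if (L > 1) for (t in (L - 1):1) {
    b <- as.numeric(P[[t + 1]] %*% (em[t + 1, ] * beta[t + 1, ]))
    beta[t, ] <- b / cvec[t + 1]
  }

  post <- alpha * beta
  post <- post / rowSums(post)
  colnames(post) <- c("TT", "het", "AA")

  # independent backward-pass log-likelihood with its own scaling
  bb <- rep(1, 3); ll_b <- 0
  if (L > 1) for (t in (L - 1):1) {
    bb <- as.numeric(P[[t + 1]] %*% (em[t + 1, ] * bb))
    s <- sum(bb); bb <- bb / s; ll_b <- ll_b + log(s)
  }
  ll_b <- ll_b + log(sum(pi0 * em[1, ] * bb))

  st <- max.col(post)
  structure(list(post = post,
                 dosage = post[, 2] + 2 * post[, 3],
                 state = st,
                 confidence = post[cbind(seq_len(L), st)],
                 loglik = sum(log(cvec)),
                 loglik_backward = ll_b),
            class = "hz_lai")
}

#' Expected alba-ancestry dosage from a local-ancestry posterior
#'
#' `dosage = 0 * P(TT) + 1 * P(het) + 2 * P(AA)`, the mapping genotype.
#' @param post An `hz_lai` or an L x 3 posterior matrix.
#' @export
expected_dosage <- function(post) {
  if (inherits(post, "hz_lai")) post <- post$post
  as.numeric(post[, 2] + 2 * post[, 3])
}

#' Local-ancestry inference for all individuals
#'
#' Runs [forward_backward()] per individual and chromosome and collects
#' the expected ancestry dosages into the sites x individuals mapping
#' matrix. Individuals with no usable data on a chromosome fall back to
#' the stationary posterior, i.e. dosage `2 * q_i` (flagged via the
#' per-run warning).
#'
#' @param gl An `hz_gl` (low-depth calls should be masked already).
#' @param panel List/data.frame with per-site `p_A`, `p_T`.
#' @param q Per-individual ancestry priors (named or in `gl$ids` order).
#' @param g,recomb_rate_cM_per_Mb,miscopy_eps HMM settings.
#' @return A list of class `hz_lai_set`: `dosage` (individuals x sites),
#'   `post` (n x L x 3 array), `state` (n x L), `loglik` (per
#'   individual), `params`.
#' @export
local_ancestry <- function(gl, panel, q, g = 5, recomb_rate_cM_per_Mb = 5,
                           miscopy_eps = 0.06) {
  n <- length(gl$ids); L <- nrow(gl$sites)
  if (!is.null(names(q))) q <- q[gl$ids]
  dosage <- matrix(NA_real_, n, L, dimnames = list(gl$ids, NULL))
  state <- matrix(NA_integer_, n, L)
  post <- array(NA_real_, c(n, L, 3))
  ll <- numeric(n)
  for (i in seq_len(n)) {
    for (ch in unique(gl$sites$chrom)) {
      sel <- which(gl$sites$chrom == ch)
      pr <- hmm_params(g, recomb_rate_cM_per_Mb, miscopy_eps, q[i])
      fb <- forward_backward(
        lik = matrix(gl$lik[i, sel, ], length(sel), 3),
        pos = gl$sites$pos[sel],
        p_A = panel$p_A[sel], p_T = panel$p_T[sel],
        params = pr, mask = gl$missing[i, sel]
      )
      dosage[i, sel] <- fb$dosage
      state[i, sel] <- fb$state
      post[i, sel, ] <- fb$post
      ll[i] <- ll[i] + fb$loglik
    }
  }
  structure(list(dosage = dosage, post = post, state = state,
                 loglik = stats::setNames(ll, gl$ids),
                 params = list(g = g,
                               recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
                               miscopy_eps = miscopy_eps)),
            class = "hz_lai_set")
}

#' Count inferred ancestry switches along chromosomes
#'
#' Number of adjacent-site changes of the max-posterior state, summed
#' over individuals and chromosomes.
#' @param lai An `hz_lai_set`.
#' @param sites Site table with `chrom` (defaults to a single chromosome).
#' @export
count_switches <- function(lai, sites = NULL) {
  st <- lai$state
  if (is.null(sites)) return(sum(st[, -1, drop = FALSE] !=
                                 st[, -ncol(st), drop = FALSE]))
  tot <- 0L
  for (ch in unique(sites$chrom)) {
    sel <- which(sites$chrom == ch)
    s <- st[, sel, drop = FALSE]
    tot <- tot + sum(s[, -1, drop = FALSE] != s[, -ncol(s), drop = FALSE])
  }
  tot
}

#' Grid scan of HMM settings by total log-likelihood
#'
#' Convenience mirror of model selection by likelihood: evaluates
#' [local_ancestry()] on a grid of (g, miscopy_eps) and reports the total
#' log-likelihood per combination.
#' @inheritParams local_ancestry
#' @param g_grid,eps_grid Parameter grids.
#' @export
lai_scan <- function(gl, panel, q, g_grid = c(2, 5), eps_grid = c(0.02, 0.06),
                     recomb_rate_cM_per_Mb = 5) {
  res <- expand.grid(g = g_grid, miscopy_eps = eps_grid)
  res$loglik <- vapply(seq_len(nrow(res)), function(r) {
    sum(local_ancestry(gl, panel, q, g = res$g[r],
                       recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
                       miscopy_eps = res$miscopy_eps[r])$loglik)
  }, numeric(1))
  res[order(-res$loglik), ]
}
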