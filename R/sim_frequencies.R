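#' Simulate diverged parental allele-frequency tracks
#'
#' Draws ancestral allele frequencies and then species frequencies under
#' the Balding-Nichols construction: given ancestral frequency p and
#' divergence F, each species' frequency is an independent
#' Beta(p(1-F)/F, (1-p)(1-F)/F) draw, so that the expected Hudson F_ST
#' across sites equals F. With `fst_target = 0` the two species are
#' identical to the ancestor. If `diag_frac > 0`, that fraction of sites
#' is overwritten with near-diagnostic frequencies (0.99 vs 0.01, random
#' orientation), emulating marker panels ascertained for species-
#' diagnostic content.
#'
#' Site positions are drawn uniformly along each chromosome and sorted.
#'
#' @param spec An [sim_spec()] object.
#' @return A data.frame of class `hz_freqs` with columns `chrom`, `pos`
#'   (1-based), `p_anc`, `p_A`, `p_T`, plus attributes
#'   `frac_fixed_diff` (fraction of sites with `|p_A - p_T| > 0.95`) and
#'   `fst_infinite` (infinite-sample Hudson F_ST, ratio of averages,
#'   computed from the generated tracks).
#' @export
simulate_parental_frequencies <- function(spec) {
  validate_sim_spec(spec)
  set.seed(spec$seed)
  L <- spec$n_sites * spec$n_chrom
  p_anc <- switch(spec$anc_freq_dist,
    uniform = stats::runif(L, 0.05, 0.95),
    beta    = pmin(pmax(stats::rbeta(L, 0.5, 0.5), 0.01), 0.99)
  )
  F <- spec$fst_target
  if (F == 0) {
    p_A <- p_anc
    p_T <- p_anc
  } else {
    shape_mult <- (1 - F) / F
    p_A <- stats::rbeta(L, p_anc * shape_mult, (1 - p_anc) * shape_mult)
    p_T <- stats::rbeta(L, p_anc * shape_mult, (1 - p_anc) * shape_mult)
  }
  if (spec$diag_frac > 0) {
    n_diag <- round(spec$diag_frac * L)
    if (n_diag > 0) {
      idx <- sample.int(L, n_diag)
      flip <- stats::runif(n_diag) < 0.5
      p_A[idx] <- ifelse(flip, 0.01, 0.99)
      p_T[idx] <- ifelse(flip, 0.99, 0.01)
    }
  }
  pos <- unlist(lapply(seq_len(spec$n_chrom), function(ch) {
    sort(sample.int(spec$chrom_length_bp, spec$n_sites))
  }))
  out <- data.frame(
    chrom = rep(paste0("chr", seq_len(spec$n_chrom)), each = spec$n_sites),
    pos = pos, p_anc = p_anc, p_A = p_A, p_T = p_T,
    stringsAsFactors = FALSE
  )
  fst <- hudson_fst(out$p_A, out$p_T, n1 = Inf, n2 = Inf)
  attr(out, "frac_fixed_diff") <- mean(abs(p_A - p_T) > 0.95)
  attr(out, "fst_infinite") <- fst$fst_mean
  class(out) <- c("hz_freqs", "data.frame")
  out
}
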