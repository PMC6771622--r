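#' Per-read alternate-allele probability for each genotype
#'
#' Read model: a read from a hom-ref genotype is alternate only through
#' sequencing error; a read from a hom-alt genotype is alternate unless
#' miscalled; a read from a heterozygote samples the alternate haplotype
#' with probability `allelic_bias` (0.5 = unbiased) and is then subject
#' to the same error.
#' @keywords internal
read_alt_prob <- function(seq_error, allelic_bias) {
  c(seq_error,
    allelic_bias * (1 - seq_error) + (1 - allelic_bias) * seq_error,
    1 - seq_error)
}

#' Simulate RAD-seq-like genotype likelihoods from true genotypes
#'
#' Depth is Poisson(`depth_mean`) per individual and site, with an extra
#' `missing_rate` chance of dropout (depth forced to 0). Alternate read
#' counts are binomial under [read_alt_prob()]; likelihoods of the three
#' genotypes follow the standard binomial read model and are normalized
#' so the largest of the triple is 1. Zero-depth entries are flagged
#' missing and carry the uninformative triple (1, 1, 1).
#'
#' @param ped An `hz_pedigree` from [simulate_hybrid_pedigree()] (or any
#'   list with `geno`, `ids`, `sites`).
#' @param spec The [sim_spec()].
#' @param seed Seed; defaults to `spec$seed + 2`.
#' @return An `hz_gl` object: `ids`, `sites`, `lik` (n x L x 3 array,
#'   normalized), `depth` (n x L), `missing` (n x L logical).
#' @export
simulate_genotype_likelihoods <- function(ped, spec, seed = spec$seed + 2L) {
  set.seed(seed)
  geno <- ped$geno
  n <- nrow(geno); L <- ncol(geno)
  depth <- matrix(stats::rpois(n * L, spec$depth_mean), n, L)
  if (spec$missing_rate > 0)
    depth[stats::runif(n * L) < spec$missing_rate] <- 0L
  p_read <- read_alt_prob(spec$seq_error, spec$allelic_bias)
  alt_reads <- matrix(stats::rbinom(n * L, depth, p_read[geno + 1L]), n, L)
  lik <- genotype_likelihoods(alt_reads, depth, spec$seq_error,
                              spec$allelic_bias)
  new_hz_gl(ids = ped$ids, sites = ped$sites, lik = lik, depth = depth)
}

#' Binomial-read genotype likelihoods
#'
#' @param alt_reads,depth Matrices (individuals x sites) of alternate-read
#'   counts and total depths.
#' @return n x L x 3 array of likelihoods normalized to max 1; zero-depth
#'   entries get (1, 1, 1).
#' @export
genotype_likelihoods <- function(alt_reads, depth, seq_error, allelic_bias) {
  p_read <- read_alt_prob(seq_error, allelic_bias)
  n <- nrow(depth); L <- ncol(depth)
  lik <- array(1, dim = c(n, L, 3))
  for (g in 0:2)
    lik[, , g + 1L] <- stats::dbinom(alt_reads, depth, p_read[g + 1L])
  mx <- pmax(lik[, , 1], lik[, , 2], lik[, , 3])
  mx[mx == 0] <- 1
  for (g in 1:3) lik[, , g] <- lik[, , g] / mx
  lik[is.na(lik)] <- 1
  lik
}

#' Construct a genotype-likelihood container
#'
#' @param ids Individual identifiers (rows of `lik`).
#' @param sites Site table with at least `chrom` and `pos` (1-based).
#' @param lik n x L x 3 likelihood array, normalized to max 1.
#' @param depth n x L read-depth matrix.
#' @param missing Optional n x L logical; defaults to `depth == 0`.
#' @export
new_hz_gl <- function(ids, sites, lik, depth, missing = NULL) {
  if (is.null(missing)) missing <- depth == 0L
  stopifnot(length(ids) == dim(lik)[1], nrow(sites) == dim(lik)[2])
  structure(list(ids = ids, sites = as.data.frame(sites), lik = lik,
                 depth = depth, missing = missing),
            class = "hz_gl")
}

#' Mask genotype calls below a read-depth threshold
#'
#' Calls supported by fewer than `min_depth` reads (default 5, the usual
#' RAD-seq masking rule) are flagged missing and their likelihood triple
#' replaced by the uninformative (1, 1, 1).
#' @param gl An `hz_gl`.
#' @param min_depth Minimum reads for a call to be kept.
#' @export
mask_low_depth <- function(gl, min_depth = 5L) {
  low <- gl$depth < min_depth
  gl$missing <- gl$missing | low
  for (g in 1:3) {
    sl <- gl$lik[, , g]
    sl[low] <- 1
    gl$lik[, , g] <- sl
  }
  gl
}

#' @export
print.hz_gl <- function(x, ...) {
  cat("<hz_gl>", length(x$ids), "individuals x", nrow(x$sites), "sites;",
      sprintf("%.1f%% missing\n", 100 * mean(x$missing)))
  invisible(x)
}
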