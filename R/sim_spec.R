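#' Specification of a synthetic hybrid-zone simulation
#'
#' Bundles every tunable of the synthetic hybrid-zone generator. Defaults
#' reflect the study system the generator emulates: two poplar species
#' diverged to F_ST ~ 0.39, reference panels of 51 diploids each, hybrid
#' swarms of up to five generations, a 5 cM/Mb recombination rate, and
#' RAD-seq-like sequencing (moderate depth, low error, possible allelic
#' bias at heterozygotes, dropout).
#'
#' @param n_sites Number of variant sites per chromosome.
#' @param n_chrom Number of chromosomes.
#' @param chrom_length_bp Chromosome length in base pairs.
#' @param fst_target Target differentiation between the parental species,
#'   in `[0, 1)`. Under the Balding-Nichols construction the expected
#'   Hudson F_ST (infinite-sample, ratio of averages) equals this value.
#' @param anc_freq_dist Distribution of ancestral allele frequencies:
#'   `"uniform"` on `[0.05, 0.95]` or `"beta"` (U-shaped, Beta(0.5, 0.5)
#'   truncated to `[0.01, 0.99]`).
#' @param diag_frac Fraction of sites replaced by near-diagnostic markers
#'   (frequencies 0.99/0.01 in the two species, random orientation).
#'   Default 0 (pure Balding-Nichols divergence); raise it to emulate
#'   panels ascertained for species-diagnostic content.
#' @param n_parents_per_species Reference-panel size (diploids per species).
#' @param g_max Generations since admixture for the hybrid swarm.
#' @param backcross_prob Probability that a parent drawn during swarm
#'   mating is a pure parental individual (split evenly between species);
#'   keeps genome-wide ancestry spread over (0, 1) as in natural zones
#'   while letting ancestry tracts shorten over the swarm generations.
#' @param recomb_rate_cM_per_Mb Recombination rate (centimorgan per megabase).
#' @param depth_mean Mean sequencing depth (reads per site per individual).
#' @param seq_error Per-read sequencing error rate.
#' @param allelic_bias Probability that a read from a heterozygote carries
#'   the alternate allele (0.5 = unbiased; RAD-seq data are often biased).
#' @param missing_rate Fraction of genotype calls dropped outright
#'   (in addition to Poisson depth-0 sites).
#' @param seed Integer seed; identical spec + seed gives identical output.
#'
#' @return An object of class `hz_spec` (a validated list).
#' @export
sim_spec <- function(n_sites = 500L,
                     n_chrom = 2L,
                     chrom_length_bp = 2.5e7,
                     fst_target = 0.39,
                     anc_freq_dist = c("uniform", "beta"),
                     diag_frac = 0,
                     n_parents_per_species = 51L,
                     g_max = 5L,
                     backcross_prob = 0.15,
                     recomb_rate_cM_per_Mb = 5,
                     depth_mean = 8,
                     seq_error = 0.005,
                     allelic_bias = 0.5,
                     missing_rate = 0.02,
                     seed = 1L) {
  anc_freq_dist <- match.arg(anc_freq_dist)
  spec <- list(
    n_sites = as.integer(n_sites), n_chrom = as.integer(n_chrom),
    chrom_length_bp = as.numeric(chrom_length_bp),
    fst_target = fst_target, anc_freq_dist = anc_freq_dist,
    diag_frac = diag_frac,
    n_parents_per_species = as.integer(n_parents_per_species),
    g_max = as.integer(g_max), backcross_prob = backcross_prob,
    recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
    depth_mean = depth_mean, seq_error = seq_error,
    allelic_bias = allelic_bias, missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  class(spec) <- "hz_spec"
  validate_sim_spec(spec)
  spec
}

validate_sim_spec <- function(spec) {
  stopifnot(inherits(spec, "hz_spec"))
  if (spec$fst_target < 0 || spec$fst_target >= 1)
    stop("fst_target must be in [0, 1)")
  if (spec$chrom_length_bp <= 0) stop("chrom_length_bp must be > 0")
  if (spec$n_sites < 1 || spec$n_chrom < 1)
    stop("n_sites and n_chrom must be >= 1")
  probs <- c(spec$diag_frac, spec$backcross_prob, spec$seq_error,
             spec$allelic_bias, spec$missing_rate)
  if (any(probs < 0 | probs > 1))
    stop("rates and probabilities must be in [0, 1]")
  if (spec$depth_mean < 0) stop("depth_mean must be >= 0")
  if (spec$recomb_rate_cM_per_Mb < 0) stop("recombination rate must be >= 0")
  if (spec$g_max < 1) stop("g_max must be >= 1")
  invisible(spec)
}

#' @export
print.hz_spec <- function(x, ...) {
  cat("<hz_spec>", x$n_chrom, "chromosomes x", x$n_sites, "sites,",
      "L =", x$chrom_length_bp / 1e6, "Mb, F_ST target", x$fst_target,
      "\n  swarm depth g =", x$g_max, "| depth", x$depth_mean,
      "| seed", x$seed, "\n")
  invisible(x)
}
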