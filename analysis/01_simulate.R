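#!/usr/bin/env Rscript
# Stage 1: generate the synthetic hybrid-zone study data set.
#
# Two parental poplar-like species diverged to F_ST ~ 0.39 (Balding-
# Nichols), a five-generation hybrid swarm of 300 seedlings genotyped at
# RAD-seq-like depth on two 12.5 Mb chromosomes, and three phenotypes of
# contrasting genomic architecture measured in two common gardens:
#   * flavonoid_like : sparse (2 ancestry QTLs) + polygenic background
#   * growth_like    : polygenic background only
#   * inert          : no genetic variance (covariates + noise)
# Writes VCF genotype likelihoods, true tract BED, phenotype/covariate TSV
# and the frequency panel under results/simdata/.

library(hybridmap)

seed <- 20260919L
out <- "results/simdata"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- sim_spec(n_sites = 500, n_chrom = 2, chrom_length_bp = 1.25e7,
                 fst_target = 0.39, depth_mean = 8, seed = seed)
freqs <- simulate_parental_frequencies(spec)
cat(sprintf("frequency tracks: %d sites, infinite-sample F_ST %.4f, %.2f%% near-fixed differences\n",
            nrow(freqs), attr(freqs, "fst_infinite"),
            100 * attr(freqs, "frac_fixed_diff")))

ped <- simulate_hybrid_pedigree(freqs, spec, n_ind = 300)
cat(sprintf("swarm of %d individuals, true q in [%.3f, %.3f], mean tract %.2f Mb\n",
            length(ped$ids), min(ped$truth$q_true), max(ped$truth$q_true),
            mean(ped$truth$tracts$end - ped$truth$tracts$start) / 1e6))

gl <- simulate_genotype_likelihoods(ped, spec)
cat(sprintf("genotype likelihoods: %.1f%% missing before depth masking\n",
            100 * mean(gl$missing)))

specs <- list(
  flavonoid_like = phenotype_spec("first", h2 = 0.5, pve = 0.6, n_qtl = 2,
                                  name = "flavonoid_like"),
  growth_like = phenotype_spec("second", pve = 0.4, name = "growth_like"),
  inert = phenotype_spec("third", name = "inert")
)
pheno <- list(); covars <- NULL; truth_qtl <- list()
for (nm in names(specs)) {
  ph <- simulate_phenotype(ped, specs[[nm]], seed = seed + match(nm, names(specs)),
                           covars = covars)
  covars <- ph$covars
  pheno[[nm]] <- round(ph$y, 6)
  if (!is.null(ph$truth$qtl)) truth_qtl[[nm]] <- ph$truth$qtl
}

write_vcf(gl, file.path(out, "genotypes.vcf"), seed = seed)
write_tracts_bed(ped$truth, file.path(out, "true_tracts.bed"), seed = seed)
covars$q <- round(covars$q, 6)
write_phenotypes(pheno, covars, file.path(out, "phenotypes.tsv"), seed = seed)
write_tsv_with_header <- hybridmap:::write_tsv_with_header
write_tsv_with_header(data.frame(freqs), file.path(out, "panel.tsv"),
                      seed = seed)
jsonlite::write_json(
  list(seed = seed, qtl = truth_qtl,
       q_true = as.list(round(ped$truth$q_true, 6))),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = 8, pretty = TRUE)
cat("wrote", out, "\n")
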