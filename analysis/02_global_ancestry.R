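#!/usr/bin/env Rscript
# Stage 2: genome-wide ancestry and species differentiation.
#
# Reads the stage-1 VCF, masks calls under 5 reads, applies the site
# filters (MAF >= 0.05, missingness <= 50%, mean depth <= 95% quantile),
# estimates per-individual ancestry q by supervised EM against the
# parental panel, classifies individuals (tremula q < 0.05, alba
# q > 0.95, hybrids between), and computes Hudson's F_ST from the panel
# frequencies. Writes results/ancestry/.

library(hybridmap)

seed <- 20260919L
simdir <- "results/simdata"
out <- "results/ancestry"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

gl <- read_vcf(file.path(simdir, "genotypes.vcf"))
panel_full <- utils::read.table(file.path(simdir, "panel.tsv"), header = TRUE,
                                comment.char = "#")
gl <- mask_low_depth(gl, 5)
glf <- filter_sites(gl, maf_min = 0.05, missing_max = 0.5, depth_q = 0.95)
cat(sprintf("site filters: %d of %d sites retained\n", nrow(glf$sites),
            nrow(gl$sites)))
keep <- match(paste(glf$sites$chrom, glf$sites$pos),
              paste(panel_full$chrom, panel_full$pos))
panel <- panel_full[keep, ]

qfit <- estimate_q_em(glf, panel = panel[c("p_A", "p_T")],
                      n_boot = 200, seed = seed)
truth <- jsonlite::read_json(file.path(simdir, "truth.json"),
                             simplifyVector = TRUE)
q_err <- abs(qfit$q - unlist(truth$q_true)[glf$ids])
cat(sprintf("EM ancestry: mean |q_hat - q_true| = %.4f (max %.4f), classes: %s\n",
            mean(q_err), max(q_err),
            paste(names(table(qfit$class)), table(qfit$class),
                  collapse = " ", sep = "=")))

fst <- hudson_fst(panel$p_A, panel$p_T, n1 = Inf, n2 = Inf)
cat(sprintf("Hudson F_ST (panel, ratio of averages): %.4f; %.2f%% of sites with |p_A - p_T| > 0.95\n",
            fst$fst_mean, 100 * fst$frac_fixed_diff))

hybridmap:::write_tsv_with_header(
  data.frame(id = glf$ids, q = round(qfit$q, 5),
             lo95 = round(qfit$ci95["lo", ], 5),
             hi95 = round(qfit$ci95["hi", ], 5), class = qfit$class),
  file.path(out, "q_global.tsv"), seed = seed)
hybridmap:::write_tsv_with_header(
  data.frame(glf$sites[c("chrom", "pos")],
             fst = round(fst$fst_site, 6)),
  file.path(out, "fst_per_site.tsv"), seed = seed)
jsonlite::write_json(
  list(fst_mean = fst$fst_mean, frac_fixed_diff = fst$frac_fixed_diff,
       n_sites = nrow(glf$sites), mean_abs_q_error = mean(q_err)),
  file.path(out, "summary.json"), auto_unbox = TRUE, digits = 8,
  pretty = TRUE)
cat("wrote", out, "\n")
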