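#!/usr/bin/env Rscript
# Stage 4: admixture linkage disequilibrium.
#
# Pairwise squared correlation of the expected ancestry dosages along
# each chromosome, binned decay with distance, and the half-decay
# distance. Admixture LD is what gives ancestry-based mapping its power:
# each window sum aggregates markers that are strongly correlated.

library(hybridmap)

seed <- 20260919L
out <- "results/ld"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

dostab <- utils::read.table("results/local_ancestry/dosage.tsv",
                            header = TRUE, comment.char = "#")
sites <- dostab[c("chrom", "pos")]
dos <- t(as.matrix(dostab[, -(1:2)]))

decays <- list()
for (ch in unique(sites$chrom)) {
  sel <- sites$chrom == ch
  ld <- ancestry_r2(dos[, sel, drop = FALSE], sites$pos[sel], chrom = ch)
  dc <- ld_decay(ld, bin_width_bp = 5e5)
  dc$chrom <- ch
  decays[[ch]] <- dc
  cat(sprintf("%s: mean R2 %.3f at 0-0.5 Mb, %.3f at 4.5-5 Mb, half-decay at %.1f Mb\n",
              ch, dc$mean_r2[1], dc$mean_r2[dc$bin_lo == 4.5e6],
              ld_half_distance(dc) / 1e6))
  hybridmap:::write_tsv_with_header(
    ld, file.path(out, paste0("pairs_", ch, ".tsv")), seed = seed)
}
dcall <- do.call(rbind, decays)
hybridmap:::write_tsv_with_header(dcall, file.path(out, "decay.tsv"),
                                  seed = seed)
cat("wrote", out, "\n")
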