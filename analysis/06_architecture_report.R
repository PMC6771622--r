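#!/usr/bin/env Rscript
# Stage 6: genomic-architecture report.
#
# Sums PIPs in nonoverlapping 0.5 Mb windows, selects windows with summed
# PIP >= 0.4, assigns each trait to one of the three architecture classes
# from its hyperparameter posterior, and annotates selected windows with
# genes from a small synthetic GFF3 (stand-in annotation generated here,
# since the analysis runs on simulated chromosomes).

library(hybridmap)

seed <- 20260919L
out <- "results/report"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

pheno <- read_phenotypes("results/simdata/phenotypes.tsv",
                         covariate_cols = c("q_true", "garden", "year"))
truth <- jsonlite::read_json("results/simdata/truth.json",
                             simplifyVector = TRUE)
chrom_lengths <- c(chr1 = 1.25e7, chr2 = 1.25e7)

# synthetic gene annotation: a gene every ~100 kb (labelled synthetic)
set.seed(seed)
gff <- file.path(out, "synthetic_genes.gff3")
lines <- c("##gff-version 3")
gid <- 0
for (ch in names(chrom_lengths)) {
  starts <- seq(1, chrom_lengths[[ch]] - 5e4, by = 1e5) +
    sample.int(4e4, length(seq(1, chrom_lengths[[ch]] - 5e4, by = 1e5)),
               replace = TRUE)
  for (s in starts) {
    gid <- gid + 1
    lines <- c(lines, sprintf(
      "%s\tsynthetic\tgene\t%d\t%d\t.\t+\t.\tID=synGene%04d", ch, s,
      s + sample(1e3:2e4, 1), gid))
  }
}
writeLines(lines, gff)
genes <- read_gff_genes(gff)

calls <- list(); seltabs <- list(); genetabs <- list()
for (tr in pheno$traits) {
  draws <- utils::read.table(sprintf("results/mapping/draws_%s.tsv", tr),
                             header = TRUE, comment.char = "#")
  piptab <- utils::read.table(sprintf("results/mapping/pip_%s.tsv", tr),
                              header = TRUE, comment.char = "#")
  track <- window_pip(piptab$pip, piptab$chrom, piptab$pos, chrom_lengths)
  selw <- select_windows(track, 0.4)
  call <- classify_architecture(draws, trait = tr)
  cat(sprintf("%-15s -> %-10s (%s); %d window(s) with PIP >= 0.4\n",
              tr, call$class, call$trace, nrow(selw)))
  hybridmap:::write_tsv_with_header(
    track, file.path(out, paste0("windows_", tr, ".tsv")), seed = seed)
  calls[[tr]] <- data.frame(trait = tr, class = call$class,
                            p_h2_ge_01 = call$p_h2_ge_01,
                            p_pve_ge_05 = call$p_pve_ge_05,
                            p_h2_lt_01 = call$p_h2_lt_01,
                            n_windows = nrow(selw))
  if (nrow(selw)) {
    selw$trait <- tr
    seltabs[[tr]] <- selw
    gt <- genes_in_windows(genes, selw)
    if (nrow(gt)) { gt$trait <- tr; genetabs[[tr]] <- gt }
  }
  if (!is.null(truth$qtl[[tr]])) {
    qtl_w <- floor((truth$qtl[[tr]]$pos - 1) / 5e5) * 5e5
    hit <- any(paste(selw$chrom, selw$start) %in%
               paste(truth$qtl[[tr]]$chrom, qtl_w))
    cat(sprintf("    true QTL window%s among selected: %s\n",
                if (nrow(truth$qtl[[tr]]) > 1) "s" else "", hit))
  }
}

hybridmap:::write_tsv_with_header(do.call(rbind, calls),
                                  file.path(out, "architecture_calls.tsv"),
                                  seed = seed)
if (length(seltabs))
  hybridmap:::write_tsv_with_header(do.call(rbind, seltabs),
                                    file.path(out, "selected_windows.tsv"),
                                    seed = seed)
if (length(genetabs))
  hybridmap:::write_tsv_with_header(do.call(rbind, genetabs),
                                    file.path(out, "genes_in_windows.tsv"),
                                    seed = seed)
cat("wrote", out, "\n")
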