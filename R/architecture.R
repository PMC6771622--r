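#' Sum posterior inclusion probabilities in nonoverlapping windows
#'
#' Neighboring markers share the association signal, so per-marker PIPs
#' are aggregated by summation over nonoverlapping windows (default
#' 0.5 Mb) tiling each chromosome from coordinate 0. Windows are 0-based
#' half-open `[k*w, (k+1)*w)`; a marker at 0-based position exactly
#' `k*w` belongs to window `k`. Empty windows are reported with sum 0.
#'
#' @param pip Per-marker PIPs.
#' @param chrom,pos Marker chromosome and position (1-based, as in VCF).
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param window_bp Window size (default 500,000).
#' @return A data.frame of class `hz_windows`: `chrom`, `start`, `end`
#'   (0-based half-open), `pip_sum`, `n_markers`.
#' @export
window_pip <- function(pip, chrom, pos, chrom_lengths, window_bp = 5e5) {
  stopifnot(length(pip) == length(chrom), length(pos) == length(chrom),
            window_bp > 0)
  pos0 <- pos - 1
  if (any(pos0 < 0 | pos0 >= chrom_lengths[chrom]))
    stop("marker positions outside chromosome lengths")
  out <- lapply(names(chrom_lengths), function(ch) {
    n_win <- ceiling(chrom_lengths[[ch]] / window_bp)
    sel <- which(chrom == ch)
    win <- floor(pos0[sel] / window_bp)
    sums <- rep(0, n_win); cnts <- rep(0L, n_win)
    if (length(sel)) {
      tab <- tapply(pip[sel], win, sum)
      sums[as.integer(names(tab)) + 1L] <- as.numeric(tab)
      cnt <- table(win)
      cnts[as.integer(names(cnt)) + 1L] <- as.integer(cnt)
    }
    data.frame(chrom = ch, start = (seq_len(n_win) - 1) * window_bp,
               end = pmin(seq_len(n_win) * window_bp, chrom_lengths[[ch]]),
               pip_sum = sums, n_markers = cnts, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("hz_windows", "data.frame")
  out
}

#' Select high-PIP windows
#'
#' Windows whose summed PIP is at least `threshold` (inclusive; default
#' 0.4), sorted by chromosome then position.
#' @param track An `hz_windows`.
#' @param threshold Selection threshold (>= 0).
#' @export
select_windows <- function(track, threshold = 0.4) {
  stopifnot(threshold >= 0)
  sel <- track[track$pip_sum >= threshold, , drop = FALSE]
  sel <- sel[order(sel$chrom, sel$start), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Classify a trait's genomic architecture from hyperparameter posteriors
#'
#' Three classes, evaluated in precedence order on pooled post-burn-in
#' draws:
#' \itemize{
#'   \item first:  `P(h2 >= 0.01) > 0.95` — detectable sparse effects on
#'     top of polygenic heritability;
#'   \item second: `P(PVE >= 0.05) > 0.97` — polygenic signal only;
#'   \item third:  `P(h2 < 0.01) >= 0.30` — no detectable heritability;
#'   \item otherwise unassigned.
#' }
#' A trait can satisfy the second and third rules simultaneously; the
#' precedence order resolves the overlap and the rule trace records all
#' three probabilities (plus an `overlap` flag). An explicit `promote`
#' reason may force a trait into the first class (mirroring judgment
#' calls for borderline traits with sharp PIP peaks); it is never
#' automatic.
#'
#' @param draws An `hz_draws` (or data.frame with `h2` and `pve`).
#' @param trait Trait id recorded in the call.
#' @param promote Optional character reason; if non-NULL the class is
#'   forced to `"first"` and the reason stored.
#' @return A list of class `hz_architecture`: `trait`, `class`,
#'   `p_h2_ge_01`, `p_pve_ge_05`, `p_h2_lt_01`, `thresholds`, `overlap`,
#'   `promoted`, `trace`.
#' @export
classify_architecture <- function(draws, trait = "trait", promote = NULL) {
  df <- if (inherits(draws, "hz_draws")) draws$draws else as.data.frame(draws)
  if (nrow(df) == 0) stop("no retained draws")
  p1 <- mean(df$h2 >= 0.01)
  p2 <- mean(df$pve >= 0.05)
  p3 <- mean(df$h2 < 0.01)
  cls <- if (p1 > 0.95) "first"
         else if (p2 > 0.97) "second"
         else if (p3 >= 0.30) "third"
         else "unassigned"
  overlap <- (p2 > 0.97) && (p3 >= 0.30)
  promoted <- FALSE
  if (!is.null(promote) && cls != "first") {
    cls <- "first"; promoted <- TRUE
  }
  trace <- sprintf(
    "P(h2>=0.01)=%.4f (first if >0.95); P(PVE>=0.05)=%.4f (second if >0.97); P(h2<0.01)=%.4f (third if >=0.30)%s%s",
    p1, p2, p3,
    if (overlap) "; second/third overlap resolved by precedence" else "",
    if (promoted) paste0("; promoted: ", promote) else ""
  )
  structure(list(trait = trait, class = cls, p_h2_ge_01 = p1,
                 p_pve_ge_05 = p2, p_h2_lt_01 = p3,
                 thresholds = c(first = 0.95, second = 0.97, third = 0.30),
                 overlap = overlap, promoted = promoted, trace = trace),
            class = "hz_architecture")
}

#' @export
print.hz_architecture <- function(x, ...) {
  cat("<hz_architecture>", x$trait, "->", x$class, "\n ", x$trace, "\n")
  invisible(x)
}

#' Variance in a trait explained by genome-wide ancestry, with bootstrap CI
#'
#' R-squared from the simple linear regression of the trait on q, with a
#' nonparametric case-resampling bootstrap percentile 95% interval
#' (default 1000 resamples).
#'
#' @param y Trait values.
#' @param q Genome-wide ancestry per individual.
#' @param n_boot Bootstrap replicates.
#' @param seed Seed for resampling.
#' @return A list of class `hz_qvar`: `r2`, `ci95`, `n`, `n_boot`, `seed`.
#' @export
r2_by_q <- function(y, q, n_boot = 1000L, seed = 1L) {
  ok <- !is.na(y) & !is.na(q)
  y <- y[ok]; q <- q[ok]
  n <- length(y)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(y) == 0 || stats::sd(q) == 0)
    stop("zero-variance trait or q")
  r2 <- stats::cor(y, q)^2
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
  r2b <- vapply(seq_len(n_boot), function(b) {
    i <- idx[, b]
    if (stats::sd(y[i]) == 0 || stats::sd(q[i]) == 0) return(NA_real_)
    stats::cor(y[i], q[i])^2
  }, numeric(1))
  ci <- stats::quantile(r2b, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(r2 = r2, ci95 = c(lo = ci[1], hi = ci[2]), n = n,
                 n_boot = n_boot, seed = seed),
            class = "hz_qvar")
}

#' Genes overlapping selected windows
#'
#' Returns every gene whose interval (GFF3 1-based inclusive, converted
#' to 0-based half-open) overlaps a window by at least 1 bp, with the
#' overlap length; a gene spanning a window boundary is reported once per
#' overlapped window with the split overlap lengths.
#'
#' @param genes A `GRanges` of gene features (e.g. from [read_gff_genes()])
#'   or a data.frame with `chrom`, `start`, `end` (1-based inclusive),
#'   `gene_id`.
#' @param windows An `hz_windows`-style data.frame (`chrom`, `start`,
#'   `end`, 0-based half-open).
#' @return data.frame: `chrom`, `win_start`, `win_end`, `gene_id`,
#'   `gene_start`, `gene_end`, `overlap_bp`.
#' @export
genes_in_windows <- function(genes, windows) {
  if (nrow(windows) == 0)
    return(data.frame(chrom = character(), win_start = numeric(),
                      win_end = numeric(), gene_id = character(),
                      gene_start = numeric(), gene_end = numeric(),
                      overlap_bp = numeric()))
  if (!methods::is(genes, "GRanges")) {
    genes <- GenomicRanges::GRanges(
      seqnames = genes$chrom,
      ranges = IRanges::IRanges(start = genes$start, end = genes$end),
      gene_id = genes$gene_id
    )
  }
  win_gr <- GenomicRanges::GRanges(
    seqnames = windows$chrom,
    ranges = IRanges::IRanges(start = windows$start + 1, end = windows$end)
  )
  hits <- GenomicRanges::findOverlaps(genes, win_gr, minoverlap = 1L)
  if (length(hits) == 0)
    return(data.frame(chrom = character(), win_start = numeric(),
                      win_end = numeric(), gene_id = character(),
                      gene_start = numeric(), gene_end = numeric(),
                      overlap_bp = numeric()))
  gi <- S4Vectors::queryHits(hits); wi <- S4Vectors::subjectHits(hits)
  inter <- IRanges::pintersect(IRanges::ranges(genes)[gi],
                               IRanges::ranges(win_gr)[wi])
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(genes))[gi],
    win_start = windows$start[wi], win_end = windows$end[wi],
    gene_id = genes$gene_id[gi],
    gene_start = GenomicRanges::start(genes)[gi],
    gene_end = GenomicRanges::end(genes)[gi],
    overlap_bp = IRanges::width(inter),
    stringsAsFactors = FALSE
  )
}
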