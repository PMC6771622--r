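#' Pairwise squared correlation of local-ancestry point estimates
#'
#' Admixture LD between sites on one chromosome: the squared Pearson
#' correlation of ancestry dosages across individuals, pairwise-complete
#' over missing entries. Sites with zero variance are excluded (their
#' pair count is reported).
#'
#' @param dosage Individuals x sites matrix of ancestry dosages.
#' @param pos Site positions (bp), same length as `ncol(dosage)`.
#' @param chrom Optional chromosome label recorded in the output.
#' @return A data.frame of class `hz_ld` with `pos1`, `pos2`, `dist_bp`,
#'   `r2`, plus attributes `n_undefined` (pairs dropped for zero
#'   variance) and `chrom`.
#' @export
ancestry_r2 <- function(dosage, pos, chrom = NA_character_) {
  L <- ncol(dosage)
  if (L < 2) stop("need at least 2 sites on the chromosome")
  stopifnot(length(pos) == L, nrow(dosage) >= 2)
  sds <- apply(dosage, 2, stats::sd, na.rm = TRUE)
  ok <- which(!is.na(sds) & sds > 0)
  cm <- suppressWarnings(
    stats::cor(dosage[, ok, drop = FALSE], use = "pairwise.complete.obs")
  )
  iu <- which(upper.tri(cm), arr.ind = TRUE)
  out <- data.frame(
    pos1 = pos[ok][iu[, 1]], pos2 = pos[ok][iu[, 2]],
    dist_bp = abs(pos[ok][iu[, 2]] - pos[ok][iu[, 1]]),
    r2 = cm[iu]^2
  )
  na_pairs <- sum(is.na(out$r2))
  out <- out[!is.na(out$r2), , drop = FALSE]
  attr(out, "n_undefined") <- choose(L, 2) - choose(length(ok), 2) + na_pairs
  attr(out, "chrom") <- chrom
  class(out) <- c("hz_ld", "data.frame")
  out
}

#' Admixture LD decay with physical distance
#'
#' Bins site pairs by separation and reports the mean R-squared and pair
#' count per bin.
#'
#' @param pairs An `hz_ld` (or data.frame with `dist_bp`, `r2`).
#' @param bin_width_bp Bin width in base pairs (> 0).
#' @return A data.frame of class `hz_ld_decay`: `bin_lo`, `bin_hi`,
#'   `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(pairs, bin_width_bp = 5e5) {
  stopifnot(bin_width_bp > 0)
  bin <- floor(pairs$dist_bp / bin_width_bp)
  agg <- stats::aggregate(pairs$r2, by = list(bin = bin),
                          FUN = function(v) c(mean(v), length(v)))
  out <- data.frame(
    bin_lo = agg$bin * bin_width_bp,
    bin_hi = (agg$bin + 1) * bin_width_bp,
    mean_r2 = agg$x[, 1],
    n_pairs = as.integer(agg$x[, 2])
  )
  class(out) <- c("hz_ld_decay", "data.frame")
  out
}

#' Distance at which mean admixture LD halves
#'
#' First bin midpoint at which the binned mean R-squared drops below half
#' its value in the first bin; `NA` if it never does.
#' @param decay An `hz_ld_decay`.
#' @export
ld_half_distance <- function(decay) {
  half <- decay$mean_r2[1] / 2
  idx <- which(decay$mean_r2 < half)[1]
  if (is.na(idx)) return(NA_real_)
  (decay$bin_lo[idx] + decay$bin_hi[idx]) / 2
}
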