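# Haplotype tract maps: list(ends, anc) with `ends` the 0-based half-open
# segment end coordinates in bp (last element = chromosome length) and
# `anc` the ancestry label per segment (0 = tremula, 1 = alba).

hap_pure <- function(anc, L_bp) list(ends = L_bp, anc = as.integer(anc))

hap_simplify <- function(h) {
  if (length(h$anc) <= 1L) return(h)
  keep <- c(h$anc[-1] != h$anc[-length(h$anc)], TRUE)
  list(ends = h$ends[keep], anc = h$anc[keep])
}

# ancestry of a haplotype at coordinates x (0-based, in [0, L))
hap_anc_at <- function(h, x) {
  h$anc[findInterval(x, h$ends, left.open = FALSE) + 1L]
}

# total alba (anc == 1) length of a haplotype
hap_alba_len <- function(h) {
  starts <- c(0, h$ends[-length(h$ends)])
  sum((h$ends - starts)[h$anc == 1L])
}

# one meiosis: recombine the two parental haplotypes of a chromosome.
# Crossovers are Poisson along the genetic map (Haldane, no interference).
sim_meiosis <- function(h1, h2, L_bp, morgan) {
  ncx <- stats::rpois(1L, morgan)
  src <- sample(1:2, 1L)
  if (ncx == 0L) return(structure(if (src == 1L) h1 else h2, n_crossovers = 0L))
  cx <- sort(stats::runif(ncx, 0, L_bp))
  cuts <- c(cx, L_bp)
  ends <- numeric(0); anc <- integer(0)
  prev <- 0
  for (k in seq_along(cuts)) {
    h <- if (src == 1L) h1 else h2
    lo <- findInterval(prev, h$ends) + 1L               # first segment ending after prev
    hi <- findInterval(cuts[k], h$ends, left.open = TRUE) + 1L  # segment containing the cut
    hi <- min(hi, length(h$ends))
    seg_ends <- pmin(h$ends[lo:hi], cuts[k])
    ends <- c(ends, seg_ends)
    anc <- c(anc, h$anc[lo:hi])
    prev <- cuts[k]
    src <- 3L - src
  }
  structure(hap_simplify(list(ends = ends, anc = anc)), n_crossovers = ncx)
}

new_parental <- function(species, chrom_lens) {
  lapply(chrom_lens, function(L) list(hap_pure(species, L), hap_pure(species, L)))
}

make_gamete <- function(ind, chrom_lens, morgans) {
  lapply(seq_along(chrom_lens), function(ci) {
    sim_meiosis(ind[[ci]][[1L]], ind[[ci]][[2L]], chrom_lens[ci], morgans[ci])
  })
}

#' Simulate a recombinant hybrid-zone pedigree with full ground truth
#'
#' Builds a hybrid swarm: generation 1 is F1 (one haplotype from each
#' species), and each later generation mates individuals drawn from the
#' previous generation, replaced with probability `backcross_prob` by a
#' pure parental (species chosen at random) so that genome-wide ancestry
#' stays spread over (0, 1) as in natural hybrid zones. Gametes carry
#' Poisson-distributed crossovers on the genetic map implied by
#' `recomb_rate_cM_per_Mb` (Haldane model, no interference). Alleles on a
#' haplotype are drawn site-independently within tracts from the carrying
#' species' frequency track (no within-species background LD).
#'
#' @param freqs Frequency tracks from [simulate_parental_frequencies()].
#' @param spec The [sim_spec()] used to generate `freqs`.
#' @param n_ind Number of individuals sampled from the final generation.
#' @param g Generations since admixture (1 = F1). Defaults to `spec$g_max`.
#' @param type `"swarm"` (default), `"F1"`, `"parental_A"` or
#'   `"parental_T"` to force a specific cross type.
#' @param seed Seed; defaults to `spec$seed + 1`.
#'
#' @return A list of class `hz_pedigree`: `ids`, `sites` (the `freqs`
#'   table), `geno` (individuals x sites alternate-allele counts),
#'   `anc_dosage` (individuals x sites alba-allele counts, 0/1/2), and
#'   `truth`, an `hz_truth` record with the diploid tract map (`tracts`:
#'   id, chrom, start/end 0-based half-open, state = alba copies), true
#'   genome-wide ancestry `q_true`, and bookkeeping slots (`qtl`,
#'   `varfrac`, `covars`) filled by [simulate_phenotype()].
#' @export
simulate_hybrid_pedigree <- function(freqs, spec, n_ind = 100L,
                                     g = spec$g_max,
                                     type = c("swarm", "F1", "parental_A",
                                              "parental_T"),
                                     seed = spec$seed + 1L) {
  type <- match.arg(type)
  stopifnot(inherits(freqs, "hz_freqs"))
  if (g < 1L) stop("empty pedigree: g must be >= 1")
  if (g > spec$g_max) stop("pedigree depth exceeds g_max")
  set.seed(seed)

  chroms <- unique(freqs$chrom)
  chrom_lens <- rep(spec$chrom_length_bp, length(chroms))
  names(chrom_lens) <- chroms
  morgans <- spec$recomb_rate_cM_per_Mb * (chrom_lens / 1e6) / 100

  inds <- switch(type,
    parental_A = replicate(n_ind, new_parental(1L, chrom_lens), simplify = FALSE),
    parental_T = replicate(n_ind, new_parental(0L, chrom_lens), simplify = FALSE),
    F1 = replicate(n_ind, lapply(chrom_lens, function(L)
      list(hap_pure(1L, L), hap_pure(0L, L))), simplify = FALSE),
    swarm = {
      pop <- replicate(max(n_ind, 20L), lapply(chrom_lens, function(L)
        list(hap_pure(1L, L), hap_pure(0L, L))), simplify = FALSE)
      if (g >= 2L) {
        for (t in 2:g) {
          pop <- replicate(max(n_ind, 20L), {
            pick <- function() {
              if (stats::runif(1) < spec$backcross_prob)
                new_parental(as.integer(stats::runif(1) < 0.5), chrom_lens)
              else pop[[sample.int(length(pop), 1L)]]
            }
            g1 <- make_gamete(pick(), chrom_lens, morgans)
            g2 <- make_gamete(pick(), chrom_lens, morgans)
            lapply(seq_along(chrom_lens), function(ci) list(g1[[ci]], g2[[ci]]))
          }, simplify = FALSE)
        }
      }
      pop[seq_len(n_ind)]
    }
  )

  ids <- sprintf("ind%03d", seq_len(n_ind))
  L <- nrow(freqs)
  geno <- matrix(0L, n_ind, L, dimnames = list(ids, NULL))
  anc_dosage <- matrix(0L, n_ind, L, dimnames = list(ids, NULL))
  tracts <- vector("list", n_ind)
  q_true <- numeric(n_ind)

  site_x <- freqs$pos - 0.5  # 0-based coordinate strictly inside the site
  chrom_of_site <- freqs$chrom

  for (i in seq_len(n_ind)) {
    ind <- inds[[i]]
    alba_len <- 0
    tr <- vector("list", length(chroms))
    for (ci in seq_along(chroms)) {
      h1 <- ind[[ci]][[1L]]; h2 <- ind[[ci]][[2L]]
      sel <- which(chrom_of_site == chroms[ci])
      x <- site_x[sel]
      a1 <- hap_anc_at(h1, x); a2 <- hap_anc_at(h2, x)
      anc_dosage[i, sel] <- a1 + a2
      pA <- freqs$p_A[sel]; pT <- freqs$p_T[sel]
      al1 <- stats::rbinom(length(sel), 1L, ifelse(a1 == 1L, pA, pT))
      al2 <- stats::rbinom(length(sel), 1L, ifelse(a2 == 1L, pA, pT))
      geno[i, sel] <- al1 + al2
      alba_len <- alba_len + hap_alba_len(h1) + hap_alba_len(h2)
      # diploid tract overlay
      cuts <- sort(unique(c(h1$ends, h2$ends)))
      starts <- c(0, cuts[-length(cuts)])
      mid <- (starts + cuts) / 2
      st <- hap_anc_at(h1, mid) + hap_anc_at(h2, mid)
      keep <- if (length(st) > 1L) c(st[-1] != st[-length(st)], TRUE) else TRUE
      ends2 <- cuts[keep]; st2 <- st[keep]
      tr[[ci]] <- data.frame(
        id = ids[i], chrom = chroms[ci],
        start = c(0, ends2[-length(ends2)]), end = ends2, state = st2,
        stringsAsFactors = FALSE
      )
    }
    tracts[[i]] <- do.call(rbind, tr)
    q_true[i] <- alba_len / (2 * sum(chrom_lens))
  }

  truth <- structure(list(
    tracts = do.call(rbind, tracts), q_true = stats::setNames(q_true, ids),
    qtl = NULL, varfrac = NULL, covars = NULL, liability_threshold = NULL
  ), class = "hz_truth")

  structure(list(ids = ids, sites = freqs, geno = geno,
                 anc_dosage = anc_dosage, truth = truth,
                 g = g, spec = spec),
            class = "hz_pedigree")
}
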