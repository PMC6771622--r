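# Readers and writers for the formats the pipeline touches. Coordinate
# conventions: VCF and GFF3 are 1-based inclusive on input; BED-like
# window/tract outputs are 0-based half-open.

pkg_version <- function() as.character(utils::packageVersion("hybridmap"))

# small deterministic polynomial hash for config provenance lines
config_hash_of <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

output_header <- function(seed = NA, config_hash = NA) {
  sprintf("# hybridmap %s | seed=%s | config=%s", pkg_version(),
          as.character(seed), as.character(config_hash))
}

write_tsv_with_header <- function(df, path, seed = NA, config_hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, config_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotype likelihoods from a VCF with GT and PL (or GL) fields
#'
#' Phred-scaled PL triples are converted to likelihoods normalized to
#' max 1 (`10^(-PL/10)`); GL (log10-likelihood) fields are used when PL
#' is absent. Non-biallelic records are skipped and counted. Depth is
#' taken from the DP FORMAT field when present, else 0/1 from
#' missingness.
#'
#' @param path VCF file (plain text or gzipped).
#' @return An `hz_gl` with attribute `n_skipped` (non-biallelic records).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- v@fix[, "ALT"]
  ref <- v@fix[, "REF"]
  biallelic <- !is.na(alt) & !grepl(",", alt) &
    nchar(alt) == 1 & nchar(ref) == 1
  n_skipped <- sum(!biallelic)
  v <- v[biallelic, ]
  sites <- data.frame(chrom = v@fix[, "CHROM"],
                      pos = as.integer(v@fix[, "POS"]),
                      ref = v@fix[, "REF"], alt = v@fix[, "ALT"],
                      stringsAsFactors = FALSE)
  fmt <- v@gt[, 1]
  has_pl <- all(grepl("PL", fmt))
  has_gl <- all(grepl("GL", fmt))
  if (!has_pl && !has_gl)
    stop(sprintf("record %s:%d has neither PL nor GL",
                 sites$chrom[1], sites$pos[1]))
  field <- if (has_pl) "PL" else "GL"
  raw <- vcfR::extract.gt(v, element = field)   # sites x individuals
  ids <- colnames(raw)
  L <- nrow(sites); n <- length(ids)
  lik <- array(1, c(n, L, 3))
  miss <- matrix(FALSE, n, L)
  parse_one <- function(s) {
    if (is.na(s) || s == ".") return(c(NA_real_, NA_real_, NA_real_))
    suppressWarnings(as.numeric(strsplit(s, ",", fixed = TRUE)[[1]][1:3]))
  }
  for (i in seq_len(n)) {
    vals <- vapply(raw[, i], parse_one, numeric(3))
    bad <- is.na(vals[1, ])
    miss[i, ] <- bad
    tri <- if (has_pl) 10^(-vals / 10) else 10^vals
    tri[, bad] <- 1
    mx <- apply(tri, 2, max)
    lik[i, , ] <- t(tri) / mx
  }
  dp <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  depth <- if (!is.null(dp) && !all(is.na(dp))) {
    dpm <- t(dp); dpm[is.na(dpm)] <- 0L; dpm
  } else matrix(ifelse(miss, 0L, 1L), n, L)
  out <- new_hz_gl(ids, sites, lik, depth, miss)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write genotype likelihoods as a VCF with GT, PL and DP fields
#'
#' Likelihood triples are written as Phred-scaled PLs (rounded, capped at
#' 255); GT is the max-likelihood genotype (./ . when missing).
#'
#' @param gl An `hz_gl`.
#' @param path Output path (plain text).
#' @param seed,config_hash Recorded in the header.
#' @export
write_vcf <- function(gl, path, seed = NA, config_hash = NA) {
  n <- length(gl$ids); L <- nrow(gl$sites)
  ref <- if ("ref" %in% names(gl$sites)) gl$sites$ref else rep("A", L)
  alt <- if ("alt" %in% names(gl$sites)) gl$sites$alt else rep("T", L)
  gt_str <- c("0/0", "0/1", "1/1")
  lines <- character(L)
  for (j in seq_len(L)) {
    cells <- character(n)
    for (i in seq_len(n)) {
      if (gl$missing[i, j]) {
        cells[i] <- "./.:.:."
      } else {
        tri <- gl$lik[i, j, ]
        pl <- round(pmin(-10 * log10(pmax(tri / max(tri), 1e-26)), 255))
        cells[i] <- sprintf("%s:%s:%d", gt_str[which.max(tri)],
                            paste(pl, collapse = ","), gl$depth[i, j])
      }
    }
    lines[j] <- paste(c(gl$sites$chrom[j], gl$sites$pos[j], ".",
                        ref[j], alt[j], ".", "PASS", ".", "GT:PL:DP",
                        cells), collapse = "\t")
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=hybridmap_%s seed=%s config=%s", pkg_version(),
            as.character(seed), as.character(config_hash)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=PL,Number=G,Type=Integer,Description="Phred-scaled genotype likelihoods">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gl$ids), collapse = "\t")
  )
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' TSV with a header, an `id` column, trait columns and covariate columns
#' (`q`, `garden`, `year` by convention). Binary-mapping eligibility per
#' trait is computed from the zero-abundance fraction (eligible when
#' > 10% of non-missing values are zero).
#'
#' @param path TSV path.
#' @param covariate_cols Covariate column names present in the file.
#' @return A list of class `hz_traits`: `data` (the table), `traits`
#'   (trait column names), `covariates`, `binary_eligible` (named
#'   logical), `zero_fraction`, `n_obs` (per trait).
#' @export
read_phenotypes <- function(path, covariate_cols = c("q", "garden", "year")) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!"id" %in% names(df)) stop("phenotype table needs an 'id' column")
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) stop("duplicate id(s): ", paste(unique(dup), collapse = ", "))
  trait_cols <- setdiff(names(df), c("id", covariate_cols))
  for (tc in trait_cols) {
    if (!is.numeric(df[[tc]]))
      stop(sprintf("trait column '%s' is not numeric", tc))
  }
  zf <- vapply(trait_cols, function(tc) {
    v <- df[[tc]]; mean(v[!is.na(v)] == 0)
  }, numeric(1))
  structure(list(
    data = df, traits = trait_cols,
    covariates = intersect(covariate_cols, names(df)),
    binary_eligible = zf > 0.10, zero_fraction = zf,
    n_obs = vapply(trait_cols, function(tc) sum(!is.na(df[[tc]])), integer(1))
  ), class = "hz_traits")
}

#' Write simulated phenotypes and covariates as TSV
#' @param pheno Named list of trait vectors (same individuals).
#' @param covars data.frame with `id`, `q`, `garden`, `year`.
#' @export
write_phenotypes <- function(pheno, covars, path, seed = NA,
                             config_hash = NA) {
  df <- cbind(covars["id"], as.data.frame(pheno),
              covars[setdiff(names(covars), "id")])
  names(df)[names(df) == "q"] <- "q_true"
  write_tsv_with_header(df, path, seed, config_hash)
}

#' Write true ancestry tracts as BED (0-based half-open) with state column
#' @param truth An `hz_truth`.
#' @export
write_tracts_bed <- function(truth, path, seed = NA, config_hash = NA) {
  tr <- truth$tracts
  df <- data.frame(chrom = tr$chrom, start = format(tr$start, scientific = FALSE, trim = TRUE),
                   end = format(tr$end, scientific = FALSE, trim = TRUE),
                   id = tr$id, state = tr$state)
  write_tsv_with_header(df, path, seed, config_hash)
}

#' Read gene features from a GFF3 annotation
#'
#' Imports the annotation and keeps `gene` features; malformed lines are
#' skipped by the parser. Returns a `GRanges` with a `gene_id` column
#' (from the ID attribute).
#' @param path GFF3 file.
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  id <- if (!is.null(genes$ID)) genes$ID else as.character(seq_along(genes))
  genes$gene_id <- id
  genes
}

#' Load and validate a pipeline run configuration
#'
#' A YAML file (or list) with stage parameters; unknown keys are
#' rejected. Defaults mirror the package function defaults.
#' @param config Path to YAML or a named list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    out_dir = "hybridmap_run",
    seed = 1L,
    n_ind = 120L, n_sites = 300L, n_chrom = 2L, chrom_length_bp = 1e7,
    fst_target = 0.39, depth_mean = 8, g = 5L,
    recomb_rate_cM_per_Mb = 5, miscopy_eps = 0.06,
    depth_mask = 5L, maf_min = 0.05, missing_max = 0.5, depth_q = 0.95,
    window_bp = 5e5, pip_threshold = 0.4,
    n_chains = 3L, n_iter = 20000L, thin = 10L,
    traits = list(
      list(name = "trait_first", class = "first", h2 = 0.3, pve = 0.6,
           n_qtl = 2L),
      list(name = "trait_second", class = "second", pve = 0.4),
      list(name = "trait_third", class = "third")
    ),
    gff = NULL
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  # modifyList merges nested lists by name; the trait list is positional
  if ("traits" %in% names(config)) cfg$traits <- config$traits
  hashed <- sort(setdiff(names(cfg), "out_dir"))  # content, not placement
  cfg$hash <- config_hash_of(vapply(cfg[hashed], function(x)
    paste(deparse(x), collapse = ""), character(1)))
  class(cfg) <- "hz_config"
  cfg
}

#' Run the full admixture-mapping pipeline on synthetic data
#'
#' Chains simulate -> depth masking and site filters -> genome-wide
#' ancestry (EM) + F_ST -> local ancestry (HMM) -> admixture LD ->
#' covariate adjustment + BSLMM per trait -> windowed PIPs + architecture
#' classification (-> gene annotation when a GFF3 is configured), writing
#' TSV outputs, a resolved-config copy and a machine-readable JSON
#' summary into `cfg$out_dir`.
#'
#' @param cfg An [run_config()] (or list/path accepted by it).
#' @return The JSON summary, invisibly (also written to disk).
#' @export
run_pipeline <- function(cfg = run_config()) {
  if (!inherits(cfg, "hz_config")) cfg <- run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  summary <- list(version = pkg_version(), seed = cfg$seed,
                  config_hash = cfg$hash)
  tryCatch({
    spec <- sim_spec(n_sites = cfg$n_sites, n_chrom = cfg$n_chrom,
                     chrom_length_bp = cfg$chrom_length_bp,
                     fst_target = cfg$fst_target,
                     depth_mean = cfg$depth_mean, seed = cfg$seed)
    freqs <- simulate_parental_frequencies(spec)
    ped <- simulate_hybrid_pedigree(freqs, spec, n_ind = cfg$n_ind,
                                    g = cfg$g)
    gl <- simulate_genotype_likelihoods(ped, spec)
    write_vcf(gl, file.path(cfg$out_dir, "genotypes.vcf"),
              cfg$seed, cfg$hash)
    write_tracts_bed(ped$truth, file.path(cfg$out_dir, "true_tracts.bed"),
                     cfg$seed, cfg$hash)

    stage <- "qglobal"
    gl <- mask_low_depth(gl, cfg$depth_mask)
    glf <- filter_sites(gl, cfg$maf_min, cfg$missing_max, cfg$depth_q)
    panel <- data.frame(p_A = glf$sites$p_A, p_T = glf$sites$p_T)
    qfit <- estimate_q_em(glf, panel = panel)
    fst <- hudson_fst(panel$p_A, panel$p_T, n1 = Inf, n2 = Inf)
    write_tsv_with_header(
      data.frame(id = glf$ids, q = round(qfit$q, 6),
                 class = qfit$class),
      file.path(cfg$out_dir, "q_global.tsv"), cfg$seed, cfg$hash)

    stage <- "lai"
    lai <- local_ancestry(glf, panel, qfit$q, g = cfg$g,
                          recomb_rate_cM_per_Mb = cfg$recomb_rate_cM_per_Mb,
                          miscopy_eps = cfg$miscopy_eps)
    dos_out <- data.frame(glf$sites[c("chrom", "pos")],
                          round(t(lai$dosage), 4))
    write_tsv_with_header(dos_out, file.path(cfg$out_dir, "dosage.tsv"),
                          cfg$seed, cfg$hash)

    stage <- "ld"
    ch1 <- unique(glf$sites$chrom)[1]
    sel <- glf$sites$chrom == ch1
    ld <- ancestry_r2(lai$dosage[, sel, drop = FALSE], glf$sites$pos[sel],
                      chrom = ch1)
    decay <- ld_decay(ld, bin_width_bp = cfg$window_bp)
    write_tsv_with_header(decay, file.path(cfg$out_dir, "ld_decay.tsv"),
                          cfg$seed, cfg$hash)

    stage <- "map"
    chrom_lengths <- stats::setNames(rep(cfg$chrom_length_bp, cfg$n_chrom),
                                     unique(glf$sites$chrom))
    per_trait <- list()
    traits_out <- list()
    shared_covars <- NULL
    for (ts in cfg$traits) {
      pspec <- phenotype_spec(
        class = ts$class,
        h2 = if (!is.null(ts$h2)) ts$h2 else 0.3,
        pve = if (!is.null(ts$pve)) ts$pve else 0.6,
        n_qtl = if (!is.null(ts$n_qtl)) ts$n_qtl else 2L,
        name = ts$name)
      ph <- simulate_phenotype(ped, pspec,
                               seed = cfg$seed + 100L + length(traits_out),
                               covars = shared_covars)
      shared_covars <- ph$covars
      traits_out[[ts$name]] <- round(ph$y, 6)
      adj <- adjust_phenotype(ph$y, ph$covars[c("q", "garden", "year")])
      fit <- bslmm(adj$residuals, lai$dosage,
                   cfg = bslmm_config(n_chains = cfg$n_chains,
                                      n_iter = cfg$n_iter, thin = cfg$thin,
                                      seed = cfg$seed))
      track <- window_pip(fit$pip, glf$sites$chrom, glf$sites$pos,
                          chrom_lengths, cfg$window_bp)
      selw <- select_windows(track, cfg$pip_threshold)
      call <- classify_architecture(fit, trait = ts$name)
      qv <- r2_by_q(ph$y, qfit$q, n_boot = 200L, seed = cfg$seed)
      per_trait[[ts$name]] <- list(
        class = call$class,
        p_h2_ge_01 = call$p_h2_ge_01, p_pve_ge_05 = call$p_pve_ge_05,
        p_h2_lt_01 = call$p_h2_lt_01,
        pve_mean = mean(fit$draws$pve), h2_mean = mean(fit$draws$h2),
        r2_q = qv$r2, r2_q_ci = unname(qv$ci95),
        n_selected_windows = nrow(selw),
        selected_windows = if (nrow(selw)) paste0(
          selw$chrom, ":", selw$start, "-", selw$end) else character(0)
      )
      write_tsv_with_header(track,
        file.path(cfg$out_dir, paste0("windows_", ts$name, ".tsv")),
        cfg$seed, cfg$hash)
      if (!is.null(cfg$gff) && nrow(selw)) {
        genes <- read_gff_genes(cfg$gff)
        gtab <- genes_in_windows(genes, selw)
        write_tsv_with_header(gtab,
          file.path(cfg$out_dir, paste0("genes_", ts$name, ".tsv")),
          cfg$seed, cfg$hash)
        per_trait[[ts$name]]$n_genes <- nrow(gtab)
      }
    }
    shared_covars$q <- round(shared_covars$q, 6)
    write_phenotypes(traits_out, shared_covars,
                     file.path(cfg$out_dir, "phenotypes.tsv"),
                     cfg$seed, cfg$hash)

    stage <- "report"
    summary$fst_mean <- fst$fst_mean
    summary$frac_fixed_diff <- fst$frac_fixed_diff
    summary$n_sites_used <- nrow(glf$sites)
    summary$traits <- per_trait
    cfg_out <- cfg; class(cfg_out) <- NULL
    yaml::write_yaml(cfg_out, file.path(cfg$out_dir, "config_resolved.yaml"))
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(summary)
}
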