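# Shared fixture builders (everything is generated in code at test time).

small_cfg <- function(seed = 1L, ...) {
  sim_config(n_genotypes = 80L, n_checks = 4L, n_chromosomes = 2L,
             snps_per_chromosome = 150L, seed = seed, ...)
}

# panel of (nearly) independent markers: short founder correlation and high
# recombination kill LD, so inter- and intra-chromosomal r2 are both ~1/n
independent_panel <- function(n = 200L, m_per_chr = 120L, n_chr = 2L,
                              seed = 1L) {
  cfg <- sim_config(n_genotypes = n, n_chromosomes = n_chr,
                    snps_per_chromosome = m_per_chr,
                    founder_ld_bp = 1e3, recomb_rate = 1e-6,
                    n_founder_haplotypes = 40L, missing_rate = 0,
                    seed = seed)
  impute_missing(qc_filter(simulate_genotypes(cfg)))
}

# hand-built panel from an explicit dosage matrix (one chromosome unless
# chrom given)
toy_panel <- function(dosage, chrom = NULL, pos = NULL) {
  m <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("C1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1e6
  colnames(dosage) <- sprintf("S%02d", seq_len(m))
  rownames(dosage) <- sprintf("G%03d", seq_len(nrow(dosage)))
  new_panel(dosage, data.frame(marker = colnames(dosage), chrom = chrom,
                               pos = pos, stringsAsFactors = FALSE))
}

# augmented-design plot table with planted genotype, sub-block and noise
# effects: 4 blocks x 2 sub-blocks, `n_checks` checks replicated 3x per
# block, a fraction of entries replicated once
make_plots <- function(n_geno = 60L, n_checks = 4L, g_sd = 1, sb_sd = 0,
                       noise_sd = 1, prop_rep = 0.3, seed = 1L,
                       g_values = NULL, sb_values = NULL) {
  set.seed(seed)
  geno <- sprintf("G%03d", seq_len(n_geno))
  checks <- geno[seq_len(n_checks)]
  others <- geno[-seq_len(n_checks)]
  sb_all <- paste0("SB", 1:8)
  blk_of <- setNames(rep(paste0("B", 1:4), each = 2), sb_all)
  rows <- list()
  for (b in 1:4) {
    sbs <- sb_all[(2 * b - 1):(2 * b)]
    for (ck in checks)
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = ck, subblock = sample(rep(sbs, length.out = 3)),
        stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    genotype = others, subblock = rep(sb_all, length.out = length(others)),
    stringsAsFactors = FALSE)
  n_rep <- round(prop_rep * length(others))
  if (n_rep > 0)
    rows[[length(rows) + 1L]] <- data.frame(
      genotype = sample(others, n_rep),
      subblock = sample(sb_all, n_rep, replace = TRUE),
      stringsAsFactors = FALSE)
  d <- do.call(rbind, rows)
  d$block <- blk_of[d$subblock]
  d$env <- "E1"
  d$is_check <- d$genotype %in% checks
  if (is.null(g_values)) g_values <- setNames(rnorm(n_geno, 0, g_sd), geno)
  if (is.null(sb_values)) sb_values <- setNames(rnorm(8, 0, sb_sd), sb_all)
  d$y <- g_values[d$genotype] + sb_values[d$subblock] +
    rnorm(nrow(d), 0, noise_sd)
  attr(d, "g_values") <- g_values
  attr(d, "sb_values") <- sb_values
  d
}

# genotype-level adjusted-means table for statistics tests
adj_table <- function(values_by_trait, env = "E1") {
  do.call(rbind, lapply(names(values_by_trait), function(tr) {
    v <- values_by_trait[[tr]]
    data.frame(genotype = names(v), env = env, trait = tr,
               value = as.numeric(v), stringsAsFactors = FALSE)
  }))
}

# Large-effect recovery scenario: three pleiotropic canopy loci (all acting
# through spike density) and three dispersion-only loci, well separated
# across six chromosomes.  The secondary-tiller channel is switched off and
# the upper-tail cap steepened so the canopy -> GSV pathway is the only
# mean-trait route into GSV; colocalisation is scored with the
# shared-member-SNP rule against the canopy components (TKW is excluded
# because heavy tail truncation couples dispersion loci to grain mass).
classification_scenario <- function(seed) {
  cfg <- sim_config(
    n_genotypes = 300, n_chromosomes = 6, snps_per_chromosome = 150,
    missing_rate = 0, effect_model = "fixed", seed = seed,
    qtl_placement = "spread",
    pleiotropy_spec = list(c("spm2", "tkw_pot"), c("spm2", "gps"),
                           c("spm2", "gps", "tkw_pot")),
    n_qtl_per_trait = c(spm2 = 3, gps = 2, tkw_pot = 2, gsv = 3),
    effect_sd = c(spm2 = 65, gps = 3, tkw_pot = 0.6, gsv = 0.22),
    tiller_params = list(cap_k0 = 1.5, cap_k1 = 1.2, sec_slope = 0),
    sigma_plot = 0.35,
    environments = default_environments()[1])
  panel <- simulate_genotypes(cfg)
  trial <- simulate_trial(cfg, panel)
  plots <- merge(trial$plots, grain_metrics_table(trial$grains),
                 by = "plot_id", sort = FALSE)
  comp <- derive_components(plots$gy, plots$spm2, plots$tkw)
  plots$gpm2 <- comp$gpm2; plots$gps <- comp$gps
  traits <- c("gsv", "spm2", "gps", "gpm2")
  adj <- do.call(rbind, lapply(traits, function(t)
    adjusted_means(plots, t)))
  pan <- impute_missing(qc_filter(panel))
  K <- kinship_loco(pan)
  scan <- do.call(rbind, lapply(traits, function(t)
    mlm_scan(adj, pan, K, t, "E1")))
  sig_gsv <- scan[scan$significant & scan$trait == "gsv", ]
  if (!nrow(sig_gsv)) return(NULL)
  crit <- critical_ld(pan, 400, seed = seed + 101)
  dec <- fit_ld_decay(pan, n_pairs = 1000, seed = seed + 102)
  q <- build_qtl(ld_blocks(sig_gsv, pan, crit), dec, crit,
                 assoc = sig_gsv, chrom_len = pan$chrom_len)
  hits <- scan[scan$significant & scan$trait != "gsv", ]
  cl <- classify_qtl(q, hits, "E1", rule = "members",
                     component_set = c("spm2", "gps", "gpm2"))
  truth <- trial$truth$qtl
  drv <- unique(truth[truth$trait == "spm2", c("chrom", "pos")])
  spc <- unique(truth[truth$trait == "gsv", c("chrom", "pos")])
  in_qtl <- function(ch, po, qi)
    ch == cl$chrom[qi] && po >= cl$start[qi] && po <= cl$end[qi]
  res <- list(correct = 0, total = 0,
              driven_recovered = 0, specific_recovered = 0)
  for (i in seq_len(nrow(cl))) {
    has_d <- any(mapply(in_qtl, drv$chrom, drv$pos, i))
    has_s <- any(mapply(in_qtl, spc$chrom, spc$pos, i))
    if (!has_d && !has_s) next
    res$total <- res$total + 1
    if (cl$class[i] == (if (has_d) "driven" else "specific"))
      res$correct <- res$correct + 1
  }
  covered_as <- function(ch, po, klass)
    any(mapply(function(c2, p2) any(cl$chrom == c2 & cl$start <= p2 &
                                      cl$end >= p2 & cl$class == klass),
               ch, po))
  res$driven_recovered <- sum(mapply(function(c2, p2)
    covered_as(c2, p2, "driven"), drv$chrom, drv$pos))
  res$specific_recovered <- sum(mapply(function(c2, p2)
    covered_as(c2, p2, "specific"), spc$chrom, spc$pos))
  res
}
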