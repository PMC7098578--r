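#' Configuration of the synthetic genotype / field-trial / grain generator
#'
#' Builds and validates the configuration object consumed by
#' [simulate_genotypes()] and [simulate_trial()].  Defaults describe a
#' desk-scale wheat panel in the spirit of the data the package is designed
#' for: an unreplicated augmented design (4 blocks x 2 sub-blocks, a few
#' replicated check genotypes), two contrasting environments (well-watered
#' vs water-deficit, with environment shifts matching typical elite-panel
#' trait means: ~600 vs ~400 spikes/m2, 32 vs 41 grains/spike, grain size
#' mean ~17 mm2), chromosome-scale LD, pleiotropic yield-component QTL and
#' variance-specific (dispersion) QTL, and 300-500 measured grains per plot.
#'
#' @param n_genotypes number of genotypes in the panel (checks included).
#' @param n_checks number of replicated check genotypes.
#' @param n_chromosomes,snps_per_chromosome,chromosome_length_bp marker map
#'   dimensions.
#' @param n_founder_haplotypes founders of the haplotype mosaic (>= 2).
#' @param recomb_rate per-bp probability of switching founder along a
#'   haplotype; controls LD decay together with `founder_ld_bp`.
#' @param founder_ld_bp correlation length (bp) of the latent process that
#'   makes founder haplotypes locally similar; the second driver of LD.
#' @param missing_rate fraction of dosage entries masked as missing.
#' @param environments list of environment descriptors, each a list with
#'   `label` and additive mean shifts `spm2`, `gps`, `area` (mm2).
#' @param n_qtl_per_trait named counts of causal loci for `spm2`, `gps`,
#'   `tkw_pot` (grain-size potential) and `gsv` (dispersion-specific).
#' @param pleiotropy_spec list of character vectors; each element is a set
#'   of mean traits sharing one causal locus (counts toward each trait's
#'   `n_qtl_per_trait`).
#' @param effect_sd named per-trait effect-size scales (trait units for
#'   `spm2`, `gps`, `tkw_pot`; log-SD units for `gsv`).
#' @param effect_model `"normal"` draws effects N(0, effect_sd); `"fixed"`
#'   uses magnitude `effect_sd` with random sign (for planted large-effect
#'   scenarios).
#' @param qtl_placement `"random"` samples causal markers anywhere;
#'   `"spread"` assigns loci round-robin across chromosomes near
#'   alternating quarter positions, giving the well-separated layouts used
#'   in recovery experiments.
#' @param sigma_subblock,sigma_plot spatial and plot-residual SDs, expressed
#'   as multipliers of each trait's internal scale.
#' @param tradeoff_gamma source-limitation slope: mm2 of mean grain area
#'   lost per `gpm2_scale` extra grains per m2 (drives the GPM2-TKW
#'   trade-off).
#' @param tiller_params list controlling the two-level grain mixture:
#'   `sec_p0` baseline secondary-spike proportion, `sec_slope` its logit
#'   slope per SPM2 scale unit, `sec_shrink`/`dist_shrink` relative size
#'   reduction of secondary-spike and distal grains, `dist_p` distal
#'   proportion, `cap_k0`/`cap_k1` upper-tail cap (in within-plot SD units)
#'   and its tightening per SPM2 scale unit.
#' @param grains_min,grains_max bounds of the per-plot grain subsample.
#' @param prop_replicated fraction of non-check genotypes receiving one
#'   replicate plot.
#' @param seed integer seed; identical configurations and seeds give
#'   bit-identical outputs.
#' @param ... advanced overrides of the internal base levels and scales
#'   (`base_spm2`, `base_gps`, `base_area`, `scale_spm2`, `scale_gps`,
#'   `scale_area`, `sigma_area`, `gpm2_ref`, `gpm2_scale`, `tradeoff_sg`,
#'   `mass_slope`, `mass_intercept`, `mass_noise_sd`, `spm2_floor`,
#'   `gps_floor`, `area_floor`).
#' @return object of class `gv_sim_config`.
#' @export
sim_config <- function(n_genotypes = 300L, n_checks = 4L,
                       n_chromosomes = 3L, snps_per_chromosome = 1000L,
                       chromosome_length_bp = 6e8,
                       n_founder_haplotypes = 16L,
                       recomb_rate = 5e-9, founder_ld_bp = 3e7,
                       missing_rate = 0.01,
                       environments = default_environments(),
                       n_qtl_per_trait = c(spm2 = 8, gps = 8,
                                           tkw_pot = 8, gsv = 6),
                       pleiotropy_spec = list(c("spm2", "tkw_pot"),
                                              c("gps", "tkw_pot"),
                                              c("spm2", "gps", "tkw_pot")),
                       effect_sd = c(spm2 = 25, gps = 2, tkw_pot = 0.35,
                                     gsv = 0.10),
                       effect_model = c("normal", "fixed"),
                       qtl_placement = c("random", "spread"),
                       sigma_subblock = 0.3, sigma_plot = 0.5,
                       tradeoff_gamma = 2.5,
                       tiller_params = default_tiller_params(),
                       grains_min = 300L, grains_max = 500L,
                       prop_replicated = 0.25,
                       seed = 1L, ...) {
  cfg <- list(n_genotypes = as.integer(n_genotypes),
              n_checks = as.integer(n_checks),
              n_chromosomes = as.integer(n_chromosomes),
              snps_per_chromosome = as.integer(snps_per_chromosome),
              chromosome_length_bp = as.numeric(chromosome_length_bp),
              n_founder_haplotypes = as.integer(n_founder_haplotypes),
              recomb_rate = recomb_rate, founder_ld_bp = founder_ld_bp,
              missing_rate = missing_rate, environments = environments,
              n_qtl_per_trait = n_qtl_per_trait,
              pleiotropy_spec = pleiotropy_spec,
              effect_sd = effect_sd,
              effect_model = match.arg(effect_model),
              qtl_placement = match.arg(qtl_placement),
              sigma_subblock = sigma_subblock, sigma_plot = sigma_plot,
              tradeoff_gamma = tradeoff_gamma,
              tiller_params = utils::modifyList(default_tiller_params(),
                                                tiller_params),
              grains_min = as.integer(grains_min),
              grains_max = as.integer(grains_max),
              prop_replicated = prop_replicated,
              seed = as.integer(seed))
  base <- list(base_spm2 = 500, base_gps = 36, base_area = 16.9,
               scale_spm2 = 70, scale_gps = 5, scale_area = 0.6,
               sigma_area = 2.4, gpm2_ref = 18000, gpm2_scale = 7000,
               tradeoff_sg = 2.5, mass_slope = 3.0, mass_intercept = -12,
               mass_noise_sd = 4.2, spm2_floor = 50, gps_floor = 5,
               area_floor = 0.5)
  extra <- list(...)
  unknown <- setdiff(names(extra), names(base))
  if (length(unknown))
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "))
  cfg <- c(cfg, utils::modifyList(base, extra))
  class(cfg) <- "gv_sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_environments <- function() {
  list(list(label = "E1", spm2 = 100, gps = -4, area = 0.2),
       list(label = "E2", spm2 = -100, gps = 5, area = 0.05))
}

#' @rdname sim_config
#' @export
default_tiller_params <- function() {
  list(sec_p0 = 0.30, sec_slope = 0.8, sec_shrink = 0.10,
       dist_p = 0.35, dist_shrink = 0.08, cap_k0 = 2.3, cap_k1 = 0.8)
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_genotypes, cfg$n_checks, cfg$n_chromosomes,
              cfg$snps_per_chromosome, cfg$grains_min, cfg$grains_max)
  if (any(counts <= 0)) stop("invalid config: all counts must be positive")
  if (cfg$n_founder_haplotypes < 2L)
    stop("invalid config: need at least 2 founder haplotypes")
  if (cfg$grains_min > cfg$grains_max)
    stop("invalid config: grains_min must not exceed grains_max")
  probs <- c(cfg$recomb_rate, cfg$missing_rate, cfg$prop_replicated,
             cfg$tiller_params$sec_p0, cfg$tiller_params$dist_p)
  if (any(probs < 0) || any(probs > 1))
    stop("invalid config: probabilities must lie in [0, 1]")
  if (cfg$n_checks >= cfg$n_genotypes)
    stop("invalid config: checks must be fewer than genotypes")
  needed <- c("spm2", "gps", "tkw_pot", "gsv")
  if (!all(needed %in% names(cfg$n_qtl_per_trait)) ||
      !all(needed %in% names(cfg$effect_sd)))
    stop("invalid config: n_qtl_per_trait and effect_sd need entries for ",
         paste(needed, collapse = ", "))
  for (set in cfg$pleiotropy_spec)
    if (!all(set %in% c("spm2", "gps", "tkw_pot")))
      stop("invalid config: pleiotropy sets may only contain mean traits")
  invisible(cfg)
}

#' Simulate a genotype panel with chromosome-wise LD structure
#'
#' Each individual carries two haplotypes built as mosaics of founder
#' haplotypes with per-bp recombination probability `recomb_rate`.  Founder
#' haplotypes themselves are locally correlated (a latent AR(1) process with
#' correlation length `founder_ld_bp` thresholded at each marker's allele
#' frequency), so LD between markers decays with physical distance through
#' two channels: founder-level similarity and mosaic break-up.
#'
#' @param cfg a [sim_config()] object.
#' @return an object of class `gv_panel`: a list with `dosage` (n x m matrix
#'   in \{0,1,2\} with NA for missing entries), `map` (data.frame `marker`,
#'   `chrom`, `pos`, `maf`, `missing`), `chrom_len` and attribute
#'   `"complete"` holding the unmasked dosages (used as simulation truth).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "gv_sim_config"))
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_genotypes
  H <- 2L * n
  nf <- cfg$n_founder_haplotypes
  m_c <- cfg$snps_per_chromosome

  dos_list <- vector("list", cfg$n_chromosomes)
  map_list <- vector("list", cfg$n_chromosomes)
  for (chr in seq_len(cfg$n_chromosomes)) {
    pos <- sort(sample.int(cfg$chromosome_length_bp, m_c))
    gaps <- diff(pos)
    p <- stats::runif(m_c, 0.1, 0.9)

    # founder haplotypes: thresholded AR(1) latent Gaussian
    G <- matrix(0, nf, m_c)
    G[, 1] <- stats::rnorm(nf)
    rho <- exp(-gaps / cfg$founder_ld_bp)
    for (j in 2:m_c)
      G[, j] <- rho[j - 1] * G[, j - 1] +
        sqrt(1 - rho[j - 1]^2) * stats::rnorm(nf)
    FA <- sweep(G, 2, stats::qnorm(p), "<=") * 1L

    # mosaic of founders along each of the 2n haplotypes
    sw_p <- 1 - exp(-cfg$recomb_rate * gaps)
    f <- sample.int(nf, H, replace = TRUE)
    A <- matrix(0L, H, m_c)
    A[, 1] <- FA[cbind(f, 1L)]
    for (j in 2:m_c) {
      sw <- stats::runif(H) < sw_p[j - 1]
      if (any(sw)) f[sw] <- sample.int(nf, sum(sw), replace = TRUE)
      A[, j] <- FA[cbind(f, j)]
    }
    dos_list[[chr]] <- A[seq(1L, H, 2L), , drop = FALSE] +
      A[seq(2L, H, 2L), , drop = FALSE]
    map_list[[chr]] <- data.frame(
      marker = sprintf("M%d_%04d", chr, seq_len(m_c)),
      chrom = paste0("C", chr), pos = pos, stringsAsFactors = FALSE)
  }
  dosage <- do.call(cbind, dos_list)
  map <- do.call(rbind, map_list)
  rownames(map) <- NULL
  rownames(dosage) <- sprintf("G%03d", seq_len(n))
  colnames(dosage) <- map$marker

  complete <- dosage
  masked <- dosage
  if (cfg$missing_rate > 0) {
    miss <- stats::runif(length(masked)) < cfg$missing_rate
    masked[miss] <- NA_integer_
  }
  chrom_len <- stats::setNames(rep(cfg$chromosome_length_bp,
                                   cfg$n_chromosomes),
                               paste0("C", seq_len(cfg$n_chromosomes)))
  panel <- new_panel(masked, map, chrom_len)
  attr(panel, "complete") <- complete
  panel
}

# pick causal loci and draw their effects; returns the truth qtl table and
# the n x 4 matrix of per-genotype genetic values
plant_qtl <- function(cfg, panel) {
  dos <- attr(panel, "complete")
  if (is.null(dos)) dos <- impute_missing(panel)$dosage
  freq <- colMeans(dos) / 2
  maf <- pmin(freq, 1 - freq)
  eligible <- which(maf >= 0.15)
  if (!length(eligible)) stop("no polymorphic markers to place QTL on")

  traits <- c("spm2", "gps", "tkw_pot", "gsv")
  nq <- cfg$n_qtl_per_trait[traits]
  n_shared <- vapply(traits, function(tr)
    sum(vapply(cfg$pleiotropy_spec, function(s) tr %in% s, logical(1))),
    numeric(1))
  n_own <- pmax(nq - n_shared, 0)
  n_loci <- length(cfg$pleiotropy_spec) + sum(n_own)
  if (n_loci > length(eligible))
    stop("not enough eligible markers for the requested QTL counts")
  if (cfg$qtl_placement == "spread") {
    chroms <- unique(panel$map$chrom)
    loci <- integer(n_loci)
    for (k in seq_len(n_loci)) {
      ch <- chroms[(k - 1L) %% length(chroms) + 1L]
      frac <- if (((k - 1L) %/% length(chroms)) %% 2L == 0L) 0.3 else 0.7
      target <- frac * cfg$chromosome_length_bp
      cand <- setdiff(eligible[panel$map$chrom[eligible] == ch], loci)
      if (!length(cand)) cand <- setdiff(eligible, loci)
      loci[k] <- cand[which.min(abs(panel$map$pos[cand] - target))]
    }
  } else {
    loci <- sample(eligible, n_loci)
  }

  draw_effect <- function(tr) {
    s <- cfg$effect_sd[[tr]]
    if (cfg$effect_model == "fixed") s * sample(c(-1, 1), 1)
    else stats::rnorm(1, 0, s)
  }
  rows <- list(); k <- 0L
  for (set in cfg$pleiotropy_spec) {
    k <- k + 1L
    for (tr in set)
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, marker_index = loci[k], effect = draw_effect(tr),
        pleiotropic = TRUE, stringsAsFactors = FALSE)
  }
  for (tr in traits) {
    for (i in seq_len(n_own[[tr]])) {
      k <- k + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, marker_index = loci[k], effect = draw_effect(tr),
        pleiotropic = FALSE, stringsAsFactors = FALSE)
    }
  }
  qtl <- do.call(rbind, rows)
  qtl$marker <- panel$map$marker[qtl$marker_index]
  qtl$chrom <- panel$map$chrom[qtl$marker_index]
  qtl$pos <- panel$map$pos[qtl$marker_index]

  W <- dos - 1  # centre at the heterozygote
  gv <- sapply(traits, function(tr) {
    sub <- qtl[qtl$trait == tr, , drop = FALSE]
    if (!nrow(sub)) return(numeric(nrow(dos)))
    drop(W[, sub$marker_index, drop = FALSE] %*% sub$effect)
  })
  rownames(gv) <- rownames(dos)
  list(qtl = qtl, genotype_values = gv)
}

# augmented layout for one environment: 4 blocks x 2 sub-blocks, checks
# replicated three times per block, a fraction of the others replicated once
build_layout <- function(cfg, geno_ids) {
  n_blocks <- 4L; sb_per_block <- 2L
  checks <- geno_ids[seq_len(cfg$n_checks)]
  others <- geno_ids[-seq_len(cfg$n_checks)]
  sb_all <- paste0("SB", seq_len(n_blocks * sb_per_block))
  sb_of_block <- split(sb_all, rep(seq_len(n_blocks), each = sb_per_block))

  rows <- list()
  for (b in seq_len(n_blocks)) {
    for (ck in checks) {
      sb <- sample(rep(sb_of_block[[b]], length.out = 3L))
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = ck, block = paste0("B", b), subblock = sb,
        rep = seq_len(3L), is_check = TRUE, stringsAsFactors = FALSE)
    }
  }
  # unreplicated entries spread round-robin over the 8 sub-blocks
  sb_assign <- rep(sb_all, length.out = length(others))
  rows[[length(rows) + 1L]] <- data.frame(
    genotype = others, block = NA_character_, subblock = sb_assign,
    rep = 1L, is_check = FALSE, stringsAsFactors = FALSE)
  n_rep <- round(cfg$prop_replicated * length(others))
  if (n_rep > 0) {
    reps <- sample(others, n_rep)
    sb_rep <- sample(sb_all, n_rep, replace = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      genotype = reps, block = NA_character_, subblock = sb_rep, rep = 2L,
      is_check = FALSE, stringsAsFactors = FALSE)
  }
  lay <- do.call(rbind, rows)
  blk_of_sb <- stats::setNames(rep(paste0("B", seq_len(n_blocks)),
                                   each = sb_per_block), sb_all)
  lay$block <- blk_of_sb[lay$subblock]
  lay
}

#' Simulate an augmented field trial with individual grain populations
#'
#' Generates, for every environment in the configuration, an augmented
#' layout and plot-level traits, then draws each plot's individual grain
#' areas from a two-level mixture (main vs secondary spikes, proximal vs
#' distal grain positions) whose upper tail is capped more tightly as spike
#' density grows.  The cap reproduces the canopy-driven loss of the largest
#' grains, which is what makes the spike density / grain-size-variance
#' correlation emerge negative.  Thousand-kernel weight is back-computed
#' from grain areas through a noisy linear area-to-mass link and expressed
#' at 15% humidity; grain yield is the exact product
#' `GY = GPM2 * TKW / 1e5` (t/ha).
#'
#' @param cfg a [sim_config()] object.
#' @param panel the matching [simulate_genotypes()] output.
#' @return list of class `gv_trial` with `plots` (design + measured traits),
#'   `grains` (long table `plot_id`, `area_mm2`) and `truth` (planted QTL,
#'   genotype genetic values, spatial effects, variance components, exact
#'   per-plot GPS/GPM2, and clipping log).
#' @export
simulate_trial <- function(cfg, panel) {
  stopifnot(inherits(cfg, "gv_sim_config"), inherits(panel, "gv_panel"))
  if (nrow(panel$dosage) != cfg$n_genotypes)
    stop("panel has ", nrow(panel$dosage), " genotypes but cfg expects ",
         cfg$n_genotypes)
  set.seed(cfg$seed + 1L)
  planted <- plant_qtl(cfg, panel)
  gv <- planted$genotype_values
  geno_ids <- rownames(panel$dosage)
  tp <- cfg$tiller_params
  clip_log <- c(spm2 = 0L, gps = 0L)

  plots_all <- list(); grains_all <- list(); spatial_all <- list()
  comp_all <- list()
  for (e in seq_along(cfg$environments)) {
    env <- cfg$environments[[e]]
    lay <- build_layout(cfg, geno_ids)
    np <- nrow(lay)
    lay$env <- env$label
    lay$plot_id <- sprintf("%s_P%03d", env$label, seq_len(np))

    sb_levels <- sort(unique(lay$subblock))
    sb_base <- stats::setNames(stats::rnorm(length(sb_levels)), sb_levels)
    sbv <- sb_base[lay$subblock]
    gidx <- match(lay$genotype, geno_ids)

    spm2 <- cfg$base_spm2 + env$spm2 + gv[gidx, "spm2"] +
      cfg$scale_spm2 * (cfg$sigma_subblock * sbv +
                          cfg$sigma_plot * stats::rnorm(np))
    clip_log["spm2"] <- clip_log["spm2"] + sum(spm2 < cfg$spm2_floor)
    spm2 <- pmax(spm2, cfg$spm2_floor)
    zs <- (spm2 - cfg$base_spm2 - env$spm2) / cfg$scale_spm2

    gps <- cfg$base_gps + env$gps + gv[gidx, "gps"] -
      cfg$tradeoff_sg * zs +
      cfg$scale_gps * (cfg$sigma_subblock * sbv +
                         cfg$sigma_plot * stats::rnorm(np))
    clip_log["gps"] <- clip_log["gps"] + sum(gps < cfg$gps_floor)
    gps <- pmax(gps, cfg$gps_floor)
    gpm2 <- spm2 * gps

    mu_area <- cfg$base_area + env$area -
      cfg$tradeoff_gamma * (gpm2 - cfg$gpm2_ref) / cfg$gpm2_scale +
      gv[gidx, "tkw_pot"] +
      cfg$scale_area * (cfg$sigma_subblock * sbv +
                          0.5 * cfg$sigma_plot * stats::rnorm(np))
    sigma_area <- cfg$sigma_area * exp(gv[gidx, "gsv"])

    p_sec <- stats::plogis(stats::qlogis(tp$sec_p0) + tp$sec_slope * zs)
    cap_c <- pmax(tp$cap_k0 - tp$cap_k1 * zs, 0.3)

    n_g <- if (cfg$grains_min == cfg$grains_max) rep(cfg$grains_min, np)
           else sample(seq(cfg$grains_min, cfg$grains_max), np,
                       replace = TRUE)
    pid <- rep(seq_len(np), n_g)
    d_sec <- tp$sec_shrink * cfg$base_area
    d_dist <- tp$dist_shrink * cfg$base_area
    centre <- p_sec * d_sec + tp$dist_p * d_dist
    is_sec <- stats::runif(length(pid)) < p_sec[pid]
    is_dist <- stats::runif(length(pid)) < tp$dist_p
    g_mean <- mu_area[pid] + centre[pid] - is_sec * d_sec - is_dist * d_dist
    g_sd <- sigma_area[pid]
    cap_abs <- mu_area[pid] + cap_c[pid] * g_sd
    area <- stats::rnorm(length(pid), g_mean, g_sd)
    bad <- which(area > cap_abs | area < cfg$area_floor)
    iter <- 0L
    while (length(bad) && iter < 1000L) {  # soft truncation by resampling
      area[bad] <- stats::rnorm(length(bad), g_mean[bad], g_sd[bad])
      bad <- bad[area[bad] > cap_abs[bad] | area[bad] < cfg$area_floor]
      iter <- iter + 1L
    }
    if (length(bad)) area[bad] <- pmin(pmax(g_mean[bad], cfg$area_floor),
                                       cap_abs[bad])

    mass <- pmax(cfg$mass_slope * area + cfg$mass_intercept +
                   stats::rnorm(length(area), 0, cfg$mass_noise_sd), 0.5)
    tkw_dry <- vapply(split(mass, pid), mean, numeric(1))
    tkw <- to_15pc_humidity(tkw_dry[as.character(seq_len(np))])
    gy <- gpm2 * tkw / 1e5

    plots_all[[e]] <- data.frame(
      plot_id = lay$plot_id, genotype = lay$genotype, env = lay$env,
      block = lay$block, subblock = lay$subblock, rep = lay$rep,
      is_check = lay$is_check, spm2 = spm2, tkw = as.numeric(tkw),
      gy = as.numeric(gy), stringsAsFactors = FALSE)
    grains_all[[e]] <- data.frame(plot_id = lay$plot_id[pid],
                                  area_mm2 = area,
                                  stringsAsFactors = FALSE)
    spatial_all[[e]] <- data.frame(env = env$label, subblock = sb_levels,
                                   value = as.numeric(sb_base),
                                   stringsAsFactors = FALSE)
    comp_all[[e]] <- data.frame(plot_id = lay$plot_id, gps = gps,
                                gpm2 = gpm2, mu_area = mu_area,
                                sigma_area = sigma_area,
                                stringsAsFactors = FALSE)
  }

  plots <- do.call(rbind, plots_all); rownames(plots) <- NULL
  grains <- do.call(rbind, grains_all); rownames(grains) <- NULL
  vc <- data.frame(
    trait = c("spm2", "gps", "tkw_pot", "gsv"),
    sigma2_G = apply(gv, 2, stats::var),
    sigma2_eps = c((cfg$sigma_plot * cfg$scale_spm2)^2,
                   (cfg$sigma_plot * cfg$scale_gps)^2,
                   (0.5 * cfg$sigma_plot * cfg$scale_area)^2, NA),
    stringsAsFactors = FALSE)
  truth <- list(qtl = planted$qtl, genotype_values = gv,
                spatial_effects = do.call(rbind, spatial_all),
                variance_components = vc,
                plot_components = do.call(rbind, comp_all),
                clipped = clip_log)
  structure(list(plots = plots, grains = grains, truth = truth),
            class = "gv_trial")
}
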