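test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_founder_haplotypes = 1), "2 founder")
  expect_error(sim_config(grains_min = 500, grains_max = 300),
               "grains_min")
  expect_error(sim_config(missing_rate = 1.5), "probabilities")
  expect_error(sim_config(n_genotypes = 0), "counts")
  expect_error(sim_config(nonsense_field = 1), "unknown configuration")
})

test_that("the generator is bit-identical under a fixed seed", {
  cfg <- small_cfg(seed = 5)
  p1 <- simulate_genotypes(cfg)
  p2 <- simulate_genotypes(cfg)
  expect_identical(p1$dosage, p2$dosage)
  expect_identical(p1$map, p2$map)
  t1 <- simulate_trial(cfg, p1)
  t2 <- simulate_trial(cfg, p2)
  expect_identical(t1$plots, t2$plots)
  expect_identical(t1$grains, t2$grains)
  expect_identical(t1$truth$qtl, t2$truth$qtl)
})

test_that("dosages, map ordering and missingness obey the contract", {
  cfg <- small_cfg(seed = 2, missing_rate = 0.05)
  p <- simulate_genotypes(cfg)
  expect_true(all(p$dosage %in% c(0, 1, 2) | is.na(p$dosage)))
  expect_false(is.unsorted(order(p$map$chrom, p$map$pos)))
  expect_gt(mean(is.na(p$dosage)), 0.02)
  expect_lt(mean(is.na(p$dosage)), 0.08)
  expect_true(all(p$map$maf >= 0 & p$map$maf <= 0.5))
})

test_that("zero recombination with two founders gives complete LD", {
  cfg <- sim_config(n_genotypes = 60, n_chromosomes = 2,
                    snps_per_chromosome = 40, n_founder_haplotypes = 2,
                    recomb_rate = 0, missing_rate = 0, seed = 3)
  p <- simulate_genotypes(cfg)
  for (ch in c("C1", "C2")) {
    idx <- which(p$map$chrom == ch)
    poly <- idx[apply(p$dosage[, idx], 2, sd) > 0]
    r2 <- pairwise_r2(p, poly)
    expect_true(all(abs(r2[upper.tri(r2)] - 1) < 1e-12))
  }
})

test_that("LD decays with physical distance", {
  # dense map so that close pairs (< 10 kb) exist
  cfg <- sim_config(n_genotypes = 150, n_chromosomes = 2,
                    snps_per_chromosome = 300, chromosome_length_bp = 2e6,
                    missing_rate = 0, seed = 4)
  p <- simulate_genotypes(cfg)
  set.seed(1)
  # oracle: direct r2 on sampled close and inter-chromosomal pairs
  close_r2 <- c(); inter_r2 <- c()
  for (k in 1:1000) {
    i <- sample(ncol(p$dosage), 1)
    same <- which(p$map$chrom == p$map$chrom[i] &
                    abs(p$map$pos - p$map$pos[i]) < 1e4 &
                    seq_len(ncol(p$dosage)) != i)
    diff <- which(p$map$chrom != p$map$chrom[i])
    if (length(same)) {
      j <- same[sample(length(same), 1)]
      r <- suppressWarnings(cor(p$dosage[, i], p$dosage[, j]))
      if (!is.na(r)) close_r2 <- c(close_r2, r^2)
    }
    j <- diff[sample(length(diff), 1)]
    r <- suppressWarnings(cor(p$dosage[, i], p$dosage[, j]))
    if (!is.na(r)) inter_r2 <- c(inter_r2, r^2)
  }
  expect_gt(length(close_r2), 100)
  expect_gt(mean(close_r2), mean(inter_r2))
})

test_that("grain count bounds are honoured exactly", {
  cfg <- small_cfg(seed = 6, grains_min = 400, grains_max = 400)
  tr <- simulate_trial(cfg, simulate_genotypes(cfg))
  counts <- table(tr$grains$plot_id)
  expect_true(all(counts == 400))
})

test_that("the degenerate generator collapses grain-size means", {
  cfg <- small_cfg(
    seed = 8, missing_rate = 0, tradeoff_gamma = 0,
    sigma_subblock = 0, sigma_plot = 0,
    effect_sd = c(spm2 = 25, gps = 2, tkw_pot = 0.35, gsv = 0),
    tiller_params = list(sec_slope = 0, sec_shrink = 0, dist_shrink = 0,
                         cap_k0 = 50, cap_k1 = 0),
    environments = list(list(label = "E1", spm2 = 0, gps = 0, area = 0)))
  tr <- simulate_trial(cfg, simulate_genotypes(cfg))
  comp <- tr$truth$plot_components
  comp$genotype <- tr$plots$genotype[match(comp$plot_id,
                                           tr$plots$plot_id)]
  mu_range <- tapply(comp$mu_area, comp$genotype,
                     function(v) diff(range(v)))
  expect_true(all(mu_range < 1e-12))
  # GSV varies across a genotype's plots only by sampling error
  gm <- grain_metrics_table(tr$grains)
  gm$genotype <- tr$plots$genotype[match(gm$plot_id, tr$plots$plot_id)]
  reps <- names(which(table(gm$genotype) >= 3))
  rel_sd <- sapply(reps, function(g) {
    v <- gm$gsv[gm$genotype == g]
    sd(v) / mean(v)
  })
  # chi-square sampling error of a variance over ~400 grains is ~7%
  expect_lt(median(rel_sd), 0.15)
})

test_that("planted truth indexes real markers with finite effects", {
  cfg <- small_cfg(seed = 9)
  p <- simulate_genotypes(cfg)
  tr <- simulate_trial(cfg, p)
  q <- tr$truth$qtl
  expect_true(all(q$marker %in% p$map$marker))
  expect_true(all(is.finite(q$effect)))
  expect_identical(p$map$pos[match(q$marker, p$map$marker)], q$pos)
  expect_equal(sort(unique(q$trait)),
               sort(c("spm2", "gps", "tkw_pot", "gsv")))
})

test_that("dispersion loci move GSV but not the mean traits", {
  # one strong dispersion locus, no mean-trait QTL: allele classes must
  # differ in GSV and not (beyond Monte-Carlo error) in SPM2/GPS/TKW
  cfg <- sim_config(
    n_genotypes = 200, n_chromosomes = 2, snps_per_chromosome = 150,
    seed = 10, missing_rate = 0, effect_model = "fixed",
    n_qtl_per_trait = c(spm2 = 1, gps = 1, tkw_pot = 1, gsv = 1),
    pleiotropy_spec = list(),
    effect_sd = c(spm2 = 0, gps = 0, tkw_pot = 0, gsv = 0.4),
    environments = list(list(label = "E1", spm2 = 0, gps = 0, area = 0)))
  p <- simulate_genotypes(cfg)
  tr <- simulate_trial(cfg, p)
  locus <- tr$truth$qtl$marker[tr$truth$qtl$trait == "gsv"]
  dos <- attr(p, "complete")[, locus]
  gm <- grain_metrics_table(tr$grains)
  d <- merge(tr$plots, gm, by = "plot_id")
  d$dose <- dos[d$genotype]
  d <- d[d$dose != 1, ]
  gsv_by <- tapply(d$gsv, d$dose, mean)
  expect_gt(abs(diff(range(gsv_by))) / min(gsv_by), 0.2)
  for (trait in c("spm2", "tkw")) {
    tt <- t.test(d[[trait]][d$dose == 0], d[[trait]][d$dose == 2])
    expect_gt(tt$p.value, 0.01)
  }
})

test_that("negative spike-density / GSV correlation emerges at defaults", {
  # quick sign check on a reduced panel; the full default-scale version
  # runs in the acceptance suite
  neg <- 0
  for (s in 1:5) {
    cfg <- sim_config(n_genotypes = 150, n_chromosomes = 2,
                      snps_per_chromosome = 200, seed = 100 + s,
                      environments = default_environments()[1])
    tr <- simulate_trial(cfg, simulate_genotypes(cfg))
    plots <- merge(tr$plots, grain_metrics_table(tr$grains),
                   by = "plot_id", sort = FALSE)
    adj_s <- adjusted_means(plots, "spm2")
    adj_v <- adjusted_means(plots, "gsv")
    r <- cor(adj_s$value, adj_v$value[match(adj_s$genotype,
                                            adj_v$genotype)])
    if (r < 0) neg <- neg + 1
  }
  expect_gte(neg, 4)
})
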