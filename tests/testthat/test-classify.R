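make_qtl_row <- function(qtl, chrom, start, end, members) {
  data.frame(qtl = qtl, chrom = chrom, start = start, end = end,
             core_start = start, core_end = end,
             size_mb = (end - start) / 1e6,
             n_snps = length(strsplit(members, ",")[[1]]),
             members = members, stringsAsFactors = FALSE)
}

test_that("driven/specific classification follows the colocalisation
           rule", {
  q <- rbind(make_qtl_row(1, "C1", 10e6, 60e6, "a,b"),
             make_qtl_row(2, "C2", 100e6, 150e6, "c"))
  hits <- data.frame(marker = "tkw_snp", chrom = "C1", pos = 30e6,
                     trait = "tkw", stringsAsFactors = FALSE)
  cl <- classify_qtl(q, hits, "E1")
  expect_equal(cl$class, c("driven", "specific"))
  expect_equal(cl$coloc_traits, c("tkw", ""))

  # empty overlap: everything specific
  none <- classify_qtl(q, hits[0, ], "E1")
  expect_true(all(none$class == "specific"))

  # member rule: position inside the interval is not enough
  cl_m <- classify_qtl(q, hits, "E1", rule = "members")
  expect_equal(cl_m$class, c("specific", "specific"))
  hits_m <- data.frame(marker = "b", chrom = "C1", pos = 55e6,
                       trait = "spm2", stringsAsFactors = FALSE)
  expect_equal(classify_qtl(q, hits_m, "E1", rule = "members")$class,
               c("driven", "specific"))

  # unknown component label is a configuration error
  bad <- data.frame(marker = "x", chrom = "C1", pos = 1, trait = "height")
  expect_error(classify_qtl(q, bad, "E1"), "unknown yield-component")
})

test_that("cross-environment commonality is shared-SNP based and the
           tallies partition", {
  qa <- classify_qtl(rbind(make_qtl_row(1, "C1", 1e6, 9e6, "a,b"),
                           make_qtl_row(2, "C2", 1e6, 9e6, "c,d")),
                     data.frame(marker = "z", chrom = "C1", pos = 2e6,
                                trait = "tkw"), "E1")
  qb_same <- classify_qtl(rbind(make_qtl_row(1, "C1", 2e6, 8e6, "b"),
                                make_qtl_row(2, "C2", 1e6, 9e6, "d")),
                          data.frame(marker = "z", chrom = "C1",
                                     pos = 2e6, trait = "tkw")[0, ], "E2")
  cx <- cross_environment(list(E1 = qa, E2 = qb_same))
  expect_true(all(cx$qtl$common_env))       # all share a member SNP

  qb_disj <- classify_qtl(make_qtl_row(1, "C1", 2e6, 8e6, "x,y"),
                          data.frame(marker = character(0),
                                     chrom = character(0),
                                     pos = numeric(0),
                                     trait = character(0)), "E2")
  cx2 <- cross_environment(list(E1 = qa, E2 = qb_disj))
  expect_false(any(cx2$qtl$common_env))

  # class tallies always sum to the total row
  t2 <- cx2$tally
  expect_equal(t2$n[t2$class == "total"],
               sum(t2$n[t2$class != "total"]))
  expect_equal(t2$pct[t2$class == "total"], 100)
})

test_that("peak selection keeps the strongest-effect member with the
           documented tie-breaks", {
  assoc <- data.frame(
    marker = c("a", "b", "c", "d"), chrom = "C1",
    pos = c(1e6, 2e6, 3e6, 4e6), lod = c(4, 6, 5, 8),
    effect = c(0.4, -0.9, 0.9, 0.2), maf = 0.3,
    stringsAsFactors = FALSE)
  q1 <- make_qtl_row(1, "C1", 1e6, 1e6, "a")          # singleton
  expect_equal(peak_selection(q1, assoc)$sel_snp, "a")
  q2 <- make_qtl_row(2, "C1", 1e6, 2e6, "a,b")        # |0.9| beats |0.4|
  expect_equal(peak_selection(q2, assoc)$sel_snp, "b")
  q3 <- make_qtl_row(3, "C1", 2e6, 3e6, "b,c")        # tie -> lower LOD loses
  expect_equal(peak_selection(q3, assoc)$sel_snp, "b")
  expect_equal(peak_selection(q3, assoc, rule = "lod")$sel_snp, "b")
  q4 <- make_qtl_row(4, "C1", 1e6, 4e6, "a,d")
  expect_equal(peak_selection(q4, assoc, rule = "lod")$sel_snp, "d")
})

test_that("variance partition is a nested-model decomposition", {
  # exactly orthogonal dosages: a full 2^6 factorial of hom/hom calls
  bits <- as.matrix(expand.grid(rep(list(c(0, 2)), 6)))
  pan <- toy_panel(bits)
  ids <- rownames(pan$dosage)
  snps <- pan$map$marker
  classes <- rep(c("specific", "driven"), each = 3)
  set.seed(21)
  betas <- c(0.8, 0.6, 0.7, 0.5, 0.9, 0.4)
  y <- drop(pan$dosage %*% betas) + rnorm(length(ids))
  adj <- data.frame(genotype = ids, value = y, stringsAsFactors = FALSE)
  peaks <- data.frame(sel_snp = snps, class = classes,
                      stringsAsFactors = FALSE)
  vp <- variance_partition(adj, pan, peaks, env = "E1")
  expect_lte(vp$r2_specific, vp$r2_all)
  expect_lte(vp$r2_driven, vp$r2_all)
  expect_gt(vp$r2_all, 0.3)

  # orthogonal decomposition: r2_all equals the sum of single-SNP r2
  singles <- vapply(snps, function(s)
    summary(lm(y ~ pan$dosage[, s]))$r.squared, numeric(1))
  expect_lt(abs(vp$r2_all - sum(singles)), 0.02)

  # null: unrelated SNPs explain almost nothing
  pan0 <- independent_panel(n = 300, m_per_chr = 40, seed = 20)
  ids0 <- rownames(pan0$dosage)
  low <- 0
  for (s in 1:20) {
    set.seed(500 + s)
    y0 <- rnorm(length(ids0))
    adj0 <- data.frame(genotype = ids0, value = y0)
    vp0 <- variance_partition(adj0, pan0,
                              data.frame(sel_snp = pan0$map$marker[1:10],
                                         class = "specific"), "E1")
    if (vp0$r2_all < 0.1) low <- low + 1
  }
  expect_gte(low, 18)
})

test_that("forward-AIC selection finds strong predictors and stays
           parsimonious", {
  pan <- independent_panel(n = 200, m_per_chr = 20, seed = 22)
  X <- pan$dosage[, 1:8]
  set.seed(23)
  y <- 1.2 * X[, 3] + rnorm(200)
  st <- stepwise_opt(y, X)
  # oracle: exhaustive single-step AIC says which predictor enters first
  first_aics <- vapply(seq_len(8), function(j)
    AIC(lm(y ~ X[, j])), numeric(1))
  expect_equal(st$selected[1], colnames(X)[which.min(first_aics)])
  expect_equal(st$selected[1], colnames(X)[3])
  expect_lte(st$r2_opt, summary(lm(y ~ X))$r.squared + 1e-9)

  # pure noise: near-empty selections.  AIC admits a null predictor with
  # probability ~0.157, so with 8 candidates P(<=2 selected) ~ 0.89 and
  # the expected count is ~1.3; the thresholds below are the 5th
  # percentiles of those binomials over 20 seeds
  n_sel <- vapply(1:20, function(s) {
    set.seed(900 + s)
    stepwise_opt(rnorm(200), X)$n_selected
  }, numeric(1))
  expect_gte(sum(n_sel <= 2), 15)
  expect_lte(mean(n_sel), 2)
})

test_that("forward selection is near-optimal against exhaustive best
           subsets", {
  pan <- independent_panel(n = 120, m_per_chr = 20, seed = 24)
  X <- pan$dosage[, seq(1, 36, by = 5)]  # 8 candidates
  ok <- 0
  for (s in 1:15) {
    set.seed(1200 + s)
    beta <- rexp(8, 4) * rbinom(8, 1, 0.4)
    y <- drop(X %*% beta) + rnorm(120)
    st <- stepwise_opt(y, X)
    aic_fwd <- st$aic
    aic_best <- oracle_best_subset_aic(y, X)
    if (aic_fwd - aic_best <= 2) ok <- ok + 1
  }
  expect_gte(ok, 13)
})
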