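test_that("pairwise r2 equals the squared hand-computed correlation", {
  x <- c(0, 1, 2, 2, 0, 1, 2, 0)
  y <- c(0, 0, 2, 1, 1, 1, 2, 0)
  pan <- toy_panel(cbind(x, y, flip = 2 - x, dup = x,
                         const = rep(1, 8)))
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_warning(r2 <- pairwise_r2(pan, c("S01", "S02", "S03", "S04",
                                          "S05")))
  expect_equal(r2["S01", "S02"], r_hand^2, tolerance = 1e-12)
  expect_equal(r2["S01", "S04"], 1)           # identical columns
  expect_equal(r2["S01", "S03"], 1)           # 0<->2 coding flip
  expect_true(all(is.na(r2["S05", ])))        # zero variance flagged
})

test_that("critical LD follows the stated percentile conventions", {
  r2 <- seq(0.01, 1, by = 0.01)
  emp <- critical_from_r2(r2, "empirical-95th")
  expect_equal(emp$value, oracle_quantile7(r2, 0.95), tolerance = 1e-12)
  par <- critical_from_r2(r2, "parametric-sqrt")
  s <- sqrt(r2)
  expect_equal(par$value,
               min((mean(s) + qnorm(0.95) * sd(s))^2, 1),  # clamped to [0,1]
               tolerance = 1e-12)
  par2 <- critical_from_r2(r2 / 4, "parametric-sqrt")
  s2 <- sqrt(r2 / 4)
  expect_equal(par2$value, (mean(s2) + qnorm(0.95) * sd(s2))^2,
               tolerance = 1e-12)

  # independent markers, many individuals: background LD is tiny
  pan <- independent_panel(n = 500, m_per_chr = 80, seed = 8)
  crit <- critical_ld(pan, 400, seed = 9)
  expect_lt(crit$value, 0.05)
  expect_gte(crit$value, 0)

  # bounds hold on an arbitrary (high-LD) panel
  cfg <- small_cfg(seed = 10, missing_rate = 0)
  pan2 <- impute_missing(qc_filter(simulate_genotypes(cfg)))
  crit2 <- critical_ld(pan2, 300, seed = 11)
  expect_true(crit2$value >= 0 && crit2$value <= 1)
})

test_that("LD pruning is the documented greedy scan", {
  # duplicated and triplicated columns collapse to one representative
  x <- c(0, 1, 2, 2, 0, 1, 0, 2, 1, 1)
  y <- c(2, 1, 0, 1, 2, 0, 1, 0, 2, 2)
  pan <- toy_panel(cbind(a = x, b = x, c = x, d = y))
  pruned <- prune_redundant(pan, 0.9)
  expect_equal(ncol(pruned$dosage), 2L)
  expect_setequal(pruned$map$marker, c("S01", "S04"))

  # greedy hand-trace oracle on a random 6-marker chromosome
  set.seed(12)
  M <- matrix(rbinom(60 * 6, 2, 0.4), 60, 6)
  M[, 2] <- M[, 1]; M[, 5] <- ifelse(runif(60) < 0.95, M[, 4],
                                     rbinom(60, 2, 0.4))
  pan2 <- toy_panel(M)
  pruned2 <- prune_redundant(pan2, 0.9)
  r2 <- suppressWarnings(cor(M)^2)
  kept <- integer(0)
  for (j in 1:6) {
    if (sd(M[, j]) == 0) next
    if (!length(kept) || all(r2[kept, j] <= 0.9)) kept <- c(kept, j)
  }
  expect_equal(pruned2$map$marker, sprintf("S%02d", kept))

  # postcondition: no retained pair above the threshold
  pan3 <- impute_missing(qc_filter(simulate_genotypes(
    small_cfg(seed = 13, missing_rate = 0))))
  pr <- prune_redundant(pan3, 0.9)
  for (ch in unique(pr$map$chrom)) {
    r2c <- pairwise_r2(pr, pr$map$marker[pr$map$chrom == ch])
    expect_lte(max(r2c[upper.tri(r2c)]), 0.9)
  }
})

test_that("LD-block clustering matches a brute-force average-linkage
           oracle", {
  # singleton input: one block of width zero
  pan <- independent_panel(n = 60, m_per_chr = 30, seed = 14)
  one <- data.frame(marker = pan$map$marker[3], chrom = pan$map$chrom[3],
                    pos = pan$map$pos[3])
  b <- ld_blocks(one, pan, 0.2)
  expect_equal(nrow(b), 1L)
  expect_equal(b$start, b$end)

  # two perfectly correlated SNPs always form one block
  x <- c(0, 1, 2, 0, 1, 2, 1, 0)
  pan2 <- toy_panel(cbind(a = x, b = x, c = rev(x)))
  two <- data.frame(marker = c("S01", "S02"), chrom = "C1",
                    pos = c(1e6, 2e6))
  expect_equal(nrow(ld_blocks(two, pan2, 0.99)), 1L)

  # random 4-SNP instances against the enumeration oracle
  for (s in 1:10) {
    pan3 <- independent_panel(n = 50, m_per_chr = 20, n_chr = 1,
                              seed = 100 + s)
    pick <- sort(sample(ncol(pan3$dosage), 4))
    sig <- pan3$map[pick, c("marker", "chrom", "pos")]
    crit <- 0.3
    blocks <- ld_blocks(sig, pan3, crit)
    r2 <- pairwise_r2(pan3, sig$marker)
    memb_oracle <- oracle_avg_linkage(1 - r2, 1 - crit)
    memb_mine <- integer(4)
    for (i in seq_len(nrow(blocks))) {
      ms <- strsplit(blocks$members[i], ",")[[1]]
      memb_mine[match(ms, sig$marker)] <- i
    }
    expect_true(same_partition(memb_mine, memb_oracle))
  }
})

test_that("Hill-Weir decay fitting recovers rho and solves the crossing", {
  n_ind <- 300
  rho_true <- 2e-7
  d <- seq(1e4, 3e8, length.out = 400)
  r2_curve <- grainvar:::hill_weir_er2(rho_true * d, n_ind)
  fit <- fit_ld_decay_points(d, r2_curve, n_ind)
  expect_lt(abs(fit$rho - rho_true) / rho_true, 0.05)

  # fitted curve decreases monotonically in distance
  grid <- fit$predict(seq(1, 1e9, length.out = 200))
  expect_true(all(diff(grid) < 0))

  # crossing satisfies the defining equation
  crit <- 0.1
  d_star <- fit$crossing(crit)
  expect_lt(abs(fit$predict(d_star) - crit), 1e-6)
  # never-crossed case flagged as Inf
  expect_equal(fit$crossing(1e-9), Inf)
  # panel-driven path runs end to end
  pan <- impute_missing(qc_filter(simulate_genotypes(
    small_cfg(seed = 15, missing_rate = 0))))
  fit2 <- fit_ld_decay(pan, n_pairs = 500, seed = 16)
  expect_gt(fit2$rho, 0)
})

test_that("QTL construction extends, clips and merges like a sweep-line
           oracle", {
  blocks <- data.frame(
    block = 1:2, chrom = c("C1", "C1"),
    start = c(10e6, 200e6), end = c(20e6, 210e6), n_snps = c(2L, 1L),
    members = c("a,b", "c"), stringsAsFactors = FALSE)
  # far apart with small extension: two QTL
  q <- build_qtl(blocks, 1e6)
  expect_equal(nrow(q), 2L)
  # large extension: extensions overlap, one merged QTL spanning both
  q2 <- build_qtl(blocks, 95e6)
  expect_equal(nrow(q2), 1L)
  expect_equal(q2$start, 1)              # clipped at 1
  expect_equal(q2$end, 210e6 + 95e6)
  expect_equal(q2$n_snps, 3L)

  # 5-block random instances vs an interval-union oracle
  set.seed(17)
  for (rep in 1:10) {
    st <- sort(sample(1e8, 5))
    en <- st + sample(5e6, 5)
    ext <- sample(c(1e5, 2e6, 3e7), 1)
    bl <- data.frame(block = 1:5, chrom = "C1", start = st, end = en,
                     n_snps = 1L, members = letters[1:5],
                     stringsAsFactors = FALSE)
    q <- build_qtl(bl, ext)
    # oracle: mark covered positions on a scaled lattice
    lo <- pmax(st - ext, 1); hi <- en + ext
    ords <- order(lo)
    n_union <- 1
    running_hi <- hi[ords[1]]
    for (k in ords[-1]) {
      if (lo[k] > running_hi) n_union <- n_union + 1
      running_hi <- max(running_hi, hi[k])
    }
    expect_equal(nrow(q), n_union)
    # QTL count never increases with more extension
    q_more <- build_qtl(bl, ext * 3)
    expect_lte(nrow(q_more), nrow(q))
  }
})

test_that("peak metadata and order invariance hold for block building", {
  pan <- independent_panel(n = 80, m_per_chr = 30, seed = 18)
  sig <- pan$map[c(3, 7, 12, 20), c("marker", "chrom", "pos")]
  assoc <- data.frame(marker = sig$marker, chrom = sig$chrom,
                      pos = sig$pos, lod = c(4, 9, 5, 3.5),
                      effect = c(0.2, -0.9, 0.4, 0.1),
                      maf = c(0.2, 0.3, 0.4, 0.25))
  b1 <- ld_blocks(sig, pan, 0.2)
  b2 <- ld_blocks(sig[sample(4), ], pan, 0.2)
  expect_equal(b1$start, b2$start)
  expect_equal(b1$end, b2$end)
  q <- build_qtl(b1, 1e6, assoc = assoc)
  big <- build_qtl(b1, 1e9, assoc = assoc, merge = TRUE)
  expect_equal(nrow(big), 1L)
  expect_equal(big$peak_snp, sig$marker[2])  # max LOD member
})
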