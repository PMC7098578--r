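#' Pairwise linkage disequilibrium as squared dosage correlation
#'
#' `r2` between markers is the squared Pearson correlation of their dosage
#' vectors (invariant to allele coding flips).
#'
#' @param panel imputed `gv_panel`.
#' @param markers marker ids (or column indices); all pairs among them are
#'   returned.
#' @return symmetric matrix of r2 values; zero-variance markers give NA
#'   rows/columns (flagged with a warning, not an error).
#' @export
pairwise_r2 <- function(panel, markers) {
  stopifnot(inherits(panel, "gv_panel"))
  M <- panel$dosage[, markers, drop = FALSE]
  if (anyNA(M)) stop("impute the panel before computing LD")
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance marker(s): LD undefined, returned as NA")
  suppressWarnings(r <- stats::cor(M))
  r[, sds == 0] <- NA; r[sds == 0, ] <- NA
  r * r
}

# r2 between two dosage vectors
r2_vec <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Critical (background) linkage disequilibrium
#'
#' Estimates the LD level expected between physically unlinked loci by
#' sampling random inter-chromosomal marker pairs.  Observed LD above this
#' threshold is taken to reflect genuine linkage.  The default method
#' returns the empirical 95th percentile of the unlinked-pair r2
#' distribution; the parametric variant square-root-transforms the r2
#' values, takes the normal-theory 95th percentile, and squares back.
#'
#' @param panel imputed `gv_panel` with at least two chromosomes.
#' @param n_pairs number of unlinked pairs to sample.
#' @param seed integer seed for the pair sampling.
#' @param method `"empirical-95th"` (default) or `"parametric-sqrt"`.
#' @return list of class `gv_critical_ld`: `value`, `n_pairs`, `method`.
#' @export
critical_ld <- function(panel, n_pairs = 500L, seed = 1L,
                        method = c("empirical-95th", "parametric-sqrt")) {
  stopifnot(inherits(panel, "gv_panel"))
  method <- match.arg(method)
  chroms <- unique(panel$map$chrom)
  if (length(chroms) < 2L)
    stop("critical LD needs markers on at least two chromosomes")
  if (anyNA(panel$dosage)) stop("impute the panel before computing LD")
  set.seed(seed)
  m <- ncol(panel$dosage)
  max_pairs <- sum(outer(table(panel$map$chrom), table(panel$map$chrom))) / 2
  if (n_pairs > max_pairs)
    warning("more pairs requested than available; sampling with ",
            "replacement")
  i <- sample.int(m, n_pairs, replace = TRUE)
  j <- sample.int(m, n_pairs, replace = TRUE)
  diffchr <- panel$map$chrom[i] != panel$map$chrom[j]
  while (!all(diffchr)) {     # redraw same-chromosome picks
    j[!diffchr] <- sample.int(m, sum(!diffchr), replace = TRUE)
    diffchr <- panel$map$chrom[i] != panel$map$chrom[j]
  }
  r <- mapply(function(a, b) stats::cor(panel$dosage[, a],
                                        panel$dosage[, b]),
              i, j)
  r2 <- r[!is.na(r)]^2
  critical_from_r2(r2, method)
}

#' @rdname critical_ld
#' @param r2 unlinked-pair r2 values already in hand.
#' @export
critical_from_r2 <- function(r2, method = c("empirical-95th",
                                            "parametric-sqrt")) {
  method <- match.arg(method)
  value <- if (method == "empirical-95th") {
    stats::quantile(r2, 0.95, names = FALSE, type = 7)
  } else {
    s <- sqrt(r2)
    min(max((mean(s) + stats::qnorm(0.95) * stats::sd(s))^2, 0), 1)
  }
  structure(list(value = min(max(value, 0), 1), n_pairs = length(r2),
                 method = method), class = "gv_critical_ld")
}

#' Prune redundant markers by pairwise LD
#'
#' Greedy left-to-right scan within each chromosome (ascending bp): a
#' marker is dropped when its r2 with any already-retained marker of the
#' chromosome exceeds `threshold`.  Among retained markers no pair exceeds
#' the threshold.
#'
#' @param panel imputed `gv_panel`.
#' @param threshold r2 above which one marker of a pair is removed.
#' @return pruned `gv_panel`; removal count in attribute `"prune_log"`.
#' @export
prune_redundant <- function(panel, threshold = 0.9) {
  stopifnot(inherits(panel, "gv_panel"))
  if (anyNA(panel$dosage)) stop("impute the panel before pruning")
  keep_all <- logical(ncol(panel$dosage))
  for (ch in unique(panel$map$chrom)) {
    idx <- which(panel$map$chrom == ch)    # map is bp-sorted
    M <- panel$dosage[, idx, drop = FALSE]
    Ms <- scale(M)
    n1 <- nrow(M) - 1
    kept <- integer(0)
    for (j in seq_along(idx)) {
      if (any(is.na(Ms[, j]))) next        # zero-variance column
      if (length(kept)) {
        r <- crossprod(Ms[, kept, drop = FALSE], Ms[, j]) / n1
        if (any(r^2 > threshold, na.rm = TRUE)) next
      }
      kept <- c(kept, j)
    }
    keep_all[idx[kept]] <- TRUE
  }
  out <- new_panel(panel$dosage[, keep_all, drop = FALSE],
                   panel$map[keep_all, c("marker", "chrom", "pos")],
                   panel$chrom_len)
  attr(out, "prune_log") <- c(removed = sum(!keep_all),
                              kept = sum(keep_all))
  out
}

#' LD blocks of significant SNPs by average-linkage clustering
#'
#' Within each chromosome, significant SNPs are clustered hierarchically
#' with average linkage on the distance `d = 1 - r2`; the tree is cut at
#' height `1 - critical LD`, so SNPs stay together exactly when their
#' average pairwise LD exceeds the unlinked background.  Each cluster
#' becomes an LD block spanning `[min bp, max bp]` of its members.
#'
#' @param sig_snps data.frame of significant markers with columns `marker`,
#'   `chrom`, `pos` (and optionally `lod`, `effect`, carried through).
#' @param panel imputed `gv_panel` containing those markers.
#' @param critical a [critical_ld()] object (or a bare number in [0,1]).
#' @return data.frame of blocks: `block`, `chrom`, `start`, `end`,
#'   `n_snps`, `members` (comma-separated marker ids).
#' @export
ld_blocks <- function(sig_snps, panel, critical) {
  stopifnot(nrow(sig_snps) >= 1)
  crit <- if (inherits(critical, "gv_critical_ld")) critical$value
          else as.numeric(critical)
  out <- list(); bid <- 0L
  for (ch in unique(sig_snps$chrom)) {
    sub <- sig_snps[sig_snps$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    if (nrow(sub) == 1L) {
      cl <- 1L
    } else {
      r2 <- pairwise_r2(panel, sub$marker)
      r2[is.na(r2)] <- 0
      d <- stats::as.dist(1 - r2)
      hc <- stats::hclust(d, method = "average")
      cl <- stats::cutree(hc, h = 1 - crit)
    }
    for (k in sort(unique(cl))) {
      bid <- bid + 1L
      mem <- sub[cl == k, , drop = FALSE]
      out[[bid]] <- data.frame(
        block = bid, chrom = ch, start = min(mem$pos), end = max(mem$pos),
        n_snps = nrow(mem),
        members = paste(mem$marker, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Hill-Weir expectation of r2 between loci at recombination C = rho * d for
# a sample of n individuals
hill_weir_er2 <- function(C, n) {
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the LD decay curve and locate the critical-LD crossing distance
#'
#' Samples intra-chromosomal marker pairs, computes their r2 and physical
#' distance, and fits the Hill-Weir expected r2 curve
#' `E[r2](d) = f(C = rho d, n)` by least squares over the single parameter
#' `rho` (profiled 1-D nonlinear least squares on the log scale).  The
#' crossing distance `d*` where the fitted curve falls to a given critical
#' LD is found by bisection; `Inf` is returned (flagged) when the curve
#' never crosses.
#'
#' @param panel imputed `gv_panel`.
#' @param max_dist_bp maximum pair distance entering the fit.
#' @param n_pairs number of intra-chromosomal pairs to sample.
#' @param seed integer seed for the pair sampling.
#' @return list of class `gv_ld_decay`: `rho`, `n`, `n_pairs`, `sse`,
#'   `predict(d)` and `crossing(critical)`.
#' @export
fit_ld_decay <- function(panel, max_dist_bp = NULL, n_pairs = 2000L,
                         seed = 1L) {
  stopifnot(inherits(panel, "gv_panel"))
  if (anyNA(panel$dosage)) stop("impute the panel before fitting LD decay")
  set.seed(seed)
  n_ind <- nrow(panel$dosage)
  dist <- numeric(0); r2 <- numeric(0)
  per_chr <- ceiling(n_pairs / length(unique(panel$map$chrom)))
  for (ch in unique(panel$map$chrom)) {
    idx <- which(panel$map$chrom == ch)
    if (length(idx) < 2) next
    i <- sample(idx, per_chr, replace = TRUE)
    j <- sample(idx, per_chr, replace = TRUE)
    ok <- i != j
    i <- i[ok]; j <- j[ok]
    d <- abs(panel$map$pos[i] - panel$map$pos[j])
    if (!is.null(max_dist_bp)) {
      ok <- d <= max_dist_bp
      i <- i[ok]; j <- j[ok]; d <- d[ok]
    }
    r <- vapply(seq_along(i), function(k)
      suppressWarnings(stats::cor(panel$dosage[, i[k]],
                                  panel$dosage[, j[k]])), numeric(1))
    keep <- !is.na(r)
    dist <- c(dist, d[keep]); r2 <- c(r2, r[keep]^2)
  }
  if (length(r2) < 10) stop("too few intra-chromosomal pairs for the fit")
  fit_ld_decay_points(dist, r2, n_ind)
}

#' @rdname fit_ld_decay
#' @param dist,r2 precomputed pair distances (bp) and r2 values.
#' @param n_ind number of individuals behind the r2 values.
#' @export
fit_ld_decay_points <- function(dist, r2, n_ind) {
  sse <- function(lrho) {
    e <- hill_weir_er2(exp(lrho) * dist, n_ind)
    sum((r2 - e)^2)
  }
  opt <- stats::optimize(sse, c(log(1e-14), log(1e-2)), tol = 1e-10)
  rho <- exp(opt$minimum)
  pred <- function(d) hill_weir_er2(rho * d, n_ind)
  crossing <- function(critical) {
    crit <- if (inherits(critical, "gv_critical_ld")) critical$value
            else as.numeric(critical)
    lo <- 1; hi <- 1e12
    if (pred(lo) <= crit) return(0)
    if (pred(hi) > crit) return(Inf)
    stats::uniroot(function(d) pred(d) - crit, c(lo, hi),
                   tol = 1e-4)$root
  }
  structure(list(rho = rho, n = n_ind, n_pairs = length(r2),
                 sse = opt$objective, predict = pred,
                 crossing = crossing),
            class = "gv_ld_decay")
}

#' Build QTL intervals from LD blocks and the LD decay distance
#'
#' Each LD block is extended by the decay crossing distance `d*` on both
#' sides (clipped to `[1, chromosome length]`); overlapping extended
#' intervals on the same chromosome are merged into one locus.  The peak
#' SNP of a QTL is its member with the highest LOD.
#'
#' @param blocks output of [ld_blocks()].
#' @param decay a [fit_ld_decay()] object, or a number taken directly as
#'   the extension distance in bp.
#' @param critical critical LD used to locate the crossing (ignored when
#'   `decay` is a number).
#' @param assoc association results ([mlm_scan()] rows) supplying per-SNP
#'   LOD, effect and MAF for peak identification.
#' @param chrom_len optional named chromosome lengths for clipping.
#' @param merge merge overlapping extended intervals (default TRUE).
#' @return data.frame of QTL: `qtl`, `chrom`, `start`, `end` (extended),
#'   `core_start`, `core_end` (pre-extension), `size_mb`, `n_snps`,
#'   `members`, `peak_snp`, `peak_lod`, `peak_effect`, `peak_maf`.
#' @export
build_qtl <- function(blocks, decay, critical = NULL, assoc = NULL,
                      chrom_len = NULL, merge = TRUE) {
  if (is.null(blocks) || !nrow(blocks)) return(empty_qtl_table())
  ext <- if (inherits(decay, "gv_ld_decay")) {
    if (is.null(critical))
      stop("critical LD needed to locate the decay crossing")
    decay$crossing(critical)
  } else as.numeric(decay)
  if (!is.finite(ext)) {
    warning("LD decay never crosses the critical LD; extending by 0")
    ext <- 0
  }
  b <- blocks
  b$ext_start <- pmax(b$start - ext, 1)
  b$ext_end <- b$end + ext
  if (!is.null(chrom_len))
    b$ext_end <- pmin(b$ext_end, chrom_len[b$chrom])

  out <- list(); qid <- 0L
  for (ch in unique(b$chrom)) {
    sub <- b[b$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$ext_start), , drop = FALSE]
    grp <- integer(nrow(sub)); cur <- 1L; grp[1] <- 1L
    if (nrow(sub) > 1 && merge) {
      hi <- sub$ext_end[1]
      for (i in 2:nrow(sub)) {
        if (sub$ext_start[i] <= hi) {
          grp[i] <- cur; hi <- max(hi, sub$ext_end[i])
        } else {
          cur <- cur + 1L; grp[i] <- cur; hi <- sub$ext_end[i]
        }
      }
    } else grp <- seq_len(nrow(sub))
    for (g in unique(grp)) {
      qid <- qid + 1L
      mm <- sub[grp == g, , drop = FALSE]
      members <- unlist(strsplit(mm$members, ",", fixed = TRUE))
      peak <- data.frame(peak_snp = NA_character_, peak_lod = NA_real_,
                         peak_effect = NA_real_, peak_maf = NA_real_)
      if (!is.null(assoc)) {
        hits <- assoc[assoc$marker %in% members, , drop = FALSE]
        if (nrow(hits)) {
          best <- hits[order(-hits$lod, hits$pos), ][1, ]
          peak <- data.frame(peak_snp = best$marker, peak_lod = best$lod,
                             peak_effect = best$effect,
                             peak_maf = best$maf)
        }
      }
      out[[qid]] <- cbind(
        data.frame(qtl = qid, chrom = ch, start = min(mm$ext_start),
                   end = max(mm$ext_end), core_start = min(mm$start),
                   core_end = max(mm$end),
                   size_mb = (max(mm$ext_end) - min(mm$ext_start)) / 1e6,
                   n_snps = length(members),
                   members = paste(members, collapse = ","),
                   stringsAsFactors = FALSE),
        peak)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_qtl_table <- function() {
  data.frame(qtl = integer(0), chrom = character(0), start = numeric(0),
             end = numeric(0), core_start = numeric(0),
             core_end = numeric(0), size_mb = numeric(0),
             n_snps = integer(0), members = character(0),
             peak_snp = character(0), peak_lod = numeric(0),
             peak_effect = numeric(0), peak_maf = numeric(0),
             stringsAsFactors = FALSE)
}
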