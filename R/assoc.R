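#' Genotype panel container
#'
#' Bundles a biallelic SNP dosage matrix (genotypes x markers, values in
#' \{0,1,2\}, NA for missing calls) with its marker map.  Markers are kept
#' sorted by (chromosome, position); per-marker minor allele frequency and
#' missingness are (re)computed on construction.
#'
#' @param dosage numeric matrix, rownames = genotype ids, colnames = marker
#'   ids.
#' @param map data.frame with columns `marker`, `chrom`, `pos` matching the
#'   dosage columns.
#' @param chrom_len optional named vector of chromosome lengths (bp).
#' @return object of class `gv_panel` with elements `dosage`, `map`
#'   (including `maf` and `missing` columns) and `chrom_len`.
#' @export
new_panel <- function(dosage, map, chrom_len = NULL) {
  dosage <- as.matrix(dosage)
  stopifnot(all(c("marker", "chrom", "pos") %in% names(map)),
            ncol(dosage) == nrow(map))
  if (is.null(colnames(dosage))) colnames(dosage) <- map$marker
  if (!identical(colnames(dosage), as.character(map$marker)))
    stop("dosage column names do not match the marker map")
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop("dosages must lie in [0, 2] (0/1/2 calls or imputed means)")
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  dosage <- dosage[, ord, drop = FALSE]
  freq <- colMeans(dosage, na.rm = TRUE) / 2
  map$maf <- pmin(freq, 1 - freq)
  map$missing <- colMeans(is.na(dosage))
  rownames(map) <- NULL
  structure(list(dosage = dosage, map = map, chrom_len = chrom_len),
            class = "gv_panel")
}

#' @export
print.gv_panel <- function(x, ...) {
  cat("<gv_panel> ", nrow(x$dosage), " genotypes x ", ncol(x$dosage),
      " markers on ", length(unique(x$map$chrom)), " chromosome(s)\n",
      sep = "")
  invisible(x)
}

#' Marker quality control
#'
#' Removes markers with missingness above `max_missing`, minor allele
#' frequency below `min_maf`, and monomorphic markers, in that order of
#' reporting.  The removal counts per rule are attached as the
#' `"qc_log"` attribute.
#'
#' @param panel a [new_panel()] object.
#' @param max_missing maximum tolerated per-marker missing fraction.
#' @param min_maf minimum minor allele frequency.
#' @return the filtered `gv_panel` (MAF recomputed).
#' @export
qc_filter <- function(panel, max_missing = 0.10, min_maf = 0.05) {
  stopifnot(inherits(panel, "gv_panel"))
  miss <- panel$map$missing > max_missing
  mono <- panel$map$maf == 0
  lowmaf <- !mono & panel$map$maf < min_maf
  keep <- !(miss | mono | lowmaf)
  if (!any(keep)) stop("QC removed every marker; panel is empty")
  out <- new_panel(panel$dosage[, keep, drop = FALSE],
                   panel$map[keep, c("marker", "chrom", "pos")],
                   panel$chrom_len)
  attr(out, "qc_log") <- c(missing = sum(miss), monomorphic = sum(mono),
                           low_maf = sum(lowmaf), kept = sum(keep))
  out
}

#' Mean-dosage imputation of missing genotype calls
#'
#' Replaces each missing dosage by its marker's mean dosage (a deterministic
#' stand-in for haplotype-based imputation, adequate after QC has capped
#' missingness at 10%).  The imputation rate is attached as attribute
#' `"impute_log"`.
#'
#' @param panel a post-QC `gv_panel`.
#' @return the panel with a complete dosage matrix.
#' @export
impute_missing <- function(panel) {
  stopifnot(inherits(panel, "gv_panel"))
  dos <- panel$dosage
  na_idx <- which(is.na(dos))
  if (length(na_idx)) {
    mns <- colMeans(dos, na.rm = TRUE)
    dos[na_idx] <- mns[((na_idx - 1L) %/% nrow(dos)) + 1L]
    panel$dosage <- dos
    panel$map$missing <- 0
  }
  attr(panel, "impute_log") <- c(imputed = length(na_idx),
                                 rate = length(na_idx) /
                                   length(dos))
  panel
}

#' Leave-one-chromosome-out genomic relationship matrices
#'
#' For each chromosome `c`, computes the VanRaden centred-crossproduct
#' relationship matrix from all markers *not* on `c`:
#' `K = (M - 2P)(M - 2P)' / (2 * sum p(1-p))`, where `M` is the dosage
#' matrix and `P` the allele-frequency matrix.  Using the off-chromosome
#' kinship when testing markers of chromosome `c` avoids absorbing the
#' tested signal into the polygenic term (proximal contamination).
#'
#' @param panel an imputed `gv_panel`.
#' @return named list of n x n matrices, one per chromosome, plus the
#'   full-genome matrix under `"all"`.  With a single chromosome, LOCO is
#'   impossible: every entry is the full-genome matrix (with a warning).
#' @export
kinship_loco <- function(panel) {
  stopifnot(inherits(panel, "gv_panel"))
  dos <- panel$dosage
  if (anyNA(dos)) stop("impute the panel before computing kinship")
  chroms <- unique(panel$map$chrom)
  vr <- function(cols) {
    M <- dos[, cols, drop = FALSE]
    p <- colMeans(M) / 2
    W <- sweep(M, 2, 2 * p)
    denom <- 2 * sum(p * (1 - p))
    if (denom <= 0) stop("no polymorphic markers for kinship")
    tcrossprod(W) / denom
  }
  K_all <- vr(seq_len(ncol(dos)))
  if (length(chroms) < 2L) {
    warning("single-chromosome panel: LOCO impossible, ",
            "using the full-genome kinship")
    out <- stats::setNames(list(K_all), chroms)
  } else {
    out <- lapply(chroms, function(ch) vr(which(panel$map$chrom != ch)))
    names(out) <- chroms
  }
  out$all <- K_all
  out
}

#' LOD score from a p-value
#' @param p p-value in (0, 1].
#' @return `-log10(p)`.
#' @export
lod_from_p <- function(p) {
  if (any(p <= 0) || any(p > 1)) stop("p must lie in (0, 1]")
  -log10(p)
}

#' Single-marker mixed-model genome scan with LOCO kinship
#'
#' Fits, for each marker, `Y = mu + X beta + G + E` where `Y` are the
#' spatially adjusted genotype means of one trait in one environment,
#' `G ~ N(0, s2g * K_chr)` is the polygenic effect with the
#' leave-one-chromosome-out relationship matrix of the marker's chromosome,
#' and `E ~ N(0, s2e * I)`.  The variance ratio is estimated once per
#' chromosome under the no-marker null (P3D/EMMAX approximation, or exact
#' per-marker REML with `per_marker_reml = TRUE`); each marker is then
#' tested by generalised least squares with a 1-df Wald test referenced to
#' the t distribution on n - 2 degrees of freedom, so that with `K`
#' proportional to the identity the test reduces exactly to ordinary
#' least-squares regression.  Effects are reported for the minor allele.
#'
#' @param adjusted data.frame of adjusted means with columns `genotype`,
#'   `env`, `trait`, `value` (as produced by [adjusted_means()]).
#' @param panel imputed `gv_panel`.
#' @param K_set output of [kinship_loco()].
#' @param trait,env which slice of `adjusted` to scan.
#' @param lod_threshold significance threshold on the LOD scale (strict
#'   `>`).
#' @param per_marker_reml re-estimate the variance ratio under each
#'   marker's model instead of once per chromosome (slower).
#' @return data.frame: `marker`, `chrom`, `pos`, `trait`, `env`, `maf`,
#'   `effect` (minor allele), `se`, `p`, `lod`, `significant`.
#' @export
mlm_scan <- function(adjusted, panel, K_set, trait, env,
                     lod_threshold = 3, per_marker_reml = FALSE) {
  stopifnot(inherits(panel, "gv_panel"))
  ph <- adjusted[adjusted$trait == trait & adjusted$env == env, ]
  if (!nrow(ph)) stop("no adjusted values for trait '", trait,
                      "' in environment '", env, "'")
  if (anyDuplicated(ph$genotype))
    stop("multiple adjusted values per genotype")
  orphans <- setdiff(ph$genotype, rownames(panel$dosage))
  if (length(orphans))
    stop("genotypes absent from the panel: ",
         paste(utils::head(orphans, 5), collapse = ", "),
         if (length(orphans) > 5) " ...")
  dos <- panel$dosage[ph$genotype, , drop = FALSE]
  if (anyNA(dos)) stop("impute the panel before scanning")
  y <- ph$value
  n <- length(y)
  ones <- rep(1, n)

  chroms <- unique(panel$map$chrom)
  res <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    K <- K_set[[ch]]
    if (is.null(K)) stop("no kinship matrix for chromosome ", ch)
    K <- K[ph$genotype, ph$genotype]
    diag(K) <- diag(K) + 1e-8      # numerical stabilisation
    cols <- which(panel$map$chrom == ch)
    M <- dos[, cols, drop = FALSE]

    null_fit <- reml_onecomp(y, matrix(1, n, 1,
                                       dimnames = list(NULL, "mu")), A = K)
    g <- null_fit$gamma
    U <- null_fit$U; d <- null_fit$d
    w <- 1 / (1 + g * d)
    yt <- drop(crossprod(U, y))
    ot <- drop(crossprod(U, ones))
    Mt <- crossprod(U, M)

    if (per_marker_reml) {
      stat <- vapply(seq_len(ncol(M)), function(j) {
        X <- cbind(mu = 1, snp = M[, j])
        if (stats::var(M[, j]) == 0) return(c(NA, NA, NA))
        f <- reml_onecomp(y, X, A = K)
        c(f$beta["snp"], sqrt(f$vcov_beta["snp", "snp"]), NA)
      }, numeric(3))
      beta <- stat[1, ]; se <- stat[2, ]
      tval <- beta / se
      p <- 2 * stats::pt(-abs(tval), n - 2)
    } else {
      S1 <- sum(w * ot * ot)
      Sy <- sum(w * ot * yt)
      Syy <- sum(w * yt * yt)
      Sg1 <- colSums(Mt * (w * ot))
      Sgg <- colSums(w * Mt * Mt)
      Sgy <- colSums(Mt * (w * yt))
      det <- S1 * Sgg - Sg1^2
      mono <- det <= 1e-12 * S1 * pmax(Sgg, 1e-300)
      beta <- (S1 * Sgy - Sg1 * Sy) / det
      mu <- (Sy - Sg1 * beta) / S1
      rss <- pmax(Syy - mu * Sy - beta * Sgy, 0)
      s2 <- rss / (n - 2)
      se <- sqrt(s2 * S1 / det)
      tval <- beta / se
      p <- 2 * stats::pt(-abs(tval), n - 2)
      beta[mono] <- NA; se[mono] <- NA; p[mono] <- NA
    }

    # report the minor-allele effect
    frq <- colMeans(M) / 2
    flip <- frq > 0.5
    beta[flip] <- -beta[flip]
    res[[ci]] <- data.frame(
      marker = panel$map$marker[cols], chrom = ch,
      pos = panel$map$pos[cols], trait = trait, env = env,
      maf = pmin(frq, 1 - frq), effect = beta, se = se, p = p,
      lod = ifelse(is.na(p) | p <= 0, NA, -log10(p)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$significant <- !is.na(out$lod) & out$lod > lod_threshold
  rownames(out) <- NULL
  out
}
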