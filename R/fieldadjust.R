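# Fixed-effect design for one environment of an augmented trial:
# intercept + sum-to-zero block contrasts + sum-to-zero genotype contrasts.
augmented_design <- function(dat) {
  dat$block <- factor(dat$block)
  dat$genotype <- factor(dat$genotype)
  terms <- "1"
  if (nlevels(dat$block) > 1) terms <- c(terms, "block")
  terms <- c(terms, "genotype")
  fm <- stats::as.formula(paste("~", paste(terms, collapse = "+")))
  ctr <- list(genotype = "contr.sum")
  if (nlevels(dat$block) > 1) ctr$block <- "contr.sum"
  X <- stats::model.matrix(fm, dat, contrasts.arg = ctr)
  list(X = X, dat = dat)
}

#' Spatially adjusted genotype means for an augmented design
#'
#' Fits, separately in each environment, the linear mixed model
#' `Y = mu + SB_j + B_k + G_i + eps` with the sub-block effect `SB_j`
#' random (single variance component, REML) and block and genotype fixed
#' with sum-to-zero constraints.  The adjusted mean of genotype i is
#' `mu_hat + G_hat_i`, i.e. the genotype value averaged over blocks after
#' removal of the estimated spatial terms.
#'
#' @param plots plot table with columns `genotype`, `env`, `block`,
#'   `subblock` and the trait column.
#' @param trait name of the trait column to adjust.
#' @return data.frame `genotype`, `env`, `trait`, `value`, `se`.
#' @export
adjusted_means <- function(plots, trait) {
  if (!trait %in% names(plots))
    stop("trait column '", trait, "' not found in the plot table")
  need <- c("genotype", "env", "block", "subblock")
  stopifnot(all(need %in% names(plots)))
  out <- lapply(split(plots, plots$env), function(dat) {
    dat <- dat[!is.na(dat[[trait]]), , drop = FALSE]
    des <- augmented_design(dat)
    X <- des$X
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
      stop("non-estimable design in environment '", dat$env[1],
           "': aliased terms ", paste(bad, collapse = ", "))
    }
    Z <- indicator_matrix(des$dat$subblock)
    fit <- reml_onecomp(dat[[trait]], X, Z = Z)
    g_lev <- levels(des$dat$genotype)
    k <- length(g_lev)
    # contrast matrix: adjusted mean = mu + G_i under sum-to-zero coding
    C <- matrix(0, k, ncol(X), dimnames = list(g_lev, colnames(X)))
    C[, "(Intercept)"] <- 1
    gcols <- grep("^genotype", colnames(X))
    for (i in seq_len(k - 1)) C[i, gcols[i]] <- 1
    C[k, gcols] <- -1
    vals <- drop(C %*% fit$beta)
    ses <- sqrt(rowSums((C %*% fit$vcov_beta) * C))
    data.frame(genotype = g_lev, env = dat$env[1], trait = trait,
               value = vals, se = ses, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# checks-only fit of the spatial model: Y = mu + B_k + G_i + SB_j(random).
# Returns per-sub-block BLUPs and per-block fixed estimates (sum-to-zero).
fit_spatial_from_checks <- function(dat) {
  checks <- dat[dat$is_check, , drop = FALSE]
  if (!nrow(checks)) stop("design error: no check plots available")
  rep_per_sb <- table(checks$subblock)
  missing_sb <- setdiff(unique(dat$subblock), names(rep_per_sb))
  if (length(missing_sb))
    stop("design error: sub-block(s) without checks: ",
         paste(missing_sb, collapse = ", "))
  if (all(table(checks$genotype) < 2))
    stop("design error: checks are not replicated")
  des <- augmented_design(checks)
  Z <- indicator_matrix(des$dat$subblock)
  fit <- reml_onecomp(checks$y, des$X, Z = Z)
  blk_lev <- levels(des$dat$block)
  blk_eff <- stats::setNames(rep(0, length(blk_lev)), blk_lev)
  if (length(blk_lev) > 1) {
    bcols <- grep("^block", colnames(des$X))
    blk_eff[seq_along(bcols)] <- fit$beta[bcols]
    blk_eff[length(blk_lev)] <- -sum(fit$beta[bcols])
  }
  sb_eff <- stats::setNames(rep(0, length(unique(dat$subblock))),
                            sort(unique(dat$subblock)))
  sb_eff[names(fit$blup)] <- fit$blup
  list(subblock = sb_eff, block = blk_eff, fit = fit)
}

# intercept-only random-genotype REML on genotype-replicated data
genotype_variance <- function(y, genotype) {
  Z <- indicator_matrix(genotype)
  fit <- reml_onecomp(y, matrix(1, length(y), 1,
                                dimnames = list(NULL, "(Intercept)")),
                      Z = Z)
  h2 <- if (fit$s2u + fit$s2e > 0) fit$s2u / (fit$s2u + fit$s2e) else 0
  list(sigma2_G = fit$s2u, sigma2_eps = fit$s2e, H2 = h2,
       truncated = fit$gamma == 0)
}

#' Broad-sense heritability, replicated-checks model
#'
#' Heritability under the model
#' `Y = mu + SB(check)_j + B_k + G_i + eps` in which the sub-block (and
#' block) spatial effects are estimated from the replicated check plots
#' only, and the genotype effect is random.  Implemented in two stages:
#' the checks-only mixed model yields the spatial effects, these are
#' subtracted from every plot, and a random-genotype REML fit on the
#' corrected values returns `sigma2_G`, `sigma2_eps` and the plot-basis
#' `H2 = sigma2_G / (sigma2_G + sigma2_eps)`.
#'
#' @param plots plot table for one environment (columns `genotype`,
#'   `block`, `subblock`, `is_check` and the trait); multi-environment
#'   tables are split on `env`.
#' @param trait trait column name.
#' @return data.frame `trait`, `env`, `sigma2_G`, `sigma2_eps`, `H2`.
#' @export
heritability_panel2016 <- function(plots, trait) {
  heritability_two_step(plots, trait, keep_check_genotype_effects = TRUE)
}

#' Broad-sense heritability, checks-only two-step model
#'
#' Two-step heritability for panels in which only the check genotypes are
#' replicated: first the checks estimate the sub-block and block spatial
#' effects (`Y = mu + SB_j + B_k + G_i + eps` on check plots), then the
#' spatially corrected phenotypes `Ycorr` of all plots are fitted with
#' `Ycorr = mu + G_i + eps`, genotype random, giving the variance
#' components and `H2`.
#'
#' @inheritParams heritability_panel2016
#' @return data.frame `trait`, `env`, `sigma2_G`, `sigma2_eps`, `H2`.
#' @export
heritability_panel2017 <- function(plots, trait) {
  heritability_two_step(plots, trait, keep_check_genotype_effects = TRUE,
                        min_checks_per_subblock = 1L)
}

heritability_two_step <- function(plots, trait,
                                  keep_check_genotype_effects = TRUE,
                                  min_checks_per_subblock = 0L) {
  if (!trait %in% names(plots))
    stop("trait column '", trait, "' not found in the plot table")
  stopifnot(all(c("genotype", "block", "subblock", "is_check") %in%
                  names(plots)))
  if (!"env" %in% names(plots)) plots$env <- "E"
  out <- lapply(split(plots, plots$env), function(dat) {
    dat <- dat[!is.na(dat[[trait]]), , drop = FALSE]
    dat$y <- dat[[trait]]
    if (min_checks_per_subblock > 0L) {
      tab <- table(dat$subblock[dat$is_check])
      short <- setdiff(unique(dat$subblock), names(tab[tab >= 1]))
      if (length(short))
        stop("design error: sub-block(s) without checks: ",
             paste(short, collapse = ", "))
    }
    sp <- fit_spatial_from_checks(dat)
    ycorr <- dat$y - sp$subblock[dat$subblock] - sp$block[dat$block]
    gv <- genotype_variance(ycorr, dat$genotype)
    data.frame(trait = trait, env = dat$env[1], sigma2_G = gv$sigma2_G,
               sigma2_eps = gv$sigma2_eps, H2 = gv$H2,
               truncated = gv$truncated, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
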