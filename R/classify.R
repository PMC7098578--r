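#' Classify grain-size-variance QTL as canopy-driven or specific
#'
#' A GSV QTL is *driven* when at least one SNP significantly associated
#' with a yield component in the same environment colocalises with it --
#' by default when such a SNP lies inside the QTL's extended interval
#' (`rule = "interval"`); alternatively only shared member SNPs count
#' (`rule = "members"`).  QTL without any yield-component colocalisation
#' are *specific*: loci acting on the variance of grain size independently
#' of canopy structure.
#'
#' @param gsv_qtl QTL table from [build_qtl()] for the GSV trait.
#' @param component_hits data.frame of significant yield-component
#'   associations (rows of [mlm_scan()] output with `significant == TRUE`),
#'   with a `trait` column; traits must belong to `component_set`.
#' @param env environment label (recorded; hits are assumed pre-filtered to
#'   this environment).
#' @param rule colocalisation rule, `"interval"` or `"members"`.
#' @param component_set admissible yield-component trait labels.
#' @return `gsv_qtl` with added columns `env`, `class` (`"driven"` /
#'   `"specific"`) and `coloc_traits` (comma-separated).
#' @export
classify_qtl <- function(gsv_qtl, component_hits, env,
                         rule = c("interval", "members"),
                         component_set = c("spm2", "gps", "gpm2", "tkw",
                                           "gy")) {
  rule <- match.arg(rule)
  if (nrow(component_hits)) {
    bad <- setdiff(unique(component_hits$trait), component_set)
    if (length(bad))
      stop("unknown yield-component trait(s): ",
           paste(bad, collapse = ", "))
  }
  out <- gsv_qtl
  if (!nrow(out)) {
    out$env <- character(0)
    out$class <- character(0)
    out$coloc_traits <- character(0)
    return(out)
  }
  out$env <- env
  out$class <- "specific"
  out$coloc_traits <- ""
  for (i in seq_len(nrow(out))) {
    if (rule == "interval") {
      hit <- component_hits$chrom == out$chrom[i] &
        component_hits$pos >= out$start[i] &
        component_hits$pos <= out$end[i]
    } else {
      members <- strsplit(out$members[i], ",", fixed = TRUE)[[1]]
      hit <- component_hits$marker %in% members
    }
    if (any(hit)) {
      out$class[i] <- "driven"
      out$coloc_traits[i] <- paste(sort(unique(component_hits$trait[hit])),
                                   collapse = ",")
    }
  }
  out
}

#' Cross-environment (and cross-panel) QTL commonality
#'
#' Two QTL detected in different environments are *common* when they share
#' at least one significantly associated GSV SNP (member identity, not mere
#' interval overlap).  Produces per-class tallies of QTL found in a single
#' environment vs common to two environments, and -- when a panel label is
#' supplied per environment -- common across panels.
#'
#' @param qtl_by_env named list (by environment) of classified QTL tables
#'   ([classify_qtl()] output).
#' @param panel_of optional named vector mapping environment -> panel
#'   label.
#' @return list with `qtl` (all QTL with `common_env` / `common_panel`
#'   flags), `tally` (counts and half-up one-decimal percentages per
#'   class), and `pairs` (the matched cross-environment QTL pairs).
#' @export
cross_environment <- function(qtl_by_env, panel_of = NULL) {
  stopifnot(length(qtl_by_env) >= 2, !is.null(names(qtl_by_env)))
  all_q <- do.call(rbind, lapply(names(qtl_by_env), function(e) {
    q <- qtl_by_env[[e]]
    if (!nrow(q)) return(NULL)
    q$env <- e
    q$uid <- paste0(e, ":", q$qtl)
    q
  }))
  if (is.null(all_q) || !nrow(all_q))
    return(list(qtl = empty_qtl_table(), tally = NULL, pairs = NULL))
  mem <- lapply(strsplit(all_q$members, ",", fixed = TRUE), unique)
  names(mem) <- all_q$uid
  pairs <- list()
  n <- nrow(all_q)
  common_env <- rep(FALSE, n); common_panel <- rep(FALSE, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (all_q$env[i] == all_q$env[j]) next
      if (!length(intersect(mem[[i]], mem[[j]]))) next
      common_env[c(i, j)] <- TRUE
      same_panel <- is.null(panel_of) ||
        panel_of[all_q$env[i]] == panel_of[all_q$env[j]]
      if (!same_panel) common_panel[c(i, j)] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(
        uid1 = all_q$uid[i], uid2 = all_q$uid[j],
        n_shared = length(intersect(mem[[i]], mem[[j]])),
        stringsAsFactors = FALSE)
    }
  }
  all_q$common_env <- common_env
  all_q$common_panel <- common_panel

  tally_row <- function(idx, label) {
    total <- nrow(all_q)
    data.frame(class = label, n = length(idx),
               pct = round_half_up(100 * length(idx) / total, 1),
               single_env = sum(!all_q$common_env[idx]),
               common_two_env = sum(all_q$common_env[idx]),
               inter_panel = sum(all_q$common_panel[idx]),
               stringsAsFactors = FALSE)
  }
  cls <- if ("class" %in% names(all_q)) all_q$class else
    rep("unclassified", n)
  tally <- rbind(tally_row(which(cls == "specific"), "specific"),
                 tally_row(which(cls == "driven"), "driven"),
                 tally_row(seq_len(n), "total"))
  list(qtl = all_q, tally = tally,
       pairs = if (length(pairs)) do.call(rbind, pairs) else NULL)
}

#' Retain one SNP per QTL: the strongest minor-allele effect
#'
#' To avoid redundancy in multi-QTL regressions, each QTL is represented by
#' its member SNP with the largest absolute minor-allele effect; ties are
#' broken by higher LOD, then lower bp (`rule = "effect"`), or the maximum
#' LOD SNP can be used directly (`rule = "lod"`).
#'
#' @param qtl_list QTL table with `members` column.
#' @param assoc association results providing `effect`, `lod`, `pos` per
#'   marker.
#' @param rule `"effect"` (default) or `"lod"`.
#' @return `qtl_list` with columns `sel_snp`, `sel_effect`, `sel_lod`.
#' @export
peak_selection <- function(qtl_list, assoc, rule = c("effect", "lod")) {
  rule <- match.arg(rule)
  out <- qtl_list
  out$sel_snp <- NA_character_
  out$sel_effect <- NA_real_
  out$sel_lod <- NA_real_
  for (i in seq_len(nrow(out))) {
    members <- strsplit(out$members[i], ",", fixed = TRUE)[[1]]
    hits <- assoc[assoc$marker %in% members, , drop = FALSE]
    if (!nrow(hits)) next
    ord <- if (rule == "effect")
      order(-abs(hits$effect), -hits$lod, hits$pos)
    else order(-hits$lod, -abs(hits$effect), hits$pos)
    best <- hits[ord[1], ]
    out$sel_snp[i] <- best$marker
    out$sel_effect[i] <- best$effect
    out$sel_lod[i] <- best$lod
  }
  out
}

# adjusted trait values + peak dosages -> aligned y and design matrix
peak_design <- function(adjusted_gsv, panel, snps) {
  y <- adjusted_gsv$value
  names(y) <- adjusted_gsv$genotype
  X <- panel$dosage[adjusted_gsv$genotype, snps, drop = FALSE]
  list(y = y, X = X)
}

r2_of_lm <- function(fit) summary(fit)$r.squared

#' Variance of GSV explained by QTL categories
#'
#' Three multiple linear regressions of the adjusted grain-size variance on
#' peak-SNP dosages -- all peaks, specific-only, driven-only -- each
#' reporting its coefficient of determination.  Collinear peaks are
#' dropped by the regression (with a warning) rather than failing.
#'
#' @param adjusted_gsv data.frame `genotype`, `value` of adjusted GSV for
#'   one environment.
#' @param panel imputed `gv_panel`.
#' @param peaks classified QTL table with `sel_snp` and `class` columns
#'   ([peak_selection()] then [classify_qtl()] output, any order).
#' @param env environment label recorded in the result.
#' @return data.frame `env`, `r2_all`, `r2_specific`, `r2_driven`,
#'   `n_all`, `n_specific`, `n_driven`.
#' @export
variance_partition <- function(adjusted_gsv, panel, peaks, env = NA) {
  peaks <- peaks[!is.na(peaks$sel_snp), , drop = FALSE]
  reg_r2 <- function(snps) {
    if (!length(snps)) return(0)
    d <- peak_design(adjusted_gsv, panel, unique(snps))
    fit <- stats::lm(d$y ~ d$X)
    if (anyNA(stats::coef(fit)))
      warning("collinear peak SNPs dropped from the regression")
    r2_of_lm(fit)
  }
  data.frame(
    env = env,
    r2_all = reg_r2(peaks$sel_snp),
    r2_specific = reg_r2(peaks$sel_snp[peaks$class == "specific"]),
    r2_driven = reg_r2(peaks$sel_snp[peaks$class == "driven"]),
    n_all = nrow(peaks),
    n_specific = sum(peaks$class == "specific"),
    n_driven = sum(peaks$class == "driven"),
    stringsAsFactors = FALSE)
}

#' Forward stepwise QTL selection by AIC
#'
#' Starting from the intercept-only model, repeatedly adds the candidate
#' peak SNP whose inclusion lowers AIC the most, stopping when no addition
#' lowers it.  Returns the selected set and the final model's r2
#' ("r2_opt"), i.e. the share of GSV variance carried by the optimal QTL
#' subset.
#'
#' @param y numeric response (adjusted GSV values).
#' @param X dosage matrix of candidate peak SNPs (columns named by SNP).
#' @return list `selected` (SNP names in selection order), `r2_opt`,
#'   `aic`, `n_selected`.
#' @export
stepwise_opt <- function(y, X) {
  X <- as.matrix(X)
  candidates <- colnames(X)
  if (is.null(candidates)) candidates <- paste0("snp", seq_len(ncol(X)))
  colnames(X) <- candidates
  selected <- character(0)
  dat <- data.frame(y = y)
  cur <- stats::lm(y ~ 1, data = dat)
  cur_aic <- stats::AIC(cur)
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    aics <- vapply(remaining, function(s) {
      M <- X[, c(selected, s), drop = FALSE]
      stats::AIC(stats::lm(y ~ M))
    }, numeric(1))
    if (min(aics) >= cur_aic) break
    best <- remaining[which.min(aics)]
    selected <- c(selected, best)
    cur_aic <- min(aics)
  }
  r2 <- if (length(selected))
    r2_of_lm(stats::lm(y ~ X[, selected, drop = FALSE])) else 0
  list(selected = selected, r2_opt = r2, aic = cur_aic,
       n_selected = length(selected))
}
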