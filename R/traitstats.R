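# deterministic half-up rounding, used wherever report tables print
# percentages (avoids the round-half-even surprises of base round())
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Coefficient of variation from a mean and standard deviation
#'
#' `100 * sd / mean`, the across-genotype CV used to compare the genetic
#' variability of grain-size distribution descriptors between environments.
#'
#' @param mean,sd summary statistics of the metric across genotypes
#'   (`mean > 0`).
#' @param digits decimals of the reported percentage (2 for report-style
#'   tables; `NULL` for the raw value).
#' @return CV in percent.
#' @examples
#' cv_from_summary(17.10, 0.93)  # 5.44
#' @export
cv_from_summary <- function(mean, sd, digits = 2) {
  if (any(mean <= 0)) stop("cv undefined: mean must be positive")
  if (any(sd < 0)) stop("sd must be non-negative")
  cv <- 100 * sd / mean
  if (is.null(digits)) cv else round_half_up(cv, digits)
}

signif_stars <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, 0.1, Inf),
      labels = c("***", "**", "*", ".", ""), right = TRUE)
}

#' Pairwise Pearson correlations among adjusted trait means
#'
#' Complete-case Pearson correlations, with two-sided p-values, between all
#' pairs of the requested traits within one environment, computed across
#' genotypes on adjusted means.
#'
#' @param adjusted data.frame with columns `genotype`, `env`, `trait`,
#'   `value`.
#' @param traits character vector of trait names.
#' @param env environment label.
#' @return data.frame `env`, `trait1`, `trait2`, `r`, `n`, `p`, `stars`;
#'   `r` is NA (flagged, not an error) when either trait is constant.
#' @export
correlation_panel <- function(adjusted, traits, env) {
  sub <- adjusted[adjusted$env == env & adjusted$trait %in% traits, ]
  if (!nrow(sub)) stop("no adjusted values for environment '", env, "'")
  wide <- stats::reshape(sub[, c("genotype", "trait", "value")],
                         idvar = "genotype", timevar = "trait",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  missing_tr <- setdiff(traits, names(wide))
  if (length(missing_tr))
    stop("traits absent from adjusted means: ",
         paste(missing_tr, collapse = ", "))
  out <- list()
  for (i in seq_along(traits)[-length(traits)]) {
    for (j in seq((i + 1), length(traits))) {
      x <- wide[[traits[i]]]; y <- wide[[traits[j]]]
      cc <- stats::complete.cases(x, y)
      n <- sum(cc)
      if (n < 3) stop("fewer than 3 complete pairs for ",
                      traits[i], " vs ", traits[j])
      if (stats::sd(x[cc]) == 0 || stats::sd(y[cc]) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- stats::cor.test(x[cc], y[cc], method = "pearson")
        r <- unname(ct$estimate); p <- ct$p.value
      }
      out[[length(out) + 1L]] <- data.frame(
        env = env, trait1 = traits[i], trait2 = traits[j],
        r = r, n = n, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out$stars <- as.character(signif_stars(out$p))
  out$stars[is.na(out$p)] <- NA_character_
  out
}

#' Compare two Pearson correlations from independent samples
#'
#' Fisher r-to-z comparison: `z = (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))`
#' with `z_i = atanh(r_i)`, and a two-sided normal p-value.  Used to ask
#' whether a trait relationship (e.g. spike density vs grain-size variance)
#' differs between environments.
#'
#' @param r1,r2 correlations (|r| < 1).
#' @param n1,n2 sample sizes (> 3).
#' @return list with `z` and `p`.
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (any(abs(c(r1, r2)) >= 1))
    stop("|r| = 1: Fisher z is infinite, comparison undefined")
  if (any(c(n1, n2) <= 3)) stop("sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# maximal non-significant runs over groups sorted by decreasing mean ->
# compact letter display (insert-and-absorb; deterministic)
compact_letters <- function(means, psig) {
  ord <- order(-means)
  k <- length(means)
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && all(psig[ord[i:(j + 1)], ord[i:(j + 1)]][
      upper.tri(matrix(0, j + 2 - i, j + 2 - i))] > 0.05, na.rm = TRUE))
      j <- j + 1
    runs[[i]] <- i:j
  }
  keep <- !vapply(seq_along(runs), function(i)
    any(vapply(seq_along(runs), function(j)
      i != j && all(runs[[i]] %in% runs[[j]]), logical(1))), logical(1))
  runs <- runs[keep]
  letters_out <- rep("", k)
  for (r in seq_along(runs)) {
    lab <- letters[r]
    for (g in runs[[r]])
      letters_out[ord[g]] <- paste0(letters_out[ord[g]], lab)
  }
  letters_out
}

#' Environment comparison by ANOVA and Tukey HSD letters
#'
#' One-way ANOVA of a trait across environments followed by Tukey honest
#' significant differences; environments sharing a letter are not
#' significantly different at the 0.05 level.
#'
#' @param adjusted data.frame with columns `env`, `trait`, `value`.
#' @param trait trait to compare.
#' @return data.frame `env`, `mean`, `sd`, `n`, `letter`, with the ANOVA
#'   p-value as attribute `"anova_p"`.
#' @export
environment_anova <- function(adjusted, trait) {
  sub <- adjusted[adjusted$trait == trait, ]
  sub <- sub[!is.na(sub$value), ]
  envs <- unique(sub$env)
  if (length(envs) < 2) stop("need at least 2 environments to compare")
  if (any(table(sub$env) < 2)) stop("need >= 2 values per environment")
  sub$env <- factor(sub$env)
  fit <- stats::aov(value ~ env, data = sub)
  tk <- stats::TukeyHSD(fit)$env
  lev <- levels(sub$env)
  k <- length(lev)
  psig <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (rn in rownames(tk)) {
    pair <- strsplit(rn, "-", fixed = TRUE)[[1]]
    psig[pair[1], pair[2]] <- psig[pair[2], pair[1]] <- tk[rn, "p adj"]
  }
  mns <- tapply(sub$value, sub$env, mean)
  out <- data.frame(env = lev, mean = as.numeric(mns[lev]),
                    sd = as.numeric(tapply(sub$value, sub$env, stats::sd)[lev]),
                    n = as.integer(table(sub$env)[lev]),
                    letter = compact_letters(as.numeric(mns[lev]), psig),
                    stringsAsFactors = FALSE)
  attr(out, "anova_p") <- summary(fit)[[1]][["Pr(>F)"]][1]
  out
}

#' Report-style summary of grain-size descriptors per environment
#'
#' Across-genotype mean, SD and CV of each metric in each environment, plus
#' the CV of the grain-size standard deviation (square root of the
#' variance), which makes the mean and dispersion metrics comparable on one
#' scale.
#'
#' @param adjusted data.frame with columns `genotype`, `env`, `trait`,
#'   `value`; the grain-size variance must be present under trait `"gsv"`.
#' @param metrics traits to summarise.
#' @return data.frame `metric`, `env`, `mean`, `sd`, `cv`.
#' @export
cv_summary <- function(adjusted, metrics = c("gsm", "gsv", "p95", "p5")) {
  out <- list()
  for (m in metrics) {
    sub <- adjusted[adjusted$trait == m & !is.na(adjusted$value), ]
    for (e in unique(sub$env)) {
      v <- sub$value[sub$env == e]
      mu <- mean(v); s <- stats::sd(v)
      out[[length(out) + 1L]] <- data.frame(
        metric = m, env = e, mean = mu, sd = s,
        cv = if (mu > 0) cv_from_summary(mu, s) else NA_real_,
        stringsAsFactors = FALSE)
      if (m == "gsv" && all(v >= 0)) {
        sdv <- sqrt(v)
        out[[length(out) + 1L]] <- data.frame(
          metric = "sqrt_gsv", env = e, mean = mean(sdv),
          sd = stats::sd(sdv),
          cv = cv_from_summary(mean(sdv), stats::sd(sdv)),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
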