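#' Configuration for a full pipeline run
#'
#' @param sim a [sim_config()] object describing the synthetic inputs, or
#'   `NULL` when `plots_csv`/`grains_csv`/`genotype_tsv`/`map_tsv` point to
#'   existing files.
#' @param plots_csv,grains_csv,genotype_tsv,map_tsv optional input paths
#'   (all four required when `sim` is NULL).
#' @param lod_threshold significance threshold (strict `>`), LOD scale.
#' @param prune_r2 LD-pruning threshold.
#' @param max_missing,min_maf marker QC thresholds.
#' @param critical_method critical-LD estimator variant.
#' @param peak_rule peak-SNP retention rule ([peak_selection()]).
#' @param coloc_rule within-environment colocalisation rule
#'   ([classify_qtl()]).
#' @param n_unlinked_pairs,decay_pairs sampling sizes for the critical-LD
#'   and LD-decay fits.
#' @param traits traits scanned genome-wide; the first must be the
#'   grain-size variance.
#' @param write_grains write the (large) long grain table to disk.
#' @param seed master seed: every stochastic stage derives its stream from
#'   it.
#' @param out_dir output directory (created if absent).
#' @return object of class `gv_run_config`.
#' @export
run_config <- function(sim = sim_config(), plots_csv = NULL,
                       grains_csv = NULL, genotype_tsv = NULL,
                       map_tsv = NULL, lod_threshold = 3, prune_r2 = 0.9,
                       max_missing = 0.10, min_maf = 0.05,
                       critical_method = c("empirical-95th",
                                           "parametric-sqrt"),
                       peak_rule = c("effect", "lod"),
                       coloc_rule = c("interval", "members"),
                       n_unlinked_pairs = 500L, decay_pairs = 2000L,
                       traits = c("gsv", "spm2", "gps", "gpm2", "tkw",
                                  "gy"),
                       write_grains = TRUE, seed = 1L,
                       out_dir = tempfile("grainvar_run_")) {
  cfg <- list(sim = sim, plots_csv = plots_csv, grains_csv = grains_csv,
              genotype_tsv = genotype_tsv, map_tsv = map_tsv,
              lod_threshold = lod_threshold, prune_r2 = prune_r2,
              max_missing = max_missing, min_maf = min_maf,
              critical_method = match.arg(critical_method),
              peak_rule = match.arg(peak_rule),
              coloc_rule = match.arg(coloc_rule),
              n_unlinked_pairs = as.integer(n_unlinked_pairs),
              decay_pairs = as.integer(decay_pairs), traits = traits,
              write_grains = isTRUE(write_grains),
              seed = as.integer(seed), out_dir = out_dir)
  stopifnot(cfg$lod_threshold > 0, cfg$prune_r2 > 0, cfg$prune_r2 <= 1,
            cfg$max_missing >= 0, cfg$max_missing <= 1,
            cfg$min_maf >= 0, cfg$min_maf < 0.5)
  if (is.null(sim)) {
    paths <- c(plots_csv, grains_csv, genotype_tsv, map_tsv)
    if (length(paths) < 4 || !all(file.exists(paths)))
      stop("without a sim config, all four input paths must exist")
  } else {
    stopifnot(inherits(sim, "gv_sim_config"))
    cfg$sim$seed <- cfg$seed
  }
  if (cfg$traits[1] != "gsv")
    stop("the first scanned trait must be 'gsv'")
  class(cfg) <- "gv_run_config"
  cfg
}

#' Run the full grain-size-variance analysis chain
#'
#' Executes, in order: data simulation (or loading), per-plot grain
#' distribution metrics and yield-component derivation, spatial adjustment
#' and heritability, descriptive statistics, marker QC / imputation /
#' pruning, LOCO kinship and the mixed-model scan over all traits and
#' environments, GSV QTL interval construction, driven/specific
#' classification with cross-environment commonality, and variance
#' partitioning with forward-AIC selection.  All intermediates are written
#' as plain text under `config$out_dir`, plus a machine-readable JSON
#' report; the run is deterministic for a fixed seed.
#'
#' @param config a [run_config()] object.
#' @return the report, invisibly also written to
#'   `file.path(out_dir, "report.json")`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "gv_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- function(f) file.path(config$out_dir, f)
  stage <- "simulate"
  report <- list(package = "grainvar",
                 version = as.character(utils::packageVersion("grainvar")),
                 seed = config$seed, stages = list(), tables = list())
  on_fail <- function(e) {
    writeLines(paste0("FAILED at stage: ", stage, "\n", conditionMessage(e)),
               od("FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    ## 1. inputs -------------------------------------------------------
    if (!is.null(config$sim)) {
      panel_raw <- simulate_genotypes(config$sim)
      trial <- simulate_trial(config$sim, panel_raw)
      plots <- trial$plots
      grains <- trial$grains
      jsonlite::write_json(
        list(qtl = trial$truth$qtl,
             variance_components = trial$truth$variance_components,
             clipped = as.list(trial$truth$clipped)),
        od("truth.json"), auto_unbox = TRUE, digits = NA, na = "null")
    } else {
      panel_raw <- read_genotypes_tsv(config$genotype_tsv, config$map_tsv)
      plots <- as.data.frame(data.table::fread(config$plots_csv))
      grains <- as.data.frame(data.table::fread(config$grains_csv))
      trial <- NULL
    }
    write_genotypes_tsv(panel_raw, od("genotypes.tsv"), od("map.tsv"))
    write_genotypes_vcf(panel_raw, od("genotypes.vcf"))
    if (config$write_grains)
      data.table::fwrite(grains, od("grains.csv"))
    report$stages$simulate <- list(n_genotypes = nrow(panel_raw$dosage),
                                   n_markers = ncol(panel_raw$dosage),
                                   n_plots = nrow(plots),
                                   n_grains = nrow(grains))

    ## 2. grain metrics + derived components --------------------------
    stage <- "metrics"
    gm <- grain_metrics_table(grains)
    plots <- merge(plots, gm, by = "plot_id", sort = FALSE)
    comp <- derive_components(plots$gy, plots$spm2, plots$tkw)
    plots$gpm2 <- comp$gpm2
    plots$gps <- comp$gps
    data.table::fwrite(plots, od("plots.csv"))
    report$stages$metrics <- list(n_plots = nrow(gm),
                                  mean_grains_per_plot =
                                    mean(gm$n_grains))

    ## 3. spatial adjustment + heritability ---------------------------
    stage <- "adjust"
    all_traits <- unique(c(config$traits, "gsm", "p5", "p95"))
    adj <- do.call(rbind, lapply(all_traits, function(tr)
      adjusted_means(plots, tr)))
    herit <- do.call(rbind, lapply(all_traits, function(tr)
      heritability_panel2016(plots, tr)))
    data.table::fwrite(adj, od("adjusted_means.csv"))
    data.table::fwrite(herit, od("heritability.csv"))
    report$stages$adjust <- list(n_adjusted = nrow(adj))
    report$tables$heritability <- herit

    ## 4. descriptive statistics --------------------------------------
    stage <- "stats"
    envs <- unique(plots$env)
    cvs <- cv_summary(adj)
    cors <- do.call(rbind, lapply(envs, function(e)
      correlation_panel(adj, config$traits, e)))
    data.table::fwrite(cvs, od("table1_cv.csv"))
    data.table::fwrite(cors, od("correlations.csv"))
    report$tables$cv <- cvs
    report$tables$correlations <- cors
    if (length(envs) >= 2) {
      anv <- do.call(rbind, lapply(c("gsm", "gsv", "p95", "p5"),
                                   function(m) {
        a <- environment_anova(adj, m); a$metric <- m; a
      }))
      data.table::fwrite(anv, od("env_anova.csv"))
      report$tables$env_anova <- anv
    }

    ## 5. marker QC and GWAS ------------------------------------------
    stage <- "gwas"
    panel <- qc_filter(panel_raw, config$max_missing, config$min_maf)
    qc_log <- attr(panel, "qc_log")
    panel <- impute_missing(panel)
    panel <- prune_redundant(panel, config$prune_r2)
    prune_log <- attr(panel, "prune_log")
    K <- kinship_loco(panel)
    scan <- do.call(rbind, lapply(envs, function(e)
      do.call(rbind, lapply(config$traits, function(tr)
        mlm_scan(adj, panel, K, tr, e,
                 lod_threshold = config$lod_threshold)))))
    data.table::fwrite(scan, od("gwas.tsv"), sep = "\t")
    report$stages$gwas <- list(
      qc = as.list(qc_log), pruned = as.list(prune_log),
      n_tests = nrow(scan),
      n_significant = sum(scan$significant, na.rm = TRUE),
      n_significant_gsv = sum(scan$significant & scan$trait == "gsv",
                              na.rm = TRUE))

    ## 6. QTL construction (GSV) --------------------------------------
    stage <- "qtl"
    crit <- critical_ld(panel, config$n_unlinked_pairs,
                        seed = config$seed + 101L,
                        method = config$critical_method)
    decay <- fit_ld_decay(panel, n_pairs = config$decay_pairs,
                          seed = config$seed + 102L)
    d_star <- decay$crossing(crit)
    qtl_by_env <- list()
    for (e in envs) {
      sig <- scan[scan$significant & scan$trait == "gsv" &
                    scan$env == e, , drop = FALSE]
      if (!nrow(sig)) {
        qtl_by_env[[e]] <- empty_qtl_table()
        next
      }
      blocks <- ld_blocks(sig, panel, crit)
      qtl_by_env[[e]] <- build_qtl(blocks, decay, crit, assoc = sig,
                                   chrom_len = panel$chrom_len)
    }
    report$stages$qtl <- list(
      critical_ld = crit$value, rho = decay$rho, d_star_bp = d_star,
      n_qtl = sum(vapply(qtl_by_env, nrow, integer(1))))

    ## 7. classification + variance partition -------------------------
    stage <- "classify"
    comp_traits <- setdiff(config$traits, "gsv")
    classified <- list()
    for (e in envs) {
      hits <- scan[scan$significant & scan$env == e &
                     scan$trait %in% comp_traits, , drop = FALSE]
      classified[[e]] <- classify_qtl(qtl_by_env[[e]], hits, e,
                                      rule = config$coloc_rule,
                                      component_set = comp_traits)
    }
    cx <- cross_environment(classified)
    parts <- list(); steps <- list()
    for (e in envs) {
      q <- classified[[e]]
      if (!nrow(q)) {
        parts[[e]] <- data.frame(env = e, r2_all = 0, r2_specific = 0,
                                 r2_driven = 0, n_all = 0L,
                                 n_specific = 0L, n_driven = 0L)
        steps[[e]] <- data.frame(env = e, n_selected = 0L,
                                 n_driven_selected = 0L, r2_opt = 0)
        next
      }
      sig_e <- scan[scan$significant & scan$trait == "gsv" &
                      scan$env == e, , drop = FALSE]
      q <- peak_selection(q, sig_e, rule = config$peak_rule)
      classified[[e]] <- q
      adj_gsv <- adj[adj$trait == "gsv" & adj$env == e, ]
      parts[[e]] <- variance_partition(adj_gsv, panel, q, env = e)
      d <- peak_design(adj_gsv, panel,
                       unique(q$sel_snp[!is.na(q$sel_snp)]))
      st <- stepwise_opt(d$y, d$X)
      n_drv <- sum(q$class[match(st$selected, q$sel_snp)] == "driven",
                   na.rm = TRUE)
      steps[[e]] <- data.frame(env = e, n_selected = st$n_selected,
                               n_driven_selected = n_drv,
                               r2_opt = st$r2_opt)
    }
    part_tab <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
    step_tab <- do.call(rbind, c(steps, list(make.row.names = FALSE)))
    class_tab <- do.call(rbind, c(unname(classified),
                                  list(make.row.names = FALSE)))
    data.table::fwrite(class_tab, od("qtl_classified.tsv"), sep = "\t")
    if (nrow(class_tab)) write_qtl_bed(class_tab, od("qtl.bed"))
    if (!is.null(cx$tally)) data.table::fwrite(cx$tally, od("table4_tally.csv"))
    data.table::fwrite(cbind(part_tab, step_tab[, -1, drop = FALSE]),
                       od("table5_partition.csv"))
    report$stages$classify <- list(
      n_classified = nrow(class_tab),
      n_driven = sum(class_tab$class == "driven"),
      n_specific = sum(class_tab$class == "specific"))
    report$tables$tally <- cx$tally
    report$tables$partition <- cbind(part_tab,
                                     step_tab[, -1, drop = FALSE])

    ## 8. report -------------------------------------------------------
    stage <- "report"
    report$config <- list(
      lod_threshold = config$lod_threshold, prune_r2 = config$prune_r2,
      max_missing = config$max_missing, min_maf = config$min_maf,
      critical_method = config$critical_method,
      peak_rule = config$peak_rule, coloc_rule = config$coloc_rule,
      traits = config$traits)
    jsonlite::write_json(report, od("report.json"), auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
    report
  }, error = on_fail)
}
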