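# Orchestration: a single entry point chaining simulate -> normalize/QC ->
# array QC -> reproducibility -> concordance, with a run manifest written
# first and a human-readable summary written last. All numeric outputs are
# plain TSV/CSV/JSON so every figure is backed by a testable table.

#' Default pipeline configuration
#'
#' @param seed simulation seed.
#' @param sim a [sim_config()] (stored as a plain list in the manifest).
#' @param stages named logical vector enabling each stage.
#' @param exclude_qc_failures drop QC-failed lanes before the
#'   reproducibility and concordance stages (the paper-style 29-of-30
#'   analysis); failures are recorded in the manifest either way.
#' @param pool_sizes pooling-curve sample sizes per group.
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, sim = sim_config(),
                            stages = c(simulate = TRUE, normalize = TRUE,
                                       array_qc = TRUE, reproducibility = TRUE,
                                       concordance = TRUE),
                            exclude_qc_failures = TRUE,
                            pool_sizes = c(3, 15, 30)) {
  structure(list(seed = seed, sim = sim, stages = stages,
                 exclude_qc_failures = exclude_qc_failures,
                 pool_sizes = pool_sizes),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys: `seed`, `exclude_qc_failures`, `pool_sizes`, `stages`
#' (named logicals) and `sim` (any [sim_config()] field). Unknown sim fields
#' are rejected.
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  bad <- setdiff(names(sim_args), names(formals(sim_config)))
  if (length(bad)) stop("unknown sim config field: ", paste(bad, collapse = ", "))
  cfg <- pipeline_config(seed = raw$seed %||% 1,
                         sim = do.call(sim_config, sim_args))
  if (!is.null(raw$stages)) {
    st <- cfg$stages
    bad <- setdiff(names(raw$stages), names(st))
    if (length(bad)) stop("unknown stage: ", paste(bad, collapse = ", "))
    st[names(raw$stages)] <- vapply(raw$stages, isTRUE, logical(1))
    cfg$stages <- st
  }
  if (!is.null(raw$exclude_qc_failures)) {
    cfg$exclude_qc_failures <- isTRUE(raw$exclude_qc_failures)
  }
  if (!is.null(raw$pool_sizes)) cfg$pool_sizes <- as.integer(raw$pool_sizes)
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) the dual-platform dataset, runs lane QC and the
#' normalization chain, the array QC metrics, the reproducibility battery
#' and the concordance stage, writing every result table under `out_dir`.
#' The manifest (config snapshot, seed, input digests, stage status,
#' excluded samples with machine-readable reasons) is written before any
#' stage runs and finalized at the end; the markdown summary is written
#' last. Outputs are deterministic given the seed.
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @param out_dir output directory.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("concordx")),
    seed = config$seed,
    config = list(sim = unclass(config$sim), stages = as.list(config$stages),
                  exclude_qc_failures = config$exclude_qc_failures,
                  pool_sizes = config$pool_sizes),
    stages = list(), excluded_samples = list(), input_digests = list())
  manifest_path <- file.path(out_dir, "manifest.json")
  save_manifest <- function() {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  save_manifest()

  results <- list()
  stage <- function(name, enabled, fun) {
    if (!enabled) {
      manifest$stages[[name]] <<- "skipped"
      save_manifest()
      return(NULL)
    }
    out <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- paste0("error: ", conditionMessage(e))
      save_manifest()
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- "ok"
    save_manifest()
    out
  }

  sim <- stage("simulate", config$stages[["simulate"]], function() {
    truth <- generate_truth(config$sim, seed = config$seed)
    design <- make_design(config$sim)
    list(truth = truth, design = design,
         count = simulate_count_platform(truth, design),
         array = simulate_array_platform(truth, design))
  })
  if (is.null(sim)) {
    message("pipeline: simulate disabled; nothing further to run")
    return(invisible(list(manifest = manifest)))
  }
  results$sim <- sim
  data_dir <- file.path(out_dir, "data")
  write_dataset(data_dir, sim$truth, sim$design, sim$count, sim$array)
  files <- list.files(data_dir, recursive = TRUE, full.names = TRUE)
  manifest$input_digests <- as.list(stats::setNames(
    unname(tools::md5sum(files)), basename(files)))
  save_manifest()

  panel <- sim$truth$panel
  meta <- sim$design
  endo_hk <- panel$probe_id[panel$code_class %in%
                              c("Endogenous", "Housekeeping")]

  norm <- stage("normalize", config$stages[["normalize"]], function() {
    qc <- qc_lanes(sim$count$lanes, panel)
    chain <- normalize_chain(sim$count$matrix, panel)
    list(qc = qc, matrix = chain$matrix, factors = chain$factors)
  })
  keep <- meta$sample_id
  if (!is.null(norm)) {
    results$norm <- norm
    utils::write.csv(norm$qc, file.path(out_dir, "lane_qc.csv"),
                     row.names = FALSE)
    write_tsv(norm$factors, file.path(out_dir, "normalization_factors.tsv"))
    write_expression_matrix(norm$matrix,
                            file.path(out_dir, "count_normalized.tsv"))
    meta$qc_pass <- norm$qc$pass[match(meta$sample_id, norm$qc$sample_id)]
    failed <- norm$qc[!norm$qc$pass, ]
    manifest$excluded_samples <- lapply(seq_len(nrow(failed)), function(i) {
      list(sample_id = failed$sample_id[i],
           reason = paste0("qc_fail:", failed$flags[i]))
    })
    if (config$exclude_qc_failures) {
      keep <- meta$sample_id[meta$qc_pass]
    }
    save_manifest()
    write_sample_table(meta, file.path(out_dir, "metadata_qc.csv"))
  }

  aqc <- stage("array_qc", config$stages[["array_qc"]], function() {
    k <- config$sim$n_probes_per_gene
    ctrl_genes <- utils::head(
      panel$probe_id[panel$code_class == "Housekeeping"], 2)
    control_map <- lapply(ctrl_genes, function(g) {
      sprintf("%s_p%02d", g, seq_len(k))
    })
    names(control_map) <- ctrl_genes
    array_qc_report(sim$array$probes, sim$array$positions, control_map)
  })
  if (!is.null(aqc)) {
    results$array_qc <- aqc
    utils::write.csv(aqc, file.path(out_dir, "array_qc.csv"),
                     row.names = FALSE)
  }

  rep_out <- stage("reproducibility", config$stages[["reproducibility"]],
                   function() {
    if (is.null(norm)) stop("reproducibility requires the normalize stage")
    raw_log2 <- expr_matrix(
      log2(sim$count$matrix$values[endo_hk, , drop = FALSE] + 1),
      "count_platform", "log2")
    outliers <- flag_distribution_outliers(raw_log2)
    m_norm <- subset_expr(norm$matrix, genes = endo_hk, samples = keep)
    m_log2 <- log2_transform(m_norm)
    meta_keep <- meta[meta$sample_id %in% keep, ]
    corr <- pairwise_pearson(m_log2)
    pca <- pca_scores(m_log2)
    clust <- hierarchical_cluster(m_log2, k = 2)
    prec <- precision_report(m_norm, meta_keep)
    lab_pair <- meta_keep[meta_keep$lab == "Lab1", ]
    partner <- sprintf("%s_Lab2_D%d", lab_pair$case_id, lab_pair$day)
    partner_ok <- partner %in% keep
    site_r <- between_group_scatter_r(
      m_log2, m_log2,
      stats::setNames(partner[partner_ok], lab_pair$sample_id[partner_ok]))
    # ANOVA needs the balanced layout, so it runs on the full design
    full_log2 <- log2_transform(subset_expr(norm$matrix, genes = endo_hk))
    anova <- lapply(c(TNB = "TNB", ERpos = "ERpos"), function(st) {
      ids <- meta$sample_id[meta$subtype == st]
      anova_ms(subset_expr(full_log2, samples = ids),
               meta[meta$sample_id %in% ids, ])
    })
    list(outliers = outliers, correlation = corr, pca = pca, clust = clust,
         precision = prec, between_site_r = site_r, anova = anova,
         raw_log2 = raw_log2, m_log2 = m_log2)
  })
  if (!is.null(rep_out)) {
    results$reproducibility <- rep_out
    writeLines(rep_out$outliers, file.path(out_dir, "outlier_samples.txt"))
    write_tsv(data.frame(sample_id = rownames(rep_out$correlation),
                         round(rep_out$correlation, 6),
                         check.names = FALSE),
              file.path(out_dir, "correlation_matrix.tsv"))
    write_tsv(data.frame(sample_id = rownames(rep_out$pca$scores),
                         rep_out$pca$scores,
                         cluster = rep_out$clust$labels[
                           rownames(rep_out$pca$scores)]),
              file.path(out_dir, "pca_scores.tsv"))
    for (st in names(rep_out$anova)) {
      if (!is.null(rep_out$anova[[st]])) {
        write_tsv(rep_out$anova[[st]]$table,
                  file.path(out_dir, paste0("anova_ms_", st, ".tsv")))
      }
    }
    write_tsv(data.frame(metric = c("median_intra_cv", "median_inter_cv",
                                    "replicate_r2_min", "between_site_r"),
                         value = c(rep_out$precision$median_intra_cv,
                                   rep_out$precision$median_inter_cv,
                                   rep_out$precision$replicate_r2_min,
                                   rep_out$between_site_r)),
              file.path(out_dir, "precision_summary.tsv"))
  }

  conc <- stage("concordance", config$stages[["concordance"]], function() {
    if (is.null(norm)) stop("concordance requires the normalize stage")
    map <- build_gene_map(panel, sim$array$annotation, sim$array$gene)
    arr <- apply_gene_map(map, sim$array$gene)
    mc_norm <- subset_expr(norm$matrix, genes = names(map$resolved),
                           samples = keep)
    arr_keep <- subset_expr(arr, samples = intersect(keep,
                                                     colnames(arr$values)))
    meta_keep <- meta[meta$sample_id %in% keep, ]
    xr <- cross_platform_sample_r(
      log2_transform(mc_norm), log2_transform(arr_keep),
      stats::setNames(colnames(mc_norm$values), colnames(mc_norm$values)))
    fc <- fold_change_table(mc_norm, arr_keep, meta_keep)
    strat <- stratified_fc_correlation(fc)
    two <- classify_twofold(fc)
    band <- classify_regression_band(two$table)
    pool <- pooling_curve(mc_norm, arr_keep, meta_keep,
                          pool_sizes = pmin(config$pool_sizes,
                                            min(table(meta_keep$subtype))),
                          n_resample = 50, seed = config$seed)
    list(map = map, cross_r = xr, fc = band$table, strat = strat,
         twofold = two, band = band, pooling = pool)
  })
  if (!is.null(conc)) {
    results$concordance <- conc
    write_tsv(conc$fc, file.path(out_dir, "foldchange_table.tsv"))
    jsonlite::write_json(conc$band$fit, file.path(out_dir, "bandfit.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(fc_correlation = conc$strat,
           twofold = list(counts = as.list(conc$twofold$summary$counts),
                          concordant_fraction =
                            conc$twofold$summary$concordant_fraction),
           band = list(counts = as.list(conc$band$summary$counts),
                       concordant_fraction =
                         conc$band$summary$concordant_fraction),
           cross_platform = conc$cross_r[c("within_count", "within_array",
                                           "between_summary")]),
      file.path(out_dir, "concordance_summary.json"),
      auto_unbox = TRUE, digits = NA)
    write_tsv(conc$pooling[, c("pool_size", "r", "r_median")],
              file.path(out_dir, "pooling_curve.tsv"))
  }

  manifest$stages[["summary"]] <- "ok"
  save_manifest()
  render_summary(out_dir)
  invisible(c(results, list(manifest = manifest)))
}

#' Render summary figures and markdown from pipeline outputs
#'
#' Reads the tables written by [run_pipeline()] and produces PNG figures
#' (raw-count boxplot, correlation heatmap, PCA scatter, dendrogram,
#' MS-vs-MS scatter, fold-change scatter with regression band) plus
#' `summary.md`. Every figure is backed by one of the TSV outputs, so its
#' numbers are testable without image parsing.
#'
#' @param out_dir a directory populated by [run_pipeline()].
#' @return paths of the files written, invisibly.
#' @export
render_summary <- function(out_dir) {
  need <- function(f) {
    p <- file.path(out_dir, f)
    if (!file.exists(p)) stop("missing stage output: ", f)
    p
  }
  written <- character(0)
  fig <- function(name, expr) {
    p <- file.path(out_dir, name)
    grDevices::png(p, width = 900, height = 700)
    on.exit(grDevices::dev.off(), add = TRUE)
    force(expr)
    written <<- c(written, p)
  }

  raw <- read_expression_matrix(need("data/count_raw.tsv"))
  fig("fig_boxplot.png", {
    graphics::boxplot(log2(raw$values + 1), las = 2, cex.axis = 0.5,
                      main = "Raw counts per lane (log2)",
                      ylab = "log2(count + 1)")
  })

  corr <- utils::read.delim(need("correlation_matrix.tsv"),
                            check.names = FALSE)
  cm <- as.matrix(corr[, -1])
  rownames(cm) <- corr$sample_id
  fig("fig_correlation_heatmap.png", {
    graphics::image(seq_len(nrow(cm)), seq_len(ncol(cm)),
                    cm[, rev(seq_len(ncol(cm)))],
                    col = grDevices::hcl.colors(64, "Blues", rev = TRUE),
                    axes = FALSE, xlab = "", ylab = "",
                    main = "Pairwise Pearson correlation")
  })

  pca <- utils::read.delim(need("pca_scores.tsv"))
  fig("fig_pca.png", {
    graphics::plot(pca$PC1, pca$PC2, col = pca$cluster, pch = 19,
                   xlab = "PC1", ylab = "PC2", main = "PCA sample scores")
  })

  fig("fig_dendrogram.png", {
    d <- stats::as.dist(1 - cm)
    graphics::plot(stats::hclust(d, method = "average"), cex = 0.5,
                   main = "Average-linkage clustering (1 - Pearson)")
  })

  ms_files <- list.files(out_dir, pattern = "^anova_ms_.*\\.tsv$")
  if (length(ms_files)) {
    fig("fig_ms_scatter.png", {
      graphics::par(mfrow = c(1, length(ms_files)))
      for (f in ms_files) {
        tab <- utils::read.delim(file.path(out_dir, f))
        lim <- range(c(tab$ms_sample, tab$ms_residual))
        graphics::plot(tab$ms_residual, tab$ms_sample, log = "xy",
                       xlim = lim, ylim = lim, pch = 20, cex = 0.5,
                       xlab = "residual MS", ylab = "case MS",
                       main = sub("^anova_ms_(.*)\\.tsv$", "\\1", f))
        graphics::abline(0, 1, col = "red")
      }
    })
  }

  fc <- utils::read.delim(need("foldchange_table.tsv"))
  band <- jsonlite::read_json(need("bandfit.json"), simplifyVector = TRUE)
  fig("fig_fc_band.png", {
    graphics::plot(fc$log2fc_array, fc$log2fc_count, pch = 20, cex = 0.6,
                   col = c(in_band = "grey40", out_band_same_dir = "darkgreen",
                           out_band_opposite = "red")[fc$tier_band],
                   xlab = "array log2 FC (ER+/TNB)",
                   ylab = "count log2 FC (ER+/TNB)",
                   main = "Cross-platform fold changes with regression band")
    graphics::abline(band$intercept, band$slope)
    graphics::abline(band$intercept + band$band_halfwidth, band$slope,
                     lty = 2, col = "red")
    graphics::abline(band$intercept - band$band_halfwidth, band$slope,
                     lty = 2, col = "red")
    graphics::legend("topleft",
                     legend = c("in band", "out of band, same direction",
                                "out of band, opposite"),
                     col = c("grey40", "darkgreen", "red"),
                     pch = 20, bty = "n")
  })

  prec <- utils::read.delim(need("precision_summary.tsv"))
  outliers <- readLines(need("outlier_samples.txt"), warn = FALSE)
  summ <- jsonlite::read_json(need("concordance_summary.json"),
                              simplifyVector = TRUE)
  md <- c(
    "# Pipeline summary", "",
    sprintf("- Flagged distribution outliers: %s",
            if (length(outliers)) paste(outliers, collapse = ", ") else "none"),
    sprintf("- Between-site pooled log2 correlation r = %.4f",
            prec$value[prec$metric == "between_site_r"]),
    sprintf("- Median intra-assay CV = %.2f%%; median inter-assay CV = %.2f%%",
            prec$value[prec$metric == "median_intra_cv"],
            prec$value[prec$metric == "median_inter_cv"]),
    sprintf("- Minimum within-case replicate R^2 = %.4f",
            prec$value[prec$metric == "replicate_r2_min"]),
    sprintf("- Fold-change correlation overall r = %.4f (low %.4f, medium %.4f, high %.4f)",
            summ$fc_correlation$overall, summ$fc_correlation$by_stratum[1],
            summ$fc_correlation$by_stratum[2],
            summ$fc_correlation$by_stratum[3]),
    sprintf("- Two-fold classifier concordant fraction = %.3f",
            summ$twofold$concordant_fraction),
    sprintf("- Regression-band classifier concordant fraction = %.3f (band half-width %.4f)",
            summ$band$concordant_fraction, band$band_halfwidth),
    "", "Figures: fig_boxplot.png, fig_correlation_heatmap.png, fig_pca.png,",
    "fig_dendrogram.png, fig_ms_scatter.png, fig_fc_band.png")
  summary_path <- file.path(out_dir, "summary.md")
  writeLines(md, summary_path)
  invisible(c(written, summary_path))
}
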