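# Dual-platform synthetic data generator with planted ground truth.
#
# The generator emulates the analytical-validation study design this package
# analyses: 10 FFPE breast-tumor cases (5 triple-negative, 5 ER+ with an
# ER+ case 1-3 vs 4-5 subgroup split), RNA extracted in 2 labs on 3 days
# (6 technical replicates per case, 60 samples), measured on a 346-probe
# count panel (325 endogenous + 7 housekeeping + 6 positive + 8 negative)
# and on a hybridization-intensity array. Counts follow a negative-binomial
# observation model; array intensities are a compressed power transform of
# the same underlying abundances with independent per-gene affinities plus a
# positive background floor, which is what makes absolute cross-platform
# correlation poor while fold changes stay moderately concordant.

#' Simulation configuration
#'
#' Returns the default configuration; override any field by argument. The
#' defaults mirror the study conditions: 60 samples, 346 probes, 2 planted
#' degraded outlier lanes (case 4 TNB and case 5 ER+, both Lab2 day 2, low
#' RNA mass), and ~5% of endogenous genes planted with opposite-signed
#' between-platform fold changes.
#'
#' @param n_endogenous,n_housekeeping,n_positive,n_negative panel composition.
#' @param n_cases_per_subtype,n_labs,n_days replicate design.
#' @param baseline_log2_mean,baseline_log2_sd log2 distribution of endogenous
#'   baseline counts at the reference (TNB) condition.
#' @param hk_baseline_log2_mean,hk_baseline_log2_sd housekeeping baselines.
#' @param subtype_effect_sd sd of per-gene log2 ER+/TNB effects (shared across
#'   platforms for concordant genes).
#' @param subgroup_fraction,subgroup_shift_sd,subgroup_cases fraction of
#'   endogenous genes carrying an extra log2 shift in the ER+ subgroup cases.
#' @param n_discordant,discordant_min_lfc,discordant_baseline_range planted
#'   discordant genes: opposite-signed platform effects with |log2FC| >= the
#'   minimum on both platforms; baselines are redrawn log-uniformly inside
#'   `discordant_baseline_range` — modestly expressed but safely
#'   quantifiable on both platforms, reflecting that probe-specific
#'   cross-platform disagreement afflicts dimmer targets more than bright
#'   ones.
#' @param fc_jitter_log2_sd,fc_jitter_ref_signal per-gene array-platform
#'   response jitter added to the subtype effect of non-discordant endogenous
#'   genes, with sd `fc_jitter_log2_sd * sqrt(ref / (ref + baseline *
#'   affinity_array))` — probe-chemistry response heterogeneity that makes
#'   fold changes noisier for weakly expressed genes.
#' @param nb_dispersion negative-binomial dispersion (1/size) of counts.
#' @param lane_scale_log2_sd lane-to-lane global efficiency jitter (log2 sd).
#' @param lab_effect_log2_sd,day_effect_log2_sd per-gene batch offsets.
#' @param affinity_log2_sd per-gene, per-platform probe affinity spread.
#' @param compression_exponent power-law signal compression of the array
#'   platform (1 = none).
#' @param array_noise_log2_sd,array_background,array_background_log2_sd
#'   multiplicative array noise and additive positive background.
#' @param probe_decay,n_probes_per_gene,probe_noise_log2_sd 3'->5' intensity
#'   decay per probe step for the synthetic probe-level array data.
#' @param pos_counts_per_fM,pos_conc,neg_mean positive-control ladder gain and
#'   nominal concentrations (fM), and negative-control background mean.
#' @param binding_density_scale total lane counts per unit binding density.
#' @param fov_requested imaging fields of view requested per lane.
#' @param outlier_samples,outlier_severity,outlier_scale_log2,
#'   outlier_extra_log2_sd planted degraded lanes: counts scaled by
#'   `2^(outlier_scale_log2 * severity)` with extra multiplicative dispersion;
#'   imaging metrics degrade with severity so maximal severity fails QC.
#' @param rna_mass_ng,outlier_rna_mass_ng,rna_mass_min_ng recorded RNA input
#'   masses and the acceptance cutoff.
#' @return named list of class `sim_config`.
#' @export
sim_config <- function(n_endogenous = 325, n_housekeeping = 7,
                       n_positive = 6, n_negative = 8,
                       n_cases_per_subtype = 5, n_labs = 2, n_days = 3,
                       baseline_log2_mean = 10.5, baseline_log2_sd = 1.3,
                       hk_baseline_log2_mean = 11, hk_baseline_log2_sd = 0.5,
                       subtype_effect_sd = 1.2,
                       subgroup_fraction = 0.25, subgroup_shift_sd = 1,
                       subgroup_cases = c("ER4", "ER5"),
                       n_discordant = 16, discordant_min_lfc = 2,
                       discordant_baseline_range = c(512, 1024),
                       fc_jitter_log2_sd = 0.8, fc_jitter_ref_signal = 256,
                       nb_dispersion = 0.005,
                       lane_scale_log2_sd = 0.15,
                       lab_effect_log2_sd = 0.05, day_effect_log2_sd = 0.03,
                       affinity_log2_sd = 1.5,
                       compression_exponent = 0.7,
                       array_noise_log2_sd = 0.35,
                       array_background = 10, array_background_log2_sd = 0.2,
                       probe_decay = 0.1, n_probes_per_gene = 11,
                       probe_noise_log2_sd = 0.05,
                       pos_counts_per_fM = 60,
                       pos_conc = c(128, 32, 8, 2, 0.5, 0.125),
                       neg_mean = 2,
                       binding_density_scale = 2.5e6,
                       fov_requested = 280,
                       outlier_samples = c("TNB4_Lab2_D2", "ER5_Lab2_D2"),
                       outlier_severity = 1,
                       outlier_scale_log2 = -3, outlier_extra_log2_sd = 1.5,
                       rna_mass_ng = 100, outlier_rna_mass_ng = 20,
                       rna_mass_min_ng = 50) {
  cfg <- as.list(environment())
  if (length(cfg$pos_conc) != cfg$n_positive) {
    stop("pos_conc must have n_positive entries")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Default panel annotation for a configuration
#'
#' Endogenous probes are named `BMK001..`, housekeeping `HK01..`, positive
#' controls `POS_A..` with the descending concentration ladder, negative
#' controls `NEG_A..`.
#'
#' @param config a [sim_config()].
#' @return `panel_annotation`.
#' @export
make_panel <- function(config = sim_config()) {
  endo <- sprintf("BMK%03d", seq_len(config$n_endogenous))
  hk <- sprintf("HK%02d", seq_len(config$n_housekeeping))
  pos <- paste0("POS_", LETTERS[seq_len(config$n_positive)])
  neg <- paste0("NEG_", LETTERS[seq_len(config$n_negative)])
  panel_annotation(data.frame(
    probe_id = c(endo, hk, pos, neg),
    gene_symbol = c(endo, hk, pos, neg),
    code_class = rep(c("Endogenous", "Housekeeping", "Positive", "Negative"),
                     times = c(length(endo), length(hk), length(pos),
                               length(neg))),
    nominal_conc = c(rep(0, length(endo) + length(hk)), config$pos_conc,
                     rep(0, length(neg))),
    stringsAsFactors = FALSE))
}

#' Default replicate design table
#'
#' Case ids are `TNB1..TNB5` and `ER1..ER5`; sample ids are
#' `<case>_<lab>_D<day>`. Planted outlier lanes are recorded with RNA mass
#' below the acceptance cutoff, as in a degraded FFPE extraction.
#'
#' @param config a [sim_config()].
#' @return `sample_table` with `n_cases * n_labs * n_days` rows.
#' @export
make_design <- function(config = sim_config()) {
  cases <- c(paste0("TNB", seq_len(config$n_cases_per_subtype)),
             paste0("ER", seq_len(config$n_cases_per_subtype)))
  grid <- expand.grid(day = seq_len(config$n_days),
                      lab = paste0("Lab", seq_len(config$n_labs)),
                      case_id = cases, stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s_%s_D%d", grid$case_id, grid$lab, grid$day)
  grid$subtype <- ifelse(grepl("^TNB", grid$case_id), "TNB", "ERpos")
  grid$operator <- ifelse(grid$lab == "Lab1", "OP1", "OP2")
  grid$rna_mass_ng <- ifelse(grid$sample_id %in% config$outlier_samples,
                             config$outlier_rna_mass_ng, config$rna_mass_ng)
  grid$qc_pass <- NA
  sample_table(grid[order(grid$sample_id),
                    c("sample_id", "case_id", "subtype", "lab", "day",
                      "operator", "rna_mass_ng", "qc_pass")])
}

#' Generate the planted ground truth
#'
#' Draws all per-gene parameters (baselines, subtype effects, ER+ subgroup
#' shifts, discordant-gene platform effects, batch offsets, platform
#' affinities) deterministically from the seed. Housekeeping genes have zero
#' subtype effect; discordant genes are endogenous only, with opposite-signed
#' effects of magnitude at least `discordant_min_lfc` on both platforms and
#' baselines forced high enough to be measurable.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the same seed and config give bit-identical
#'   truth and downstream simulated data.
#' @return list of class `synthetic_truth`.
#' @export
generate_truth <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_discordant > config$n_endogenous) {
    stop("n_discordant exceeds the number of endogenous genes")
  }
  set.seed(seed)
  panel <- make_panel(config)
  endo <- panel$probe_id[panel$code_class == "Endogenous"]
  hk <- panel$probe_id[panel$code_class == "Housekeeping"]
  genes <- c(endo, hk)
  ng <- length(genes)
  is_hk <- genes %in% hk

  baseline <- 2^c(stats::rnorm(length(endo), config$baseline_log2_mean,
                               config$baseline_log2_sd),
                  stats::rnorm(length(hk), config$hk_baseline_log2_mean,
                               config$hk_baseline_log2_sd))
  effect <- stats::rnorm(ng, 0, config$subtype_effect_sd)
  effect[is_hk] <- 0

  n_sub <- floor(config$subgroup_fraction * length(endo))
  subgroup_genes <- sort(sample(endo, n_sub))
  subgroup_shift <- numeric(ng)
  subgroup_shift[genes %in% subgroup_genes] <-
    stats::rnorm(n_sub, 0, config$subgroup_shift_sd)

  discordant <- sort(sample(endo, config$n_discordant))
  is_disc <- genes %in% discordant

  affinity_count <- stats::setNames(
    2^stats::rnorm(ng, 0, config$affinity_log2_sd), genes)
  affinity_array <- stats::setNames(
    2^stats::rnorm(ng, 0, config$affinity_log2_sd), genes)

  if (any(is_disc)) {
    sgn <- sample(c(-1, 1), sum(is_disc), replace = TRUE)
    mag_c <- config$discordant_min_lfc + abs(stats::rnorm(sum(is_disc), 0, 0.5))
    mag_a <- config$discordant_min_lfc + abs(stats::rnorm(sum(is_disc), 0, 0.5))
    # modest but safely quantifiable baselines, drawn log-uniformly
    baseline[is_disc] <- 2^stats::runif(
      sum(is_disc), log2(config$discordant_baseline_range[1]),
      log2(config$discordant_baseline_range[2]))
  }

  # platform response jitter: per-gene array-side effect perturbation whose
  # sd shrinks with array signal (probe-chemistry heterogeneity near
  # background); never applied to housekeeping or planted discordant genes
  jitter_sd <- config$fc_jitter_log2_sd *
    sqrt(config$fc_jitter_ref_signal /
           (config$fc_jitter_ref_signal + baseline * affinity_array))
  fc_jitter <- stats::rnorm(ng, 0, 1) * jitter_sd
  fc_jitter[is_hk | is_disc] <- 0

  effect_count <- effect
  effect_array <- effect + fc_jitter
  if (any(is_disc)) {
    effect_count[is_disc] <- sgn * mag_c
    effect_array[is_disc] <- -sgn * mag_a
  }

  lab_effect <- matrix(stats::rnorm(ng * config$n_labs, 0,
                                    config$lab_effect_log2_sd),
                       ng, config$n_labs,
                       dimnames = list(genes,
                                       paste0("Lab", seq_len(config$n_labs))))
  day_effect <- matrix(stats::rnorm(ng * config$n_days, 0,
                                    config$day_effect_log2_sd),
                       ng, config$n_days,
                       dimnames = list(genes, paste0("D",
                                                     seq_len(config$n_days))))

  outliers <- data.frame(sample_id = config$outlier_samples,
                         severity = rep_len(config$outlier_severity,
                                            length(config$outlier_samples)),
                         stringsAsFactors = FALSE)

  structure(list(
    seed = seed, config = config, panel = panel,
    genes = data.frame(gene_id = genes,
                       class = ifelse(is_hk, "Housekeeping", "Endogenous"),
                       baseline = baseline,
                       effect_count = effect_count,
                       effect_array = effect_array,
                       subgroup_shift = subgroup_shift,
                       discordant = is_disc,
                       stringsAsFactors = FALSE),
    discordant_genes = discordant,
    subgroup_genes = subgroup_genes,
    subgroup_cases = config$subgroup_cases,
    lab_effect = lab_effect, day_effect = day_effect,
    affinity_count = affinity_count, affinity_array = affinity_array,
    compression_exponent = config$compression_exponent,
    outliers = outliers), class = "synthetic_truth")
}

# expected (noise-free) endogenous+housekeeping count-platform mean for one
# sample, excluding lane-level jitter; used by the simulator and by tests
planted_count_mean <- function(truth, case_id, subtype, lab, day) {
  g <- truth$genes
  er <- as.numeric(subtype == "ERpos")
  sub <- as.numeric(case_id %in% truth$subgroup_cases)
  log2mu <- log2(g$baseline) + g$effect_count * er + g$subgroup_shift * sub +
    truth$lab_effect[, lab] + truth$day_effect[, day]
  stats::setNames(2^log2mu * truth$affinity_count[g$gene_id], g$gene_id)
}

planted_array_signal <- function(truth, case_id, subtype, lab, day) {
  g <- truth$genes
  er <- as.numeric(subtype == "ERpos")
  sub <- as.numeric(case_id %in% truth$subgroup_cases)
  log2mu <- log2(g$baseline) + g$effect_array * er + g$subgroup_shift * sub +
    truth$lab_effect[, lab] + truth$day_effect[, day]
  stats::setNames((2^log2mu * truth$affinity_array[g$gene_id]) ^
                    truth$compression_exponent, g$gene_id)
}

#' Simulate the count platform
#'
#' Endogenous and housekeeping counts are negative-binomial around the
#' planted means times a lane-level efficiency factor; positive controls are
#' Poisson around the nominal ladder times the lane factor; negative controls
#' are Poisson background. Planted outlier lanes have counts globally scaled
#' down, extra multiplicative dispersion, reduced imaging FOV and low binding
#' density, so at maximal severity they fail lane QC by construction.
#'
#' @param truth a [generate_truth()] result.
#' @param design a `sample_table` covering any subgrid of the known cases.
#' @return list with `lanes` (list of `lane_counts`), `matrix` (raw
#'   `expr_matrix`, all panel probes), and `mu` (the planted endogenous +
#'   housekeeping mean matrix before lane effects, for verification).
#' @export
simulate_count_platform <- function(truth, design) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(design, "sample_table"))
  cfg <- truth$config
  known_cases <- c(paste0("TNB", seq_len(cfg$n_cases_per_subtype)),
                   paste0("ER", seq_len(cfg$n_cases_per_subtype)))
  bad <- setdiff(design$case_id, known_cases)
  if (length(bad)) stop("unknown case_id: ", paste(bad, collapse = ", "))

  panel <- truth$panel
  sev <- stats::setNames(rep(0, nrow(design)), design$sample_id)
  hit <- intersect(truth$outliers$sample_id, design$sample_id)
  sev[hit] <- truth$outliers$severity[match(hit, truth$outliers$sample_id)]

  set.seed(truth$seed + 1L)
  lane_scale <- stats::setNames(
    2^stats::rnorm(nrow(design), 0, cfg$lane_scale_log2_sd), design$sample_id)

  genes <- truth$genes$gene_id
  pos_ids <- panel$probe_id[panel$code_class == "Positive"]
  neg_ids <- panel$probe_id[panel$code_class == "Negative"]
  mu <- matrix(0, length(genes), nrow(design),
               dimnames = list(genes, design$sample_id))
  vals <- matrix(0, nrow(panel), nrow(design),
                 dimnames = list(panel$probe_id, design$sample_id))
  lanes <- vector("list", nrow(design))
  names(lanes) <- design$sample_id
  size <- if (cfg$nb_dispersion > 0) 1 / cfg$nb_dispersion else Inf

  for (i in seq_len(nrow(design))) {
    s <- design$sample_id[i]
    m0 <- planted_count_mean(truth, design$case_id[i], design$subtype[i],
                             design$lab[i], design$day[i])
    mu[, i] <- m0
    m <- m0 * lane_scale[s] * 2^(cfg$outlier_scale_log2 * sev[s])
    if (sev[s] > 0) {
      m <- m * 2^stats::rnorm(length(m), 0, cfg$outlier_extra_log2_sd * sev[s])
    }
    cnt <- if (is.finite(size)) {
      stats::rnbinom(length(m), mu = m, size = size)
    } else {
      stats::rpois(length(m), m)
    }
    pos_mu <- cfg$pos_conc * cfg$pos_counts_per_fM * lane_scale[s] *
      2^(cfg$outlier_scale_log2 * sev[s])
    pos_cnt <- stats::rpois(length(pos_mu), pos_mu)
    neg_cnt <- stats::rpois(length(neg_ids), cfg$neg_mean)
    counts <- stats::setNames(
      c(cnt, pos_cnt, neg_cnt)[match(panel$probe_id,
                                     c(genes, pos_ids, neg_ids))],
      panel$probe_id)
    fov_counted <- if (sev[s] > 0) {
      round(cfg$fov_requested * (1 - 0.35 * sev[s]))
    } else {
      cfg$fov_requested - stats::rpois(1, 2)
    }
    bd <- sum(counts) / cfg$binding_density_scale
    lanes[[s]] <- lane_counts(s, counts, cfg$fov_requested, fov_counted, bd)
    vals[, i] <- counts
  }
  list(lanes = lanes,
       matrix = expr_matrix(vals, "count_platform", "raw"),
       mu = mu)
}

#' Simulate the array platform
#'
#' Gene-level values are the compressed planted signal times multiplicative
#' log-normal noise plus a positive log-normal background, emulating
#' already-normalized hybridization intensities. The probe-level matrix
#' expands every gene into `n_probes_per_gene` ordered probes (position 1 =
#' 5'-most) with a geometric 3'->5' intensity gain of `1/(1 - probe_decay)`
#' per step, for QC-metric testing. No outlier lanes are planted on this
#' platform.
#'
#' @param truth a [generate_truth()] result.
#' @param design a `sample_table`.
#' @return list with `gene` (normalized `expr_matrix`), `probes` (raw
#'   probe-level `expr_matrix`), `positions` (probe_id, gene_id, position),
#'   and `annotation` (gene_symbol -> probe_set_id map for gene mapping).
#' @export
simulate_array_platform <- function(truth, design) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(design, "sample_table"))
  cfg <- truth$config
  known_cases <- c(paste0("TNB", seq_len(cfg$n_cases_per_subtype)),
                   paste0("ER", seq_len(cfg$n_cases_per_subtype)))
  bad <- setdiff(design$case_id, known_cases)
  if (length(bad)) stop("unknown case_id: ", paste(bad, collapse = ", "))

  set.seed(truth$seed + 2L)
  genes <- truth$genes$gene_id
  ng <- length(genes)
  vals <- matrix(0, ng, nrow(design),
                 dimnames = list(genes, design$sample_id))
  for (i in seq_len(nrow(design))) {
    sig <- planted_array_signal(truth, design$case_id[i], design$subtype[i],
                                design$lab[i], design$day[i])
    v <- sig * 2^stats::rnorm(ng, 0, cfg$array_noise_log2_sd)
    if (cfg$array_background > 0) {
      v <- v + cfg$array_background *
        2^stats::rnorm(ng, 0, cfg$array_background_log2_sd)
    }
    vals[, i] <- v
  }

  k <- cfg$n_probes_per_gene
  gain <- (1 / (1 - cfg$probe_decay))^(seq_len(k) - 1)
  probe_ids <- as.vector(t(outer(genes, seq_len(k),
                                 function(g, p) sprintf("%s_p%02d", g, p))))
  pv <- matrix(0, ng * k, nrow(design),
               dimnames = list(probe_ids, design$sample_id))
  for (i in seq_len(nrow(design))) {
    base <- rep(vals[, i], each = k) * rep(gain, times = ng)
    pv[, i] <- base * 2^stats::rnorm(ng * k, 0, cfg$probe_noise_log2_sd)
  }
  positions <- data.frame(probe_id = probe_ids,
                          gene_id = rep(genes, each = k),
                          position = rep(seq_len(k), times = ng),
                          stringsAsFactors = FALSE)
  list(gene = expr_matrix(vals, "array_platform", "normalized"),
       probes = expr_matrix(pv, "array_platform", "raw"),
       positions = positions,
       annotation = data.frame(gene_symbol = genes, probe_set_id = genes,
                               stringsAsFactors = FALSE))
}

#' Write a complete simulated dataset to disk
#'
#' Writes the panel CSV, metadata CSV, one RCC-lite file per lane, raw count
#' and array matrices (TSV), probe-level matrix and positions CSV, the array
#' annotation CSV, and the planted truth as JSON.
#'
#' @param dir output directory (created if needed).
#' @param truth,design,count_sim,array_sim generator outputs.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dir, truth, design, count_sim, array_sim) {
  dir.create(file.path(dir, "rcc"), recursive = TRUE, showWarnings = FALSE)
  write_panel_annotation(truth$panel, file.path(dir, "panel.csv"))
  write_sample_table(design, file.path(dir, "metadata.csv"))
  for (lane in count_sim$lanes) {
    write_rcc_lite(lane, truth$panel,
                   file.path(dir, "rcc", paste0(lane$sample_id, ".csv")))
  }
  write_expression_matrix(count_sim$matrix, file.path(dir, "count_raw.tsv"))
  write_expression_matrix(array_sim$gene, file.path(dir, "array_gene.tsv"))
  write_expression_matrix(array_sim$probes, file.path(dir, "array_probes.tsv"))
  utils::write.csv(array_sim$positions, file.path(dir, "positions.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(array_sim$annotation, file.path(dir, "annotation.csv"),
                   row.names = FALSE, quote = FALSE)
  tr <- truth
  tr$panel <- NULL
  tr$config <- unclass(tr$config)
  jsonlite::write_json(unclass(tr), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
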