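# Cross-platform stage: gene mapping, absolute-level correlation,
# ratio-of-means fold changes, tertile-stratified correlation, the two-fold
# concordance classifier and the regression residual-band classifier, and the
# pooling curve.

#' Map panel genes to array rows
#'
#' Maps every endogenous and housekeeping panel gene to exactly one array
#' matrix row via the array annotation; genes covered by several probe sets
#' are collapsed by `collapse_rule`. Positive and negative controls are
#' excluded from the map. Unmapped genes are reported, not fatal.
#'
#' @param panel `panel_annotation`.
#' @param array_annotation data.frame with columns `gene_symbol`,
#'   `probe_set_id`.
#' @param array_matrix `expr_matrix` whose rows are probe-set ids.
#' @param collapse_rule `"max_mean"` (probe set with highest mean expression
#'   across samples; the default), `"best_single"` (lexicographically first
#'   probe set), or `"mean_of_sets"` (average the probe sets; the resolved
#'   row is virtual and materialized by [apply_gene_map()]).
#' @return list of class `gene_map`: `resolved` (gene -> row id), `sets`
#'   (gene -> all probe sets), `unmapped`, `collapse_rule`.
#' @export
build_gene_map <- function(panel, array_annotation, array_matrix,
                           collapse_rule = c("max_mean", "best_single",
                                             "mean_of_sets")) {
  collapse_rule <- match.arg(collapse_rule)
  stopifnot(inherits(array_matrix, "expr_matrix"))
  genes <- panel$gene_symbol[panel$code_class %in%
                               c("Endogenous", "Housekeeping")]
  rows <- rownames(array_matrix$values)
  sets <- lapply(genes, function(g) {
    ps <- array_annotation$probe_set_id[array_annotation$gene_symbol == g]
    sort(intersect(ps, rows))
  })
  names(sets) <- genes
  mapped <- genes[lengths(sets) > 0]
  unmapped <- genes[lengths(sets) == 0]
  resolved <- vapply(mapped, function(g) {
    ps <- sets[[g]]
    if (length(ps) == 1) return(ps)
    switch(collapse_rule,
           max_mean = ps[which.max(rowMeans(
             array_matrix$values[ps, , drop = FALSE]))],
           best_single = ps[1],
           mean_of_sets = paste0(g, ":mean"))
  }, character(1))
  structure(list(resolved = resolved, sets = sets[mapped],
                 unmapped = unmapped, collapse_rule = collapse_rule),
            class = "gene_map")
}

#' @rdname build_gene_map
#' @param map a `gene_map`.
#' @return `apply_gene_map()`: `expr_matrix` with one row per mapped panel
#'   gene, named by panel gene id.
#' @export
apply_gene_map <- function(map, array_matrix) {
  stopifnot(inherits(map, "gene_map"), inherits(array_matrix, "expr_matrix"))
  genes <- names(map$resolved)
  out <- matrix(0, length(genes), ncol(array_matrix$values),
                dimnames = list(genes, colnames(array_matrix$values)))
  for (g in genes) {
    if (map$collapse_rule == "mean_of_sets" && length(map$sets[[g]]) > 1) {
      out[g, ] <- colMeans(array_matrix$values[map$sets[[g]], , drop = FALSE])
    } else {
      out[g, ] <- array_matrix$values[map$resolved[[g]], ]
    }
  }
  expr_matrix(out, array_matrix$platform, array_matrix$scale)
}

#' Within- and between-platform sample correlation summary
#'
#' Computes the pairwise Pearson correlations within each platform and the
#' per-sample correlation between platforms over the mapped genes, on log2
#' values.
#'
#' @param m_count,m_array log2 `expr_matrix` objects (count rows named by
#'   panel gene ids; array matrix already collapsed via [apply_gene_map()]).
#' @param pairing named vector: count sample id -> array sample id.
#' @return list: `within_count`, `within_array` (min/median/max of
#'   off-diagonal pairwise r), `between` (per-pair r), `between_summary`.
#' @export
cross_platform_sample_r <- function(m_count, m_array, pairing) {
  genes <- intersect(rownames(m_count$values), rownames(m_array$values))
  if (length(genes) < 3) stop("at least 3 shared genes required")
  mc <- subset_expr(m_count, genes = genes)
  ma <- subset_expr(m_array, genes = genes)
  summ <- function(r) {
    off <- r[upper.tri(r)]
    c(min = min(off), median = stats::median(off), max = max(off))
  }
  rc <- pairwise_pearson(mc)
  ra <- pairwise_pearson(ma)
  if (!all(names(pairing) %in% colnames(mc$values)) ||
      !all(pairing %in% colnames(ma$values))) {
    stop("unpaired sample in pairing")
  }
  between <- vapply(names(pairing), function(s) {
    stats::cor(mc$values[, s], ma$values[, pairing[[s]]])
  }, numeric(1))
  list(within_count = summ(rc), within_array = summ(ra),
       between = between, between_summary = summ_between(between))
}

summ_between <- function(x) {
  c(min = min(x), median = stats::median(x), max = max(x))
}

#' Ratio-of-means fold-change table
#'
#' For each mapped gene and each platform, the log2 ratio of the group-A mean
#' to the group-B mean, computed on the linear (normalized) scale with a
#' pseudocount added to both means so zero-mean genes stay finite. Genes are
#' stratified into expression tertiles (low/medium/high) by the
#' cross-platform average log2 mean expression, ties broken by gene order.
#'
#' @param m_count,m_array normalized-scale `expr_matrix` objects sharing the
#'   mapped panel gene ids (array collapsed via [apply_gene_map()]).
#' @param meta `sample_table`.
#' @param group_a,group_b subtype labels forming the ratio numerator and
#'   denominator (default ER+ over TNB).
#' @param samples optional sample subset (applied to both platforms).
#' @param eps pseudocount added to group means (default 0.5).
#' @param ratio_direction `"a_over_b"` or `"b_over_a"`.
#' @return data.frame of class `fold_change_table`.
#' @export
fold_change_table <- function(m_count, m_array, meta,
                              group_a = "ERpos", group_b = "TNB",
                              samples = NULL, eps = 0.5,
                              ratio_direction = c("a_over_b", "b_over_a")) {
  ratio_direction <- match.arg(ratio_direction)
  stopifnot(inherits(m_count, "expr_matrix"), inherits(m_array, "expr_matrix"))
  if (m_count$scale != "normalized" || m_array$scale != "normalized") {
    stop("fold changes are computed on the normalized (linear) scale")
  }
  genes <- intersect(rownames(m_count$values), rownames(m_array$values))
  if (!is.null(samples)) meta <- meta[meta$sample_id %in% samples, ]
  ids_a <- meta$sample_id[meta$subtype == group_a]
  ids_b <- meta$sample_id[meta$subtype == group_b]
  groups <- function(m) {
    list(a = intersect(ids_a, colnames(m$values)),
         b = intersect(ids_b, colnames(m$values)))
  }
  gc <- groups(m_count)
  ga <- groups(m_array)
  if (!length(gc$a) || !length(gc$b) || !length(ga$a) || !length(ga$b)) {
    stop("empty comparison group")
  }
  mean_of <- function(m, ids) rowMeans(m$values[genes, ids, drop = FALSE])
  ma_c <- mean_of(m_count, gc$a); mb_c <- mean_of(m_count, gc$b)
  ma_a <- mean_of(m_array, ga$a); mb_a <- mean_of(m_array, ga$b)
  lfc <- function(num, den) log2((num + eps) / (den + eps))
  fc_count <- lfc(ma_c, mb_c)
  fc_array <- lfc(ma_a, mb_a)
  if (ratio_direction == "b_over_a") {
    fc_count <- -fc_count
    fc_array <- -fc_array
  }
  avg_expr <- (log2(rowMeans(m_count$values[genes, , drop = FALSE]) + eps) +
                 log2(rowMeans(m_array$values[genes, , drop = FALSE]) + eps)) / 2
  n <- length(genes)
  ord <- order(avg_expr, seq_len(n))
  stratum <- character(n)
  bounds <- round(c(n / 3, 2 * n / 3))
  stratum[ord[seq_len(bounds[1])]] <- "low"
  stratum[ord[(bounds[1] + 1):bounds[2]]] <- "medium"
  stratum[ord[(bounds[2] + 1):n]] <- "high"
  out <- data.frame(gene_id = genes,
                    mean_a_count = ma_c, mean_b_count = mb_c,
                    mean_a_array = ma_a, mean_b_array = mb_a,
                    log2fc_count = fc_count, log2fc_array = fc_array,
                    avg_log2_expr = avg_expr,
                    stratum = factor(stratum,
                                     levels = c("low", "medium", "high")),
                    zero_flag = (ma_c + mb_c == 0) | (ma_a + mb_a == 0),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("fold_change_table", "data.frame")
  out
}

#' Fold-change correlation, overall and by expression stratum
#'
#' @param fc a [fold_change_table()].
#' @param min_n minimum genes per stratum for a defined correlation.
#' @return list: `overall`, `by_stratum` (named numeric, NA where undefined).
#' @export
stratified_fc_correlation <- function(fc, min_n = 3) {
  stopifnot(inherits(fc, "fold_change_table"))
  by_str <- vapply(levels(fc$stratum), function(s) {
    sub <- fc[fc$stratum == s, ]
    if (nrow(sub) < min_n) return(NA_real_)
    stats::cor(sub$log2fc_count, sub$log2fc_array)
  }, numeric(1))
  list(overall = stats::cor(fc$log2fc_count, fc$log2fc_array),
       by_stratum = by_str)
}

#' Two-fold concordance classifier
#'
#' Partitions genes into three tiers from their per-platform log2 fold
#' changes: `within2fold` if |log2FC| < threshold on both platforms (or the
#' fold changes disagree in sign but at least one platform is below the
#' threshold), `concordant_change` if both platforms exceed the threshold in
#' magnitude on at least one side with agreeing signs, `discordant` if the
#' signs disagree with magnitude >= threshold on both platforms. Concordant
#' fraction = (within2fold + concordant_change) / total.
#'
#' @param fc a [fold_change_table()].
#' @param threshold_log2 fold-change threshold on the log2 scale (default 1,
#'   i.e. two-fold).
#' @return list: `table` (fc table + `tier_twofold`), `summary` (counts,
#'   percentages, concordant fraction).
#' @export
classify_twofold <- function(fc, threshold_log2 = 1) {
  stopifnot(inherits(fc, "fold_change_table"))
  x <- fc$log2fc_count
  y <- fc$log2fc_array
  opposite <- x * y < 0
  big_both <- abs(x) >= threshold_log2 & abs(y) >= threshold_log2
  small_both <- abs(x) < threshold_log2 & abs(y) < threshold_log2
  tier <- ifelse(opposite & big_both, "discordant",
                 ifelse(!opposite & !small_both, "concordant_change",
                        "within2fold"))
  # opposite-sign pairs with one platform under threshold fall in within2fold
  tier[opposite & !big_both] <- "within2fold"
  fc$tier_twofold <- factor(tier, levels = c("within2fold",
                                             "concordant_change",
                                             "discordant"))
  counts <- table(fc$tier_twofold)
  list(table = fc,
       summary = list(counts = counts,
                      percent = 100 * as.vector(counts) / nrow(fc),
                      concordant_fraction =
                        unname((counts["within2fold"] +
                                  counts["concordant_change"]) / nrow(fc))))
}

#' Regression residual-band concordance classifier
#'
#' Fits ordinary least squares of the count-platform log2 fold change on the
#' array-platform log2 fold change, so systematic slope/offset differences
#' between platforms are absorbed by the line. Genes within
#' `z * residual_sd` of the fitted line are `in_band`; genes outside the band
#' are split by whether the two platforms' fold changes agree in sign
#' (`out_band_same_dir`) or not (`out_band_opposite`). Concordant = in_band +
#' out_band_same_dir.
#'
#' @param fc a [fold_change_table()] with >= 3 genes.
#' @param z band half-width in residual standard deviations (default 1.96).
#' @param response which platform's fold change is the regression response.
#' @return list: `fit` (slope, intercept, residual_sd with n-2 denominator,
#'   band_halfwidth), `table` (fc table + `tier_band` + `residual`),
#'   `summary`.
#' @export
classify_regression_band <- function(fc, z = 1.96,
                                     response = c("count", "array")) {
  stopifnot(inherits(fc, "fold_change_table"))
  response <- match.arg(response)
  if (nrow(fc) < 3) stop("at least 3 genes required")
  y <- if (response == "count") fc$log2fc_count else fc$log2fc_array
  x <- if (response == "count") fc$log2fc_array else fc$log2fc_count
  if (stats::sd(x) == 0) stop("degenerate fit: zero predictor variance")
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  residual_sd <- sqrt(sum(res^2) / (length(res) - 2))
  half <- z * residual_sd
  in_band <- abs(res) <= half
  same_dir <- fc$log2fc_count * fc$log2fc_array >= 0
  tier <- ifelse(in_band, "in_band",
                 ifelse(same_dir, "out_band_same_dir", "out_band_opposite"))
  fc$tier_band <- factor(tier, levels = c("in_band", "out_band_same_dir",
                                          "out_band_opposite"))
  fc$residual <- res
  counts <- table(fc$tier_band)
  list(fit = list(slope = unname(stats::coef(fit)[2]),
                  intercept = unname(stats::coef(fit)[1]),
                  residual_sd = residual_sd, z = z, band_halfwidth = half,
                  response = response),
       table = fc,
       summary = list(counts = counts,
                      percent = 100 * as.vector(counts) / nrow(fc),
                      concordant_fraction =
                        unname((counts["in_band"] +
                                  counts["out_band_same_dir"]) / nrow(fc))))
}

#' Pooling curve: fold-change correlation vs samples per group
#'
#' Recomputes the fold-change table with `n` samples per group for each pool
#' size and reports the overall fold-change correlation. The deterministic
#' point uses the first `n` samples of each group by sorted sample id;
#' optional resampling draws `n_resample` random subsets per pool size.
#'
#' @param m_count,m_array normalized-scale matrices as in
#'   [fold_change_table()].
#' @param meta `sample_table`.
#' @param pool_sizes integer vector of samples per group.
#' @param group_a,group_b subtype labels.
#' @param n_resample resampled subsets per pool size (0 = deterministic
#'   only).
#' @param seed seed for the resampling.
#' @return data.frame: pool_size, r (deterministic), r_median and r_resamples
#'   list-column when resampling.
#' @export
pooling_curve <- function(m_count, m_array, meta, pool_sizes,
                          group_a = "ERpos", group_b = "TNB",
                          n_resample = 0, seed = 1) {
  common <- intersect(colnames(m_count$values), colnames(m_array$values))
  meta <- meta[meta$sample_id %in% common, ]
  ids_a <- sort(meta$sample_id[meta$subtype == group_a])
  ids_b <- sort(meta$sample_id[meta$subtype == group_b])
  if (any(pool_sizes > length(ids_a)) || any(pool_sizes > length(ids_b))) {
    stop("pool size exceeds group size")
  }
  fc_r <- function(sel) {
    fc <- fold_change_table(m_count, m_array, meta, group_a, group_b,
                            samples = sel)
    stats::cor(fc$log2fc_count, fc$log2fc_array)
  }
  out <- data.frame(pool_size = pool_sizes, r = NA_real_,
                    r_median = NA_real_)
  resamples <- vector("list", length(pool_sizes))
  set.seed(seed)
  for (i in seq_along(pool_sizes)) {
    n <- pool_sizes[i]
    out$r[i] <- fc_r(c(ids_a[seq_len(n)], ids_b[seq_len(n)]))
    if (n_resample > 0) {
      rs <- vapply(seq_len(n_resample), function(j) {
        fc_r(c(sample(ids_a, n), sample(ids_b, n)))
      }, numeric(1))
      resamples[[i]] <- rs
      out$r_median[i] <- stats::median(rs)
    }
  }
  attr(out, "resamples") <- resamples
  out
}
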