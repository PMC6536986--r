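# Technical-reproducibility battery: distribution-outlier flagging, pairwise
# Pearson correlation, between-site pooled correlation, intra/inter-assay
# precision (%CV), PCA, hierarchical clustering, and the per-gene two-way
# ANOVA mean-square diagnostic.

#' Flag samples with outlying expression distributions
#'
#' Operationalizes boxplot-based outlier screening: each sample is summarized
#' by its median expression, and samples whose median falls outside
#' `[Q1 - k*IQR, Q3 + k*IQR]` of the per-sample medians are flagged.
#'
#' @param m `expr_matrix` on the log2 scale.
#' @param k fence multiplier (default 3).
#' @return character vector of flagged sample ids (possibly empty).
#' @export
flag_distribution_outliers <- function(m, k = 3) {
  stopifnot(inherits(m, "expr_matrix"))
  if (ncol(m$values) < 4) stop("at least 4 samples required")
  med <- apply(m$values, 2, stats::median)
  q <- stats::quantile(med, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  names(med)[med < q[1] - k * iqr | med > q[2] + k * iqr]
}

#' Pairwise Pearson correlation between samples
#'
#' @param m `expr_matrix` on the log2 scale with >= 3 genes.
#' @param samples optional sample subset.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pairwise_pearson <- function(m, samples = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!is.null(samples)) m <- subset_expr(m, samples = samples)
  if (ncol(m$values) < 2) stop("at least 2 samples required")
  if (nrow(m$values) < 3) stop("at least 3 genes required")
  sds <- apply(m$values, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance sample vector: ",
         paste(colnames(m$values)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(m$values)
  diag(r) <- 1
  r
}

#' Pooled between-group scatter correlation
#'
#' Pools all (gene, sample-pair) value pairs across a set of paired samples
#' (e.g. same case and day prepared in two labs) and returns the single
#' Pearson correlation of the pooled scatter, as in a between-site
#' log2-expression scatter plot.
#'
#' @param m_a,m_b log2 `expr_matrix` objects sharing gene order.
#' @param pairing named character vector: sample id in `m_a` -> paired sample
#'   id in `m_b`.
#' @return Pearson r over all pooled points.
#' @export
between_group_scatter_r <- function(m_a, m_b, pairing) {
  stopifnot(inherits(m_a, "expr_matrix"), inherits(m_b, "expr_matrix"))
  if (!identical(rownames(m_a$values), rownames(m_b$values))) {
    stop("matrices must share gene order")
  }
  if (!all(names(pairing) %in% colnames(m_a$values)) ||
      !all(pairing %in% colnames(m_b$values))) {
    stop("unpaired sample in pairing")
  }
  x <- as.vector(m_a$values[, names(pairing)])
  y <- as.vector(m_b$values[, pairing])
  stats::cor(x, y)
}

#' Intra- and inter-assay precision report
#'
#' Percent coefficients of variation on the normalized (linear) scale:
#' intra-assay %CV per gene within each (case, lab) group across days;
#' inter-assay %CV per gene across all replicates of a case. Median %CVs are
#' compared against the acceptance thresholds (<10% intra, <15% inter), and
#' the minimum pairwise within-case replicate R^2 (on log2 values) is
#' reported.
#'
#' @param m normalized-scale `expr_matrix`.
#' @param meta `sample_table` covering the matrix samples.
#' @param intra_max,inter_max acceptance thresholds in percent.
#' @return list of class `precision_report`: `intra` and `inter` %CV
#'   matrices (genes x groups), `median_intra_cv`, `median_inter_cv`,
#'   `pass_intra`, `pass_inter`, `replicate_r2_min`, `n_undefined`.
#' @export
precision_report <- function(m, meta, intra_max = 10, inter_max = 15) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "normalized") {
    stop("precision is computed on the normalized (linear) scale")
  }
  meta <- meta[meta$sample_id %in% colnames(m$values), ]
  v <- m$values[, meta$sample_id, drop = FALSE]

  cv_by <- function(groups) {
    out <- sapply(unique(groups), function(g) {
      sub <- v[, groups == g, drop = FALSE]
      if (ncol(sub) < 2) stop("fewer than 2 replicates in group ", g)
      mu <- rowMeans(sub)
      s <- apply(sub, 1, stats::sd)
      ifelse(mu == 0, NA_real_, 100 * s / mu)
    })
    colnames(out) <- unique(groups)
    out
  }
  intra <- cv_by(paste(meta$case_id, meta$lab, sep = "_"))
  inter <- cv_by(meta$case_id)

  r2_min <- Inf
  lg <- log2(v + 1)
  for (case in unique(meta$case_id)) {
    ids <- meta$sample_id[meta$case_id == case]
    if (length(ids) < 2) next
    # constant replicate vectors (e.g. exact copies) have undefined r; they
    # carry no disagreement, so they are skipped rather than propagated
    rc <- suppressWarnings(stats::cor(lg[, ids, drop = FALSE]))^2
    vals <- rc[upper.tri(rc)]
    if (any(!is.na(vals))) r2_min <- min(r2_min, vals, na.rm = TRUE)
  }

  structure(list(
    intra = intra, inter = inter,
    median_intra_cv = stats::median(intra, na.rm = TRUE),
    median_inter_cv = stats::median(inter, na.rm = TRUE),
    pass_intra = stats::median(intra, na.rm = TRUE) < intra_max,
    pass_inter = stats::median(inter, na.rm = TRUE) < inter_max,
    replicate_r2_min = r2_min,
    n_undefined = sum(is.na(intra)) + sum(is.na(inter))),
    class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf("precision: median intra CV %.2f%% (%s), median inter CV %.2f%% (%s), min replicate R^2 %.4f\n",
              x$median_intra_cv, if (x$pass_intra) "pass" else "FAIL",
              x$median_inter_cv, if (x$pass_inter) "pass" else "FAIL",
              x$replicate_r2_min))
  invisible(x)
}

#' PCA sample scores
#'
#' Genes are mean-centered (no scaling) and the centered sample x gene
#' matrix is decomposed by SVD. Component signs are fixed so that each
#' component's largest-magnitude gene loading is positive, making scores
#' reproducible across platforms and BLAS builds.
#'
#' @param m log2 `expr_matrix`.
#' @param n_components number of components to return.
#' @return list: `scores` (samples x components), `explained_variance`
#'   (fractions, non-increasing), `loadings` (genes x components).
#' @export
pca_scores <- function(m, n_components = 2) {
  stopifnot(inherits(m, "expr_matrix"))
  x <- t(m$values)
  if (nrow(x) < 2) stop("at least 2 samples required")
  if (n_components > min(dim(x))) stop("n_components exceeds matrix rank bound")
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  flip <- vapply(seq_len(n_components), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(sv$u[, seq_len(n_components), drop = FALSE] %*%
                    diag(sv$d[seq_len(n_components)], n_components),
                  2, flip, `*`)
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(n_components)))
  loadings <- sweep(sv$v[, seq_len(n_components), drop = FALSE], 2, flip, `*`)
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(n_components)))
  ev <- sv$d^2 / sum(sv$d^2)
  list(scores = scores,
       explained_variance = ev[seq_len(n_components)],
       loadings = loadings)
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering with distance `1 - Pearson(sample vectors)` and
#' average linkage. Samples are processed in lexicographic id order so tied
#' merges resolve deterministically.
#'
#' @param m log2 `expr_matrix`.
#' @param k number of clusters to cut.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return list: `labels` (named integer vector), `tree` (hclust object).
#' @export
hierarchical_cluster <- function(m, k, linkage = "average") {
  stopifnot(inherits(m, "expr_matrix"))
  if (ncol(m$values) < k) stop("fewer samples than clusters")
  ord <- order(colnames(m$values))
  r <- pairwise_pearson(subset_expr(m, samples = colnames(m$values)[ord]))
  tree <- stats::hclust(stats::as.dist(1 - r), method = linkage)
  labels <- stats::cutree(tree, k = k)
  list(labels = labels, tree = tree)
}

#' Per-gene balanced two-way ANOVA mean squares
#'
#' For each gene, decomposes the variation across samples into a biological
#' factor (case), a batch factor (lab x day replicate batch), and a residual,
#' using the balanced two-way additive decomposition. The headline diagnostic
#' is the fraction of genes whose case mean square exceeds the residual mean
#' square: well above the null fraction indicates biological variation beyond
#' system noise.
#'
#' @param m log2 `expr_matrix` (typically one subtype's samples).
#' @param meta `sample_table` covering the matrix samples.
#' @return list of class `anova_ms_table`: `table` (per gene: ss/ms for
#'   sample, batch, residual, `f_sample`), `df` (degrees of freedom),
#'   `fraction_above_diagonal`.
#' @export
anova_ms <- function(m, meta) {
  stopifnot(inherits(m, "expr_matrix"))
  meta <- meta[match(colnames(m$values), meta$sample_id), ]
  if (anyNA(meta$sample_id)) stop("sample missing from metadata")
  a <- factor(meta$case_id)
  b <- factor(paste(meta$lab, meta$day, sep = "_"))
  cell <- table(a, b)
  if (any(cell == 0) || length(unique(as.vector(cell))) != 1) {
    miss <- which(cell == 0, arr.ind = TRUE)
    stop("unbalanced design; missing/unequal cells: ",
         paste(rownames(cell)[miss[, 1]], colnames(cell)[miss[, 2]],
               sep = "x", collapse = ", "))
  }
  v <- m$values
  n <- ncol(v)
  na <- nlevels(a)
  nb <- nlevels(b)
  grand <- rowMeans(v)
  mean_by <- function(f) {
    sums <- v %*% stats::model.matrix(~ f - 1)
    sweep(sums, 2, as.vector(table(f)), `/`)
  }
  ma <- mean_by(a)   # genes x case levels
  mb <- mean_by(b)   # genes x batch levels
  ss_a <- (n / na) * rowSums((ma - grand)^2)
  ss_b <- (n / nb) * rowSums((mb - grand)^2)
  fitted <- ma[, as.integer(a), drop = FALSE] +
    mb[, as.integer(b), drop = FALSE] - grand
  ss_res <- rowSums((v - fitted)^2)
  ss_total <- rowSums((v - grand)^2)
  df_a <- na - 1
  df_b <- nb - 1
  df_res <- n - na - nb + 1
  ms_a <- ss_a / df_a
  ms_b <- ss_b / df_b
  ms_res <- ss_res / df_res
  tab <- data.frame(gene_id = rownames(v),
                    ss_sample = ss_a, ss_batch = ss_b, ss_residual = ss_res,
                    ss_total = ss_total,
                    ms_sample = ms_a, ms_batch = ms_b, ms_residual = ms_res,
                    f_sample = ms_a / ms_res,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab,
                 df = c(sample = df_a, batch = df_b, residual = df_res),
                 fraction_above_diagonal = mean(ms_a > ms_res)),
            class = "anova_ms_table")
}

#' @export
print.anova_ms_table <- function(x, ...) {
  cat(sprintf("two-way ANOVA on %d genes (df: sample %d, batch %d, residual %d); fraction MS_sample > MS_residual = %.3f\n",
              nrow(x$table), x$df["sample"], x$df["batch"], x$df["residual"],
              x$fraction_above_diagonal))
  invisible(x)
}
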