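# Lane-level QC and the canonical three-step normalization chain for the
# count platform: positive-control geometric-mean scaling -> negative-control
# background subtraction -> housekeeping geometric-mean scaling.

#' Lane QC thresholds
#'
#' Vendor-convention defaults: imaging FOV ratio >= 0.75, binding density in
#' [0.1, 2.25] spots/um^2, positive-control log-log linearity R^2 >= 0.95,
#' and the designated limit-of-detection positive probe (default 0.5 fM)
#' above mean + 2 sd of the negative controls.
#'
#' @param fov_min minimum counted/requested FOV ratio.
#' @param bd_range allowed binding-density interval.
#' @param pos_r2_min minimum positive-control linearity R^2.
#' @param lod_conc nominal concentration (fM) of the LOD probe.
#' @param lod_sd_mult multiplier of the negative-control sd for the LOD
#'   threshold.
#' @return named list.
#' @export
qc_thresholds <- function(fov_min = 0.75, bd_range = c(0.1, 2.25),
                          pos_r2_min = 0.95, lod_conc = 0.5,
                          lod_sd_mult = 2) {
  list(fov_min = fov_min, bd_range = bd_range, pos_r2_min = pos_r2_min,
       lod_conc = lod_conc, lod_sd_mult = lod_sd_mult)
}

#' Lane-level QC report
#'
#' Computes the four standard lane metrics and flags failures. The
#' positive-control linearity R^2 is the squared Pearson correlation of
#' log2(count) vs log2(nominal concentration) over the positive probes
#' excluding the lowest-concentration one; the LOD check requires the
#' designated low positive probe to exceed mean + `lod_sd_mult` * sd of the
#' negative controls.
#'
#' @param lane a `lane_counts`.
#' @param panel the `panel_annotation`.
#' @param thresholds a [qc_thresholds()] list.
#' @return one-row data.frame: sample_id, fov_ratio, binding_density,
#'   pos_control_r2, lod_pass, flags (comma-joined), pass.
#' @export
qc_lane <- function(lane, panel, thresholds = qc_thresholds()) {
  stopifnot(inherits(lane, "lane_counts"), inherits(panel, "panel_annotation"))
  pos <- panel[panel$code_class == "Positive", ]
  if (nrow(pos) < 3) stop("fewer than 3 positive probes: R^2 undefined")
  neg_ids <- panel$probe_id[panel$code_class == "Negative"]

  fov_ratio <- lane$fov_counted / lane$fov_requested
  keep <- pos$nominal_conc > min(pos$nominal_conc)
  x <- log2(pos$nominal_conc[keep])
  y <- log2(lane$counts[pos$probe_id[keep]] + 0.5)
  r2 <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)^2

  negs <- lane$counts[neg_ids]
  lod_threshold <- mean(negs) + thresholds$lod_sd_mult * stats::sd(negs)
  lod_probe <- pos$probe_id[which.min(abs(pos$nominal_conc -
                                            thresholds$lod_conc))]
  lod_pass <- unname(lane$counts[lod_probe] > lod_threshold)

  flags <- character(0)
  if (fov_ratio < thresholds$fov_min) flags <- c(flags, "fov")
  if (lane$binding_density < thresholds$bd_range[1] ||
      lane$binding_density > thresholds$bd_range[2]) {
    flags <- c(flags, "binding_density")
  }
  if (r2 < thresholds$pos_r2_min) flags <- c(flags, "pos_r2")
  if (!lod_pass) flags <- c(flags, "lod")

  data.frame(sample_id = lane$sample_id, fov_ratio = fov_ratio,
             binding_density = lane$binding_density, pos_control_r2 = r2,
             lod_pass = lod_pass, flags = paste(flags, collapse = ","),
             pass = length(flags) == 0, stringsAsFactors = FALSE)
}

#' @rdname qc_lane
#' @param lanes list of `lane_counts`.
#' @return `qc_lanes`: data.frame with one row per lane.
#' @export
qc_lanes <- function(lanes, panel, thresholds = qc_thresholds()) {
  do.call(rbind, lapply(lanes, qc_lane, panel = panel,
                        thresholds = thresholds))
}

pos_hk_geomeans <- function(m, panel, class) {
  ids <- panel$probe_id[panel$code_class == class]
  v <- m$values[ids, , drop = FALSE]
  if (any(v == 0)) {
    warning(class, " probe count of 0: applying +0.5 offset for geometric mean")
    v <- v + 0.5
  }
  apply(v, 2, geomean)
}

#' Positive-control scaling
#'
#' Per sample, the scaling factor is the across-sample geometric mean of the
#' positive-control geometric means divided by the sample's own, so the
#' factors themselves have geometric mean 1. All probes in a lane are scaled.
#'
#' @param m raw-count `expr_matrix` (count platform).
#' @param panel `panel_annotation`.
#' @return list with `matrix` (scale tag `normalized`) and `factors`
#'   (data.frame sample_id, pos_factor).
#' @export
normalize_positive <- function(m, panel) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "raw") stop("normalize_positive expects a raw-count matrix")
  if (m$platform != "count_platform") stop("count-platform input required")
  g <- pos_hk_geomeans(m, panel, "Positive")
  factors <- geomean(g) / g
  out <- sweep(m$values, 2, factors, `*`)
  list(matrix = expr_matrix(out, m$platform, "normalized"),
       factors = data.frame(sample_id = colnames(m$values),
                            pos_factor = unname(factors),
                            stringsAsFactors = FALSE))
}

#' Background subtraction from negative controls
#'
#' Per sample, a background level is estimated from the 8 negative-control
#' probes (default: mean + 2 sample sd) and subtracted from every endogenous
#' and housekeeping value, flooring at 1 count so subsequent log transforms
#' are defined. Control probes are left untouched.
#'
#' @param m `expr_matrix` on the normalized scale (after positive scaling).
#' @param panel `panel_annotation`.
#' @param method background estimator.
#' @param floor lower bound applied after subtraction.
#' @return list with `matrix` and `background` (per-sample levels).
#' @export
subtract_background <- function(m, panel,
                                method = c("mean_plus_2sd", "mean", "max"),
                                floor = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "normalized") {
    stop("subtract_background expects a normalized-scale matrix")
  }
  method <- match.arg(method)
  neg <- m$values[panel$probe_id[panel$code_class == "Negative"], ,
                  drop = FALSE]
  b <- switch(method,
              mean_plus_2sd = apply(neg, 2, function(x) {
                mean(x) + 2 * stats::sd(x)
              }),
              mean = colMeans(neg),
              max = apply(neg, 2, max))
  ids <- panel$probe_id[panel$code_class %in% c("Endogenous", "Housekeeping")]
  out <- m$values
  out[ids, ] <- pmax(sweep(out[ids, , drop = FALSE], 2, b, `-`), floor)
  list(matrix = expr_matrix(out, m$platform, "normalized"),
       background = data.frame(sample_id = colnames(out),
                               background = unname(b),
                               stringsAsFactors = FALSE))
}

#' Housekeeping normalization
#'
#' Per sample, the factor is the across-sample geometric mean of the
#' housekeeping geometric means divided by the sample's own; endogenous and
#' housekeeping values are scaled. After scaling, housekeeping geometric
#' means are identical across samples (to floating-point tolerance) and the
#' factors have geometric mean 1.
#'
#' @param m `expr_matrix` on the normalized scale (after background
#'   subtraction).
#' @param panel `panel_annotation`.
#' @return list with `matrix` and `factors` (sample_id, hk_factor).
#' @export
normalize_housekeeping <- function(m, panel) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "normalized") {
    stop("normalize_housekeeping expects a normalized-scale matrix")
  }
  h <- pos_hk_geomeans(m, panel, "Housekeeping")
  factors <- geomean(h) / h
  ids <- panel$probe_id[panel$code_class %in% c("Endogenous", "Housekeeping")]
  out <- m$values
  out[ids, ] <- sweep(out[ids, , drop = FALSE], 2, factors, `*`)
  list(matrix = expr_matrix(out, m$platform, "normalized"),
       factors = data.frame(sample_id = colnames(out),
                            hk_factor = unname(factors),
                            stringsAsFactors = FALSE))
}

#' Log2 transform
#'
#' @param m `expr_matrix` on the normalized scale.
#' @param offset pseudocount added before the log (default 1).
#' @return `expr_matrix` with scale `log2`.
#' @export
log2_transform <- function(m, offset = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "normalized") stop("log2_transform expects a normalized matrix")
  if (offset <= 0) stop("offset must be positive")
  if (any(m$values < 0)) stop("negative input value")
  expr_matrix(log2(m$values + offset), m$platform, "log2")
}

#' Full count-platform normalization chain
#'
#' Positive-control scaling, background subtraction, housekeeping
#' normalization, in that order; each step can be switched off. The chain is
#' invariant to a global per-sample rescaling of the raw counts.
#'
#' @param m raw `expr_matrix`.
#' @param panel `panel_annotation`.
#' @param background_method passed to [subtract_background()].
#' @param steps character subset of `c("positive", "background",
#'   "housekeeping")`.
#' @return list with `matrix` (normalized scale) and `factors` (data.frame
#'   sample_id, pos_factor, background, hk_factor).
#' @export
normalize_chain <- function(m, panel,
                            background_method = "mean_plus_2sd",
                            steps = c("positive", "background",
                                      "housekeeping")) {
  samples <- colnames(m$values)
  factors <- data.frame(sample_id = samples, pos_factor = 1, background = 0,
                        hk_factor = 1, stringsAsFactors = FALSE)
  cur <- m
  if ("positive" %in% steps) {
    step <- normalize_positive(cur, panel)
    cur <- step$matrix
    factors$pos_factor <- step$factors$pos_factor
  } else if (cur$scale == "raw") {
    cur <- expr_matrix(cur$values, cur$platform, "normalized")
  }
  if ("background" %in% steps) {
    step <- subtract_background(cur, panel, method = background_method)
    cur <- step$matrix
    factors$background <- step$background$background
  }
  if ("housekeeping" %in% steps) {
    step <- normalize_housekeeping(cur, panel)
    cur <- step$matrix
    factors$hk_factor <- step$factors$hk_factor
  }
  list(matrix = cur, factors = factors)
}
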