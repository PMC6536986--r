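# Simplified hybridization-array QC metrics computed on probe-level data:
# scale factor, 3'/5' intensity ratios for designated control genes, and the
# RNA-degradation slope of the standardized mean-by-position profile.

#' Array scale factor
#'
#' `target / trimmed_mean(sample)`, the classic global-scaling diagnostic:
#' values far from 1 indicate an overall intensity level far from the target.
#'
#' @param probe_level raw probe-level `expr_matrix`.
#' @param target target trimmed-mean intensity (default 500).
#' @param trim fraction trimmed from each tail (default 0.02).
#' @return named numeric vector, one factor per sample.
#' @export
array_scale_factor <- function(probe_level, target = 500, trim = 0.02) {
  stopifnot(inherits(probe_level, "expr_matrix"))
  if (probe_level$scale != "raw") stop("probe-level raw matrix required")
  tm <- apply(probe_level$values, 2, mean, trim = trim)
  if (any(tm == 0)) stop("all-zero sample: scale factor undefined")
  target / tm
}

#' 3'/5' intensity ratio of control genes
#'
#' For each control gene with probes ordered 5' to 3', the ratio of the
#' 3'-most probe intensity to the 5'-most. Elevated ratios indicate RNA
#' degradation (3' bias).
#'
#' @param probe_level raw probe-level `expr_matrix`.
#' @param control_map named list: gene -> character vector of probe ids
#'   ordered 5' to 3' (length >= 2).
#' @return matrix genes x samples of ratios.
#' @export
three_prime_five_prime_ratio <- function(probe_level, control_map) {
  stopifnot(inherits(probe_level, "expr_matrix"), is.list(control_map))
  v <- probe_level$values
  out <- matrix(NA_real_, length(control_map), ncol(v),
                dimnames = list(names(control_map), colnames(v)))
  for (g in names(control_map)) {
    probes <- control_map[[g]]
    if (length(probes) < 2) stop("gene ", g, " has fewer than 2 ordered probes")
    if (!all(probes %in% rownames(v))) stop("unknown probe id for gene ", g)
    five <- v[probes[1], ]
    three <- v[probes[length(probes)], ]
    if (any(five == 0)) stop("5' probe intensity of 0 for gene ", g)
    out[g, ] <- three / five
  }
  out
}

#' RNA degradation slope
#'
#' For each sample, probe intensities are averaged over genes at each ordinal
#' probe position (1 = 5'-most), the positional mean series is standardized
#' (centered and divided by its sd), and the least-squares slope of the
#' standardized series against position is returned. Standardization makes
#' the slope invariant to any global rescaling of a sample.
#'
#' @param probe_level raw probe-level `expr_matrix`.
#' @param positions data.frame with columns `probe_id` and `position`
#'   (ordinal, shared across genes; at least 3 positions).
#' @return named numeric vector of slopes, one per sample.
#' @export
rna_degradation_slope <- function(probe_level, positions) {
  stopifnot(inherits(probe_level, "expr_matrix"))
  if (!all(c("probe_id", "position") %in% names(positions))) {
    stop("positions requires columns probe_id, position")
  }
  pos <- positions$position[match(rownames(probe_level$values),
                                  positions$probe_id)]
  if (anyNA(pos)) stop("probe without a position entry")
  k <- sort(unique(pos))
  if (length(k) < 3) stop("fewer than 3 probe positions")
  v <- probe_level$values
  apply(v, 2, function(x) {
    m <- tapply(x, pos, mean)[as.character(k)]
    s <- stats::sd(m)
    z <- if (s == 0) rep(0, length(m)) else (m - mean(m)) / s
    unname(stats::coef(stats::lm(z ~ k))[2])
  })
}

#' Array QC report
#'
#' Combines the scale factor, control-gene 3'/5' ratios, degradation slope
#' and an informational fraction of probes above the sample background
#' (mean + 2 sd of the lowest decile of intensities). Thresholds are
#' conservative conventions exposed as arguments; every metric is reported
#' regardless of flags.
#'
#' @param probe_level raw probe-level `expr_matrix`.
#' @param positions probe position table (see [rna_degradation_slope()]).
#' @param control_map control-gene probe map (see
#'   [three_prime_five_prime_ratio()]).
#' @param scale_factor_range,ratio_max,slope_max flagging thresholds.
#' @return data.frame, one row per sample, with metrics, `flags`, `pass`.
#' @export
array_qc_report <- function(probe_level, positions, control_map,
                            scale_factor_range = c(0.2, 5),
                            ratio_max = 10, slope_max = 0.6) {
  sf <- array_scale_factor(probe_level)
  ratios <- three_prime_five_prime_ratio(probe_level, control_map)
  slope <- rna_degradation_slope(probe_level, positions)
  frac_above <- apply(probe_level$values, 2, function(x) {
    low <- x[x <= stats::quantile(x, 0.1)]
    mean(x > mean(low) + 2 * stats::sd(low))
  })
  report <- data.frame(sample_id = colnames(probe_level$values),
                       scale_factor = unname(sf),
                       degradation_slope = unname(slope),
                       frac_above_background = unname(frac_above),
                       stringsAsFactors = FALSE)
  for (g in rownames(ratios)) {
    report[[paste0("ratio_", g)]] <- unname(ratios[g, ])
  }
  flags <- vapply(seq_len(nrow(report)), function(i) {
    f <- character(0)
    if (sf[i] < scale_factor_range[1] || sf[i] > scale_factor_range[2]) {
      f <- c(f, "scale_factor")
    }
    if (any(ratios[, i] > ratio_max)) f <- c(f, "three_five_ratio")
    if (slope[i] > slope_max) f <- c(f, "degradation_slope")
    paste(f, collapse = ",")
  }, character(1))
  report$flags <- flags
  report$pass <- flags == ""
  report
}
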