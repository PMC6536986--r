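toy_fc <- function(count, array) {
  n <- length(count)
  fc <- data.frame(gene_id = sprintf("G%02d", seq_len(n)),
                   mean_a_count = 2^count, mean_b_count = 1,
                   mean_a_array = 2^array, mean_b_array = 1,
                   log2fc_count = count, log2fc_array = array,
                   avg_log2_expr = seq_len(n),
                   stratum = factor(rep(c("low", "medium", "high"),
                                        length.out = n),
                                    levels = c("low", "medium", "high")),
                   zero_flag = FALSE, stringsAsFactors = FALSE)
  class(fc) <- c("fold_change_table", "data.frame")
  fc
}

test_that("gene mapping collapses multi-probe-set genes and excludes controls", {
  panel <- toy_panel()
  ann <- data.frame(gene_symbol = c("G01", "G02", "G02", "HKA", "HKB", "P1"),
                    probe_set_id = c("ps1", "ps2a", "ps2b", "psH1", "psH2",
                                     "psP"),
                    stringsAsFactors = FALSE)
  v <- rbind(ps1 = c(5, 5), ps2a = c(120, 120), ps2b = c(80, 80),
             psH1 = c(9, 9), psH2 = c(4, 4), psP = c(2, 2))
  am <- expr_matrix(cbind(S1 = v[, 1], S2 = v[, 2]), "array_platform",
                    "normalized")
  rownames(am$values) <- rownames(v)
  map <- build_gene_map(panel, ann, am)
  expect_equal(unname(map$resolved["G01"]), "ps1")
  expect_equal(unname(map$resolved["G02"]), "ps2a")   # max_mean picks 120
  expect_false(any(c("P1", "N1") %in% names(map$resolved)))
  expect_true("G03" %in% map$unmapped)
  collapsed <- apply_gene_map(map, am)
  expect_equal(unname(collapsed$values["G02", "S1"]), 120)

  map_mean <- build_gene_map(panel, ann, am, collapse_rule = "mean_of_sets")
  expect_equal(unname(apply_gene_map(map_mean, am)$values["G02", "S1"]), 100)
  map_first <- build_gene_map(panel, ann, am, collapse_rule = "best_single")
  expect_equal(unname(map_first$resolved["G02"]), "ps2a")
})

test_that("cross-platform correlation separates within from between", {
  v <- matrix(rnorm(40, 8, 2), 10, 4,
              dimnames = list(paste0("G", 1:10), paste0("S", 1:4)))
  mc <- expr_matrix(v, "count_platform", "log2")
  ma <- expr_matrix(0.5 * v + 1, "array_platform", "log2")
  pairing <- stats::setNames(colnames(v), colnames(v))
  out <- cross_platform_sample_r(mc, ma, pairing)
  expect_equal(unname(out$between), rep(1, 4))  # affine transform
  tiny <- expr_matrix(v[1:2, ], "count_platform", "log2")
  tiny_a <- expr_matrix(0.5 * v[1:2, ], "array_platform", "log2")
  expect_error(cross_platform_sample_r(tiny, tiny_a, pairing), "3 shared")

  fx <- default_fixture()
  out_fx <- cross_platform_sample_r(fx$m_log2, log2_transform(fx$arr_keep),
                                    stats::setNames(fx$keep, fx$keep))
  expect_lt(out_fx$between_summary["median"],
            min(out_fx$within_count["median"],
                out_fx$within_array["median"]))
})

test_that("fold-change table uses pseudocounted ratio of linear means with tertiles", {
  meta <- sample_table(data.frame(
    sample_id = c("E_Lab1_D1", "E_Lab1_D2", "T_Lab1_D1", "T_Lab1_D2"),
    case_id = c("E", "E", "T", "T"),
    subtype = c("ERpos", "ERpos", "TNB", "TNB"),
    lab = "Lab1", day = c(1, 2, 1, 2), operator = "OP",
    rna_mass_ng = 100, qc_pass = TRUE))
  set.seed(5)
  v <- matrix(100, 12, 4, dimnames = list(sprintf("G%02d", 1:12),
                                          meta$sample_id))
  v[1, ] <- c(200, 200, 100, 100)   # means 200 vs 100
  v[2, ] <- 50                      # equal means -> fc 0
  v <- v * rep(2^seq(0, 5.5, by = 0.5), times = 4)  # spread expression
  mc <- expr_matrix(v, "count_platform", "normalized")
  ma <- expr_matrix(v, "array_platform", "normalized")
  fc <- fold_change_table(mc, ma, meta)
  expect_equal(fc$log2fc_count[1], 0.9964067353, tolerance = 1e-9)
  expect_equal(fc$log2fc_count[2], 0)
  expect_equal(as.vector(table(fc$stratum)), c(4, 4, 4))
  expect_error(fold_change_table(mc, ma, meta[meta$subtype == "TNB", ]),
               "empty comparison group")
  expect_error(fold_change_table(log2_transform(mc), ma, meta), "linear")
})

test_that("hand-computed pseudocount fold change is exact", {
  meta <- sample_table(data.frame(
    sample_id = c("E_Lab1_D1", "T_Lab1_D1"), case_id = c("E", "T"),
    subtype = c("ERpos", "TNB"), lab = "Lab1", day = 1, operator = "OP",
    rna_mass_ng = 100, qc_pass = TRUE))
  v <- matrix(c(200, 10, 20, 100, 10, 20), 3, 2,
              dimnames = list(c("G1", "G2", "G3"), meta$sample_id))
  mc <- expr_matrix(v, "count_platform", "normalized")
  fc <- fold_change_table(mc, expr_matrix(v, "array_platform", "normalized"),
                          meta)
  expect_equal(fc$log2fc_count[fc$gene_id == "G1"], 0.9964067353,
               tolerance = 1e-9)
})

test_that("two-fold classifier partitions the paper's example cases", {
  fc <- toy_fc(count = c(0.5, 1.5, 1.5, 0, -0.4, 2.5),
               array = c(0.9, 2.0, -1.2, 0, 1.8, -0.5))
  tier <- classify_twofold(fc)$table$tier_twofold
  expect_equal(as.character(tier),
               c("within2fold",        # (0.5, 0.9): both under 2-fold
                 "concordant_change",  # (1.5, 2.0): big, same direction
                 "discordant",         # (1.5, -1.2): big, opposite
                 "within2fold",        # (0, 0)
                 "within2fold",        # (-0.4, 1.8): opposite, one small
                 "within2fold"))       # (2.5, -0.5): opposite, one small
})

test_that("two-fold classifier is platform-symmetric and direction-symmetric", {
  set.seed(14)
  for (i in 1:25) {
    x <- rnorm(20, 0, 1.5); y <- rnorm(20, 0, 1.5)
    t1 <- classify_twofold(toy_fc(x, y))$table$tier_twofold
    t_swap <- classify_twofold(toy_fc(y, x))$table$tier_twofold
    expect_identical(t1 == "discordant", t_swap == "discordant")
    t_neg <- classify_twofold(toy_fc(-x, -y))$table$tier_twofold
    expect_identical(t1, t_neg)
  }
})

test_that("regression band matches brute-force OLS on a planted-outlier toy set", {
  xs <- c(-2, -1.5, -1, -0.5, 0.5, 1, 1.5, 2, 2.5, 1.8)
  ys <- 1.2 * xs + 0.1
  ys[10] <- -2.5  # opposite-sign outlier, ~2.6 residual sd from the line
  out <- classify_regression_band(toy_fc(count = ys, array = xs))
  expect_equal(out$fit$slope, 0.9119738527, tolerance = 1e-9)
  expect_equal(out$fit$intercept, -0.2521487567, tolerance = 1e-9)
  expect_equal(out$fit$residual_sd, 1.5212480028, tolerance = 1e-9)
  expect_equal(which(out$table$tier_band != "in_band"), 10L)
  expect_equal(as.character(out$table$tier_band[10]), "out_band_opposite")

  # perfect fit: zero residual sd, everything in band
  perfect <- classify_regression_band(toy_fc(count = xs, array = xs))
  expect_equal(perfect$fit$residual_sd, 0)
  expect_true(all(perfect$table$tier_band == "in_band"))
  expect_equal(perfect$summary$concordant_fraction, 1)

  # gene order permutation leaves the classification invariant
  perm <- sample(10)
  out_p <- classify_regression_band(toy_fc(count = ys[perm],
                                           array = xs[perm]))
  expect_identical(as.character(out_p$table$tier_band),
                   as.character(out$table$tier_band)[perm])

  flat <- toy_fc(count = ys, array = rep(1, 10))
  expect_error(classify_regression_band(flat), "degenerate")
})

test_that("stratified correlation reports overall and per-stratum r", {
  fc <- toy_fc(count = c(1, -1, 2, 0.5, 1.5, -2, 0.1, 0.7, -0.9),
               array = c(1, -1, 2, 0.5, 1.5, -2, 0.1, 0.7, -0.9))
  st <- stratified_fc_correlation(fc)
  expect_equal(st$overall, 1)
  expect_equal(unname(st$by_stratum), rep(1, 3))
  small <- toy_fc(count = c(1, 2), array = c(1, 2))
  small$stratum <- factor(c("low", "low"), levels = levels(small$stratum))
  expect_true(is.na(stratified_fc_correlation(small)$by_stratum[["high"]]))
})

test_that("pooling curve is consistent with the full-group fold-change correlation", {
  fx <- default_fixture()
  mcn <- subset_expr(fx$chain$matrix, genes = names(fx$map$resolved),
                     samples = fx$keep)
  full_n <- min(table(fx$meta$subtype))
  pool <- pooling_curve(mcn, fx$arr_keep, fx$meta,
                        pool_sizes = c(1, full_n))
  fc <- fold_change_table(mcn, fx$arr_keep, fx$meta)
  expect_equal(pool$r[2], stratified_fc_correlation(fc)$overall,
               tolerance = 1e-9)
  expect_true(is.finite(pool$r[1]))
  expect_error(pooling_curve(mcn, fx$arr_keep, fx$meta, pool_sizes = 99),
               "exceeds group size")
})
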