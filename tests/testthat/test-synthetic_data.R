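test_that("truth generation is deterministic and honours planted constraints", {
  cfg <- sim_config()
  t1 <- generate_truth(cfg, seed = 1)
  t2 <- generate_truth(cfg, seed = 1)
  expect_identical(t1, t2)

  # discordant genes: endogenous only, opposite signs, magnitude >= minimum,
  # baseline inside the detectable band
  g <- t1$genes
  disc <- g[g$discordant, ]
  expect_true(all(disc$class == "Endogenous"))
  expect_true(all(disc$effect_count * disc$effect_array < 0))
  expect_true(all(abs(disc$effect_count) >= cfg$discordant_min_lfc))
  expect_true(all(abs(disc$effect_array) >= cfg$discordant_min_lfc))
  expect_true(all(disc$baseline >= 500))
  expect_equal(nrow(disc), cfg$n_discordant)

  # housekeeping genes carry no subtype effect
  hk <- g[g$class == "Housekeeping", ]
  expect_true(all(hk$effect_count == 0) && all(hk$effect_array == 0))

  t0 <- generate_truth(sim_config(n_discordant = 0), seed = 1)
  expect_length(t0$discordant_genes, 0)
  expect_error(generate_truth(sim_config(n_discordant = 326), seed = 1),
               "exceeds")
})

test_that("count simulation is deterministic and rejects unknown cases", {
  fx <- default_fixture()
  again <- simulate_count_platform(fx$truth, fx$design)
  expect_identical(again$matrix$values, fx$count$matrix$values)
  bad <- as.data.frame(fx$design)
  bad$case_id[1] <- "TNB99"
  bad$sample_id[1] <- "TNB99_Lab1_D1"
  expect_error(simulate_count_platform(fx$truth, sample_table(bad)),
               "unknown case_id")
})

test_that("count sample means converge to planted means as noise vanishes", {
  # near-zero dispersion, no batch/lane/affinity variation, baseline 1000
  cfg <- sim_config(n_endogenous = 20, n_discordant = 0,
                    baseline_log2_mean = log2(1000), baseline_log2_sd = 0,
                    subtype_effect_sd = 0, subgroup_fraction = 0,
                    nb_dispersion = 1e-8, lane_scale_log2_sd = 0,
                    lab_effect_log2_sd = 0, day_effect_log2_sd = 0,
                    affinity_log2_sd = 0, fc_jitter_log2_sd = 0,
                    outlier_samples = character(0))
  truth <- generate_truth(cfg, seed = 3)
  design <- make_design(cfg)
  # 4 independent simulations x 60 lanes = 240 replicate lanes
  endo <- truth$genes$gene_id[truth$genes$class == "Endogenous"]
  sums <- 0
  for (k in 0:3) {
    tk <- truth
    tk$seed <- truth$seed + 10 * k
    sums <- sums + rowMeans(simulate_count_platform(tk, design)$matrix$values[endo, ])
  }
  grand_mean <- sums / 4
  expect_true(all(abs(grand_mean - 1000) / 1000 < 0.02))
})

test_that("maximal-severity outlier lanes fail lane QC by construction", {
  fx <- default_fixture()
  planted <- fx$truth$outliers$sample_id
  for (s in planted) {
    rep <- qc_lane(fx$count$lanes[[s]], fx$panel)
    expect_false(rep$pass)
    expect_match(rep$flags, "fov")
  }
  clean <- setdiff(fx$design$sample_id, planted)
  expect_true(all(fx$qc$pass[fx$qc$sample_id %in% clean]))
})

test_that("array platform reduces to count-platform means in the degenerate config", {
  cfg <- sim_config(n_endogenous = 15, n_discordant = 0,
                    subgroup_fraction = 0,
                    compression_exponent = 1, affinity_log2_sd = 0,
                    array_noise_log2_sd = 0, array_background = 0,
                    fc_jitter_log2_sd = 0, lane_scale_log2_sd = 0,
                    nb_dispersion = 1e-8, outlier_samples = character(0))
  truth <- generate_truth(cfg, seed = 5)
  design <- make_design(cfg)
  arr <- simulate_array_platform(truth, design)
  cnt <- simulate_count_platform(truth, design)
  expect_equal(arr$gene$values, cnt$mu, tolerance = 1e-12)
  # determinism
  arr2 <- simulate_array_platform(truth, design)
  expect_identical(arr$gene$values, arr2$gene$values)
})

test_that("probe-level decay follows the closed-form 3'/5' ratio", {
  cfg <- sim_config(n_endogenous = 10, n_discordant = 0,
                    probe_noise_log2_sd = 0,
                    probe_decay = 0.1, n_probes_per_gene = 11)
  truth <- generate_truth(cfg, seed = 2)
  arr <- simulate_array_platform(truth, make_design(cfg))
  cm <- list(BMK001 = sprintf("BMK001_p%02d", 1:11))
  ratio <- three_prime_five_prime_ratio(arr$probes, cm)
  expect_equal(unname(ratio[1, ]), rep((1 / 0.9)^10, ncol(ratio)),
               tolerance = 1e-10)
})

test_that("with discordance off and noise low, fold changes agree across platforms", {
  cfg <- sim_config(n_discordant = 0, compression_exponent = 1,
                    fc_jitter_log2_sd = 0, nb_dispersion = 1e-6,
                    array_noise_log2_sd = 0.01, array_background = 0,
                    outlier_samples = character(0))
  truth <- generate_truth(cfg, seed = 4)
  design <- make_design(cfg)
  cnt <- simulate_count_platform(truth, design)
  arr <- simulate_array_platform(truth, design)
  panel <- truth$panel
  chain <- normalize_chain(cnt$matrix, panel)
  map <- build_gene_map(panel, arr$annotation, arr$gene)
  fc <- fold_change_table(
    subset_expr(chain$matrix, genes = names(map$resolved)),
    apply_gene_map(map, arr$gene), design)
  agree <- abs(fc$log2fc_count - fc$log2fc_array) <= 0.1
  expect_gte(mean(agree), 0.95)
})

test_that("write_dataset emits a complete, reloadable directory", {
  cfg <- sim_config(n_endogenous = 8, n_discordant = 2)
  truth <- generate_truth(cfg, seed = 6)
  design <- make_design(cfg)
  cnt <- simulate_count_platform(truth, design)
  arr <- simulate_array_platform(truth, design)
  dir <- withr::local_tempdir()
  write_dataset(dir, truth, design, cnt, arr)
  panel <- suppressMessages(read_panel_annotation(file.path(dir, "panel.csv")))
  expect_equal(nrow(panel), 8 + 7 + 6 + 8)
  lane <- read_rcc_lite(file.path(dir, "rcc", "TNB1_Lab1_D1.csv"), panel)
  expect_identical(lane$counts,
                   cnt$lanes[["TNB1_Lab1_D1"]]$counts)
  m <- read_expression_matrix(file.path(dir, "count_raw.tsv"))
  expect_identical(m$values, cnt$matrix$values)
  expect_true(file.exists(file.path(dir, "truth.json")))
})
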