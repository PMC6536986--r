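test_that("panel annotation validates the default codebook and degenerate inputs", {
  panel <- make_panel(sim_config())
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel_annotation(panel, path)
  reread <- suppressMessages(read_panel_annotation(path))
  expect_equal(unname(panel_class_counts(reread)), c(325, 7, 6, 8))
  expect_equal(nrow(reread), 346)
  expect_identical(as.data.frame(reread), as.data.frame(panel))

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("probe_id,gene_symbol,code_class,nominal_conc", empty)
  expect_error(read_panel_annotation(empty), "no probes")

  one <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("probe_id,gene_symbol,code_class,nominal_conc",
               "G1,G1,Endogenous,0"), one)
  p1 <- suppressMessages(read_panel_annotation(one))
  expect_equal(unname(panel_class_counts(p1)), c(1, 0, 0, 0))
})

test_that("panel annotation rejects structural violations", {
  df <- data.frame(probe_id = c("A", "A"), gene_symbol = c("A", "A"),
                   code_class = "Endogenous", nominal_conc = 0)
  expect_error(panel_annotation(df), "duplicate probe_id")
  df2 <- data.frame(probe_id = "A", gene_symbol = "A",
                    code_class = "Mystery", nominal_conc = 0)
  expect_error(panel_annotation(df2), "unknown code_class")
  df3 <- data.frame(probe_id = c("P1", "P2"), gene_symbol = c("P1", "P2"),
                    code_class = "Positive", nominal_conc = c(8, 32))
  expect_error(panel_annotation(df3), "strictly decreasing")
  df4 <- data.frame(probe_id = "P1", gene_symbol = "P1",
                    code_class = "Positive", nominal_conc = 0)
  expect_error(panel_annotation(df4), "nominal_conc")
})

test_that("RCC-lite lane files round-trip and parse order-insensitively", {
  panel <- toy_panel()
  counts <- stats::setNames(c(10, 20, 30, 100, 200, 900, 250, 70, 12,
                              3, 2, 1, 4, 2, 0, 3, 1), panel$probe_id)
  lane <- lane_counts("S1", counts, 280, 210, 0.55)
  path <- withr::local_tempfile(fileext = ".csv")
  write_rcc_lite(lane, panel, path)
  back <- read_rcc_lite(path, panel)
  expect_identical(back$counts, lane$counts)
  expect_equal(back$fov_counted / back$fov_requested, 0.75)
  expect_equal(back$binding_density, 0.55)

  # permute Code_Summary rows: identical LaneCounts
  lines <- readLines(path)
  body <- grep("^(Endogenous|Housekeeping|Positive|Negative),", lines)
  set.seed(42)
  lines[body] <- lines[sample(body)]
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, path2)
  expect_identical(read_rcc_lite(path2, panel)$counts, lane$counts)

  # missing section
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines[!grepl("Code_Summary", lines)][1:6], path3)
  expect_error(read_rcc_lite(path3, panel), "missing section <Code_Summary>")

  # extra probe in file: warn and drop; missing panel probe: error
  lines4 <- append(readLines(path), "Endogenous,NOT_IN_PANEL,NM_X,5",
                   after = body[1])
  path4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines4, path4)
  expect_warning(l4 <- read_rcc_lite(path4, panel), "absent from panel")
  expect_identical(l4$counts, lane$counts)
  lines5 <- readLines(path)
  path5 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines5[!grepl("^Endogenous,G01,", lines5)], path5)
  expect_error(read_rcc_lite(path5, panel), "absent from lane file")
})

test_that("expression matrix TSV round-trips exactly with metadata tags", {
  m <- toy_matrix(matrix(c(1.5, 2.25, 1 / 3, 1e6 + 0.1), 2, 2),
                  platform = "array_platform", scale = "normalized")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, path)
  back <- read_expression_matrix(path)
  expect_identical(back$values, m$values)
  expect_identical(back$platform, "array_platform")
  expect_identical(back$scale, "normalized")
  # write(read(x)) is byte-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("expression matrix reader rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# platform=count_platform", "# scale=raw",
               "gene_id\tS1\tS1", "G1\t1\t2", "G2\t3\t4"), path)
  expect_error(read_expression_matrix(path), "duplicate sample_id")
  writeLines(c("# platform=count_platform", "# scale=raw",
               "gene_id\tS1\tS2", "G1\t1\t2", "G2\t3"), path)
  expect_error(read_expression_matrix(path), "ragged")
  writeLines(c("gene_id\tS1", "G1\t1"), path)
  expect_error(read_expression_matrix(path), "sidecar")
  writeLines(c("# platform=count_platform", "# scale=raw",
               "gene_id\tS1\tS2", "G1\t1\tx", "G2\t3\t4"), path)
  expect_error(read_expression_matrix(path), "non-numeric")
})

test_that("sample table enforces the replicate-design key", {
  design <- make_design(sim_config())
  expect_equal(nrow(design), 60)
  expect_equal(length(unique(design$case_id)), 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sample_table(design, path)
  expect_equal(as.data.frame(read_sample_table(path)),
               as.data.frame(design))
  dup <- as.data.frame(design)
  dup$sample_id[2] <- paste0(dup$sample_id[2], "b")
  dup$case_id[2] <- dup$case_id[1]
  dup$lab[2] <- dup$lab[1]
  dup$day[2] <- dup$day[1]
  expect_error(sample_table(dup), "unique")
})
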