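make_lane <- function(panel, counts, fov_req = 280, fov_cnt = 275, bd = 0.6) {
  lane_counts("L1", stats::setNames(counts, panel$probe_id), fov_req,
              fov_cnt, bd)
}

test_that("lane QC computes the four standard metrics", {
  panel <- toy_panel()
  # positives exactly proportional to nominal concentration -> R^2 = 1
  base <- c(10, 20, 30, 100, 200)
  pos <- round(panel$nominal_conc[panel$code_class == "Positive"] * 50)
  lane <- make_lane(panel, c(base, pos, rep(2, 8)))
  rep <- qc_lane(lane, panel)
  expect_equal(rep$pos_control_r2, 1, tolerance = 1e-4)
  expect_true(rep$lod_pass)
  expect_true(rep$pass)

  # fov 210/280 = 0.75 passes at the >= 0.75 threshold
  lane2 <- make_lane(panel, c(base, pos, rep(2, 8)), fov_cnt = 210)
  rep2 <- qc_lane(lane2, panel)
  expect_equal(rep2$fov_ratio, 0.75)
  expect_true(rep2$pass)
  rep2b <- qc_lane(make_lane(panel, c(base, pos, rep(2, 8)), fov_cnt = 209),
                   panel)
  expect_match(rep2b$flags, "fov")

  # zero-variance negatives at 10, designated low positive at 9 -> lod fails
  pos3 <- c(6400, 1600, 400, 9)
  lane3 <- make_lane(panel, c(base, pos3, rep(10, 8)))
  rep3 <- qc_lane(lane3, panel)
  expect_false(rep3$lod_pass)
  expect_match(rep3$flags, "lod")

  # binding density outside [0.1, 2.25]
  rep4 <- qc_lane(make_lane(panel, c(base, pos, rep(2, 8)), bd = 0.05), panel)
  expect_match(rep4$flags, "binding_density")

  two_pos <- panel_annotation(data.frame(
    probe_id = c("G1", "P1", "P2", "N1"), gene_symbol = c("G1", "P1", "P2", "N1"),
    code_class = c("Endogenous", "Positive", "Positive", "Negative"),
    nominal_conc = c(0, 32, 8, 0)))
  lane5 <- lane_counts("L", stats::setNames(c(5, 100, 25, 2),
                                            two_pos$probe_id), 280, 275, 0.5)
  expect_error(qc_lane(lane5, two_pos), "fewer than 3 positive")
})

test_that("positive-control scaling uses geometric means with unit-geomean factors", {
  panel <- toy_panel()
  # two samples whose positive geomeans are 100 and 400 -> factors 2 and 0.5
  v <- matrix(1, nrow(panel), 2, dimnames = list(panel$probe_id, c("S1", "S2")))
  v[panel$code_class == "Positive", 1] <- c(200, 100, 50, 100)   # geomean 100
  v[panel$code_class == "Positive", 2] <- c(800, 400, 200, 400)  # geomean 400
  v["G01", ] <- c(30, 40)
  m <- expr_matrix(v, "count_platform", "raw")
  out <- normalize_positive(m, panel)
  expect_equal(out$factors$pos_factor, c(2, 0.5))
  expect_equal(unname(out$matrix$values["G01", ]), c(60, 20))

  # identical samples -> all factors 1, matrix unchanged
  v2 <- v; v2[, 2] <- v2[, 1]
  out2 <- normalize_positive(expr_matrix(v2, "count_platform", "raw"), panel)
  expect_equal(out2$factors$pos_factor, c(1, 1))
  expect_equal(out2$matrix$values, v2)

  # idempotence: renormalizing the output gives factors of 1
  renorm <- expr_matrix(out$matrix$values, "count_platform", "raw")
  out3 <- normalize_positive(renorm, panel)
  expect_equal(out3$factors$pos_factor, c(1, 1), tolerance = 1e-12)

  # zero positive count -> +0.5 offset with a warning
  v4 <- v; v4[panel$probe_id == "P4", 1] <- 0
  expect_warning(normalize_positive(expr_matrix(v4, "count_platform", "raw"),
                                    panel), "offset")
})

test_that("background subtraction matches hand-computed thresholds and floors", {
  panel <- toy_panel()
  v <- matrix(1, nrow(panel), 1, dimnames = list(panel$probe_id, "S1"))
  v[panel$code_class == "Negative", 1] <- 10
  v["G01", 1] <- 15
  v["G02", 1] <- 3
  m <- expr_matrix(v, "count_platform", "normalized")
  out <- subtract_background(m, panel)
  expect_equal(unname(out$matrix$values["G01", 1]), 5)   # 15 - 10, sd 0
  expect_equal(unname(out$matrix$values["G02", 1]), 1)   # floored
  # negatives {8,12,8,12,...}: mean 10, sample sd 2.1380899, threshold
  # 14.2761799; 20 - threshold = 5.7238201
  v2 <- v
  v2[panel$code_class == "Negative", 1] <- rep(c(8, 12), 4)
  v2["G01", 1] <- 20
  out2 <- subtract_background(expr_matrix(v2, "count_platform", "normalized"),
                              panel)
  expect_equal(unname(out2$background$background), 14.2761798706,
               tolerance = 1e-9)
  expect_equal(unname(out2$matrix$values["G01", 1]), 5.7238201294,
               tolerance = 1e-9)
  # controls untouched
  expect_equal(unname(out2$matrix$values["P1", 1]), 1)
})

test_that("housekeeping normalization equalizes housekeeping geometric means", {
  panel <- toy_panel()
  v <- matrix(5, nrow(panel), 2, dimnames = list(panel$probe_id, c("S1", "S2")))
  v["HKA", ] <- c(50, 200)
  v["HKB", ] <- c(200, 800)   # geomeans 100 and 400
  m <- expr_matrix(v, "count_platform", "normalized")
  out <- normalize_housekeeping(m, panel)
  expect_equal(out$factors$hk_factor, c(2, 0.5))
  hk_geo <- apply(out$matrix$values[c("HKA", "HKB"), ], 2,
                  function(x) exp(mean(log(x))))
  expect_lt(diff(range(hk_geo)) / mean(hk_geo), 1e-9)

  single <- expr_matrix(v[, 1, drop = FALSE], "count_platform", "normalized")
  expect_equal(normalize_housekeeping(single, panel)$factors$hk_factor, 1)

  v3 <- v; v3["HKA", ] <- 100; v3["HKB", ] <- 100
  out3 <- normalize_housekeeping(expr_matrix(v3, "count_platform",
                                             "normalized"), panel)
  expect_equal(out3$factors$hk_factor, c(1, 1))
})

test_that("log2 transform applies the offset and guards its domain", {
  m <- toy_matrix(matrix(c(0, 1023, 5.724, 7), 2, 2), scale = "normalized")
  out <- log2_transform(m)
  expect_equal(out$values[1, 1], 0)
  expect_equal(out$values[2, 1], 10)
  expect_equal(out$values[1, 2], log2(6.724), tolerance = 1e-9)
  expect_equal(out$scale, "log2")
  expect_error(log2_transform(out), "normalized")
  expect_error(log2_transform(m, offset = 0), "positive")
})

test_that("the full chain is scale-equivariant and tightens technical replicates", {
  fx <- default_fixture()
  raw <- fx$count$matrix
  n <- ncol(raw$values)
  scaled <- raw$values
  scaled[, 3] <- scaled[, 3] * 5
  out_scaled <- suppressWarnings(
    normalize_chain(expr_matrix(scaled, "count_platform", "raw"), fx$panel))
  a <- fx$chain$matrix$values[fx$endo_hk, ]
  b <- out_scaled$matrix$values[fx$endo_hk, ]
  # scaling one lane rescales every normalized value by the single constant
  # c^(1/n); dividing it out recovers the original matrix exactly on every
  # cell not clamped at the background floor before housekeeping scaling
  unfloored <- chain_floor_mask(raw, fx$panel, fx$endo_hk) &
    chain_floor_mask(expr_matrix(scaled, "count_platform", "raw"), fx$panel,
                     fx$endo_hk)
  expect_gt(mean(unfloored), 0.8)
  expect_equal(unname(stats::median((b / a)[unfloored])), 5^(1 / n),
               tolerance = 1e-9)
  expect_equal(b[unfloored] / 5^(1 / n), a[unfloored], tolerance = 1e-9)

  # median within-case replicate distance shrinks versus raw data
  rep_dist <- function(vals) {
    lg <- log2(vals + 1)
    d <- c()
    for (case in unique(fx$meta$case_id)) {
      ids <- fx$meta$sample_id[fx$meta$case_id == case]
      pairs <- utils::combn(ids, 2)
      d <- c(d, apply(pairs, 2, function(p) {
        mean(abs(lg[, p[1]] - lg[, p[2]]))
      }))
    }
    stats::median(d)
  }
  expect_lt(rep_dist(fx$chain$matrix$values[fx$endo_hk, fx$keep]),
            rep_dist(raw$values[fx$endo_hk, fx$keep]))
})

test_that("chain steps refuse wrong-scale input", {
  fx <- default_fixture()
  norm <- fx$chain$matrix
  expect_error(normalize_positive(norm, fx$panel), "raw")
  expect_error(subtract_background(fx$count$matrix, fx$panel), "normalized")
})
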