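# Shared fixtures. The default study fixture (60 samples, 346 probes,
# 2 planted outlier lanes, 16 planted discordant genes) is simulated once per
# test run and cached; individual tests use small hand-built objects where a
# full dataset is unnecessary.

.fixture_cache <- new.env(parent = emptyenv())

default_fixture <- function(seed = 1) {
  key <- paste0("fx", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cfg <- sim_config()
  truth <- generate_truth(cfg, seed = seed)
  design <- make_design(cfg)
  count <- simulate_count_platform(truth, design)
  array <- simulate_array_platform(truth, design)
  qc <- qc_lanes(count$lanes, truth$panel)
  chain <- suppressWarnings(normalize_chain(count$matrix, truth$panel))
  panel <- truth$panel
  endo_hk <- panel$probe_id[panel$code_class %in%
                              c("Endogenous", "Housekeeping")]
  keep <- qc$sample_id[qc$pass]
  m_norm <- subset_expr(chain$matrix, genes = endo_hk, samples = keep)
  map <- build_gene_map(panel, array$annotation, array$gene)
  arr <- apply_gene_map(map, array$gene)
  fx <- list(cfg = cfg, truth = truth, design = design, count = count,
             array = array, qc = qc, chain = chain, panel = panel,
             endo_hk = endo_hk, keep = keep,
             meta = design[design$sample_id %in% keep, ],
             m_norm = m_norm, m_log2 = log2_transform(m_norm),
             map = map, arr = arr,
             arr_keep = subset_expr(arr, samples = keep),
             raw_log2 = expr_matrix(
               log2(count$matrix$values[endo_hk, , drop = FALSE] + 1),
               "count_platform", "log2"))
  .fixture_cache[[key]] <- fx
  fx
}

# minimal hand-built panel: n endogenous + 2 housekeeping + 4 positive +
# 8 negative probes (the full-size panel's negative-control count)
toy_panel <- function(n_endo = 3) {
  panel_annotation(data.frame(
    probe_id = c(sprintf("G%02d", seq_len(n_endo)), "HKA", "HKB",
                 paste0("P", 1:4), paste0("N", 1:8)),
    gene_symbol = c(sprintf("G%02d", seq_len(n_endo)), "HKA", "HKB",
                    paste0("P", 1:4), paste0("N", 1:8)),
    code_class = rep(c("Endogenous", "Housekeeping", "Positive", "Negative"),
                     times = c(n_endo, 2, 4, 8)),
    nominal_conc = c(rep(0, n_endo + 2), c(128, 32, 8, 0.5), rep(0, 8)),
    stringsAsFactors = FALSE))
}

# cells strictly above the background-subtraction floor of 1, evaluated at
# the stage where the floor is applied (before housekeeping scaling)
chain_floor_mask <- function(raw, panel, genes) {
  pos <- suppressWarnings(normalize_positive(raw, panel))
  bg <- subtract_background(pos$matrix, panel)
  bg$matrix$values[genes, , drop = FALSE] > 1
}

toy_matrix <- function(values, platform = "count_platform", scale = "raw",
                       genes = NULL, samples = NULL) {
  v <- as.matrix(values)
  rownames(v) <- genes %||% sprintf("G%02d", seq_len(nrow(v)))
  colnames(v) <- samples %||% sprintf("S%d", seq_len(ncol(v)))
  expr_matrix(v, platform, scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
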