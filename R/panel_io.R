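# Data model and plain-text readers/writers. Every downstream stage consumes
# only these types: panel annotation, per-lane raw counts (RCC-lite sectioned
# CSV), gene x sample expression matrices (TSV with sidecar metadata lines),
# and the sample/design table.

PANEL_CLASSES <- c("Endogenous", "Housekeeping", "Positive", "Negative")

#' Construct and validate a panel annotation
#'
#' The codebook of the targeted panel: one row per probe with its class
#' (Endogenous, Housekeeping, Positive, Negative) and, for positive controls,
#' the nominal spike-in concentration in fM. Positive controls must form a
#' strictly decreasing concentration ladder; all other probes carry 0.
#'
#' @param df data.frame with columns `probe_id`, `gene_symbol`, `code_class`,
#'   `nominal_conc`.
#' @return data.frame of class `panel_annotation`.
#' @export
panel_annotation <- function(df) {
  need <- c("probe_id", "gene_symbol", "code_class", "nominal_conc")
  if (!all(need %in% names(df))) {
    stop("panel annotation requires columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0) stop("no probes")
  df <- df[, need]
  df$probe_id <- as.character(df$probe_id)
  df$gene_symbol <- as.character(df$gene_symbol)
  df$code_class <- as.character(df$code_class)
  df$nominal_conc <- as.numeric(df$nominal_conc)
  if (anyDuplicated(df$probe_id)) {
    stop("duplicate probe_id: ",
         paste(unique(df$probe_id[duplicated(df$probe_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(df$code_class), PANEL_CLASSES)
  if (length(bad)) stop("unknown code_class: ", paste(bad, collapse = ", "))
  pos <- df$code_class == "Positive"
  if (any(df$nominal_conc[pos] <= 0)) {
    stop("Positive probe with nominal_conc <= 0")
  }
  if (any(df$nominal_conc[!pos] != 0)) {
    stop("non-Positive probes must have nominal_conc = 0")
  }
  conc <- df$nominal_conc[pos]
  if (length(conc) > 1 && any(diff(conc) >= 0)) {
    stop("Positive probes must have strictly decreasing nominal_conc")
  }
  rownames(df) <- NULL
  class(df) <- c("panel_annotation", "data.frame")
  df
}

#' @rdname panel_annotation
#' @param panel a `panel_annotation`.
#' @return named integer vector of probe counts per class.
#' @export
panel_class_counts <- function(panel) {
  vapply(PANEL_CLASSES, function(cl) sum(panel$code_class == cl), integer(1))
}

#' Read a panel annotation CSV
#'
#' @param path CSV with header `probe_id,gene_symbol,code_class,nominal_conc`.
#' @return validated `panel_annotation`; class counts are reported via
#'   [message()].
#' @export
read_panel_annotation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("no probes")
  panel <- panel_annotation(df)
  cc <- panel_class_counts(panel)
  message(sprintf("panel: %d probes (%s)", nrow(panel),
                  paste(names(cc), cc, sep = "=", collapse = ", ")))
  panel
}

#' @rdname read_panel_annotation
#' @param panel a `panel_annotation` to write.
#' @export
write_panel_annotation <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-lane raw counts with lane QC attributes
#'
#' @param sample_id lane/sample identifier.
#' @param counts named non-negative integer vector keyed exactly by the
#'   panel's probe ids.
#' @param fov_requested,fov_counted imaging fields of view requested/counted.
#' @param binding_density reporter spot density (spots/um^2).
#' @return object of class `lane_counts`.
#' @export
lane_counts <- function(sample_id, counts, fov_requested, fov_counted,
                        binding_density) {
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  if (any(counts < 0) || any(counts != trunc(counts))) {
    stop("counts must be non-negative integers")
  }
  if (fov_requested <= 0) stop("fov_requested must be positive")
  if (fov_counted < 0 || fov_counted > fov_requested) {
    stop("fov_counted must lie in [0, fov_requested]")
  }
  if (binding_density < 0) stop("binding_density must be non-negative")
  structure(list(sample_id = as.character(sample_id), counts = counts,
                 fov_requested = as.integer(fov_requested),
                 fov_counted = as.integer(fov_counted),
                 binding_density = as.numeric(binding_density)),
            class = "lane_counts")
}

#' Read an RCC-lite lane file
#'
#' RCC-lite is a simplified sectioned-CSV dialect of the nCounter lane output:
#' a `<Lane_Attributes>` block (`ID`, `FovCount`, `FovCounted`,
#' `BindingDensity`) followed by a `<Code_Summary>` block with header
#' `CodeClass,Name,Accession,Count`. Probe matching is by `Name`, exact and
#' case-sensitive.
#'
#' @param path lane file path.
#' @param panel `panel_annotation`; every panel probe must be present in the
#'   file. Probes in the file absent from the panel are dropped with a
#'   warning.
#' @return `lane_counts` with counts ordered as the panel.
#' @export
read_rcc_lite <- function(path, panel) {
  lines <- readLines(path, warn = FALSE)
  section <- function(name) {
    open <- match(sprintf("<%s>", name), lines)
    close <- match(sprintf("</%s>", name), lines)
    if (is.na(open) || is.na(close) || close <= open) {
      stop("missing section <", name, "> in ", path)
    }
    lines[(open + 1):(close - 1)]
  }
  attrs_raw <- section("Lane_Attributes")
  kv <- strsplit(attrs_raw, ",", fixed = TRUE)
  attrs <- stats::setNames(vapply(kv, `[`, character(1), 2),
                           vapply(kv, `[`, character(1), 1))
  for (k in c("ID", "FovCount", "FovCounted", "BindingDensity")) {
    if (!k %in% names(attrs)) stop("lane attribute missing: ", k)
  }
  body <- section("Code_Summary")
  tab <- utils::read.csv(text = paste(body, collapse = "\n"),
                         stringsAsFactors = FALSE)
  if (!all(c("CodeClass", "Name", "Accession", "Count") %in% names(tab))) {
    stop("Code_Summary header must be CodeClass,Name,Accession,Count")
  }
  extra <- setdiff(tab$Name, panel$probe_id)
  if (length(extra)) {
    warning("dropping ", length(extra), " probe(s) absent from panel: ",
            paste(utils::head(extra, 5), collapse = ", "))
    tab <- tab[!tab$Name %in% extra, ]
  }
  missing <- setdiff(panel$probe_id, tab$Name)
  if (length(missing)) {
    stop("panel probe(s) absent from lane file: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  counts <- stats::setNames(as.numeric(tab$Count), tab$Name)[panel$probe_id]
  lane_counts(attrs[["ID"]], counts,
              fov_requested = as.numeric(attrs[["FovCount"]]),
              fov_counted = as.numeric(attrs[["FovCounted"]]),
              binding_density = as.numeric(attrs[["BindingDensity"]]))
}

#' @rdname read_rcc_lite
#' @param lane a `lane_counts` to write.
#' @export
write_rcc_lite <- function(lane, panel, path) {
  stopifnot(inherits(lane, "lane_counts"), inherits(panel, "panel_annotation"))
  counts <- lane$counts[panel$probe_id]
  lines <- c(
    "<Lane_Attributes>",
    paste0("ID,", lane$sample_id),
    paste0("FovCount,", lane$fov_requested),
    paste0("FovCounted,", lane$fov_counted),
    paste0("BindingDensity,", fmt_num(lane$binding_density)),
    "</Lane_Attributes>",
    "<Code_Summary>",
    "CodeClass,Name,Accession,Count",
    sprintf("%s,%s,%s,%s", panel$code_class, panel$probe_id,
            panel$gene_symbol, fmt_num(counts)),
    "</Code_Summary>")
  writeLines(lines, path)
  invisible(path)
}

#' Genes x samples expression matrix with platform and scale tags
#'
#' Every matrix in the pipeline declares which platform produced it and what
#' scale its values are on (`raw` -> `normalized` -> `log2`); operations
#' refuse input on the wrong scale, which prevents silent double-log and
#' double-normalization bugs.
#'
#' @param values numeric genes x samples matrix with unique dimnames, no
#'   missing cells; non-negative unless `scale = "log2"`.
#' @param platform `"count_platform"` or `"array_platform"`.
#' @param scale `"raw"`, `"normalized"` or `"log2"`.
#' @return object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, platform = c("count_platform", "array_platform"),
                        scale = c("raw", "normalized", "log2")) {
  platform <- match.arg(platform)
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix requires gene and sample dimnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene_id")
  if (anyDuplicated(colnames(values))) stop("duplicate sample_id")
  if (anyNA(values)) stop("missing cells are not allowed")
  if (scale != "log2" && any(values < 0)) {
    stop("negative values on a ", scale, " scale matrix")
  }
  storage.mode(values) <- "double"
  structure(list(values = values, platform = platform, scale = scale),
            class = "expr_matrix")
}

#' @rdname expr_matrix
#' @param m an `expr_matrix`.
#' @export
gene_ids <- function(m) rownames(m$values)

#' @rdname expr_matrix
#' @export
sample_ids <- function(m) colnames(m$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s, %s]\n",
              nrow(x$values), ncol(x$values), x$platform, x$scale))
  invisible(x)
}

#' Subset an expression matrix
#'
#' @param m an `expr_matrix`.
#' @param genes,samples character vectors of ids to keep (NULL = all).
#' @return `expr_matrix` with the same platform/scale tags.
#' @export
subset_expr <- function(m, genes = NULL, samples = NULL) {
  v <- m$values
  if (!is.null(genes)) {
    if (!all(genes %in% rownames(v))) stop("unknown gene id in subset")
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    if (!all(samples %in% colnames(v))) stop("unknown sample id in subset")
    v <- v[, samples, drop = FALSE]
  }
  expr_matrix(v, m$platform, m$scale)
}

#' Read/write an expression matrix TSV
#'
#' The on-disk format is a TSV whose first column is `gene_id`, preceded by
#' two sidecar metadata lines `# platform=...` and `# scale=...`. Writing then
#' reading preserves values exactly.
#'
#' @param path TSV file path.
#' @return an `expr_matrix`.
#' @export
read_expression_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^# ", "", ln), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  if (is.null(meta$platform) || is.null(meta$scale)) {
    stop("missing '# platform=' / '# scale=' sidecar header")
  }
  body <- lines[!grepl("^# ", lines)]
  nfield <- lengths(strsplit(body, "\t", fixed = TRUE))
  if (length(unique(nfield)) != 1) stop("ragged rows in ", path)
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene_id") stop("first column must be gene_id")
  sample_names <- names(tab)[-1]
  if (anyDuplicated(sample_names)) stop("duplicate sample_id column")
  if (anyDuplicated(tab$gene_id)) stop("duplicate gene_id row")
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric cell in ", path)
  rownames(vals) <- tab$gene_id
  expr_matrix(vals, platform = meta$platform, scale = meta$scale)
}

#' @rdname read_expression_matrix
#' @param m the `expr_matrix` to write.
#' @export
write_expression_matrix <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- m$values
  rows <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], fmt_num(v[i, ])), collapse = "\t")
  }, character(1))
  lines <- c(paste0("# platform=", m$platform),
             paste0("# scale=", m$scale),
             paste(c("gene_id", colnames(v)), collapse = "\t"),
             rows)
  writeLines(lines, path)
  invisible(path)
}

#' Construct and validate the sample/design table
#'
#' One row per assayed specimen: biological case, subtype, extraction lab,
#' day, operator and RNA input mass. The full study design is 10 cases
#' (5 TNB + 5 ER+) x 2 labs x 3 days = 60 technical-replicate samples.
#'
#' @param df data.frame with columns `sample_id`, `case_id`, `subtype`
#'   (`TNB`/`ERpos`), `lab` (`Lab1`/`Lab2`), `day` (1-3), `operator`,
#'   `rna_mass_ng`, `qc_pass`.
#' @return data.frame of class `sample_table`.
#' @export
sample_table <- function(df) {
  need <- c("sample_id", "case_id", "subtype", "lab", "day", "operator",
            "rna_mass_ng", "qc_pass")
  if (!all(need %in% names(df))) {
    stop("sample table requires columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id")
  if (!all(df$subtype %in% c("TNB", "ERpos"))) stop("unknown subtype")
  if (!all(df$lab %in% c("Lab1", "Lab2"))) stop("unknown lab")
  if (!all(df$day %in% 1:3)) stop("day must be in 1..3")
  if (any(df$rna_mass_ng <= 0)) stop("rna_mass_ng must be positive")
  key <- paste(df$case_id, df$lab, df$day)
  if (anyDuplicated(key)) stop("(case_id, lab, day) must be unique")
  df$day <- as.integer(df$day)
  df$qc_pass <- as.logical(df$qc_pass)
  rownames(df) <- NULL
  class(df) <- c("sample_table", "data.frame")
  df
}

#' @rdname sample_table
#' @param path metadata CSV path.
#' @export
read_sample_table <- function(path) {
  sample_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname sample_table
#' @param meta a `sample_table` to write.
#' @export
write_sample_table <- function(meta, path) {
  utils::write.csv(as.data.frame(meta), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
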