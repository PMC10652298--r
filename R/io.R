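# Domain tables and their TSV readers/writers.
#
# Every table is a plain data.frame with a fixed, documented column schema
# (one header line, tab-separated, explicit "NA" token for missing values).
# Readers parse all fields as character first and convert with per-row
# checks, so a malformed value is reported with its table and row number
# rather than silently becoming NA. Coordinates follow the BED convention:
# 0-based start, exclusive end.

PEAK_COLS <- c("chrom", "start", "end", "peak_id", "gene_symbol",
               "chromatin_state", "coef_abeta", "fdr")
DEG_COLS <- c("gene_symbol", "cell_type", "log2fc", "adj_p")
HOMOLOG_COLS <- c("human_gene", "fly_gene", "confidence")
EXPR_COLS <- c("cell_type", "gene_symbol", "mean_expr", "frac_expressing")
GO_COLS <- c("term_id", "term_name", "gene_symbol")
EPHYS_COLS <- c("genotype", "phtx", "mepsp_mv", "epsp_mv")
INTEGRATED_COLS <- c("gene_symbol", "cell_type", "coef_abeta", "log2fc",
                     "same_sign", "is_primary_assignment")

read_raw_tsv <- function(path, cols, table) {
  if (!file.exists(path)) stop(sprintf("%s: file not found: %s", table, path),
                               call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stop(sprintf("%s: missing column(s): %s", table,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df[cols]
}

parse_num <- function(x, table, col, allow_na = FALSE) {
  out <- suppressWarnings(as.numeric(x))
  is_na_tok <- !is.na(x) & x == "NA"
  bad <- which(is.na(out) & !is_na_tok)
  if (length(bad) > 0L)
    stop_row(table, bad[1L],
             sprintf("non-numeric value '%s' in column %s", x[bad[1L]], col))
  if (!allow_na && any(is_na_tok))
    stop_row(table, which(is_na_tok)[1L], sprintf("NA not allowed in column %s", col))
  out
}

parse_lgl <- function(x, table, col) {
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "true")] <- TRUE
  out[x %in% c("FALSE", "false")] <- FALSE
  bad <- which(is.na(out) & x != "NA")
  if (length(bad) > 0L)
    stop_row(table, bad[1L],
             sprintf("non-logical value '%s' in column %s", x[bad[1L]], col))
  out
}

check_nonempty <- function(x, table, col) {
  bad <- which(is.na(x) | !nzchar(x) | x == "NA")
  if (length(bad) > 0L)
    stop_row(table, bad[1L], sprintf("empty %s", col))
  invisible(TRUE)
}

check_levels <- function(x, levels, table, col) {
  bad <- which(!(x %in% levels))
  if (length(bad) > 0L)
    stop_row(table, bad[1L],
             sprintf("unknown %s label '%s' (expected one of: %s)",
                     col, x[bad[1L]], paste(levels, collapse = ", ")))
  invisible(TRUE)
}

# ---- validators ------------------------------------------------------------

#' Validate an H3K9ac peak table
#'
#' Checks the invariants of the peak table: BED-style coordinates with
#' `start < end`, non-empty gene symbols, a known chromatin-state label and
#' FDR within `[0, 1]`. The per-peak amyloid regression coefficient
#' (`coef_abeta`) quantifies how strongly the peak's H3K9ac signal tracks
#' amyloid-beta pathology burden across donors.
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end`, `peak_id`,
#'   `gene_symbol`, `chromatin_state`, `coef_abeta`, `fdr`.
#' @return `peaks`, invisibly, on success; otherwise an error naming the
#'   offending row.
#' @export
validate_peaks <- function(peaks) {
  stopifnot(is.data.frame(peaks))
  tb <- "peak table"
  check_nonempty(peaks$peak_id, tb, "peak_id")
  check_nonempty(peaks$gene_symbol, tb, "gene_symbol")
  check_nonempty(peaks$chrom, tb, "chrom")
  check_levels(peaks$chromatin_state, CHROMATIN_STATES, tb, "chromatin_state")
  check_numeric_in(peaks$fdr, 0, 1, "fdr", tb)
  if (any(!is.finite(peaks$coef_abeta)))
    stop_row(tb, which(!is.finite(peaks$coef_abeta))[1L], "non-finite coef_abeta")
  bad <- which(!(peaks$start < peaks$end))
  if (length(bad) > 0L)
    stop_row(tb, bad[1L], sprintf("malformed coordinates (start %d >= end %d)",
                                  peaks$start[bad[1L]], peaks$end[bad[1L]]))
  if (any(peaks$start < 0))
    stop_row(tb, which(peaks$start < 0)[1L], "negative start coordinate")
  invisible(peaks)
}

#' Validate a cell-type-resolved differential-expression table
#'
#' One row per (gene, cell type) differential-expression call, with the six
#' cell-type labels of [CELL_TYPES], a log2 fold change and an adjusted
#' p-value in `[0, 1]`.
#'
#' @param degs data.frame with columns `gene_symbol`, `cell_type`, `log2fc`,
#'   `adj_p`.
#' @return `degs`, invisibly, on success.
#' @export
validate_degs <- function(degs) {
  stopifnot(is.data.frame(degs))
  tb <- "DEG table"
  check_nonempty(degs$gene_symbol, tb, "gene_symbol")
  check_levels(degs$cell_type, CELL_TYPES, tb, "cell_type")
  check_numeric_in(degs$adj_p, 0, 1, "adj_p", tb)
  if (any(!is.finite(degs$log2fc)))
    stop_row(tb, which(!is.finite(degs$log2fc))[1L], "non-finite log2fc")
  invisible(degs)
}

validate_homologs <- function(homologs) {
  tb <- "homologue map"
  check_nonempty(homologs$human_gene, tb, "human_gene")
  check_nonempty(homologs$fly_gene, tb, "fly_gene")
  if (any(!is.finite(homologs$confidence) | homologs$confidence < 0))
    stop_row(tb, which(!is.finite(homologs$confidence) | homologs$confidence < 0)[1L],
             "confidence must be a finite value >= 0")
  invisible(homologs)
}

validate_expression <- function(expr, table = "expression summary") {
  check_nonempty(expr$cell_type, table, "cell_type")
  check_nonempty(expr$gene_symbol, table, "gene_symbol")
  if (any(!is.finite(expr$mean_expr) | expr$mean_expr < 0))
    stop_row(table, which(!is.finite(expr$mean_expr) | expr$mean_expr < 0)[1L],
             "mean_expr must be finite and >= 0")
  check_numeric_in(expr$frac_expressing, 0, 1, "frac_expressing", table)
  invisible(expr)
}

validate_go <- function(go) {
  tb <- "GO annotation"
  check_nonempty(go$term_id, tb, "term_id")
  check_nonempty(go$term_name, tb, "term_name")
  check_nonempty(go$gene_symbol, tb, "gene_symbol")
  invisible(go)
}

#' Validate an electrophysiology cohort table
#'
#' One row per recorded cell: genotype, philanthotoxin condition
#' (`absent`/`present`) and the miniature and evoked excitatory postsynaptic
#' potential amplitudes in mV, which must be strictly positive.
#'
#' @param cells data.frame with columns `genotype`, `phtx`, `mepsp_mv`,
#'   `epsp_mv`.
#' @return `cells`, invisibly, on success.
#' @export
validate_ephys <- function(cells) {
  tb <- "ephys table"
  check_nonempty(cells$genotype, tb, "genotype")
  check_levels(cells$phtx, PHTX_LEVELS, tb, "phtx")
  if (any(!is.finite(cells$mepsp_mv) | cells$mepsp_mv <= 0))
    stop_row(tb, which(!is.finite(cells$mepsp_mv) | cells$mepsp_mv <= 0)[1L],
             "mepsp_mv must be finite and > 0")
  if (any(!is.finite(cells$epsp_mv) | cells$epsp_mv <= 0))
    stop_row(tb, which(!is.finite(cells$epsp_mv) | cells$epsp_mv <= 0)[1L],
             "epsp_mv must be finite and > 0")
  invisible(cells)
}

validate_integrated <- function(records) {
  tb <- "integrated table"
  check_nonempty(records$gene_symbol, tb, "gene_symbol")
  check_levels(records$cell_type, CELL_TYPES, tb, "cell_type")
  both_nonzero <- records$coef_abeta != 0 & records$log2fc != 0
  bad <- which(both_nonzero & is.na(records$same_sign))
  if (length(bad) > 0L)
    stop_row(tb, bad[1L], "same_sign undefined although coef_abeta and log2fc are both nonzero")
  bad <- which(!both_nonzero & !is.na(records$same_sign))
  if (length(bad) > 0L)
    stop_row(tb, bad[1L], "same_sign defined although coef_abeta or log2fc is zero")
  if (any(records$is_primary_assignment, na.rm = TRUE)) {
    per_gene <- tapply(records$is_primary_assignment,
                       records$gene_symbol, sum)
    off <- names(per_gene)[per_gene != 1L]
    if (length(off) > 0L)
      stop(sprintf("integrated table: gene %s does not have exactly one primary assignment",
                   off[1L]), call. = FALSE)
  }
  invisible(records)
}

# ---- readers ---------------------------------------------------------------

#' Read pipeline input tables
#'
#' Readers for every TSV the pipeline consumes. All tables carry a single
#' header line, are tab-separated, and use an explicit `"NA"` token for
#' missing values; numeric blanks are rejected with the offending row
#' identified. The peak table is BED-like (`chrom`, `start`, `end`,
#' `peak_id`, `gene_symbol`, `chromatin_state`, `coef_abeta`, `fdr`) with
#' 0-based half-open coordinates.
#'
#' @param path Path to a TSV file.
#' @return A validated data.frame; row order is preserved.
#' @seealso [write_peaks()] and friends for the inverse operation,
#'   [read_input_bundle()] to load a directory of tables at once.
#' @export
read_peaks <- function(path) {
  raw <- read_raw_tsv(path, PEAK_COLS, "peak table")
  tb <- "peak table"
  df <- data.frame(
    chrom = raw$chrom,
    start = parse_num(raw$start, tb, "start"),
    end = parse_num(raw$end, tb, "end"),
    peak_id = raw$peak_id,
    gene_symbol = raw$gene_symbol,
    chromatin_state = raw$chromatin_state,
    coef_abeta = parse_num(raw$coef_abeta, tb, "coef_abeta"),
    fdr = parse_num(raw$fdr, tb, "fdr"),
    stringsAsFactors = FALSE
  )
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  validate_peaks(df)
  df
}

#' @rdname read_peaks
#' @export
read_degs <- function(path) {
  raw <- read_raw_tsv(path, DEG_COLS, "DEG table")
  tb <- "DEG table"
  df <- data.frame(
    gene_symbol = raw$gene_symbol,
    cell_type = raw$cell_type,
    log2fc = parse_num(raw$log2fc, tb, "log2fc"),
    adj_p = parse_num(raw$adj_p, tb, "adj_p"),
    stringsAsFactors = FALSE
  )
  validate_degs(df)
  df
}

#' @rdname read_peaks
#' @export
read_homolog_map <- function(path) {
  raw <- read_raw_tsv(path, HOMOLOG_COLS, "homologue map")
  df <- data.frame(
    human_gene = raw$human_gene,
    fly_gene = raw$fly_gene,
    confidence = parse_num(raw$confidence, "homologue map", "confidence"),
    stringsAsFactors = FALSE
  )
  validate_homologs(df)
  df
}

#' @rdname read_peaks
#' @export
read_expression_summary <- function(path) {
  raw <- read_raw_tsv(path, EXPR_COLS, "expression summary")
  tb <- "expression summary"
  df <- data.frame(
    cell_type = raw$cell_type,
    gene_symbol = raw$gene_symbol,
    mean_expr = parse_num(raw$mean_expr, tb, "mean_expr"),
    frac_expressing = parse_num(raw$frac_expressing, tb, "frac_expressing"),
    stringsAsFactors = FALSE
  )
  validate_expression(df)
  df
}

#' @rdname read_peaks
#' @export
read_go_annotations <- function(path) {
  raw <- read_raw_tsv(path, GO_COLS, "GO annotation")
  df <- data.frame(
    term_id = raw$term_id,
    term_name = raw$term_name,
    gene_symbol = raw$gene_symbol,
    stringsAsFactors = FALSE
  )
  validate_go(df)
  df
}

#' @rdname read_peaks
#' @export
read_ephys_cells <- function(path) {
  raw <- read_raw_tsv(path, EPHYS_COLS, "ephys table")
  tb <- "ephys table"
  df <- data.frame(
    genotype = raw$genotype,
    phtx = raw$phtx,
    mepsp_mv = parse_num(raw$mepsp_mv, tb, "mepsp_mv"),
    epsp_mv = parse_num(raw$epsp_mv, tb, "epsp_mv"),
    stringsAsFactors = FALSE
  )
  validate_ephys(df)
  df
}

#' @rdname read_peaks
#' @export
read_integrated_records <- function(path) {
  raw <- read_raw_tsv(path, INTEGRATED_COLS, "integrated table")
  tb <- "integrated table"
  df <- data.frame(
    gene_symbol = raw$gene_symbol,
    cell_type = raw$cell_type,
    coef_abeta = parse_num(raw$coef_abeta, tb, "coef_abeta"),
    log2fc = parse_num(raw$log2fc, tb, "log2fc"),
    same_sign = parse_lgl(raw$same_sign, tb, "same_sign"),
    is_primary_assignment = parse_lgl(raw$is_primary_assignment, tb,
                                      "is_primary_assignment"),
    stringsAsFactors = FALSE
  )
  validate_integrated(df)
  df
}

#' Load a directory of pipeline input tables
#'
#' @param paths Named list or vector of file paths; recognised names are
#'   `peaks`, `degs`, `homologs`, `human_expr`, `fly_expr`, `go`, `ephys`.
#'   Unrecognised names are an error; absent names are simply not loaded.
#' @return Named list of validated data.frames.
#' @export
read_input_bundle <- function(paths) {
  readers <- list(peaks = read_peaks, degs = read_degs,
                  homologs = read_homolog_map,
                  human_expr = read_expression_summary,
                  fly_expr = read_expression_summary,
                  go = read_go_annotations, ephys = read_ephys_cells)
  unknown <- setdiff(names(paths), names(readers))
  if (length(unknown) > 0L)
    stop("unknown input table name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- lapply(names(paths), function(nm) readers[[nm]](paths[[nm]]))
  names(out) <- names(paths)
  out
}

# ---- writers ---------------------------------------------------------------

write_tsv_checked <- function(df, path, cols) {
  df <- df[cols]
  for (cl in names(df)) {
    v <- df[[cl]]
    if (is.numeric(v)) {
      s <- vapply(v, function(z) {
        if (is.na(z)) "NA" else format(z, digits = 15, scientific = FALSE, trim = TRUE)
      }, character(1L))
      df[[cl]] <- s
    } else if (is.logical(v)) {
      df[[cl]] <- ifelse(is.na(v), "NA", ifelse(v, "TRUE", "FALSE"))
    }
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop(sprintf("cannot write table to '%s': %s", path, conditionMessage(ok)),
         call. = FALSE)
  invisible(path)
}

#' Write pipeline tables
#'
#' Writers matching the [read_peaks()] family. Round-tripping a table
#' through its writer and reader reproduces every field (numeric values to
#' at least 12 significant digits; undefined values as an explicit `NA`
#' token).
#'
#' @param x A validated table of the corresponding type.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_peaks <- function(x, path) {
  validate_peaks(x)
  write_tsv_checked(x, path, PEAK_COLS)
}

#' @rdname write_peaks
#' @export
write_degs <- function(x, path) {
  validate_degs(x)
  write_tsv_checked(x, path, DEG_COLS)
}

#' @rdname write_peaks
#' @export
write_homolog_map <- function(x, path) {
  validate_homologs(x)
  write_tsv_checked(x, path, HOMOLOG_COLS)
}

#' @rdname write_peaks
#' @export
write_expression_summary <- function(x, path) {
  validate_expression(x)
  write_tsv_checked(x, path, EXPR_COLS)
}

#' @rdname write_peaks
#' @export
write_go_annotations <- function(x, path) {
  validate_go(x)
  write_tsv_checked(x, path, GO_COLS)
}

#' @rdname write_peaks
#' @export
write_ephys_cells <- function(x, path) {
  validate_ephys(x)
  write_tsv_checked(x, path, EPHYS_COLS)
}

#' @rdname write_peaks
#' @export
write_integrated_records <- function(x, path) {
  validate_integrated(x)
  write_tsv_checked(x, path, INTEGRATED_COLS)
}
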