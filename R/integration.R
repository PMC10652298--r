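# Epigenome-transcriptome integration: filter amyloid-associated H3K9ac
# peaks, collapse peaks to genes, overlap with cell-type-resolved DEGs,
# assign each gene a primary cell type and tabulate direction counts.

#' Filter amyloid-associated H3K9ac peaks
#'
#' Retains exactly the peaks with `fdr < fdr_max` (strict inequality, per
#' the original selection criterion), preserving input order. Idempotent.
#'
#' @param peaks Validated peak table.
#' @param fdr_max FDR threshold; default 0.05.
#' @return The retained rows of `peaks` (possibly empty).
#' @export
filter_abeta_peaks <- function(peaks, fdr_max = 0.05) {
  validate_peaks(peaks)
  out <- peaks[peaks$fdr < fdr_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse peaks to genes
#'
#' Reduces an amyloid-filtered peak table to one row per unique gene. When
#' several peaks annotate the same gene, the peak with the smallest FDR
#' supplies the gene's amyloid coefficient and chromatin state; ties are
#' broken by the largest `|coef_abeta|`, then by file order. The collapse
#' rule is this pipeline's own choice (the original study does not state
#' one) and is therefore explicit and deterministic.
#'
#' @param peaks Validated (typically amyloid-filtered) peak table.
#' @return data.frame with one row per gene: `gene_symbol`, `coef_abeta`,
#'   `chromatin_state`, `fdr` (of the representative peak), `n_peaks`.
#' @export
peaks_to_genes <- function(peaks) {
  validate_peaks(peaks)
  if (nrow(peaks) == 0L)
    return(data.frame(gene_symbol = character(0), coef_abeta = numeric(0),
                      chromatin_state = character(0), fdr = numeric(0),
                      n_peaks = integer(0), stringsAsFactors = FALSE))
  ord <- order(factor(peaks$gene_symbol, levels = unique(peaks$gene_symbol)),
               peaks$fdr, -abs(peaks$coef_abeta), seq_len(nrow(peaks)))
  sorted <- peaks[ord, , drop = FALSE]
  first <- !duplicated(sorted$gene_symbol)
  rep_peaks <- sorted[first, , drop = FALSE]
  counts <- table(peaks$gene_symbol)
  out <- data.frame(
    gene_symbol = rep_peaks$gene_symbol,
    coef_abeta = rep_peaks$coef_abeta,
    chromatin_state = rep_peaks$chromatin_state,
    fdr = rep_peaks$fdr,
    n_peaks = as.integer(counts[rep_peaks$gene_symbol]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Overlap amyloid-target genes with cell-type DEGs
#'
#' The unit of analysis is the (gene, cell type) record: every DEG row whose
#' gene is among the amyloid-associated H3K9ac-target genes yields one
#' integrated record carrying both the gene's amyloid coefficient and the
#' record's log2 fold change, so a gene that is a DEG in several cell types
#' contributes several records. The `same_sign` flag is computed with
#' [same_sign()] (undefined when either value is exactly zero).
#'
#' @param gene_map Output of [peaks_to_genes()].
#' @param degs Validated DEG table.
#' @return Integrated-record data.frame (`gene_symbol`, `cell_type`,
#'   `coef_abeta`, `log2fc`, `same_sign`, `is_primary_assignment`); the
#'   primary-assignment flag is initialised to `FALSE` and set by
#'   [assign_primary_cell_type()].
#' @export
overlap_with_degs <- function(gene_map, degs) {
  validate_degs(degs)
  hit <- degs$gene_symbol %in% gene_map$gene_symbol
  sub <- degs[hit, , drop = FALSE]
  idx <- match(sub$gene_symbol, gene_map$gene_symbol)
  out <- data.frame(
    gene_symbol = sub$gene_symbol,
    cell_type = sub$cell_type,
    coef_abeta = gene_map$coef_abeta[idx],
    log2fc = sub$log2fc,
    stringsAsFactors = FALSE
  )
  out$same_sign <- as.logical(same_sign(out$coef_abeta, out$log2fc))
  out$is_primary_assignment <- rep(FALSE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Assign each gene its primary cell type
#'
#' When a gene is a DEG in multiple cell types it is assigned to the cell
#' type with the largest absolute log2 fold change. Exactly one record per
#' gene is flagged; an exact tie in `|log2fc|` is broken by the fixed
#' cell-type order Ex, In, Ast, Oli, OPC, Mic, so the assignment is
#' invariant under permutations of the input rows.
#'
#' @param records Integrated-record data.frame from [overlap_with_degs()].
#' @return `records` with `is_primary_assignment` set.
#' @export
assign_primary_cell_type <- function(records) {
  if (nrow(records) == 0L) return(records)
  records$is_primary_assignment <- FALSE
  key <- order(records$gene_symbol, -abs(records$log2fc),
               match(records$cell_type, CELL_TYPES))
  winners <- key[!duplicated(records$gene_symbol[key])]
  records$is_primary_assignment[winners] <- TRUE
  validate_integrated(records)
  records
}

#' Per-cell-type direction counts
#'
#' Tabulates, for each cell type, the number of integrated records, how
#' many are up- and down-regulated, and the percentage down. A log2 fold
#' change of exactly zero is directionless: it counts in `n_total` but in
#' neither direction.
#'
#' @param records Integrated-record data.frame.
#' @return data.frame with one row per cell type (`cell_type`, `n_total`,
#'   `n_up`, `n_down`, `pct_down`, `pct_up`); empty input yields an empty
#'   table.
#' @export
direction_counts <- function(records) {
  if (nrow(records) == 0L)
    return(data.frame(cell_type = character(0), n_total = integer(0),
                      n_up = integer(0), n_down = integer(0),
                      pct_down = numeric(0), pct_up = numeric(0),
                      stringsAsFactors = FALSE))
  ct <- factor(records$cell_type, levels = CELL_TYPES)
  n_total <- as.integer(table(ct))
  n_up <- as.integer(table(ct[records$log2fc > 0]))
  n_down <- as.integer(table(ct[records$log2fc < 0]))
  out <- data.frame(
    cell_type = CELL_TYPES, n_total = n_total, n_up = n_up, n_down = n_down,
    pct_down = ifelse(n_total > 0, 100 * n_down / n_total, NA_real_),
    pct_up = ifelse(n_total > 0, 100 * n_up / n_total, NA_real_),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Run the full integration stage
#'
#' Convenience wrapper: amyloid-FDR filter, per-gene peak collapse, DEG
#' overlap, primary-cell-type assignment and direction counts in one call.
#'
#' @param peaks Validated peak table.
#' @param degs Validated DEG table.
#' @param fdr_max FDR threshold for the amyloid filter.
#' @return List with `gene_map`, `records` (primary assignment set) and
#'   `counts`.
#' @export
integrate_peaks_degs <- function(peaks, degs, fdr_max = 0.05) {
  filtered <- filter_abeta_peaks(peaks, fdr_max)
  gene_map <- peaks_to_genes(filtered)
  records <- assign_primary_cell_type(overlap_with_degs(gene_map, degs))
  list(gene_map = gene_map, records = records,
       counts = direction_counts(records))
}
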