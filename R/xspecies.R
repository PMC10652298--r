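# Cross-species synaptic-gene enrichment: select the top-N most highly
# expressed "synaptic" genes per human cell type, map them to fly
# homologues, and ask whether those homologues are more highly expressed in
# a target fly cell type (perineurial glia) than random expressed genes,
# via a bootstrap percentile in the spirit of expression-weighted cell-type
# enrichment (EWCE).

#' Select genes annotated to "synaptic" GO terms
#'
#' Union of the gene sets of every term whose name contains the keyword
#' (case-insensitive substring match).
#'
#' @param annotations GO annotation data.frame (long format).
#' @param keyword Substring to match in term names; default `"synaptic"`.
#' @return Character vector of genes (possibly empty, with a warning when
#'   no term matches).
#' @export
select_synaptic_genes <- function(annotations, keyword = "synaptic") {
  validate_go(annotations)
  hit <- grepl(keyword, annotations$term_name, ignore.case = TRUE, fixed = FALSE)
  if (!any(hit)) {
    warning(sprintf("no GO term name contains keyword '%s'", keyword))
    return(character(0))
  }
  sort(unique(annotations$gene_symbol[hit]))
}

#' Top-N most highly expressed candidate genes in one cell type
#'
#' Ranks the candidate genes by mean expression in the given cell type,
#' descending, with ties broken alphabetically (deterministic across runs),
#' and returns the first `n`. If fewer than `n` candidates are measured in
#' the cell type, all are returned with a warning.
#'
#' @param expr Expression summary data.frame.
#' @param cell_type Cell type to rank within.
#' @param candidates Character vector of candidate genes.
#' @param n Number of genes to return; default 20.
#' @return Character vector of up to `n` genes, highest expression first.
#' @export
top_expressed_genes <- function(expr, cell_type, candidates, n = 20) {
  stopifnot(n >= 1)
  validate_expression(expr)
  sub <- expr[expr$cell_type == cell_type &
                expr$gene_symbol %in% candidates, , drop = FALSE]
  sub <- sub[order(-sub$mean_expr, sub$gene_symbol), , drop = FALSE]
  if (nrow(sub) < n)
    warning(sprintf("only %d of %d requested candidates measured in %s",
                    nrow(sub), n, cell_type))
  utils::head(sub$gene_symbol, n)
}

#' Resolve a homologue map to one fly gene per human gene
#'
#' One-to-many relations are resolved by the highest mapping confidence,
#' then alphabetically by fly gene name.
#'
#' @param homologs Homologue-map data.frame.
#' @return Homologue map with one row per human gene.
#' @export
resolve_homologs <- function(homologs) {
  validate_homologs(homologs)
  ord <- order(homologs$human_gene, -homologs$confidence, homologs$fly_gene)
  sorted <- homologs[ord, , drop = FALSE]
  out <- sorted[!duplicated(sorted$human_gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bootstrap enrichment percentile of a gene set in one fly cell type
#'
#' The observed statistic is the mean of the per-gene mean expression of
#' the target genes in `cell_type`. The null distribution is the same
#' statistic for `n_boot` random subsets of the expressed universe of the
#' same size, drawn without replacement. The percentile is
#' `100 * (fraction of null draws strictly below the observed statistic)`;
#' a null draw equal to the observed statistic counts as not-below. A
#' percentile of 99.8 reads as: the target genes are more highly expressed
#' than 99.8% of random same-size sets of expressed genes.
#'
#' @param target_genes Character vector of fly genes; must be a subset of
#'   the expressed universe and strictly smaller than it.
#' @param fly_expr Fly expression summary data.frame.
#' @param cell_type Target fly cell type; default `"perineurial_glia"`.
#' @param expressed_universe Optional character vector of background genes.
#'   When `NULL`, the universe is every gene with
#'   `frac_expressing > expressed_min_frac` in `cell_type`.
#' @param n_boot Number of bootstrap draws; default 10000 (percentile
#'   standard error at most 0.5).
#' @param seed Integer seed for the bootstrap.
#' @param expressed_min_frac Expression threshold defining the universe.
#' @param statistic `"mean_expr"` (default: mean of mean-expression values)
#'   or `"specificity"` (mean of the gene's expression proportion in
#'   `cell_type` relative to its total across cell types, as in EWCE).
#' @return An `enrichment_result` list: `statistic_obs`, `percentile`,
#'   `n_target`, `n_universe`, `n_boot`, `seed`, `statistic`, `cell_type`.
#' @export
enrichment_percentile <- function(target_genes, fly_expr,
                                  cell_type = "perineurial_glia",
                                  expressed_universe = NULL,
                                  n_boot = 10000, seed = 1L,
                                  expressed_min_frac = 0.01,
                                  statistic = c("mean_expr", "specificity")) {
  statistic <- match.arg(statistic)
  validate_expression(fly_expr)
  sub <- fly_expr[fly_expr$cell_type == cell_type, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop(sprintf("no expression rows for cell type '%s'", cell_type), call. = FALSE)
  if (is.null(expressed_universe))
    expressed_universe <- sub$gene_symbol[sub$frac_expressing > expressed_min_frac]
  expressed_universe <- unique(expressed_universe)
  target_genes <- unique(target_genes)
  if (!all(target_genes %in% expressed_universe))
    stop("target genes must be a subset of the expressed universe", call. = FALSE)
  if (length(expressed_universe) <= length(target_genes))
    stop("expressed universe must be larger than the target set", call. = FALSE)
  if (statistic == "mean_expr") {
    value <- sub$mean_expr
    names(value) <- sub$gene_symbol
  } else {
    totals <- tapply(fly_expr$mean_expr, fly_expr$gene_symbol, sum)
    value <- sub$mean_expr / as.numeric(totals[sub$gene_symbol])
    value[!is.finite(value)] <- 0
    names(value) <- sub$gene_symbol
  }
  value <- value[expressed_universe]
  if (anyNA(value))
    stop("expressed universe contains genes without expression values",
         call. = FALSE)
  obs <- mean(value[target_genes])
  k <- length(target_genes)
  null_stats <- with_seed(substream_seed(seed, "enrichment_boot"), {
    vapply(seq_len(n_boot),
           function(i) mean(value[sample.int(length(value), k)]),
           numeric(1))
  })
  out <- list(statistic_obs = obs,
              percentile = 100 * mean(null_stats < obs),
              n_target = k, n_universe = length(value),
              n_boot = n_boot, seed = as.integer(seed),
              statistic = statistic, cell_type = cell_type)
  class(out) <- "enrichment_result"
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Bootstrap expression enrichment in %s\n", x$cell_type))
  cat(sprintf("  %d target genes vs %d expressed genes (%s statistic)\n",
              x$n_target, x$n_universe, x$statistic))
  cat(sprintf("  observed mean = %.4g; higher than %.1f%% of %d random sets\n",
              x$statistic_obs, x$percentile, x$n_boot))
  invisible(x)
}

#' Cross-species expression correlation over homologue pairs
#'
#' Spearman correlation between human expression (mean expression in one
#' human cell type) and the fly value of the mapped homologue in a fly cell
#' type -- either the homologue's mean expression or the fraction of cells
#' expressing it.
#'
#' @param genes Human genes to correlate (for example a top-20 list).
#' @param human_expr,fly_expr Expression summary data.frames.
#' @param homologs Homologue map (resolved 1:1 internally via
#'   [resolve_homologs()]).
#' @param human_cell_type,fly_cell_type Cell types to compare.
#' @param metric `"mean_expr"` or `"frac_expressing"` (fly-side value).
#' @return data.frame row: `human_cell_type`, `metric`, `n_pairs`,
#'   `spearman_r`, `p`.
#' @export
xspecies_expression_cor <- function(genes, human_expr, fly_expr, homologs,
                                    human_cell_type,
                                    fly_cell_type = "perineurial_glia",
                                    metric = c("mean_expr", "frac_expressing")) {
  metric <- match.arg(metric)
  map <- resolve_homologs(homologs)
  map <- map[map$human_gene %in% genes, , drop = FALSE]
  hsub <- human_expr[human_expr$cell_type == human_cell_type, , drop = FALSE]
  fsub <- fly_expr[fly_expr$cell_type == fly_cell_type, , drop = FALSE]
  hidx <- match(map$human_gene, hsub$gene_symbol)
  fidx <- match(map$fly_gene, fsub$gene_symbol)
  keep <- !is.na(hidx) & !is.na(fidx)
  if (sum(keep) < 3)
    stop(sprintf("fewer than 3 mapped homologue pairs for %s", human_cell_type),
         call. = FALSE)
  hval <- hsub$mean_expr[hidx[keep]]
  fval <- if (metric == "mean_expr") fsub$mean_expr[fidx[keep]]
          else fsub$frac_expressing[fidx[keep]]
  ct <- cor_with_p(hval, fval, "spearman")
  data.frame(human_cell_type = human_cell_type, metric = metric,
             n_pairs = ct$n, spearman_r = ct$r, p = ct$p,
             stringsAsFactors = FALSE)
}

#' Full cross-species synaptic enrichment analysis
#'
#' For each human cell type: take the top-`n_top` most highly expressed
#' "synaptic" genes (per the GO keyword), map them to fly homologues, and
#' compute (i) the bootstrap enrichment percentile of those homologues in
#' the target fly cell type and (ii) the cross-species Spearman
#' correlations for both fly-side metrics.
#'
#' @param human_expr,fly_expr Expression summary data.frames.
#' @param homologs Homologue map.
#' @param annotations GO annotation data.frame.
#' @param n_top Number of top genes per cell type; default 20.
#' @param n_boot,seed,expressed_min_frac,statistic Passed to
#'   [enrichment_percentile()].
#' @param keyword GO term keyword; default `"synaptic"`.
#' @param fly_cell_type Target fly cell type.
#' @return List with data.frames `enrichment` (per human cell type:
#'   `n_top`, `n_mapped`, `percentile`, `n_boot`, `seed`) and
#'   `correlations` (both metrics per cell type).
#' @export
xspecies_enrichment <- function(human_expr, fly_expr, homologs, annotations,
                                n_top = 20, n_boot = 10000, seed = 1L,
                                expressed_min_frac = 0.01,
                                statistic = c("mean_expr", "specificity"),
                                keyword = "synaptic",
                                fly_cell_type = "perineurial_glia") {
  statistic <- match.arg(statistic)
  synaptic <- select_synaptic_genes(annotations, keyword)
  map <- resolve_homologs(homologs)
  enr <- list(); cors <- list()
  for (ct in intersect(CELL_TYPES, unique(human_expr$cell_type))) {
    top <- top_expressed_genes(human_expr, ct, synaptic, n_top)
    fly_genes <- map$fly_gene[match(top, map$human_gene)]
    fly_genes <- fly_genes[!is.na(fly_genes)]
    fsub <- fly_expr[fly_expr$cell_type == fly_cell_type, , drop = FALSE]
    universe <- fsub$gene_symbol[fsub$frac_expressing > expressed_min_frac]
    fly_genes <- intersect(fly_genes, universe)
    res <- if (length(fly_genes) >= 2) {
      enrichment_percentile(fly_genes, fly_expr, fly_cell_type,
                            n_boot = n_boot,
                            seed = substream_seed(seed, paste0("enr_", ct)),
                            expressed_min_frac = expressed_min_frac,
                            statistic = statistic)
    } else NULL
    enr[[ct]] <- data.frame(
      human_cell_type = ct, n_top = length(top), n_mapped = length(fly_genes),
      percentile = if (is.null(res)) NA_real_ else res$percentile,
      n_boot = n_boot, seed = as.integer(seed), stringsAsFactors = FALSE)
    for (metric in c("mean_expr", "frac_expressing")) {
      row <- tryCatch(
        xspecies_expression_cor(top, human_expr, fly_expr, homologs, ct,
                                fly_cell_type, metric),
        error = function(e) data.frame(human_cell_type = ct, metric = metric,
                                       n_pairs = NA_integer_,
                                       spearman_r = NA_real_, p = NA_real_,
                                       stringsAsFactors = FALSE))
      cors[[paste(ct, metric)]] <- row
    }
  }
  list(enrichment = do.call(rbind, c(enr, list(make.row.names = FALSE))),
       correlations = do.call(rbind, c(cors, list(make.row.names = FALSE))))
}
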