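# Small in-code fixtures used across test files.

make_peaks <- function(gene = c("A", "B", "C"),
                       fdr = c(0.01, 0.04, 0.2),
                       coef = c(0.5, -0.3, 1.2),
                       state = c("promoter", "enhancer", "other")) {
  n <- length(gene)
  data.frame(
    chrom = rep("chr1", n),
    start = as.integer(seq(100L, by = 1000L, length.out = n)),
    end = as.integer(seq(100L, by = 1000L, length.out = n) + 500L),
    peak_id = sprintf("pk%02d", seq_len(n)),
    gene_symbol = gene,
    chromatin_state = rep_len(state, n),
    coef_abeta = coef,
    fdr = fdr,
    stringsAsFactors = FALSE
  )
}

make_degs <- function(gene = c("A", "A", "B"),
                      ct = c("Ex", "Oli", "In"),
                      log2fc = c(0.1, -0.5, -1),
                      adj_p = 0.01) {
  data.frame(gene_symbol = gene, cell_type = ct, log2fc = log2fc,
             adj_p = rep_len(adj_p, length(gene)), stringsAsFactors = FALSE)
}

make_records <- function(gene, ct, coef, log2fc) {
  df <- data.frame(gene_symbol = gene, cell_type = ct, coef_abeta = coef,
                   log2fc = log2fc, stringsAsFactors = FALSE)
  df$same_sign <- same_sign(df$coef_abeta, df$log2fc)
  df$is_primary_assignment <- FALSE
  df
}

make_ephys <- function(genotype = "wt",
                       mepsp_minus = c(1, 1.1, 0.9),
                       epsp_minus = c(40, 44, 36),
                       mepsp_plus = c(0.5, 0.55, 0.45),
                       epsp_plus = c(40, 44, 36)) {
  rbind(
    data.frame(genotype = genotype, phtx = "absent", mepsp_mv = mepsp_minus,
               epsp_mv = epsp_minus, stringsAsFactors = FALSE),
    data.frame(genotype = genotype, phtx = "present", mepsp_mv = mepsp_plus,
               epsp_mv = epsp_plus, stringsAsFactors = FALSE)
  )
}

make_expr <- function(ct, gene, mean_expr, frac = NULL) {
  if (is.null(frac)) frac <- pmin(1, mean_expr / (mean_expr + 1))
  data.frame(cell_type = ct, gene_symbol = gene, mean_expr = mean_expr,
             frac_expressing = frac, stringsAsFactors = FALSE)
}

make_go <- function(terms, genes_by_term) {
  do.call(rbind, lapply(seq_along(terms), function(i)
    data.frame(term_id = sprintf("GO:%04d", i), term_name = terms[i],
               gene_symbol = genes_by_term[[i]], stringsAsFactors = FALSE)))
}
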