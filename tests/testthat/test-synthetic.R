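# Synthetic-data generators: determinism, ground-truth control and
# parameterization errors.

test_that("generators are pure functions of (truth, seed)", {
  truth <- simulation_truth(seed = 17)
  a <- gen_peak_deg_tables(truth, 300)
  b <- gen_peak_deg_tables(truth, 300)
  expect_identical(a, b)
  expect_identical(gen_ephys_cohort(truth, 5), gen_ephys_cohort(truth, 5))
  expect_identical(gen_fly_expression(truth, "tg1"),
                   gen_fly_expression(truth, "tg1"))
  # a different seed changes the draw
  truth2 <- simulation_truth(seed = 18)
  expect_false(identical(gen_peak_deg_tables(truth2, 300), a))
  # the caller's RNG stream is left untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(gen_peak_deg_tables(truth, 50)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("null correlation and full concordance cases behave as designed", {
  truth0 <- simulation_truth(rho = 0, same_sign_frac = 0.5, seed = 2)
  pd <- gen_peak_deg_tables(truth0, 5000)
  rec <- integrate_peaks_degs(pd$peaks, pd$degs)$records
  expect_lt(abs(cor(rec$coef_abeta, rec$log2fc)), 3 / sqrt(nrow(rec)))
  # same_sign_frac = 1: every associated pair matches signs (rho must then
  # lie in the attainable band, here 0.8)
  truth1 <- simulation_truth(rho = 0.8, same_sign_frac = 1, seed = 2)
  pd1 <- gen_peak_deg_tables(truth1, 2000)
  rec1 <- integrate_peaks_degs(pd1$peaks, pd1$degs)$records
  expect_true(all(rec1$same_sign))
})

test_that("unattainable (rho, same-sign) combinations raise parameterization errors", {
  expect_error(gen_peak_deg_tables(simulation_truth(rho = 0.9, same_sign_frac = 0.55),
                                   100), "unattainable")
  expect_error(gen_peak_deg_tables(simulation_truth(rho = 0.37, same_sign_frac = 0.5),
                                   100), "unattainable")
  # concordant majority forces positive correlation
  expect_error(gen_peak_deg_tables(simulation_truth(rho = 0, same_sign_frac = 0.69),
                                   100), "unattainable")
  expect_error(gen_peak_deg_tables(simulation_truth(rho = -0.3, same_sign_frac = 0.7),
                                   100), "unattainable")
})

test_that("peak/DEG tables carry the designed FDR and direction structure", {
  truth <- simulation_truth(seed = 9)
  pd <- gen_peak_deg_tables(truth, 4000)
  gt <- attr(pd, "gene_truth")
  assoc <- gt$gene_symbol[gt$is_assoc]
  expect_true(all(pd$peaks$fdr[pd$peaks$gene_symbol %in% assoc] < 0.05))
  expect_true(all(pd$peaks$fdr[!(pd$peaks$gene_symbol %in% assoc)] >= 0.05))
  # per-cell-type down fractions approach truth at scale (secondary records
  # dilute them toward 0.5, so the defaults get a loose tolerance ...)
  rec <- integrate_peaks_degs(pd$peaks, pd$degs)$records
  cts <- direction_counts(rec)
  for (ct in c("Ex", "Oli")) {
    expect_lt(abs(cts$pct_down[cts$cell_type == ct] / 100 -
                    truth$celltype_down_frac[[ct]]), 0.12)
  }
  # ... and are exact up to sampling error without multi-cell-type records
  truth1 <- simulation_truth(multi_celltype_frac = 0, seed = 9)
  rec1 <- integrate_peaks_degs(gen_peak_deg_tables(truth1, 4000)$peaks,
                               gen_peak_deg_tables(truth1, 4000)$degs)$records
  cts1 <- direction_counts(rec1)
  for (ct in c("Ex", "Oli", "Mic")) {
    n_ct <- cts1$n_total[cts1$cell_type == ct]
    d_ct <- truth1$celltype_down_frac[[ct]]
    expect_lt(abs(cts1$pct_down[cts1$cell_type == ct] / 100 - d_ct),
              3 * sqrt(max(d_ct * (1 - d_ct), 0.05) / n_ct) + 0.01)
  }
  # DEG records over distinct genes mirrors the multi-cell-type rate
  ratio <- nrow(rec) / length(unique(rec$gene_symbol))
  expect_lt(abs(ratio - (1 + truth$multi_celltype_frac)), 0.05)
})

test_that("fly expression scales target genes by the enrichment factor", {
  targets <- sprintf("tg%02d", 1:20)
  t10 <- simulation_truth(enrichment_factor = 10, n_fly_genes = 500, seed = 4)
  expr <- gen_fly_expression(t10, targets)
  expect_true(all(expr$mean_expr >= 0))
  expect_true(all(expr$frac_expressing >= 0 & expr$frac_expressing <= 1))
  pg <- expr[expr$cell_type == "perineurial_glia", ]
  m_t <- mean(pg$mean_expr[pg$gene_symbol %in% targets])
  m_b <- mean(pg$mean_expr[!(pg$gene_symbol %in% targets)])
  expect_gt(m_t / m_b, 3)     # 10x scaling on a log-normal background
  # enrichment is confined to the target cell type
  other <- expr[expr$cell_type == "neuron", ]
  expect_lt(mean(other$mean_expr[other$gene_symbol %in% targets]) /
              mean(other$mean_expr[!(other$gene_symbol %in% targets)]), 2)
  expect_error(gen_fly_expression(t10, character(0)), "non-empty")
})

test_that("ephys cohorts follow the homeostatic gain algebra", {
  # gain = 1, phtx_effect = 0.5: EPSP restored (~100%), QC doubled (~200%)
  t1 <- simulation_truth(homeostatic_gain = c(wt = 1), phtx_effect = 0.5, seed = 6)
  cells <- gen_ephys_cohort(t1, 400)
  s <- summarize_genotype(cells, "wt")
  expect_lt(abs(s$pct_epsp - 100), 6)
  expect_lt(abs(s$pct_qc - 200), 10)
  expect_lt(abs(s$pct_mepsp - 50), 4)
  # gain = 0: QC unchanged, EPSP drops with the mEPSP
  t0 <- simulation_truth(homeostatic_gain = c(mut = 0), phtx_effect = 0.5, seed = 6)
  s0 <- summarize_genotype(gen_ephys_cohort(t0, 400), "mut")
  expect_lt(abs(s0$pct_qc - 100), 6)
  expect_lt(abs(s0$pct_epsp - 50), 4)
  expect_true(all(cells$mepsp_mv > 0) && all(cells$epsp_mv > 0))
  expect_error(gen_ephys_cohort(t1, 2), "n_cells_per_group")
  expect_error(simulation_truth(phtx_effect = 1.2), "phtx_effect")
})

test_that("homologue maps hit the requested coverage exactly", {
  genes <- sprintf("G%03d", 1:100)
  expect_identical(nrow(gen_homolog_map(genes, 1, 1)), 100L)
  expect_identical(nrow(gen_homolog_map(genes, 0, 1)), 0L)
  half <- gen_homolog_map(genes, 0.5, 1)
  expect_identical(nrow(half), 50L)
  expect_identical(anyDuplicated(half$human_gene), 0L)
  expect_identical(anyDuplicated(half$fly_gene), 0L)
})
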