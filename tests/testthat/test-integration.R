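# Integration stage: amyloid-FDR filter, peak-to-gene collapse, DEG
# overlap, primary cell-type assignment and direction counts.

test_that("filter_abeta_peaks applies a strict threshold and is idempotent", {
  pk <- make_peaks(fdr = c(0.01, 0.04, 0.2))
  kept <- filter_abeta_peaks(pk)
  expect_identical(kept$peak_id, pk$peak_id[1:2])
  # boundary: fdr exactly at the threshold is excluded
  pk2 <- make_peaks(fdr = c(0.05, 0.0499999, 0.9))
  expect_identical(filter_abeta_peaks(pk2)$peak_id, "pk02")
  expect_identical(filter_abeta_peaks(kept), kept)
  expect_identical(nrow(filter_abeta_peaks(make_peaks(fdr = rep(0.9, 3)))), 0L)
})

test_that("peaks_to_genes collapses multi-peak genes by minimum FDR", {
  pk <- make_peaks(gene = c("A", "A", "B"), fdr = c(0.03, 0.01, 0.02),
                   coef = c(0.5, -0.9, 1))
  gm <- peaks_to_genes(pk)
  expect_identical(gm$gene_symbol, c("A", "B"))
  expect_identical(gm$coef_abeta[gm$gene_symbol == "A"], -0.9)  # fdr 0.01 wins
  expect_identical(gm$n_peaks, c(2L, 1L))
  # FDR tie: larger |coef| wins; full tie: file order
  pk2 <- make_peaks(gene = c("A", "A"), fdr = c(0.01, 0.01), coef = c(0.2, -0.8))
  expect_identical(peaks_to_genes(pk2)$coef_abeta, -0.8)
  pk3 <- make_peaks(gene = c("A", "A"), fdr = c(0.01, 0.01), coef = c(0.3, -0.3))
  expect_identical(peaks_to_genes(pk3)$coef_abeta, 0.3)
  # duplicate-free input passes through at the same size
  pk4 <- make_peaks()
  expect_identical(nrow(peaks_to_genes(pk4)), nrow(pk4))
})

test_that("overlap_with_degs yields one record per matching (gene, cell type)", {
  gm <- peaks_to_genes(make_peaks(gene = c("A", "B", "C")))
  degs <- make_degs(gene = c("A", "A", "Z"), ct = c("Ex", "Oli", "In"),
                    log2fc = c(0.1, -0.5, -1))
  rec <- overlap_with_degs(gm, degs)
  expect_identical(nrow(rec), 2L)
  expect_setequal(rec$cell_type, c("Ex", "Oli"))
  expect_identical(rec$coef_abeta, rep(gm$coef_abeta[gm$gene_symbol == "A"], 2))
  # no shared genes -> empty
  none <- overlap_with_degs(gm, make_degs(gene = c("X", "Y", "Z")))
  expect_identical(nrow(none), 0L)
})

test_that("primary assignment picks the largest |log2fc| with fixed-order tie-break", {
  rec <- make_records(gene = c("g1", "g1", "g2"),
                      ct = c("Ex", "Oli", "Mic"),
                      coef = c(1, 1, -1), log2fc = c(0.1, -0.5, 0.2))
  out <- assign_primary_cell_type(rec)
  expect_identical(out$cell_type[out$is_primary_assignment & out$gene_symbol == "g1"],
                   "Oli")
  expect_true(out$is_primary_assignment[out$gene_symbol == "g2"])
  # exact tie |+0.3| vs |-0.3|: Ex precedes Oli in the fixed order
  tie <- make_records(gene = c("g", "g"), ct = c("Oli", "Ex"),
                      coef = c(1, 1), log2fc = c(-0.3, 0.3))
  out2 <- assign_primary_cell_type(tie)
  expect_identical(out2$cell_type[out2$is_primary_assignment], "Ex")
})

test_that("primary assignment is invariant under row permutation", {
  truth <- simulation_truth(seed = 5)
  pd <- gen_peak_deg_tables(truth, 400)
  rec <- overlap_with_degs(peaks_to_genes(filter_abeta_peaks(pd$peaks)), pd$degs)
  a <- assign_primary_cell_type(rec)
  perm <- with_seed(1, sample.int(nrow(rec)))
  b <- assign_primary_cell_type(rec[perm, , drop = FALSE])
  key <- function(d) {
    d <- d[order(d$gene_symbol, d$cell_type), , drop = FALSE]
    paste(d$gene_symbol, d$cell_type, d$is_primary_assignment)
  }
  expect_identical(key(a), key(b))
  # exactly one primary flag per gene
  expect_true(all(tapply(a$is_primary_assignment, a$gene_symbol, sum) == 1L))
})

test_that("direction counts classify signs and treat zero as directionless", {
  rec <- make_records(gene = c("a", "b", "c"), ct = rep("Ex", 3),
                      coef = c(1, 1, 1), log2fc = c(-1, -2, 1))
  ct <- direction_counts(rec)
  ex <- ct[ct$cell_type == "Ex", ]
  expect_identical(ex$n_total, 3L)
  expect_equal(ex$pct_down, 100 * 2 / 3, tolerance = 1e-12)
  # zero log2fc: counted in n_total, in neither direction
  rec0 <- make_records(gene = "z", ct = "Oli", coef = 1, log2fc = 0)
  ct0 <- direction_counts(rec0)
  oli <- ct0[ct0$cell_type == "Oli", ]
  expect_identical(c(oli$n_total, oli$n_up, oli$n_down), c(1L, 0L, 0L))
  expect_identical(nrow(direction_counts(rec[0, ])), 0L)
})

test_that("per-cell-type totals sum to the number of integrated records", {
  truth <- simulation_truth(seed = 21)
  pd <- gen_peak_deg_tables(truth, 800)
  res <- integrate_peaks_degs(pd$peaks, pd$degs)
  expect_identical(sum(res$counts$n_total), nrow(res$records))
})
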