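# Cross-species synaptic enrichment: gene selection, top-N ranking,
# bootstrap percentile and expression correlations.

test_that("synaptic gene selection is a case-insensitive substring union", {
  go <- make_go(c("synaptic vesicle cycle", "myelination", "Synaptic membrane"),
                list(c("A", "B"), c("C"), c("B", "D")))
  expect_setequal(select_synaptic_genes(go), c("A", "B", "D"))
  expect_setequal(select_synaptic_genes(go, "SYNAPTIC"), c("A", "B", "D"))
  expect_warning(none <- select_synaptic_genes(go, "ribosome"), "no GO term")
  expect_identical(none, character(0))
})

test_that("top-N ranking is deterministic with alphabetical tie-breaks", {
  expr <- make_expr("Ast", c("g1", "g2", "g3", "g4", "g5"),
                    c(5, 9, 7, 1, 3))
  expect_identical(top_expressed_genes(expr, "Ast", expr$gene_symbol, 3),
                   c("g2", "g3", "g1"))
  # tie at the boundary: alphabetical winner
  expr2 <- make_expr("Ast", c("zz", "aa", "mm"), c(4, 4, 9))
  expect_identical(top_expressed_genes(expr2, "Ast", expr2$gene_symbol, 2),
                   c("mm", "aa"))
  expect_warning(all3 <- top_expressed_genes(expr2, "Ast", expr2$gene_symbol, 10),
                 "only 3")
  expect_identical(length(all3), 3L)
})

test_that("one-to-many homologue relations resolve by confidence then name", {
  hm <- data.frame(human_gene = c("A", "A", "B", "B"),
                   fly_gene = c("fly2", "fly1", "flyB", "flyA"),
                   confidence = c(0.9, 0.7, 0.8, 0.8),
                   stringsAsFactors = FALSE)
  out <- resolve_homologs(hm)
  expect_identical(out$fly_gene[out$human_gene == "A"], "fly2")  # higher conf
  expect_identical(out$fly_gene[out$human_gene == "B"], "flyA")  # alphabetical
})

test_that("enrichment percentile is maximal for the top-expressed target set", {
  genes <- sprintf("f%03d", 1:200)
  expr <- make_expr("perineurial_glia", genes, c(rep(50, 10), runif(190, 0.1, 5)),
                    frac = 0.9)
  res <- enrichment_percentile(genes[1:10], expr, n_boot = 500, seed = 3)
  expect_equal(res$percentile, 100)
  expect_identical(res$n_target, 10L)
  # identical across runs with the same seed
  res2 <- enrichment_percentile(genes[1:10], expr, n_boot = 500, seed = 3)
  expect_identical(res$percentile, res2$percentile)
  # errors: universe not larger than target, target outside universe
  expect_error(enrichment_percentile(genes, expr), "larger than")
  expect_error(enrichment_percentile("nope", expr), "subset")
})

test_that("enrichment percentile is monotone under uniform target scaling", {
  set.seed(11)
  genes <- sprintf("f%03d", 1:300)
  base_expr <- runif(300, 0.5, 10)
  percs <- vapply(c(1, 2, 5), function(scale) {
    e <- base_expr
    e[1:15] <- e[1:15] * scale
    expr <- make_expr("perineurial_glia", genes, e, frac = 0.9)
    enrichment_percentile(genes[1:15], expr, n_boot = 2000, seed = 5)$percentile
  }, numeric(1))
  expect_true(all(diff(percs) >= 0))
})

test_that("null enrichment percentiles are roughly uniform across seeds", {
  truth <- simulation_truth(enrichment_factor = 1, n_fly_genes = 400)
  targets <- sprintf("FBg%04d", 1:20)   # arbitrary members of the background
  percs <- vapply(1:120, function(s) {
    tr <- simulation_truth(enrichment_factor = 1, n_fly_genes = 400, seed = s)
    expr <- gen_fly_expression(tr, targets)
    enrichment_percentile(targets, expr, n_boot = 400, seed = s)$percentile
  }, numeric(1))
  expect_gt(mean(percs), 38)
  expect_lt(mean(percs), 62)
})

test_that("cross-species correlation handles monotone and undersized inputs", {
  hm <- data.frame(human_gene = sprintf("h%02d", 1:10),
                   fly_gene = sprintf("f%02d", 1:10),
                   confidence = 1, stringsAsFactors = FALSE)
  h_expr <- make_expr("Oli", hm$human_gene, 1:10)
  f_expr <- make_expr("perineurial_glia", hm$fly_gene, exp(1:10 / 3), frac = 0.5)
  out <- xspecies_expression_cor(hm$human_gene, h_expr, f_expr, hm, "Oli")
  expect_equal(out$spearman_r, 1, tolerance = 1e-12)
  f_rev <- make_expr("perineurial_glia", hm$fly_gene, rev(1:10), frac = 0.5)
  out_rev <- xspecies_expression_cor(hm$human_gene, h_expr, f_rev, hm, "Oli")
  expect_equal(out_rev$spearman_r, -1, tolerance = 1e-12)
  expect_error(
    xspecies_expression_cor(hm$human_gene[1:2], h_expr, f_expr, hm, "Oli"),
    "fewer than 3")
})

test_that("the full cross-species analysis reports enrichment per human cell type", {
  truth <- simulation_truth(seed = 23, n_fly_genes = 300, enrichment_factor = 8)
  bundle <- simulate_bundle(truth, n_genes = 300, n_cells_per_group = 4)
  xs <- xspecies_enrichment(bundle$human_expr, bundle$fly_expr, bundle$homologs,
                            bundle$go, n_top = 10, n_boot = 300, seed = 23)
  expect_setequal(xs$enrichment$human_cell_type, CELL_TYPES)
  expect_true(all(xs$enrichment$percentile >= 80, na.rm = TRUE))
  expect_true(all(xs$enrichment$n_mapped <= xs$enrichment$n_top))
  expect_setequal(unique(xs$correlations$metric),
                  c("mean_expr", "frac_expressing"))
})
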