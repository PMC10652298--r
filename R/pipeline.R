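# End-to-end pipeline: optional simulation of a full input bundle, then
# integration -> concordance -> cross-species enrichment -> quantal PHP,
# with all stage outputs written as TSV, a machine-readable JSON summary
# and a plain-text run log. A single config (R list or YAML file) drives
# every stage; identical config + seed gives a byte-identical summary.

ANNOT_COLS <- c("genotype", "human_gene", "abs_log2fc", "abs_coef_abeta")

#' Read / write per-genotype dysregulation annotations
#'
#' The quantal stage correlates PHP metrics with the magnitude of each
#' genotype's human-gene dysregulation; this table carries that link:
#' `genotype`, `human_gene`, `abs_log2fc`, `abs_coef_abeta`.
#'
#' @param path TSV path.
#' @return Validated data.frame.
#' @export
read_genotype_annotations <- function(path) {
  raw <- read_raw_tsv(path, ANNOT_COLS, "genotype annotations")
  tb <- "genotype annotations"
  df <- data.frame(
    genotype = raw$genotype,
    human_gene = raw$human_gene,
    abs_log2fc = parse_num(raw$abs_log2fc, tb, "abs_log2fc"),
    abs_coef_abeta = parse_num(raw$abs_coef_abeta, tb, "abs_coef_abeta"),
    stringsAsFactors = FALSE
  )
  check_nonempty(df$genotype, tb, "genotype")
  df
}

#' @rdname read_genotype_annotations
#' @param x Annotation data.frame.
#' @export
write_genotype_annotations <- function(x, path) {
  write_tsv_checked(x, path, ANNOT_COLS)
}

#' Simulate and write a complete input bundle
#'
#' Materialises every pipeline input with known ground truth: peak and DEG
#' tables, human and fly expression summaries, a homologue map, GO
#' annotations, an electrophysiology cohort, and per-genotype dysregulation
#' annotations, plus a `truth.json` sidecar recording the generating
#' parameters. The fly enrichment targets are the homologues of the top
#' "synaptic" genes per human cell type, so the bundle carries genuine
#' enrichment signal at `truth$enrichment_factor`.
#'
#' @param truth A [simulation_truth()] object.
#' @param n_genes Genes in the simulated universe.
#' @param n_cells_per_group Cells per (genotype, PhTX) group.
#' @param dir Output directory (created if needed); when `NULL` nothing is
#'   written and the tables are only returned.
#' @param n_top Top-N used to pick enrichment target genes.
#' @return Named list of tables (`peaks`, `degs`, `human_expr`, `fly_expr`,
#'   `homologs`, `go`, `ephys`, `annotations`), invisibly when writing.
#' @export
simulate_bundle <- function(truth, n_genes = 1200, n_cells_per_group = 12,
                            dir = NULL, n_top = 20) {
  stopifnot(inherits(truth, "simulation_truth"))
  pd <- gen_peak_deg_tables(truth, n_genes)
  genes <- unique(pd$peaks$gene_symbol)
  human_expr <- gen_human_expression(truth, genes)
  go <- gen_go_annotations(truth, genes)
  homologs <- gen_homolog_map(genes, truth$homolog_coverage, truth$seed)
  synaptic <- select_synaptic_genes(go)
  top_union <- unique(unlist(lapply(CELL_TYPES, function(ct)
    suppressWarnings(top_expressed_genes(human_expr, ct, synaptic, n_top)))))
  map <- resolve_homologs(homologs)
  targets <- map$fly_gene[match(top_union, map$human_gene)]
  targets <- targets[!is.na(targets)]
  fly_expr <- gen_fly_expression(truth, targets)
  ephys <- gen_ephys_cohort(truth, n_cells_per_group)

  # annotate mutant genotypes with glial integrated records (largest
  # |log2fc| among glial primary assignments, like the screen's gene list)
  integ <- integrate_peaks_degs(pd$peaks, pd$degs)
  rec <- integ$records
  glial <- rec[rec$is_primary_assignment &
                 rec$cell_type %in% c("Ast", "Oli", "OPC", "Mic"), , drop = FALSE]
  glial <- glial[order(-abs(glial$log2fc)), , drop = FALSE]
  mutants <- setdiff(names(truth$homeostatic_gain), "wt")
  n_ann <- min(length(mutants), nrow(glial))
  annotations <- data.frame(
    genotype = mutants[seq_len(n_ann)],
    human_gene = glial$gene_symbol[seq_len(n_ann)],
    abs_log2fc = abs(glial$log2fc[seq_len(n_ann)]),
    abs_coef_abeta = abs(glial$coef_abeta[seq_len(n_ann)]),
    stringsAsFactors = FALSE
  )

  bundle <- list(peaks = pd$peaks, degs = pd$degs, human_expr = human_expr,
                 fly_expr = fly_expr, homologs = homologs, go = go,
                 ephys = ephys, annotations = annotations)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_peaks(bundle$peaks, file.path(dir, "peaks.tsv"))
    write_degs(bundle$degs, file.path(dir, "degs.tsv"))
    write_expression_summary(bundle$human_expr, file.path(dir, "human_expr.tsv"))
    write_expression_summary(bundle$fly_expr, file.path(dir, "fly_expr.tsv"))
    write_homolog_map(bundle$homologs, file.path(dir, "homologs.tsv"))
    write_go_annotations(bundle$go, file.path(dir, "go.tsv"))
    write_ephys_cells(bundle$ephys, file.path(dir, "ephys.tsv"))
    write_genotype_annotations(bundle$annotations,
                               file.path(dir, "annotations.tsv"))
    truth_plain <- unclass(truth)
    jsonlite::write_json(truth_plain, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(bundle))
  }
  bundle
}

#' Default demonstration configuration
#'
#' A small simulated run (1200 genes, 12 cells per ephys group, 500
#' bootstrap draws) that completes in well under a minute on one CPU.
#'
#' @param out_dir Output directory for the run.
#' @param seed Integer seed.
#' @return Config list accepted by [run_pipeline()].
#' @export
demo_config <- function(out_dir = file.path(tempdir(), "gliaPHP-demo"),
                        seed = 42L) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(n_genes = 1200, n_cells_per_group = 12),
    options = list(fdr_max = 0.05, binom_method = "minlik", top_n = 20,
                   n_boot = 500, expressed_min_frac = 0.01,
                   enrichment_statistic = "mean_expr",
                   t_var_equal = FALSE, alpha = 0.05,
                   qc_method = "per_cell")
  )
}

normalize_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path", call. = FALSE)
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (!has_sim && !has_inp)
    stop("configuration error: config must name either a simulation block or input paths",
         call. = FALSE)
  if (has_sim && has_inp)
    stop("configuration error: config names both a simulation block and input paths",
         call. = FALSE)
  if (is.null(config$out_dir))
    stop("configuration error: out_dir is required", call. = FALSE)
  defaults <- demo_config()$options
  config$options <- utils::modifyList(defaults, config$options %||% list())
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> integrate -> concordance -> cross-species
#' -> quantal, writing every stage output as TSV under `out_dir`, a
#' machine-readable `summary.json`, and a `run_log.txt` recording seeds and
#' every statistical option in effect. The run is deterministic: an
#' identical config and seed reproduce a byte-identical summary. In input
#' mode the cross-species and quantal stages run only when their tables are
#' provided; missing blocks are recorded as absent in the summary.
#'
#' @param config Config list or path to a YAML file. Required: `out_dir`
#'   and exactly one of `simulate` (fields `n_genes`,
#'   `n_cells_per_group`, optional `truth` overrides for
#'   [simulation_truth()]) or `inputs` (named paths: `peaks`, `degs`, and
#'   optionally `homologs`, `human_expr`, `fly_expr`, `go`, `ephys`,
#'   `annotations`). Optional: `seed`, `options` (`fdr_max`,
#'   `binom_method`, `top_n`, `n_boot`, `expressed_min_frac`,
#'   `enrichment_statistic`, `t_var_equal`, `alpha`, `qc_method`).
#' @return The summary list, invisibly; side effect: files under `out_dir`.
#' @export
run_pipeline <- function(config) {
  config <- normalize_config(config)
  opts <- config$options
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("gliaPHP pipeline run",
                 sprintf("seed: %d", config$seed),
                 sprintf("package version: %s",
                         as.character(utils::packageVersion("gliaPHP"))),
                 "options in effect:",
                 sprintf("  %s: %s", names(opts),
                         vapply(opts, function(v) paste(format(v), collapse = ","),
                                character(1))))
  summary <- list(seed = config$seed, options = opts)

  # ---- stage 0: obtain inputs ---------------------------------------------
  if (!is.null(config$simulate)) {
    truth_args <- config$simulate$truth %||% list()
    truth_args$seed <- config$seed
    truth <- do.call(simulation_truth, truth_args)
    bundle <- simulate_bundle(truth,
                              n_genes = config$simulate$n_genes %||% 1200,
                              n_cells_per_group = config$simulate$n_cells_per_group %||% 12,
                              dir = file.path(out_dir, "inputs"),
                              n_top = opts$top_n)
    log_lines <- c(log_lines, "stage simulate: wrote input bundle")
    summary$simulate <- list(n_genes = config$simulate$n_genes %||% 1200,
                             n_cells_per_group = config$simulate$n_cells_per_group %||% 12,
                             rho = truth$rho,
                             same_sign_frac = truth$same_sign_frac)
  } else {
    bundle <- read_input_bundle(config$inputs[setdiff(names(config$inputs),
                                                      "annotations")])
    if (!is.null(config$inputs$annotations))
      bundle$annotations <- read_genotype_annotations(config$inputs$annotations)
    log_lines <- c(log_lines, "stage load: read input tables")
  }
  if (is.null(bundle$peaks) || is.null(bundle$degs))
    stop("pipeline requires peak and DEG tables", call. = FALSE)

  # ---- stage 1-2: integration ---------------------------------------------
  integ <- integrate_peaks_degs(bundle$peaks, bundle$degs, opts$fdr_max)
  write_integrated_records(integ$records,
                           file.path(out_dir, "integrated_records.tsv"))
  write_tsv_checked(integ$counts, file.path(out_dir, "direction_counts.tsv"),
                    names(integ$counts))
  summary$integration <- list(
    n_peaks = nrow(bundle$peaks),
    n_abeta_peaks = nrow(filter_abeta_peaks(bundle$peaks, opts$fdr_max)),
    n_abeta_genes = nrow(integ$gene_map),
    n_records = nrow(integ$records),
    n_distinct_genes = length(unique(integ$records$gene_symbol)),
    direction_counts = integ$counts
  )
  log_lines <- c(log_lines, sprintf(
    "stage integrate: %d peaks -> %d amyloid genes -> %d records (%d genes)",
    nrow(bundle$peaks), nrow(integ$gene_map), nrow(integ$records),
    summary$integration$n_distinct_genes))

  # ---- stage 3: concordance -----------------------------------------------
  conc <- concordance_by_scope(integ$records, binom_method = opts$binom_method)
  write_tsv_checked(as.data.frame(conc), file.path(out_dir, "concordance.tsv"),
                    names(conc))
  scatter <- integ$records[c("coef_abeta", "log2fc", "same_sign", "cell_type")]
  write_tsv_checked(scatter, file.path(out_dir, "scatter_data.tsv"),
                    names(scatter))
  summary$concordance <- as.data.frame(conc)
  log_lines <- c(log_lines, sprintf(
    "stage concordance: %d/%d same sign (%.1f%%), all-scope pearson r = %.3f",
    conc$k_same_sign[1], conc$n[1], conc$pct_same_sign[1], conc$pearson_r[1]))

  # ---- stage 4: cross-species ---------------------------------------------
  if (!is.null(bundle$human_expr) && !is.null(bundle$fly_expr) &&
      !is.null(bundle$homologs) && !is.null(bundle$go)) {
    xs <- xspecies_enrichment(bundle$human_expr, bundle$fly_expr,
                              bundle$homologs, bundle$go,
                              n_top = opts$top_n, n_boot = opts$n_boot,
                              seed = config$seed,
                              expressed_min_frac = opts$expressed_min_frac,
                              statistic = opts$enrichment_statistic)
    write_tsv_checked(xs$enrichment, file.path(out_dir, "enrichment.tsv"),
                      names(xs$enrichment))
    write_tsv_checked(xs$correlations,
                      file.path(out_dir, "xspecies_correlations.tsv"),
                      names(xs$correlations))
    summary$xspecies <- xs
    log_lines <- c(log_lines, sprintf(
      "stage xspecies: enrichment percentiles %s",
      paste(sprintf("%s=%.1f", xs$enrichment$human_cell_type,
                    xs$enrichment$percentile), collapse = ", ")))
  } else {
    summary$xspecies <- NULL
    log_lines <- c(log_lines, "stage xspecies: skipped (inputs not provided)")
  }

  # ---- stage 5: quantal PHP -----------------------------------------------
  if (!is.null(bundle$ephys)) {
    phps <- summarize_genotypes(bundle$ephys, alpha = opts$alpha,
                                var_equal = opts$t_var_equal,
                                qc_method = opts$qc_method)
    write_tsv_checked(as.data.frame(phps),
                      file.path(out_dir, "genotype_summary.tsv"), names(phps))
    summary$quantal <- list(genotypes = as.data.frame(phps))
    if (!is.null(bundle$annotations) && nrow(bundle$annotations) >= 3) {
      cors <- tryCatch(php_dysregulation_cor(phps, bundle$annotations),
                       error = function(e) NULL)
      if (!is.null(cors)) {
        write_tsv_checked(cors, file.path(out_dir, "php_correlations.tsv"),
                          names(cors))
        summary$quantal$correlations <- cors
      }
    }
    log_lines <- c(log_lines, sprintf(
      "stage quantal: %d genotypes, PHP intact in %d",
      nrow(phps), sum(phps$php_intact, na.rm = TRUE)))
  } else {
    summary$quantal <- NULL
    log_lines <- c(log_lines, "stage quantal: skipped (no ephys input)")
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "columns", null = "null")
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(summary)
}

#' Render a human-readable report from a pipeline summary
#'
#' Formats the per-cell-type direction counts, the concordance table, the
#' cross-species enrichment table and the per-genotype PHP percentage table
#' with p-values from a summary produced by [run_pipeline()]. Missing
#' blocks are flagged rather than fatal.
#'
#' @param summary Summary list, or path to a `summary.json`.
#' @return Character vector of report lines, invisibly; the report is also
#'   printed.
#' @export
render_report <- function(summary) {
  if (is.character(summary) && length(summary) == 1L)
    summary <- jsonlite::read_json(summary, simplifyVector = TRUE)
  lines <- c("=== Integrative H3K9ac / transcriptome / PHP report ===", "")
  fmt_tab <- function(df) {
    out <- utils::capture.output(print(format(as.data.frame(df), digits = 4),
                                       row.names = FALSE))
    paste0("  ", out)
  }
  if (!is.null(summary$integration)) {
    it <- summary$integration
    lines <- c(lines,
               sprintf("Integration: %s peaks; %s amyloid-associated genes; %s gene x cell-type records (%s distinct genes)",
                       it$n_peaks, it$n_abeta_genes, it$n_records, it$n_distinct_genes),
               "Per-cell-type direction counts:", fmt_tab(it$direction_counts), "")
  } else lines <- c(lines, "[missing block: integration]", "")
  if (!is.null(summary$concordance)) {
    lines <- c(lines, "Concordance (same sign vs 50%, Pearson r):",
               fmt_tab(summary$concordance), "")
  } else lines <- c(lines, "[missing block: concordance]", "")
  if (!is.null(summary$xspecies)) {
    lines <- c(lines, "Cross-species synaptic enrichment (percentile vs random expressed genes):",
               fmt_tab(summary$xspecies$enrichment),
               "Cross-species Spearman correlations:",
               fmt_tab(summary$xspecies$correlations), "")
  } else lines <- c(lines, "[missing block: xspecies]", "")
  if (!is.null(summary$quantal)) {
    lines <- c(lines, "Quantal PHP metrics (% of -PhTX baseline; t-test on quantal content):",
               fmt_tab(summary$quantal$genotypes))
    if (!is.null(summary$quantal$correlations))
      lines <- c(lines, "PHP impairment vs dysregulation magnitude:",
                 fmt_tab(summary$quantal$correlations))
    lines <- c(lines, "")
  } else lines <- c(lines, "[missing block: quantal]", "")
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
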