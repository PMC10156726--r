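#' Pipeline configuration
#'
#' Bundles file paths and the analysis constants. Every stochastic stage of
#' [run_pipeline()] consumes a stage-specific child seed derived from
#' `seed` via [child_seed()], so stages are independently reproducible.
#'
#' @param vcf,gff,qtl_bed,sweep_tsv,go_tsv,keyword_tsv,motif_tsv,pop_map_tsv
#'   input paths (as written by [emit_fixture_set()]).
#' @param outdir output directory for stage TSVs.
#' @param window_bp summary-statistic window (default 50 kb).
#' @param scan_snps SNPs per eigen-scan window (default 50).
#' @param n_perm_scan,n_perm_qtl permutation counts (defaults 10000, 5000).
#' @param alpha eigen-scan significance level (default 0.01).
#' @param flank DMC flank, bp (default 10 kb).
#' @param thin_bp thinning interval for intergenic coancestry sites
#'   (default 50 kb; reduce for short synthetic chromosomes).
#' @param ne,rec_rate,mu effective size, recombination rate (Morgans/bp) and
#'   mutation rate defaults (1e5, 1.16e-8, 3.5e-9).
#' @param max_dmc_genes cap on the number of candidate genes sent to the
#'   composite-likelihood fit (keeps desk-scale runs fast).
#' @param seed master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, gff, qtl_bed, sweep_tsv, go_tsv,
                            keyword_tsv, motif_tsv, pop_map_tsv,
                            outdir = tempfile("repadapt_out"),
                            window_bp = 50000, scan_snps = 50,
                            n_perm_scan = 10000, n_perm_qtl = 5000,
                            alpha = 0.01, flank = 10000, thin_bp = 50000,
                            ne = 1e5, rec_rate = 1.16e-8, mu = 3.5e-9,
                            max_dmc_genes = 10, seed = 1L) {
  cfg <- as.list(environment())
  for (f in c("vcf", "gff", "qtl_bed", "sweep_tsv", "go_tsv", "keyword_tsv",
              "motif_tsv", "pop_map_tsv"))
    if (!file.exists(cfg[[f]])) stop("missing input file for ", f, ": ", cfg[[f]])
  stopifnot(window_bp > 0, scan_snps > 1, n_perm_scan > 0, n_perm_qtl > 0,
            alpha > 0, alpha < 1, flank >= 0, ne > 0, rec_rate > 0, mu > 0)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline on one input set
#'
#' Stages: site filters -> windowed statistics -> sweep intersections ->
#' eigen reuse scan -> composite-likelihood mode fits on candidate genes ->
#' enrichment / motif-loss / gene-length statistics -> summary report.
#' A stage failure aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `pipeline_report` with one element per stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  pop_map <- stage("inputs", read_tsv(config$pop_map_tsv))
  geno <- stage("read_vcf", read_vcf_genotypes(config$vcf, pop_map))
  filt <- stage("filters", apply_site_filters(geno))
  panel <- stage("panel", genotypes_to_panel(filt$geno))
  annotation <- stage("annotation", read_gff(config$gff))

  wstats <- stage("windowed_stats", windowed_stats(panel, config$window_bp))
  write_tsv(wstats, file.path(config$outdir, "windowed_stats.tsv"))

  sweeps <- stage("sweep_table", read_sweep_table(config$sweep_tsv))
  caves <- panel$pops$pop[panel$pops$ecotype == "cave"]
  surfs <- panel$pops$pop[panel$pops$ecotype == "surface"]
  cand <- stage("overlapping_sweeps",
                overlapping_sweeps(sweeps, annotation, caves, surfs))

  design <- panel_design(panel)
  scan <- stage("reuse_scan",
                reuse_scan(panel, design, n_snps = config$scan_snps,
                           n_perm = config$n_perm_scan, alpha = config$alpha,
                           seed = child_seed(config$seed, "reuse_scan")))
  write_tsv(as.data.frame(scan), file.path(config$outdir, "reuse_scan.tsv"))
  scan_genes <- stage("windows_to_genes", windows_to_genes(scan, annotation))

  dmc_genes <- utils::head(cand, config$max_dmc_genes)
  Fhat <- stage("neutral_F",
                estimate_neutral_F(panel,
                                   neutral_sites(panel, annotation,
                                                 config$thin_bp)))
  fits <- stage("dmc", lapply(dmc_genes, function(g)
    dmc_fit(panel, g, annotation, Fhat, caves,
            model_set = c("independent", "standing", "migration",
                          "mixed_migration", "mixed_standing"),
            flank = config$flank, ne = config$ne,
            rec_rate = config$rec_rate)))
  fits <- Filter(Negate(is.null), fits)
  modes <- if (length(fits)) summarize_mode_assignments(fits) else NULL

  qtl <- stage("qtl", read_qtl_bed(config$qtl_bed))
  qtl_test <- stage("qtl_permutation",
                    qtl_overlap_permutation(cand, annotation, qtl,
                                            n_perm = config$n_perm_qtl,
                                            seed = child_seed(config$seed, "qtl")))
  go <- stage("go", read_tsv(config$go_tsv))
  keywords <- stage("keywords", read_tsv(config$keyword_tsv))
  categories <- stage("categories",
                      assign_phenotype_categories(go, keywords, cand))
  motif <- stage("motifs", read_tsv(config$motif_tsv))
  losses <- stage("tfbs", tfbs_loss_filter(motif, surfs, caves))
  lengths <- if (length(cand) >= 2 && length(cand) < nrow(annotation$genes) - 1)
    tryCatch(length_comparison(cand, annotation, "transcript_length"),
             error = function(e) {
               warning("gene-length comparison unavailable: ",
                       conditionMessage(e))
               NULL
             })
  else NULL

  report <- list(
    filter_report = filt$report,
    panel = panel,
    windowed_stats = wstats,
    candidates = cand,
    scan = scan,
    scan_genes = scan_genes,
    neutral_F = Fhat,
    dmc_fits = fits,
    mode_summary = modes,
    qtl_test = qtl_test,
    categories = categories,
    tfbs_losses = losses,
    length_test = lengths,
    seed = config$seed
  )
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat("  sites in -> retained: ", x$filter_report$input, " -> ",
      x$filter_report$retained, "\n", sep = "")
  cat("  candidate genes (overlapping sweeps): ", length(x$candidates), "\n",
      sep = "")
  cat("  scan windows: ", nrow(x$scan), " (",
      sum(x$scan$classification != "none"), " significant)\n", sep = "")
  if (!is.null(x$mode_summary)) {
    cat("  mode assignments:\n")
    print(x$mode_summary)
  }
  cat("  QTL overlap: obs ", x$qtl_test$observed, ", Z ",
      round(x$qtl_test$z, 2), ", p ", signif(x$qtl_test$p, 3), "\n", sep = "")
  cat("  TFBS losses: ", nrow(x$tfbs_losses), "\n", sep = "")
  invisible(x)
}
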