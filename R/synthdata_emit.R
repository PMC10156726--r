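# Fixture emission: every downstream input format, derived from the
# simulated panel and the truth records. TSV dialect throughout: tab
# separated, header row, '.' for missing.

write_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) df2[[j]][is.na(df2[[j]])] <- "."
  utils::write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, na.strings = ".", stringsAsFactors = FALSE)
}

#' Write a panel to a plain-text VCF 4.2 file
#'
#' One diploid sample column per sampled individual; genotypes are drawn
#' binomially from the population frequency (two Bernoulli draws per
#' individual), so reading the file back reproduces the panel frequencies up
#' to binomial sampling error.
#'
#' @param panel an [af_panel()].
#' @param path output file.
#' @param seed seed for the genotype draws.
#' @return A data.frame mapping sample names to populations (the `pop_map`
#'   that [read_vcf_to_panel()] expects), invisibly.
#' @export
write_panel_vcf <- function(panel, path, seed = 1L) {
  set.seed(seed)
  S <- ncol(panel$freq)
  n_dip <- panel$n[, 1] %/% 2L
  samples <- unlist(lapply(seq_len(nrow(panel$pops)), function(j)
    sprintf("%s_s%02d", panel$pops$pop[j], seq_len(n_dip[j]))))
  pop_of <- rep(panel$pops$pop, n_dip)

  gts <- matrix("", nrow = S, ncol = length(samples))
  col <- 0L
  for (j in seq_len(nrow(panel$pops))) {
    for (k in seq_len(n_dip[j])) {
      col <- col + 1L
      a1 <- stats::rbinom(S, 1L, panel$freq[j, ])
      a2 <- stats::rbinom(S, 1L, panel$freq[j, ])
      gts[, col] <- paste0(a1, "/", a2)
    }
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(panel$sites$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(panel$sites$chrom, panel$sites$pos,
                sprintf("snp%d", seq_len(S)), "A", "T", ".", "PASS", ".",
                "GT", apply(gts, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(data.frame(sample = samples, pop = pop_of,
                       stringsAsFactors = FALSE))
}

#' Derive a sweep-call table from truth records
#'
#' Deterministic stand-in for a sweep classifier's per-population 5-kb window
#' calls: inside a selected region, windows whose centre retains the sweeping
#' haplotype with probability > 0.9 are `hard`, other swept windows `soft`;
#' windows adjacent to a hard/soft window are `hardLinked`/`softLinked`; all
#' remaining windows are `neutral`.
#'
#' @param truths list of [scenario_truth()] records.
#' @param config the [demography_config()].
#' @param pops character vector of all population labels.
#' @param window_bp window size (default 5000).
#' @return data.frame with columns `chrom`, `start`, `end`, `pop`, `class`
#'   (`start`/`end` 0-based half-open).
#' @export
truth_sweep_calls <- function(truths, config, pops, window_bp = 5000) {
  n_win <- ceiling(config$chrom_length / window_bp)
  starts <- (seq_len(n_win) - 1L) * window_bp
  out <- do.call(rbind, lapply(pops, function(p) {
    cls <- rep("neutral", n_win)
    for (tr in truths) {
      if (tr$scenario == "neutral" || !(p %in% tr$selected_pops)) next
      centre <- starts + window_bp / 2
      inside <- centre >= tr$region_start & centre < tr$region_end
      y <- sweep_retention(abs(centre - tr$selected_position), tr$s,
                           config$ancestral_ne, config$recombination_rate)
      swept <- inside & y > 0.1
      cls[swept & y > 0.9] <- "hard"
      cls[swept & y <= 0.9] <- "soft"
      sw <- which(swept)
      if (length(sw)) {
        for (i in sw) {
          lab <- if (cls[i] == "hard") "hardLinked" else "softLinked"
          for (nb in c(i - 1L, i + 1L))
            if (nb >= 1 && nb <= n_win && cls[nb] == "neutral") cls[nb] <- lab
        }
      }
    }
    data.frame(chrom = "chr1", start = starts,
               end = pmin(starts + window_bp, config$chrom_length),
               pop = p, class = cls, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

default_keyword_table <- function() {
  data.frame(
    category = c("pigmentation", "pigmentation", "vision", "vision", "vision",
                 "metabolism", "metabolism", "sleep", "sleep",
                 "mechanosensory", "mechanosensory"),
    keyword = c("pigment", "melanosome", "eye", "retina", "photoreceptor",
                "lipid", "insulin", "sleep", "circadian",
                "neuromast", "lateral line"),
    stringsAsFactors = FALSE
  )
}

go_vocabulary <- function() {
  c("melanosome transport", "pigment cell differentiation",
    "eye morphogenesis", "retina development", "photoreceptor maintenance",
    "lipid metabolic process", "response to insulin",
    "circadian sleep/wake cycle", "sleep homeostasis",
    "neuromast development", "lateral line nerve development",
    "DNA repair", "cilium assembly", "heart development")
}

#' Emit the full synthetic fixture set
#'
#' Writes every downstream input the pipeline consumes: VCF, GFF3 gene
#' models, QTL BED intervals, a truth-derived sweep-call table, a motif
#' presence table (with convergent losses implanted in swept genes), a GO
#' annotation table, the phenotype keyword table, and the truth TSV itself.
#' The generator's formulas are stand-ins for observational data; a README
#' written alongside the fixtures says so.
#'
#' @param panel an [af_panel()] (after any [implant_sweep()] calls).
#' @param truths list of [scenario_truth()] records.
#' @param config the [demography_config()].
#' @param outdir output directory (created if needed).
#' @param seed seed for the stochastic pieces (genotype draws, GO
#'   assignment, motif backgrounds).
#' @return Named list of written paths plus the sample-to-population map.
#' @export
emit_fixture_set <- function(panel, truths, config, outdir, seed = 1L) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  }
  paths <- list()
  pop_map <- write_panel_vcf(panel, file.path(outdir, "panel.vcf"), seed = seed)
  paths$vcf <- file.path(outdir, "panel.vcf")
  paths$pop_map <- file.path(outdir, "pop_map.tsv")
  write_tsv(cbind(pop_map,
                  ecotype = panel$pops$ecotype[match(pop_map$pop, panel$pops$pop)],
                  lineage = panel$pops$lineage[match(pop_map$pop, panel$pops$pop)]),
            paths$pop_map)

  models <- make_gene_models(config$chrom_length)
  paths$gff <- file.path(outdir, "genes.gff3")
  write_gff3(models, paths$gff)

  # 3 QTL intervals covering ~25% of the chromosome
  L <- config$chrom_length
  qtl <- data.frame(chrom = "chr1",
                    start = as.integer(c(0.05, 0.40, 0.75) * L),
                    end = as.integer(c(0.05, 0.40, 0.75) * L + 0.085 * L))
  paths$qtl <- file.path(outdir, "qtl.bed")
  writeLines(paste(qtl$chrom, qtl$start, qtl$end,
                   sprintf("qtl%d", seq_len(nrow(qtl))), sep = "\t"),
             paths$qtl)

  sweeps <- truth_sweep_calls(truths, config, panel$pops$pop)
  paths$sweeps <- file.path(outdir, "sweep_calls.tsv")
  write_tsv(sweeps, paths$sweeps)

  set.seed(seed + 1L)
  vocab <- go_vocabulary()
  go <- do.call(rbind, lapply(models$genes$gene_id, function(g) {
    k <- sample(0:3, 1)
    if (k == 0) return(NULL)
    terms <- sample(vocab, k)
    data.frame(gene_id = g,
               go_id = sprintf("GO:%07d", match(terms, vocab)),
               go_name = terms, stringsAsFactors = FALSE)
  }))
  paths$go <- file.path(outdir, "go_terms.tsv")
  write_tsv(go, paths$go)

  paths$keywords <- file.path(outdir, "keywords.tsv")
  write_tsv(default_keyword_table(), paths$keywords)

  # motif presence: background presence 0.9 everywhere; genes inside a
  # cave-swept region lose motif_loss in every cave population
  cave_pops <- panel$pops$pop[panel$pops$ecotype == "cave"]
  swept_spans <- do.call(rbind, lapply(truths, function(tr) {
    if (tr$scenario == "neutral") return(NULL)
    data.frame(start = tr$region_start, end = tr$region_end)
  }))
  in_sweep <- rep(FALSE, nrow(models$genes))
  if (!is.null(swept_spans))
    for (i in seq_len(nrow(swept_spans)))
      in_sweep <- in_sweep | (models$genes$start < swept_spans$end[i] &
                                models$genes$end > swept_spans$start[i])
  n_dip <- panel$n[, 1] %/% 2L
  motifs <- c("motif_loss", "motif_bg1", "motif_bg2")
  motif_rows <- list()
  for (gi in seq_len(nrow(models$genes))) {
    for (fl in c("upstream", "downstream")) {
      for (m in motifs) {
        for (j in seq_len(nrow(panel$pops))) {
          p_pres <- 0.9
          if (m == "motif_loss" && in_sweep[gi] &&
              panel$pops$pop[j] %in% cave_pops) p_pres <- 0.05
          pres <- stats::rbinom(n_dip[j], 1, p_pres)
          motif_rows[[length(motif_rows) + 1L]] <- data.frame(
            gene_id = models$genes$gene_id[gi], flank = fl, motif = m,
            pop = panel$pops$pop[j],
            genome = sprintf("%s_s%02d", panel$pops$pop[j], seq_len(n_dip[j])),
            present = pres, stringsAsFactors = FALSE)
        }
      }
    }
  }
  paths$motifs <- file.path(outdir, "motif_presence.tsv")
  write_tsv(do.call(rbind, motif_rows), paths$motifs)

  truth_df <- do.call(rbind, lapply(truths, function(tr) data.frame(
    region_id = tr$region_id, scenario = tr$scenario,
    chrom = "chr1", region_start = tr$region_start, region_end = tr$region_end,
    selected_position = tr$selected_position,
    s = tr$s, t_standing = tr$t_standing, g = tr$g,
    source_pop = tr$source_pop,
    selected_pops = paste(tr$selected_pops, collapse = ","),
    seed = tr$seed, stringsAsFactors = FALSE)))
  paths$truth <- file.path(outdir, "truth.tsv")
  write_tsv(truth_df, paths$truth)

  writeLines(c(
    "Synthetic fixture set.",
    "All files here are generated by a parametric stand-in generator",
    "(Wright-Fisher diffusion drift plus deterministic sweep surgery), not by",
    "a coalescent or forward simulator, and not from any sequenced sample.",
    "Sweep calls, motif presence and GO annotations are fabricated from the",
    "truth records in truth.tsv."), file.path(outdir, "README.txt"))
  paths
}
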