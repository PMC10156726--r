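#' Simulate a full study panel with implanted regions of known mode
#'
#' Convenience builder used by the validation suite and the reproduction
#' script: tiles a chromosome into fixed-width regions, implants one
#' scenario per region, applies the finite-sample binomial step, and
#' returns everything downstream analyses need (panel, truth records, a
#' one-gene-per-region annotation, and the neutral-region site indices for
#' estimating the coancestry null).
#'
#' Modes per region:
#' * `neutral` - untouched;
#' * `independent` / `standing` / `migration` - one sweep across all cave
#'   populations via [implant_sweep()];
#' * `locus` - two sweeps at the same position, one per lineage, each
#'   sharing a haplotype only within its lineage (independent origins
#'   between lineages - the locus-reuse configuration).
#'
#' @param modes character vector, one mode per region, from
#'   `{neutral, independent, standing, migration, locus}`.
#' @param region_bp region width (default 50 kb; sweeps are confined to
#'   their region).
#' @param gene_bp width of the gene centred in each region (default 12 kb).
#' @param s selection coefficient for implanted sweeps (default 0.1).
#' @param t_standing standing time for standing-mode regions, generations
#'   (default 500).
#' @param snp_per_bp SNP density (default 1/150).
#' @param seed master seed; region surgeries use `seed + region index`.
#' @param ... further arguments to [demography_config()].
#' @return A list with `panel` (sampled frequencies), `truths`,
#'   `annotation` (a [gene_models()]; gene i sits in region i), `config`,
#'   `modes`, `neutral_idx` (thinned sites in neutral regions), and
#'   `region_centers`.
#' @export
simulate_study_panel <- function(modes, region_bp = 50000, gene_bp = 12000,
                                 s = 0.1, t_standing = 500,
                                 snp_per_bp = 1 / 150, seed = 1L, ...) {
  stopifnot(all(modes %in% c("neutral", "independent", "standing",
                             "migration", "locus")))
  n_reg <- length(modes)
  config <- demography_config(
    snp_count = round(n_reg * region_bp * snp_per_bp),
    chrom_length = n_reg * region_bp, seed = seed, ...)
  sim <- simulate_neutral_panel(config)
  panel <- sim$panel
  caves <- panel$pops$pop[panel$pops$ecotype == "cave"]
  lin_of <- panel$pops$lineage[match(caves, panel$pops$pop)]

  truths <- list()
  for (i in seq_len(n_reg)) {
    if (modes[i] == "neutral") next
    rs <- (i - 1) * region_bp
    ctr <- rs + region_bp / 2
    if (modes[i] == "locus") {
      for (l in unique(lin_of)) {
        grp <- caves[lin_of == l]
        tr <- scenario_truth(sprintf("r%04d_L%d", i, l), "migration", ctr,
                             rs, rs + region_bp, selected_pops = grp, s = s,
                             source_pop = grp[1],
                             seed = seed + 10000L * l + i)
        truths[[length(truths) + 1L]] <- tr
        panel <- implant_sweep(panel, tr, config)
      }
    } else {
      tr <- scenario_truth(sprintf("r%04d", i), modes[i], ctr, rs,
                           rs + region_bp, selected_pops = caves, s = s,
                           t_standing = if (modes[i] == "standing") t_standing else NA,
                           source_pop = if (modes[i] == "migration") caves[1] else NA,
                           seed = seed + i)
      truths[[length(truths) + 1L]] <- tr
      panel <- implant_sweep(panel, tr, config)
    }
  }
  panel <- sample_panel_freqs(panel, seed = seed + 90000L)

  starts <- as.integer((seq_len(n_reg) - 1) * region_bp +
                         region_bp / 2 - gene_bp / 2)
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n_reg)), chrom = "chr1",
    start = starts, end = as.integer(starts + gene_bp),
    strand = rep(c("+", "-"), length.out = n_reg),
    transcript_length = as.integer(0.6 * gene_bp),
    cds_length = as.integer(0.5 * gene_bp),
    exon_count = 3L, isoform_count = 1L, stringsAsFactors = FALSE)
  annotation <- gene_models(genes)

  pos <- panel$sites$pos
  in_neut <- rep(FALSE, length(pos))
  for (i in which(modes == "neutral"))
    in_neut <- in_neut | (pos > (i - 1) * region_bp & pos <= i * region_bp)
  neutral_idx <- which(in_neut)
  neutral_idx <- neutral_idx[!duplicated((pos[neutral_idx] - 1) %/% 1000)]

  list(panel = panel, truths = truths, annotation = annotation,
       config = config, modes = modes, neutral_idx = neutral_idx,
       region_centers = (seq_len(n_reg) - 1) * region_bp + region_bp / 2)
}
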