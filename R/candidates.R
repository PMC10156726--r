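# Sweep-intersection logic and downstream statistics on candidate gene sets.

sweep_classes_positive <- c("hard", "soft")
sweep_classes_negative <- c("neutral", "hardLinked", "softLinked")

# per-gene window classes for one population: list of class vectors
gene_window_classes <- function(sweeps, models, pop) {
  sw <- sweeps[sweeps$pop == pop, , drop = FALSE]
  gr_win <- GenomicRanges::GRanges(sw$chrom,
                                   IRanges::IRanges(sw$start + 1L, sw$end))
  gr_gene <- GenomicRanges::GRanges(
    models$genes$chrom,
    IRanges::IRanges(models$genes$start + 1L, models$genes$end))
  hits <- GenomicRanges::findOverlaps(gr_gene, gr_win)
  out <- rep(list(character()), nrow(models$genes))
  sp <- split(sw$class[S4Vectors::subjectHits(hits)],
              S4Vectors::queryHits(hits))
  for (nm in names(sp)) out[[as.integer(nm)]] <- sp[[nm]]
  names(out) <- models$genes$gene_id
  out
}

#' Cave-adaptive genes for one cave/surface pair
#'
#' A gene qualifies iff at least one window overlapping its span (introns
#' included) carries a hard or soft sweep call in the cave population AND
#' every window overlapping its span in the same-lineage surface population
#' is neutral or linked. Skipped windows are evidence-neutral.
#'
#' @param sweeps sweep-call table (`chrom start end pop class`).
#' @param models a [gene_models()] object.
#' @param cave_pop,surface_pop population labels (must belong to the same
#'   lineage when `lineages` is supplied).
#' @param lineages optional named vector mapping populations to lineages,
#'   used to reject cross-lineage pairings.
#' @return Character vector of gene ids.
#' @export
cave_adaptive_genes <- function(sweeps, models, cave_pop, surface_pop,
                                lineages = NULL) {
  if (!is.null(lineages) &&
      lineages[[cave_pop]] != lineages[[surface_pop]])
    stop("cave and surface population must belong to the same lineage")
  cave_cls <- gene_window_classes(sweeps, models, cave_pop)
  surf_cls <- gene_window_classes(sweeps, models, surface_pop)
  ok <- vapply(seq_along(cave_cls), function(i) {
    cc <- setdiff(cave_cls[[i]], "skipped")
    sc <- setdiff(surf_cls[[i]], "skipped")
    any(cc %in% sweep_classes_positive) &&
      (length(sc) == 0 || all(sc %in% sweep_classes_negative))
  }, logical(1))
  models$genes$gene_id[ok]
}

#' Genes with overlapping sweeps across several cave populations
#'
#' The cave-adaptive condition must hold simultaneously for every listed
#' cave population against every listed surface population.
#'
#' @param sweeps sweep-call table.
#' @param models a [gene_models()] object.
#' @param cave_pops,surface_pops population label vectors.
#' @return Character vector of gene ids (a subset of every constituent
#'   pairwise [cave_adaptive_genes()] result by construction).
#' @export
overlapping_sweeps <- function(sweeps, models, cave_pops, surface_pops) {
  sets <- list()
  for (cv in cave_pops) for (sf in surface_pops)
    sets[[paste(cv, sf)]] <- cave_adaptive_genes(sweeps, models, cv, sf)
  Reduce(intersect, sets)
}

#' Assign phenotype categories by GO keyword
#'
#' A gene joins every category one of whose keywords substring-matches
#' (case-insensitively) any of its GO term names; multi-assignment allowed.
#'
#' @param go data.frame with `gene_id`, `go_name` (one row per annotation).
#' @param keywords data.frame with `category`, `keyword`.
#' @param genes optional gene universe to restrict to.
#' @return data.frame with `gene_id`, `category`.
#' @export
assign_phenotype_categories <- function(go, keywords, genes = NULL) {
  if (!nrow(keywords)) stop("empty keyword table")
  if (!is.null(genes)) go <- go[go$gene_id %in% genes, , drop = FALSE]
  rows <- list()
  for (ci in seq_len(nrow(keywords))) {
    hit <- grepl(keywords$keyword[ci], go$go_name, ignore.case = TRUE,
                 fixed = FALSE)
    if (any(hit))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = go$gene_id[hit], category = keywords$category[ci],
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), category = character()))
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Permutation test for gene-set overlap with QTL intervals
#'
#' Observed = number of set genes whose span overlaps any QTL interval;
#' the null redraws equal-size gene sets without replacement from the
#' universe. `p = (1 + #[null >= obs]) / (n_perm + 1)`. A degenerate null
#' (sd = 0) reports `Z = NA`.
#'
#' @param gene_set character vector (subset of the universe).
#' @param models a [gene_models()] object defining the gene universe.
#' @param qtl data.frame `chrom`, `start`, `end` (0-based half-open).
#' @param n_perm permutations (default 5000).
#' @param seed integer seed.
#' @return A list with `observed`, `null_mean`, `null_sd`, `z`, `p`.
#' @export
qtl_overlap_permutation <- function(gene_set, models, qtl, n_perm = 5000,
                                    seed = 1L) {
  universe <- models$genes$gene_id
  if (length(gene_set) > length(universe))
    stop("gene set larger than the universe")
  if (!all(gene_set %in% universe))
    stop("gene set must be a subset of the annotation universe")
  overlaps_qtl <- rep(FALSE, nrow(models$genes))
  if (nrow(qtl)) {
    gr_gene <- GenomicRanges::GRanges(
      models$genes$chrom,
      IRanges::IRanges(models$genes$start + 1L, models$genes$end))
    gr_qtl <- GenomicRanges::GRanges(qtl$chrom,
                                     IRanges::IRanges(qtl$start + 1L, qtl$end))
    overlaps_qtl <- GenomicRanges::countOverlaps(gr_gene, gr_qtl) > 0
  }
  names(overlaps_qtl) <- universe
  obs <- sum(overlaps_qtl[gene_set])
  if (!nrow(qtl) || !any(overlaps_qtl))
    return(list(observed = 0L, null_mean = 0, null_sd = 0, z = NA_real_, p = 1))
  set.seed(seed)
  k <- length(gene_set)
  null <- vapply(seq_len(n_perm), function(i)
    sum(overlaps_qtl[sample.int(length(universe), k)]), numeric(1))
  nsd <- stats::sd(null)
  # degenerate null (e.g. QTL covering every gene): the permutation
  # distribution carries no information; report the resolution limit
  p <- if (nsd > 0) (1 + sum(null >= obs)) / (n_perm + 1)
  else 1 / (n_perm + 1)
  list(observed = obs, null_mean = mean(null), null_sd = nsd,
       z = if (nsd > 0) (obs - mean(null)) / nsd else NA_real_,
       p = p)
}

#' Fisher enrichment of a gene set against a background
#'
#' Exact hypergeometric two-sided test on the 2x2 table
#' `{k_set, n_set - k_set; k_bg - k_set, (n_bg - n_set) - (k_bg - k_set)}`.
#'
#' @param k_set annotated genes in the set.
#' @param n_set set size.
#' @param k_bg annotated genes in the background (including the set).
#' @param n_bg background size (including the set).
#' @return A list with `odds_ratio`, `p`, `table`.
#' @export
fisher_enrichment <- function(k_set, n_set, k_bg, n_bg) {
  tab <- matrix(c(k_set, n_set - k_set,
                  k_bg - k_set, (n_bg - n_set) - (k_bg - k_set)),
                nrow = 2, byrow = TRUE)
  if (any(tab < 0)) stop("negative cell: set must be a subset of background")
  res <- stats::fisher.test(tab)
  list(odds_ratio = unname(res$estimate), p = res$p.value, table = tab)
}

#' Welch comparison of gene-structure fields
#'
#' Two-sided Welch unequal-variance t-test (fractional degrees of freedom)
#' of a gene-structure field between a candidate set and the rest of the
#' genome; sign convention candidate minus genome.
#'
#' @param candidate_genes character vector of gene ids.
#' @param models a [gene_models()] object.
#' @param field one of `transcript_length`, `cds_length`, `exon_count`,
#'   `isoform_count`.
#' @param background `"rest"` (default, genome minus candidates) or `"all"`.
#' @return A list with `t`, `df`, `p`, `mean_candidate`, `mean_background`.
#' @export
length_comparison <- function(candidate_genes, models,
                              field = c("transcript_length", "cds_length",
                                        "exon_count", "isoform_count"),
                              background = c("rest", "all")) {
  field <- match.arg(field)
  background <- match.arg(background)
  is_cand <- models$genes$gene_id %in% candidate_genes
  x <- models$genes[[field]][is_cand]
  y <- models$genes[[field]][if (background == "rest") !is_cand else TRUE]
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 genes per group")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("zero variance in both groups")
  res <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, mean_candidate = mean(x), mean_background = mean(y))
}

#' Kruskal-Wallis comparison of sweep ages across phenotype categories
#'
#' @param ages numeric vector of sweep/variant ages (generations).
#' @param categories parallel category labels (>= 2 categories with >= 2
#'   ages each).
#' @return A list with `h`, `df`, `p`.
#' @export
sweep_age_by_category <- function(ages, categories) {
  categories <- as.factor(categories)
  if (nlevels(droplevels(categories)) < 2)
    stop("need at least two categories")
  res <- stats::kruskal.test(ages, categories)
  list(h = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Convergent transcription-factor-binding-site losses
#'
#' A (gene, flank, motif) loss is reported iff the presence fraction is
#' >= 0.80 in every surface population AND strictly < 0.20 in every cave
#' population.
#'
#' @param motif_table data.frame with columns `gene_id`, `flank`, `motif`,
#'   `pop`, `genome`, `present` (0/1).
#' @param surface_pops,cave_pops population labels.
#' @return data.frame of losses with per-population presence fractions in a
#'   `fractions` attribute-free long format: columns `gene_id`, `flank`,
#'   `motif`.
#' @export
tfbs_loss_filter <- function(motif_table, surface_pops, cave_pops) {
  stopifnot(length(surface_pops) >= 1, length(cave_pops) >= 1)
  mt <- motif_table[motif_table$pop %in% c(surface_pops, cave_pops), ]
  agg <- stats::aggregate(present ~ gene_id + flank + motif + pop, mt, mean)
  ncount <- stats::aggregate(present ~ gene_id + flank + motif + pop, mt, length)
  if (any(ncount$present == 0)) stop("population with zero genomes")
  key <- function(d) paste(d$gene_id, d$flank, d$motif, sep = "\r")
  ukeys <- unique(key(agg))
  losses <- vapply(ukeys, function(kk) {
    sub <- agg[key(agg) == kk, ]
    surf <- sub$present[sub$pop %in% surface_pops]
    cave <- sub$present[sub$pop %in% cave_pops]
    length(surf) == length(surface_pops) && length(cave) == length(cave_pops) &&
      all(surf >= 0.80) && all(cave < 0.20)
  }, logical(1))
  parts <- do.call(rbind, strsplit(ukeys[losses], "\r"))
  if (is.null(parts))
    return(data.frame(gene_id = character(), flank = character(),
                      motif = character()))
  out <- data.frame(gene_id = parts[, 1], flank = parts[, 2],
                    motif = parts[, 3], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize per-population candidate-gene counts
#'
#' @param gene_sets named list of per-population gene-id vectors.
#' @param annotation_total total annotated genes (for the fraction).
#' @return A list with `counts`, `mean_count` (nearest integer), and
#'   `mean_percent` (nearest whole percent, half away from zero).
#' @export
summarize_category_counts <- function(gene_sets, annotation_total) {
  counts <- vapply(gene_sets, length, integer(1))
  m <- mean(counts)
  pct <- 100 * m / annotation_total
  list(counts = counts,
       mean_count = sign(m) * floor(abs(m) + 0.5),
       mean_percent = sign(pct) * floor(abs(pct) + 0.5))
}
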