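#' Genotype table
#'
#' Per-sample diploid calls at candidate sites, the substrate of the site
#' filter cascade.
#'
#' @param chrom,pos site coordinates (pos 1-based bp).
#' @param n_alleles total number of alleles observed at the site (REF+ALT).
#' @param gt sites x samples integer matrix of alternate-allele copy counts
#'   (0, 1, 2, or `NA` for missing).
#' @param samples data.frame with columns `sample`, `pop` (and optionally
#'   `ecotype`, `lineage`).
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(chrom, pos, n_alleles, gt, samples) {
  gt <- as.matrix(gt)
  stopifnot(length(chrom) == nrow(gt), length(pos) == nrow(gt),
            length(n_alleles) == nrow(gt), nrow(samples) == ncol(gt),
            all(c("sample", "pop") %in% names(samples)))
  structure(list(chrom = chrom, pos = pos, n_alleles = as.integer(n_alleles),
                 gt = gt, samples = samples), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("<genotype_table> ", nrow(x$gt), " sites x ", ncol(x$gt), " samples (",
      length(unique(x$samples$pop)), " populations)\n", sep = "")
  invisible(x)
}

#' Site filter cascade
#'
#' Applies, in order: (1) retain biallelic sites only; (2) remove sites with
#' more than `max_missing` missing data within any single population;
#' (3) remove variants with pooled minor allele frequency below `min_maf`;
#' (4) remove sites where every called sample in some population is
#' heterozygous (collapsed-paralog signature). Each site is counted against
#' the first rule that removes it.
#'
#' @param geno a [genotype_table()].
#' @param max_missing maximum tolerated per-population missingness
#'   (default 0.2).
#' @param min_maf minimum pooled minor-allele frequency (default 0.01).
#' @return A list with `geno` (the filtered table) and `report`, a list with
#'   `input`, `removed` (named vector over the four rules), and `retained`;
#'   `sum(removed) + retained == input` always.
#' @export
apply_site_filters <- function(geno, max_missing = 0.2, min_maf = 0.01) {
  stopifnot(inherits(geno, "genotype_table"))
  n <- nrow(geno$gt)
  if (n == 0) stop("empty genotype table")
  pops <- unique(geno$samples$pop)
  pop_cols <- lapply(pops, function(p) which(geno$samples$pop == p))

  removed <- c(non_biallelic = 0L, missingness = 0L, maf = 0L,
               all_heterozygous = 0L)
  keep <- rep(TRUE, n)

  fail_bi <- geno$n_alleles != 2L
  removed["non_biallelic"] <- sum(fail_bi)
  keep[fail_bi] <- FALSE

  miss_any <- rep(FALSE, n)
  for (cols in pop_cols) {
    frac <- rowMeans(is.na(geno$gt[, cols, drop = FALSE]))
    miss_any <- miss_any | frac > max_missing
  }
  fail_miss <- keep & miss_any
  removed["missingness"] <- sum(fail_miss)
  keep[fail_miss] <- FALSE

  called <- rowSums(!is.na(geno$gt))
  p <- rowSums(geno$gt, na.rm = TRUE) / (2 * pmax(called, 1))
  maf <- pmin(p, 1 - p)
  fail_maf <- keep & (called == 0 | maf < min_maf)
  removed["maf"] <- sum(fail_maf)
  keep[fail_maf] <- FALSE

  allhet_any <- rep(FALSE, n)
  for (cols in pop_cols) {
    sub <- geno$gt[, cols, drop = FALSE]
    n_called <- rowSums(!is.na(sub))
    n_het <- rowSums(sub == 1L, na.rm = TRUE)
    allhet_any <- allhet_any | (n_called > 0 & n_het == n_called)
  }
  fail_het <- keep & allhet_any
  removed["all_heterozygous"] <- sum(fail_het)
  keep[fail_het] <- FALSE

  out <- genotype_table(geno$chrom[keep], geno$pos[keep],
                        geno$n_alleles[keep],
                        geno$gt[keep, , drop = FALSE], geno$samples)
  list(geno = out,
       report = list(input = n, removed = removed, retained = sum(keep)))
}

#' Collapse a genotype table to population allele frequencies
#'
#' @param geno a [genotype_table()] whose `samples` carry `ecotype` and
#'   `lineage` columns.
#' @return An [af_panel()]. Frequencies are set to `NA` where a population
#'   has fewer than one called sample at a site.
#' @export
genotypes_to_panel <- function(geno) {
  stopifnot(all(c("ecotype", "lineage") %in% names(geno$samples)))
  pops <- unique(geno$samples[, c("pop", "ecotype", "lineage")])
  rownames(pops) <- NULL
  freq <- matrix(NA_real_, nrow(pops), nrow(geno$gt))
  nmat <- matrix(0L, nrow(pops), nrow(geno$gt))
  for (j in seq_len(nrow(pops))) {
    cols <- which(geno$samples$pop == pops$pop[j])
    sub <- geno$gt[, cols, drop = FALSE]
    called <- rowSums(!is.na(sub))
    nmat[j, ] <- 2L * called
    f <- rowSums(sub, na.rm = TRUE) / (2 * pmax(called, 1))
    f[called == 0] <- NA_real_
    freq[j, ] <- f
  }
  freq[nmat < 2] <- NA_real_
  nmat[nmat < 2] <- 2L  # placeholder under NA frequencies
  af_panel(freq, nmat, pops,
           data.frame(chrom = geno$chrom, pos = geno$pos,
                      stringsAsFactors = FALSE))
}
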