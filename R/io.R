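#' Read a VCF into a genotype table
#'
#' Parses diploid GT calls via `vcfR`. Records with more than one ALT allele
#' are kept in the table with their allele count so that the biallelic filter
#' can count them; `./.` calls become `NA`.
#'
#' @param path VCF 4.2 file.
#' @param pop_map data.frame with columns `sample`, `pop` and optionally
#'   `ecotype`, `lineage`; every VCF sample must appear.
#' @return A [genotype_table()].
#' @export
read_vcf_genotypes <- function(path, pop_map) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt_chr <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt_chr)
  missing_map <- setdiff(samples, pop_map$sample)
  if (length(missing_map))
    stop("samples absent from pop_map: ", paste(missing_map, collapse = ", "))
  pop_map <- pop_map[match(samples, pop_map$sample), , drop = FALSE]

  count_alt <- function(x) {
    out <- rep(NA_integer_, length(x))
    ok <- !is.na(x) & !grepl("\\.", x)
    parts <- strsplit(x[ok], "[/|]")
    out[ok] <- vapply(parts, function(a) sum(a != "0"), integer(1))
    out
  }
  gt <- apply(gt_chr, 2, count_alt)
  if (is.null(dim(gt))) gt <- matrix(gt, ncol = length(samples))
  alt <- v@fix[, "ALT"]
  n_alleles <- 1L + vapply(strsplit(ifelse(is.na(alt), "", alt), ","),
                           function(a) sum(nzchar(a)), integer(1))
  genotype_table(v@fix[, "CHROM"], as.integer(v@fix[, "POS"]), n_alleles,
                 gt, pop_map)
}

#' Read a VCF straight into an allele-frequency panel
#'
#' Convenience composition of [read_vcf_genotypes()] and
#' [genotypes_to_panel()]; multiallelic records are dropped (with a count
#' reported as an attribute). No other filtering is applied.
#'
#' @inheritParams read_vcf_genotypes
#' @return An [af_panel()] with attribute `n_multiallelic_dropped`.
#' @export
read_vcf_to_panel <- function(path, pop_map) {
  geno <- read_vcf_genotypes(path, pop_map)
  multi <- geno$n_alleles != 2L
  keep <- which(!multi)
  geno2 <- genotype_table(geno$chrom[keep], geno$pos[keep],
                          geno$n_alleles[keep],
                          geno$gt[keep, , drop = FALSE], geno$samples)
  panel <- genotypes_to_panel(geno2)
  attr(panel, "n_multiallelic_dropped") <- sum(multi)
  panel
}

#' Read a QTL BED file
#'
#' @param path BED file (0-based half-open).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open,
#'   i.e. BED coordinates kept as-is internally).
#' @export
read_qtl_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read a per-population sweep-call table
#'
#' @param path TSV with header `chrom start end pop class`.
#' @return data.frame; classes validated against the closed vocabulary
#'   `neutral/hard/soft/hardLinked/softLinked/skipped`.
#' @export
read_sweep_table <- function(path) {
  df <- read_tsv(path)
  need <- c("chrom", "start", "end", "pop", "class")
  if (!all(need %in% names(df)))
    stop("sweep table must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$class),
                 c("neutral", "hard", "soft", "hardLinked", "softLinked", "skipped"))
  if (length(bad)) stop("unknown sweep classes: ", paste(bad, collapse = ", "))
  df
}

#' Derive a deterministic child seed for a named pipeline stage
#'
#' Stages of [run_pipeline()] each consume `child_seed(master, stage)` so
#' that any stage can be reproduced in isolation.
#'
#' @param master master integer seed.
#' @param stage stage name.
#' @return An integer seed in `[0, 2^31)`.
#' @export
child_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483647)
}
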