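#' Gene model set
#'
#' Internal representation of an annotation: a `genes` table plus a
#' `features` table of sub-features (CDS, five_prime_UTR, three_prime_UTR,
#' exon). All coordinates are 0-based half-open; conversion to/from the
#' 1-based inclusive GFF3 convention happens only at the I/O boundary.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `transcript_length`, `cds_length`, `exon_count`,
#'   `isoform_count`.
#' @param features data.frame with columns `gene_id`, `type`, `start`, `end`.
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(genes, features = NULL) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  if (any(genes$end <= genes$start)) stop("gene spans must have positive length")
  if (is.null(features))
    features <- data.frame(gene_id = character(), type = character(),
                           start = integer(), end = integer())
  structure(list(genes = genes, features = features), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("<gene_models> ", nrow(x$genes), " genes, ", nrow(x$features),
      " sub-features\n", sep = "")
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS/UTR features via `rtracklayer`. Transcript
#' length is the summed exon length of the longest transcript, CDS length the
#' summed CDS length (introns excluded), and coordinates are converted to the
#' internal 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @return A [gene_models()] object.
#' @export
read_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$start0 <- df$start - 1L
  df$end0 <- df$end
  first_chr <- function(x) vapply(x, function(v) as.character(v)[1], character(1))
  df$parent <- if ("Parent" %in% names(df)) {
    vapply(df$Parent, function(v) if (length(v)) as.character(v)[1] else NA_character_,
           character(1))
  } else NA_character_
  df$id <- if ("ID" %in% names(df)) as.character(df$ID) else NA_character_

  g <- df[df$type == "gene", ]
  tx <- df[df$type %in% c("mRNA", "transcript"), ]
  tx$gene <- tx$parent
  sub <- df[df$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR"), ]
  sub$tx <- sub$parent
  sub$gene <- tx$gene[match(sub$tx, tx$id)]
  # clamp children to the parent gene span (tolerate slightly sloppy files)
  gi <- match(sub$gene, g$id)
  clamped <- !is.na(gi) & (sub$start0 < g$start0[gi] | sub$end0 > g$end0[gi])
  if (any(clamped)) {
    warning(sum(clamped), " sub-feature(s) extended past their gene span; clamped")
    sub$start0 <- pmax(sub$start0, g$start0[gi])
    sub$end0 <- pmin(sub$end0, g$end0[gi])
  }

  per_gene <- lapply(seq_len(nrow(g)), function(i) {
    gid <- g$id[i]
    txs <- tx[!is.na(tx$gene) & tx$gene == gid, ]
    iso <- nrow(txs)
    tlen <- 0L; ecnt <- 0L
    if (iso > 0) {
      lens <- vapply(txs$id, function(t) {
        sum(sub$end0[sub$type == "exon" & sub$tx == t] -
              sub$start0[sub$type == "exon" & sub$tx == t])
      }, numeric(1))
      best <- which.max(lens)
      tlen <- lens[best]
      ecnt <- sum(sub$type == "exon" & sub$tx == txs$id[best])
    }
    clen <- sum(sub$end0[sub$type == "CDS" & !is.na(sub$gene) & sub$gene == gid] -
                  sub$start0[sub$type == "CDS" & !is.na(sub$gene) & sub$gene == gid])
    data.frame(gene_id = gid, chrom = as.character(g$seqnames[i]),
               start = g$start0[i], end = g$end0[i],
               strand = as.character(g$strand[i]),
               transcript_length = tlen, cds_length = clen,
               exon_count = ecnt, isoform_count = iso,
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, per_gene)
  rownames(genes) <- NULL
  feats <- sub[!is.na(sub$gene),
               c("gene", "type", "start0", "end0")]
  names(feats) <- c("gene_id", "type", "start", "end")
  feats$type <- as.character(feats$type)
  gene_models(genes, feats)
}

#' Write gene models to GFF3
#'
#' @param models a [gene_models()] object (as produced by
#'   [make_gene_models()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  g <- models$genes
  f <- models$features
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    lines <- c(lines, paste(g$chrom[i], "synth", "gene", g$start[i] + 1L,
                            g$end[i], ".", g$strand[i], ".",
                            sprintf("ID=%s", gid), sep = "\t"))
    tid <- paste0(gid, ".t1")
    lines <- c(lines, paste(g$chrom[i], "synth", "mRNA", g$start[i] + 1L,
                            g$end[i], ".", g$strand[i], ".",
                            sprintf("ID=%s;Parent=%s", tid, gid), sep = "\t"))
    fi <- f[f$gene_id == gid, ]
    for (j in seq_len(nrow(fi))) {
      lines <- c(lines, paste(g$chrom[i], "synth", fi$type[j],
                              fi$start[j] + 1L, fi$end[j], ".", g$strand[i],
                              if (fi$type[j] == "CDS") "0" else ".",
                              sprintf("ID=%s.%s%d;Parent=%s", gid,
                                      tolower(substr(fi$type[j], 1, 3)), j, tid),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Tile synthetic gene models over a chromosome
#'
#' 10-kb genes every 50 kb, each with one transcript of three 2-kb exons
#' (500 bp UTRs at the outer ends), alternating strand. Gives downstream
#' interval logic (window-to-gene mapping, QTL permutation, site
#' classification) a non-degenerate substrate.
#'
#' @param chrom_length chromosome length, bp.
#' @param chrom chromosome name.
#' @param gene_length,spacing gene length and tiling period, bp.
#' @return A [gene_models()] object.
#' @export
make_gene_models <- function(chrom_length, chrom = "chr1",
                             gene_length = 10000, spacing = 50000) {
  starts <- seq(10000, chrom_length - gene_length - 1, by = spacing)
  genes <- data.frame(
    gene_id = sprintf("gene%03d", seq_along(starts)),
    chrom = chrom, start = as.integer(starts),
    end = as.integer(starts + gene_length),
    strand = rep(c("+", "-"), length.out = length(starts)),
    transcript_length = 6000L, cds_length = 5000L,
    exon_count = 3L, isoform_count = 1L,
    stringsAsFactors = FALSE
  )
  feats <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    s <- genes$start[i]
    ex <- data.frame(type = "exon",
                     start = s + c(0L, 4000L, 8000L),
                     end = s + c(2000L, 6000L, 10000L))
    plus <- genes$strand[i] == "+"
    utr5 <- data.frame(type = "five_prime_UTR",
                       start = if (plus) s else s + 9500L,
                       end = if (plus) s + 500L else s + 10000L)
    utr3 <- data.frame(type = "three_prime_UTR",
                       start = if (plus) s + 9500L else s,
                       end = if (plus) s + 10000L else s + 500L)
    cds <- data.frame(type = "CDS",
                      start = s + c(500L, 4000L, 8000L),
                      end = s + c(2000L, 6000L, 9500L))
    out <- rbind(ex, cds, utr5, utr3)
    out$gene_id <- genes$gene_id[i]
    out[, c("gene_id", "type", "start", "end")]
  }))
  gene_models(genes, feats)
}

#' Sites overlapping each gene span
#'
#' @param panel an [af_panel()].
#' @param models a [gene_models()] object.
#' @return A list of integer site-index vectors, one per gene.
#' @export
sites_in_genes <- function(panel, models) {
  gr_sites <- GenomicRanges::GRanges(
    panel$sites$chrom, IRanges::IRanges(panel$sites$pos, width = 1))
  gr_genes <- GenomicRanges::GRanges(
    models$genes$chrom,
    IRanges::IRanges(models$genes$start + 1L, models$genes$end))
  hits <- GenomicRanges::findOverlaps(gr_genes, gr_sites)
  out <- rep(list(integer()), nrow(models$genes))
  sp <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  for (nm in names(sp)) out[[as.integer(nm)]] <- sp[[nm]]
  names(out) <- models$genes$gene_id
  out
}
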