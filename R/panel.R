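#' Allele-frequency panel
#'
#' The central data container: alternate-allele frequencies and haploid
#' observation counts for a set of populations at a set of biallelic SNP
#' sites. Every scan and model in the package consumes this object.
#'
#' @param freq numeric matrix, populations x sites, values in `[0, 1]` or `NA`
#'   for missing.
#' @param n integer matrix of the same shape: haploid observation counts
#'   (must be >= 2 wherever the frequency is defined).
#' @param pops data.frame with columns `pop`, `ecotype` (`"cave"` or
#'   `"surface"`) and `lineage` (integer); row order matches `freq` rows.
#' @param sites data.frame with columns `chrom` and `pos` (1-based bp,
#'   strictly increasing within each chromosome).
#'
#' @return An object of class `af_panel`: a list with elements `freq`, `n`,
#'   `pops`, `sites`.
#' @export
af_panel <- function(freq, n, pops, sites) {
  freq <- as.matrix(freq)
  n <- as.matrix(n)
  stopifnot(
    is.data.frame(pops), all(c("pop", "ecotype", "lineage") %in% names(pops)),
    is.data.frame(sites), all(c("chrom", "pos") %in% names(sites)),
    nrow(freq) == nrow(pops), ncol(freq) == nrow(sites),
    all(dim(freq) == dim(n))
  )
  if (!all(pops$ecotype %in% c("cave", "surface")))
    stop("pops$ecotype must be 'cave' or 'surface'")
  bad <- freq[!is.na(freq)]
  if (length(bad) && (min(bad) < 0 || max(bad) > 1))
    stop("frequencies must lie in [0, 1]")
  if (any(!is.na(freq) & (is.na(n) | n < 2)))
    stop("defined frequencies require a haploid count n >= 2")
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  rownames(freq) <- rownames(n) <- pops$pop
  structure(list(freq = freq, n = n, pops = pops, sites = sites),
            class = "af_panel")
}

#' @export
print.af_panel <- function(x, ...) {
  cat("<af_panel> ", nrow(x$freq), " populations x ", ncol(x$freq), " sites\n",
      sep = "")
  cat("  populations:",
      paste0(x$pops$pop, " (", x$pops$ecotype, ", L", x$pops$lineage, ")",
             collapse = ", "), "\n")
  cat("  chromosomes:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  cat("  missing frequencies:", sum(is.na(x$freq)), "\n")
  invisible(x)
}

#' @export
dim.af_panel <- function(x) dim(x$freq)

#' Subset a panel by site index
#'
#' @param panel an [af_panel()].
#' @param idx integer vector of site (column) indices, in increasing order.
#' @return An `af_panel` restricted to the selected sites.
#' @export
panel_subset <- function(panel, idx) {
  af_panel(panel$freq[, idx, drop = FALSE], panel$n[, idx, drop = FALSE],
           panel$pops, panel$sites[idx, , drop = FALSE])
}

pop_index <- function(panel, pop) {
  i <- match(pop, panel$pops$pop)
  if (anyNA(i)) stop("unknown population(s): ", paste(pop[is.na(i)], collapse = ", "))
  i
}
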