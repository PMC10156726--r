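#' Replicate surface-cave design
#'
#' @param surface,cave,lineage parallel vectors describing each replicate
#'   surface->cave comparison and the cave lineage it belongs to.
#' @return data.frame of class `replicate_design`.
#' @export
replicate_design <- function(surface, cave, lineage) {
  stopifnot(length(surface) == length(cave), length(cave) == length(lineage),
            length(cave) >= 2)
  structure(data.frame(surface = surface, cave = cave, lineage = lineage,
                       stringsAsFactors = FALSE),
            class = c("replicate_design", "data.frame"))
}

#' Default design for a panel: each cave against its lineage's surface
#'
#' @param panel an [af_panel()].
#' @return A [replicate_design()].
#' @export
panel_design <- function(panel) {
  caves <- panel$pops[panel$pops$ecotype == "cave", ]
  surf <- panel$pops[panel$pops$ecotype == "surface", ]
  replicate_design(surf$pop[match(caves$lineage, surf$lineage)],
                   caves$pop, caves$lineage)
}

#' Allele-frequency-change matrix for one window
#'
#' Row j is the cave-minus-surface frequency difference of replicate j over
#' the window's SNPs, normalised to unit Euclidean length. Rows with zero
#' norm are dropped and the window flagged unusable.
#'
#' @param panel an [af_panel()].
#' @param design a [replicate_design()].
#' @param window_sites integer site indices (typically 50).
#' @return Matrix with attribute `dropped` (indices of zero-norm replicates);
#'   a zero-row matrix with attribute `unusable = TRUE` if any frequency is
#'   missing or all rows are zero.
#' @export
af_change_matrix <- function(panel, design, window_sites) {
  si <- pop_index(panel, design$surface)
  ci <- pop_index(panel, design$cave)
  unusable <- function() {
    out <- matrix(numeric(0), 0, length(window_sites))
    attr(out, "unusable") <- TRUE
    out
  }
  A <- panel$freq[ci, window_sites, drop = FALSE] -
    panel$freq[si, window_sites, drop = FALSE]
  if (anyNA(A)) return(unusable())
  nr <- sqrt(rowSums(A^2))
  dropped <- which(nr == 0)
  if (length(dropped) == nrow(A)) return(unusable())
  keep <- setdiff(seq_len(nrow(A)), dropped)
  A <- A[keep, , drop = FALSE] / nr[keep]
  rownames(A) <- design$cave[keep]
  attr(A, "dropped") <- dropped
  A
}

#' Eigen decomposition of a window's replicate-by-replicate similarity
#'
#' Decomposes `C = A A^T` (k x k for k unit-norm rows). Eigenvalues sum to k
#' (trace conservation). Sign convention: each eigenvector is flipped so its
#' largest-magnitude loading is positive.
#'
#' @param A matrix from [af_change_matrix()].
#' @return A list with `values` (descending) and `vectors` (k x k loadings,
#'   columns are eigenvectors).
#' @export
eigen_scan <- function(A) {
  C <- A %*% t(A)
  e <- eigen(C, symmetric = TRUE)
  for (j in seq_len(ncol(e$vectors))) {
    i <- which.max(abs(e$vectors[, j]))
    if (e$vectors[i, j] < 0) e$vectors[, j] <- -e$vectors[, j]
  }
  rownames(e$vectors) <- rownames(A)
  list(values = e$values, vectors = e$vectors)
}

#' Permutation null for the eigen scan
#'
#' Each permutation assembles a pseudo-window of `n_snps` SNPs sampled
#' uniformly at random genome-wide (same sites across replicates, new sites
#' each permutation), destroying linkage while preserving the marginal
#' distribution of allele-frequency change. Returns the cumulative
#' eigenvalue sums for m = 1..k and their 99th percentiles.
#'
#' @param panel an [af_panel()].
#' @param design a [replicate_design()].
#' @param n_snps SNPs per pseudo-window (default 50).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @param alpha tail probability for the reported quantiles (default 0.01).
#' @return A list with `cum` (n_perm x k matrix of cumulative sums) and
#'   `q` (the per-m `1 - alpha` quantiles).
#' @export
null_distribution <- function(panel, design, n_snps = 50, n_perm = 10000,
                              seed = 1L, alpha = 0.01) {
  set.seed(seed)
  si <- pop_index(panel, design$surface)
  ci <- pop_index(panel, design$cave)
  ok <- !colSums(is.na(panel$freq[c(si, ci), , drop = FALSE]))
  pool <- which(ok)
  replace <- length(pool) < 10 * n_snps
  if (replace)
    warning("fewer than 10x n_snps eligible SNPs; sampling with replacement")
  k <- length(ci)
  cum <- matrix(NA_real_, n_perm, k)
  for (b in seq_len(n_perm)) {
    idx <- sample(pool, n_snps, replace = replace)
    A <- af_change_matrix(panel, design, idx)
    if (is.null(A) || nrow(A) < k) next
    cum[b, ] <- cumsum(eigen_scan(A)$values)
  }
  cum <- cum[stats::complete.cases(cum), , drop = FALSE]
  list(cum = cum, q = apply(cum, 2, stats::quantile, probs = 1 - alpha,
                            names = FALSE))
}

# Rotation-invariant lineage-partition test in the top-2 eigenspace. Each
# replicate's coordinates on eigenvectors 1-2 are scaled by sqrt(lambda)
# (so they reproduce the rows' actual geometry, C ~ W W'); within each
# lineage the scaled coordinate vectors must point in a common direction,
# and the two lineages' directions must disagree. Near-equal leading
# eigenvalues make individual eigenvectors arbitrary rotations of the
# lineage blocks, so the raw eigenvector-2 sign pattern alone is not
# stable; directions in the spanned plane, eigenvalue-weighted, are.
lineage_partition <- function(eig, lineages, tol = 0.05) {
  if (length(unique(lineages)) < 2) return(FALSE)
  W <- eig$vectors[, 1:2, drop = FALSE] %*%
    diag(sqrt(pmax(eig$values[1:2], 0)), 2)
  len <- sqrt(rowSums(W^2))
  if (any(len <= tol * max(len))) return(FALSE)
  U <- W / len
  cs <- U %*% t(U)  # cosine similarity between replicate directions
  same_lin <- outer(lineages, lineages, "==")
  off <- !diag(nrow(U))
  within_ok <- all(cs[same_lin & off] > 0.7)
  between_ok <- all(abs(cs[!same_lin]) < 0.7)
  within_ok && between_ok
}

#' Classify one window's mode of repeated evolution
#'
#' * `allele_reuse`: leading cumulative eigenvalue exceeds its null
#'   quantile, every replicate loads non-negligibly on eigenvector 1 with a
#'   common sign, and the top-2 eigenspace does not split by lineage.
#' * `locus_reuse`: the m = 2 cumulative eigenvalue exceeds its null
#'   quantile (joint test; set `joint = FALSE` to require only the second
#'   eigenvector's increment) and replicate loadings partition by lineage.
#' * `antiparallel`: eigenvector-1 significant with mixed signs not
#'   explained by lineage.
#' * `divergent`: m = 2 significant without a lineage partition.
#' * `none` otherwise.
#'
#' Loadings within `tol` of zero are sign-neutral.
#'
#' @param eig result of [eigen_scan()].
#' @param null_q per-m null quantiles from [null_distribution()].
#' @param lineages lineage label per replicate (row of A).
#' @param tol sign-neutrality tolerance (default 0.05).
#' @param joint use the joint m = 2 cumulative statistic for locus reuse
#'   (default) rather than eigenvector 2 alone.
#' @return One of `"allele_reuse"`, `"locus_reuse"`, `"antiparallel"`,
#'   `"divergent"`, `"none"`.
#' @export
classify_window <- function(eig, null_q, lineages, tol = 0.05, joint = TRUE) {
  k <- length(eig$values)
  cum <- cumsum(eig$values)
  sig1 <- cum[1] > null_q[1]
  sig2 <- if (k >= 2) {
    if (joint) cum[2] > null_q[2]
    else (cum[2] - cum[1]) > (null_q[2] - null_q[1])
  } else FALSE
  have_lineage <- !is.null(lineages) && !anyNA(lineages)
  if (!have_lineage) warning("no lineage labels: locus reuse unavailable")

  v1 <- eig$vectors[, 1]
  signs <- sign(v1) * (abs(v1) > tol)
  unanimous <- all(signs != 0) && (all(signs > 0) || all(signs < 0))
  part <- have_lineage && k >= 2 && lineage_partition(eig, lineages, tol)

  if (sig1 && unanimous && !part) return("allele_reuse")
  if (have_lineage && sig2 && part) return("locus_reuse")
  if (sig1 && all(signs != 0) && !part) return("antiparallel")
  if (sig2) return("divergent")
  "none"
}

#' Genome scan for repeated allele-frequency change
#'
#' Slides non-overlapping windows of `n_snps` SNPs along each chromosome,
#' eigen-decomposes each window's allele-frequency-change matrix, assigns
#' empirical p-values against the permutation null and classifies each
#' window. Windows with fewer than `n_snps` eligible SNPs at a chromosome
#' end are skipped.
#'
#' @param panel an [af_panel()].
#' @param design a [replicate_design()].
#' @param n_snps SNPs per window (default 50).
#' @param n_perm permutations for the null (default 10000).
#' @param alpha significance level (default 0.01, i.e. the 99th percentile).
#' @param seed integer seed.
#' @param null optional precomputed [null_distribution()] result (reused
#'   across panels of the same design).
#' @return An object of class `reuse_scan`: a data.frame with window span,
#'   eigenvalues, per-m empirical p-values and `classification`, carrying
#'   the null quantiles as an attribute.
#' @export
reuse_scan <- function(panel, design, n_snps = 50, n_perm = 10000,
                       alpha = 0.01, seed = 1L, null = NULL) {
  si <- pop_index(panel, design$surface)
  ci <- pop_index(panel, design$cave)
  ok <- !colSums(is.na(panel$freq[c(si, ci), , drop = FALSE]))
  eligible <- which(ok)
  if (is.null(null))
    null <- null_distribution(panel, design, n_snps, n_perm, seed, alpha)
  k <- length(ci)
  n_win <- length(eligible) %/% n_snps
  rows <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    idx <- eligible[((w - 1) * n_snps + 1):(w * n_snps)]
    A <- af_change_matrix(panel, design, idx)
    if (is.null(A) || nrow(A) < k) {
      rows[[w]] <- NULL
      next
    }
    eig <- eigen_scan(A)
    cum <- cumsum(eig$values)
    pvals <- vapply(seq_len(k), function(m)
      (1 + sum(null$cum[, m] >= cum[m])) / (nrow(null$cum) + 1), numeric(1))
    cls <- classify_window(eig, null$q, design$lineage)
    rec <- data.frame(chrom = panel$sites$chrom[idx[1]],
                      start = panel$sites$pos[idx[1]],
                      end = panel$sites$pos[idx[n_snps]],
                      n_snps = n_snps, stringsAsFactors = FALSE)
    for (m in seq_len(k)) rec[[paste0("lambda", m)]] <- eig$values[m]
    for (m in seq_len(k)) rec[[paste0("p_cum", m)]] <- pvals[m]
    rec$classification <- cls
    rows[[w]] <- rec
  }
  out <- do.call(rbind, rows)
  attr(out, "null_q") <- null$q
  attr(out, "alpha") <- alpha
  class(out) <- c("reuse_scan", class(out))
  out
}

#' @export
print.reuse_scan <- function(x, ...) {
  cat("<reuse_scan> ", nrow(x), " windows\n", sep = "")
  print(table(x$classification))
  invisible(x)
}

#' Map significant scan windows to genes
#'
#' A gene is listed once per classification if any overlapping window
#' carries it; a gene overlapping both an allele-reuse and a locus-reuse
#' window carries both labels.
#'
#' @param scan a [reuse_scan()] result.
#' @param models a [gene_models()] object.
#' @param classes classifications of interest.
#' @return data.frame with `gene_id` and `classification`.
#' @export
windows_to_genes <- function(scan, models,
                             classes = c("allele_reuse", "locus_reuse")) {
  sig <- scan[scan$classification %in% classes, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(gene_id = character(), classification = character()))
  gr_win <- GenomicRanges::GRanges(sig$chrom,
                                   IRanges::IRanges(sig$start, sig$end))
  gr_gene <- GenomicRanges::GRanges(
    models$genes$chrom,
    IRanges::IRanges(models$genes$start + 1L, models$genes$end))
  hits <- GenomicRanges::findOverlaps(gr_gene, gr_win)
  out <- unique(data.frame(
    gene_id = models$genes$gene_id[S4Vectors::queryHits(hits)],
    classification = sig$classification[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
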