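#' Per-site nucleotide diversity
#'
#' Sample-size corrected expected heterozygosity at a biallelic site:
#' `2 p (1 - p) n / (n - 1)` with `n` haploid observations.
#'
#' @param p alternate-allele frequency in `[0, 1]`.
#' @param n haploid observation count (>= 2).
#' @return Per-site pi.
#' @export
site_pi <- function(p, n) {
  if (any(n < 2, na.rm = TRUE)) stop("n must be >= 2")
  2 * p * (1 - p) * n / (n - 1)
}

#' Per-site absolute divergence (Dxy)
#'
#' `p1 (1 - p2) + p2 (1 - p1)`; symmetric in its arguments.
#'
#' @param p1,p2 allele frequencies in the two populations.
#' @return Per-site Dxy.
#' @export
site_dxy <- function(p1, p2) p1 * (1 - p2) + p2 * (1 - p1)

# Hudson Fst numerator/denominator, exposed separately so windows can
# aggregate as a ratio of sums.
fst_components <- function(p1, n1, p2, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = num, den = den)
}

#' Per-site Hudson Fst
#'
#' Hudson's estimator with sample-size correction:
#' `[(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)] / [p1(1-p2) + p2(1-p1)]`.
#' Returns `NA` where the denominator is zero (monomorphic across both
#' populations).
#'
#' @param p1,p2 allele frequencies.
#' @param n1,n2 haploid sample sizes (>= 2).
#' @return Per-site Fst (possibly `NA`).
#' @export
site_fst <- function(p1, n1, p2, n2) {
  if (any(c(n1, n2) < 2, na.rm = TRUE)) stop("n must be >= 2")
  k <- fst_components(p1, n1, p2, n2)
  out <- k$num / k$den
  out[k$den == 0] <- NA_real_
  out
}

#' Windowed summary statistics
#'
#' Mean pi per population, mean Dxy and ratio-of-sums Hudson Fst per
#' population pair, in non-overlapping windows of `window_bp` (default
#' 50 kb). Sites with missing frequency are excluded pairwise per statistic.
#'
#' @param panel an [af_panel()].
#' @param window_bp window size in bp.
#' @return data.frame with one row per (chrom, window): `chrom`, `start`,
#'   `end` (0-based half-open), `n_sites`, `pi_<pop>` columns, and
#'   `dxy_<p1>.<p2>` / `fst_<p1>.<p2>` columns for every pair.
#' @export
windowed_stats <- function(panel, window_bp = 50000) {
  sites <- panel$sites
  win <- floor((sites$pos - 1) / window_bp)
  key <- paste(sites$chrom, win, sep = ":")
  ukey <- unique(key)
  idx <- match(key, ukey)
  nwin <- length(ukey)
  chrom <- sub(":.*", "", ukey)
  wstart <- as.integer(sub(".*:", "", ukey)) * window_bp

  mean_by <- function(x) {
    ok <- !is.na(x)
    s <- rowsum(ifelse(ok, x, 0), idx, reorder = TRUE)
    m <- rowsum(as.numeric(ok), idx, reorder = TRUE)
    out <- rep(NA_real_, nwin)
    present <- sort(unique(idx))
    out[present] <- ifelse(m[, 1] > 0, s[, 1] / m[, 1], NA_real_)
    out
  }
  sum_by <- function(x) {
    ok <- !is.na(x)
    s <- rowsum(ifelse(ok, x, 0), idx, reorder = TRUE)
    out <- rep(NA_real_, nwin)
    out[sort(unique(idx))] <- s[, 1]
    out
  }

  out <- data.frame(chrom = chrom, start = wstart, end = wstart + window_bp,
                    n_sites = as.integer(tabulate(idx, nwin)),
                    stringsAsFactors = FALSE)
  pops <- panel$pops$pop
  for (j in seq_along(pops))
    out[[paste0("pi_", pops[j])]] <-
      mean_by(site_pi(panel$freq[j, ], panel$n[j, ]))
  for (a in seq_along(pops)) for (b in seq_along(pops)) if (a < b) {
    pa <- panel$freq[a, ]; pb <- panel$freq[b, ]
    out[[paste0("dxy_", pops[a], ".", pops[b])]] <- mean_by(site_dxy(pa, pb))
    k <- fst_components(pa, panel$n[a, ], pb, panel$n[b, ])
    num <- sum_by(ifelse(is.na(pa) | is.na(pb), NA, k$num))
    den <- sum_by(ifelse(is.na(pa) | is.na(pb), NA, k$den))
    out[[paste0("fst_", pops[a], ".", pops[b])]] <-
      ifelse(!is.na(den) & den > 0, num / den, NA_real_)
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Per-gene summary statistics
#'
#' Min, max and mean of per-site pi (per population) and Dxy (per pair) over
#' the SNPs falling inside each gene span. Uses per-site values directly, not
#' window averages; genes with no SNPs get an `NA` row.
#'
#' @param panel an [af_panel()].
#' @param models a [gene_models()] object.
#' @return Long data.frame: `gene_id`, `stat`, `pop1`, `pop2`, `n_sites`,
#'   `min`, `max`, `mean`.
#' @export
gene_stats <- function(panel, models) {
  site_idx <- sites_in_genes(panel, models)
  pops <- panel$pops$pop
  rows <- list()
  smry <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) c(NA_real_, NA_real_, NA_real_)
    else c(min(v), max(v), mean(v))
  }
  for (gi in seq_along(site_idx)) {
    idx <- site_idx[[gi]]
    gid <- models$genes$gene_id[gi]
    for (j in seq_along(pops)) {
      v <- if (length(idx)) site_pi(panel$freq[j, idx], panel$n[j, idx]) else numeric()
      s <- smry(v)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, stat = "pi", pop1 = pops[j], pop2 = NA_character_,
        n_sites = length(idx), min = s[1], max = s[2], mean = s[3],
        stringsAsFactors = FALSE)
    }
    for (a in seq_along(pops)) for (b in seq_along(pops)) if (a < b) {
      v <- if (length(idx)) site_dxy(panel$freq[a, idx], panel$freq[b, idx]) else numeric()
      s <- smry(v)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, stat = "dxy", pop1 = pops[a], pop2 = pops[b],
        n_sites = length(idx), min = s[1], max = s[2], mean = s[3],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Time to the common ancestor from Dxy
#'
#' Inverts `Dxy = 2 mu T`: `T = Dxy / (2 mu)` generations.
#'
#' @param dxy absolute divergence.
#' @param mu per-bp per-generation mutation rate (default 3.5e-9).
#' @return Generations.
#' @export
tmrca_from_dxy <- function(dxy, mu = 3.5e-9) {
  if (any(mu <= 0)) stop("mu must be > 0")
  dxy / (2 * mu)
}

#' Generations since the onset of admixture from ancestry tracts
#'
#' `T_admix = 1 / (L_M * p_B)` where `L_M` is the mean minor-parent tract
#' length in Morgans and `p_B` the proportion of the genome derived from the
#' major parent.
#'
#' @param tracts data.frame with columns `individual`, `source` (`"minor"`
#'   or `"major"`) and `length_bp`.
#' @param rec_rate recombination rate in Morgans/bp (default 1.16e-8).
#' @return A list with `t_admix` (generations), `l_minor_morgans`,
#'   `p_major`.
#' @export
admixture_time <- function(tracts, rec_rate = 1.16e-8) {
  stopifnot(all(c("source", "length_bp") %in% names(tracts)))
  if (any(tracts$length_bp <= 0)) stop("tract lengths must be positive")
  minor <- tracts$length_bp[tracts$source == "minor"]
  if (!length(minor)) stop("need at least one minor-parent tract")
  l_m <- mean(minor) * rec_rate
  p_b <- sum(tracts$length_bp[tracts$source == "major"]) / sum(tracts$length_bp)
  if (p_b <= 0 || p_b >= 1) stop("major-parent fraction must be in (0, 1)")
  list(t_admix = 1 / (l_m * p_b), l_minor_morgans = l_m, p_major = p_b)
}

#' Frequency-based ABBA-BABA D statistic
#'
#' `D = sum[(1-p1) p2 p3 (1-p4) - p1 (1-p2) p3 (1-p4)] /
#'      sum[(1-p1) p2 p3 (1-p4) + p1 (1-p2) p3 (1-p4)]`
#' with a block-jackknife standard error over blocks of `block_snps` SNPs.
#' P4 is the outgroup defining the ancestral state.
#'
#' @param p1,p2,p3,p4 aligned derived-allele frequency vectors.
#' @param block_snps jackknife block size in SNPs (default 500).
#' @return A list with `d`, `se`, `z`, `n_blocks`, `n_sites`. `d` is `NA`
#'   when the denominator is zero.
#' @export
patterson_d <- function(p1, p2, p3, p4, block_snps = 500) {
  stopifnot(length(p1) == length(p2), length(p2) == length(p3),
            length(p3) == length(p4))
  ok <- !(is.na(p1) | is.na(p2) | is.na(p3) | is.na(p4))
  p1 <- p1[ok]; p2 <- p2[ok]; p3 <- p3[ok]; p4 <- p4[ok]
  abba <- (1 - p1) * p2 * p3 * (1 - p4)
  baba <- p1 * (1 - p2) * p3 * (1 - p4)
  den <- sum(abba + baba)
  if (den == 0)
    return(list(d = NA_real_, se = NA_real_, z = NA_real_,
                n_blocks = 0L, n_sites = length(p1)))
  d <- sum(abba - baba) / den
  blk <- (seq_along(p1) - 1L) %/% block_snps
  nb <- length(unique(blk))
  se <- NA_real_; z <- NA_real_
  if (nb >= 2) {
    loo <- vapply(unique(blk), function(b) {
      keep <- blk != b
      s <- sum(abba[keep] + baba[keep])
      if (s == 0) return(NA_real_)
      sum(abba[keep] - baba[keep]) / s
    }, numeric(1))
    loo <- loo[!is.na(loo)]
    nb <- length(loo)
    se <- sqrt((nb - 1) / nb * sum((loo - mean(loo))^2))
    z <- if (se > 0) d / se else NA_real_
  }
  list(d = d, se = se, z = z, n_blocks = nb, n_sites = length(p1))
}

#' Compare genome fractions under selection between ecotypes
#'
#' One-sided Wilcoxon rank-sum test that the per-population fraction of
#' windows under selection is larger in cave than in surface populations.
#' Exact when group sizes permit and there are no ties; midranks otherwise.
#'
#' @param fractions_cave,fractions_surface numeric vectors (>= 2 values
#'   each).
#' @return A list with `w` and `p`.
#' @export
compare_sweep_fractions <- function(fractions_cave, fractions_surface) {
  stopifnot(length(fractions_cave) >= 2, length(fractions_surface) >= 2)
  res <- suppressWarnings(stats::wilcox.test(
    fractions_cave, fractions_surface, alternative = "greater",
    exact = length(fractions_cave) <= 10 && length(fractions_surface) <= 10))
  list(w = unname(res$statistic), p = res$p.value)
}
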