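# Composite-likelihood discrimination of modes of repeated adaptation:
# neutral / independent mutation / standing variation / migration / two
# mixed models, fitted against a coancestry null estimated from thinned
# intergenic sites.

#' Standardize panel frequencies
#'
#' Per site, `x = (p - pbar) / sqrt(pden (1 - pden))` with `pbar` the
#' across-population mean and `pden` the mean over `denom_pops` (all
#' populations by default, giving the classic
#' `(p - pbar)/sqrt(pbar(1-pbar))`). Passing the unselected populations as
#' `denom_pops` makes the scale robust to a sweep in the selected
#' populations, which drags the pooled mean; the centering stays on the
#' all-population mean so the vectors remain in the mean-orthogonal
#' subspace. Sites where the denominator degenerates or any frequency is
#' missing are dropped.
#'
#' @param panel an [af_panel()].
#' @param idx site indices (default all).
#' @param denom_pops population indices used for the denominator mean
#'   (default all).
#' @return A list with `X` (k x S' matrix) and `idx` (the retained site
#'   indices).
#' @export
standardize_freqs <- function(panel, idx = seq_len(ncol(panel$freq)),
                              denom_pops = NULL, denom_range = c(0, 1)) {
  P <- panel$freq[, idx, drop = FALSE]
  pbar <- colMeans(P)
  pden <- if (is.null(denom_pops)) pbar
  else colMeans(P[denom_pops, , drop = FALSE])
  ok <- !is.na(pbar) & !is.na(pden) &
    pden > max(0, denom_range[1]) & pden < min(1, denom_range[2]) &
    pden > 0 & pden < 1 & colSums(is.na(P)) == 0
  P <- P[, ok, drop = FALSE]
  X <- sweep(P, 2, pbar[ok]) /
    rep(sqrt(pden[ok] * (1 - pden[ok])), each = nrow(P))
  list(X = X, idx = idx[ok])
}

#' Intergenic sites thinned for the coancestry null
#'
#' All sites outside every gene span, thinned to at most one site per
#' `thin_bp` (the first in each bin).
#'
#' @param panel an [af_panel()].
#' @param models a [gene_models()] object.
#' @param thin_bp thinning interval (default 50 kb).
#' @return Integer site indices.
#' @export
neutral_sites <- function(panel, models, thin_bp = 50000) {
  in_gene <- rep(FALSE, ncol(panel$freq))
  for (i in seq_len(nrow(models$genes))) {
    g <- models$genes[i, ]
    in_gene <- in_gene | (panel$sites$chrom == g$chrom &
                            panel$sites$pos - 1 >= g$start &
                            panel$sites$pos - 1 < g$end)
  }
  idx <- which(!in_gene)
  bin <- paste(panel$sites$chrom[idx],
               (panel$sites$pos[idx] - 1) %/% thin_bp)
  idx[!duplicated(bin)]
}

#' Estimate the neutral coancestry matrix F
#'
#' Empirical covariance of standardized allele frequencies at putatively
#' neutral (intergenic, thinned) sites, with a small ridge on the diagonal.
#'
#' @param panel an [af_panel()].
#' @param idx neutral site indices (from [neutral_sites()]).
#' @param eps diagonal regularization (default 1e-6).
#' @return A list of class `neutral_cov`: `F` (k x k), `n_sites`, `eps`,
#'   `pops`.
#' @export
estimate_neutral_F <- function(panel, idx, eps = 1e-6) {
  if (length(idx) < 100) stop("need at least 100 neutral sites")
  st <- standardize_freqs(panel, idx)
  Fm <- stats::cov(t(st$X))
  Fm <- Fm + diag(eps, nrow(Fm))
  dimnames(Fm) <- list(panel$pops$pop, panel$pops$pop)
  structure(list(F = Fm, n_sites = ncol(st$X), eps = eps,
                 pops = panel$pops$pop), class = "neutral_cov")
}

#' @export
print.neutral_cov <- function(x, ...) {
  cat("<neutral_cov> ", nrow(x$F), " populations, ", x$n_sites,
      " neutral sites (ridge ", x$eps, ")\n", sep = "")
  print(round(x$F, 4))
  invisible(x)
}

dmc_model_codes <- c(neutral = 0L, independent = 1L, standing = 2L,
                     migration = 3L, mixed_migration = 4L,
                     mixed_standing = 5L)

# live (likelihood-affecting) parameters per model; the independent model
# carries t_st in its grid for reporting but t_st does not enter its
# covariance, so its MCLE sits at the grid minimum by construction.
dmc_live_params <- c(neutral = 0L, independent = 1L, standing = 3L,
                     migration = 2L, mixed_migration = 2L, mixed_standing = 3L)

#' Default parameter grids for the convergence-mode fit
#'
#' @param ne diploid effective population size (sets the minimum standing
#'   frequency `1/(2 Ne)`).
#' @return A list with `s`, `t_st`, `g`, `m`.
#' @export
dmc_grids <- function(ne = 1e5) {
  list(s = c(1e-4, 1e-3, 1e-2, 1e-1),
       t_st = c(5, 10, 25, 50, 100, 500, 1000),
       g = c(1 / (2 * ne), 1e-3, 1e-2, 1e-1),
       m = c(1e-5, 1e-4, 1e-3, 1e-2))
}

dmc_combos <- function(model, grids) {
  g1 <- function(x) if (length(x)) x else NA_real_
  switch(model,
    neutral = cbind(s = 0, t_st = 0, g = 0, m = 0),
    independent = as.matrix(expand.grid(s = grids$s, t_st = grids$t_st,
                                        g = 0, m = 0)),
    standing = as.matrix(expand.grid(s = grids$s, t_st = grids$t_st,
                                     g = grids$g, m = 0)),
    migration = as.matrix(expand.grid(s = grids$s, t_st = 0, g = 0,
                                      m = grids$m)),
    mixed_migration = as.matrix(expand.grid(s = grids$s, t_st = 0, g = 0,
                                            m = grids$m)),
    mixed_standing = as.matrix(expand.grid(s = grids$s, t_st = grids$t_st,
                                           g = grids$g, m = 0)),
    stop("unknown model: ", model))
}

#' Orthonormal basis of the mean-orthogonal subspace
#'
#' Standardized frequency vectors sum to zero across populations, so all
#' densities live in the (k-1)-dimensional subspace orthogonal to the ones
#' vector. Returns a k x (k-1) matrix with orthonormal columns spanning it.
#'
#' @param k number of populations.
#' @return k x (k-1) matrix `Q` with `t(Q) %*% Q = I` and `t(Q) %*% 1 = 0`.
#' @export
mean_contrast_basis <- function(k) {
  Q <- qr.Q(qr(cbind(rep(1, k), diag(k)[, -k])))[, -1, drop = FALSE]
  Q
}

#' Model covariance at one distance (reference implementation)
#'
#' Plain-R construction of the per-SNP raw-scale covariance `F + D` used by
#' the composite likelihood; the compiled kernel implements the same
#' algebra in the mean-orthogonal subspace. `D` approximates the second
#' moments implied by the sweep-implant generator: with retention
#' `y = exp(-r tau)`, a selected population's frequency is a single
#' haplotype's allele state (unit standardized variance) with probability
#' `y`; that haplotype carries its origin's coancestry with every other
#' population (zero for the ancestral origin assumed under standing
#' variation, the source population's row of `F` under migration). Shared
#' capture across two populations requires both (`y^2`), and a standing
#' haplotype must survive `t_st` generations of recombination in each
#' population (`q = exp(-r t_st)`, pair factor `q^2`, reduced by the
#' standing frequency `g`). The origin's own drift variance is left out of
#' the diagonal and pair terms so that the standing and migration models
#' differ in decay shape and origin coancestry, not overall scale. All
#' models reduce to `F` as `y -> 0`; the standing model reduces to the
#' independent model as `t_st -> Inf`.
#'
#' @param model model name.
#' @param F neutral coancestry matrix.
#' @param sel indices of selected populations.
#' @param r_bp distance from the proposed selected site, bp.
#' @param params named vector/list with `s`, `t_st`, `g`, `m` (as relevant).
#' @param ne,rec_rate effective size and recombination rate.
#' @param group sharing subgroup for mixed models (default `sel`).
#' @param origin index of the sweeping haplotype's origin population
#'   (default: first of `group`).
#' @param svar per-population sampling variance of the frequency estimates
#'   (standardized units, about `1/n` haploids), added to the diagonal of
#'   every model including the neutral one.
#' @return k x k covariance matrix (raw scale, before projection).
#' @export
model_covariance <- function(model, F, sel, r_bp, params, ne,
                             rec_rate = 1.16e-8, group = sel,
                             origin = group[1], svar = 0) {
  F_obs <- F + diag(rep_len(svar, nrow(F)), nrow(F))
  if (model == "neutral") return(F_obs)
  s <- params[["s"]]
  if (is.null(s) || s <= 0) stop("s must be > 0")
  y <- sweep_retention(r_bp, s, ne, rec_rate)
  standing_like <- model %in% c("standing", "mixed_standing")
  migration_like <- model %in% c("migration", "mixed_migration")
  q <- if (standing_like) exp(-r_bp * rec_rate * params[["t_st"]]) else 1
  share <- if (standing_like) q^2 * (1 - params[["g"]])
  else if (migration_like)
    exp(-2 * r_bp * rec_rate / (4 * ne * params[["m"]]))
  else 0
  k <- nrow(F)
  D <- matrix(0, k, k)
  for (i in sel) {
    D[i, i] <- if (model == "independent" || !(i %in% group)) y
    else if (standing_like) y * (1 - q * F[i, i])
    else y * (1 - F[i, i])
  }
  if (model != "independent") {
    for (a in seq_along(group)) {
      i <- group[a]
      for (b in seq_along(group)) if (b > a) {
        j <- group[b]
        D[i, j] <- D[j, i] <- share * y^2 * (1 - F[i, j])
      }
      for (u in setdiff(seq_len(k), c(group, i))) {
        d <- if (standing_like) -y * q * F[i, u]
        else y * (F[origin, u] - F[i, u])
        D[i, u] <- D[i, u] + d
        D[u, i] <- D[u, i] + d
      }
    }
  }
  F_obs + D
}

#' Composite log likelihood (reference implementation)
#'
#' Sum over SNPs of the log multivariate-normal density of the reduced
#' standardized frequency vector `Q'x`, mean zero, covariance
#' `Q' model_covariance(...) Q` at each SNP's distance from the proposed
#' selected site (sites treated as independent). Slow but transparent;
#' [dmc_fit()] uses the compiled kernel, which implements identical
#' algebra.
#'
#' @param X k x S standardized frequencies (full space).
#' @param positions SNP positions, bp.
#' @param proposed_site proposed selected site, bp.
#' @param model model name.
#' @param params named parameters.
#' @param F neutral coancestry matrix.
#' @param sel selected population indices.
#' @param ne,rec_rate effective size and recombination rate.
#' @param group sharing subgroup for mixed models.
#' @param origin origin population index (default first of `group`).
#' @param svar per-population sampling variance (see [model_covariance()]).
#' @return Scalar composite log likelihood.
#' @export
composite_loglik <- function(X, positions, proposed_site, model, params, F,
                             sel, ne, rec_rate = 1.16e-8, group = sel,
                             origin = group[1], svar = 0) {
  k <- nrow(X)
  Q <- mean_contrast_basis(k)
  Xs <- t(Q) %*% X
  ll <- 0
  for (j in seq_len(ncol(X))) {
    Sigma <- model_covariance(model, F, sel, abs(positions[j] - proposed_site),
                              params, ne, rec_rate, group, origin, svar)
    Ss <- t(Q) %*% Sigma %*% Q
    ch <- tryCatch(chol(Ss), error = function(e) NULL)
    if (is.null(ch)) {
      # clip sub-PSD approximations rather than censoring the grid point
      e <- eigen(Ss, symmetric = TRUE)
      Ss <- e$vectors %*% (pmax(e$values, 1e-4) * t(e$vectors))
      ch <- chol(Ss)
    }
    z <- backsolve(ch, Xs[, j], transpose = TRUE)
    ll <- ll - 0.5 * ((k - 1) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
  }
  ll
}

#' Fit convergence-mode models to one candidate gene
#'
#' Grid search over models x parameter combinations x `n_sites` evenly
#' spaced proposed selected sites across the gene span plus `flank` on each
#' side. The best model maximizes the penalized maximum composite log
#' likelihood (penalty = `complexity_penalty` per live parameter, breaking
#' near-ties toward the simpler model); exact ties also resolve toward
#' fewer live parameters.
#'
#' @param panel an [af_panel()].
#' @param gene_id gene to analyse.
#' @param annotation a [gene_models()] object containing the gene.
#' @param F_est a `neutral_cov` from [estimate_neutral_F()].
#' @param sel_pops selected population labels (e.g. the cave populations).
#' @param model_set models to fit (always includes `"neutral"`).
#' @param grids parameter grids, see [dmc_grids()].
#' @param flank flank in bp (default 10 kb).
#' @param n_sites number of evenly spaced proposed sites (default 50).
#' @param ne,rec_rate effective size and recombination rate.
#' @param mixed_group subgroup sharing the allele under the mixed models
#'   (defaults to the selected populations of the first lineage with >= 2
#'   selected populations).
#' @param complexity_penalty log-likelihood units per live parameter
#'   (default 1).
#' @param max_gene_bp genes longer than this are skipped (default 400 kb).
#' @param denom_range sites whose unselected-mean frequency falls outside
#'   this range are excluded (extreme standardization weights destabilize
#'   the composite likelihood).
#' @return An object of class `dmc_fit`, or `NULL` (with a message) for a
#'   skipped gene (no SNPs in span, or oversized).
#' @export
dmc_fit <- function(panel, gene_id, annotation, F_est, sel_pops,
                    model_set = c("independent", "standing", "migration"),
                    grids = dmc_grids(ne), flank = 10000, n_sites = 50,
                    ne = 1e5, rec_rate = 1.16e-8, mixed_group = NULL,
                    complexity_penalty = 1, max_gene_bp = 400000,
                    denom_range = c(0.1, 0.9)) {
  gi <- match(gene_id, annotation$genes$gene_id)
  if (is.na(gi)) stop("unknown gene: ", gene_id)
  gene <- annotation$genes[gi, ]
  if (gene$end - gene$start > max_gene_bp) {
    message("gene ", gene_id, " longer than ", max_gene_bp, " bp: skipped")
    return(NULL)
  }
  span <- c(gene$start - flank, gene$end + flank)
  idx <- which(panel$sites$chrom == gene$chrom &
                 panel$sites$pos - 1 >= span[1] &
                 panel$sites$pos - 1 < span[2])
  sel0 <- pop_index(panel, sel_pops)
  unsel <- setdiff(seq_len(nrow(panel$pops)), sel0)
  st <- standardize_freqs(panel, idx,
                          denom_pops = if (length(unsel)) unsel else NULL,
                          denom_range = denom_range)
  if (ncol(st$X) < 1) {
    message("gene ", gene_id, " has no usable SNPs in span: skipped")
    return(NULL)
  }
  sel <- pop_index(panel, sel_pops)
  group <- sel
  mixed_sel <- if (is.null(mixed_group)) {
    lin <- panel$pops$lineage[sel]
    tab <- table(lin)
    pick <- as.integer(names(tab)[tab >= 2][1])
    sel[lin == pick]
  } else pop_index(panel, mixed_group)

  model_set <- union("neutral", model_set)
  prop <- seq(span[1] + 1, span[2], length.out = n_sites)
  pos <- panel$sites$pos[st$idx]
  k <- nrow(st$X)
  Q <- mean_contrast_basis(k)
  Xs <- t(Q) %*% st$X
  # The empirical neutral covariance carries the binomial sampling variance
  # of the frequency estimates on its diagonal; the model separates drift
  # (which the sweep terms rescale) from sampling noise (which they do
  # not), so the sampling part is removed here and re-added uniformly
  # inside the kernel.
  svar <- 1 / rowMeans(panel$n[, idx, drop = FALSE])
  Fd <- F_est$F
  diag(Fd) <- pmax(diag(Fd) - svar, 1e-4)

  fits <- list()
  for (mod in model_set) {
    combos <- dmc_combos(mod, grids)
    grp <- if (mod %in% c("mixed_migration", "mixed_standing")) mixed_sel else sel
    ll <- cpp_dmc_grid(Xs, pos, prop, Fd, Q, sel - 1L, grp - 1L,
                       grp[1] - 1L, dmc_model_codes[[mod]],
                       unname(combos), ne, rec_rate, svar)
    best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    fits[[mod]] <- list(
      max_loglik = max(ll),
      params = stats::setNames(as.numeric(combos[best[1], ]),
                               c("s", "t_st", "g", "m")),
      site = prop[best[2]])
  }
  score <- vapply(model_set, function(m)
    fits[[m]]$max_loglik - complexity_penalty * dmc_live_params[[m]],
    numeric(1))
  ord <- order(-score, dmc_live_params[model_set])
  best_model <- model_set[ord[1]]

  site <- fits[[best_model]]$site
  site_class <- classify_selected_site(site, gene_id, annotation, flank)
  structure(list(
    gene_id = gene_id, span = span, n_snps = ncol(st$X),
    models = fits, best_model = best_model,
    loglik = vapply(fits, `[[`, numeric(1), "max_loglik"),
    score = score,
    mcle = fits[[best_model]]$params,
    selected_site = site, site_class = site_class,
    sel_pops = sel_pops, ne = ne, rec_rate = rec_rate,
    complexity_penalty = complexity_penalty
  ), class = "dmc_fit")
}

#' @export
print.dmc_fit <- function(x, ...) {
  cat("<dmc_fit> gene ", x$gene_id, " (", x$n_snps, " SNPs in span ",
      x$span[1], "-", x$span[2], ")\n", sep = "")
  cat("  best model: ", x$best_model, "\n", sep = "")
  cat("  selected site: ", round(x$selected_site), " (", x$site_class, ")\n",
      sep = "")
  invisible(x)
}

#' @export
summary.dmc_fit <- function(object, ...) {
  tab <- data.frame(
    model = names(object$loglik),
    max_loglik = unname(object$loglik),
    score = unname(object$score[names(object$loglik)]),
    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$score), ]
  rownames(tab) <- NULL
  cat("Convergence-mode fit for gene", object$gene_id, "\n")
  print(tab, digits = 6)
  cat("\nMCLE under", object$best_model, "model:\n")
  print(object$mcle)
  cat("selected site", round(object$selected_site), "->", object$site_class, "\n")
  invisible(tab)
}

#' @export
coef.dmc_fit <- function(object, ...) object$mcle

#' @export
logLik.dmc_fit <- function(object, ...) {
  structure(object$loglik[[object$best_model]],
            df = dmc_live_params[[object$best_model]], class = "logLik")
}

#' Classify a proposed selected site against a gene model
#'
#' Inside the gene span, priority CDS > UTR > intron; outside,
#' `upstream10k`/`downstream10k` by strand-aware orientation within `flank`
#' bp of the span.
#'
#' @param position site position, bp.
#' @param gene_id gene.
#' @param annotation a [gene_models()] object.
#' @param flank flank size (default 10 kb).
#' @return One of `"CDS"`, `"UTR5"`, `"UTR3"`, `"intron"`,
#'   `"upstream10k"`, `"downstream10k"`.
#' @export
classify_selected_site <- function(position, gene_id, annotation,
                                   flank = 10000) {
  gi <- match(gene_id, annotation$genes$gene_id)
  if (is.na(gi)) stop("unknown gene: ", gene_id)
  gene <- annotation$genes[gi, ]
  pos0 <- position - 1
  if (pos0 < gene$start - flank || pos0 >= gene$end + flank)
    stop("position outside gene span + flanks")
  covers <- function(type) {
    f <- annotation$features
    any(f$gene_id == gene_id & f$type == type &
          f$start <= pos0 & pos0 < f$end)
  }
  if (pos0 >= gene$start && pos0 < gene$end) {
    if (covers("CDS")) return("CDS")
    if (covers("five_prime_UTR")) return("UTR5")
    if (covers("three_prime_UTR")) return("UTR3")
    return("intron")
  }
  before <- pos0 < gene$start
  if (gene$strand == "+") {
    if (before) "upstream10k" else "downstream10k"
  } else {
    if (before) "downstream10k" else "upstream10k"
  }
}

#' Summarize best-model assignments
#'
#' Counts and percentages (nearest whole percent, half away from zero,
#' computed on the assigned total) per model.
#'
#' @param results either a list of [dmc_fit()] objects or a character
#'   vector/data.frame with a `best_model` column.
#' @return data.frame with `model`, `count`, `percent`.
#' @export
summarize_mode_assignments <- function(results) {
  models <- if (is.character(results)) results
  else if (is.data.frame(results)) results$best_model
  else vapply(Filter(Negate(is.null), results), `[[`, character(1), "best_model")
  if (!length(models)) stop("no results to summarize")
  tab <- table(models)
  total <- sum(tab)
  pct <- sign(100 * tab / total) * floor(abs(100 * tab / total) + 0.5)
  out <- data.frame(model = names(tab), count = as.integer(tab),
                    percent = as.numeric(pct), stringsAsFactors = FALSE)
  out[order(-out$count), , drop = FALSE]
}
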