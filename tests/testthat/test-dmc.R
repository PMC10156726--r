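test_that("sweep retention matches the hitchhiking form", {
  expect_equal(sweep_retention(0, 0.1, 1e5), 1)
  expect_equal(sweep_retention(10000, 0.01, 1e5),
               exp(-10000 * 1.16e-8 * log(4e5 * 0.01) / 0.01))
  expect_equal(round(sweep_retention(10000, 0.01, 1e5), 3), 0.908)
  # monotone decreasing in distance, increasing in s (for 4 Ne s > e)
  r <- seq(0, 50000, by = 5000)
  y <- sweep_retention(r, 0.01, 1e5)
  expect_true(all(diff(y) < 0))
  expect_true(all(sweep_retention(10000, c(0.01, 0.05, 0.1), 1e5) ==
                    cummax(sweep_retention(10000, c(0.01, 0.05, 0.1), 1e5))))
  expect_error(sweep_retention(100, -0.1, 1e5))
})

test_that("model covariances reduce to the neutral matrix in the no-sweep limit", {
  rec <- fx_recovery()
  F <- rec$Fhat$F
  sel <- match(rec$caves, rownames(F))
  far <- 5e7  # far enough that y underflows to 0
  for (mod in c("independent", "standing", "migration",
                "mixed_migration", "mixed_standing")) {
    S <- model_covariance(mod, F, sel, far,
                          list(s = 1e-4, t_st = 5, g = 1e-3, m = 1e-3),
                          ne = 1e4, group = if (grepl("mixed", mod)) sel[1:2] else sel)
    expect_equal(S, model_covariance("neutral", F, sel, far, list(), 1e4),
                 tolerance = 1e-8)
  }
})

test_that("independent model leaves between-selected covariance at neutrality", {
  rec <- fx_recovery()
  F <- rec$Fhat$F
  sel <- match(rec$caves, rownames(F))
  S <- model_covariance("independent", F, sel, 1000,
                        list(s = 0.1, t_st = 5, g = 0, m = 0), ne = 1e4)
  off <- S[sel, sel]; offF <- F[sel, sel]
  diag(off) <- diag(offF) <- 0
  expect_equal(off, offF)
  expect_true(all(diag(S[sel, sel]) > diag(F[sel, sel])))
})

test_that("standing model with infinite standing time reduces to independent", {
  rec <- fx_recovery()
  F <- rec$Fhat$F
  sel <- match(rec$caves, rownames(F))
  st <- model_covariance("standing", F, sel, 2000,
                         list(s = 0.1, t_st = 1e9, g = 1e-3), ne = 1e4)
  ind <- model_covariance("independent", F, sel, 2000,
                          list(s = 0.1, t_st = 5), ne = 1e4)
  expect_equal(st, ind, tolerance = 1e-8)
})

test_that("composite likelihood equals a brute-force MVN oracle to 1e-8", {
  rec <- fx_recovery()
  panel <- rec$study$panel
  sel <- match(rec$caves, panel$pops$pop)
  svar <- 0.05
  Fd <- rec$Fhat$F
  diag(Fd) <- diag(Fd) - svar  # drift part; sampling variance re-added below
  st <- standardize_freqs(panel, rec$study$neutral_idx[1:10])
  X <- st$X[, 1:8, drop = FALSE]
  pos <- panel$sites$pos[st$idx][1:8]
  prop <- pos[4] + 100
  Q <- mean_contrast_basis(6)
  for (mod in c("neutral", "independent", "standing", "migration")) {
    params <- list(s = 0.01, t_st = 100, g = 1e-2, m = 1e-3)
    ll <- composite_loglik(X, pos, prop, mod, params, Fd, sel,
                           ne = 1e4, svar = svar)
    oracle <- 0
    for (j in 1:8) {
      Sig <- model_covariance(mod, Fd, sel, abs(pos[j] - prop), params,
                              ne = 1e4, svar = svar)
      oracle <- oracle + oracle_mvn_loglik(t(Q) %*% X[, j],
                                           t(Q) %*% Sig %*% Q)
    }
    expect_equal(ll, oracle, tolerance = 1e-8)
    # compiled kernel agrees with the R reference
    combos <- matrix(c(params$s, params$t_st, params$g, params$m), 1)
    llc <- repadapt:::cpp_dmc_grid(
      t(Q) %*% X, pos, prop, Fd, Q, sel - 1L, sel - 1L, sel[1] - 1L,
      c(neutral = 0L, independent = 1L, standing = 2L, migration = 3L)[[mod]],
      combos, 1e4, 1.16e-8, rep(svar, 6))
    expect_equal(as.numeric(llc), ll, tolerance = 1e-6)
  }
})

test_that("composite likelihood is additive over sites", {
  rec <- fx_recovery()
  F <- rec$Fhat$F
  panel <- rec$study$panel
  sel <- match(rec$caves, panel$pops$pop)
  st <- standardize_freqs(panel, rec$study$neutral_idx[21:24])
  X <- st$X; pos <- panel$sites$pos[st$idx]
  params <- list(s = 0.01, t_st = 50, g = 1e-3, m = 1e-4)
  ll_all <- composite_loglik(X, pos, pos[1], "standing", params, F, sel,
                             ne = 1e4, svar = 0.05)
  ll_dup <- composite_loglik(cbind(X, X[, 2]), c(pos, pos[2]), pos[1],
                             "standing", params, F, sel, ne = 1e4,
                             svar = 0.05)
  ll_one <- composite_loglik(X[, 2, drop = FALSE], pos[2], pos[1],
                             "standing", params, F, sel, ne = 1e4,
                             svar = 0.05)
  expect_equal(ll_dup, ll_all + ll_one, tolerance = 1e-8)
})

test_that("neutral-panel data favours the neutral model in expectation", {
  rec <- fx_recovery()
  study <- rec$study
  neutral_regions <- which(study$modes == "neutral")[1:10]
  caves <- rec$caves
  wins <- 0
  for (i in neutral_regions) {
    fit <- dmc_fit(study$panel, study$annotation$genes$gene_id[i],
                   study$annotation, rec$Fhat, caves,
                   model_set = c("independent", "standing", "migration"),
                   ne = study$config$ancestral_ne,
                   rec_rate = study$config$recombination_rate,
                   grids = dmc_grids(study$config$ancestral_ne))
    wins <- wins + (fit$best_model == "neutral")
  }
  expect_gte(wins, 8)
})

test_that("proposed sites are evenly spaced and oversized genes are skipped", {
  rec <- fx_recovery()
  fit <- rec$fits[[1]]
  expect_equal(fit$span, c(rec$study$annotation$genes$start[1] - 10000,
                           rec$study$annotation$genes$end[1] + 10000))
  big <- rec$study$annotation
  big$genes$end[1] <- big$genes$start[1] + 500000
  expect_message(
    out <- dmc_fit(rec$study$panel, big$genes$gene_id[1], big, rec$Fhat,
                   rec$caves, ne = 1e4),
    "skipped")
  expect_null(out)
})

test_that("site classification respects feature priority and strand", {
  models <- make_gene_models(200000)
  g <- models$genes[1, ]  # plus strand, span [10000, 20000)
  expect_equal(classify_selected_site(g$start + 1000, g$gene_id, models), "CDS")
  expect_equal(classify_selected_site(g$start + 100, g$gene_id, models), "UTR5")
  expect_equal(classify_selected_site(g$start + 9900, g$gene_id, models), "UTR3")
  expect_equal(classify_selected_site(g$start + 3000, g$gene_id, models), "intron")
  expect_equal(classify_selected_site(g$start - 5000, g$gene_id, models),
               "upstream10k")
  expect_equal(classify_selected_site(g$end + 5000, g$gene_id, models),
               "downstream10k")
  g2 <- models$genes[2, ]  # minus strand
  expect_equal(classify_selected_site(g2$end + 5000, g2$gene_id, models),
               "upstream10k")
  expect_error(classify_selected_site(g$end + 50000, g$gene_id, models))
})

test_that("mode summaries reproduce printed count arithmetic", {
  s <- summarize_mode_assignments(
    rep(c("independent", "standing", "migration"), c(304, 404, 52)))
  expect_equal(s$percent[match(c("standing", "independent", "migration"),
                               s$model)], c(53, 40, 7))
  expect_equal(sum(s$count), 760)
  s2 <- summarize_mode_assignments(
    rep(c("standing", "independent", "migration"), c(163, 3, 6)))
  expect_equal(s2$percent[match(c("standing", "independent", "migration"),
                                s2$model)], c(95, 2, 3))
  expect_equal(summarize_mode_assignments("standing")$percent, 100)
})
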