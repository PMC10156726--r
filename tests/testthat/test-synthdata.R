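test_that("config validation rejects degenerate inputs", {
  expect_error(demography_config(snp_count = 0))
  expect_error(demography_config(ancestral_ne = -1))
  expect_error(scenario_truth("r", "standing", 100, 0, 1000,
                              selected_pops = "cave1a", s = -0.1))
  expect_error(scenario_truth("r", "migration", 5000, 0, 1000,
                              selected_pops = "cave1a", s = 0.1))
})

test_that("zero branch lengths give every population the ancestral frequency", {
  cfg <- demography_config(snp_count = 500, chrom_length = 100000,
                           t_root_lineage = 0, t_lineage_pop = 0, seed = 3)
  sim <- simulate_neutral_panel(cfg)
  for (j in seq_len(nrow(sim$panel$freq)))
    expect_equal(unname(sim$panel$freq[j, ]), sim$ancestral)
})

test_that("panels are deterministic under a fixed seed", {
  cfg <- demography_config(snp_count = 400, chrom_length = 80000, seed = 11)
  a <- simulate_neutral_panel(cfg, haplotypes = TRUE)
  b <- simulate_neutral_panel(cfg, haplotypes = TRUE)
  expect_identical(a$panel$freq, b$panel$freq)
  expect_identical(a$panel$sites, b$panel$sites)
  expect_identical(a$haplotypes, b$haplotypes)
})

test_that("frequencies stay in [0,1] with no NaN, positions increase", {
  p <- fx_panel()$panel
  expect_false(anyNA(p$freq))
  expect_true(all(p$freq >= 0 & p$freq <= 1))
  expect_true(!is.unsorted(p$sites$pos, strictly = TRUE))
})

test_that("shared drift makes within-lineage covariance exceed between", {
  cfg <- demography_config(snp_count = 6000, chrom_length = 900000,
                           ancestral_ne = 1000, branch_ne = 1000,
                           t_root_lineage = 200, t_lineage_pop = 200,
                           seed = 21)
  sim <- simulate_neutral_panel(cfg)
  st <- standardize_freqs(sim$panel)
  F <- cov(t(st$X))
  within <- c(F[1, 2], F[1, 3], F[2, 3], F[4, 5], F[4, 6], F[5, 6])
  between <- as.vector(F[1:3, 4:6])
  expect_gt(mean(within), mean(between))
})

test_that("neutral windowed Fst is lower within than between lineages", {
  p <- fx_panel()$panel
  w <- windowed_stats(p, window_bp = 50000)
  within <- c(w$fst_cave1a.cave1b, w$fst_cave2a.cave2b)
  between <- c(w$fst_cave1a.cave2a, w$fst_cave1a.cave2b,
               w$fst_cave1b.cave2a, w$fst_cave1b.cave2b)
  expect_lt(mean(within, na.rm = TRUE), mean(between, na.rm = TRUE))
})

test_that("neutral scenario leaves the panel untouched", {
  sim <- fx_panel()
  cfg <- demography_config(snp_count = 3000, chrom_length = 450000, seed = 101)
  tr <- scenario_truth("r0", "neutral", 100, 0, 450000)
  expect_identical(implant_sweep(sim$panel, tr, cfg)$freq, sim$panel$freq)
})

test_that("sweep surgery fixes the selected site and reduces diversity", {
  cfg <- demography_config(snp_count = 3000, chrom_length = 450000, seed = 101)
  sim <- simulate_neutral_panel(cfg)
  caves <- sim$panel$pops$pop[sim$panel$pops$ecotype == "cave"]
  tr <- scenario_truth("r1", "migration", 225000, 200000, 250000,
                       selected_pops = caves, s = 0.1,
                       source_pop = caves[1], seed = 9)
  p2 <- implant_sweep(sim$panel, tr, cfg)
  pos <- p2$sites$pos
  sel_site <- which.min(abs(pos - 225000))
  ci <- match(caves, p2$pops$pop)
  # retention probability 1 at r = 0: every selected pop at 1 - eps
  expect_equal(unname(p2$freq[ci, sel_site]), rep(0.99, 4))
  expect_equal(sweep_retention(0, 0.1, 1e4), 1)
  # unselected populations untouched
  si <- which(p2$pops$ecotype == "surface")
  expect_identical(p2$freq[si, ], sim$panel$freq[si, ])
  # pi collapses inside the swept window relative to the neutral panel
  inw <- which(pos >= 200000 & pos < 250000)
  expect_lt(mean(site_pi(p2$freq[ci[1], inw], 20)),
            0.25 * mean(site_pi(sim$panel$freq[ci[1], inw], 20)))
  expect_error(implant_sweep(sim$panel,
    scenario_truth("bad", "independent", 225000, 200000, 250000,
                   selected_pops = caves, s = 1), cfg), NA)
})

test_that("shared-haplotype sweeps correlate cave frequency changes more than independent ones", {
  cfg <- demography_config(snp_count = 600, chrom_length = 90000, seed = 31)
  base <- simulate_neutral_panel(cfg)$panel
  cor_for <- function(scenario, seed) {
    tr <- scenario_truth("r", scenario, 45000, 20000, 70000,
                         selected_pops = c("cave1a", "cave2a"), s = 0.1,
                         t_standing = 50,
                         source_pop = "cave1a", seed = seed)
    p2 <- implant_sweep(base, tr, cfg)
    inw <- which(p2$sites$pos >= 20000 & p2$sites$pos < 70000)
    d1 <- p2$freq[2, inw] - base$freq[2, inw]
    d2 <- p2$freq[5, inw] - base$freq[5, inw]
    suppressWarnings(cor(d1, d2))
  }
  seeds <- 1:200
  mig <- vapply(seeds, function(s) cor_for("migration", s), numeric(1))
  ind <- vapply(seeds, function(s) cor_for("independent", s), numeric(1))
  expect_gt(mean(mig, na.rm = TRUE), mean(ind, na.rm = TRUE) + 0.2)
})

test_that("implanted regions lose within-population diversity on average", {
  rec <- fx_recovery()
  study <- rec$study
  pos <- study$panel$sites$pos
  reg_of <- floor((pos - 1) / 50000) + 1
  swept <- study$modes[reg_of] != "neutral"
  cave1 <- study$panel$freq[2, ]
  pi_all <- site_pi(cave1, 20)
  expect_lt(mean(pi_all[swept]), 0.5 * mean(pi_all[!swept]))
})

test_that("finite-sample step preserves frequencies in expectation", {
  p <- fx_panel()$panel
  ps <- sample_panel_freqs(p, seed = 4)
  bound <- 4 * sqrt(p$freq * (1 - p$freq) / p$n) + 1e-12
  expect_gt(mean(abs(ps$freq - p$freq) <= bound), 0.995)
  expect_lt(max(abs(ps$freq - p$freq)), 0.5)
  expect_lt(abs(mean(ps$freq) - mean(p$freq)), 0.01)
})
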