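# Shared fixtures, built once per test run and memoized. Everything is
# generated in code under fixed seeds; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# small neutral panel for unit tests
fx_panel <- function() fixture("panel", function() {
  cfg <- demography_config(snp_count = 3000, chrom_length = 450000, seed = 101)
  simulate_neutral_panel(cfg)
})

# tiny hand-built panel: 6 pops x 8 sites with known frequencies
fx_tiny_panel <- function() fixture("tiny", function() {
  pops <- data.frame(
    pop = c("surface1", "cave1a", "cave1b", "surface2", "cave2a", "cave2b"),
    ecotype = c("surface", "cave", "cave", "surface", "cave", "cave"),
    lineage = c(1, 1, 1, 2, 2, 2), stringsAsFactors = FALSE)
  freq <- matrix(seq(0.05, 0.95, length.out = 48), nrow = 6)
  n <- matrix(20L, 6, 8)
  af_panel(freq, n, pops,
           data.frame(chrom = "chr1", pos = seq(1000, 8000, by = 1000)))
})

# study panel with implanted regions of every mode (shared by the DMC and
# eigen-scan recovery checks); sizes chosen for the validation suite
fx_recovery <- function() fixture("recovery", function() {
  modes <- c(rep("independent", 50), rep("standing", 50),
             rep("migration", 50), rep("neutral", 30))
  study <- simulate_study_panel(modes, seed = 2024)
  caves <- study$panel$pops$pop[study$panel$pops$ecotype == "cave"]
  Fhat <- estimate_neutral_F(study$panel, study$neutral_idx)
  sel_regions <- which(modes != "neutral")
  fits <- lapply(sel_regions, function(i)
    dmc_fit(study$panel, study$annotation$genes$gene_id[i],
            study$annotation, Fhat, caves,
            model_set = c("independent", "standing", "migration"),
            ne = study$config$ancestral_ne,
            rec_rate = study$config$recombination_rate,
            grids = dmc_grids(study$config$ancestral_ne)))
  list(study = study, Fhat = Fhat, caves = caves,
       truth = modes[sel_regions],
       called = vapply(fits, `[[`, character(1), "best_model"),
       fits = fits)
})

fx_eigen_scan <- function() fixture("eigen_scan", function() {
  modes <- c(rep("migration", 50), rep("locus", 50), rep("neutral", 20))
  study <- simulate_study_panel(modes, seed = 515)
  design <- panel_design(study$panel)
  scan <- reuse_scan(study$panel, design, n_snps = 50, n_perm = 2000,
                     seed = 99)
  # classification of the window containing each region centre
  centre_call <- vapply(seq_along(modes), function(i) {
    ctr <- study$region_centers[i]
    w <- which(scan$start <= ctr & scan$end >= ctr)
    if (length(w)) scan$classification[w[1]] else NA_character_
  }, character(1))
  list(study = study, design = design, scan = scan,
       centre_call = centre_call, modes = modes)
})

# fully neutral panel for scan calibration
fx_neutral_scan <- function() fixture("neutral_scan", function() {
  cfg <- demography_config(snp_count = 100000, chrom_length = 15000000,
                           seed = 77)
  panel <- sample_panel_freqs(simulate_neutral_panel(cfg)$panel, seed = 78)
  design <- panel_design(panel)
  scan <- reuse_scan(panel, design, n_snps = 50, n_perm = 10000, seed = 79)
  list(panel = panel, design = design, scan = scan)
})

# emitted fixture set on disk (temp dir), shared by io/pipeline tests
fx_fixture_dir <- function() fixture("fixture_dir", function() {
  modes <- c("migration", "neutral", "independent", rep("neutral", 5))
  study <- simulate_study_panel(modes, seed = 321)
  outdir <- file.path(tempdir(), "repadapt_fixture")
  paths <- emit_fixture_set(study$panel, study$truths, study$config,
                            outdir, seed = 5)
  list(study = study, paths = paths, outdir = outdir)
})

# independently coded multivariate-normal log density (test oracle)
oracle_mvn_loglik <- function(x, sigma) {
  ev <- eigen(sigma, symmetric = TRUE)
  stopifnot(all(ev$values > 0))
  z <- t(ev$vectors) %*% x
  -0.5 * (length(x) * log(2 * pi) + sum(log(ev$values)) +
            sum(z^2 / ev$values))
}
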