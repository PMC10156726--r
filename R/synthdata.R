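#' Demography configuration for the synthetic panel
#'
#' Describes a two-lineage population tree: an ancestral population splits
#' into two lineages, and each lineage splits into one surface population and
#' one or more cave populations. Defaults give a desk-scale panel whose
#' shared-drift covariance structure (stronger within than between lineages)
#' matches what the downstream scans assume.
#'
#' @param n_caves_per_lineage caves per lineage (>= 1).
#' @param sample_size diploid individuals sampled per population.
#' @param snp_count number of biallelic SNPs.
#' @param chrom_length chromosome length in bp.
#' @param ancestral_ne diploid effective size of the ancestral population.
#' @param branch_ne diploid effective size along every descendant branch
#'   (a single value; per-branch drift scales as t / (2 Ne)).
#' @param t_root_lineage generations on each root -> lineage branch.
#' @param t_lineage_pop generations on each lineage -> population branch.
#' @param recombination_rate Morgans per bp (default 1.16e-8, i.e. 1.16 cM/Mb).
#' @param mutation_rate per-bp per-generation mutation rate (default 3.5e-9).
#' @param exact_wf if `TRUE`, drift is simulated generation by generation with
#'   binomial Wright-Fisher sampling (2*Ne draws per generation); the default
#'   uses a single variance-matched Gaussian step per branch
#'   (variance x(1-x) t / (2 Ne), truncated to `[0, 1]`).
#' @param seed integer seed for the panel.
#' @return A list of class `demography_config`.
#' @export
demography_config <- function(n_caves_per_lineage = 2,
                              sample_size = 10,
                              snp_count = 20000,
                              chrom_length = 3e6,
                              ancestral_ne = 10000,
                              branch_ne = ancestral_ne,
                              t_root_lineage = 2000,
                              t_lineage_pop = 1000,
                              recombination_rate = 1.16e-8,
                              mutation_rate = 3.5e-9,
                              exact_wf = FALSE,
                              seed = 1L) {
  stopifnot(
    n_caves_per_lineage >= 1, sample_size > 0, snp_count > 0,
    chrom_length > 0, ancestral_ne > 0, branch_ne > 0,
    t_root_lineage >= 0, t_lineage_pop >= 0,
    recombination_rate >= 0, mutation_rate >= 0
  )
  structure(list(
    n_caves_per_lineage = as.integer(n_caves_per_lineage),
    sample_size = as.integer(sample_size),
    snp_count = as.integer(snp_count),
    chrom_length = as.integer(chrom_length),
    ancestral_ne = ancestral_ne,
    branch_ne = branch_ne,
    t_root_lineage = t_root_lineage,
    t_lineage_pop = t_lineage_pop,
    recombination_rate = recombination_rate,
    mutation_rate = mutation_rate,
    exact_wf = isTRUE(exact_wf),
    seed = as.integer(seed)
  ), class = "demography_config")
}

#' Truth record for one implanted scenario
#'
#' @param region_id identifier for the genomic region the scenario occupies.
#' @param scenario one of `"neutral"`, `"independent"`, `"standing"`,
#'   `"migration"`.
#' @param selected_position bp position of the selected site (must lie inside
#'   `[region_start, region_end)`).
#' @param region_start,region_end region span in bp (0-based half-open);
#'   frequency surgery is confined to this span.
#' @param selected_pops character vector of selected population labels.
#' @param s selection coefficient (> 0 for non-neutral scenarios).
#' @param t_standing generations the allele stood before selection
#'   (standing scenario).
#' @param g frequency of the standing variant (standing scenario; recorded
#'   for truth tables, the surgery itself conditions on the drawn haplotype).
#' @param source_pop origin population of the shared haplotype (migration).
#' @param seed integer seed for this region's surgery.
#' @return A list of class `scenario_truth`.
#' @export
scenario_truth <- function(region_id, scenario, selected_position,
                           region_start, region_end,
                           selected_pops = character(),
                           s = NA_real_, t_standing = NA_real_, g = NA_real_,
                           source_pop = NA_character_, seed = 1L) {
  scenario <- match.arg(scenario, c("neutral", "independent", "standing", "migration"))
  if (scenario != "neutral") {
    if (!is.finite(s) || s <= 0) stop("non-neutral scenario requires s > 0")
    if (!length(selected_pops)) stop("non-neutral scenario requires selected_pops")
    if (selected_position < region_start || selected_position >= region_end)
      stop("selected_position must lie inside the region")
  }
  if (scenario == "standing" && (!is.finite(t_standing) || t_standing < 0))
    stop("standing scenario requires t_standing >= 0")
  if (scenario == "migration" && is.na(source_pop))
    source_pop <- selected_pops[1L]
  structure(list(
    region_id = region_id, scenario = scenario,
    selected_position = selected_position,
    region_start = region_start, region_end = region_end,
    selected_pops = selected_pops, s = s, t_standing = t_standing, g = g,
    source_pop = source_pop, seed = as.integer(seed)
  ), class = "scenario_truth")
}

# One Gaussian (or exact binomial WF) drift step down a branch, vectorised
# over sites. Truncation to [0,1] is the stated diffusion shortcut.
drift_step <- function(x, t, ne, exact = FALSE) {
  if (t == 0) return(x)
  if (exact) {
    n2 <- round(2 * ne)
    for (i in seq_len(t)) x <- stats::rbinom(length(x), n2, x) / n2
    return(x)
  }
  v <- x * (1 - x) * t / (2 * ne)
  pmin(pmax(x + stats::rnorm(length(x), 0, sqrt(v)), 0), 1)
}

#' Simulate a neutral multi-population SNP panel
#'
#' Ancestral frequencies are drawn uniformly on `[0.05, 0.95]` per SNP and
#' evolved down the two-lineage tree by Wright-Fisher drift (Gaussian
#' diffusion step per branch by default, exact per-generation binomial when
#' `config$exact_wf`). Haplotypes, when requested, are independent Bernoulli
#' draws given the population frequency; linkage arises only inside swept
#' regions after [implant_sweep()], where frequencies collapse to the
#' sweeping haplotype's allele states.
#'
#' @param config a [demography_config()].
#' @param haplotypes if `TRUE` also return a per-population haplotype matrix.
#' @return A list with `panel` (an [af_panel()]), `ancestral` (the ancestral
#'   frequency per SNP), and `haplotypes` (list of 2*sample_size x snp 0/1
#'   matrices per population, or `NULL`).
#' @export
simulate_neutral_panel <- function(config, haplotypes = FALSE) {
  stopifnot(inherits(config, "demography_config"))
  if (config$snp_count < 1) stop("snp_count must be positive")
  set.seed(config$seed)
  S <- config$snp_count
  pos <- sort(sample.int(config$chrom_length - 1L, S)) # strictly increasing
  p_anc <- stats::runif(S, 0.05, 0.95)

  nc <- config$n_caves_per_lineage
  pops <- do.call(rbind, lapply(1:2, function(l) {
    data.frame(
      pop = c(sprintf("surface%d", l), sprintf("cave%d%s", l, letters[seq_len(nc)])),
      ecotype = c("surface", rep("cave", nc)),
      lineage = l,
      stringsAsFactors = FALSE
    )
  }))

  freq <- matrix(NA_real_, nrow(pops), S)
  for (l in 1:2) {
    p_lin <- drift_step(p_anc, config$t_root_lineage, config$branch_ne,
                        config$exact_wf)
    for (j in which(pops$lineage == l)) {
      freq[j, ] <- drift_step(p_lin, config$t_lineage_pop, config$branch_ne,
                              config$exact_wf)
    }
  }
  n_hap <- matrix(2L * config$sample_size, nrow(pops), S)
  panel <- af_panel(freq, n_hap,
                    pops, data.frame(chrom = "chr1", pos = pos,
                                     stringsAsFactors = FALSE))
  attr(panel, "ancestral") <- p_anc
  haps <- NULL
  if (haplotypes) {
    haps <- lapply(seq_len(nrow(pops)), function(j) {
      matrix(stats::rbinom(2L * config$sample_size * S, 1L,
                           rep(freq[j, ], each = 2L * config$sample_size)),
             nrow = 2L * config$sample_size)
    })
    names(haps) <- pops$pop
  }
  list(panel = panel, ancestral = p_anc, haplotypes = haps)
}

#' Replace population frequencies by finite-sample estimates
#'
#' Draws, for every population and site, a binomial sample of the panel's
#' haploid size and replaces the frequency by the sample estimate. This
#' emulates panels computed from a finite number of sequenced individuals
#' (the situation every real resequencing study is in) and is applied after
#' any [implant_sweep()] calls.
#'
#' @param panel an [af_panel()].
#' @param seed integer seed.
#' @return The panel with sampled frequencies.
#' @export
sample_panel_freqs <- function(panel, seed = 1L) {
  set.seed(seed)
  for (j in seq_len(nrow(panel$freq))) {
    ok <- !is.na(panel$freq[j, ])
    n <- panel$n[j, ok]
    panel$freq[j, ok] <- stats::rbinom(sum(ok), n, panel$freq[j, ok]) / n
  }
  panel
}

#' Hitchhiking retention probability
#'
#' Probability that a neutral lineage at recombination distance `r` (Morgans)
#' from a selected site stays associated with the sweeping background through
#' a sweep of duration `tau = log(4 Ne s) / s` generations:
#' `y(r) = exp(-r * tau)`.
#'
#' @param r_bp distance from the selected site in bp (>= 0).
#' @param s selection coefficient (> 0).
#' @param ne diploid effective population size.
#' @param rec_rate recombination rate in Morgans/bp.
#' @return Retention probability in `[0, 1]`.
#' @export
sweep_retention <- function(r_bp, s, ne, rec_rate = 1.16e-8) {
  if (any(s <= 0)) stop("s must be > 0")
  if (any(r_bp < 0)) stop("r_bp must be >= 0")
  tau <- log(4 * ne * s) / s
  exp(-r_bp * rec_rate * tau)
}

#' Implant a convergent sweep of known mode
#'
#' Deterministic frequency surgery: the beneficial allele is set to frequency
#' `1 - eps` at the selected site in every selected population, and each
#' flanking SNP within the truth's region is replaced, with probability
#' `y(r) = exp(-r * tau)` (see [sweep_retention()]), by the allele state of
#' the sweeping haplotype. Haplotype origin encodes the mode: independent
#' draws one haplotype per selected population (at its own pre-sweep
#' frequency); migration shares a single haplotype drawn at the source
#' population's pre-sweep frequency; standing shares a haplotype drawn at
#' the ancestral frequency (the variant stood in the common ancestral
#' population), and each flanking replacement must additionally survive
#' `t_standing` generations of recombination (probability
#' `exp(-r * t_standing)`), otherwise an independent draw is used.
#' Unselected populations are untouched.
#'
#' @param panel an [af_panel()].
#' @param truth a [scenario_truth()].
#' @param config the [demography_config()] used to build the panel (supplies
#'   Ne and the recombination rate).
#' @param eps final frequency shortfall of the beneficial allele (default
#'   0.01, so swept sites stay polymorphic and pass MAF filters).
#' @return The modified `af_panel`.
#' @export
implant_sweep <- function(panel, truth, config, eps = 0.01) {
  stopifnot(inherits(panel, "af_panel"), inherits(truth, "scenario_truth"))
  if (truth$scenario == "neutral") return(panel)
  sel <- pop_index(panel, truth$selected_pops)
  set.seed(truth$seed)

  pos <- panel$sites$pos
  in_region <- which(pos >= truth$region_start & pos < truth$region_end)
  if (!length(in_region)) return(panel)
  sel_site <- in_region[which.min(abs(pos[in_region] - truth$selected_position))]
  r_bp <- abs(pos[in_region] - pos[sel_site])
  y <- sweep_retention(r_bp, truth$s, config$ancestral_ne,
                       config$recombination_rate)

  pre <- panel$freq[, in_region, drop = FALSE]
  anc <- attr(panel, "ancestral")
  origin_freq <- if (truth$scenario == "migration") {
    pre[pop_index(panel, truth$source_pop), ]
  } else if (!is.null(anc)) {
    anc[in_region]  # standing: the variant stood in the ancestral population
  } else {
    pre[sel[1L], ]
  }
  shared <- stats::rbinom(length(in_region), 1L, origin_freq)

  for (j in sel) {
    replaced <- stats::rbinom(length(in_region), 1L, y) == 1L
    hap <- switch(truth$scenario,
      independent = stats::rbinom(length(in_region), 1L, pre[j, ]),
      migration = shared,
      standing = {
        survive <- stats::rbinom(length(in_region), 1L,
                                 exp(-r_bp * config$recombination_rate *
                                       truth$t_standing)) == 1L
        ifelse(survive, shared, stats::rbinom(length(in_region), 1L, pre[j, ]))
      })
    newf <- panel$freq[j, in_region]
    newf[replaced] <- hap[replaced]
    newf[which(in_region == sel_site)] <- 1 - eps
    panel$freq[j, in_region] <- newf
  }
  panel
}
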