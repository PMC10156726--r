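---
title: "Detecting and classifying repeated adaptation with repadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying repeated adaptation with repadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When replicate populations colonize the same novel environment — the
motivating system is cave-dwelling fish populations derived from surface
stock along two independent lineages — the same traits often evolve
repeatedly. Three genetic routes can produce that repetition at a locus:
selection on **standing variation** already segregating in the shared
ancestral population, **migration** spreading a single adaptive allele
between populations, and **independent de novo mutations** at the same gene.
The first two reuse the same allele ("allele reuse"); the third reuses only
the locus ("locus reuse"). `repadapt` implements, as one tested toolchain,
the statistics that separate these situations:

1. site filters and windowed summary statistics (&pi;, D~xy~, Hudson F~ST~);
2. dating identities (D~xy~ = 2&mu;T for allele splits; T~admix~ =
   1/(L~M~&middot;p~B~) for admixture tracts) and the ABBA-BABA D statistic;
3. sweep-intersection logic over per-population 5-kb sweep-classification
   tables (cave-adaptive alleles, overlapping sweeps);
4. an eigen-decomposition scan of allele-frequency-change vectors across
   replicate surface&rarr;cave pairs (allele reuse vs locus reuse);
5. composite-likelihood discrimination of convergence modes against a
   coancestry null (neutral / independent / standing / migration / two mixed
   models);
6. downstream enrichment, gene-length, sweep-age, and convergent
   motif-loss tests.

A synthetic-data module generates multi-population SNP panels with the
shared-drift covariance structure these analyses assume and implants sweeps
of known mode, so every stage can be validated end to end against truth.

## The coancestry null and the convergence-mode models

Allele frequencies at a site are standardized,
$x_j = (p_j - \bar p)/\sqrt{\bar p (1-\bar p)}$, and their covariance across
populations at putatively neutral sites (intergenic, thinned) is the
coancestry matrix $F$: shared drift makes same-lineage populations covary.
Because the $x_j$ sum to zero across populations, all densities are
evaluated in the $(k-1)$-dimensional subspace orthogonal to the ones vector
(`mean_contrast_basis()`).

A sweep at recombination distance $r$ Morgans from a focal site retains the
sweeping haplotype with probability $y(r) = e^{-r\tau}$, where
$\tau = \log(4N_e s)/s$ generations is the sweep duration. A swept
population's frequency is then a single haplotype's allele state with
probability $y$, which inflates its variance and — when the haplotype is
shared — the covariance between selected populations:

* **independent**: each population draws its own background;
  $D_{ii} = y$, no pair term.
* **standing** (origin: the ancestral population): survival of the standing
  phase attenuates sharing, $q = e^{-r t_{st}}$;
  $D_{ii} = y(1 - qF_{ii})$, $D_{ij} = q^2(1-g)\,y^2(1 - F_{ij})$, and
  coancestry with unselected populations is pulled toward zero
  ($D_{iu} = -yqF_{iu}$).
* **migration** (origin: the source population $o$): sharing is complete up
  to recombination during the migrant's arrival delay,
  $w = e^{-2r/(4N_e m)}$; $D_{ii} = y(1-F_{ii})$,
  $D_{ij} = w\,y^2(1-F_{ij})$, and selected populations inherit the
  source's coancestry with everyone else
  ($D_{iu} = y(F_{ou} - F_{iu})$).
* the two **mixed** models apply the shared-mode terms within a designated
  subgroup (by default the first lineage with two selected populations) and
  the independent diagonal elsewhere.

Three points about these forms deserve emphasis. First, they are mixture
*moments*; the composite likelihood treats each site as Gaussian with that
covariance, so the model can dip slightly below positive semi-definite at
extreme sharing — such matrices are eigenvalue-clipped (floor `1e-4`)
rather than rejected, because rejection would silently censor the
high-sharing region of the parameter grid. Second, the binomial sampling
variance of the frequency estimates (about $1/n$ per population in
standardized units, taken from the panel's haploid counts) rides on the
diagonal of every model and is correspondingly subtracted from the
estimated $F$ diagonal; without it the full-sharing corner is degenerate
and the likelihood is dominated by a handful of discordant sites. Third,
the origin's own drift variance is deliberately excluded from the diagonal
and pair terms so that standing and migration differ in *decay shape* and
*origin coancestry* rather than overall scale — per-site standardization
distorts scale far more than shape.

The standing model reduces to the independent model as
$t_{st} \to \infty$, and every model reduces to $F$ as $y \to 0$; both
limits are asserted by the test suite, and the composite likelihood is
checked to $10^{-8}$ against an independently coded multivariate-normal
density.

### Standardization at candidate windows

Inside a swept window the pooled mean frequency is dragged toward the
selected haplotype. The centering (a linear operation) is modelled exactly
by the subspace projection, but a dragged *denominator* is not, so
candidate windows are standardized with the unselected populations' mean in
the denominator (sweep-robust; identical in expectation at neutral sites)
and sites whose unselected-mean falls outside [0.1, 0.9] are excluded —
extreme standardization weights otherwise dominate the likelihood.

### Fitting and model choice

`dmc_fit()` grid-searches models &times; parameter combinations &times; 50
evenly spaced proposed sites across the gene &plusmn; 10 kb. Default grids:
$s \in \{10^{-4},10^{-3},10^{-2},10^{-1}\}$,
$t_{st} \in \{5,10,25,50,100,500,1000\}$ generations,
$g \in \{1/2N_e,10^{-3},10^{-2},10^{-1}\}$,
$m \in \{10^{-5},10^{-4},10^{-3},10^{-2}\}$ per generation. The best model
maximizes the penalized maximum composite log likelihood, one log unit per
live parameter (neutral 0; independent 1; migration and mixed-migration 2;
standing and mixed-standing 3). The penalty is the working form of "ties
resolve toward the simpler model": at full sharing the standing model's
$t_{st}$ grid minimum is numerically almost indistinguishable from
migration, so exact-tie breaking alone would be vacuous. The standing time
does not enter the independent model's covariance (each sweep draws its own
background), so its MCLE sits at the grid minimum of 5 generations by
construction — the degenerate "5.00 &plusmn; 0.00" signature expected when
independent-mode data are summarized under that model. Genes longer than
400 kb are skipped with a message. The selected-site position is classified
against the annotation (CDS &gt; UTR &gt; intron inside the span;
strand-aware `upstream10k`/`downstream10k` outside).

## The eigen reuse scan

For each non-overlapping window of 50 SNPs, row $j$ of the matrix $A$ is
replicate $j$'s cave-minus-surface frequency-change vector, normalized to
unit length; the spectrum of $C = AA^\top$ ($\sum\lambda_i = k$) summarizes
how many directions of repeated change the replicates share. Significance
uses cumulative eigenvalue sums against a permutation null: each of 10,000
permutations assembles a pseudo-window of 50 SNPs drawn uniformly
genome-wide (destroying linkage, preserving the marginal distribution), and
windows above the 99th percentile are significant.

Classification: *allele reuse* needs a significant leading eigenvalue with
every replicate loading non-negligibly (|loading| &gt; 0.05) and with a
common sign, and no lineage split; *locus reuse* needs the joint m = 2
statistic significant (a flag switches to the eigenvector-2 increment
alone) and the replicates to split by lineage; mixed signs without a
lineage split are *antiparallel*; significant two-dimensional structure
without a lineage split is *divergent*. The lineage split is tested
rotation-invariantly in the top-2 eigenspace with
$\sqrt\lambda$-scaled coordinates: near-equal leading eigenvalues make the
individual eigenvectors arbitrary rotations of the lineage blocks, and
unscaled directions would let a negligible eigenvector-2 contrast (always
present, because same-lineage replicates share a surface population)
override a dominant shared axis. Classification is invariant to replicate
order and to reference/alternate allele flips, which negate columns of $A$
and leave $C$ unchanged.

## What the synthetic generator does and does not emulate

`simulate_neutral_panel()` draws ancestral frequencies uniformly on
[0.05, 0.95] and evolves them down a two-lineage tree (root &rarr; lineage
&rarr; populations) with a single variance-matched Gaussian step per branch
(variance $x(1-x)t/2N_e$, truncated; exact generation-by-generation
binomial sampling is available via `exact_wf`). Defaults — two lineages
&times; (1 surface + 2 caves), 10 diploids per population, $N_e$ = 10,000,
2,000 generations to each lineage ancestor and 1,000 more to each
population, ~1 SNP per 150 bp — were chosen once as a desk-scale regime
with clearly measurable shared drift (within-lineage coancestry &asymp;
0.03–0.04) and realistic teleost-like SNP density. The recombination rate
(1.16 cM/Mb) and mutation rate (3.5&times;10^-9^) defaults are the focal
system's published estimates.

`implant_sweep()` performs deterministic frequency surgery rather than
forward simulation — the point is exact control of mode and hitchhiking
decay for parameter-recovery tests. The beneficial allele is set to
1 &minus; 0.01 at the selected site (so it stays polymorphic and passes MAF
filters); each flanking SNP inside the truth's region is replaced by the
sweeping haplotype's allele state with probability $y(r)$; the haplotype is
drawn per population (independent), shared from the source population
(migration), or shared from the ancestral frequency with per-population
survival $e^{-rt_{st}}$ (standing). `sample_panel_freqs()` then replaces
population frequencies by binomial sample estimates, matching the study
condition that panels come from finitely many sequenced individuals.

What passing tests therefore show: the scan and the model fit recover the
implanted mode under the generator's own hitchhiking geometry, with
realistic drift structure and sampling noise. What they do not show:
robustness to coalescent linkage disequilibrium, demographic
misspecification, background selection, sequencing error, or unmodeled
gene flow — none of which the generator produces. The fixture README
written by `emit_fixture_set()` repeats this caveat next to the data.

## Other analysis conventions

* Filters run in the stated order: biallelic &rarr; per-population
  missingness &le; 20% &rarr; pooled MAF &ge; 1% &rarr; removal of sites
  where every called sample in some population is heterozygous (collapsed
  paralogs). Each site counts against the first rule that removes it.
* F~ST~ is Hudson's estimator with sample-size correction, aggregated as a
  ratio of sums within windows; missing frequencies are excluded pairwise.
* Intervals are 0-based half-open internally; conversion happens only at
  the GFF3/BED/VCF boundary.
* Sweep-table intersection treats `skipped` windows as evidence-neutral,
  and "no sweep in surface" admits linked classes.
* The QTL permutation test resamples gene sets of equal size (not shifted
  intervals); a degenerate null (sd = 0) reports Z as missing and
  p = 1/(n~perm~+1).
* Percentages round to the nearest whole percent, half away from zero.
* The D statistic uses a 500-SNP block jackknife.
* Phenotype categories attach by case-insensitive substring match of
  keywords against GO term names; multi-assignment is allowed.

## Validation problem sizes

The test suite and the reproduction script run the full recovery design at
50 regions per mode (s = 0.1, standing time 500 generations, 50-kb regions,
12-kb genes), an eigen-scan fixture with 50 shared-haplotype and 50
per-lineage ("locus-reuse") regions, and a fully neutral 100,000-SNP panel
(2,000 windows, 10,000 permutations) for calibration. These sizes keep a
complete run in minutes on one core while leaving the Monte-Carlo error of
each asserted rate well inside its tolerance.

## Known limitations

* The composite likelihood treats sites as independent; with real linkage
  the likelihood surface is overconfident, which is why model choice is
  reported as a label rather than with likelihood-ratio calibration.
* The mode models are approximate mixture moments under a stylized sweep;
  parameters ($t_{st}$, $m$, $g$, $s$) are grid MCLEs useful for ranking
  models, not calibrated estimates with intervals.
* The migration model designates a single source population; inference
  about *which* population was the source is outside scope.
* Locus-reuse classification needs lineage labels and at least one
  replicate pair per lineage; without them the scan degrades to
  allele-reuse/antiparallel calls with a warning.
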