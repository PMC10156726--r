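# Small hand-built sweep table: 5-kb windows over two genes
mk_sweeps <- function(classes_by_pop) {
  do.call(rbind, lapply(names(classes_by_pop), function(p) {
    cls <- classes_by_pop[[p]]
    data.frame(chrom = "chr1", start = (seq_along(cls) - 1) * 5000,
               end = seq_along(cls) * 5000, pop = p, class = cls,
               stringsAsFactors = FALSE)
  }))
}

mk_models <- function() gene_models(data.frame(
  gene_id = c("g1", "g2"), chrom = "chr1", start = c(1000, 11000),
  end = c(4000, 14000), strand = "+", transcript_length = c(3000L, 2400L),
  cds_length = c(2000L, 1500L), exon_count = c(3L, 2L),
  isoform_count = c(1L, 2L)))

test_that("cave-adaptive rule requires a sweep in cave and none in surface", {
  models <- mk_models()
  sw <- mk_sweeps(list(
    cave = c("soft", "neutral", "hardLinked", "neutral"),
    surface = c("neutral", "neutral", "neutral", "neutral")))
  expect_equal(cave_adaptive_genes(sw, models, "cave", "surface"), "g1")
  # linked is not a sweep
  sw2 <- mk_sweeps(list(cave = c("hardLinked", "neutral", "soft", "neutral"),
                        surface = rep("neutral", 4)))
  expect_equal(cave_adaptive_genes(sw2, models, "cave", "surface"), "g2")
  # a surface sweep vetoes
  sw3 <- mk_sweeps(list(cave = c("hard", "neutral", "hard", "neutral"),
                        surface = c("soft", "neutral", "softLinked", "neutral")))
  expect_equal(cave_adaptive_genes(sw3, models, "cave", "surface"), "g2")
  # skipped windows are evidence-neutral
  sw4 <- mk_sweeps(list(cave = c("hard", "skipped", "skipped", "neutral"),
                        surface = c("skipped", "neutral", "neutral", "neutral")))
  expect_equal(cave_adaptive_genes(sw4, models, "cave", "surface"), "g1")
  expect_error(cave_adaptive_genes(sw, models, "cave", "surface",
                                   lineages = c(cave = 1, surface = 2)))
})

test_that("overlapping sweeps require the rule for every cave against every surface", {
  models <- mk_models()
  sw <- mk_sweeps(list(
    caveA = c("hard", "neutral", "soft", "neutral"),
    caveB = c("soft", "neutral", "soft", "neutral"),
    caveC = c("hard", "neutral", "neutral", "neutral"),
    surf1 = rep("neutral", 4),
    surf2 = c("neutral", "neutral", "softLinked", "neutral")))
  out <- overlapping_sweeps(sw, models, c("caveA", "caveB", "caveC"),
                            c("surf1", "surf2"))
  expect_equal(out, "g1")  # caveC lacks a sweep over g2; linked surface ok
  # set containment in each constituent pair
  for (cv in c("caveA", "caveB", "caveC")) for (sf in c("surf1", "surf2"))
    expect_true(all(out %in% cave_adaptive_genes(sw, models, cv, sf)))
})

test_that("keyword matching is case-insensitive substring with multi-assignment", {
  go <- data.frame(gene_id = c("g1", "g1", "g2", "g3"),
                   go_name = c("Melanosome transport", "DNA repair",
                               "eye morphogenesis", "cilium assembly"),
                   stringsAsFactors = FALSE)
  kw <- data.frame(category = c("pigmentation", "vision", "vision"),
                   keyword = c("melanosome", "eye", "repair"),
                   stringsAsFactors = FALSE)
  out <- assign_phenotype_categories(go, kw)
  expect_setequal(out$category[out$gene_id == "g1"],
                  c("pigmentation", "vision"))
  expect_equal(out$category[out$gene_id == "g2"], "vision")
  expect_false("g3" %in% out$gene_id)
  expect_error(assign_phenotype_categories(go, kw[0, ]))
})

test_that("QTL permutation handles degenerate and empty inputs", {
  models <- make_gene_models(500000)
  qtl_all <- data.frame(chrom = "chr1", start = 0, end = 500000)
  gs <- models$genes$gene_id[1:4]
  r <- qtl_overlap_permutation(gs, models, qtl_all, n_perm = 100, seed = 1)
  expect_equal(r$observed, 4L)
  expect_true(is.na(r$z))
  expect_equal(r$p, 1 / 101)
  empty <- qtl_overlap_permutation(gs, models, qtl_all[0, ], n_perm = 100)
  expect_equal(empty$observed, 0L)
  expect_equal(empty$p, 1)
  expect_error(qtl_overlap_permutation(c(gs, "nope"), models, qtl_all))
})

test_that("QTL permutation Z is calibrated for random sets", {
  models <- make_gene_models(2000000)  # 40 genes
  qtl <- data.frame(chrom = "chr1", start = c(0, 1200000),
                    end = c(450000, 1500000))
  set.seed(33)
  zs <- replicate(120, {
    gs <- sample(models$genes$gene_id, 10)
    qtl_overlap_permutation(gs, models, qtl, n_perm = 400,
                            seed = sample.int(1e6, 1))$z
  })
  expect_true(all(abs(zs) < 4, na.rm = TRUE))
  expect_lt(abs(mean(zs, na.rm = TRUE)), 0.5)
})

test_that("Fisher enrichment is exact hypergeometric with stable odds ratio", {
  r <- fisher_enrichment(2, 10, 22, 110)
  expect_equal(r$p, 1)
  expect_equal(unname(r$odds_ratio), 1, tolerance = 0.05)
  r2 <- fisher_enrichment(2 * 2, 2 * 10, 2 * 22, 2 * 110)
  expect_equal(unname(r2$odds_ratio), unname(r$odds_ratio), tolerance = 0.05)
  # complete separation: p from exact enumeration = 2 / C(20, 10)
  sep <- fisher_enrichment(10, 10, 10, 20)
  expect_equal(sep$p, 2 / choose(20, 10))
  expect_equal(unname(sep$odds_ratio), Inf)
  expect_error(fisher_enrichment(5, 4, 10, 100))
})

test_that("gene-structure comparison is a Welch test with the stated sign convention", {
  models <- mk_models()
  models$genes <- models$genes[rep(1:2, each = 30), ]
  models$genes$gene_id <- sprintf("g%03d", 1:60)
  set.seed(2)
  models$genes$transcript_length <- as.integer(
    c(rnorm(30, 4000, 300), rnorm(30, 3000, 300)))
  cand <- models$genes$gene_id[1:30]
  r <- length_comparison(cand, models, "transcript_length")
  expect_gt(r$t, 0)  # candidates longer
  or <- t.test(models$genes$transcript_length[1:30],
               models$genes$transcript_length[31:60])
  expect_equal(r$t, unname(or$statistic))
  expect_equal(r$df, unname(or$parameter))
  # Welch-Satterthwaite df oracle
  x <- models$genes$transcript_length[1:30]
  y <- models$genes$transcript_length[31:60]
  v1 <- var(x) / 30; v2 <- var(y) / 30
  expect_equal(r$df, (v1 + v2)^2 / (v1^2 / 29 + v2^2 / 29))
  # both groups constant -> no test
  expect_error(length_comparison(cand, models, "exon_count"), "variance")
})

test_that("sweep-age comparison matches the exact Kruskal-Wallis statistic", {
  r <- sweep_age_by_category(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))
  expect_equal(r$h, 3.857142857, tolerance = 1e-8)
  expect_equal(r$df, 1)
  expect_error(sweep_age_by_category(1:5, rep("a", 5)))
  # permuting labels of a separated instance destroys significance on average
  set.seed(11)
  p_perm <- replicate(50, {
    lab <- sample(rep(c("a", "b"), each = 3))
    sweep_age_by_category(c(1, 2, 3, 11, 12, 13), lab)$p
  })
  expect_gt(mean(p_perm), r$p)
})

test_that("Kruskal-Wallis p-values are uniform under the null", {
  set.seed(7)
  ps <- replicate(500, {
    ages <- rexp(30, 1e-5)
    sweep_age_by_category(ages, rep(c("a", "b", "c"), each = 10))$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("TFBS loss filter enforces exact boundary semantics and monotonicity", {
  mk_motif <- function(surf_frac, cave_frac, n = 10) {
    rows <- list()
    for (p in names(surf_frac))
      rows[[p]] <- data.frame(gene_id = "g1", flank = "upstream",
                              motif = "m1", pop = p,
                              genome = sprintf("%s_%02d", p, 1:n),
                              present = rep(c(1L, 0L),
                                            c(round(surf_frac[[p]] * n),
                                              n - round(surf_frac[[p]] * n))))
    for (p in names(cave_frac))
      rows[[p]] <- data.frame(gene_id = "g1", flank = "upstream",
                              motif = "m1", pop = p,
                              genome = sprintf("%s_%02d", p, 1:n),
                              present = rep(c(1L, 0L),
                                            c(round(cave_frac[[p]] * n),
                                              n - round(cave_frac[[p]] * n))))
    do.call(rbind, rows)
  }
  # clear loss
  t1 <- mk_motif(c(s1 = 1, s2 = 1), c(c1 = 0, c2 = 0))
  expect_equal(nrow(tfbs_loss_filter(t1, c("s1", "s2"), c("c1", "c2"))), 1L)
  # exactly 80% surface passes, exactly 20% cave fails
  t2 <- mk_motif(c(s1 = 0.8, s2 = 0.8), c(c1 = 0.2, c2 = 0))
  expect_equal(nrow(tfbs_loss_filter(t2, c("s1", "s2"), c("c1", "c2"))), 0L)
  t3 <- mk_motif(c(s1 = 0.8, s2 = 0.8), c(c1 = 0.1, c2 = 0))
  expect_equal(nrow(tfbs_loss_filter(t3, c("s1", "s2"), c("c1", "c2"))), 1L)
  # 79% in one surface population blocks the call
  t4 <- mk_motif(c(s1 = 0.7, s2 = 1), c(c1 = 0, c2 = 0))
  expect_equal(nrow(tfbs_loss_filter(t4, c("s1", "s2"), c("c1", "c2"))), 0L)
  # monotonicity: adding surface presence never removes a loss
  t5 <- t3
  t5$present[t5$pop == "s1"] <- 1L
  expect_equal(nrow(tfbs_loss_filter(t5, c("s1", "s2"), c("c1", "c2"))), 1L)
})

test_that("category count summaries reproduce printed means and fractions", {
  r <- summarize_category_counts(list(rascon = seq_len(739),
                                      mante = seq_len(1101)), 26698)
  expect_equal(r$mean_count, 920)
  expect_equal(r$mean_percent, 3)
  one <- summarize_category_counts(list(a = seq_len(42)), 100)
  expect_equal(one$mean_count, 42)
  frac <- summarize_category_counts(list(x = seq_len(6223)), 26698)
  expect_equal(frac$mean_percent, 23)
})
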