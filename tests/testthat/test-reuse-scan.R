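test_that("allele-frequency-change rows are unit-norm and scale-invariant", {
  p <- fx_tiny_panel()
  des <- panel_design(p)
  A <- af_change_matrix(p, des, 1:8)
  expect_equal(unname(sqrt(rowSums(A^2))), rep(1, 4), tolerance = 1e-12)
  # doubling every difference leaves A unchanged (normalization)
  p2 <- p
  si <- match(des$surface, p$pops$pop); ci <- match(des$cave, p$pops$pop)
  for (k in seq_len(4)) {
    d <- p$freq[ci[k], ] - p$freq[si[k], ]
    p2$freq[ci[k], ] <- pmin(pmax(p$freq[si[k], ] + 2 * d, 0), 1)
  }
  A2 <- af_change_matrix(p2, des, 1:8)
  expect_equal(A2, A, tolerance = 1e-12)
})

test_that("degenerate windows are flagged unusable", {
  p <- fx_tiny_panel()
  p$freq[2, ] <- p$freq[1, ]  # cave1a identical to its surface
  p$freq[3, ] <- p$freq[1, ]
  p$freq[5, ] <- p$freq[4, ]
  p$freq[6, ] <- p$freq[4, ]
  A <- af_change_matrix(p, panel_design(p), 1:8)
  expect_equal(nrow(A), 0L)
  expect_true(attr(A, "unusable"))
})

test_that("eigen decomposition matches block examples and conserves the trace", {
  u <- c(3, 4, 0) / 5
  e1 <- eigen_scan(rbind(u, u))
  expect_equal(e1$values, c(2, 0), tolerance = 1e-12)
  expect_true(all(e1$vectors[, 1] > 0))  # equal-sign loadings

  v <- c(0, 0, 1)
  e2 <- eigen_scan(rbind(u, v))
  expect_equal(e2$values, c(1, 1), tolerance = 1e-12)

  e3 <- eigen_scan(rbind(u, -u))
  expect_equal(e3$values, c(2, 0), tolerance = 1e-12)
  expect_lt(min(e3$vectors[, 1]) * max(e3$vectors[, 1]), 0)  # opposite signs

  # trace conservation on random unit-row matrices
  set.seed(5)
  for (i in 1:25) {
    M <- matrix(rnorm(4 * 50), 4)
    M <- M / sqrt(rowSums(M^2))
    expect_equal(sum(eigen_scan(M)$values), 4, tolerance = 1e-10)
  }
})

test_that("window classification follows the reuse taxonomy", {
  null_q <- c(1.5, 2.5, 3.2, 4)
  lineages <- c(1, 1, 2, 2)
  u <- rep(0.5, 4)
  allele <- eigen_scan(rbind(u, u, u, u) +
                         matrix(rnorm(16, 0, 1e-3), 4))
  expect_equal(classify_window(allele, null_q, lineages), "allele_reuse")

  a <- c(1, 0, 0, 0); b <- c(0, 1, 0, 0)
  locus <- eigen_scan(rbind(a, a, b, b) + matrix(rnorm(16, 0, 1e-3), 4))
  expect_equal(classify_window(locus, null_q, lineages), "locus_reuse")

  anti <- eigen_scan(rbind(u, -u, u, -u)[c(1, 3, 2, 4), ] +
                       matrix(rnorm(16, 0, 1e-3), 4))
  expect_equal(classify_window(anti, null_q, lineages), "antiparallel")

  # everything below its null quantile: none
  low <- list(values = c(1.2, 0.9, 0.9, 1), vectors = diag(4))
  expect_equal(classify_window(low, c(2, 3, 3.5, 4), lineages), "none")

  # no lineage labels: locus reuse unavailable
  expect_warning(classify_window(locus, null_q, NULL), "lineage")
})

test_that("classification is invariant to replicate order and allele flips", {
  rec <- fx_eigen_scan()
  study <- rec$study
  design <- rec$design
  scan <- rec$scan
  sig <- which(scan$classification != "none")[1:5]
  flip_panel <- study$panel
  set.seed(42)
  flip_sites <- sample(ncol(flip_panel$freq), ncol(flip_panel$freq) %/% 2)
  flip_panel$freq[, flip_sites] <- 1 - flip_panel$freq[, flip_sites]
  perm <- c(3, 1, 4, 2)
  design_perm <- replicate_design(design$surface[perm], design$cave[perm],
                                  design$lineage[perm])

  ok <- !colSums(is.na(study$panel$freq))
  eligible <- which(ok)
  for (w in sig) {
    idx <- eligible[which(study$panel$sites$pos[eligible] >= scan$start[w] &
                            study$panel$sites$pos[eligible] <= scan$end[w])][1:50]
    base <- classify_window(eigen_scan(af_change_matrix(study$panel, design, idx)),
                            attr(scan, "null_q"), design$lineage)
    flip <- classify_window(eigen_scan(af_change_matrix(flip_panel, design, idx)),
                            attr(scan, "null_q"), design$lineage)
    reord <- classify_window(eigen_scan(af_change_matrix(study$panel, design_perm, idx)),
                             attr(scan, "null_q"), design_perm$lineage)
    expect_equal(flip, base)
    expect_equal(reord, base)
  }
})

test_that("permutation null conserves the trace and is seed-reproducible", {
  p <- fx_panel()$panel
  des <- panel_design(p)
  n1 <- null_distribution(p, des, n_snps = 50, n_perm = 300, seed = 5)
  n2 <- null_distribution(p, des, n_snps = 50, n_perm = 300, seed = 5)
  expect_identical(n1$cum, n2$cum)
  expect_equal(unname(n1$cum[, 4]), rep(4, nrow(n1$cum)), tolerance = 1e-10)
  expect_equal(unname(n1$q[4]), 4, tolerance = 1e-10)
})

test_that("significant windows map to overlapping genes with multi-labels", {
  scan <- data.frame(
    chrom = "chr1", start = c(1000, 6000, 20000), end = c(5000, 9000, 24000),
    n_snps = 50, classification = c("allele_reuse", "locus_reuse", "none"),
    stringsAsFactors = FALSE)
  class(scan) <- c("reuse_scan", "data.frame")
  models <- gene_models(data.frame(
    gene_id = c("gBoth", "gNone", "gB"), chrom = "chr1",
    start = c(500, 30000, 6500), end = c(8000, 31000, 7000), strand = "+",
    transcript_length = 1L, cds_length = 1L, exon_count = 1L,
    isoform_count = 1L))
  out <- windows_to_genes(scan, models)
  both <- out$classification[out$gene_id == "gBoth"]
  expect_setequal(both, c("allele_reuse", "locus_reuse"))
  expect_false("gNone" %in% out$gene_id)
  expect_true(all(out$classification != "none"))
  # window overlapping two genes lists both
  expect_setequal(out$gene_id[out$classification == "locus_reuse"],
                  c("gBoth", "gB"))
})
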