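test_that("count_in_peaks sums raw strand-matched bin counts", {
  tr_p <- mk_track(c(3, 4, 5, 7, 0), strand = "+")
  tr_m <- mk_track(c(1, 1, 1, 1, 1), strand = "-")
  trks <- list(s1 = list("+" = tr_p, "-" = tr_m))
  pk <- GRanges("chr1", IRanges(1, 300), strand = "+")
  mcols(pk)$peak_id <- "p1"
  expect_equal(unname(count_in_peaks(pk, trks)[1, 1]), 12L)

  expect_equal(nrow(count_in_peaks(GRanges(), trks)), 0L)

  trks2 <- list(s1 = list("+" = mk_track(2 * c(3, 4, 5, 7, 0), strand = "+"),
                          "-" = tr_m))
  expect_equal(unname(count_in_peaks(pk, trks2)[1, 1]), 24L)

  # unstranded peak sums both strands
  pk2 <- GRanges("chr1", IRanges(1, 300), strand = "*")
  mcols(pk2)$peak_id <- "p2"
  expect_equal(unname(count_in_peaks(pk2, trks)[1, 1]), 15L)

  bad <- GRanges("chr1", IRanges(400, 900), strand = "+")
  expect_error(count_in_peaks(bad, trks), "past end")
})

test_that("median-of-ratios size factors match the hand computation", {
  counts <- matrix(c(10, 100, 20, 200), 2, 2)
  sf <- size_factors(counts)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  same <- matrix(rep(c(5, 50, 500), 3), 3, 3)
  expect_equal(unname(size_factors(same)), rep(1, 3))

  set.seed(8)
  for (i in 1:10) {
    m <- matrix(rnbinom(60, mu = 100, size = 2) + 1, 20, 3)
    c_scale <- 3
    m2 <- m; m2[, 2] <- m2[, 2] * c_scale
    r <- size_factors(m2) / size_factors(m)
    # scaling one column by c scales its factor by c (up to renorm)
    expect_equal(unname(r[2] / exp(mean(log(r)))),
                 c_scale / c_scale^(1 / 3) / 1, tolerance = 1e-9)
  }
})

test_that("dispersion estimation has the right limits", {
  conds <- rep(c("a", "b"), each = 2)
  set.seed(15)
  pois <- matrix(rpois(4000 * 4, lambda = 500), ncol = 4)
  d <- estimate_dispersion(pois, rep(1, 4), conds)
  expect_lte(median(d$alpha), 0.01)

  nb <- matrix(rnbinom(4000 * 4, mu = 1000, size = 1 / 0.2), ncol = 4)
  d2 <- estimate_dispersion(nb, rep(1, 4), conds)
  expect_gte(median(d2$alpha), 0.1)
  expect_lte(median(d2$alpha), 0.4)

  const <- matrix(50, 10, 4)
  d3 <- estimate_dispersion(const, rep(1, 4), conds)
  expect_true(all(d3$alpha_mom == 0))

  expect_error(estimate_dispersion(pois[, 1:3], rep(1, 3),
                                   c("a", "a", "b")), "replicates")
})

test_that("the Wald fit is exactly symmetric under equal group means", {
  counts <- matrix(c(10, 20, 14, 16), 1, 4)  # both condition means 15
  res <- nb_wald_test(counts, rep(1, 4), 1e-12,
                      rep(c("a", "b"), each = 2))
  expect_equal(res$log2FC, 0, tolerance = 1e-8)
})

test_that("planted effects are recovered without bias", {
  set.seed(33)
  n <- 2000
  mu <- exp(runif(n, log(300), log(800)))
  eff <- sample(c(-1, 1), n, TRUE)
  conds <- rep(c("control", "depleted"), each = 2)
  cnt <- vapply(seq_len(4), function(j) {
    m <- if (conds[j] == "depleted") mu * 2^eff else mu
    rnbinom(n, mu = m, size = 1 / 0.05)
  }, numeric(n))
  sf <- size_factors(cnt)
  d <- estimate_dispersion(cnt, sf, conds)
  r <- nb_wald_test(cnt, sf, d$alpha, conds, reference = "control")
  expect_lt(abs(mean(r$log2FC[eff == 1]) - 1), 0.1)
  expect_lt(abs(mean(r$log2FC[eff == -1]) + 1), 0.1)
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(12)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))^2
    got <- bh_adjust(p)
    expect_equal(got, p.adjust(p, "BH"))  # independent oracle
    expect_true(all(got >= p - 1e-12))    # 1-ulp float slack at rank m
    o <- order(p)
    expect_true(all(diff(got[o]) >= -1e-12))
  }
  p_na <- c(0.01, NA, 0.5)
  got <- bh_adjust(p_na)
  expect_true(is.na(got[2]))
  expect_equal(got[c(1, 3)], p.adjust(p_na[c(1, 3)], "BH"))
})

test_that("gain/loss calls follow the padj and fold-change gates", {
  res <- data.frame(log2FC = log2(c(1.30, 0.70, 3.0, 1.30)),
                    pvalue = c(0.001, 0.001, 0.5, 0.5))
  res$padj <- c(0.05, 0.05, 0.20, 0.20)
  out <- call_diff_peaks(res)
  expect_equal(out$call, c("gain", "loss", "nochange", "nochange"))
  # boundary: FC exactly 1.25 is not a gain
  res2 <- data.frame(log2FC = log2(1.25), pvalue = 0.001, padj = 0.01)
  expect_equal(call_diff_peaks(res2)$call, "nochange")
})

test_that("gene classification applies the 5:1 and 5 kb rules", {
  expect_equal(classify_tallies(6L, 1L), "RLG")
  expect_equal(classify_tallies(5L, 1L), "RLG")
  expect_equal(classify_tallies(4L, 1L), "mixed")
  expect_equal(classify_tallies(1L, 6L), "RLL")
  expect_equal(classify_tallies(0L, 0L), "none")
  expect_equal(classify_tallies(1L, 0L), "RLG")
  expect_equal(classify_tallies(2L, 2L), "mixed")

  genes <- GRanges("chr1", IRanges(c(1e4, 5e4), width = c(4000, 6000)),
                   strand = "+")
  mcols(genes)$gene_id <- c("short", "long")
  pk <- GRanges("chr1", IRanges(c(1.1e4, 5.1e4), width = 500),
                strand = "+")
  mcols(pk)$call <- c("gain", "gain")
  cls <- classify_genes(pk, genes)
  expect_false("short" %in% cls$gene_id)  # < 5 kb eliminated
  expect_equal(cls$class[cls$gene_id == "long"], "RLG")

  # strand-aware assignment: a peak on the opposite strand never counts
  pk_op <- GRanges("chr1", IRanges(5.1e4, width = 500), strand = "-")
  mcols(pk_op)$call <- "gain"
  cls2 <- classify_genes(pk_op, genes)
  expect_equal(cls2$class[cls2$gene_id == "long"], "none")
})

test_that("RNA-seq DE calls use the 1.5-fold / padj 0.05 gates", {
  sim <- small_sim()
  cnt <- simulate_expression_counts(sim)
  res <- rnaseq_de(cnt, attr(cnt, "conditions"), reference = "control")
  truth <- setNames(rep(0, nrow(cnt)), rownames(cnt))
  truth[sim$de_genes$gene_id] <- sim$de_genes$log2fc
  # planted 2-fold genes are mostly detected in the right direction
  up <- names(truth)[truth > 0]
  if (length(up) >= 2) expect_gte(mean(res[up, "call"] == "up"), 0.5)
  # nearly all null genes stay nochange
  null_g <- names(truth)[truth == 0]
  expect_gte(mean(res[null_g, "call"] == "nochange"), 0.9)
})

test_that("chromosome density versus gain/loss ratio behaves", {
  genes <- GRanges(rep(paste0("chr", 1:4), each = 10),
                   IRanges(seq(1e4, by = 2e4, length.out = 40),
                           width = 1e4))
  mcols(genes)$gene_id <- sprintf("g%02d", 1:40)
  cs <- setNames(c(4e6, 2e6, 1e6, 5e5), paste0("chr", 1:4))
  # denser chromosomes lose more (ratio falls with density)
  cl <- data.frame(gene_id = genes$gene_id,
                   class = rep(c("RLG", "RLL"), c(6, 4)))
  cl$class <- c(rep("RLG", 6), rep("RLL", 4),   # chr1: ratio 1.5
                rep("RLG", 5), rep("RLL", 5),   # chr2: 1.0
                rep("RLG", 4), rep("RLL", 6),   # chr3: 0.67
                rep("RLG", 2), rep("RLL", 8))   # chr4: 0.25
  out <- chromosome_gain_loss_ratio(cl, genes, cs)
  expect_lt(out$r, 0)
  # joint permutation of chromosome labels leaves r unchanged
  perm <- c(chr1 = "chrB", chr2 = "chrA", chr3 = "chrD", chr4 = "chrC")
  genes2 <- GRanges(perm[as.character(seqnames(genes))], ranges(genes))
  mcols(genes2)$gene_id <- genes$gene_id
  cs2 <- setNames(cs, perm[names(cs)])
  out2 <- chromosome_gain_loss_ratio(cl, genes2, cs2)
  expect_equal(out2$r, out$r, tolerance = 1e-12)

  cl_flat <- cl; cl_flat$class <- rep(c("RLG", "RLL"), 20)
  cs_flat <- setNames(rep(1e6, 4), paste0("chr", 1:4))
  genes_flat <- genes
  # identical densities and ratios: zero variance is an error
  expect_error(chromosome_gain_loss_ratio(cl_flat, genes_flat, cs_flat),
               "variance|RLL")
})
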