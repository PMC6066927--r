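# A tiny annotated world for matching tests: two genes plus peaks.
mk_annotated <- function() {
  genes <- GRanges("chr1", IRanges(c(1e5, 5e5, 9e5), width = c(5e4, 5.2e4, 5e4)),
                   strand = "+")
  mcols(genes)$gene_id <- c("t", "c_ok", "c_far")
  mcols(genes)$expression <- c(10, 11, 200)
  pk <- GRanges("chr1", IRanges(c(1e5 - 500, 5e5 - 500, 9e5 - 500),
                                width = 1500), strand = "+")
  peaks <- annotate_peak_compartments(pk, genes)
  list(genes = genes, peaks = peaks)
}

test_that("matching honours compartment and log2 tolerances", {
  w <- mk_annotated()
  tg <- w$peaks[1]
  cand <- w$peaks[2:3]
  mcs <- suppressWarnings(select_matched_controls(
    tg, cand, n_matches = 1L, genes = w$genes, seed = 1))
  # the 52 kb / 11-unit gene is within tolerance; the 200-unit gene is not
  expect_equal(mcols(mcs$controls)$gene_id, "c_ok")
  # every emitted control satisfies the tolerances actually used
  expect_lte(abs(log2(mcols(mcs$controls)$gene_length /
                        mcols(mcs$targets)$gene_length)),
             0.5 * 2^mcs$relaxed[1])
  # determinism
  mcs2 <- suppressWarnings(select_matched_controls(
    tg, cand, n_matches = 1L, genes = w$genes, seed = 1))
  expect_identical(as.data.frame(mcs$controls),
                   as.data.frame(mcs2$controls))
})

test_that("matching validity holds on the default dataset", {
  dm <- default_matched()
  for (mcs in list(dm$rlg, dm$rll)) {
    tol <- mcs$tol
    ti <- mcols(mcs$controls)$target_idx
    f <- 2^mcs$relaxed[ti]
    expect_true(all(abs(log2(mcols(mcs$controls)$gene_length /
                               mcols(mcs$targets)$gene_length[ti])) <=
                      tol[["len"]] * f + 1e-9))
    expect_true(all(abs(log2(mcols(mcs$controls)$gene_expression /
                               mcols(mcs$targets)$gene_expression[ti])) <=
                      tol[["expr"]] * f + 1e-9))
    expect_true(all(mcols(mcs$controls)$compartment ==
                      mcols(mcs$targets)$compartment[ti]))
    # controls come from unaffected genes only
    cls <- setNames(dm$sim$genes$class, dm$sim$genes$gene_id)
    expect_true(all(cls[mcols(mcs$controls)$gene_id] %in%
                      c("none", "mixed")))
  }
})

test_that("promoter controls keep the target's anchor offset", {
  dm <- default_matched()
  mcs <- dm$rll
  prom <- which(mcols(mcs$targets)$compartment == "promoter")[1]
  ctl <- mcs$controls[mcols(mcs$controls)$target_idx == prom]
  genes <- dm$sim$genes
  tssm <- setNames(gene_tss(genes), genes$gene_id)
  dirm <- setNames(ifelse(as.character(strand(genes)) == "-", -1L, 1L),
                   genes$gene_id)
  gid <- mcols(ctl)$gene_id
  p5 <- ifelse(dirm[gid] > 0, start(ctl), end(ctl))
  offs <- dirm[gid] * (p5 - tssm[gid])
  expect_true(all(offs == mcols(mcs$targets)$anchor_offset[prom]))
})

test_that("overlap enrichment handles saturation and planted separation", {
  set.seed(4)
  tg <- mk_rand_peaks(100, 1e6)
  ctl <- mk_rand_peaks(1000, 1e6)
  mcs <- mk_mcs(tg, ctl, 10L)
  whole <- GRanges("chr1", IRanges(1, 1e6))
  e <- overlap_enrichment(mcs, whole, n_mc = 249, seed = 1)
  expect_equal(e$observed, 1)
  expect_equal(e$expected, 1)
  expect_equal(e$ratio, 1)
  expect_equal(e$p, 1)
  expect_equal(e$stars, "***")

  # targets inside the feature, controls never: p attains the 1/125 floor
  tg2 <- GRanges("chr1", IRanges(seq(1e5, 2e5, length.out = 50), width = 100))
  ctl2 <- GRanges("chr1", IRanges(rep(seq(5e5, 6e5, length.out = 100), 5),
                                  width = 100))
  e2 <- overlap_enrichment(mk_mcs(tg2, ctl2, 10L),
                           GRanges("chr1", IRanges(1e5, 2.1e5)),
                           n_mc = 124, seed = 1)
  expect_gt(e2$ratio, 1)
  expect_equal(e2$p_enrich, 1 / 125)

  # star classes follow the absolute observed overlap
  tg3 <- mk_rand_peaks(100, 1e6)
  feat3 <- reduce(GRanges("chr1", IRanges(start(tg3)[1:30], width = 50)))
  e3 <- overlap_enrichment(mk_mcs(tg3, ctl, 10L), feat3, n_mc = 49,
                           seed = 2)
  expect_equal(e3$stars, "**")  # observed 0.30 sits in the 25-50% class

  e4 <- overlap_enrichment(mcs, GRanges(), n_mc = 49, seed = 1)
  expect_true(is.na(e4$ratio))
  expect_match(e4$flag, "empty")
})

test_that("distance_to_nearest equals the brute-force oracle", {
  pk <- GRanges("chr1", IRanges(101, 200))
  feat <- GRanges("chr1", IRanges(301, 400))
  expect_equal(distance_to_nearest(pk, feat), 100)
  expect_equal(distance_to_nearest(pk, GRanges("chr1", IRanges(150, 160))), 0)
  expect_equal(distance_to_nearest(pk, GRanges("chr2", IRanges(1, 10))), Inf)

  set.seed(19)
  for (rep_i in 1:5) {
    pk <- mk_rand_peaks(200, 1e6, width = sample(100:2000, 1))
    ft <- reduce(mk_rand_peaks(40, 1e6, width = sample(100:5000, 1)))
    got <- distance_to_nearest(pk, ft)
    oracle <- vapply(seq_along(pk), function(i) {
      d <- pmax(pmax(start(ft) - end(pk)[i], start(pk)[i] - end(ft)) - 1, 0)
      min(d)
    }, 0)
    expect_equal(got, oracle)
  }
})

test_that("Mann-Whitney matches exact enumeration and is symmetric", {
  r <- compare_distance_sets(c(1, 2, 3), c(10, 20, 30))
  expect_equal(r$p, 0.1)
  expect_equal(r$method, "exact")

  same <- compare_distance_sets(1:20, 1:20)
  expect_equal(same$p, 1)

  a <- c(5, 1, 9, 13); b <- c(2, 8, 20)
  expect_equal(compare_distance_sets(a, b)$p,
               compare_distance_sets(b, a)$p)

  # oracle: stats::wilcox.test exact p on tie-free small samples
  set.seed(6)
  for (i in 1:10) {
    a <- sample(1000, sample(4:8, 1))
    b <- sample(2000:3000, sample(4:8, 1))
    ours <- compare_distance_sets(a, b)
    ref <- wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
  # large samples: normal approximation close to the reference
  a <- rlnorm(60, 10, 1); b <- rlnorm(80, 10.4, 1)
  ours <- compare_distance_sets(a, b)
  ref <- wilcox.test(a, b, correct = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 0.02)
})

test_that("equal-occupancy binning and its correlation behave", {
  set.seed(30)
  fc <- rnorm(100)
  b <- foldchange_bins(fc, fc, n_bins = 10)
  expect_true(all(b$bins$n == 10))
  expect_equal(b$r, 1)

  b2 <- foldchange_bins(rnorm(103), rnorm(103), n_bins = 10)
  expect_lte(diff(range(b2$bins$n)), 1)

  expect_error(foldchange_bins(rep(1, 50), rnorm(50), 5), "constant")

  # planted association: gains live on long genes
  sim <- default_sim()
  pk <- sim$peaks
  glen <- setNames(width(sim$genes), sim$genes$gene_id)
  set.seed(31)
  fc <- pk$planted_log2fc + rnorm(length(pk), 0, 0.2)
  fb <- foldchange_bins(fc, unname(glen[pk$gene_id]), n_bins = 10,
                        ids = pk$peak_id)
  expect_gt(fb$r, 0)
})

test_that("replication phase assignment uses argmax with early ties", {
  cs <- c(chr1 = 10000L)
  mk_phase <- function(v) binned_track(list(chr1 = v), 1000L, cs)
  zero <- rep(0, 10)
  tracks <- list(G1b = mk_phase(c(5, zero[-1])), S1 = mk_phase(zero),
                 S2 = mk_phase(zero), S3 = mk_phase(zero),
                 S4 = mk_phase(zero), G2 = mk_phase(zero))
  pk <- GRanges("chr1", IRanges(c(1, 5001), width = 500))
  out <- repliseq_phase_assignment(pk, tracks)
  expect_equal(as.character(out$phase[1]), "G1b")
  expect_true(is.na(out$phase[2]))
  expect_equal(out$n_unassigned, 1L)

  tie <- list(G1b = mk_phase(zero), S1 = mk_phase(rep(2, 10)),
              S2 = mk_phase(zero), S3 = mk_phase(rep(2, 10)),
              S4 = mk_phase(zero), G2 = mk_phase(zero))
  out2 <- repliseq_phase_assignment(pk[1], tie)
  expect_equal(as.character(out2$phase[1]), "S1")
})

test_that("origin-proximal loss peaks replicate earlier than controls", {
  dm <- default_matched()
  rs <- simulate_repliseq(dm$sim)
  rs <- normalize_depth(rs)
  out <- repliseq_phase_assignment(dm$rll$targets, rs, mcs = dm$rll,
                                   n_mc = 99, seed = 3)
  expect_gt(out$distribution[["G1b"]], out$expected[["G1b"]])
})
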