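test_that("metagene peak density counts bins per gene category", {
  genes <- GRanges("chr1", IRanges(c(10001, 100001), width = c(8000, 40000)),
                   strand = "+")
  mcols(genes)$gene_id <- c("a", "b")
  # one peak spanning gene a entirely
  pk <- GRanges("chr1", IRanges(9000, 19000), strand = "+")
  mg <- metagene_peak_density(pk, genes, length_breaks = c(0, 2e4, Inf))
  expect_equal(mg[["[0,2e+04)"]]$density, rep(1, 40))
  expect_equal(sum(mg[["[2e+04,Inf]"]]$density), 0)

  up <- GRanges("chr1", IRanges(1, 500), strand = "+")
  mg2 <- metagene_peak_density(up, genes, length_breaks = c(0, Inf))
  expect_equal(sum(mg2[[1]]$density), 0)

  # strand-flip: a peak at the 3' end of a minus gene mirrors the plus case
  gplus <- GRanges("chr1", IRanges(10001, 50000), strand = "+")
  mcols(gplus)$gene_id <- "p"
  gminus <- GRanges("chr1", IRanges(10001, 50000), strand = "-")
  mcols(gminus)$gene_id <- "m"
  pk3p <- GRanges("chr1", IRanges(48001, 50000), strand = "+")  # 3' of plus
  pk3m <- GRanges("chr1", IRanges(10001, 12000), strand = "-")  # 3' of minus
  a <- metagene_peak_density(pk3p, gplus, c(0, Inf))[[1]]$density
  b <- metagene_peak_density(pk3m, gminus, c(0, Inf))[[1]]$density
  expect_equal(a, b)
  expect_gt(sum(a[36:40]), 0)
  expect_equal(sum(a[1:30]), 0)
})

test_that("signal metaplots summarize anchored windows strand-awarely", {
  genes <- GRanges("chr1", IRanges(c(50001, 150001), width = 20000),
                   strand = "+")
  mcols(genes)$gene_id <- c("a", "b")
  uni <- list("+" = mk_track(rep(1, 3000), strand = "+"),
              "-" = mk_track(rep(1, 3000), strand = "-"))
  mp <- signal_metaplot(uni, genes, anchor = "TSS", window = 10e3)
  expect_true(all(mp$summary == 1))
  expect_true(all(mp$spread == 0))

  # genes on minus strand, signal only on plus, template mode: zero profile
  gm <- GRanges("chr1", IRanges(50001, width = 20000), strand = "-")
  mcols(gm)$gene_id <- "m"
  hot <- list("+" = mk_track(rep(5, 3000), strand = "+"),
              "-" = mk_track(rep(0, 3000), strand = "-"))
  mp2 <- signal_metaplot(hot, gm, anchor = "TSS", window = 10e3,
                         strand_mode = "template")
  expect_true(all(mp2$summary == 0))
  mp3 <- signal_metaplot(hot, gm, anchor = "TSS", window = 10e3,
                         strand_mode = "nontemplate")
  expect_true(all(mp3$summary == 5))

  # median of identical genes equals the single-gene profile
  g5 <- rep(GRanges("chr1", IRanges(50001, width = 20000), strand = "+"), 5)
  mcols(g5)$gene_id <- letters[1:5]
  set.seed(2)
  ramp <- list("+" = mk_track(runif(3000), strand = "+"),
               "-" = mk_track(rep(0, 3000), strand = "-"))
  m5 <- signal_metaplot(ramp, g5, anchor = "TSS", window = 10e3)
  m1 <- signal_metaplot(ramp, g5[1], anchor = "TSS", window = 10e3)
  expect_equal(m5$summary, m1$summary)

  # off-chromosome windows are skipped and counted
  edge <- GRanges("chr1", IRanges(1000, width = 5000), strand = "+")
  mcols(edge)$gene_id <- "e"
  mpe <- signal_metaplot(uni, edge, anchor = "TSS", window = 10e3)
  expect_equal(attr(mpe, "n_skipped"), 1L)
})

test_that("strand-flip invariance: mirrored genome, identical profiles", {
  sim <- small_sim()
  L <- sim$chrom_sizes[[1]]
  trks <- simulate_coverage(sim, "depleted", 1)
  genes <- sim$genes
  # mirror: reverse coordinates, swap strands, reverse tracks
  mirror_gr <- function(gr) {
    out <- GRanges(seqnames(gr), IRanges(L - end(gr) + 1, L - start(gr) + 1),
                   strand = ifelse(as.character(strand(gr)) == "+", "-",
                                   ifelse(as.character(strand(gr)) == "-",
                                          "+", "*")))
    mcols(out) <- mcols(gr)
    out
  }
  mirror_track <- function(tr, new_strand) {
    tr$values$chr1 <- rev(tr$values$chr1)
    tr$mask$chr1 <- rev(tr$mask$chr1)
    tr$strand <- new_strand
    tr
  }
  m_trks <- list("+" = mirror_track(trks[["-"]], "+"),
                 "-" = mirror_track(trks[["+"]], "-"))
  m_genes <- mirror_gr(genes)

  mp <- signal_metaplot(trks, genes, anchor = "TSS", window = 10e3,
                        strand_mode = "template")
  m_mp <- signal_metaplot(m_trks, m_genes, anchor = "TSS", window = 10e3,
                          strand_mode = "template")
  expect_equal(m_mp$summary, mp$summary)

  mg <- metagene_peak_density(sim$peaks, genes, c(0, 2e4, Inf))
  m_mg <- metagene_peak_density(mirror_gr(sim$peaks), m_genes,
                                c(0, 2e4, Inf))
  for (nm in names(mg)) expect_equal(m_mg[[nm]]$density, mg[[nm]]$density)
})

test_that("LAD boundary promoter density respects sign and orientation", {
  lads <- GRanges("chr1", IRanges(100001, 200000))
  # TSS at the start boundary transcribing away from the interior (left)
  g_away <- GRanges("chr1", IRanges(50001, 100001), strand = "-")
  mcols(g_away)$gene_id <- "away"
  out <- lad_boundary_promoter_density(g_away, lads, window = 50e3,
                                       binsize = 5e3)
  ctr_bin <- which(out$away$position > -5e3 & out$away$position < 5e3)
  expect_gt(sum(out$away$density[ctr_bin]), 0)
  expect_equal(sum(out$toward$density), 0)

  # gene inside the LAD transcribing deeper: toward, negative position
  g_in <- GRanges("chr1", IRanges(120001, 140000), strand = "+")
  mcols(g_in)$gene_id <- "in"
  out2 <- lad_boundary_promoter_density(g_in, lads, window = 50e3,
                                        binsize = 5e3)
  expect_equal(sum(out2$away$density), 0)
  expect_gt(sum(out2$toward$density[out2$toward$position < 0]), 0)

  expect_error(lad_boundary_promoter_density(g_in, GRanges()), "LAD")

  # densities integrate to counted TSS / boundaries
  sim <- small_sim()
  out3 <- lad_boundary_promoter_density(sim$genes, sim$features$LAD,
                                        window = 10e6, binsize = 1e5)
  total <- sum(out3$away$density) + sum(out3$toward$density)
  expect_equal(total * out3$n_boundaries, length(sim$genes))
})

test_that("pausing index and categories", {
  genes <- GRanges("chr1", IRanges(50001, 80000), strand = "+")
  mcols(genes)$gene_id <- "g"
  mcols(genes)$expression <- 10
  flat <- mk_track(rep(4, 1000), strand = ".")
  pc <- pausing_index(flat, genes)
  expect_equal(pc$index, 1)
  expect_equal(pc$category, "non-paused")

  v <- rep(4, 1000)
  v[500:503] <- 40  # TSS-proximal bins ~10x the body
  pc2 <- pausing_index(mk_track(v, strand = "."), genes)
  expect_gte(pc2$index, 5)
  expect_equal(pc2$category, "paused")

  low <- genes
  mcols(low)$expression <- 0.1
  pc3 <- pausing_index(mk_track(v, strand = "."), low)
  expect_equal(pc3$category, "low-expressed")
})

test_that("TSS ratio profiles are exact for proportional tracks", {
  genes <- GRanges("chr1", IRanges(50001, 80000), strand = "+")
  mcols(genes)$gene_id <- "g"
  a <- mk_track(rep(3, 1000), strand = ".")
  r1 <- tss_ratio_profile(a, a, genes, window = 4e3)
  expect_true(all(r1$ratio == 1))
  b <- mk_track(rep(6, 1000), strand = ".")
  r2 <- tss_ratio_profile(b, a, genes, window = 4e3, eps = 0)
  expect_true(all(r2$ratio == 2))
})
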