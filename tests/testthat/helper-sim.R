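suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# Expensive shared fixtures are built once per test run and memoized.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# The default synthetic dataset of the stated world (2 x 10 Mb, 500 genes,
# SNR 10), fixed seed.
default_sim <- function() fixture("default_sim",
  simulate_dataset(sim_config(seed = 101)))

# A small, fast dataset for module-level tests.
small_sim <- function() fixture("small_sim",
  simulate_dataset(sim_config(seed = 202, n_chroms = 1,
                              chrom_length = 2e6, n_genes = 60)))

# Full peak-calling + differential pipeline on the default dataset.
default_pipeline <- function() fixture("default_pipeline", {
  sim <- default_sim()
  samples <- names(sim$depth_factors)
  tracks <- list(); peaks_hs <- list(); peaks_std <- list()
  for (s in samples) {
    cond <- sub("_[0-9]+$", "", s)
    rep_i <- as.integer(sub(".*_", "", s))
    trks <- lapply(simulate_coverage(sim, cond, rep_i), exclude_regions,
                   blacklist = sim$features$blacklist)
    tracks[[s]] <- trks
    for (str in c("+", "-")) {
      fit <- fit_hmm(trks[[str]])
      peaks_hs[[paste0(s, str)]] <- decode_peaks(
        fit, trks[[str]], mode = "high_sensitivity", sample = s)
      if (s == samples[1])
        peaks_std[[paste0(s, str)]] <- decode_peaks(
          fit, trks[[str]], mode = "standard", sample = s)
    }
  }
  un <- union_peaks(peaks_hs)
  cnt <- count_in_peaks(un, tracks)
  conds <- sub("_[0-9]+$", "", samples)
  sf <- size_factors(cnt)
  disp <- estimate_dispersion(cnt, sf, conds)
  res <- call_diff_peaks(nb_wald_test(cnt, sf, disp$alpha, conds,
                                      reference = "control"))
  mcols(un)$call <- res$call
  mcols(un)$log2FC <- res$log2FC
  classes <- classify_genes(un, sim$genes)
  list(sim = sim, tracks = tracks, peaks_hs = peaks_hs,
       peaks_std = peaks_std, union = un, counts = cnt, sf = sf,
       disp = disp, res = res, classes = classes, conds = conds)
})

# Annotated planted peaks + matched control sets on the default dataset.
default_matched <- function() fixture("default_matched", {
  sim <- default_sim()
  pk <- annotate_peak_compartments(sim$peaks, sim$genes)
  cls <- setNames(sim$genes$class, sim$genes$gene_id)
  pcls <- cls[pk$gene_id]
  rlg_t <- pk[pcls == "RLG" & pk$planted_log2fc > 0]
  rll_t <- pk[pcls == "RLL" & pk$planted_log2fc < 0]
  pool <- pk[pcls %in% c("none", "mixed")]
  mk <- function(ts) suppressWarnings(select_matched_controls(
    ts, pool, genes = sim$genes, chrom_sizes = sim$chrom_sizes, seed = 42))
  list(sim = sim, rlg = mk(rlg_t), rll = mk(rll_t), pool = pool)
})

# Quick single-chromosome track from a numeric vector of bin values.
mk_track <- function(values, bin_width = 100L, strand = "+",
                     chrom = "chr1", total = sum(values)) {
  cs <- setNames(length(values) * bin_width, chrom)
  binned_track(setNames(list(as.numeric(values)), chrom), bin_width, cs,
               strand = strand, mapped_read_total = total)
}

# Random peaks on one chromosome (sorted, fixed width).
mk_rand_peaks <- function(n, chrom_len = 10e6, width = 1000L) {
  s <- sort(sample.int(chrom_len - width, n))
  GRanges("chr1", IRanges(s, s + width - 1L))
}

# A MatchedControlSet built directly from target/control peaks (used for
# null-calibration tests of the Monte-Carlo machinery in isolation).
mk_mcs <- function(targets, controls, n_matches) {
  mcols(controls)$target_idx <- rep(seq_along(targets), each = n_matches)
  mcols(controls)$match_idx <- rep(seq_len(n_matches), length(targets))
  structure(list(targets = targets, controls = controls,
                 n_matches = n_matches, dropped = integer(0)),
            class = "MatchedControlSet")
}

# Jaccard index of one interval against a set of called intervals.
jaccard_vs <- function(truth_one, called) {
  ov <- called[IRanges::overlapsAny(called, truth_one,
                                    ignore.strand = TRUE)]
  if (!length(ov)) return(0)
  sum(width(GenomicRanges::intersect(truth_one, ov,
                                     ignore.strand = TRUE))) /
    sum(width(GenomicRanges::union(truth_one, ov, ignore.strand = TRUE)))
}
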