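#' Configuration for the synthetic R-loop dataset
#'
#' The generator states a toy world mirroring the biology the pipeline is
#' built for: two conditions (control and a topoisomerase-depleted state),
#' strand-specific R-loop coverage with negative-binomial counting noise,
#' and planted structure — R-loop gain (RLG) genes that are long, highly
#' expressed, isolated, flanked by H3K9me3 patches or LAD boundaries; R-loop
#' loss (RLL) genes in gene-dense territory whose promoters/terminators sit
#' on replication origins; mixed genes carrying one gain and one loss; and
#' an invariant background that doubles as the matched-control pool.
#'
#' @param seed integer master seed; every randomized step derives its own
#'   stream from it, so outputs are fully reproducible.
#' @param n_chroms,chrom_length toy genome shape (default 2 x 10 Mb).
#' @param n_genes number of genes (default 500).
#' @param frac_rlg,frac_rll,frac_mixed class fractions (remainder is the
#'   invariant "none" class); must sum to at most 1.
#' @param bin_width coverage bin width in bp.
#' @param replicates replicates per condition.
#' @param dispersion NB dispersion of bin counts.
#' @param background_mean mean background coverage per bin (counts).
#' @param snr peak signal-to-background ratio.
#' @param gain_log2fc,loss_log2fc planted effects (depleted vs control) on
#'   gain and loss peaks; defaults +1 / -1 (2x and 0.5x).
#' @param gene_length_meanlog,gene_length_sdlog log-normal gene lengths.
#' @param rlg_length_mult multiplier on the RLG length median (>= 2.5x by
#'   default so the planted long-gene contrast is unambiguous).
#' @param expression_meanlog,expression_sdlog log-normal expression.
#' @param rlg_expr_mult expression multiplier for RLG genes.
#' @param depth_sdlog log-normal sd of per-sample depth factors.
#' @param tail_frac fraction of gain peaks receiving a 1 kb decaying 3'
#'   tail (the "trailing signal" the high-sensitivity decoder targets).
#' @param origin_halfwidth half-width of planted SNS-seq origin intervals.
#' @param feature_upstream_max maximum gap between a planted chromatin
#'   patch / LAD boundary and the TSS of its RLG gene.
#' @param baseline_feature_frac fraction of control-pool (none/mixed) genes
#'   that also receive origins / H3K9me3 so control overlap is non-zero.
#' @param rfd_bin_width,rfd_reads_per_bin OK-seq binning and mean fragment
#'   count per bin.
#' @param okseq_zone_halfwidth half-width of the RFD ascending ramp planted
#'   at each origin.
#' @param repliseq_bin_width Repli-seq track bin width.
#' @param de_frac,de_log2fc fraction of genes differentially expressed at
#'   the RNA level and their effect (kept small: the assayed R-loop changes
#'   are mostly expression-independent).
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 10e6,
                       n_genes = 500L,
                       frac_rlg = 0.10, frac_rll = 0.15, frac_mixed = 0.25,
                       bin_width = 100L, replicates = 2L,
                       dispersion = 0.05, background_mean = 2, snr = 10,
                       gain_log2fc = 1, loss_log2fc = -1,
                       gene_length_meanlog = log(15e3),
                       gene_length_sdlog = 0.5,
                       rlg_length_mult = 3,
                       expression_meanlog = log(10), expression_sdlog = 0.8,
                       rlg_expr_mult = 2.5,
                       depth_sdlog = 0.15,
                       tail_frac = 0.3,
                       origin_halfwidth = 5e3,
                       feature_upstream_max = 4e3,
                       baseline_feature_frac = 0.15,
                       rfd_bin_width = 1000L, rfd_reads_per_bin = 50,
                       okseq_zone_halfwidth = 20e3,
                       repliseq_bin_width = 1000L,
                       de_frac = 0.05, de_log2fc = 1) {
  cfg <- as.list(environment())
  if (frac_rlg + frac_rll + frac_mixed > 1)
    stopf("class fractions must sum to at most 1")
  rates <- c(chrom_length, n_genes, bin_width, replicates, dispersion,
             background_mean, snr, rfd_reads_per_bin)
  if (any(rates <= 0) || depth_sdlog < 0)
    stopf("all rates and sizes must be positive")
  structure(cfg, class = "sim_config")
}

# Place genes of given lengths on one chromosome without overlap; RLG genes
# get large isolation gaps. Returns start positions or NULL if infeasible.
place_genes_on_chrom <- function(lens, is_rlg, chrom_len, margin = 60e3) {
  n <- length(lens)
  if (n == 0L) return(integer(0))
  gaps <- runif(n, 2e3, 8e3)
  iso <- runif(n, 30e3, 60e3)
  near_rlg <- is_rlg | c(FALSE, is_rlg[-n])
  gaps[near_rlg] <- pmax(gaps[near_rlg], iso[near_rlg])
  avail <- chrom_len - 2 * margin
  need <- sum(lens) + sum(gaps)
  if (need > avail) {
    slack <- avail - sum(lens)
    if (slack < 500 * n) return(NULL)
    gaps <- pmax(gaps * slack / sum(gaps), 500)
    if (sum(lens) + sum(gaps) > avail) return(NULL)
  }
  margin + cumsum(gaps) + cumsum(c(0, lens[-n]))
}

# Random feature patches avoiding an exclusion set.
rand_patches <- function(n_per_chrom, width_lo, width_hi, chrom_sizes,
                         exclude = NULL, exclude_flank = 0, max_try = 200L) {
  out <- list()
  for (ch in names(chrom_sizes)) {
    got <- 0L; try <- 0L
    starts <- integer(0); ends <- integer(0)
    while (got < n_per_chrom && try < max_try * n_per_chrom) {
      try <- try + 1L
      w <- round(runif(1, width_lo, width_hi))
      s <- round(runif(1, 1, chrom_sizes[[ch]] - w))
      cand <- GRanges(ch, IRanges(s, s + w - 1L))
      if (!is.null(exclude) && length(exclude)) {
        pad <- suppressWarnings(GRanges(
          ch, IRanges(pmax(1, s - exclude_flank),
                      pmin(chrom_sizes[[ch]], s + w - 1L + exclude_flank))))
        if (any(IRanges::overlapsAny(pad, exclude, ignore.strand = TRUE)))
          next
      }
      starts <- c(starts, s); ends <- c(ends, s + w - 1L)
      got <- got + 1L
    }
    out[[ch]] <- GRanges(ch, IRanges(starts, ends))
  }
  do.call(bind_gr, unname(out))
}

#' Generate the synthetic genome, annotation and ground truth
#'
#' Same seed, same output, byte for byte. Genes are placed without overlap;
#' RLG genes are drawn long, highly expressed and isolated on the gene-poor
#' chromosome(s), with an H3K9me3 patch and/or LAD boundary placed at or
#' just upstream of their TSS; RLL genes sit in gene-dense territory with a
#' replication origin overlapping their promoter or terminator. A fraction
#' of control-pool genes receives the same features at a baseline rate so
#' matched-control overlap is non-degenerate.
#'
#' @param config a [sim_config()].
#' @return A list of class \code{rloop_sim} with elements \code{genes}
#'   (gene models with class, expression, paused flag), \code{peaks}
#'   (planted R-loop peaks with effects), \code{features} (named list of
#'   feature \code{GRanges}: LAD, H3K9me3, H3K27me3, SNS_origin,
#'   blacklist), \code{okseq_zones}, \code{depth_factors}, \code{de_genes},
#'   \code{chrom_sizes} and \code{config}.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 1L), simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  chrom_sizes <- setNames(rep(as.integer(cfg$chrom_length), cfg$n_chroms),
                          chroms)

  n_rlg <- round(cfg$n_genes * cfg$frac_rlg)
  n_rll <- round(cfg$n_genes * cfg$frac_rll)
  n_mixed <- round(cfg$n_genes * cfg$frac_mixed)
  n_none <- cfg$n_genes - n_rlg - n_rll - n_mixed
  classes <- c(rep("RLG", n_rlg), rep("RLL", n_rll),
               rep("mixed", n_mixed), rep("none", n_none))

  # chromosome density gradient: low index = gene-poor, holds RLG genes
  w <- seq_len(cfg$n_chroms)
  p_dense <- w / sum(w)
  p_sparse <- rev(p_dense)

  for (attempt in seq_len(20L)) {
    chrom_of <- character(cfg$n_genes)
    chrom_of[classes == "RLG"] <- sample(chroms, n_rlg, TRUE, p_sparse)
    chrom_of[classes != "RLG"] <- sample(chroms, cfg$n_genes - n_rlg, TRUE,
                                         p_dense)
    lens <- round(rlnorm(cfg$n_genes, cfg$gene_length_meanlog,
                         cfg$gene_length_sdlog))
    lens[classes == "RLG"] <- round(rlnorm(
      n_rlg, cfg$gene_length_meanlog + log(cfg$rlg_length_mult),
      cfg$gene_length_sdlog))
    lens <- pmin(pmax(lens, 6e3), 400e3)

    starts <- integer(cfg$n_genes)
    ok <- TRUE
    for (ch in chroms) {
      idx <- which(chrom_of == ch)
      idx <- sample(idx)  # random gene order along the chromosome
      st <- place_genes_on_chrom(lens[idx], classes[idx] == "RLG",
                                 chrom_sizes[[ch]])
      if (is.null(st)) { ok <- FALSE; break }
      starts[idx] <- st
    }
    if (ok) break
    if (attempt == 20L)
      stopf("gene placement infeasible after 20 attempts; reduce n_genes")
  }

  strand_of <- sample(c("+", "-"), cfg$n_genes, TRUE)
  expr <- rlnorm(cfg$n_genes, cfg$expression_meanlog, cfg$expression_sdlog)
  expr[classes == "RLG"] <- expr[classes == "RLG"] * cfg$rlg_expr_mult
  paused <- runif(cfg$n_genes) < ifelse(classes == "RLG", 0.8, 0.3)

  genes <- GRanges(chrom_of, IRanges(starts, starts + lens - 1L),
                   strand = strand_of)
  mcols(genes)$gene_id <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  mcols(genes)$class <- classes
  mcols(genes)$expression <- expr
  mcols(genes)$paused <- paused
  GenomeInfoDb::seqlevels(genes) <- chroms
  genes <- sort(genes, ignore.strand = TRUE)

  peaks <- plant_peaks(genes, cfg)
  feats <- plant_features(genes, peaks, cfg, chrom_sizes)

  n_samp <- 2L * cfg$replicates
  depth <- rlnorm(n_samp, 0, cfg$depth_sdlog)
  names(depth) <- paste0(rep(c("control", "depleted"), each = cfg$replicates),
                         "_", rep(seq_len(cfg$replicates), 2L))

  none_ids <- genes$gene_id[genes$class == "none"]
  n_de <- round(length(none_ids) * cfg$de_frac / (1 - cfg$frac_rlg -
                                                    cfg$frac_rll -
                                                    cfg$frac_mixed))
  n_de <- min(n_de, length(none_ids))
  de_ids <- sample(none_ids, n_de)
  de_genes <- data.frame(
    gene_id = de_ids,
    log2fc = sample(c(-1, 1), n_de, TRUE) * cfg$de_log2fc,
    stringsAsFactors = FALSE)

  structure(list(genes = genes, peaks = peaks, features = feats$features,
                 okseq_zones = feats$okseq_zones,
                 depth_factors = depth, de_genes = de_genes,
                 chrom_sizes = chrom_sizes, config = cfg),
            class = "rloop_sim")
}

# Planted R-loop peaks: promoter and terminator peaks on every gene, body
# peaks on genes long enough; all on the template strand (= gene strand).
plant_peaks <- function(genes, cfg) {
  rows <- list()
  tss <- gene_tss(genes); pas <- gene_pas(genes)
  dir <- ifelse(as.character(strand(genes)) == "-", -1L, 1L)
  for (i in seq_along(genes)) {
    g <- list(chrom = as.character(seqnames(genes))[i],
              strand = as.character(strand(genes))[i],
              id = genes$gene_id[i], class = genes$class[i])
    # promoter peak: [-500, +1000] around TSS in the transcription frame
    p_lo <- tss[i] + ifelse(dir[i] > 0, -500L, -1000L)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = g$chrom, start = p_lo, end = p_lo + 1500L, strand = g$strand,
      gene_id = g$id, kind = "promoter")
    t_lo <- pas[i] + ifelse(dir[i] > 0, -1000L, -500L)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = g$chrom, start = t_lo, end = t_lo + 1500L, strand = g$strand,
      gene_id = g$id, kind = "terminator")
    len <- width(genes)[i]
    if (len >= 9e3) {
      nb <- max(1L, min(3L, len %/% 20e3))
      lo <- start(genes)[i] + 2500L
      hi <- end(genes)[i] - 2500L - 2000L
      # body peaks span the transcribed portion, the first near the 5' end
      cc <- round(seq(lo + 1000, hi, length.out = nb + 1L)[1:nb])
      if (as.character(strand(genes))[i] == "-")
        cc <- rev(start(genes)[i] + end(genes)[i] - cc - 2000L)
      for (ctr in cc)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = g$chrom, start = ctr, end = ctr + 2000L,
          strand = g$strand, gene_id = g$id, kind = "body")
    }
  }
  df <- do.call(rbind, rows)
  lfc <- numeric(nrow(df))
  cls <- genes$class[match(df$gene_id, genes$gene_id)]
  lfc[cls == "RLG" & df$kind == "body"] <- cfg$gain_log2fc
  lfc[cls == "RLL" & df$kind %in% c("promoter", "terminator")] <-
    cfg$loss_log2fc
  # mixed genes: one gain (first body peak, or terminator) + promoter loss
  for (gid in unique(df$gene_id[cls == "mixed"])) {
    sel <- which(df$gene_id == gid)
    body <- sel[df$kind[sel] == "body"]
    gain_at <- if (length(body)) body[1] else sel[df$kind[sel] == "terminator"]
    lfc[gain_at] <- cfg$gain_log2fc
    lfc[sel[df$kind[sel] == "promoter"]] <- cfg$loss_log2fc
  }
  tail_flag <- lfc > 0 & df$kind == "body" & runif(nrow(df)) < cfg$tail_frac
  pk <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
  mcols(pk)$peak_id <- sprintf("tpeak_%05d", seq_len(nrow(df)))
  mcols(pk)$gene_id <- df$gene_id
  mcols(pk)$kind <- df$kind
  mcols(pk)$planted_log2fc <- lfc
  mcols(pk)$tail <- tail_flag
  pk
}

plant_features <- function(genes, peaks, cfg, chrom_sizes) {
  tss <- gene_tss(genes)
  pas <- gene_pas(genes)
  dir <- ifelse(as.character(strand(genes)) == "-", -1L, 1L)
  cls <- genes$class
  is_ctrl <- cls %in% c("none", "mixed")

  # A planted chromatin patch anchored on a gene in the transcription
  # frame: the patch 3' edge sits at offset `edge` downstream of the TSS
  # (negative = upstream) and the patch extends `w` bp upstream of it. With
  # probability cover_p the edge reaches into the gene body (so planted
  # body peaks can overlap the patch, as observed for
  # heterochromatin-adjacent gain genes); otherwise it stays at/upstream of
  # the promoter.
  patch_on_gene <- function(idx, w_lo, w_hi, cover_p = 0.6,
                            reach = c(0.1, 0.7)) {
    if (!length(idx)) return(GRanges())
    w <- round(runif(length(idx), w_lo, w_hi))
    edge_off <- ifelse(
      runif(length(idx)) < cover_p,
      round(runif(length(idx), reach[1], reach[2]) * width(genes)[idx]),
      -round(runif(length(idx), 500, cfg$feature_upstream_max)))
    edge <- tss[idx] + dir[idx] * edge_off
    s <- ifelse(dir[idx] > 0, edge - w + 1L, edge)
    s <- pmax(1, pmin(s, chrom_sizes[as.character(seqnames(genes))[idx]] - w))
    GRanges(as.character(seqnames(genes))[idx], IRanges(s, s + w - 1L))
  }

  rlg <- which(cls == "RLG")
  k9_idx <- rlg[runif(length(rlg)) < 0.8]
  lad_idx <- rlg[runif(length(rlg)) < 0.5]
  # every RLG gene carries at least one of the two anchoring features
  orphan <- setdiff(rlg, union(k9_idx, lad_idx))
  k9_idx <- sort(c(k9_idx, orphan))
  # baseline features go to control-pool genes that are not immediate
  # neighbours of RLL genes, so the planted loss class stays distal
  rll_genes <- genes[cls == "RLL"]
  near_rll <- IRanges::overlapsAny(genes, rll_genes + 25e3,
                                   ignore.strand = TRUE)
  ctrl_pool <- which(is_ctrl & !near_rll)
  base_k9 <- ctrl_pool[runif(length(ctrl_pool)) < cfg$baseline_feature_frac]
  h3k9 <- bind_gr(patch_on_gene(k9_idx, 15e3, 35e3, cover_p = 0.65),
                  patch_on_gene(base_k9, 15e3, 35e3, cover_p = 0.65))
  bg_k9 <- rand_patches(12L, 5e3, 20e3, chrom_sizes,
                        exclude = rll_genes, exclude_flank = 50e3)
  h3k9 <- feature_set(bind_gr(h3k9, bg_k9), "H3K9me3")

  # LADs extend 60-120 kb upstream from an edge that is either right at
  # the promoter (the gene transcribes away from the LAD interior, its
  # promoter at the boundary) or reaches into the gene body so early body
  # peaks fall inside the LAD.
  plant_lads <- function(idx) {
    if (!length(idx)) return(GRanges())
    lad_len <- round(runif(length(idx), 60e3, 120e3))
    edge_off <- ifelse(runif(length(idx)) < 0.5,
                       round(runif(length(idx), -2e3, 2e3)),
                       round(runif(length(idx), 0.1, 0.6) *
                               width(genes)[idx]))
    lad_edge <- tss[idx] + dir[idx] * edge_off
    lad_s <- pmax(1, ifelse(dir[idx] > 0, lad_edge - lad_len + 1L,
                            lad_edge))
    lad_e <- pmin(lad_s + lad_len - 1L,
                  chrom_sizes[as.character(seqnames(genes))[idx]])
    GRanges(as.character(seqnames(genes))[idx], IRanges(lad_s, lad_e))
  }
  # baseline LADs live on the gene-poor chromosome(s): lamina-associated
  # chromatin is gene-poor, so the dense territory housing RLL genes stays
  # LAD-free
  sparse_chroms <- names(chrom_sizes)[seq_len(max(1L,
                                                  length(chrom_sizes) %/% 2L))]
  lad_pool <- ctrl_pool[as.character(seqnames(genes))[ctrl_pool] %in%
                          sparse_chroms]
  base_lad <- lad_pool[runif(length(lad_pool)) < cfg$baseline_feature_frac]
  lads <- bind_gr(plant_lads(lad_idx), plant_lads(base_lad))
  bg_lad <- rand_patches(1L, 60e3, 120e3, chrom_sizes,
                         exclude = bind_gr(granges(rll_genes), lads),
                         exclude_flank = 50e3)
  lads <- feature_set(bind_gr(lads, bg_lad), "LAD")

  rll <- which(cls == "RLL")
  anchor <- ifelse(runif(length(rll)) < 0.5, tss[rll], pas[rll])
  base_or <- which(is_ctrl)[runif(sum(is_ctrl)) < cfg$baseline_feature_frac]
  anchor_b <- ifelse(runif(length(base_or)) < 0.5, tss[base_or],
                     pas[base_or])
  ori_centers <- data.frame(
    chrom = c(as.character(seqnames(genes))[rll],
              as.character(seqnames(genes))[base_or]),
    center = c(anchor, anchor_b))
  # random background origins, kept away from RLG genes (origin depletion)
  rlg_genes <- genes[cls == "RLG"]
  bg_or <- rand_patches(10L, 2L, 2L, chrom_sizes,
                        exclude = rlg_genes, exclude_flank = 120e3)
  ori_centers <- rbind(ori_centers,
                       data.frame(chrom = as.character(seqnames(bg_or)),
                                  center = start(bg_or)))
  hw <- cfg$origin_halfwidth
  ori <- GRanges(ori_centers$chrom,
                 IRanges(pmax(1, ori_centers$center - hw),
                         ori_centers$center + hw))
  origins <- feature_set(ori, "SNS_origin")

  # OK-seq initiation zones: wider ramps centered on merged origin centers
  zc <- round((start(origins) + end(origins)) / 2)
  zhw <- cfg$okseq_zone_halfwidth
  zones <- reduce(GRanges(seqnames(origins),
                          IRanges(pmax(1, zc - zhw),
                                  pmin(zc + zhw,
                                       chrom_sizes[as.character(
                                         seqnames(origins))]))))
  metadata(zones)$name <- "OKseq_AS"

  k27_idx <- c(rll[runif(length(rll)) < 0.6],
               which(is_ctrl)[runif(sum(is_ctrl)) < cfg$baseline_feature_frac])
  h3k27 <- feature_set(patch_on_gene(k27_idx, 3e3, 10e3, cover_p = 0.3,
                                     reach = c(0.02, 0.1)),
                       "H3K27me3")

  blacklist <- feature_set(
    rand_patches(3L, 10e3, 30e3, chrom_sizes,
                 exclude = bind_gr(granges(genes), granges(origins)),
                 exclude_flank = 10e3),
    "blacklist")

  list(features = list(LAD = lads, H3K9me3 = h3k9, H3K27me3 = h3k27,
                       SNS_origin = origins, blacklist = blacklist),
       okseq_zones = zones)
}

#' Simulate strand-specific coverage for one sample
#'
#' Background bins are NB with a low mean; bins under a planted peak have
#' mean \code{background x snr} (times a decaying multiplier over 1 kb
#' tails); in the depleted condition, planted effects multiply the peak
#' mean by \code{2^planted_log2fc}. The sample's depth factor scales every
#' mean; \code{mapped_read_total} records the realized total over both
#' strands.
#'
#' @param sim a [simulate_dataset()] result.
#' @param condition \code{"control"} or \code{"depleted"}.
#' @param replicate replicate number (1-based).
#' @return Named list of two [binned_track()]s (\code{"+"}, \code{"-"}).
#' @export
simulate_coverage <- function(sim, condition = c("control", "depleted"),
                              replicate = 1L) {
  condition <- match.arg(condition)
  cfg <- sim$config
  samp <- paste0(condition, "_", replicate)
  if (!samp %in% names(sim$depth_factors)) stopf("unknown sample %s", samp)
  depth <- sim$depth_factors[[samp]]
  seed <- derive_seed(cfg$seed, 2L, match(condition, c("control", "depleted")),
                      replicate)
  with_seed(seed, {
    tracks <- lapply(c("+", "-"), function(str) {
      vals <- lapply(names(sim$chrom_sizes), function(ch) {
        n <- ceiling(sim$chrom_sizes[[ch]] / cfg$bin_width)
        mult <- rep(1, n)
        pk <- sim$peaks[as.character(seqnames(sim$peaks)) == ch &
                          as.character(strand(sim$peaks)) == str]
        if (length(pk)) {
          eff <- if (condition == "depleted")
            2^pk$planted_log2fc else rep(1, length(pk))
          for (i in seq_along(pk)) {
            b1 <- (start(pk)[i] - 1L) %/% cfg$bin_width + 1L
            b2 <- (end(pk)[i] - 1L) %/% cfg$bin_width + 1L
            b1 <- max(1L, b1); b2 <- min(n, b2)
            mult[b1:b2] <- pmax(mult[b1:b2], cfg$snr * eff[i])
            if (isTRUE(pk$tail[i])) {
              ntail <- max(1L, 1000L %/% cfg$bin_width)
              dec <- exp(-(seq_len(ntail)) / (ntail / 3))
              tb <- if (str == "-") (b1 - 1L) - seq_len(ntail) + 1L
                    else b2 + seq_len(ntail)
              keep <- tb >= 1L & tb <= n
              mult[tb[keep]] <- pmax(mult[tb[keep]],
                                     1 + (cfg$snr * eff[i] - 1) * dec[keep])
            }
          }
        }
        mu <- cfg$background_mean * mult * depth
        rnbinom(n, mu = mu, size = 1 / cfg$dispersion)
      })
      names(vals) <- names(sim$chrom_sizes)
      binned_track(vals, cfg$bin_width, sim$chrom_sizes, strand = str)
    })
    names(tracks) <- c("+", "-")
    total <- sum(vapply(tracks, function(t) sum(unlist(t$values)), 0))
    tracks <- lapply(tracks, function(t) { t$mapped_read_total <- total; t })
    tracks
  })
}

#' Simulate per-gene RNA-seq counts
#'
#' Counts are NB with mean proportional to expression times gene length;
#' the small planted DE set (\code{de_genes}) changes in the depleted
#' condition.
#'
#' @param sim a [simulate_dataset()] result.
#' @return Integer matrix genes x samples with a \code{conditions}
#'   attribute.
#' @export
simulate_expression_counts <- function(sim) {
  cfg <- sim$config
  genes <- sim$genes
  base_mu <- genes$expression * width(genes) / 1e3
  lfc <- setNames(rep(0, length(genes)), genes$gene_id)
  lfc[sim$de_genes$gene_id] <- sim$de_genes$log2fc
  samples <- names(sim$depth_factors)
  conds <- sub("_[0-9]+$", "", samples)
  with_seed(derive_seed(cfg$seed, 3L), {
    counts <- vapply(seq_along(samples), function(j) {
      mu <- base_mu * sim$depth_factors[[j]] *
        (if (conds[j] == "depleted") 2^lfc else 1)
      rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion)
    }, numeric(length(genes)))
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(genes$gene_id, samples)
    attr(counts, "conditions") <- conds
    counts
  })
}

#' Simulate an RNA polymerase ChIP track
#'
#' Unstranded coverage: gene bodies carry density proportional to
#' expression; the promoter-proximal window (TSS -50..+300) of paused genes
#' is amplified by the pausing index, with further TSS accumulation in the
#' depleted condition.
#'
#' @param sim a [simulate_dataset()] result.
#' @param condition \code{"control"} or \code{"depleted"}.
#' @param pause_index promoter/body density ratio of paused genes.
#' @param depletion_tss_gain extra TSS multiplier in the depleted condition
#'   (paused genes only).
#' @return A [binned_track()].
#' @export
simulate_rnap_chip <- function(sim, condition = c("control", "depleted"),
                               pause_index = 6, depletion_tss_gain = 1.5) {
  condition <- match.arg(condition)
  cfg <- sim$config
  genes <- sim$genes
  tss <- gene_tss(genes)
  dir <- ifelse(as.character(strand(genes)) == "-", -1L, 1L)
  seed <- derive_seed(cfg$seed, 4L, match(condition, c("control", "depleted")))
  with_seed(seed, {
    vals <- lapply(names(sim$chrom_sizes), function(ch) {
      n <- ceiling(sim$chrom_sizes[[ch]] / cfg$bin_width)
      mu <- rep(0.2, n)
      idx <- which(as.character(seqnames(genes)) == ch)
      for (i in idx) {
        dens <- genes$expression[i] / 5
        b1 <- (start(genes)[i] - 1L) %/% cfg$bin_width + 1L
        b2 <- (end(genes)[i] - 1L) %/% cfg$bin_width + 1L
        mu[max(1L, b1):min(n, b2)] <- dens
        pi_g <- if (genes$paused[i]) pause_index else 1
        if (condition == "depleted" && genes$paused[i])
          pi_g <- pi_g * depletion_tss_gain
        w_lo <- tss[i] + ifelse(dir[i] > 0, -50L, -300L)
        w_hi <- tss[i] + ifelse(dir[i] > 0, 300L, 50L)
        t1 <- max(1L, (w_lo - 1L) %/% cfg$bin_width + 1L)
        t2 <- min(n, (w_hi - 1L) %/% cfg$bin_width + 1L)
        mu[t1:t2] <- dens * pi_g
      }
      rnbinom(n, mu = mu, size = 1 / cfg$dispersion)
    })
    names(vals) <- names(sim$chrom_sizes)
    tr <- binned_track(vals, cfg$bin_width, sim$chrom_sizes, strand = ".")
    tr$mapped_read_total <- sum(unlist(tr$values))
    tr
  })
}

#' Simulate Repli-seq per-phase tracks
#'
#' The replication timing of a bin is set by its distance to the nearest
#' planted origin center: near-origin bins replicate in G1b, distal bins in
#' progressively later phases. Each phase track carries high signal where
#' its phase matches, shoulder signal one phase away, and low background.
#'
#' @param sim a [simulate_dataset()] result.
#' @param phase_scale bp of distance per phase step.
#' @return Named list of six [binned_track()]s (G1b, S1, S2, S3, S4, G2),
#'   depth-comparable by construction.
#' @export
simulate_repliseq <- function(sim, phase_scale = 150e3) {
  cfg <- sim$config
  phases <- c("G1b", "S1", "S2", "S3", "S4", "G2")
  bw <- cfg$repliseq_bin_width
  ori <- sim$features$SNS_origin
  with_seed(derive_seed(cfg$seed, 5L), {
    per_chrom_phase <- lapply(names(sim$chrom_sizes), function(ch) {
      n <- ceiling(sim$chrom_sizes[[ch]] / bw)
      ctr <- (seq_len(n) - 0.5) * bw
      oc <- sort(round((start(ori) + end(ori)) / 2)[
        as.character(seqnames(ori)) == ch])
      if (!length(oc)) return(rep(6L, n))
      lo <- findInterval(ctr, oc)
      d_lo <- ifelse(lo >= 1, ctr - oc[pmax(lo, 1)], Inf)
      d_hi <- ifelse(lo < length(oc), oc[pmin(lo + 1, length(oc))] - ctr, Inf)
      d <- pmin(d_lo, d_hi)
      pmin(floor(d / phase_scale), 5) + 1L
    })
    names(per_chrom_phase) <- names(sim$chrom_sizes)
    out <- lapply(seq_along(phases), function(p) {
      vals <- lapply(names(sim$chrom_sizes), function(ch) {
        ph <- per_chrom_phase[[ch]]
        mu <- ifelse(ph == p, 10, ifelse(abs(ph - p) == 1L, 3, 0.5))
        rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion)
      })
      names(vals) <- names(sim$chrom_sizes)
      tr <- binned_track(vals, bw, sim$chrom_sizes, strand = ".")
      tr$mapped_read_total <- sum(unlist(tr$values))
      tr
    })
    names(out) <- phases
    out
  })
}

#' Simulate OK-seq strand counts
#'
#' The underlying replication fork directionality (RFD) ramps linearly from
#' -0.8 to +0.8 across every planted initiation zone and decays linearly
#' between zones (termination). Per bin, a Poisson number of Okazaki
#' fragments is split binomially between Crick and Watson according to the
#' local RFD.
#'
#' @param sim a [simulate_dataset()] result.
#' @return List with \code{crick} and \code{watson} [binned_track()]s and
#'   the noise-free \code{rfd_true} per chromosome.
#' @export
simulate_okseq <- function(sim) {
  cfg <- sim$config
  bw <- cfg$rfd_bin_width
  zones <- sim$okseq_zones
  with_seed(derive_seed(cfg$seed, 6L), {
    rfd_true <- lapply(names(sim$chrom_sizes), function(ch) {
      n <- ceiling(sim$chrom_sizes[[ch]] / bw)
      ctr <- (seq_len(n) - 0.5) * bw
      z <- zones[as.character(seqnames(zones)) == ch]
      if (!length(z)) return(rep(0, n))
      zs <- start(z); ze <- end(z)
      r <- numeric(n)
      # inside a zone: ascending ramp -0.8 -> +0.8
      for (i in seq_along(z)) {
        sel <- ctr >= zs[i] & ctr <= ze[i]
        r[sel] <- -0.8 + 1.6 * (ctr[sel] - zs[i]) / (ze[i] - zs[i])
      }
      # between zones: descend from +0.8 back to -0.8
      bounds <- c(1, zs, sim$chrom_sizes[[ch]])
      for (i in seq_len(length(z) + 1L)) {
        lo <- if (i == 1L) 1 else ze[i - 1L]
        hi <- if (i > length(z)) sim$chrom_sizes[[ch]] else zs[i]
        if (hi <= lo) next
        sel <- ctr > lo & ctr < hi
        if (i == 1L) r[sel] <- -0.8
        else if (i > length(z)) r[sel] <- 0.8
        else r[sel] <- 0.8 - 1.6 * (ctr[sel] - lo) / (hi - lo)
      }
      r
    })
    names(rfd_true) <- names(sim$chrom_sizes)
    crick <- list(); watson <- list()
    for (ch in names(sim$chrom_sizes)) {
      n <- length(rfd_true[[ch]])
      tot <- rpois(n, cfg$rfd_reads_per_bin)
      cr <- rbinom(n, tot, (1 + rfd_true[[ch]]) / 2)
      crick[[ch]] <- as.numeric(cr)
      watson[[ch]] <- as.numeric(tot - cr)
    }
    ct <- binned_track(crick, bw, sim$chrom_sizes, strand = ".")
    wt <- binned_track(watson, bw, sim$chrom_sizes, strand = ".")
    ct$mapped_read_total <- sum(unlist(ct$values))
    wt$mapped_read_total <- sum(unlist(wt$values))
    list(crick = ct, watson = wt, rfd_true = rfd_true)
  })
}

#' Write a simulated dataset to disk
#'
#' Emits bedGraph coverage per strand per sample, BED feature sets, BED12
#' gene models, OK-seq strand counts, Repli-seq phase tracks, RNAP ChIP
#' tracks, expression counts, ground-truth tables, a chrom.sizes file and a
#' manifest listing each file with its role. Re-reading through the core
#' I/O reproduces the in-memory values exactly.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return The manifest as a data.frame, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2L) != 0L) stopf("directory %s is not writable", dir)
  manifest <- list()
  add <- function(file, role) manifest[[length(manifest) + 1L]] <<-
    data.frame(file = file, role = role, stringsAsFactors = FALSE)

  write_chrom_sizes(sim$chrom_sizes, file.path(dir, "genome.chrom.sizes"))
  add("genome.chrom.sizes", "chrom_sizes")
  write_bed12_genes(sim$genes, file.path(dir, "genes.bed12"))
  add("genes.bed12", "gene_annotation")
  for (nm in names(sim$features)) {
    f <- paste0("feature_", nm, ".bed")
    write_bed(sim$features[[nm]], file.path(dir, f))
    add(f, paste0("feature:", nm))
  }
  write_bed(sim$okseq_zones, file.path(dir, "okseq_zones.bed"))
  add("okseq_zones.bed", "feature:OKseq_AS")

  for (cond in c("control", "depleted"))
    for (rep_i in seq_len(sim$config$replicates)) {
      trks <- simulate_coverage(sim, cond, rep_i)
      for (str in c("+", "-")) {
        f <- sprintf("dripc_%s_rep%d_%s.bedgraph", cond, rep_i,
                     ifelse(str == "+", "plus", "minus"))
        write_bedgraph(trks[[str]], file.path(dir, f))
        add(f, sprintf("coverage:%s:rep%d:%s", cond, rep_i, str))
      }
    }

  ok <- simulate_okseq(sim)
  write_bedgraph(ok$crick, file.path(dir, "okseq_crick.bedgraph"))
  write_bedgraph(ok$watson, file.path(dir, "okseq_watson.bedgraph"))
  add("okseq_crick.bedgraph", "okseq:crick")
  add("okseq_watson.bedgraph", "okseq:watson")

  rs <- simulate_repliseq(sim)
  for (ph in names(rs)) {
    f <- sprintf("repliseq_%s.bedgraph", ph)
    write_bedgraph(rs[[ph]], file.path(dir, f))
    add(f, paste0("repliseq:", ph))
  }
  for (cond in c("control", "depleted")) {
    f <- sprintf("rnap_chip_%s.bedgraph", cond)
    write_bedgraph(simulate_rnap_chip(sim, cond), file.path(dir, f))
    add(f, paste0("rnap_chip:", cond))
  }

  counts <- simulate_expression_counts(sim)
  cdt <- data.table(gene_id = rownames(counts))
  for (j in colnames(counts)) cdt[[j]] <- counts[, j]
  fwrite(cdt, file.path(dir, "expression_counts.tsv"), sep = "\t")
  add("expression_counts.tsv", "expression_counts")

  gt <- as.data.frame(sim$genes)
  fwrite(as.data.table(gt), file.path(dir, "truth_genes.tsv"), sep = "\t")
  add("truth_genes.tsv", "ground_truth:genes")
  pt <- as.data.frame(sim$peaks)
  fwrite(as.data.table(pt), file.path(dir, "truth_peaks.tsv"), sep = "\t")
  add("truth_peaks.tsv", "ground_truth:peaks")
  fwrite(data.table(sample = names(sim$depth_factors),
                    depth_factor = unname(sim$depth_factors)),
         file.path(dir, "truth_depth_factors.tsv"), sep = "\t")
  add("truth_depth_factors.tsv", "ground_truth:depth")

  mf <- do.call(rbind, manifest)
  fwrite(as.data.table(mf), file.path(dir, "manifest.tsv"), sep = "\t")
  invisible(mf)
}
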