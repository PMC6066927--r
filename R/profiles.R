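#' @title Strand-aware metagene and anchor-centered profiles
#' @description Scaled-gene peak-density metagenes, TSS/PAS-anchored signal
#'   metaplots resolved by template vs non-template strand, promoter
#'   density around LAD boundaries by transcriptional orientation, RNAP
#'   pausing-index categories and TSS ratio plots. The template-strand
#'   convention: R-loop signal on a gene's annotated strand reports
#'   template-strand R-loops (the sequenced moiety is the nascent
#'   transcript).
#' @name profiles
NULL

#' Scaled-gene metagene of peak density
#'
#' Each gene span is divided into \code{n_bins} equal bins (bin 1 at the
#' TSS; minus-strand genes are flipped); a peak adds 1 to every bin it
#' overlaps and per-bin counts are divided by the number of genes in the
#' gene's length category.
#'
#' @param peaks peak \code{GRanges}.
#' @param genes gene \code{GRanges}.
#' @param length_breaks breaks (bp) partitioning genes by length.
#' @param n_bins number of metagene bins (default 40).
#' @return Named list (one per non-empty category) of data.frames
#'   \code{bin}, \code{density}; attribute \code{n_genes}.
#' @export
metagene_peak_density <- function(peaks, genes,
                                  length_breaks = c(0, 20e3, 50e3, Inf),
                                  n_bins = 40L) {
  cat_of <- cut(width(genes), length_breaks, right = FALSE,
                include.lowest = TRUE)
  hits <- findOverlaps(peaks, granges(genes), ignore.strand = TRUE)
  out <- list()
  for (lv in levels(cat_of)) {
    gidx <- which(cat_of == lv)
    if (!length(gidx)) next
    counts <- numeric(n_bins)
    sel <- subjectHits(hits) %in% gidx
    qh <- queryHits(hits)[sel]; sh <- subjectHits(hits)[sel]
    for (k in seq_along(qh)) {
      g <- sh[k]
      gl <- width(genes)[g]
      rel_lo <- (max(start(peaks)[qh[k]], start(genes)[g]) -
                   start(genes)[g]) / gl
      rel_hi <- (min(end(peaks)[qh[k]], end(genes)[g]) -
                   start(genes)[g] + 1) / gl
      b1 <- min(floor(rel_lo * n_bins) + 1L, n_bins)
      b2 <- min(ceiling(rel_hi * n_bins), n_bins)
      bins <- b1:b2
      if (as.character(strand(genes))[g] == "-")
        bins <- n_bins + 1L - bins
      counts[bins] <- counts[bins] + 1
    }
    df <- data.frame(bin = seq_len(n_bins),
                     density = counts / length(gidx))
    attr(df, "n_genes") <- length(gidx)
    out[[lv]] <- df
  }
  out
}

#' Anchor-centered signal metaplot
#'
#' Per gene, depth-normalized signal over \code{anchor +/- window/2} at
#' track resolution, reversed for minus-strand genes; the template strand
#' is the track whose strand equals the gene's. The per-position summary is
#' the median (or mean) across genes with its SD or SE.
#'
#' @param tracks named list with elements \code{"+"} and \code{"-"} (or a
#'   single unstranded track under \code{"."}).
#' @param genes gene \code{GRanges}.
#' @param anchor \code{"TSS"} or \code{"PAS"}.
#' @param window total window width in bp (default 20 kb).
#' @param strand_mode \code{"template"} or \code{"nontemplate"} (ignored
#'   for unstranded input).
#' @param summary \code{"median"} or \code{"mean"}.
#' @param spread \code{"sd"} or \code{"se"}.
#' @return data.frame \code{position} (bp relative to anchor, bin
#'   centers), \code{summary}, \code{spread}; attributes \code{n_genes},
#'   \code{n_skipped}.
#' @export
signal_metaplot <- function(tracks, genes, anchor = c("TSS", "PAS"),
                            window = 20e3,
                            strand_mode = c("template", "nontemplate"),
                            summary = c("median", "mean"),
                            spread = c("sd", "se")) {
  anchor <- match.arg(anchor)
  strand_mode <- match.arg(strand_mode)
  summary <- match.arg(summary)
  spread <- match.arg(spread)
  if (is.null(names(tracks)) && inherits(tracks, "BinnedTrack"))
    tracks <- list("." = tracks)
  bw <- tracks[[1]]$bin_width
  half <- floor(window / 2 / bw)
  # window is symmetric about the anchor bin (2*half + 1 bins) so that
  # mirroring the genome maps windows onto reversed windows exactly
  npos <- 2L * half + 1L
  pos <- if (anchor == "TSS") gene_tss(genes) else gene_pas(genes)
  mat <- matrix(NA_real_, length(genes), npos)
  skipped <- 0L
  for (i in seq_along(genes)) {
    gstr <- as.character(strand(genes))[i]
    tkey <- if ("." %in% names(tracks)) "." else
      if (strand_mode == "template") gstr else setdiff(c("+", "-"), gstr)
    tr <- tracks[[tkey]]
    ch <- as.character(seqnames(genes))[i]
    cbin <- (pos[i] - 1L) %/% bw + 1L
    b1 <- cbin - half; b2 <- cbin + half
    nb <- length(tr$values[[ch]])
    if (b1 < 1L || b2 > nb) { skipped <- skipped + 1L; next }
    v <- tr$values[[ch]][b1:b2]
    if (gstr == "-") v <- rev(v)
    mat[i, ] <- v
  }
  mat <- mat[rowSums(is.na(mat)) == 0, , drop = FALSE]
  sm <- if (summary == "median") apply(mat, 2, median) else colMeans(mat)
  sdv <- apply(mat, 2, sd)
  if (spread == "se") sdv <- sdv / sqrt(max(nrow(mat), 1))
  df <- data.frame(position = (seq_len(npos) - half - 1) * bw,
                   summary = sm, spread = sdv)
  attr(df, "n_genes") <- nrow(mat)
  attr(df, "n_skipped") <- skipped
  df
}

#' Promoter density around LAD boundaries by orientation
#'
#' For each TSS, the signed position relative to the nearest LAD boundary
#' (negative = inside the LAD) and whether the gene transcribes away from
#' or toward the LAD interior; densities are TSS counts per position bin
#' per boundary.
#'
#' @param genes gene \code{GRanges}.
#' @param lads LAD \code{GRanges} (merged).
#' @param window half-window around boundaries (bp).
#' @param binsize position bin width (bp).
#' @return List with data.frames \code{away} and \code{toward}
#'   (\code{position}, \code{density}) plus \code{n_boundaries}.
#' @export
lad_boundary_promoter_density <- function(genes, lads, window = 100e3,
                                          binsize = 5e3) {
  if (!length(lads)) stopf("no LADs supplied")
  lads <- reduce(sort(lads), ignore.strand = TRUE)
  bch <- c(as.character(seqnames(lads)), as.character(seqnames(lads)))
  bpos <- c(start(lads), end(lads))
  bdir <- c(rep(1L, length(lads)), rep(-1L, length(lads)))
  # bdir: +1 = interior to the right of the boundary (a LAD start)
  tss <- gene_tss(genes)
  gdir <- ifelse(as.character(strand(genes)) == "-", -1L, 1L)
  gch <- as.character(seqnames(genes))
  brk <- seq(-window, window, by = binsize)
  ctr <- head(brk, -1) + binsize / 2
  away <- numeric(length(ctr)); toward <- numeric(length(ctr))
  nb <- length(bpos)
  for (i in seq_along(genes)) {
    sel <- which(bch == gch[i])
    if (!length(sel)) next
    d <- tss[i] - bpos[sel]
    j <- sel[which.min(abs(d))]
    delta <- tss[i] - bpos[j]
    inside <- (bdir[j] > 0 && delta > 0) || (bdir[j] < 0 && delta < 0)
    p <- if (inside) -abs(delta) else abs(delta)
    if (p < -window || p > window) next
    bin <- min(findInterval(p, brk, rightmost.closed = TRUE),
               length(ctr))
    if (bin < 1L) next
    to_interior <- gdir[i] == bdir[j]
    if (to_interior) toward[bin] <- toward[bin] + 1
    else away[bin] <- away[bin] + 1
  }
  list(away = data.frame(position = ctr, density = away / nb),
       toward = data.frame(position = ctr, density = toward / nb),
       n_boundaries = nb)
}

#' RNAP pausing index and category
#'
#' Index = mean ChIP density over the promoter-proximal window (TSS -50 to
#' +300 in the transcription frame) over mean density across the gene body
#' (TSS +300 to PAS). Categories: \code{low-expressed} below the
#' expression threshold; else \code{paused} if the index is at least
#' \code{index_threshold}, otherwise \code{non-paused}. A zero body
#' density with TSS signal gives an infinite index (paused).
#'
#' @param chip_track unstranded RNAP ChIP [binned_track()].
#' @param genes gene \code{GRanges} with \code{expression}.
#' @param tss_window promoter window around the TSS, transcription frame.
#' @param body_offset start of the gene body relative to the TSS (bp).
#' @param expr_threshold expression below which a gene is low-expressed.
#' @param index_threshold pausing call threshold (default 2).
#' @return data.frame \code{gene_id}, \code{index}, \code{category}.
#' @export
pausing_index <- function(chip_track, genes, tss_window = c(-50, 300),
                          body_offset = 300, expr_threshold = 1,
                          index_threshold = 2) {
  tss <- gene_tss(genes); pas <- gene_pas(genes)
  dir <- ifelse(as.character(strand(genes)) == "-", -1L, 1L)
  idx <- numeric(length(genes))
  for (i in seq_along(genes)) {
    ch <- as.character(seqnames(genes))[i]
    w <- sort(tss[i] + dir[i] * tss_window)
    b <- sort(c(tss[i] + dir[i] * body_offset, pas[i]))
    mdens <- function(lo, hi) {
      br <- bin_range(chip_track, max(1, lo),
                      min(hi, chip_track$chrom_sizes[[ch]]))
      mean(chip_track$values[[ch]][br[1]:br[2]])
    }
    tssd <- mdens(w[1], w[2])
    bodyd <- mdens(b[1], b[2])
    idx[i] <- if (bodyd > 0) tssd / bodyd else if (tssd > 0) Inf else NA
  }
  expr <- if ("expression" %in% names(mcols(genes))) genes$expression else
    rep(Inf, length(genes))
  cat <- ifelse(expr < expr_threshold, "low-expressed",
                ifelse(!is.na(idx) & idx >= index_threshold, "paused",
                       "non-paused"))
  data.frame(gene_id = genes$gene_id, index = idx, category = cat,
             stringsAsFactors = FALSE)
}

#' TSS-centered ratio profile between conditions
#'
#' Per position, the ratio of the group-mean depleted signal over the
#' group-mean control signal, each guarded with a pseudocount.
#'
#' @param chip_depleted,chip_control depth-normalized unstranded tracks.
#' @param genes gene \code{GRanges}.
#' @param window total window around the TSS (bp).
#' @param eps pseudocount (normalized units).
#' @return data.frame \code{position}, \code{ratio}.
#' @export
tss_ratio_profile <- function(chip_depleted, chip_control, genes,
                              window = 4e3, eps = 0.5) {
  dep <- signal_metaplot(list("." = chip_depleted), genes, anchor = "TSS",
                         window = window, summary = "mean")
  ctl <- signal_metaplot(list("." = chip_control), genes, anchor = "TSS",
                         window = window, summary = "mean")
  data.frame(position = dep$position,
             ratio = (dep$summary + eps) / (ctl$summary + eps))
}
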