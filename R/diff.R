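#' @title Negative-binomial differential testing ("NB-lite")
#' @description A self-contained re-implementation of the standard RNA-seq
#'   style count test applied to union-peak counts: median-of-ratios size
#'   factors, method-of-moments dispersions shrunk toward a parametric
#'   trend, a per-row NB GLM Wald test, and Benjamini-Hochberg adjustment.
#'   Gains and losses are called at padj < 0.1 with fold change > 1.25x or
#'   < 0.8x; genes shorter than 5 kb are excluded from classification and
#'   a gene needs a minimal 5:1 ratio of peak gains to losses (or vice
#'   versa) to be classed RLG (or RLL).
#' @name diff-rloop
NULL

#' Count raw bin signal in peaks
#'
#' For each peak and sample, the rounded sum of raw (un-normalized) bin
#' counts of the strand-matched track over all bins overlapping the peak.
#' Unstranded peaks sum both strands.
#'
#' @param peaks \code{GRanges} of (union) peaks.
#' @param sample_tracks named list (one entry per sample) of lists with
#'   elements \code{"+"} and \code{"-"} (or \code{"."}) of
#'   [binned_track()]s of raw counts.
#' @return Integer matrix peaks x samples; row names are peak ids when
#'   available.
#' @export
count_in_peaks <- function(peaks, sample_tracks) {
  samples <- names(sample_tracks)
  out <- matrix(0L, length(peaks), length(samples),
                dimnames = list(mcols(peaks)$peak_id, samples))
  if (!length(peaks)) return(out)
  pstr <- as.character(strand(peaks))
  pch <- as.character(seqnames(peaks))
  for (j in seq_along(samples)) {
    trks <- sample_tracks[[j]]
    for (i in seq_along(peaks)) {
      strands <- if (pstr[i] %in% c("+", "-")) pstr[i] else names(trks)
      tot <- 0
      for (s in strands) {
        tr <- trks[[s]]
        if (is.null(tr)) next
        if (!pch[i] %in% names(tr$values))
          stopf("peak %d on %s outside track", i, pch[i])
        if (end(peaks)[i] > tr$chrom_sizes[[pch[i]]])
          stopf("peak %d extends past end of %s", i, pch[i])
        br <- bin_range(tr, start(peaks)[i], end(peaks)[i])
        v <- tr$values[[pch[i]]][br[1]:br[2]]
        m <- tr$mask[[pch[i]]][br[1]:br[2]]
        tot <- tot + sum(v[!m])
      }
      out[i, j] <- as.integer(round(tot))
    }
  }
  out
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over rows (with all-positive counts) of the
#' ratio of that sample's count to the row geometric mean, renormalized so
#' the factors have geometric mean one. When no row is all-positive, rows
#' with a positive geometric mean over their positive entries are used with
#' a warning.
#'
#' @param counts non-negative count matrix (rows = peaks/genes, columns =
#'   samples).
#' @return Named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warnf("no row with all-positive counts; using positive-subset medians")
    lg <- log(counts)
    lg[!is.finite(lg)] <- NA
    logmeans <- rowMeans(lg, na.rm = TRUE)
    use <- is.finite(logmeans)
    sf <- apply(counts, 2, function(cnt) {
      r <- log(cnt[use]) - logmeans[use]
      exp(median(r[is.finite(r)]))
    })
  } else {
    lg <- log(counts[pos, , drop = FALSE])
    logmeans <- rowMeans(lg)
    sf <- apply(lg, 2, function(l) exp(median(l - logmeans)))
  }
  sf <- sf / geometric_mean(sf)
  setNames(sf, colnames(counts))
}

#' Trend-shrunken method-of-moments dispersions
#'
#' Per row, the raw dispersion is the method-of-moments estimate
#' \code{max(0, (s2 - mu) / mu^2)} on size-factor-normalized counts with
#' the variance pooled within condition; a parametric trend
#' \code{alpha(mu) = a1/mu + a0} is fitted across rows by least squares and
#' each raw estimate is shrunk toward the trend on the log scale with a
#' fixed weight (raw estimates are winsorized around the trend first so
#' zero estimates stay finite).
#'
#' @param counts count matrix.
#' @param sf size factors from [size_factors()].
#' @param conditions character vector of condition labels per column (two
#'   levels, each with >= 2 replicates).
#' @param shrink_weight weight on the trend in the log-scale combination.
#' @return List with \code{alpha} (final per-row dispersion),
#'   \code{alpha_mom} (raw), \code{trend} (function of the mean).
#' @export
estimate_dispersion <- function(counts, sf, conditions,
                                shrink_weight = 0.7) {
  counts <- as.matrix(counts)
  lev <- unique(conditions)
  if (length(lev) != 2L || any(table(conditions) < 2L))
    stopf("need two conditions with >= 2 replicates each")
  norm <- sweep(counts, 2, sf, "/")
  mu <- rowMeans(norm)
  s2 <- rowMeans(vapply(lev, function(l) {
    m <- norm[, conditions == l, drop = FALSE]
    apply(m, 1, var)
  }, numeric(nrow(counts))))
  alpha_mom <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)

  use <- mu > 0 & alpha_mom > 0
  if (sum(use) >= 10L) {
    x <- 1 / mu[use]; y <- alpha_mom[use]
    fit <- stats::lm.fit(cbind(a0 = 1, a1 = x), y)
    a0 <- max(fit$coefficients[["a0"]], 1e-6)
    a1 <- max(fit$coefficients[["a1"]], 0)
  } else {
    a0 <- max(mean(alpha_mom), 1e-6); a1 <- 0
  }
  trend <- function(m) pmax(a1 / pmax(m, 1e-8) + a0, 1e-8)
  tr <- trend(mu)
  raw <- pmin(pmax(alpha_mom, tr / 8), tr * 8)  # winsorize around trend
  alpha <- exp(shrink_weight * log(tr) + (1 - shrink_weight) * log(raw))
  list(alpha = alpha, alpha_mom = alpha_mom, trend = trend,
       coef = c(a0 = a0, a1 = a1))
}

#' Per-row NB GLM Wald test
#'
#' For each row, a negative-binomial GLM with log link, log size factors as
#' offsets and a single condition coefficient is fitted by IRLS (vectorized
#' across rows); the Wald statistic is the coefficient over its standard
#' error, with a two-sided p from the standard normal. The fold change is
#' reported in base 2 and is shrinkage-free. The squared standard error
#' carries a finite-sample variance-inflation factor \code{(m + 1) / m}
#' (m = number of samples), compensating the plug-in of estimated group
#' means and dispersions at small replicate numbers (analogous in spirit
#' to moderated-t degrees-of-freedom corrections); without it the test is
#' measurably liberal at 2 vs 2.
#'
#' @param counts count matrix.
#' @param sf size factors.
#' @param alpha per-row dispersions.
#' @param conditions condition labels per column; \code{reference} names
#'   the baseline level (fold changes are treatment over reference).
#' @param reference reference condition (default: first label).
#' @return \code{data.frame} with \code{baseMean}, \code{log2FC},
#'   \code{se}, \code{stat}, \code{pvalue}. Rows where IRLS fails get NA.
#' @export
nb_wald_test <- function(counts, sf, alpha, conditions,
                         reference = conditions[1]) {
  counts <- as.matrix(counts)
  x <- as.numeric(conditions != reference)
  if (all(x == 0) || all(x == 1)) stopf("need both conditions present")
  n <- nrow(counts); m <- ncol(counts)
  off <- log(sf)

  norm <- sweep(counts, 2, sf, "/")
  mu_ref <- rowMeans(norm[, x == 0, drop = FALSE])
  mu_trt <- rowMeans(norm[, x == 1, drop = FALSE])
  b0 <- log(pmax(mu_ref, 1e-8))
  b1 <- log(pmax(mu_trt, 1e-8)) - b0
  ok <- rowSums(counts) > 0
  b0[!ok] <- NA

  for (iter in seq_len(50L)) {
    eta <- outer(b0, rep(1, m)) + outer(b1, x) +
      matrix(off, n, m, byrow = TRUE)
    mu <- pmin(exp(eta), 1e12)
    W <- mu / (1 + alpha * mu)
    z <- (counts - mu) / pmax(mu, 1e-12)
    # weighted LS normal equations, closed form for the 2-column design
    Sw <- rowSums(W); Swx <- W %*% x; Swxx <- W %*% (x * x)
    r <- W * z
    Sr <- rowSums(r); Srx <- r %*% x
    det <- Sw * Swxx - Swx^2
    db0 <- (Swxx * Sr - Swx * Srx) / det
    db1 <- (Sw * Srx - Swx * Sr) / det
    db0[!ok] <- 0; db1[!ok] <- 0
    step <- pmax(abs(db0), abs(db1))
    db0 <- pmin(pmax(db0, -2), 2); db1 <- pmin(pmax(db1, -2), 2)
    b0 <- b0 + as.numeric(db0); b1 <- b1 + as.numeric(db1)
    if (all(step[ok & is.finite(step)] < 1e-10)) break
  }
  eta <- outer(b0, rep(1, m)) + outer(b1, x) +
    matrix(off, n, m, byrow = TRUE)
  mu <- pmin(exp(eta), 1e12)
  W <- mu / (1 + alpha * mu)
  Sw <- rowSums(W); Swx <- as.numeric(W %*% x)
  Swxx <- as.numeric(W %*% (x * x))
  det <- Sw * Swxx - Swx^2
  se <- sqrt(Sw / det * (m + 1) / m)  # finite-sample inflation
  stat <- b1 / se
  bad <- !ok | !is.finite(stat)
  p <- 2 * pnorm(-abs(stat))
  p[bad] <- NA
  data.frame(baseMean = rowMeans(norm),
             log2FC = ifelse(bad, NA, b1 / log(2)),
             se = se / log(2), stat = stat, pvalue = p,
             row.names = rownames(counts))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment \code{p * m / rank} with cumulative-minimum
#' monotonicity enforcement; NAs are excluded from \code{m} and propagate.
#'
#' @param pvalues numeric vector in \code{[0, 1]} (NAs allowed).
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  ok <- which(!is.na(pvalues))
  m <- length(ok)
  if (!m) return(out)
  p <- pvalues[ok]
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * m / (m:1)))
  out[ok[o]] <- adj
  out
}

#' Call peak gains and losses
#'
#' A peak is a gain iff padj < \code{padj_cut} and fold change >
#' \code{fc_gain}; a loss iff padj < \code{padj_cut} and fold change <
#' \code{fc_loss}; otherwise (including NA) no change.
#'
#' @param res a [nb_wald_test()] result (a \code{padj} column is added if
#'   missing).
#' @param padj_cut,fc_gain,fc_loss thresholds (defaults 0.1, 1.25, 0.8).
#' @return \code{res} with \code{padj} and \code{call} columns.
#' @export
call_diff_peaks <- function(res, padj_cut = 0.1, fc_gain = 1.25,
                            fc_loss = 0.8) {
  if (is.null(res$padj)) res$padj <- bh_adjust(res$pvalue)
  fc <- 2^res$log2FC
  call <- rep("nochange", nrow(res))
  call[!is.na(res$padj) & res$padj < padj_cut & fc > fc_gain] <- "gain"
  call[!is.na(res$padj) & res$padj < padj_cut & fc < fc_loss] <- "loss"
  res$call <- call
  res
}

#' Assign peaks to genes
#'
#' A peak is assigned to every gene whose flank-extended extent
#' \code{[TSS - flank, PAS + flank]} it overlaps on the gene's strand
#' (unstranded peaks match any gene).
#'
#' @param peaks peak \code{GRanges}.
#' @param genes gene \code{GRanges} with \code{gene_id}.
#' @param flank promoter/terminator flank in bp.
#' @return \code{data.frame} with columns \code{peak} (index),
#'   \code{gene_id}.
#' @export
assign_peaks_to_genes <- function(peaks, genes, flank = 2000L) {
  ext <- suppressWarnings(GRanges(
    seqnames(genes),
    IRanges(pmax(1L, start(genes) - flank), end(genes) + flank),
    strand = strand(genes)))
  hits <- findOverlaps(peaks, ext, ignore.strand = FALSE)
  data.frame(peak = queryHits(hits),
             gene_id = genes$gene_id[subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Classify genes by their gain/loss peak tallies
#'
#' Genes shorter than \code{min_gene_length} (default 5 kb) are excluded.
#' A gene is RLG iff its gains outnumber losses at least
#' \code{ratio}-to-one (with at least one gain), RLL for the mirror image,
#' \code{none} with no called peaks at all, else \code{mixed}.
#'
#' @param peaks peak \code{GRanges} whose metadata carries a \code{call}
#'   column (from [call_diff_peaks()]).
#' @param genes gene \code{GRanges} with \code{gene_id}.
#' @param flank flank used for peak-to-gene assignment.
#' @param min_gene_length exclusion threshold in bp.
#' @param ratio the gains:losses dominance ratio.
#' @return \code{data.frame}: \code{gene_id}, \code{n_gain}, \code{n_loss},
#'   \code{class}.
#' @export
classify_genes <- function(peaks, genes, flank = 2000L,
                           min_gene_length = 5000L, ratio = 5) {
  keep <- width(genes) >= min_gene_length
  genes <- genes[keep]
  asg <- assign_peaks_to_genes(peaks, genes, flank)
  call <- mcols(peaks)$call
  tal <- data.frame(gene_id = genes$gene_id, n_gain = 0L, n_loss = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(asg)) {
    gains <- table(asg$gene_id[call[asg$peak] == "gain"])
    losses <- table(asg$gene_id[call[asg$peak] == "loss"])
    tal$n_gain <- as.integer(gains[tal$gene_id]); tal$n_gain[is.na(tal$n_gain)] <- 0L
    tal$n_loss <- as.integer(losses[tal$gene_id]); tal$n_loss[is.na(tal$n_loss)] <- 0L
  }
  tal$class <- classify_tallies(tal$n_gain, tal$n_loss, ratio)
  tal
}

#' @rdname classify_genes
#' @param n_gain,n_loss integer tallies.
#' @export
classify_tallies <- function(n_gain, n_loss, ratio = 5) {
  ifelse(n_gain == 0L & n_loss == 0L, "none",
         ifelse(n_gain >= ratio * n_loss & n_gain >= 1L, "RLG",
                ifelse(n_loss >= ratio * n_gain & n_loss >= 1L, "RLL",
                       "mixed")))
}

#' RNA-seq differential expression calls
#'
#' The same NB machinery applied to gene counts with the expression-level
#' thresholds: fold change at least 1.5x up or down and padj < 0.05.
#'
#' @param counts gene count matrix.
#' @param conditions condition labels per column.
#' @param reference baseline condition.
#' @param fc_min,padj_cut thresholds (defaults 1.5, 0.05).
#' @return \code{data.frame} per gene with test columns and \code{call} in
#'   \{up, down, nochange\}.
#' @export
rnaseq_de <- function(counts, conditions, reference = conditions[1],
                      fc_min = 1.5, padj_cut = 0.05) {
  sf <- size_factors(counts)
  disp <- estimate_dispersion(counts, sf, conditions)
  res <- nb_wald_test(counts, sf, disp$alpha, conditions, reference)
  res$padj <- bh_adjust(res$pvalue)
  fc <- 2^res$log2FC
  call <- rep("nochange", nrow(res))
  sig <- !is.na(res$padj) & res$padj < padj_cut
  call[sig & fc >= fc_min] <- "up"
  call[sig & fc <= 1 / fc_min] <- "down"
  res$call <- call
  res
}

#' Chromosome gene density versus gain/loss ratio
#'
#' Per chromosome, the gene density (genes per Mb) and the ratio of RLG to
#' RLL gene counts, with the Pearson correlation across chromosomes.
#'
#' @param gene_classes a [classify_genes()] result (or any data.frame with
#'   \code{gene_id}, \code{class}).
#' @param genes gene \code{GRanges} with \code{gene_id}.
#' @param chrom_sizes named chromosome lengths.
#' @return List with \code{per_chrom} (data.frame), \code{r}, \code{p}.
#' @export
chromosome_gain_loss_ratio <- function(gene_classes, genes, chrom_sizes) {
  ch <- as.character(seqnames(genes))[match(gene_classes$gene_id,
                                            genes$gene_id)]
  per <- lapply(names(chrom_sizes), function(cc) {
    sel <- ch == cc
    data.frame(chrom = cc,
               density = sum(sel) / (chrom_sizes[[cc]] / 1e6),
               n_rlg = sum(gene_classes$class[sel] == "RLG"),
               n_rll = sum(gene_classes$class[sel] == "RLL"))
  })
  per <- do.call(rbind, per)
  per$ratio <- ifelse(per$n_rll > 0, per$n_rlg / per$n_rll, NA)
  use <- !is.na(per$ratio)
  if (sum(use) < 3L)
    stopf("need at least 3 chromosomes with RLL genes")
  if (sd(per$density[use]) == 0 || sd(per$ratio[use]) == 0)
    stopf("zero variance across chromosomes; correlation undefined")
  ct <- cor.test(per$density[use], per$ratio[use])
  list(per_chrom = per, r = unname(ct$estimate), p = ct$p.value)
}
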