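#' @title Matched-control Monte-Carlo enrichment
#' @description Chromatin-feature enrichment of differential peak sets is
#'   judged against control peaks drawn from R-loop-forming genes that were
#'   not affected by the depletion (class none or mixed), matched on gene
#'   expression, gene length, genic compartment and peak length; promoter
#'   and terminator controls keep the target peak's precise offset relative
#'   to the control gene's TSS/PAS. Significance is Monte-Carlo:
#'   p = (1 + exceedances) / (1 + randomizations).
#' @name matched-enrichment
NULL

#' Annotate peaks with their gene and compartment
#'
#' Compartments: promoter = TSS +/- \code{flank}, terminator = PAS +/-
#' \code{flank}, gene body = the remainder of the gene, intergenic
#' otherwise; precedence promoter > terminator > body. The assigned gene is
#' the strand-matched gene whose flank-extended extent the peak overlaps
#' (first by precedence when several).
#'
#' @param peaks peak \code{GRanges}.
#' @param genes gene \code{GRanges} with \code{gene_id} and optionally
#'   \code{expression}.
#' @param flank compartment half-width (bp).
#' @return \code{peaks} with \code{gene_id}, \code{compartment},
#'   \code{gene_length}, \code{gene_expression}, \code{anchor_offset}
#'   metadata (offset of the peak start from the gene's TSS/PAS in the
#'   transcription frame; NA for body/intergenic).
#' @export
annotate_peak_compartments <- function(peaks, genes, flank = 2000L) {
  tss <- gene_tss(genes); pas <- gene_pas(genes)
  mk <- function(pos) suppressWarnings(GRanges(
    seqnames(genes), IRanges(pmax(1L, pos - flank), pos + flank),
    strand = strand(genes)))
  prom <- mk(tss); term <- mk(pas)
  n <- length(peaks)
  gene_idx <- rep(NA_integer_, n); comp <- rep("intergenic", n)
  fill <- function(region, label) {
    hits <- findOverlaps(peaks, region, ignore.strand = FALSE, select = "first")
    sel <- !is.na(hits) & is.na(gene_idx)
    gene_idx[sel] <<- hits[sel]
    comp[sel] <<- label
  }
  fill(prom, "promoter")
  fill(term, "terminator")
  fill(granges(genes), "body")
  mcols(peaks)$gene_id <- ifelse(is.na(gene_idx), NA,
                                 genes$gene_id[gene_idx])
  mcols(peaks)$compartment <- comp
  mcols(peaks)$gene_length <- ifelse(is.na(gene_idx), NA,
                                     width(genes)[gene_idx])
  expr <- if ("expression" %in% names(mcols(genes))) genes$expression else
    rep(NA_real_, length(genes))
  mcols(peaks)$gene_expression <- ifelse(is.na(gene_idx), NA,
                                         expr[gene_idx])
  dirg <- ifelse(as.character(strand(genes)) == "-", -1L, 1L)
  anchor <- ifelse(comp == "promoter", tss[gene_idx], pas[gene_idx])
  p5 <- ifelse(dirg[gene_idx] > 0, start(peaks), end(peaks))
  offs <- ifelse(comp %in% c("promoter", "terminator"),
                 dirg[gene_idx] * (p5 - anchor), NA)
  mcols(peaks)$anchor_offset <- offs
  peaks
}

#' Select matched control peaks
#'
#' For each target peak, \code{n_matches} control peaks are sampled without
#' replacement from candidates on unaffected (none/mixed) genes in the same
#' compartment, within \code{tol} (log2) of the target's gene length, gene
#' expression and peak length. If fewer than \code{n_matches} candidates
#' qualify, all tolerances are doubled stepwise (with a warning) up to
#' \code{max_relax} times; targets still unmatched are dropped and logged.
#' Promoter/terminator controls are re-positioned to the target's offset
#' from the control gene's anchor.
#'
#' @param targets annotated peaks ([annotate_peak_compartments()]) to match.
#' @param candidates annotated candidate peaks (control pool).
#' @param tol named log2 tolerances (\code{len}, \code{expr}, \code{peak}).
#' @param n_matches controls per target.
#' @param genes gene \code{GRanges} (needed to re-anchor
#'   promoter/terminator controls).
#' @param chrom_sizes named chromosome lengths for clipping.
#' @param seed RNG seed (reproducible matching).
#' @return List of class \code{MatchedControlSet}: \code{targets} (the
#'   matched subset), \code{controls} (\code{GRanges} with
#'   \code{target_idx}, \code{match_idx}), \code{n_matches},
#'   \code{dropped} (indices), \code{relaxed} (per-target relaxation
#'   steps).
#' @export
select_matched_controls <- function(targets, candidates,
                                    tol = c(len = 0.5, expr = 0.5,
                                            peak = 0.5),
                                    n_matches = 10L, genes = NULL,
                                    chrom_sizes = NULL, seed = NULL) {
  stopifnot(length(targets) > 0, length(candidates) > 0)
  with_seed(seed, {
    tmc <- mcols(targets); cmc <- mcols(candidates)
    dirg <- NULL
    if (!is.null(genes))
      dirg <- setNames(ifelse(as.character(strand(genes)) == "-", -1L, 1L),
                       genes$gene_id)
    ctl_rows <- list(); kept <- integer(0); relaxed <- integer(0)
    dropped <- integer(0)
    any_relaxed <- FALSE
    for (i in seq_along(targets)) {
      found <- NULL; level <- 0L
      repeat {
        f <- 2^level
        elig <- which(
          cmc$compartment == tmc$compartment[i] &
            cmc$gene_id != tmc$gene_id[i] &
            abs(log2(cmc$gene_length / tmc$gene_length[i])) <= tol[["len"]] * f &
            abs(log2(cmc$gene_expression / tmc$gene_expression[i])) <=
              tol[["expr"]] * f &
            abs(log2(width(candidates) / width(targets)[i])) <=
              tol[["peak"]] * f)
        if (length(elig) >= n_matches || level >= 4L) { found <- elig; break }
        level <- level + 1L
        any_relaxed <- TRUE
      }
      if (length(found) < 1L) { dropped <- c(dropped, i); next }
      pick <- if (length(found) <= n_matches) found else
        sample(found, n_matches)
      kept <- c(kept, i); relaxed <- c(relaxed, level)
      ctl_rows[[length(ctl_rows) + 1L]] <-
        data.frame(target = i, cand = pick,
                   match_idx = seq_along(pick))
    }
    if (!length(kept)) stopf("no target could be matched")
    df <- do.call(rbind, ctl_rows)
    ctl <- candidates[df$cand]
    # re-anchor promoter/terminator controls at the target's offset
    reanchor <- tmc$compartment[df$target] %in% c("promoter", "terminator")
    if (any(reanchor) && !is.null(genes)) {
      tssm <- setNames(gene_tss(genes), genes$gene_id)
      pasm <- setNames(gene_pas(genes), genes$gene_id)
      idx <- which(reanchor)
      gid <- mcols(ctl)$gene_id[idx]
      comp <- tmc$compartment[df$target[idx]]
      anch <- ifelse(comp == "promoter", tssm[gid], pasm[gid])
      d <- dirg[gid]
      offs <- tmc$anchor_offset[df$target[idx]]
      w <- width(ctl)[idx]
      p5 <- anch + d * offs
      new_start <- ifelse(d > 0, p5, p5 - w + 1L)
      if (!is.null(chrom_sizes)) {
        cs <- chrom_sizes[as.character(seqnames(ctl))[idx]]
        new_start <- pmax(1L, pmin(new_start, cs - w + 1L))
      } else new_start <- pmax(1L, new_start)
      ranges(ctl)[idx] <- IRanges(as.integer(new_start),
                                  width = w)
    }
    mcols(ctl)$target_idx <- match(df$target, kept)
    mcols(ctl)$match_idx <- df$match_idx
    if (any_relaxed)
      warnf("matching tolerances were relaxed for some targets")
    structure(list(targets = targets[kept], controls = ctl,
                   n_matches = n_matches, dropped = dropped,
                   relaxed = relaxed, tol = tol),
              class = "MatchedControlSet")
  })
}

#' Monte-Carlo overlap enrichment against matched controls
#'
#' Observed = share of targets overlapping the feature by >= 1 bp;
#' expected = mean share over \code{n_mc} control sets, each built by
#' drawing one matched control per target (resampling match indices when
#' \code{n_matches < n_mc}). The Monte-Carlo p is
#' \code{(1 + b) / (1 + n_mc)} for enrichment, mirrored for depletion,
#' two-sided = \code{2 min}, capped at 1. The star class reflects the
#' absolute observed overlap: < 10\% none, 10-25\% *, 25-50\% **, > 50\%
#' ***.
#'
#' @param mcs a [select_matched_controls()] result.
#' @param feature feature \code{GRanges}.
#' @param n_mc number of Monte-Carlo control sets (default 249).
#' @param seed RNG seed.
#' @return List of class \code{EnrichmentResult}: \code{feature},
#'   \code{observed}, \code{expected}, \code{ratio}, \code{stars},
#'   \code{p}, \code{p_enrich}, \code{p_deplete}, \code{n_targets},
#'   \code{flag}.
#' @export
overlap_enrichment <- function(mcs, feature, n_mc = 249L, seed = NULL) {
  stopifnot(inherits(mcs, "MatchedControlSet"))
  nm <- if (!is.null(metadata(feature)$name)) metadata(feature)$name else
    "feature"
  nt <- length(mcs$targets)
  if (length(feature) == 0L)
    return(structure(list(feature = nm, observed = NA, expected = NA,
                          ratio = NA, stars = NA, p = NA,
                          p_enrich = NA, p_deplete = NA, n_targets = nt,
                          flag = "empty feature"),
                     class = "EnrichmentResult"))
  obs_hit <- IRanges::overlapsAny(mcs$targets, feature,
                                  ignore.strand = TRUE)
  observed <- mean(obs_hit)
  ctl_hit <- IRanges::overlapsAny(mcs$controls, feature,
                                  ignore.strand = TRUE)
  tidx <- mcols(mcs$controls)$target_idx
  avail <- split(seq_along(ctl_hit), tidx)
  flat <- unlist(avail, use.names = FALSE)
  ln <- lengths(avail)
  off <- cumsum(c(0L, ln[-length(ln)]))
  fracs <- with_seed(seed, {
    vapply(seq_len(n_mc), function(s) {
      ki <- floor(runif(length(ln)) * ln) + 1L
      mean(ctl_hit[flat[off + ki]])
    }, 0)
  })
  expected <- mean(fracs)
  p_en <- (1 + sum(fracs >= observed)) / (1 + n_mc)
  p_de <- (1 + sum(fracs <= observed)) / (1 + n_mc)
  stars <- if (observed < 0.10) "none" else if (observed < 0.25) "*" else
    if (observed < 0.50) "**" else "***"
  ratio <- if (expected > 0) observed / expected else
    if (observed > 0) Inf else NA
  structure(list(feature = nm, observed = observed, expected = expected,
                 ratio = ratio,
                 stars = stars, p = min(1, 2 * min(p_en, p_de)),
                 p_enrich = p_en, p_deplete = p_de, n_targets = nt,
                 flag = NA_character_),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("%s: observed %.3f expected %.3f ratio %.2f [%s] p=%.4g\n",
              x$feature, x$observed, x$expected, x$ratio, x$stars, x$p))
  invisible(x)
}

#' Distance to the nearest feature interval
#'
#' Edge-to-edge gap in bp (0 when overlapping), strand-agnostic, by a
#' per-chromosome sorted sweep. Peaks on chromosomes without features get
#' \code{Inf}.
#'
#' @param peaks peak \code{GRanges}.
#' @param feature feature \code{GRanges} (merged).
#' @return Numeric vector of distances, one per peak.
#' @export
distance_to_nearest <- function(peaks, feature) {
  out <- rep(Inf, length(peaks))
  if (!length(peaks) || !length(feature)) return(out)
  fch <- as.character(seqnames(feature))
  pch <- as.character(seqnames(peaks))
  for (ch in unique(pch)) {
    fi <- which(fch == ch)
    if (!length(fi)) next
    fs <- start(feature)[fi]; fe <- end(feature)[fi]
    o <- order(fs)
    fs <- fs[o]; fe <- fe[o]
    fe_max <- cummax(fe)  # rightmost end seen so far, for the left gap
    pi <- which(pch == ch)
    ps <- start(peaks)[pi]; pe <- end(peaks)[pi]
    k <- findInterval(pe, fs)  # last feature starting at or before peak end
    left <- ifelse(k >= 1, ps - fe_max[pmax(k, 1)] - 1, Inf)
    right <- ifelse(k < length(fs), fs[pmin(k + 1, length(fs))] - pe - 1,
                    Inf)
    d <- pmax(pmin(left, right), 0)
    # overlap: a feature starting before peak end whose running max end
    # reaches the peak start
    ovl <- k >= 1 & fe_max[pmax(k, 1)] >= ps
    d[ovl] <- 0
    out[pi] <- d
  }
  out
}

#' Compare two distance samples (Mann-Whitney)
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum test: exact by full
#' enumeration when both samples have at most \code{exact_max}
#' observations, otherwise a normal approximation with tie correction and
#' continuity correction. Non-finite values are dropped (and counted).
#'
#' @param a,b numeric samples.
#' @param exact_max enumeration threshold (default 8).
#' @return List: \code{median_a}, \code{median_b}, \code{U} (for sample a),
#'   \code{p}, \code{method}, \code{n_dropped}.
#' @export
compare_distance_sets <- function(a, b, exact_max = 8L) {
  dropped <- sum(!is.finite(a)) + sum(!is.finite(b))
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) stopf("empty sample after dropping Inf/NA")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    comb <- utils::combn(n1 + n2, n1)
    rs <- colSums(matrix(r[comb], nrow = n1))
    Us <- rs - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(Us <= U), mean(Us >= U)))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    if (sig2 == 0) z <- 0
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(median_a = median(a), median_b = median(b), U = U, p = p,
       method = method, n_dropped = dropped)
}

#' Equal-occupancy fold-change bins
#'
#' Peaks are sorted by log2 fold change (ties broken by a stable sort on
#' id) and cut into \code{n_bins} bins whose occupancies differ by at most
#' one; per-bin medians of the fold change and a covariate are correlated
#' (Pearson) across bins.
#'
#' @param log2fc per-peak log2 fold changes.
#' @param covariate per-peak covariate (gene length, distance, replication
#'   signal, ...).
#' @param n_bins number of bins.
#' @param ids peak ids for deterministic tie-breaking.
#' @return List: \code{bins} (data.frame bin, n, median_log2fc,
#'   median_covariate), \code{r}, \code{p}, \code{assignment}.
#' @export
foldchange_bins <- function(log2fc, covariate, n_bins = 10L,
                            ids = seq_along(log2fc)) {
  n <- length(log2fc)
  stopifnot(length(covariate) == n, n >= n_bins)
  if (length(unique(log2fc)) == 1L)
    stopf("degenerate binning: constant log2FC")
  o <- order(log2fc, ids)
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  assign <- integer(n)
  assign[o] <- rep(seq_len(n_bins), sizes)
  bins <- do.call(rbind, lapply(seq_len(n_bins), function(bnum) {
    sel <- assign == bnum
    data.frame(bin = bnum, n = sum(sel),
               median_log2fc = median(log2fc[sel]),
               median_covariate = median(covariate[sel]))
  }))
  ct <- cor.test(bins$median_log2fc, bins$median_covariate)
  list(bins = bins, r = unname(ct$estimate), p = ct$p.value,
       assignment = assign)
}

#' Replication-timing phase assignment
#'
#' Each peak is assigned the phase whose depth-normalized mean signal over
#' the peak is largest (ties go to the earlier phase, in the order the
#' tracks are given); peaks with all-zero signal are unassigned. When a
#' matched-control set is supplied, the per-phase fractions of the targets
#' are compared to Monte-Carlo control sets.
#'
#' @param peaks peak \code{GRanges}.
#' @param phase_tracks named list of [binned_track()]s in cell-cycle order
#'   (e.g. G1b, S1, S2, S3, S4, G2), already depth-normalized.
#' @param mcs optional [select_matched_controls()] result whose targets are
#'   \code{peaks}.
#' @param n_mc Monte-Carlo control sets for the comparison.
#' @param seed RNG seed.
#' @return List: \code{phase} (factor per peak, NA if unassigned),
#'   \code{distribution}, and with controls \code{expected} and \code{p}
#'   (per-phase two-sided Monte-Carlo p).
#' @export
repliseq_phase_assignment <- function(peaks, phase_tracks, mcs = NULL,
                                      n_mc = 249L, seed = NULL) {
  phases <- names(phase_tracks)
  mean_sig <- function(gr) {
    sig <- vapply(phase_tracks, function(tr) {
      vapply(seq_along(gr), function(i) {
        ch <- as.character(seqnames(gr))[i]
        if (!ch %in% names(tr$values)) return(0)
        br <- bin_range(tr, start(gr)[i], min(end(gr)[i],
                                              tr$chrom_sizes[[ch]]))
        mean(tr$values[[ch]][br[1]:br[2]])
      }, 0)
    }, numeric(length(gr)))
    matrix(sig, nrow = length(gr))
  }
  assign_phase <- function(sig) {
    tot <- rowSums(sig)
    ph <- apply(sig, 1, which.max)  # which.max = earliest on ties
    ph[tot == 0] <- NA
    factor(phases[ph], levels = phases)
  }
  sig <- mean_sig(peaks)
  phase <- assign_phase(sig)
  distr <- prop.table(table(phase))
  out <- list(phase = phase, distribution = distr,
              n_unassigned = sum(is.na(phase)))
  if (!is.null(mcs)) {
    csig <- mean_sig(mcs$controls)
    cphase <- assign_phase(csig)
    tidx <- mcols(mcs$controls)$target_idx
    avail <- split(seq_along(cphase), tidx)
    flat <- unlist(avail, use.names = FALSE)
    ln <- lengths(avail)
    off <- cumsum(c(0L, ln[-length(ln)]))
    mats <- with_seed(seed, {
      vapply(seq_len(n_mc), function(s) {
        ki <- floor(runif(length(ln)) * ln) + 1L
        as.numeric(prop.table(table(cphase[flat[off + ki]])))
      }, numeric(length(phases)))
    })
    obs <- as.numeric(prop.table(table(factor(phase, levels = phases))))
    p <- vapply(seq_along(phases), function(k) {
      hi <- (1 + sum(mats[k, ] >= obs[k])) / (1 + n_mc)
      lo <- (1 + sum(mats[k, ] <= obs[k])) / (1 + n_mc)
      min(1, 2 * min(hi, lo))
    }, 0)
    out$expected <- setNames(rowMeans(mats), phases)
    out$p <- setNames(p, phases)
  }
  out
}
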