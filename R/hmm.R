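#' @title Two-state HMM peak calling
#' @description A hidden Markov model with a background and a peak state
#'   segments binned, strand-specific coverage into R-loop peaks. Emissions
#'   are negative binomial on bin counts (matching the counting noise of
#'   the assay) with a Gaussian-on-log1p fallback. Masked (blacklisted)
#'   bins break the chain: each uninterrupted stretch is treated as its own
#'   observation sequence.
#' @name peakcall-hmm
NULL

new_hmm_params <- function(pi, A, emission, bin_width = NA_integer_) {
  stopifnot(abs(sum(pi) - 1) < 1e-8, all(abs(rowSums(A) - 1) < 1e-8))
  structure(list(pi = pi, A = A, emission = emission,
                 bin_width = bin_width), class = "HmmParams")
}

#' @export
print.HmmParams <- function(x, ...) {
  cat(sprintf("HmmParams (%s emissions): background mean %.3g, peak mean %.3g\n",
              x$emission$type, x$emission$mu[1], x$emission$mu[2]))
  invisible(x)
}

# Per-state log emission densities for an observation vector.
hmm_logemit <- function(params, obs) {
  em <- params$emission
  K <- length(em$mu)
  out <- matrix(0, length(obs), K)
  if (em$type == "nb") {
    x <- round(obs)
    for (k in seq_len(K))
      out[, k] <- dnbinom(x, mu = em$mu[k],
                          size = 1 / max(em$alpha[k], 1e-8), log = TRUE)
  } else {
    y <- log1p(obs)
    for (k in seq_len(K))
      out[, k] <- dnorm(y, em$mu[k], max(em$sd[k], 1e-6), log = TRUE)
  }
  out
}

# Unmasked runs of a track as a list of (chrom, bins, values).
track_segments <- function(track, min_len = 1L) {
  segs <- list()
  for (ch in names(track$values)) {
    runs <- true_runs(!track$mask[[ch]])
    if (!nrow(runs)) next
    for (i in seq_len(nrow(runs))) {
      if (runs[i, 2] - runs[i, 1] + 1L < min_len) next
      segs[[length(segs) + 1L]] <- list(
        chrom = ch, from = runs[i, 1], to = runs[i, 2],
        values = track$values[[ch]][runs[i, 1]:runs[i, 2]])
    }
  }
  segs
}

#' Fit the two-state HMM by Baum-Welch
#'
#' EM on the unmasked bins of a track. States are relabeled at the end so
#' state 2 (peak) has the larger emission mean. The log-likelihood is
#' non-decreasing across iterations up to numerical tolerance; if
#' \code{max_iter} is reached without convergence the best parameters so
#' far are returned with a warning.
#'
#' @param track a [binned_track()] of raw bin counts.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @param emission \code{"nb"} (negative binomial on counts, default) or
#'   \code{"gaussian"} (Gaussian on log1p values).
#' @return An object of class \code{HmmParams}.
#' @export
fit_hmm <- function(track, max_iter = 50L, tol = 1e-6,
                    emission = c("nb", "gaussian")) {
  emission <- match.arg(emission)
  segs <- track_segments(track)
  allv <- unlist(lapply(segs, `[[`, "values"))
  if (length(allv) < 100L) stopf("need at least 100 unmasked bins")
  if (all(allv == 0)) stopf("degenerate fit: track is all zero")
  if (length(unique(allv)) == 1L)
    stopf("degenerate fit: constant track, states collapse")

  if (emission == "nb") {
    obs <- lapply(segs, function(s) round(s$values))
    mu0 <- max(mean(allv[allv <= quantile(allv, 0.9)]), 0.05)
    mu1 <- max(mean(allv[allv > quantile(allv, 0.98)]), mu0 * 3)
    em <- list(type = "nb", mu = c(mu0, mu1), alpha = c(0.1, 0.1))
  } else {
    obs <- lapply(segs, `[[`, "values")
    y <- log1p(allv)
    em <- list(type = "gaussian",
               mu = c(quantile(y, 0.4), quantile(y, 0.99)),
               sd = c(max(sd(y), 0.1), max(sd(y), 0.1)))
  }
  params <- new_hmm_params(c(0.9, 0.1),
                           matrix(c(0.995, 0.005, 0.05, 0.95), 2, 2,
                                  byrow = TRUE),
                           em, track$bin_width)

  best <- params; best_ll <- -Inf; prev_ll <- -Inf; converged <- FALSE
  for (iter in seq_len(max_iter)) {
    ll <- 0
    g1 <- numeric(2); trans <- matrix(0, 2, 2)
    sw <- numeric(2); swx <- numeric(2); swx2 <- numeric(2)
    for (s in seq_along(obs)) {
      le <- hmm_logemit(params, obs[[s]])
      fb <- hmm_forward_backward(le, log(params$A), log(params$pi))
      ll <- ll + fb$loglik
      g1 <- g1 + fb$gamma1
      trans <- trans + fb$trans
      x <- if (params$emission$type == "nb") round(obs[[s]]) else
        log1p(obs[[s]])
      for (k in 1:2) {
        gk <- fb$gamma[, k]
        sw[k] <- sw[k] + sum(gk)
        swx[k] <- swx[k] + sum(gk * x)
        swx2[k] <- swx2[k] + sum(gk * x^2)
      }
    }
    if (ll > best_ll) { best_ll <- ll; best <- params }
    if (is.finite(prev_ll) &&
        abs(ll - prev_ll) < tol * (abs(prev_ll) + 1)) {
      converged <- TRUE
      break
    }
    prev_ll <- ll
    mu <- swx / pmax(sw, 1e-12)
    vv <- swx2 / pmax(sw, 1e-12) - mu^2
    if (params$emission$type == "nb") {
      mu <- pmax(mu, 1e-4)
      params$emission$mu <- mu
      params$emission$alpha <- pmax((vv - mu) / mu^2, 1e-6)
    } else {
      params$emission$mu <- mu
      params$emission$sd <- sqrt(pmax(vv, 1e-8))
    }
    A <- trans / pmax(rowSums(trans), 1e-12)
    A <- pmax(A, 1e-6); A <- A / rowSums(A)
    params$A <- A
    pi <- g1 / sum(g1)
    params$pi <- pmax(pi, 1e-6) / sum(pmax(pi, 1e-6))
  }
  if (!converged)
    warnf("Baum-Welch did not converge in %d iterations; returning best fit",
          max_iter)
  params <- best
  # identifiability: state 2 is the peak state (larger mean)
  if (params$emission$mu[2] < params$emission$mu[1]) {
    sw2 <- c(2L, 1L)
    params$pi <- params$pi[sw2]
    params$A <- params$A[sw2, sw2]
    params$emission$mu <- params$emission$mu[sw2]
    if (!is.null(params$emission$alpha))
      params$emission$alpha <- params$emission$alpha[sw2]
    if (!is.null(params$emission$sd))
      params$emission$sd <- params$emission$sd[sw2]
  }
  if (abs(params$emission$mu[2] - params$emission$mu[1]) <
      1e-3 * (params$emission$mu[1] + 1e-9))
    stopf("degenerate fit: emission states collapsed")
  params
}

#' Most probable state path
#'
#' Standard Viterbi decoding; ties are broken toward the background state
#' so ambiguous bins are not called peaks.
#'
#' @param params an \code{HmmParams}.
#' @param observations numeric vector of bin values.
#' @return Integer vector of states (1 = background, 2 = peak); empty input
#'   gives an empty path.
#' @export
viterbi <- function(params, observations) {
  if (length(observations) == 0L) return(integer(0))
  le <- hmm_logemit(params, observations)
  as.integer(hmm_viterbi(le, log(params$A), log(params$pi)))
}

#' Posterior state probabilities
#'
#' Forward-backward posteriors; rows sum to one.
#'
#' @inheritParams viterbi
#' @return Matrix (length x 2) of posterior probabilities.
#' @export
state_posterior <- function(params, observations) {
  if (length(observations) == 0L) return(matrix(0, 0, 2))
  le <- hmm_logemit(params, observations)
  hmm_forward_backward(le, log(params$A), log(params$pi))$gamma
}

#' Decode peaks from a fitted HMM
#'
#' \code{"standard"} mode reports maximal runs of Viterbi peak-state bins.
#' \code{"high_sensitivity"} mode targets lower and trailing signal: bins
#' with posterior peak probability at least \code{p_core} (or called by
#' Viterbi) seed peaks, which are then extended outward through contiguous
#' bins with posterior at least \code{p_tail}. In both modes runs closer
#' than \code{merge_gap} are merged and runs shorter than
#' \code{min_peak_length} dropped; every standard-mode peak is contained in
#' some high-sensitivity peak by construction.
#'
#' @param params fitted \code{HmmParams} (compatible bin width).
#' @param track the [binned_track()] to decode.
#' @param mode \code{"standard"} or \code{"high_sensitivity"}.
#' @param p_core,p_tail posterior thresholds for seeds and tails.
#' @param merge_gap merge peaks separated by at most this many bp.
#' @param min_peak_length drop peaks shorter than this (bp).
#' @param sample sample identifier stored on each peak.
#' @return \code{GRanges} of peaks with \code{sample},
#'   \code{mean_posterior} and \code{mean_signal} metadata.
#' @export
decode_peaks <- function(params, track,
                         mode = c("standard", "high_sensitivity"),
                         p_core = 0.9, p_tail = 0.5, merge_gap = 500L,
                         min_peak_length = 300L, sample = "sample") {
  mode <- match.arg(mode)
  if (!is.na(params$bin_width) && params$bin_width != track$bin_width)
    stopf("params fitted at bin width %d, track has %d", params$bin_width,
          track$bin_width)
  bw <- track$bin_width
  res <- list()
  for (seg in track_segments(track)) {
    obs <- if (params$emission$type == "nb") round(seg$values) else
      seg$values
    vit <- viterbi(params, obs)
    post <- state_posterior(params, obs)[, 2]
    sel <- if (mode == "standard") {
      vit == 2L
    } else {
      cand <- post >= p_tail | vit == 2L
      seed <- post >= p_core | vit == 2L
      runs <- true_runs(cand)
      keep <- logical(length(cand))
      for (i in seq_len(nrow(runs)))
        if (any(seed[runs[i, 1]:runs[i, 2]]))
          keep[runs[i, 1]:runs[i, 2]] <- TRUE
      keep
    }
    runs <- true_runs(sel)
    if (!nrow(runs)) next
    gstart <- (seg$from + runs[, 1] - 2L) * bw + 1L
    gend <- pmin((seg$from + runs[, 2] - 1L) * bw,
                 track$chrom_sizes[[seg$chrom]])
    mp <- vapply(seq_len(nrow(runs)), function(i)
      mean(post[runs[i, 1]:runs[i, 2]]), 0)
    ms <- vapply(seq_len(nrow(runs)), function(i)
      mean(seg$values[runs[i, 1]:runs[i, 2]]), 0)
    res[[length(res) + 1L]] <- data.frame(
      chrom = seg$chrom, start = gstart, end = gend,
      mean_posterior = mp, mean_signal = ms)
  }
  if (!length(res))
    return(GRanges())
  df <- do.call(rbind, res)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = track$strand)
  mcols(gr)$mean_posterior <- df$mean_posterior
  mcols(gr)$mean_signal <- df$mean_signal
  gr <- sort(gr, ignore.strand = TRUE)
  # merge across gaps, then length filter
  merged <- reduce(gr, min.gapwidth = merge_gap + 1L, ignore.strand = FALSE,
                   with.revmap = TRUE)
  rv <- mcols(merged)$revmap
  mcols(merged)$mean_posterior <- vapply(rv, function(i)
    sum(gr$mean_posterior[i] * width(gr)[i]) / sum(width(gr)[i]), 0)
  mcols(merged)$mean_signal <- vapply(rv, function(i)
    sum(gr$mean_signal[i] * width(gr)[i]) / sum(width(gr)[i]), 0)
  mcols(merged)$revmap <- NULL
  merged <- merged[width(merged) >= min_peak_length]
  mcols(merged)$sample <- if (length(merged)) sample else character(0)
  merged
}

#' Union of peaks across samples
#'
#' Per strand, the interval union of every sample's peaks ("present in at
#' least one sample"); each union peak records the contributing samples.
#'
#' @param per_sample_peaks list of peak \code{GRanges} (as from
#'   [decode_peaks()]).
#' @return \code{GRanges} of union peaks with a comma-separated
#'   \code{samples} column and \code{peak_id}.
#' @export
union_peaks <- function(per_sample_peaks) {
  per_sample_peaks <- per_sample_peaks[lengths(per_sample_peaks) > 0]
  if (!length(per_sample_peaks)) return(GRanges())
  all_pk <- do.call(c, unname(lapply(per_sample_peaks, granges)))
  samples <- unlist(lapply(per_sample_peaks, function(p)
    as.character(mcols(p)$sample)))
  un <- reduce(sort(all_pk), ignore.strand = FALSE)
  hits <- findOverlaps(un, all_pk)
  contrib <- vapply(seq_along(un), function(i) {
    s <- unique(samples[subjectHits(hits)[queryHits(hits) == i]])
    paste(sort(s), collapse = ",")
  }, "")
  mcols(un)$samples <- contrib
  mcols(un)$peak_id <- sprintf("upeak_%06d", seq_along(un))
  un
}
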