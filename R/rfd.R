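#' @title Replication fork directionality segmentation
#' @description RFD = (C - W) / (C + W) from OK-seq Crick/Watson fragment
#'   counts per bin, segmented by a three-state HMM on smoothed bin-to-bin
#'   RFD increments into ascending (AS, replication initiation), descending
#'   (DS, termination) and flat states. Ascending runs are emitted as
#'   initiation zones.
#' @name rfd-hmm
NULL

#' Compute an RFD profile
#'
#' @param crick,watson [binned_track()]s of strand-specific fragment
#'   counts with identical binning.
#' @param min_count bins with fewer total fragments are set NA.
#' @return List of class \code{RFDProfile}: \code{rfd} (named list per
#'   chromosome, values in \code{[-1, 1]} or NA), \code{bin_width},
#'   \code{chrom_sizes}.
#' @export
compute_rfd <- function(crick, watson, min_count = 10L) {
  stopifnot(crick$bin_width == watson$bin_width,
            identical(names(crick$values), names(watson$values)))
  rfd <- lapply(names(crick$values), function(ch) {
    cc <- crick$values[[ch]]; ww <- watson$values[[ch]]
    if (any(cc < 0) || any(ww < 0)) stopf("negative counts on %s", ch)
    tot <- cc + ww
    r <- ifelse(tot >= min_count, (cc - ww) / pmax(tot, 1), NA_real_)
    r
  })
  names(rfd) <- names(crick$values)
  structure(list(rfd = rfd, bin_width = crick$bin_width,
                 chrom_sizes = crick$chrom_sizes),
            class = "RFDProfile")
}

#' Build an RFD profile from values
#'
#' Convenience constructor for pre-computed RFD tracks.
#'
#' @param rfd named list (per chromosome) of RFD values in \code{[-1, 1]}
#'   (NA allowed).
#' @param bin_width bin width in bp.
#' @param chrom_sizes named chromosome lengths.
#' @return An \code{RFDProfile}.
#' @export
rfd_profile <- function(rfd, bin_width, chrom_sizes) {
  if (is.numeric(rfd)) rfd <- setNames(list(rfd), names(chrom_sizes)[1])
  for (ch in names(rfd)) {
    v <- rfd[[ch]]
    if (any(v < -1 - 1e-9 | v > 1 + 1e-9, na.rm = TRUE))
      stopf("RFD outside [-1, 1] on %s", ch)
  }
  structure(list(rfd = rfd, bin_width = as.integer(bin_width),
                 chrom_sizes = chrom_sizes), class = "RFDProfile")
}

#' Segment an RFD profile into AS / DS / flat states
#'
#' The RFD signal is smoothed with a short running mean, differenced, and
#' decoded with a three-state HMM whose Gaussian emissions have fixed
#' means \code{+mu} (AS), \code{-mu} (DS) and 0 (flat); only the common
#' variance is estimated (EM). NA bins break the chain. Ascending runs of
#' at least \code{min_zone_bins} bins become initiation zones. The
#' construction is symmetric: negating the profile exactly swaps AS and DS
#' labels.
#'
#' @param profile an \code{RFDProfile}.
#' @param mu expected per-bin RFD increment inside a ramp (default 0.01 at
#'   1 kb bins; scale with bin width / expected zone size).
#' @param smooth_bins running-mean window (odd; default 7).
#' @param stay HMM self-transition probability.
#' @param min_zone_bins minimum AS run length kept as a zone.
#' @param max_iter EM iterations for the variance.
#' @return List: \code{zones} (\code{GRanges} of initiation zones with
#'   \code{mean_drfd}), \code{segments} (data.frame chrom, start, end,
#'   state), \code{sigma}.
#' @export
segment_rfd <- function(profile, mu = 0.01, smooth_bins = 7L, stay = 0.995,
                        min_zone_bins = 5L, max_iter = 25L) {
  stopifnot(inherits(profile, "RFDProfile"))
  bw <- profile$bin_width
  n_ok <- sum(vapply(profile$rfd, function(v) sum(!is.na(v)), 0))
  if (n_ok < 100L) stopf("need at least 100 non-NA bins")
  move <- (1 - stay) / 2
  A <- matrix(move, 3, 3); diag(A) <- stay
  logA <- log(A)
  logpi <- log(c(0.8, 0.1, 0.1))
  means <- c(0, mu, -mu)  # state 1 flat, 2 AS, 3 DS (ties favor flat)

  # gather diff segments
  segs <- list()
  for (ch in names(profile$rfd)) {
    runs <- true_runs(!is.na(profile$rfd[[ch]]))
    if (!nrow(runs)) next
    for (i in seq_len(nrow(runs))) {
      if (runs[i, 2] - runs[i, 1] + 1L < 3L) next
      x <- profile$rfd[[ch]][runs[i, 1]:runs[i, 2]]
      xs <- running_mean(x, smooth_bins)
      segs[[length(segs) + 1L]] <- list(chrom = ch, from = runs[i, 1],
                                        d = diff(xs))
    }
  }
  alld <- unlist(lapply(segs, `[[`, "d"))
  if (length(alld) < 10L || sd(alld) == 0)
    return(list(zones = GRanges(), segments = data.frame(), sigma = NA,
                flag = "degenerate (constant) profile"))
  sigma <- max(sd(alld), 1e-6)
  for (it in seq_len(max_iter)) {
    s2num <- 0; s2den <- 0
    for (s in segs) {
      le <- vapply(means, function(m) dnorm(s$d, m, sigma, log = TRUE),
                   numeric(length(s$d)))
      fb <- hmm_forward_backward(matrix(le, ncol = 3), logA, logpi)
      for (k in 1:3) {
        s2num <- s2num + sum(fb$gamma[, k] * (s$d - means[k])^2)
        s2den <- s2den + sum(fb$gamma[, k])
      }
    }
    new_sigma <- max(sqrt(s2num / s2den), 1e-6)
    if (abs(new_sigma - sigma) < 1e-8) { sigma <- new_sigma; break }
    sigma <- new_sigma
  }

  # Because the transition matrix has equal diagonal and equal off-diagonal
  # entries, moving a run-boundary bin into the neighbouring run changes
  # the path score only by the emission difference at that bin. Boundary
  # bins whose emissions tie exactly (possible with discrete count data)
  # are therefore reassigned canonically — to flat when a flat run is
  # involved, otherwise to the left run — so that negating the profile
  # swaps AS and DS labels exactly.
  canonicalize_ties <- function(path, le, tol = 1e-9) {
    n <- length(path)
    repeat {
      changed <- FALSE
      for (t in 2:n) {
        a <- path[t - 1L]; b <- path[t]
        if (a == b) next
        tgt_of <- function(x, y) if (x == 1L || y == 1L) 1L else x
        if (abs(le[t, a] - le[t, b]) < tol) {
          tgt <- tgt_of(a, b)
          if (path[t] != tgt) { path[t] <- tgt; changed <- TRUE }
        } else if (abs(le[t - 1L, a] - le[t - 1L, b]) < tol) {
          tgt <- tgt_of(a, b)
          if (tgt == 1L && path[t - 1L] != 1L) {
            path[t - 1L] <- 1L; changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    path
  }

  seg_rows <- list(); zone_rows <- list()
  for (s in segs) {
    le <- vapply(means, function(m) dnorm(s$d, m, sigma, log = TRUE),
                 numeric(length(s$d)))
    le <- matrix(le, ncol = 3)
    path <- as.integer(hmm_viterbi(le, logA, logpi))
    if (length(path) > 1L) path <- canonicalize_ties(path, le)
    lab <- c("flat", "AS", "DS")[path]
    r <- rle(lab)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      # diff index i sits between rfd bins i and i+1; a run i1..i2 of
      # drift spans rfd bins i1..i2+1
      b1 <- s$from + starts[j] - 1L
      b2 <- s$from + ends[j]
      gs <- (b1 - 1L) * bw + 1L
      ge <- min(b2 * bw, profile$chrom_sizes[[s$chrom]])
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        chrom = s$chrom, start = gs, end = ge, state = r$values[j])
      if (r$values[j] == "AS" && r$lengths[j] >= min_zone_bins)
        zone_rows[[length(zone_rows) + 1L]] <- data.frame(
          chrom = s$chrom, start = gs, end = ge,
          mean_drfd = mean(s$d[starts[j]:ends[j]]))
    }
  }
  segments <- if (length(seg_rows)) do.call(rbind, seg_rows) else
    data.frame()
  zones <- if (length(zone_rows)) {
    zdf <- do.call(rbind, zone_rows)
    z <- GRanges(zdf$chrom, IRanges(zdf$start, zdf$end))
    mcols(z)$mean_drfd <- zdf$mean_drfd
    sort(z)
  } else GRanges()
  list(zones = zones, segments = segments, sigma = sigma)
}
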