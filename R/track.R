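#' Binned coverage track
#'
#' Fixed-width binned coverage over a genome, one value per bin per
#' chromosome, with an optional exclusion mask (e.g. from a blacklist) and
#' the sample's mapped-read total used for depth normalization. Bin \code{i}
#' of a chromosome covers the 0-based half-open interval
#' \code{[(i-1)*bin_width, i*bin_width)}, clipped at the chromosome end; the
#' number of bins is \code{ceiling(chrom_length / bin_width)}.
#'
#' @param values named list (one entry per chromosome) of non-negative
#'   numeric vectors, or a single numeric vector with \code{chrom_sizes} of
#'   length one.
#' @param bin_width bin width in bp.
#' @param chrom_sizes named integer vector of chromosome lengths (bp).
#' @param strand one of \code{"+"}, \code{"-"}, \code{"."}.
#' @param mapped_read_total total mapped reads for the sample (> 0 required
#'   by [normalize_depth()]).
#' @param mask optional named list of logicals marking excluded bins.
#' @return An object of class \code{BinnedTrack}.
#' @export
binned_track <- function(values, bin_width, chrom_sizes, strand = ".",
                         mapped_read_total = NA_real_, mask = NULL) {
  if (is.numeric(values)) {
    if (length(chrom_sizes) != 1L)
      stopf("bare numeric `values` requires a single chromosome")
    values <- setNames(list(values), names(chrom_sizes))
  }
  if (!all(names(values) %in% names(chrom_sizes)))
    stopf("values name chromosomes absent from chrom_sizes")
  chrom_sizes <- chrom_sizes[names(values)]
  n_bins <- ceiling(chrom_sizes / bin_width)
  for (ch in names(values)) {
    v <- values[[ch]]
    if (length(v) != n_bins[[ch]])
      stopf("chromosome %s: expected %d bins, got %d", ch, n_bins[[ch]],
            length(v))
    if (any(v < 0, na.rm = TRUE))
      stopf("chromosome %s: negative bin values", ch)
  }
  if (is.null(mask))
    mask <- lapply(values, function(v) rep(FALSE, length(v)))
  stopifnot(strand %in% c("+", "-", "."))
  structure(list(values = values, mask = mask,
                 bin_width = as.integer(bin_width),
                 chrom_sizes = chrom_sizes, strand = strand,
                 mapped_read_total = mapped_read_total),
            class = "BinnedTrack")
}

#' @export
print.BinnedTrack <- function(x, ...) {
  cat(sprintf(
    "BinnedTrack: %d chromosome(s), bin %d bp, strand %s, %d bins (%d masked)\n",
    length(x$values), x$bin_width, x$strand,
    sum(lengths(x$values)), sum(vapply(x$mask, sum, 0L))))
  invisible(x)
}

# Bin index range overlapped by a 1-based closed interval.
bin_range <- function(track, start, end) {
  b1 <- (start - 1L) %/% track$bin_width + 1L
  b2 <- (end - 1L) %/% track$bin_width + 1L
  c(b1, b2)
}

# Genomic start (1-based) of each bin of a chromosome.
bin_starts <- function(track, chrom) {
  n <- length(track$values[[chrom]])
  (seq_len(n) - 1L) * track$bin_width + 1L
}

#' Mask or drop regions overlapping a blacklist
#'
#' Bins of a [binned_track()] that overlap any blacklist interval by at
#' least 1 bp are masked and ignored by all downstream counting, fitting and
#' decoding; intervals of a \code{GRanges} overlapping the blacklist are
#' dropped. The operation is idempotent and an empty blacklist is the
#' identity.
#'
#' @param x a \code{BinnedTrack} or a \code{GRanges}.
#' @param blacklist a \code{GRanges} of regions to exclude.
#' @return An object of the same type as \code{x}.
#' @export
exclude_regions <- function(x, blacklist) UseMethod("exclude_regions")

#' @export
exclude_regions.BinnedTrack <- function(x, blacklist) {
  if (length(blacklist) == 0L) return(x)
  bl <- as.data.frame(blacklist)
  for (ch in names(x$values)) {
    rows <- bl$seqnames == ch
    if (!any(rows)) next
    for (i in which(rows)) {
      br <- bin_range(x, bl$start[i], min(bl$end[i], x$chrom_sizes[[ch]]))
      if (br[1] <= length(x$mask[[ch]]))
        x$mask[[ch]][br[1]:min(br[2], length(x$mask[[ch]]))] <- TRUE
    }
  }
  x
}

#' @export
exclude_regions.GRanges <- function(x, blacklist) {
  if (length(blacklist) == 0L) return(x)
  x[!IRanges::overlapsAny(x, blacklist, ignore.strand = TRUE)]
}

#' Depth-normalize a set of binned tracks
#'
#' Scales every track by \code{reference / mapped_read_total}, where the
#' reference is the geometric mean of the mapped-read totals, so that bin
#' ratios within a sample are preserved exactly and the result does not
#' depend on sample order. Tracks belonging to the same sample (e.g. the
#' two strands) should carry the same \code{mapped_read_total}.
#'
#' @param tracks list of [binned_track()] objects.
#' @return List of scaled tracks (attribute \code{depth_scale} records the
#'   factor applied to each).
#' @export
normalize_depth <- function(tracks) {
  single <- inherits(tracks, "BinnedTrack")
  if (single) tracks <- list(tracks)
  totals <- vapply(tracks, function(t) as.double(t$mapped_read_total), 0)
  if (any(!is.finite(totals) | totals <= 0))
    stopf("every track needs mapped_read_total > 0")
  ref <- geometric_mean(totals)
  out <- lapply(seq_along(tracks), function(i) {
    t <- tracks[[i]]
    sc <- ref / totals[i]
    t$values <- lapply(t$values, function(v) v * sc)
    attr(t, "depth_scale") <- sc
    t
  })
  names(out) <- names(tracks)
  if (single) out[[1]] else out
}
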