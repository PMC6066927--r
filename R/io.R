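#' @title Standard-format I/O
#' @description Readers and writers for BED3/6/12, GTF, bedGraph and
#'   chrom.sizes files. Files use the 0-based half-open BED convention (GTF
#'   is 1-based closed); in memory everything is a \code{GRanges} under the
#'   usual Bioconductor 1-based closed convention, converted at the file
#'   boundary.
#' @name core-io
NULL

#' Read a chrom.sizes file
#' @param path two-column TSV (chromosome, length).
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 2L) stopf("%s: expected two columns", path)
  setNames(as.integer(dt[[2]]), as.character(dt[[1]]))
}

#' Write a chrom.sizes file
#' @param chrom_sizes named integer vector.
#' @param path output path.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  fwrite(data.table(names(chrom_sizes), unname(chrom_sizes)), path,
         sep = "\t", col.names = FALSE)
  invisible(path)
}

# Shared BED-style line validation; start0/end0 are 0-based half-open.
validate_bed_coords <- function(path, start0, end0) {
  bad <- which(!is.finite(start0) | !is.finite(end0))
  if (length(bad))
    stopf("%s: malformed coordinates at line %d", path, bad[1])
  bad <- which(end0 <= start0)
  if (length(bad))
    stopf("%s: end <= start at line %d", path, bad[1])
  bad <- which(start0 < 0)
  if (length(bad))
    stopf("%s: negative start at line %d", path, bad[1])
  invisible(TRUE)
}

#' Read intervals or genes from BED/GTF
#'
#' \code{format = "bed"} accepts BED3 or BED6 and returns a \code{GRanges}
#' (strand from column 6 when present). \code{format = "bed12"} and
#' \code{format = "gtf"} return gene models: a \code{GRanges} with
#' \code{gene_id} metadata. \code{"auto"} guesses from the file extension.
#' Malformed lines raise an error naming the line number; intervals with
#' \code{end <= start} are a validation error.
#'
#' @param path input file.
#' @param format one of \code{"auto"}, \code{"bed"}, \code{"bed12"},
#'   \code{"gtf"}.
#' @return A \code{GRanges}.
#' @export
read_intervals <- function(path, format = c("auto", "bed", "bed12", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, gtf = "gtf", gff = "gtf", bed12 = "bed12", "bed")
  }
  switch(format,
         bed = read_bed(path),
         bed12 = read_bed12_genes(path),
         gtf = read_gtf_genes(path))
}

#' @rdname read_intervals
#' @export
read_bed <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
              colClasses = list(character = 1))
  if (nrow(dt) == 0L)
    return(GRanges())
  if (ncol(dt) < 3L) stopf("%s: fewer than 3 BED columns", path)
  start0 <- suppressWarnings(as.numeric(dt[[2]]))
  end0 <- suppressWarnings(as.numeric(dt[[3]]))
  validate_bed_coords(path, start0, end0)
  str <- if (ncol(dt) >= 6L) {
    s <- as.character(dt[[6]])
    s[!s %in% c("+", "-")] <- "*"
    s
  } else "*"
  gr <- GRanges(dt[[1]], IRanges(start0 + 1, end0), strand = str)
  if (ncol(dt) >= 4L) mcols(gr)$name <- as.character(dt[[4]])
  if (ncol(dt) >= 5L) mcols(gr)$score <- suppressWarnings(as.numeric(dt[[5]]))
  gr
}

#' @rdname read_intervals
#' @export
read_bed12_genes <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 12L) stopf("%s: fewer than 12 BED12 columns", path)
  start0 <- as.numeric(dt[[2]]); end0 <- as.numeric(dt[[3]])
  validate_bed_coords(path, start0, end0)
  gr <- GRanges(dt[[1]], IRanges(start0 + 1, end0),
                strand = ifelse(dt[[6]] %in% c("+", "-"), dt[[6]], "*"))
  mcols(gr)$gene_id <- as.character(dt[[4]])
  gr
}

#' @rdname read_intervals
#' @export
read_gtf_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if ("type" %in% names(mcols(gr)) && any(gr$type == "gene"))
    gr <- gr[gr$type == "gene"]
  out <- granges(gr)
  mcols(out)$gene_id <- if ("gene_id" %in% names(mcols(gr)))
    as.character(gr$gene_id) else as.character(seq_along(gr))
  out
}

#' Write intervals as BED
#'
#' BED6 with 0-based half-open coordinates. \code{name} and \code{score}
#' default to the corresponding metadata columns when present.
#'
#' @param gr a \code{GRanges}.
#' @param path output path.
#' @param name,score optional vectors overriding metadata columns.
#' @export
write_bed <- function(gr, path, name = NULL, score = NULL) {
  mc <- mcols(gr)
  if (is.null(name)) name <- if ("name" %in% names(mc))
    as.character(mc$name) else rep(".", length(gr))
  if (is.null(score)) score <- if ("score" %in% names(mc))
    mc$score else rep(0, length(gr))
  str <- as.character(strand(gr)); str[str == "*"] <- "."
  fwrite(data.table(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                    name, score, str),
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write gene models as BED12
#' @param genes \code{GRanges} with a \code{gene_id} column.
#' @param path output path.
#' @export
write_bed12_genes <- function(genes, path) {
  str <- as.character(strand(genes)); str[str == "*"] <- "."
  fwrite(data.table(as.character(seqnames(genes)), start(genes) - 1L,
                    end(genes), genes$gene_id, 0L, str,
                    start(genes) - 1L, end(genes), "0,0,0", 1L,
                    width(genes), 0L),
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph into a binned track
#'
#' Each bin value is the length-weighted mean of the bedGraph values
#' covering it; uncovered bases contribute zero. Track definition lines are
#' ignored. Intervals extending past the chromosome end are a validation
#' error.
#'
#' @param path bedGraph file (0-based half-open, non-overlapping intervals
#'   per chromosome).
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param bin_width bin width in bp (default 100).
#' @param strand strand label for the resulting track.
#' @param mapped_read_total mapped-read total carried by the track.
#' @return A [binned_track()].
#' @export
read_bedgraph <- function(path, chrom_sizes, bin_width = 100L, strand = ".",
                          mapped_read_total = NA_real_) {
  dt <- if (file.exists(path) && file.size(path) > 0) {
    d <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
               colClasses = list(character = 1))
    if (nrow(d)) d[!grepl("^track|^#", d[[1]])] else d
  } else data.table()
  n_bins <- ceiling(chrom_sizes / bin_width)
  values <- lapply(n_bins, function(n) numeric(n))
  if (nrow(dt) > 0L) {
    if (ncol(dt) < 4L) stopf("%s: fewer than 4 bedGraph columns", path)
    chrom <- as.character(dt[[1]])
    start0 <- suppressWarnings(as.numeric(dt[[2]]))
    end0 <- suppressWarnings(as.numeric(dt[[3]]))
    val <- suppressWarnings(as.numeric(dt[[4]]))
    validate_bed_coords(path, start0, end0)
    bad <- which(is.na(val))
    if (length(bad)) stopf("%s: non-numeric value at line %d", path, bad[1])
    unknown <- which(!chrom %in% names(chrom_sizes))
    if (length(unknown))
      stopf("%s: unknown chromosome '%s' at line %d", path,
            chrom[unknown[1]], unknown[1])
    over <- which(end0 > chrom_sizes[chrom])
    if (length(over))
      stopf("%s: interval past chromosome end at line %d", path, over[1])
    for (ch in unique(chrom)) {
      rows <- chrom == ch
      values[[ch]] <- bin_cover(start0[rows], end0[rows], val[rows],
                                n_bins[[ch]], bin_width,
                                chrom_sizes[[ch]])
    }
  }
  binned_track(values, bin_width, chrom_sizes, strand = strand,
               mapped_read_total = mapped_read_total)
}

# Length-weighted aggregation of 0-based half-open intervals onto bins.
bin_cover <- function(start0, end0, val, n_bins, bin_width, chrom_len) {
  out <- numeric(n_bins)
  b1 <- start0 %/% bin_width + 1
  b2 <- (end0 - 1) %/% bin_width + 1
  one <- b1 == b2
  if (any(one))  # fast path: interval within one bin
    out <- out + unname(tapply2(val[one] * (end0[one] - start0[one]),
                                b1[one], n_bins))
  for (i in which(!one)) {
    bins <- b1[i]:b2[i]
    lo <- pmax(start0[i], (bins - 1) * bin_width)
    hi <- pmin(end0[i], bins * bin_width)
    out[bins] <- out[bins] + val[i] * (hi - lo)
  }
  span <- pmin(bin_width, chrom_len - (seq_len(n_bins) - 1) * bin_width)
  out / span
}

tapply2 <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Write a binned track as bedGraph
#'
#' Runs of equal-valued bins are merged; zero-valued runs are omitted
#' (uncovered bases read back as zero). Values are written with full
#' precision so a read/write/read round trip is exact.
#'
#' @param track a [binned_track()].
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  pieces <- list()
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0
    if (!any(keep)) next
    pieces[[ch]] <- data.table(
      chrom = ch,
      start = (starts[keep] - 1L) * track$bin_width,
      end = pmin(ends[keep] * track$bin_width, track$chrom_sizes[[ch]]),
      value = r$values[keep])
  }
  dt <- if (length(pieces)) data.table::rbindlist(pieces) else
    data.table(chrom = character(), start = integer(), end = integer(),
               value = numeric())
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Build a feature set
#'
#' Sorts and merges intervals into the canonical per-chromosome
#' non-overlapping form used by all overlap and distance analyses.
#'
#' @param gr a \code{GRanges}.
#' @param name feature-set name (e.g. \code{"LAD"}, \code{"H3K9me3"}).
#' @return A merged, sorted \code{GRanges} with \code{metadata(x)$name} set.
#' @export
feature_set <- function(gr, name = "feature") {
  out <- reduce(sort(gr), ignore.strand = TRUE)
  metadata(out)$name <- name
  out
}

#' TSS and PAS positions of gene models
#'
#' The transcription start site is the 5' end (start for \code{+} genes,
#' end for \code{-} genes); the polyadenylation site is the 3' end.
#'
#' @param genes \code{GRanges} gene models.
#' @return Integer vector of positions (1-based).
#' @export
gene_tss <- function(genes)
  ifelse(as.character(strand(genes)) == "-", end(genes), start(genes))

#' @rdname gene_tss
#' @export
gene_pas <- function(genes)
  ifelse(as.character(strand(genes)) == "-", start(genes), end(genes))
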