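# Coordinate and proportion arithmetic.  Internal convention: 1-based
# inclusive endpoints as printed in genome reports; segment lengths are the
# plain coordinate difference |b - a| (printed Mb figures are differences,
# not inclusive lengths).

#' Segment length from a coordinate pair
#'
#' Length of the segment between two genomic coordinates, as the plain
#' absolute difference in bp, plus the same value in Mb rounded
#' half-away-from-zero to two decimals (the precision used for printed
#' block sizes such as "40.09 Mb").
#'
#' @param a,b coordinates in bp (1-based, order-free).
#' @return list with `bp` and `mb`.
#' @export
#' @examples
#' segment_length(44595487, 84684295)  # 40088808 bp, 40.09 Mb
segment_length <- function(a, b) {
  if (any(c(a, b) < 1)) stop_cfg("coordinates must be >= 1")
  bp <- abs(b - a)
  list(bp = bp, mb = round_half_away(bp / 1e6, 2))
}

#' Percentage of a count
#'
#' `100 * k / n`, rounded half-away-from-zero to two decimals, the rounding
#' needed to reproduce conventionally printed proportions (e.g. 143 of 189
#' genes = 75.66).
#'
#' @param k numerator count, `0 <= k <= n`.
#' @param n denominator count, `>= 1`.
#' @return percentage with two decimals.
#' @export
percent <- function(k, n) {
  if (length(n) != length(k) && length(n) != 1)
    stop_cfg("k and n lengths differ")
  if (any(n < 1)) stop_cfg("undefined denominator: n must be >= 1")
  if (any(k < 0 | k > n)) stop_cfg("k must satisfy 0 <= k <= n")
  round_half_away(100 * k / n, 2)
}

#' Read genomic intervals
#'
#' Reads BED (0-based half-open, converted on read) or a 2/3-column TSV of
#' printed 1-based inclusive coordinates into the internal 1-based inclusive
#' convention.  Start/end are normalized so start <= end.
#'
#' @param path file path; format chosen by extension (`.bed` vs anything
#'   else) unless `format` is given.
#' @param format `"bed"` or `"tsv"`.
#' @return data.frame with `contig`, `start`, `end`, `name`.
#' @export
read_intervals <- function(path, format = NULL) {
  format <- format %||% if (grepl("\\.bed$", path, ignore.case = TRUE))
    "bed" else "tsv"
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    df <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     name = if (!is.null(gr$name)) gr$name else
                       paste0("iv", seq_along(gr)),
                     stringsAsFactors = FALSE)
  } else {
    raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                      comment.char = "#")
    if (ncol(raw) < 3) stop_cfg("interval TSV needs contig, start, end")
    df <- data.frame(contig = as.character(raw[[1]]),
                     start = as.numeric(raw[[2]]), end = as.numeric(raw[[3]]),
                     name = if (ncol(raw) >= 4) as.character(raw[[4]]) else
                       paste0("iv", seq_len(nrow(raw))),
                     stringsAsFactors = FALSE)
  }
  swap <- df$start > df$end
  if (any(swap)) {
    tmp <- df$start[swap]; df$start[swap] <- df$end[swap]; df$end[swap] <- tmp
  }
  df
}

#' Overlapping interval pairs
#'
#' All pairs (one interval from `a`, one from `b`) whose 1-based inclusive
#' spans intersect in at least 1 bp on the same contig.
#'
#' @param a,b interval data.frames as from [read_intervals()].
#' @return data.frame of index pairs `i` (into `a`), `j` (into `b`) and the
#'   intersection length `overlap_bp`.
#' @export
interval_overlaps <- function(a, b) {
  gra <- GenomicRanges::GRanges(a$contig, IRanges::IRanges(a$start, a$end))
  grb <- GenomicRanges::GRanges(b$contig, IRanges::IRanges(b$start, b$end))
  hits <- GenomicRanges::findOverlaps(gra, grb, minoverlap = 1L)
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[i], b$end[j]) - pmax(a$start[i], b$start[j]) + 1
  data.frame(i = i, j = j, overlap_bp = ov)
}

#' Write intervals as BED
#'
#' Converts the internal 1-based inclusive intervals to BED's 0-based
#' half-open convention.
#'
#' @param df data.frame with `contig`, `start`, `end` and optional `name`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(df$contig, as.integer(df$start) - 1L, as.integer(df$end),
                    if (!is.null(df$name)) df$name else ".")
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
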