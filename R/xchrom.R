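# Reference-relative haplotype coding over an X-chromosome LD block,
# classification into the two major backgrounds (N, S) and recombinant
# mosaics, and localization/aggregation of recombination intervals.

#' Encode block haplotypes relative to the reference genome
#'
#' For each haplotype and block marker: 0 when the carried allele equals
#' the reference allele, 1 when opposite, `NA` when missing.  Males (sex
#' `"M"`) contribute a single haplotype; females both phased haplotypes.
#'
#' @param gt a `genotype_table`.
#' @param block list or data.frame row with `contig`, `start`, `end`.
#' @param ref_alleles optional 0/1 vector giving, per block marker, which
#'   allele index is the reference background (default 0 for all markers,
#'   i.e. the VCF REF allele).
#' @return matrix haplotypes x markers with rownames
#'   `<sample>.a`/`<sample>.b` (males `.a` only); attributes `positions`
#'   and `sample` (sample of each row).
#' @export
encode_reference_relative <- function(gt, block, ref_alleles = NULL) {
  vi <- which(gt$variants$contig == block$contig &
                gt$variants$pos >= block$start & gt$variants$pos <= block$end)
  if (!length(vi)) stop_cfg("no markers inside the block interval")
  ref_alleles <- ref_alleles %||% rep(0L, length(vi))
  if (length(ref_alleles) != length(vi))
    stop_cfg("ref_alleles must have one entry per block marker")
  if (anyNA(ref_alleles)) stop_cfg("marker lacking reference allele")
  H <- haplotype_matrix(subset_gt(gt, variants = vi))
  male <- gt$samples$sex == "M" & !is.na(gt$samples$sex)
  drop_col <- rep(FALSE, ncol(H))
  drop_col[2 * which(male)] <- TRUE       # males: haplotype .b is a copy
  H <- H[, !drop_col, drop = FALSE]
  M <- t(H)                               # haplotypes x markers
  M <- 1L * sweep(M, 2, ref_alleles, `!=`)
  attr(M, "positions") <- gt$variants$pos[vi]
  attr(M, "sample") <- sub("\\.[ab]$", "", rownames(M))
  M
}

.match_fraction <- function(row, consensus, informative) {
  ok <- informative & !is.na(row) & !is.na(consensus)
  if (!any(ok)) return(NA_real_)
  mean(row[ok] == consensus[ok])
}

#' Call major block haplotypes and recombinants
#'
#' Builds per-marker majority consensus haplotypes N and S from declared
#' anchor haplotype rows, then scores every haplotype row by its match
#' fraction to each consensus over informative markers (where N and S
#' differ).  Rows matching exactly one consensus at `>= purity` are classed
#' N or S; rows that fit an N/S mosaic with every segment matching its
#' background at `>= purity` are recombinants (with breakpoint intervals
#' from [localize_breakpoints()]); everything else is unclassified.
#'
#' @param M reference-relative matrix from [encode_reference_relative()].
#' @param anchors_n,anchors_s character vectors of sample names anchoring
#'   the N and S backgrounds.
#' @param purity minimum per-class match fraction (default 0.95).
#' @param switch_penalty mismatch-equivalent cost of a background switch in
#'   the segmentation dynamic program (default 3).
#' @return list: `consensus_n`, `consensus_s`, `informative` (logical per
#'   marker), `calls` (data.frame: hap, sample, class, match_n, match_s,
#'   n_breakpoints), `breakpoints` (data.frame of intervals: hap, sample,
#'   left_pos, right_pos).
#' @export
call_major_haplotypes <- function(M, anchors_n, anchors_s, purity = 0.95,
                                  switch_penalty = 3) {
  smp <- attr(M, "sample")
  pos <- attr(M, "positions")
  rows_n <- smp %in% anchors_n
  rows_s <- smp %in% anchors_s
  if (!any(rows_n)) stop_cfg("empty N anchor set")
  if (!any(rows_s)) stop_cfg("empty S anchor set")
  cons <- function(rows) {
    cm <- colMeans(M[rows, , drop = FALSE], na.rm = TRUE)
    out <- as.integer(cm >= 0.5)
    out[is.nan(cm)] <- NA_integer_
    out
  }
  consN <- cons(rows_n); consS <- cons(rows_s)
  informative <- !is.na(consN) & !is.na(consS) & consN != consS
  calls <- list(); bps <- list()
  for (r in seq_len(nrow(M))) {
    row <- M[r, ]
    mn <- .match_fraction(row, consN, informative)
    ms <- .match_fraction(row, consS, informative)
    cls <- "unclassified"; nbp <- 0L
    if (!is.na(mn) && !is.na(ms)) {
      if (mn >= purity && ms < purity) cls <- "N"
      else if (ms >= purity && mn < purity) cls <- "S"
      else if (mn >= purity && ms >= purity) cls <- if (mn >= ms) "N" else "S"
      else {
        seg <- .segment_backgrounds(row, consN, consS, informative,
                                    switch_penalty)
        if (!is.null(seg) && length(seg$segments) > 1 &&
            all(vapply(seg$segments, `[[`, numeric(1), "match") >= purity)) {
          cls <- sprintf("recombinant-%d", length(seg$segments) - 1L)
          nbp <- length(seg$segments) - 1L
          iv <- localize_breakpoints(row, consN, consS, pos,
                                    informative, switch_penalty)
          if (nrow(iv)) {
            iv$hap <- rownames(M)[r]; iv$sample <- smp[r]
            bps[[length(bps) + 1]] <- iv
          }
        }
      }
    }
    calls[[r]] <- data.frame(hap = rownames(M)[r], sample = smp[r],
                             class = cls, match_n = mn, match_s = ms,
                             n_breakpoints = nbp, stringsAsFactors = FALSE)
  }
  list(consensus_n = consN, consensus_s = consS, informative = informative,
       calls = do.call(rbind, calls),
       breakpoints = if (length(bps)) do.call(rbind, bps) else
         data.frame(left_pos = numeric(), right_pos = numeric(),
                    hap = character(), sample = character()))
}

# Viterbi segmentation of one haplotype row into N/S background runs over
# informative markers: per-marker cost = mismatch to the segment's
# background; switching backgrounds costs `switch_penalty` mismatches.
.segment_backgrounds <- function(row, consN, consS, informative,
                                 switch_penalty) {
  use <- which(informative & !is.na(row))
  if (!length(use)) return(NULL)
  mmN <- as.integer(row[use] != consN[use])
  mmS <- as.integer(row[use] != consS[use])
  k <- length(use)
  costN <- numeric(k); costS <- numeric(k)
  fromN <- integer(k); fromS <- integer(k)     # 1 = stayed, 2 = switched
  costN[1] <- mmN[1]; costS[1] <- mmS[1]
  for (t in 2:max(k, 2)) {
    if (k == 1) break
    # ties prefer the switch, so an exactly balanced mosaic is segmented
    stayN <- costN[t - 1]; swN <- costS[t - 1] + switch_penalty
    costN[t] <- mmN[t] + min(stayN, swN); fromN[t] <- if (stayN < swN) 1L else 2L
    stayS <- costS[t - 1]; swS <- costN[t - 1] + switch_penalty
    costS[t] <- mmS[t] + min(stayS, swS); fromS[t] <- if (stayS < swS) 1L else 2L
  }
  state <- character(k)
  state[k] <- if (costN[k] < costS[k] ||
                  (costN[k] == costS[k] && mmN[k] <= mmS[k])) "N" else "S"
  if (k > 1) for (t in k:2) {
    sw <- if (state[t] == "N") fromN[t] else fromS[t]
    state[t - 1] <- if (sw == 1L) state[t] else setdiff(c("N", "S"), state[t])
  }
  runs <- rle(state)
  stops <- cumsum(runs$lengths)
  starts <- c(1, head(stops, -1) + 1)
  segments <- lapply(seq_along(runs$values), function(s) {
    idx <- use[starts[s]:stops[s]]
    bg <- runs$values[s]
    mm <- if (bg == "N") row[idx] != consN[idx] else row[idx] != consS[idx]
    list(background = bg, first = idx[1], last = idx[length(idx)],
         match = 1 - mean(mm))
  })
  list(segments = segments, marker_index = use, state = state)
}

#' Localize recombination breakpoints in a mosaic haplotype
#'
#' Segments the haplotype into N/S background runs (dynamic program with a
#' switch penalty) over informative markers, and reports each breakpoint as
#' the open interval between the last informative marker matching the left
#' background and the first informative marker matching the right
#' background.
#'
#' @param row 0/1 reference-relative haplotype vector.
#' @param consN,consS consensus background vectors.
#' @param positions marker positions (bp).
#' @param informative logical: markers where the consensuses differ
#'   (computed when `NULL`).
#' @param switch_penalty segmentation switch cost (default 3).
#' @return data.frame of intervals: `left_pos`, `right_pos`, `left_bg`,
#'   `right_bg`.
#' @export
localize_breakpoints <- function(row, consN, consS, positions,
                                 informative = NULL, switch_penalty = 3) {
  informative <- informative %||%
    (!is.na(consN) & !is.na(consS) & consN != consS)
  if (!any(informative & !is.na(row)))
    stop_cfg("no informative markers for breakpoint localization")
  seg <- .segment_backgrounds(row, consN, consS, informative, switch_penalty)
  segs <- seg$segments
  if (length(segs) < 2)
    return(data.frame(left_pos = numeric(), right_pos = numeric(),
                      left_bg = character(), right_bg = character()))
  do.call(rbind, lapply(seq_len(length(segs) - 1), function(s)
    data.frame(left_pos = positions[segs[[s]]$last],
               right_pos = positions[segs[[s + 1]]$first],
               left_bg = segs[[s]]$background,
               right_bg = segs[[s + 1]]$background,
               stringsAsFactors = FALSE)))
}

#' Aggregate recombination intervals and the conserved core
#'
#' Clusters per-haplotype breakpoint intervals by positional overlap into
#' interval groups; each group's maximal range is the union (min left, max
#' right).  With at least two groups, the conserved core is the segment
#' between the first group's right edge and the second group's left edge
#' (plain-difference length, reported in bp and Mb).
#'
#' @param breakpoints data.frame with `left_pos`, `right_pos` (one row per
#'   breakpoint interval).
#' @return list: `groups` (data.frame group, start, end, n_intervals),
#'   `core` (`NULL` or list interval + length), empty result when no
#'   recombinants.
#' @export
aggregate_recomb_intervals <- function(breakpoints) {
  if (is.null(breakpoints) || nrow(breakpoints) == 0)
    return(list(groups = data.frame(group = integer(), start = numeric(),
                                    end = numeric(), n_intervals = integer()),
                core = NULL))
  iv <- breakpoints[order(breakpoints$left_pos), , drop = FALSE]
  grp <- integer(nrow(iv)); g <- 1L; grp[1] <- 1L
  cur_end <- iv$right_pos[1]
  for (r in seq_len(nrow(iv))[-1]) {
    if (iv$left_pos[r] <= cur_end) {
      grp[r] <- g
      cur_end <- max(cur_end, iv$right_pos[r])
    } else {
      g <- g + 1L; grp[r] <- g; cur_end <- iv$right_pos[r]
    }
  }
  groups <- do.call(rbind, lapply(seq_len(g), function(k)
    data.frame(group = k, start = min(iv$left_pos[grp == k]),
               end = max(iv$right_pos[grp == k]),
               n_intervals = sum(grp == k))))
  core <- NULL
  if (g >= 2) {
    a <- groups$end[1]; b <- groups$start[2]
    len <- segment_length(a, b)
    core <- list(start = a, end = b, bp = len$bp, mb = len$mb)
  }
  list(groups = groups, core = core)
}
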