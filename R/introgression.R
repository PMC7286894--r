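# Windowed haplotype-sharing introgression scan between group pairs.
# Sharing is genotype-level IBS/2: identical genotypes score 1, one shared
# allele 0.5, none 0.

#' Pairwise allele sharing between two samples
#'
#' Mean over non-missing SNPs of the allele-sharing score
#' `1 - |g_i - g_j| / 2` on dosage.
#'
#' @param gi,gj dosage vectors (0/1/2, `NA` allowed) over the same sites.
#' @return the mean sharing fraction; `NA` when no site is comparable.
#' @export
pairwise_sharing <- function(gi, gj) {
  d <- abs(gi - gj)
  ok <- !is.na(d)
  if (!any(ok)) return(NA_real_)
  1 - mean(d[ok]) / 2
}

#' Windowed haplotype-sharing ratio scan
#'
#' For every focal sample of the two groups and every non-overlapping
#' window (anchored at contig position 1) with at least `min_snps` SNPs and
#' at least `min_comparisons` genotyped partners in each group, computes
#' S_own (mean sharing with own-group members), S_cross (mean sharing with
#' the other group) and the ratio `R = S_own / S_cross`; windows with
#' `R < ratio_threshold` are flagged as putatively introgressed.  Windows
#' failing the eligibility rules are skipped, not emitted.
#'
#' @param gt a `genotype_table`.
#' @param groups length-2 character vector of group labels.
#' @param window_bp window width (default 100 Kb).
#' @param min_snps minimum SNPs per window (default 10).
#' @param min_comparisons minimum genotyped partners per group (default 3).
#' @param ratio_threshold flag threshold on R (default 0.8).
#' @param contigs contigs to scan (default all).
#' @return data.frame: sample, group, other_group, contig, start, end,
#'   n_snps, s_own, s_cross, ratio, introgressed.
#' @export
sharing_ratio_scan <- function(gt, groups, window_bp = 1e5, min_snps = 10,
                               min_comparisons = 3, ratio_threshold = 0.8,
                               contigs = NULL) {
  stopifnot(length(groups) == 2)
  for (g in groups) group_samples(gt, g)    # validates labels
  g <- geno_dosage(gt)
  snp <- gt$variants$class == "SNP"
  contigs <- contigs %||% unique(gt$variants$contig)
  grp_of <- gt$samples$group
  rows <- list()
  for (cn in contigs) {
    vi <- which(snp & gt$variants$contig == cn)
    if (!length(vi)) next
    starts <- seq(1, max(gt$variants$pos[vi]), by = window_bp)
    widx <- findInterval(gt$variants$pos[vi], starts)
    for (w in unique(widx)) {
      sel <- vi[widx == w]
      if (length(sel) < min_snps) next
      gw <- g[sel, , drop = FALSE]
      genotyped <- colSums(!is.na(gw)) > 0
      for (focal in which(grp_of %in% groups)) {
        own <- setdiff(which(grp_of == grp_of[focal] & genotyped), focal)
        other_grp <- setdiff(groups, grp_of[focal])
        cross <- which(grp_of == other_grp & genotyped)
        if (length(own) < min_comparisons || length(cross) < min_comparisons)
          next
        s_own <- mean(vapply(own, function(j)
          pairwise_sharing(gw[, focal], gw[, j]), numeric(1)), na.rm = TRUE)
        s_cross <- mean(vapply(cross, function(j)
          pairwise_sharing(gw[, focal], gw[, j]), numeric(1)), na.rm = TRUE)
        R <- s_own / s_cross
        rows[[length(rows) + 1]] <- data.frame(
          sample = gt$samples$sample[focal], group = grp_of[focal],
          other_group = other_grp, contig = cn, start = starts[w],
          end = starts[w] + window_bp - 1, n_snps = length(sel),
          s_own = s_own, s_cross = s_cross, ratio = R,
          introgressed = is.finite(R) && R < ratio_threshold,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(sample = character(), group = character(),
                      other_group = character(), contig = character(),
                      start = numeric(), end = numeric(), n_snps = integer(),
                      s_own = numeric(), s_cross = numeric(),
                      ratio = numeric(), introgressed = logical()))
  do.call(rbind, rows)
}

#' High-sharing regions
#'
#' Per focal sample and window, the maximum over other-group members of the
#' fraction of shared SNPs; windows with fraction >= `threshold` are
#' flagged and merged into segments.  A SNP counts as shared when the
#' pairwise sharing score reaches `share_score_min`: with the default 1 the
#' two genotypes must be identical, which is what gives the criterion power
#' to separate copied (identical-by-descent) material from background
#' sharing — counting single shared alleles (`share_score_min = 0.5`)
#' saturates near 1 even between unrelated animals.
#'
#' @inheritParams sharing_ratio_scan
#' @param threshold shared-SNP fraction threshold (default 0.90).
#' @param share_score_min minimum sharing score for a SNP to count as
#'   shared (default 1: identical genotypes).
#' @return list: `windows` (per-window table with `shared_frac`, `flagged`)
#'   and `segments` (merged flagged runs, from [merge_flagged_windows()]).
#' @export
high_sharing_regions <- function(gt, groups, window_bp = 1e5, min_snps = 10,
                                 min_comparisons = 3, threshold = 0.90,
                                 share_score_min = 1, contigs = NULL) {
  stopifnot(length(groups) == 2)
  for (g in groups) group_samples(gt, g)
  g <- geno_dosage(gt)
  snp <- gt$variants$class == "SNP"
  contigs <- contigs %||% unique(gt$variants$contig)
  grp_of <- gt$samples$group
  rows <- list()
  for (cn in contigs) {
    vi <- which(snp & gt$variants$contig == cn)
    if (!length(vi)) next
    starts <- seq(1, max(gt$variants$pos[vi]), by = window_bp)
    widx <- findInterval(gt$variants$pos[vi], starts)
    for (w in unique(widx)) {
      sel <- vi[widx == w]
      if (length(sel) < min_snps) next
      gw <- g[sel, , drop = FALSE]
      genotyped <- colSums(!is.na(gw)) > 0
      for (focal in which(grp_of %in% groups)) {
        other_grp <- setdiff(groups, grp_of[focal])
        cross <- which(grp_of == other_grp & genotyped)
        own <- setdiff(which(grp_of == grp_of[focal] & genotyped), focal)
        if (length(own) < min_comparisons || length(cross) < min_comparisons)
          next
        fracs <- vapply(cross, function(j) {
          score <- 1 - abs(gw[, focal] - gw[, j]) / 2
          ok <- !is.na(score)
          if (!any(ok)) return(NA_real_)
          mean(score[ok] >= share_score_min)
        }, numeric(1))
        sf <- suppressWarnings(max(fracs, na.rm = TRUE))
        if (!is.finite(sf)) next
        rows[[length(rows) + 1]] <- data.frame(
          sample = gt$samples$sample[focal], group = grp_of[focal],
          other_group = other_grp, contig = cn, start = starts[w],
          end = starts[w] + window_bp - 1, n_snps = length(sel),
          shared_frac = sf, flagged = sf >= threshold,
          stringsAsFactors = FALSE)
      }
    }
  }
  windows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample = character(), contig = character(), start = numeric(),
               end = numeric(), shared_frac = numeric(), flagged = logical())
  list(windows = windows,
       segments = merge_flagged_windows(windows, flag_col = "flagged"))
}

#' Merge flagged windows into segments
#'
#' Consecutive flagged windows of the same focal sample (and contig/group
#' pair) are merged; a gap tolerance of `k` allows up to `k` unflagged
#' windows inside a segment (default 0: strict adjacency).
#'
#' @param windows window table from [sharing_ratio_scan()] or
#'   [high_sharing_regions()], sorted by position.
#' @param gap_tolerance allowed unflagged windows inside a segment.
#' @param flag_col name of the logical flag column.
#' @return data.frame of segments: sample, group, other_group, contig,
#'   start, end, n_windows, mean_ratio (when a `ratio` column exists).
#' @export
merge_flagged_windows <- function(windows, gap_tolerance = 0,
                                  flag_col = "introgressed") {
  if (is.null(windows) || nrow(windows) == 0 || !any(windows[[flag_col]]))
    return(data.frame(sample = character(), group = character(),
                      other_group = character(), contig = character(),
                      start = numeric(), end = numeric(),
                      n_windows = integer(), mean_ratio = numeric()))
  win_bp <- windows$end[1] - windows$start[1] + 1
  out <- list()
  for (key in unique(paste(windows$sample, windows$contig,
                           windows$other_group %||% ""))) {
    sub <- windows[paste(windows$sample, windows$contig,
                         windows$other_group %||% "") == key, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    flag_idx <- which(sub[[flag_col]])
    if (!length(flag_idx)) next
    widx <- round((sub$start - 1) / win_bp)   # window ordinal
    cur <- list(first = flag_idx[1], last = flag_idx[1])
    flush <- function(cur) {
      rng <- cur$first:cur$last
      rows <- sub[rng, , drop = FALSE]
      rows <- rows[rows[[flag_col]], , drop = FALSE]
      data.frame(sample = sub$sample[1], group = sub$group[1] %||% NA,
                 other_group = sub$other_group[1] %||% NA,
                 contig = sub$contig[1],
                 start = sub$start[cur$first], end = sub$end[cur$last],
                 n_windows = nrow(rows),
                 mean_ratio = if (!is.null(sub$ratio))
                   mean(rows$ratio) else NA_real_,
                 stringsAsFactors = FALSE)
    }
    for (fi in flag_idx[-1]) {
      gap <- widx[fi] - widx[cur$last] - 1
      if (gap <= gap_tolerance) cur$last <- fi
      else {
        out[[length(out) + 1]] <- flush(cur)
        cur <- list(first = fi, last = fi)
      }
    }
    out[[length(out) + 1]] <- flush(cur)
  }
  res <- do.call(rbind, out)
  res[order(res$sample, res$contig, res$start), , drop = FALSE]
}

#' Window likelihood-ratio test of ancestral contribution
#'
#' Compares the likelihood of a focal individual's window genotypes under
#' the allele frequencies of two candidate source groups.  Per group the
#' log-likelihood is `sum_sites [g log f + (2-g) log(1-f)]` with
#' frequencies clamped to `[1/(2n+2), 1 - 1/(2n+2)]`;
#' `Lambda = 2 (lnL_A - lnL_B)`, positive values favoring ancestry from
#' group A.
#'
#' @param g_focal dosage vector of the focal individual over window sites.
#' @param freq_a,freq_b allele frequencies of the two groups at those
#'   sites.
#' @param n_a,n_b diploid sample sizes behind the frequency estimates
#'   (for clamping).
#' @return list: `lambda`, `lnl_a`, `lnl_b`, `favored` (`"A"`/`"B"`/
#'   `"tie"`); `NA` lambda when no usable site.
#' @export
window_lrt <- function(g_focal, freq_a, freq_b, n_a, n_b) {
  clamp <- function(f, n) pmin(pmax(f, 1 / (2 * n + 2)), 1 - 1 / (2 * n + 2))
  fa <- clamp(freq_a, n_a); fb <- clamp(freq_b, n_b)
  ok <- !is.na(g_focal) & !is.na(fa) & !is.na(fb)
  if (!any(ok)) return(list(lambda = NA_real_, lnl_a = NA_real_,
                            lnl_b = NA_real_, favored = NA_character_))
  g <- g_focal[ok]; fa <- fa[ok]; fb <- fb[ok]
  lnl_a <- sum(g * log(fa) + (2 - g) * log(1 - fa))
  lnl_b <- sum(g * log(fb) + (2 - g) * log(1 - fb))
  lambda <- 2 * (lnl_a - lnl_b)
  list(lambda = lambda, lnl_a = lnl_a, lnl_b = lnl_b,
       favored = if (lambda > 0) "A" else if (lambda < 0) "B" else "tie")
}
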