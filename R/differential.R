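# Group-contrast variant scans: near-fixation filter, Pearson chi-square
# on allele counts with FDR/Bonferroni correction, coverage filtering, and
# top-K structural-variant selection.

#' Near-fixation allele-frequency scan
#'
#' Keeps variants whose alternate-allele frequency is strictly above `hi`
#' in one group and strictly below `lo` in the other (either orientation) —
#' the ">80% in one group, <20% in the other" candidate filter.  Optionally
#' restricted to a set of effect labels.
#'
#' @param gt a `genotype_table`.
#' @param group1,group2 group labels (e.g. the large and small size
#'   classes, passed via `by = "size_class"`).
#' @param hi,lo thresholds (defaults 0.80, 0.20; strict inequalities).
#' @param by metadata column holding the labels (default `"group"`).
#' @param effects optional character vector of effect labels to keep
#'   (requires an `effect` column in `gt$variants`).
#' @return data.frame of hits: variant index, id, freq1, freq2, direction.
#' @export
near_fixation_scan <- function(gt, group1, group2, hi = 0.80, lo = 0.20,
                               by = "group", effects = NULL) {
  lab <- gt$samples[[by]]
  in1 <- !is.na(lab) & lab == group1
  in2 <- !is.na(lab) & lab == group2
  if (!any(in1)) stop_cfg("empty group '", group1, "'")
  if (!any(in2)) stop_cfg("empty group '", group2, "'")
  g <- geno_dosage(gt)
  f1 <- rowSums(g[, in1, drop = FALSE], na.rm = TRUE) /
    (2 * rowSums(!is.na(g[, in1, drop = FALSE])))
  f2 <- rowSums(g[, in2, drop = FALSE], na.rm = TRUE) /
    (2 * rowSums(!is.na(g[, in2, drop = FALSE])))
  keep <- (f1 > hi & f2 < lo) | (f2 > hi & f1 < lo)
  keep[is.na(keep)] <- FALSE
  if (!is.null(effects)) {
    if (is.null(gt$variants$effect))
      stop_cfg("effects filter requested but variants carry no effect labels")
    keep <- keep & gt$variants$effect %in% effects
  }
  data.frame(variant = which(keep), id = gt$variants$id[keep],
             freq1 = f1[keep], freq2 = f2[keep],
             direction = ifelse(f1[keep] > f2[keep], group1, group2),
             stringsAsFactors = FALSE)
}

#' Pearson chi-square on a group allele-count contrast
#'
#' Classical Pearson chi-square (no continuity correction, 1 df) on the
#' 2x2 allele-count table of a biallelic variant in two groups.
#'
#' @param alt1,ref1 allele counts in group 1.
#' @param alt2,ref2 allele counts in group 2.
#' @return list: `chisq`, `p`; both `NA` with a warning when a table
#'   margin is zero.
#' @export
group_chisq <- function(alt1, ref1, alt2, ref2) {
  tab <- matrix(c(alt1, ref1, alt2, ref2), 2, 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin in allele-count table; chi-square undefined")
    return(list(chisq = NA_real_, p = NA_real_))
  }
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chisq = unname(res$statistic), p = unname(res$p.value))
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up (`"BH"`) or Bonferroni (`min(m p, 1)`),
#' preserving input order.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @param method `"BH"` or `"bonferroni"`.
#' @return adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_cfg("p-values must lie in [0, 1]")
  p.adjust(p, method = method)
}

#' Coverage filter for genotyped samples per group
#'
#' Retains variants with at least `min_per_group` genotyped samples in
#' every listed group — the minimum needed for the chi-square expected
#' counts to be meaningful.
#'
#' @param gt a `genotype_table`.
#' @param groups group labels to require coverage in.
#' @param min_per_group minimum genotyped samples (default 5).
#' @param by metadata column holding the labels.
#' @return integer vector of retained variant indices.
#' @export
coverage_filter <- function(gt, groups, min_per_group = 5, by = "group") {
  g <- geno_dosage(gt)
  lab <- gt$samples[[by]]
  ok <- rep(TRUE, n_variants(gt))
  for (grp in groups) {
    cols <- !is.na(lab) & lab == grp
    ok <- ok & rowSums(!is.na(g[, cols, drop = FALSE])) >= min_per_group
  }
  which(ok)
}

#' Chi-square scan over variants between two groups
#'
#' Allele-count chi-square per variant with multiplicity adjustment.
#'
#' @param gt a `genotype_table`.
#' @param group1,group2 group labels.
#' @param method adjustment method (`"BH"` or `"bonferroni"`).
#' @param by metadata column.
#' @param variants optional variant index subset.
#' @return data.frame: variant, id, class, freq1, freq2, chisq, p, p_adj.
#' @export
chisq_scan <- function(gt, group1, group2, method = "bonferroni",
                       by = "group", variants = NULL) {
  vi <- variants %||% seq_len(n_variants(gt))
  g <- geno_dosage(gt)
  lab <- gt$samples[[by]]
  c1 <- !is.na(lab) & lab == group1
  c2 <- !is.na(lab) & lab == group2
  res <- lapply(vi, function(v) {
    g1 <- g[v, c1]; g2 <- g[v, c2]
    alt1 <- sum(g1, na.rm = TRUE); ref1 <- 2 * sum(!is.na(g1)) - alt1
    alt2 <- sum(g2, na.rm = TRUE); ref2 <- 2 * sum(!is.na(g2)) - alt2
    ch <- suppressWarnings(group_chisq(alt1, ref1, alt2, ref2))
    data.frame(variant = v, id = gt$variants$id[v],
               class = gt$variants$class[v],
               freq1 = alt1 / (alt1 + ref1), freq2 = alt2 / (alt2 + ref2),
               chisq = ch$chisq, p = ch$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- adjust_pvalues(out$p, method)
  out
}

#' Top-K structural variants by group contrast
#'
#' Chi-square on per-sample presence/absence counts between groups, BH
#' adjustment, retention at `p_adj < alpha`, ranking by (adjusted, raw)
#' p-value, truncation to the top `k`.
#'
#' @param presence 0/1 matrix, SVs x samples (rownames = SV ids).
#' @param groups character vector of group labels per sample (same order
#'   as columns).
#' @param group1,group2 the two labels to contrast.
#' @param k number of top SVs to keep (default 100).
#' @param alpha adjusted-p threshold (default 0.01).
#' @return data.frame of ranked hits: sv, n1_present, n2_present, chisq,
#'   p, p_adj.
#' @export
top_k_sv <- function(presence, groups, group1, group2, k = 100,
                     alpha = 0.01) {
  if (k <= 0) stop_cfg("k must be positive")
  c1 <- groups == group1; c2 <- groups == group2
  ids <- rownames(presence) %||% sprintf("sv%03d", seq_len(nrow(presence)))
  res <- lapply(seq_len(nrow(presence)), function(v) {
    p1 <- sum(presence[v, c1] == 1, na.rm = TRUE)
    a1 <- sum(presence[v, c1] == 0, na.rm = TRUE)
    p2 <- sum(presence[v, c2] == 1, na.rm = TRUE)
    a2 <- sum(presence[v, c2] == 0, na.rm = TRUE)
    ch <- suppressWarnings(group_chisq(p1, a1, p2, a2))
    data.frame(sv = ids[v], n1_present = p1, n2_present = p2,
               chisq = ch$chisq, p = ch$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- adjust_pvalues(out$p, "BH")
  out <- out[!is.na(out$p_adj) & out$p_adj < alpha, , drop = FALSE]
  out <- out[order(out$p_adj, out$p), , drop = FALSE]
  rownames(out) <- NULL
  head(out, k)
}
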