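# Windowed diversity and differentiation statistics over haplotype
# matrices (sites x haplotypes, entries 0/1/NA).

.site_freq_n <- function(H) {
  n <- rowSums(!is.na(H))
  p <- rowSums(H, na.rm = TRUE) / n
  list(p = p, n = n)
}

#' Nucleotide diversity (theta-pi) per Kb
#'
#' Mean pairwise difference per site, summed over sites and scaled to the
#' window length in Kb.  Uses the unbiased frequency form
#' `sum_sites 2 p (1-p) n/(n-1)` with `n` the non-missing haplotypes at
#' each site (pairwise-complete), identical to averaging raw differences
#' over all haplotype pairs.
#'
#' @param H 0/1 haplotype matrix for the window, sites x haplotypes.
#' @param window_bp window length in bp.
#' @return theta-pi per Kb.
#' @export
theta_pi <- function(H, window_bp) {
  if (window_bp < 1) stop_cfg("window length must be >= 1 bp")
  if (nrow(H) == 0) return(0)
  fr <- .site_freq_n(H)
  if (ncol(H) == 0 || all(fr$n == 0))
    stop_cfg("zero usable haplotypes in window")
  use <- fr$n >= 2
  pi_sites <- 2 * fr$p[use] * (1 - fr$p[use]) * fr$n[use] / (fr$n[use] - 1)
  sum(pi_sites) / (window_bp / 1000)
}

#' Watterson's theta per Kb
#'
#' Segregating sites scaled by the harmonic number
#' `a_n = sum_{i=1}^{n-1} 1/i`; with missing data each segregating site
#' contributes `1/a_{n_site}` for its own non-missing `n`.
#'
#' @inheritParams theta_pi
#' @return theta-w per Kb.
#' @export
theta_w <- function(H, window_bp) {
  if (window_bp < 1) stop_cfg("window length must be >= 1 bp")
  if (nrow(H) == 0) return(0)
  fr <- .site_freq_n(H)
  seg <- fr$n >= 2 & fr$p > 0 & fr$p < 1
  if (!any(seg)) return(0)
  a_n <- vapply(fr$n[seg], function(n) sum(1 / seq_len(n - 1)), numeric(1))
  sum(1 / a_n) / (window_bp / 1000)
}

#' Hudson's F_ST (ratio of averages)
#'
#' `1 - pi_within / pi_between` summed over window sites, where pi_within
#' is the mean of the two unbiased within-group per-site diversities and
#' pi_between the mean between-group allele difference
#' `p_A (1-p_B) + p_B (1-p_A)`.  Ratio-of-averages (sums over sites first)
#' for stability with few sites.
#'
#' @param HA,HB 0/1 haplotype matrices of the two groups (same site rows).
#' @return F_ST; `NA` with a warning when pi_between is 0 over the window.
#' @export
hudson_fst <- function(HA, HB) {
  if (nrow(HA) != nrow(HB)) stop_cfg("site rows differ between groups")
  fa <- .site_freq_n(HA); fb <- .site_freq_n(HB)
  use <- fa$n >= 2 & fb$n >= 2
  if (!any(use)) stop_cfg("no site with >= 2 haplotypes in both groups")
  pa <- fa$p[use]; pb <- fb$p[use]; na <- fa$n[use]; nb <- fb$n[use]
  w_a <- 2 * pa * (1 - pa) * na / (na - 1)
  w_b <- 2 * pb * (1 - pb) * nb / (nb - 1)
  pi_w <- sum((w_a + w_b) / 2)
  pi_b <- sum(pa * (1 - pb) + pb * (1 - pa))
  if (pi_b == 0) {
    warning("pi_between is 0; F_ST undefined in window")
    return(NA_real_)
  }
  1 - pi_w / pi_b
}

#' Windowed diversity and differentiation scan
#'
#' Non-overlapping fixed-width windows anchored at position 1 of each
#' contig.  Reports per-window theta-pi/Kb, theta-w/Kb and (when two groups
#' are named) Hudson F_ST.
#'
#' @param gt a fully phased `genotype_table`.
#' @param window_bp window width (default 100 Kb).
#' @param groups optional length-2 character vector of group labels for
#'   F_ST.
#' @param contigs contigs to scan (default all).
#' @return data.frame: contig, start, end, n_sites, n_haplotypes,
#'   theta_pi_kb, theta_w_kb, fst.
#' @export
windowed_diversity <- function(gt, window_bp = 1e5, groups = NULL,
                               contigs = NULL) {
  H <- haplotype_matrix(gt)
  contigs <- contigs %||% unique(gt$variants$contig)
  ga <- gb <- NULL
  if (!is.null(groups)) {
    stopifnot(length(groups) == 2)
    ga <- rep(gt$samples$group, each = 2) == groups[1]
    gb <- rep(gt$samples$group, each = 2) == groups[2]
  }
  rows <- list()
  for (cn in contigs) {
    vi <- which(gt$variants$contig == cn)
    if (!length(vi)) next
    clen <- if (!is.null(gt$contig_lengths) && cn %in% names(gt$contig_lengths))
      gt$contig_lengths[[cn]] else max(gt$variants$pos[vi])
    starts <- seq(1, clen, by = window_bp)
    widx <- findInterval(gt$variants$pos[vi], starts)
    for (w in unique(widx)) {
      sel <- vi[widx == w]
      Hw <- H[sel, , drop = FALSE]
      fst <- NA_real_
      if (!is.null(groups)) {
        fst <- tryCatch(suppressWarnings(
          hudson_fst(Hw[, ga, drop = FALSE], Hw[, gb, drop = FALSE])),
          error = function(e) NA_real_)
      }
      rows[[length(rows) + 1]] <- data.frame(
        contig = cn, start = starts[w],
        end = min(starts[w] + window_bp - 1, clen),
        n_sites = length(sel), n_haplotypes = ncol(Hw),
        theta_pi_kb = theta_pi(Hw, window_bp),
        theta_w_kb = theta_w(Hw, window_bp), fst = fst,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-sample homozygous/heterozygous ratio
#'
#' Ratio of homozygous-alternate to heterozygous calls per sample (missing
#' excluded); elevated values indicate bottlenecks or inbreeding.
#'
#' @param gt a `genotype_table`.
#' @param classes variant classes to count (default `"SNP"`).
#' @return data.frame: sample, n_hom_alt, n_het, hom_het_ratio (`Inf` with
#'   a warning when a sample has no heterozygous call).
#' @export
hom_het_ratio <- function(gt, classes = "SNP") {
  vi <- gt$variants$class %in% classes
  g <- geno_dosage(gt)[vi, , drop = FALSE]
  n_hom <- colSums(g == 2L, na.rm = TRUE)
  n_het <- colSums(g == 1L, na.rm = TRUE)
  if (any(n_het == 0))
    warning("sample(s) with zero heterozygous calls: ratio is Inf")
  data.frame(sample = gt$samples$sample, n_hom_alt = n_hom, n_het = n_het,
             hom_het_ratio = ifelse(n_het == 0, Inf, n_hom / n_het),
             row.names = NULL, stringsAsFactors = FALSE)
}
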