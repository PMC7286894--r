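# Pairwise linkage disequilibrium, EM haplotype phasing, LD decay, and
# Gabriel confidence-interval block detection.

#' Pairwise LD between two sites
#'
#' From phased haplotypes at two biallelic sites (pairwise-complete over
#' haplotypes), computes `D = p_AB - p_A p_B`, `r^2 = D^2 / (p_A(1-p_A)
#' p_B(1-p_B))`, `D' = D / D_max` with the sign-appropriate bound, and a
#' likelihood-based confidence interval for |D'|: the multinomial
#' likelihood of the four haplotype counts is profiled over |D'| on a grid
#' of step 0.001 (allele frequencies held at their MLEs), normalized, and
#' the 2.5% / 97.5% quantiles of the resulting distribution reported.
#'
#' @param hi,hj 0/1 allele vectors over the same haplotypes.
#' @return list: `D`, `Dprime` (|D'|), `r2`, `ci_low`, `ci_high`, `n`.
#'   All `NA` (with `informative = FALSE`) when either site is monomorphic.
#' @export
pairwise_ld <- function(hi, hj) {
  ok <- !is.na(hi) & !is.na(hj)
  hi <- hi[ok]; hj <- hj[ok]
  n <- length(hi)
  pA <- mean(hi); pB <- mean(hj)
  if (n == 0 || pA %in% c(0, 1) || pB %in% c(0, 1))
    return(list(D = NA_real_, Dprime = NA_real_, r2 = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_, n = n))
  pAB <- mean(hi == 1 & hj == 1)
  D <- pAB - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  Dmax <- if (D >= 0) min(pA * (1 - pB), pB * (1 - pA)) else
    min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (Dmax == 0) 0 else abs(D) / Dmax
  ci <- .dprime_ci(hi, hj, pA, pB, sign(D) * Dmax)
  list(D = D, Dprime = min(dprime, 1), r2 = min(r2, 1),
       ci_low = ci[1], ci_high = ci[2], n = n)
}

# profile-likelihood CI over |D'| on a 0.001 grid
.dprime_ci <- function(hi, hj, pA, pB, signedDmax, grid_step = 0.001,
                       lo_q = 0.025, hi_q = 0.975) {
  n11 <- sum(hi == 1 & hj == 1); n10 <- sum(hi == 1 & hj == 0)
  n01 <- sum(hi == 0 & hj == 1); n00 <- sum(hi == 0 & hj == 0)
  dgrid <- seq(0, 1, by = grid_step)
  eps <- 1e-10
  D <- dgrid * signedDmax
  ll <- n11 * log(pmax(pA * pB + D, eps)) +
    n10 * log(pmax(pA * (1 - pB) - D, eps)) +
    n01 * log(pmax((1 - pA) * pB - D, eps)) +
    n00 * log(pmax((1 - pA) * (1 - pB) + D, eps))
  w <- exp(ll - max(ll))
  cdf <- cumsum(w) / sum(w)
  c(dgrid[which(cdf >= lo_q)[1]], dgrid[which(cdf >= hi_q)[1]])
}

#' All pairwise LD within a marker set
#'
#' @param H 0/1 haplotype matrix, sites x haplotypes.
#' @param positions site positions (bp), same order as rows.
#' @param max_distance only pairs within this distance (bp).
#' @return data.frame: i, j, distance, D, Dprime, r2, ci_low, ci_high.
#' @export
ld_pairs <- function(H, positions, max_distance = 5e5) {
  m <- nrow(H)
  rows <- list()
  for (i in seq_len(max(m - 1, 0))) for (j in (i + 1):m) {
    if (m < 2) break
    d <- abs(positions[j] - positions[i])
    if (d > max_distance) next
    ld <- pairwise_ld(H[i, ], H[j, ])
    rows[[length(rows) + 1]] <- data.frame(
      i = i, j = j, distance = d, D = ld$D, Dprime = ld$Dprime, r2 = ld$r2,
      ci_low = ld$ci_low, ci_high = ld$ci_high)
  }
  if (!length(rows))
    return(data.frame(i = integer(), j = integer(), distance = numeric(),
                      D = numeric(), Dprime = numeric(), r2 = numeric(),
                      ci_low = numeric(), ci_high = numeric()))
  do.call(rbind, rows)
}

#' Genome-wide LD decay curve
#'
#' Bins all intra-contig marker pairs within `max_distance` by distance
#' (5 Kb bins), averages r^2 per bin, and reports the half-decay distance:
#' the first distance, interpolated linearly between bin midpoints, where
#' mean r^2 falls to half its maximum.
#'
#' @param H phased 0/1 haplotype matrix, sites x haplotypes.
#' @param positions marker positions (one contig; for several contigs call
#'   per contig and pool with [pool_decay()]).
#' @param max_distance maximum pair distance (default 500 Kb).
#' @param bin_bp bin width (default 5 Kb).
#' @return list: `curve` (data.frame midpoint, mean_r2, n_pairs),
#'   `half_decay_bp` (`NA` when the half maximum is never reached),
#'   `r2_max`, `r2_half`.
#' @export
ld_decay <- function(H, positions, max_distance = 5e5, bin_bp = 5e3) {
  pairs <- ld_pairs(H, positions, max_distance)
  pairs <- pairs[!is.na(pairs$r2), , drop = FALSE]
  if (!nrow(pairs)) stop_cfg("no informative pair within range")
  bin <- pmin(floor(pairs$distance / bin_bp), ceiling(max_distance / bin_bp) - 1)
  agg <- aggregate(pairs$r2, by = list(bin = bin), FUN = mean)
  cnt <- as.vector(table(bin))
  curve <- data.frame(midpoint = (agg$bin + 0.5) * bin_bp,
                      mean_r2 = agg$x, n_pairs = cnt)
  curve <- curve[order(curve$midpoint), ]
  r2max <- max(curve$mean_r2)
  half <- r2max / 2
  below <- which(curve$mean_r2 <= half)
  half_bp <- NA_real_
  if (length(below)) {
    b <- below[1]
    if (b == 1) half_bp <- curve$midpoint[1]
    else {
      x0 <- curve$midpoint[b - 1]; y0 <- curve$mean_r2[b - 1]
      x1 <- curve$midpoint[b]; y1 <- curve$mean_r2[b]
      half_bp <- x0 + (half - y0) / (y1 - y0) * (x1 - x0)
    }
  }
  list(curve = curve, half_decay_bp = half_bp, r2_max = r2max, r2_half = half)
}

#' EM haplotype phasing for a marker window
#'
#' Standard EM over haplotype frequencies for up to 12 biallelic markers:
#' frequencies are restricted to haplotypes compatible with at least one
#' observed genotype; the E-step splits each multi-heterozygote across its
#' compatible ordered haplotype pairs in proportion to the product of
#' current frequencies; the M-step renormalizes expected counts.  Each
#' individual's phase is the a-posteriori most probable pair.
#'
#' @param G dosage matrix (individuals x markers, 0/1/2, `NA` allowed).
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @return list: `haplotypes` (matrix of distinct haplotypes x markers),
#'   `frequencies`, `phase` (list per individual: `h1`, `h2` haplotype row
#'   indices, `posterior`), `loglik` trace.
#' @export
em_phase_window <- function(G, tol = 1e-6, max_iter = 1000) {
  G <- as.matrix(G)
  m <- ncol(G)
  if (m > 12) stop_cfg("window has ", m, " markers; phase at most 12 at a ",
                       "time (use windowed calls)")
  n <- nrow(G)
  pair_list <- lapply(seq_len(n), function(i) .compatible_pairs(G[i, ]))
  hap_keys <- sort(unique(unlist(lapply(pair_list, function(p)
    c(p$h1, p$h2)))))
  if (!length(hap_keys)) stop_cfg("no genotype information to phase")
  H <- length(hap_keys)
  idx <- function(keys) match(keys, hap_keys)
  pair_list <- lapply(pair_list, function(p)
    list(h1 = idx(p$h1), h2 = idx(p$h2)))
  f <- rep(1 / H, H)
  ll_trace <- numeric(); ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    counts <- numeric(H)
    ll <- 0
    for (i in seq_len(n)) {
      p <- pair_list[[i]]
      w <- f[p$h1] * f[p$h2]
      s <- sum(w)
      if (s <= 0) { w <- rep(1 / length(w), length(w)); s <- 1 }
      ll <- ll + log(s)
      w <- w / s
      for (k in seq_along(w)) {
        counts[p$h1[k]] <- counts[p$h1[k]] + w[k]
        counts[p$h2[k]] <- counts[p$h2[k]] + w[k]
      }
    }
    f <- counts / (2 * n)
    ll_trace <- c(ll_trace, ll)
    if (ll - ll_old < tol && it > 1) break
    ll_old <- ll
  }
  phase <- lapply(seq_len(n), function(i) {
    p <- pair_list[[i]]
    w <- f[p$h1] * f[p$h2]
    w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(w), length(w))
    b <- which.max(w)
    list(h1 = p$h1[b], h2 = p$h2[b], posterior = w[b])
  })
  haps <- t(vapply(hap_keys, .key_to_hap, integer(m), m = m))
  list(haplotypes = haps, frequencies = f, phase = phase, loglik = ll_trace)
}

# enumerate ordered haplotype pairs compatible with one genotype vector;
# haplotypes encoded as integer keys (bit per marker)
.compatible_pairs <- function(g) {
  m <- length(g)
  het <- which(!is.na(g) & g == 1L)
  mis <- which(is.na(g))
  base <- integer(m)
  base[!is.na(g) & g == 2L] <- 1L
  free <- c(het, mis)
  combos <- if (length(free)) expand.grid(rep(list(0:1), length(free)))
  else data.frame(row.names = 1)
  h1s <- integer(nrow(combos)); h2s <- integer(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    h1 <- base; h2 <- base
    if (length(het)) {
      bits <- as.integer(combos[r, seq_along(het)])
      h1[het] <- bits; h2[het] <- 1L - bits
    }
    if (length(mis)) {
      bits <- as.integer(combos[r, length(het) + seq_along(mis)])
      h1[mis] <- bits; h2[mis] <- bits   # missing: treat as homozygous either way
    }
    h1s[r] <- .hap_to_key(h1); h2s[r] <- .hap_to_key(h2)
  }
  # de-duplicate unordered pairs
  key <- paste(pmin(h1s, h2s), pmax(h1s, h2s))
  keep <- !duplicated(key)
  list(h1 = h1s[keep], h2 = h2s[keep])
}

.hap_to_key <- function(h) sum(h * 2L^(seq_along(h) - 1L))
.key_to_hap <- function(key, m) as.integer(bitwAnd(key %/% 2L^(0:(m - 1)), 1L))

#' Thin markers to a minimum spacing
#'
#' Greedy scan keeping the first marker, then every next marker at least
#' `min_gap` bp from the last kept one.
#'
#' @param positions sorted ascending positions (bp).
#' @param min_gap minimum inter-marker distance (default 3 Kb).
#' @return integer indices of retained markers.
#' @export
thin_markers <- function(positions, min_gap = 3000) {
  if (length(positions) == 0) return(integer())
  if (is.unsorted(positions)) stop_cfg("positions must be sorted ascending")
  keep <- 1L
  last <- positions[1]
  for (i in seq_along(positions)[-1]) {
    if (positions[i] - last >= min_gap) {
      keep <- c(keep, i)
      last <- positions[i]
    }
  }
  keep
}

#' Gabriel confidence-interval LD blocks
#'
#' Marker pairs are classed *strong LD* when the |D'| CI satisfies
#' `low >= ci_strong_low` and `high >= ci_strong_high`, and *strong
#' recombination* when `high < ci_recomb`; other pairs are uninformative.
#' A candidate block is a marker run whose outermost pair is strong LD and
#' in which at least `frac_strong` of informative pairs are strong LD.
#' Candidates are accepted greedily longest-first (bp span), discarding
#' overlaps.
#'
#' @param H phased 0/1 haplotype matrix, sites x haplotypes (one contig,
#'   positions ascending).
#' @param positions marker positions (bp).
#' @param min_maf minimum minor-allele frequency (default 0, i.e. keep all
#'   polymorphic markers).
#' @param max_distance maximum pair span considered (default 500 Kb).
#' @param ci_strong_low,ci_strong_high,ci_recomb,frac_strong Gabriel
#'   thresholds (defaults 0.70, 0.98, 0.90, 0.95).
#' @return data.frame of blocks: start, end (bp), first, last (marker
#'   indices into the retained set), n_markers, frac_strong; attribute
#'   `"markers"` holds the retained marker indices into the input.
#' @export
gabriel_blocks <- function(H, positions, min_maf = 0, max_distance = 5e5,
                           ci_strong_low = 0.70, ci_strong_high = 0.98,
                           ci_recomb = 0.90, frac_strong = 0.95) {
  if (is.unsorted(positions)) stop_cfg("markers must be ordered by position")
  maf <- pmin(rowMeans(H, na.rm = TRUE), 1 - rowMeans(H, na.rm = TRUE))
  keep <- which(!is.na(maf) & maf > 0 & maf >= min_maf)
  H <- H[keep, , drop = FALSE]; pos <- positions[keep]
  m <- length(pos)
  empty <- data.frame(start = numeric(), end = numeric(), first = integer(),
                      last = integer(), n_markers = integer(),
                      frac_strong = numeric())
  attr(empty, "markers") <- keep
  if (m < 2) return(empty)
  # pair classification: 1 strong LD, -1 strong recombination, 0 uninformative
  cls <- matrix(NA_integer_, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (pos[j] - pos[i] > max_distance) next
    ld <- pairwise_ld(H[i, ], H[j, ])
    cls[i, j] <- if (is.na(ld$ci_low)) 0L
    else if (ld$ci_low >= ci_strong_low && ld$ci_high >= ci_strong_high) 1L
    else if (ld$ci_high < ci_recomb) -1L else 0L
  }
  cand <- list()
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (is.na(cls[i, j]) || cls[i, j] != 1L) next
    sub <- cls[i:j, i:j]
    vals <- sub[upper.tri(sub)]
    vals <- vals[!is.na(vals)]
    n_inf <- sum(vals != 0L)
    if (n_inf == 0) next
    fs <- sum(vals == 1L) / n_inf
    if (fs >= frac_strong)
      cand[[length(cand) + 1]] <- data.frame(
        start = pos[i], end = pos[j], first = i, last = j,
        n_markers = j - i + 1L, frac_strong = fs)
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-(cand$end - cand$start), cand$start), , drop = FALSE]
  accepted <- list()
  used <- logical(m)
  for (r in seq_len(nrow(cand))) {
    span <- cand$first[r]:cand$last[r]
    if (any(used[span])) next
    used[span] <- TRUE
    accepted[[length(accepted) + 1]] <- cand[r, ]
  }
  out <- do.call(rbind, accepted)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "markers") <- keep
  out
}
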