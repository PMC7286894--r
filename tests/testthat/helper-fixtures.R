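# Small in-code fixtures shared across tests.

# build a SNP-only genotype table from allele matrices
make_gt <- function(h1, h2, pos = NULL, contig = "chr1", groups = NULL,
                    sex = NULL, phased = NULL, contig_lengths = NULL,
                    size_class = NULL) {
  h1 <- as.matrix(h1); h2 <- as.matrix(h2)
  nv <- nrow(h1); ns <- ncol(h1)
  pos <- pos %||% (seq_len(nv) * 100L)
  variants <- data.frame(contig = rep(contig, length.out = nv), pos = pos,
                         id = sprintf("v%03d", seq_len(nv)),
                         ref = rep("A", nv), alt = rep("G", nv),
                         class = rep("SNP", nv), stringsAsFactors = FALSE)
  samples <- data.frame(sample = sprintf("s%02d", seq_len(ns)),
                        group = groups %||% rep("g1", ns),
                        sex = sex %||% rep("F", ns),
                        size_class = size_class %||% NA_character_,
                        stringsAsFactors = FALSE)
  genotype_table(variants, h1, h2, phased, samples, contig_lengths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mean pairwise difference per site over all haplotype pairs: independent
# brute-force oracle for theta_pi
theta_pi_pairs_oracle <- function(H, window_bp) {
  n <- ncol(H)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- H[, i] != H[, j]
    tot <- tot + sum(d, na.rm = TRUE)
  }
  tot / choose(n, 2) / (window_bp / 1000)
}

# BH step-up written out longhand, as an independent oracle
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- Inf
  for (k in m:1) {
    i <- ord[k]
    val <- min(p[i] * m / k, 1)
    prev <- min(prev, val)
    adj[i] <- prev
  }
  adj
}

# exhaustive Gabriel block caller: enumerate every span, test the two rules
# directly on the pair classification, accept longest-first
gabriel_oracle <- function(H, positions, ci_strong_low = 0.70,
                           ci_strong_high = 0.98, ci_recomb = 0.90,
                           frac_strong = 0.95) {
  maf <- pmin(rowMeans(H), 1 - rowMeans(H))
  keep <- which(maf > 0)
  H <- H[keep, , drop = FALSE]; positions <- positions[keep]
  m <- length(positions)
  class_pair <- function(i, j) {
    ld <- pairwise_ld(H[i, ], H[j, ])
    if (is.na(ld$ci_low)) return(0L)
    if (ld$ci_low >= ci_strong_low && ld$ci_high >= ci_strong_high) return(1L)
    if (ld$ci_high < ci_recomb) return(-1L)
    0L
  }
  cand <- list()
  for (i in seq_len(max(m - 1, 0))) for (j in (i + 1):m) {
    if (class_pair(i, j) != 1L) next
    cls <- c()
    for (a in i:(j - 1)) for (b in (a + 1):j) cls <- c(cls, class_pair(a, b))
    inf <- cls[cls != 0L]
    if (!length(inf)) next
    if (mean(inf == 1L) >= frac_strong)
      cand[[length(cand) + 1]] <- c(start = positions[i], end = positions[j],
                                    first = i, last = j)
  }
  if (!length(cand)) return(data.frame(start = numeric(), end = numeric()))
  cand <- as.data.frame(do.call(rbind, cand))
  cand <- cand[order(-(cand$end - cand$start), cand$start), ]
  used <- logical(m); keep_rows <- c()
  for (r in seq_len(nrow(cand))) {
    span <- cand$first[r]:cand$last[r]
    if (any(used[span])) next
    used[span] <- TRUE; keep_rows <- c(keep_rows, r)
  }
  out <- cand[keep_rows, c("start", "end")]
  out[order(out$start), , drop = FALSE]
}

# random additive tree as a path-length distance matrix, plus the tree
random_additive_tree <- function(n_taxa, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_taxa, br = function(k) runif(k, 0.1, 1))
    tr <- ape::unroot(tr)
    list(tree = tr, D = cophenetic(tr))
  })
}
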