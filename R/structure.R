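# Population-structure inference: p-distance matrix, Saitou-Nei
# neighbor-joining, PCA on standardized genotypes, and EM admixture under
# the unsupervised binomial mixture model.

#' Pairwise p-distance matrix
#'
#' Diploid allele-sharing distance: per pair of samples the mean over
#' pairwise-complete sites of `1 - IBS/2`, where IBS counts shared alleles
#' between the two genotypes (so het-vs-het identical genotypes share 2).
#' Equals `mean(|g_i - g_j|) / 2` on dosage.
#'
#' @param gt a `genotype_table` (or a dosage matrix, variants x samples).
#' @return symmetric numeric matrix with sample names.
#' @export
p_distance_matrix <- function(gt) {
  g <- if (inherits(gt, "genotype_table")) geno_dosage(gt) else as.matrix(gt)
  ns <- ncol(g)
  if (ns < 2) stop_cfg("need >= 2 samples")
  D <- matrix(0, ns, ns, dimnames = list(colnames(g), colnames(g)))
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    diff <- abs(g[, i] - g[, j])
    ok <- !is.na(diff)
    if (!any(ok))
      stop_cfg("no comparable sites for pair ", colnames(g)[i], " / ",
               colnames(g)[j])
    D[i, j] <- D[j, i] <- mean(diff[ok]) / 2
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration: repeatedly join the pair minimizing the
#' Q-criterion, with the standard branch-length formulas; negative branch
#' lengths are clamped to zero and the excess moved to the sister branch so
#' path lengths are preserved.  Returns an unrooted `phylo` object (ape).
#'
#' @param D symmetric distance matrix with row/col names, `n >= 3`.
#' @return an object of class `phylo`.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop_cfg("distance matrix must be symmetric")
  n <- nrow(D)
  if (n < 3) stop_cfg("need >= 3 taxa")
  labels <- rownames(D) %||% paste0("t", seq_len(n))
  # nodes are newick fragments built bottom-up
  frag <- labels
  active <- seq_len(n)
  repeat {
    m <- length(active)
    if (m == 3) break
    d <- D[active, active]
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    dij <- d[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_frag <- sprintf("(%s:%.10g,%s:%.10g)",
                        frag[active[i]], li, frag[active[j]], lj)
    dk <- (d[i, ] + d[j, ] - dij) / 2
    ai <- active[i]
    D[ai, active] <- dk; D[active, ai] <- dk; D[ai, ai] <- 0
    frag[ai] <- new_frag
    active <- active[-j]
  }
  d <- D[active, active]
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  ls <- pmax(c(l1, l2, l3), 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[active[1]], ls[1], frag[active[2]], ls[2],
                 frag[active[3]], ls[3])
  ape::read.tree(text = nwk)
}

#' PCA of genotype dosages
#'
#' Genotypes coded 0/1/2 with missing values imputed to the column mean;
#' monomorphic columns dropped; columns centered and scaled by
#' `sqrt(p(1-p))` with `p` the sample allele frequency; eigendecomposition
#' of the sample covariance `X X' / n_sites`.
#'
#' @param gt a `genotype_table` or dosage matrix (variants x samples).
#' @param n_pc number of component coordinates to return.
#' @return list with `eigenvalues` (descending) and `coordinates`
#'   (samples x PCs).
#' @export
pca_genotypes <- function(gt, n_pc = 10) {
  g <- if (inherits(gt, "genotype_table")) geno_dosage(gt) else as.matrix(gt)
  X <- t(g)                              # samples x sites
  cm <- colMeans(X, na.rm = TRUE)
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas)) X[nas] <- cm[nas[, 2]]
  p <- cm / 2
  poly <- p > 0 & p < 1 & !is.na(p)
  if (!any(poly)) stop_cfg("all sites monomorphic; PCA undefined")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  X <- sweep(X, 2, 2 * p)
  X <- sweep(X, 2, sqrt(p * (1 - p)), "/")
  C <- tcrossprod(X) / ncol(X)
  e <- eigen(C, symmetric = TRUE)
  k <- min(n_pc, ncol(e$vectors))
  coords <- e$vectors[, seq_len(k), drop = FALSE]
  rownames(coords) <- rownames(X) %||%
    (if (inherits(gt, "genotype_table")) gt$samples$sample else NULL)
  colnames(coords) <- paste0("PC", seq_len(k))
  list(eigenvalues = pmax(e$values, 0), coordinates = coords)
}

#' EM admixture estimation
#'
#' Unsupervised binomial mixture: the likelihood of dosage `g_il` is
#' `Binom(g_il; 2, sum_k q_ik f_kl)`; classical EM updates of ancestry
#' proportions Q and component frequencies F, with multiple seeded random
#' restarts, stopping when the log-likelihood gain drops below `tol` or at
#' `max_iter`.  Missing genotypes contribute nothing.
#'
#' @param gt a `genotype_table` or dosage matrix (variants x samples).
#' @param K number of ancestral components.
#' @param seed integer seed for initialization.
#' @param max_iter maximum EM iterations (default 10000).
#' @param tol log-likelihood convergence tolerance.
#' @param n_restarts random restarts; best final likelihood wins.
#' @return list: `Q` (samples x K), `F` (K x sites), `loglik` (trace of the
#'   winning run), `K`.
#' @export
admixture_em <- function(gt, K, seed = 1L, max_iter = 10000, tol = 1e-6,
                         n_restarts = 5) {
  g <- if (inherits(gt, "genotype_table")) geno_dosage(gt) else as.matrix(gt)
  G <- t(g)                              # individuals x sites
  n <- nrow(G); L <- ncol(G)
  if (K < 1) stop_cfg("K must be >= 1")
  if (K > n) warning("K exceeds the number of samples")
  if (K == 1) {
    f <- colMeans(G, na.rm = TRUE) / 2
    ll <- .admix_loglik(G, matrix(1, n, 1), matrix(f, 1, L))
    return(list(Q = matrix(1, n, 1, dimnames = list(rownames(G), "K1")),
                F = matrix(f, 1, L), loglik = ll, K = 1L))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(sub_seed(seed, r), .admix_em_once(G, K, max_iter, tol))
    if (is.null(best) || tail(fit$loglik, 1) > tail(best$loglik, 1)) best <- fit
  }
  rownames(best$Q) <- rownames(G)
  colnames(best$Q) <- paste0("K", seq_len(K))
  best$K <- as.integer(K)
  best
}

.admix_loglik <- function(G, Q, F) {
  P <- Q %*% F
  P <- pmin(pmax(P, 1e-10), 1 - 1e-10)
  sum(G * log(P) + (2 - G) * log(1 - P), na.rm = TRUE)
}

.admix_em_once <- function(G, K, max_iter, tol) {
  n <- nrow(G); L <- ncol(G)
  Q <- matrix(stats::rgamma(n * K, 1), n, K); Q <- Q / rowSums(Q)
  F <- matrix(runif(K * L, 0.05, 0.95), K, L)
  obs <- !is.na(G)
  G0 <- G; G0[!obs] <- 0
  two_obs <- 2 * obs
  ll_trace <- numeric()
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    P <- Q %*% F
    P <- pmin(pmax(P, 1e-10), 1 - 1e-10)
    # expected allele-1 / allele-0 copy counts attributed to component k
    A_tot <- G0 / P                       # n x L
    B_tot <- (two_obs - G0) / (1 - P)
    Anum <- matrix(0, n, K); Fnum <- matrix(0, K, L); Fden <- matrix(0, K, L)
    for (k in seq_len(K)) {
      ak <- (A_tot * rep(F[k, ], each = n)) * Q[, k]   # q_ik f_kl g/P
      bk <- (B_tot * rep(1 - F[k, ], each = n)) * Q[, k]
      Fnum[k, ] <- colSums(ak)
      Fden[k, ] <- colSums(ak + bk)
      Anum[, k] <- rowSums(ak + bk)
    }
    F <- Fnum / pmax(Fden, 1e-12)
    F <- pmin(pmax(F, 1e-6), 1 - 1e-6)
    Q <- Anum / pmax(rowSums(Anum), 1e-12)
    if (any(colSums(Q) < 1e-8)) {        # degenerate component: re-jitter
      Q <- Q + 0.01; Q <- Q / rowSums(Q)
    }
    ll <- .admix_loglik(G, Q, F)
    ll_trace <- c(ll_trace, ll)
    if (ll - ll_old < tol && it > 1) break
    ll_old <- ll
  }
  list(Q = Q, F = F, loglik = ll_trace)
}

#' Align admixture components to reference labels
#'
#' Greedy matching of estimated components to a truth assignment (used in
#' recovery checks): permutes columns of Q so component k best matches
#' reference group k.
#'
#' @param Q estimated ancestry matrix (samples x K).
#' @param groups character vector of true group labels per sample.
#' @return Q with columns permuted and named by group.
#' @export
align_components <- function(Q, groups) {
  gs <- unique(groups)
  K <- ncol(Q)
  means <- sapply(seq_len(K), function(k)
    sapply(gs, function(g) mean(Q[groups == g, k])))
  means <- matrix(means, nrow = length(gs), dimnames = list(gs, NULL))
  perm <- integer(length(gs))
  taken <- logical(K)
  for (g in seq_along(gs)) {
    ord <- order(means[g, ], decreasing = TRUE)
    ord <- ord[!taken[ord]]
    perm[g] <- ord[1]; taken[ord[1]] <- TRUE
  }
  out <- Q[, perm, drop = FALSE]
  colnames(out) <- gs
  out
}
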