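#' Genotype table
#'
#' The central data container: an ordered set of biallelic variant records,
#' an ordered set of samples with metadata, and per-sample diploid genotypes
#' stored as two allele matrices (`h1`, `h2`, variants x samples, entries 0 =
#' reference allele, 1 = alternate allele, `NA` = missing) plus a logical
#' `phased` matrix.  When every heterozygous call is phased, `h1` and `h2`
#' are the two haplotypes of each sample.
#'
#' @param variants data.frame with columns `contig`, `pos` (1-based bp),
#'   `id`, `ref`, `alt`, `class` (one of `"SNP"`, `"indel"`, `"SV"`).
#' @param h1,h2 integer matrices (variants x samples) of allele indices.
#' @param phased logical matrix, same shape; `TRUE` where the genotype
#'   separator is `|`.
#' @param samples data.frame with columns `sample`, `group`, `sex`,
#'   `size_class` (extra columns allowed; `NA` permitted except in `sample`).
#' @param contig_lengths optional named numeric vector of contig lengths (bp).
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(variants, h1, h2, phased = NULL, samples,
                           contig_lengths = NULL) {
  variants <- as.data.frame(variants)
  samples <- as.data.frame(samples)
  need_v <- c("contig", "pos", "id", "ref", "alt", "class")
  if (!all(need_v %in% names(variants)))
    stop_cfg("variants must have columns: ", paste(need_v, collapse = ", "))
  if (!"sample" %in% names(samples))
    stop_cfg("samples must have a 'sample' column")
  for (col in c("group", "sex", "size_class"))
    if (!col %in% names(samples)) samples[[col]] <- NA_character_
  h1 <- as.matrix(h1); h2 <- as.matrix(h2)
  nv <- nrow(variants); ns <- nrow(samples)
  if (!all(dim(h1) == c(nv, ns)) || !all(dim(h2) == c(nv, ns)))
    stop_cfg("genotype matrices must be n_variants x n_samples")
  if (is.null(phased)) phased <- matrix(TRUE, nv, ns)
  if (!all(dim(phased) == c(nv, ns)))
    stop_cfg("phased must be n_variants x n_samples")
  if (any(variants$pos < 1)) stop_cfg("variant pos must be >= 1")
  bad <- !nchar(variants$ref) | !nchar(variants$alt)
  if (any(bad)) stop_cfg("empty alleles at record ", which(bad)[1])
  miss <- is.na(h1) != is.na(h2)
  if (any(miss)) stop_cfg("half-missing genotypes are not representable")
  phased[is.na(h1)] <- TRUE     # phase of a missing call is vacuous
  colnames(h1) <- colnames(h2) <- colnames(phased) <- samples$sample
  structure(
    list(variants = variants, h1 = h1, h2 = h2, phased = phased,
         samples = samples, contig_lengths = contig_lengths),
    class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d variants x %d samples\n",
              n_variants(x), n_samples(x)))
  cat("  classes:", paste(sprintf("%s=%d", names(table(x$variants$class)),
                                  table(x$variants$class)), collapse = " "), "\n")
  grp <- table(x$samples$group, useNA = "no")
  if (length(grp))
    cat("  groups: ", paste(sprintf("%s=%d", names(grp), grp), collapse = " "), "\n")
  invisible(x)
}

#' @rdname genotype_table
#' @param gt a `genotype_table`.
#' @export
n_variants <- function(gt) nrow(gt$variants)

#' @rdname genotype_table
#' @export
n_samples <- function(gt) nrow(gt$samples)

#' Genotype dosage matrix
#'
#' Count of alternate alleles per variant and sample (0/1/2, `NA` missing).
#'
#' @param gt a `genotype_table`.
#' @return integer matrix, variants x samples.
#' @export
geno_dosage <- function(gt) gt$h1 + gt$h2

#' Haplotype matrix
#'
#' Expand a fully phased table into a variants x (2 * samples) matrix of
#' 0/1 alleles, columns named `<sample>.a` / `<sample>.b`.  Heterozygous
#' unphased calls make haplotypes undefined and raise an error.
#'
#' @param gt a `genotype_table`.
#' @return integer matrix of haplotypes.
#' @export
haplotype_matrix <- function(gt) {
  het <- !is.na(gt$h1) & gt$h1 != gt$h2
  if (any(het & !gt$phased))
    stop_cfg("phase required: table contains unphased heterozygous genotypes")
  m <- matrix(NA_integer_, n_variants(gt), 2L * n_samples(gt))
  m[, seq(1, ncol(m), by = 2)] <- gt$h1
  m[, seq(2, ncol(m), by = 2)] <- gt$h2
  colnames(m) <- paste(rep(gt$samples$sample, each = 2), c("a", "b"), sep = ".")
  m
}

#' Subset a genotype table
#'
#' @param gt a `genotype_table`.
#' @param variants index vector into variant rows (default all).
#' @param samples index vector or character vector of sample names.
#' @return a `genotype_table`.
#' @export
subset_gt <- function(gt, variants = NULL, samples = NULL) {
  vi <- variants %||% seq_len(n_variants(gt))
  si <- samples %||% seq_len(n_samples(gt))
  if (is.character(si)) si <- match(si, gt$samples$sample)
  if (anyNA(si)) stop_cfg("unknown sample name in subset")
  genotype_table(gt$variants[vi, , drop = FALSE],
                 gt$h1[vi, si, drop = FALSE], gt$h2[vi, si, drop = FALSE],
                 gt$phased[vi, si, drop = FALSE],
                 gt$samples[si, , drop = FALSE], gt$contig_lengths)
}

#' Samples belonging to a group label
#'
#' @param gt a `genotype_table`.
#' @param group group label as used in the sample metadata.
#' @return character vector of sample names.
#' @export
group_samples <- function(gt, group) {
  hit <- !is.na(gt$samples$group) & gt$samples$group == group
  if (!any(hit)) stop_cfg("no samples in group '", group, "'")
  gt$samples$sample[hit]
}

#' Per-group alternate-allele frequencies
#'
#' @param gt a `genotype_table`.
#' @param groups group labels (default: all distinct labels present).
#' @return numeric matrix, variants x groups; `NA` where no sample genotyped.
#' @export
group_frequencies <- function(gt, groups = NULL) {
  groups <- groups %||% sort(unique(stats::na.omit(gt$samples$group)))
  g <- geno_dosage(gt)
  out <- sapply(groups, function(grp) {
    cols <- gt$samples$sample %in% group_samples(gt, grp)
    sub <- g[, cols, drop = FALSE]
    rowSums(sub, na.rm = TRUE) / (2 * rowSums(!is.na(sub)))
  })
  out <- matrix(out, nrow = n_variants(gt),
                dimnames = list(NULL, groups))
  out[is.nan(out)] <- NA_real_
  out
}

#' Attach sample metadata to a genotype table
#'
#' @param gt a `genotype_table`.
#' @param meta data.frame with `sample` plus metadata columns; must cover all
#'   table samples.
#' @return the table with updated sample metadata.
#' @export
attach_metadata <- function(gt, meta) {
  idx <- match(gt$samples$sample, meta$sample)
  if (anyNA(idx))
    stop_cfg("metadata missing for sample(s): ",
             paste(gt$samples$sample[is.na(idx)], collapse = ", "))
  for (col in setdiff(names(meta), "sample"))
    gt$samples[[col]] <- meta[[col]][idx]
  gt
}
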