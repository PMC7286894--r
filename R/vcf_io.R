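# VCF and metadata I/O.  Reading goes through vcfR; writing is a small
# deterministic plain-text VCF v4.2 writer (GT-only FORMAT) so that equal
# tables always serialize to identical bytes.

#' Read a multi-sample VCF into a genotype table
#'
#' Loads a VCF v4.x (plain or gzipped) and returns a [genotype_table()].
#' Only the GT field is used.  Multi-allelic records are split into one
#' biallelic record per alternate allele (genotypes carrying a different
#' alternate become missing in that split record) and tagged in the `id`,
#' with a warning.
#'
#' @param path VCF file path.
#' @param metadata optional path to a sample metadata TSV
#'   (see [read_sample_metadata()]).
#' @return a `genotype_table`.
#' @export
read_vcf <- function(path, metadata = NULL) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop_cfg("VCF parse error in '", path,
                                             "': ", conditionMessage(e)))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    smp <- colnames(v@gt)[-1] %||% character()
    return(genotype_table(
      data.frame(contig = character(), pos = integer(), id = character(),
                 ref = character(), alt = character(), class = character()),
      matrix(integer(), 0, length(smp)), matrix(integer(), 0, length(smp)),
      matrix(logical(), 0, length(smp)),
      data.frame(sample = smp)))
  }
  gtf <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gtf)
  pos <- as.integer(fix$POS)
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  multi <- lengths(alts) > 1
  if (any(multi))
    warning(sum(multi), " multi-allelic record(s) split into biallelic records")
  contig_lengths <- .vcf_contig_lengths(v)

  rows <- vector("list", sum(lengths(alts)))
  k <- 0
  for (i in seq_len(nrow(fix))) {
    raw <- gtf[i, ]
    a1 <- .gt_allele(raw, 1L); a2 <- .gt_allele(raw, 2L)
    ph <- grepl("|", raw, fixed = TRUE)
    hap <- is.na(a2) & !is.na(a1)       # haploid call: code as homozygous
    a2[hap] <- a1[hap]; ph[hap] <- TRUE
    for (ai in seq_along(alts[[i]])) {
      k <- k + 1
      alt <- alts[[i]][ai]
      id <- if (is.na(fix$ID[i]) || fix$ID[i] == ".")
        sprintf("%s_%d", fix$CHROM[i], pos[i]) else fix$ID[i]
      if (multi[i]) id <- sprintf("%s_alt%d", id, ai)
      h1 <- .recode_allele(a1, ai); h2 <- .recode_allele(a2, ai)
      drop <- is.na(h1) | is.na(h2)
      h1[drop] <- NA_integer_; h2[drop] <- NA_integer_
      rows[[k]] <- list(
        variant = data.frame(contig = fix$CHROM[i], pos = pos[i], id = id,
                             ref = fix$REF[i], alt = alt,
                             class = variant_class(fix$REF[i], alt),
                             stringsAsFactors = FALSE),
        h1 = h1, h2 = h2, ph = ph)
    }
  }
  variants <- do.call(rbind, lapply(rows, `[[`, "variant"))
  h1 <- do.call(rbind, lapply(rows, `[[`, "h1"))
  h2 <- do.call(rbind, lapply(rows, `[[`, "h2"))
  ph <- do.call(rbind, lapply(rows, `[[`, "ph"))
  ord <- order(variants$contig, variants$pos)
  gt <- genotype_table(variants[ord, , drop = FALSE],
                       h1[ord, , drop = FALSE], h2[ord, , drop = FALSE],
                       ph[ord, , drop = FALSE],
                       data.frame(sample = samples, stringsAsFactors = FALSE),
                       contig_lengths)
  if (!is.null(metadata)) gt <- attach_metadata(gt, read_sample_metadata(metadata))
  gt
}

.gt_allele <- function(raw, which) {
  part <- vapply(strsplit(sub(":.*", "", raw), "[/|]"), function(p)
    if (length(p) >= which) p[which] else NA_character_, character(1))
  suppressWarnings(as.integer(ifelse(part %in% c(".", "", NA), NA, part)))
}

.recode_allele <- function(a, alt_index) {
  out <- rep(NA_integer_, length(a))
  out[a == 0L] <- 0L
  out[a == alt_index] <- 1L
  out
}

.vcf_contig_lengths <- function(v) {
  meta <- v@meta
  ln <- grep("^##contig=", meta, value = TRUE)
  if (!length(ln)) return(NULL)
  ids <- sub(".*ID=([^,>]+).*", "\\1", ln)
  lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", ln)))
  setNames(lens, ids)
}

#' Variant class from alleles
#'
#' `"SNP"` when both alleles are single bases, `"SV"` when the length
#' difference exceeds 45 bp (the conventional small-variant bound), else
#' `"indel"`.
#'
#' @param ref,alt allele strings.
#' @return character vector of classes.
#' @export
variant_class <- function(ref, alt) {
  ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNP",
         ifelse(abs(nchar(ref) - nchar(alt)) > 45, "SV", "indel"))
}

#' Write a genotype table as VCF v4.2
#'
#' Deterministic plain-text writer: records sorted by (contig, pos), phased
#' genotypes serialized with `|`, unphased with `/`, missing as `./.`.
#'
#' @param gt a `genotype_table`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(gt, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=pigpopgen",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(gt$contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(gt$contig_lengths),
                          as.integer(gt$contig_lengths)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", gt$samples$sample),
                      collapse = "\t"))
  ord <- order(gt$variants$contig, gt$variants$pos)
  lines <- hdr
  if (n_variants(gt) > 0) {
    sep <- ifelse(gt$phased[ord, , drop = FALSE], "|", "/")
    h1 <- gt$h1[ord, , drop = FALSE]; h2 <- gt$h2[ord, , drop = FALSE]
    cell <- matrix(paste0(ifelse(is.na(h1), ".", h1),
                          ifelse(is.na(h1), "/", sep),
                          ifelse(is.na(h2), ".", h2)),
                   nrow = length(ord))
    v <- gt$variants[ord, , drop = FALSE]
    body <- paste(v$contig, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".",
                  "GT", apply(cell, 1, paste, collapse = "\t"), sep = "\t")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write sample metadata
#'
#' Tab-separated table with header columns `sample`, `group`, `sex`,
#' `size_class`.
#'
#' @param path file path.
#' @return data.frame of metadata.
#' @export
read_sample_metadata <- function(path) {
  meta <- read.delim(path, stringsAsFactors = FALSE)
  if (!"sample" %in% names(meta))
    stop_cfg("metadata must have a 'sample' column")
  meta
}

#' @rdname read_sample_metadata
#' @param meta metadata data.frame.
#' @export
write_sample_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
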