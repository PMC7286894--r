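# Toy genome annotation and a minimal coding-effect classifier.

#' Generate a toy reference genome and annotation
#'
#' Random reference sequence per contig plus non-overlapping single-exon
#' protein-coding genes: each gene has one CDS (length a multiple of 3,
#' phase 0) flanked by `intron_pad` bp of non-coding gene body, so variants
#' can fall in CDS, intron, 5 Kb up/downstream, or intergenic space.
#'
#' @param contig_lengths named numeric vector of contig lengths (bp).
#' @param genes_per_mb gene density (default 10).
#' @param cds_length CDS length in bp, multiple of 3.
#' @param intron_pad non-coding gene body on each side of the CDS.
#' @param seed integer seed.
#' @param dir optional directory; when given, writes `reference.fa` and
#'   `annotation.gff3`.
#' @return list with `reference` (`DNAStringSet`), `features` (data.frame
#'   contig/start/end/strand/type/gene_id/phase) and, if written, `paths`.
#' @export
emit_genome_annotation <- function(contig_lengths, genes_per_mb = 10,
                                   cds_length = 300, intron_pad = 500,
                                   seed = 1L, dir = NULL) {
  if (cds_length %% 3 != 0) stop_cfg("cds_length must be a multiple of 3")
  if (any(cds_length > contig_lengths))
    stop_cfg("CDS longer than contig")
  with_seed(seed, {
    seqs <- Biostrings::DNAStringSet(vapply(contig_lengths, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1)))
    names(seqs) <- names(contig_lengths)
    feats <- list()
    for (cn in names(contig_lengths)) {
      L <- contig_lengths[[cn]]
      ng <- max(0L, round(genes_per_mb * L / 1e6))
      if (ng == 0) next
      span <- cds_length + 2 * intron_pad
      slot <- floor(L / max(ng, 1))
      if (slot <= span + 2) { ng <- floor(L / (span + 10)); slot <- floor(L / max(ng, 1)) }
      if (ng < 1) next
      gstart <- (seq_len(ng) - 1) * slot +
        sample.int(max(1L, slot - span - 1L), ng, replace = TRUE)
      strand <- sample(c("+", "-"), ng, replace = TRUE)
      gid <- sprintf("%s_g%03d", cn, seq_len(ng))
      feats[[cn]] <- rbind(
        data.frame(contig = cn, start = gstart, end = gstart + span - 1,
                   strand = strand, type = "gene", gene_id = gid, phase = NA,
                   stringsAsFactors = FALSE),
        data.frame(contig = cn, start = gstart + intron_pad,
                   end = gstart + intron_pad + cds_length - 1,
                   strand = strand, type = "CDS", gene_id = gid, phase = 0L,
                   stringsAsFactors = FALSE))
    }
    features <- if (length(feats)) do.call(rbind, feats) else
      data.frame(contig = character(), start = numeric(), end = numeric(),
                 strand = character(), type = character(),
                 gene_id = character(), phase = integer())
    rownames(features) <- NULL
    out <- list(reference = seqs, features = features)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      fa <- file.path(dir, "reference.fa")
      Biostrings::writeXStringSet(seqs, fa)
      gff <- file.path(dir, "annotation.gff3")
      write_gff3(features, gff)
      out$paths <- c(fasta = fa, gff = gff)
    }
    out
  })
}

#' Write / read a feature table as GFF3
#'
#' @param features feature data.frame as from [emit_genome_annotation()].
#' @param path file path.
#' @return the path (write) or a feature data.frame (read).
#' @export
write_gff3 <- function(features, path) {
  gr <- GenomicRanges::GRanges(
    features$contig, IRanges::IRanges(features$start, features$end),
    strand = features$strand)
  gr$type <- features$type
  gr$ID <- paste0(features$gene_id, ifelse(features$type == "CDS", ".cds", ""))
  gr$phase <- as.integer(features$phase)
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  ph <- if (!is.null(gr$phase)) as.integer(gr$phase) else NA_integer_
  gid <- sub("\\.cds$", "", as.character(gr$ID))
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             type = as.character(gr$type), gene_id = gid, phase = ph,
             stringsAsFactors = FALSE)
}

.effect_severity <- c(stop_gain = 1, frameshift = 2, nonsynonymous = 3,
                      nonframeshift = 4, synonymous = 5, intronic = 6,
                      updownstream_5kb = 7, intergenic = 8)

#' Classify the coding effect of a variant
#'
#' SNPs inside a CDS are translated ref-vs-alt with the standard genetic
#' code (reverse-complemented for minus-strand CDS) and labeled synonymous,
#' nonsynonymous or stop_gain; indels inside a CDS are frameshift when the
#' length difference is not a multiple of 3, else nonframeshift.  Variants
#' inside a gene but outside its CDS are intronic; within 5 Kb of a gene,
#' updownstream_5kb; otherwise intergenic.  When several genes overlap a
#' variant the most severe label wins (stop_gain > frameshift >
#' nonsynonymous > nonframeshift > synonymous > intronic).
#'
#' @param contig,pos,ref,alt variant record fields (vectorized).
#' @param reference `DNAStringSet` of contig sequences.
#' @param features feature data.frame (`type` gene/CDS with `strand`,
#'   `phase`, `gene_id`).
#' @param flank_bp up/downstream window (default 5000).
#' @return character vector of effect labels.
#' @export
classify_coding_effect <- function(contig, pos, ref, alt, reference, features,
                                   flank_bp = 5000) {
  n <- length(pos)
  out <- rep("intergenic", n)
  genes <- features[features$type == "gene", , drop = FALSE]
  cdss <- features[features$type == "CDS", , drop = FALSE]
  for (i in seq_len(n)) {
    vlen <- abs(nchar(ref[i]) - nchar(alt[i]))
    vend <- pos[i] + max(nchar(ref[i]) - 1, 0)
    hit_cds <- cdss[cdss$contig == contig[i] & cdss$start <= vend &
                      cdss$end >= pos[i], , drop = FALSE]
    labels <- character()
    if (nrow(hit_cds)) {
      for (j in seq_len(nrow(hit_cds))) {
        cds <- hit_cds[j, ]
        if (pos[i] < cds$start || vend > cds$end) {
          warning("variant ", contig[i], ":", pos[i],
                  " overlaps a CDS boundary; labeled by CDS rule")
        }
        if (vlen == 0 && nchar(ref[i]) == 1) {
          labels <- c(labels, .snp_cds_effect(contig[i], pos[i], ref[i],
                                              alt[i], reference, cds))
        } else {
          labels <- c(labels,
                      if (vlen %% 3 != 0) "frameshift" else "nonframeshift")
        }
      }
    }
    in_gene <- any(genes$contig == contig[i] & genes$start <= pos[i] &
                     genes$end >= pos[i])
    near_gene <- any(genes$contig == contig[i] &
                       genes$start - flank_bp <= pos[i] &
                       genes$end + flank_bp >= pos[i])
    if (!length(labels)) {
      labels <- if (in_gene) "intronic" else
        if (near_gene) "updownstream_5kb" else "intergenic"
    }
    out[i] <- labels[which.min(.effect_severity[labels])]
  }
  out
}

.snp_cds_effect <- function(contig, pos, ref, alt, reference, cds) {
  seq <- reference[[contig]]
  phase <- if (is.na(cds$phase)) 0L else as.integer(cds$phase)
  if (cds$strand == "-") {
    offset <- cds$end - pos - phase
  } else {
    offset <- pos - cds$start - phase
  }
  if (offset < 0) return("intronic")   # inside the phase-skipped bases
  cidx <- offset %/% 3
  within <- offset %% 3
  if (cds$strand == "+") {
    cstart <- cds$start + phase + 3 * cidx
    if (cstart + 2 > length(seq)) return("synonymous")
    codon <- as.character(Biostrings::subseq(seq, cstart, cstart + 2))
    mut <- codon
    substr(mut, within + 1, within + 1) <- alt
  } else {
    cend <- cds$end - phase - 3 * cidx
    if (cend - 2 < 1) return("synonymous")
    fwd <- Biostrings::subseq(seq, cend - 2, cend)
    codon <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      as.character(fwd))))
    mut <- codon
    comp <- c(A = "T", C = "G", G = "C", T = "A")[[alt]]
    substr(mut, within + 1, within + 1) <- comp
  }
  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[codon]); aa_alt <- unname(code[mut])
  if (is.na(aa_ref) || is.na(aa_alt)) return("synonymous")
  if (aa_alt == "*" && aa_ref != "*") return("stop_gain")
  if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
}

#' Nonsynonymous/synonymous ratio
#'
#' The genome-wide ratio of nonsynonymous to synonymous SNP counts (often
#' written as omega), a coarse signal of relaxed or strengthened purifying
#' selection at the population level.
#'
#' @param labels character vector of effect labels (or a named count vector
#'   with entries `nonsynonymous`, `synonymous`).
#' @return the ratio, rounded to 2 decimals; `NA` when no synonymous sites.
#' @export
ns_s_ratio <- function(labels) {
  if (!is.null(names(labels)) && is.numeric(labels)) {
    ns <- labels[["nonsynonymous"]]; s <- labels[["synonymous"]]
  } else {
    ns <- sum(labels == "nonsynonymous"); s <- sum(labels == "synonymous")
  }
  if (s == 0) {
    warning("no synonymous variants; NS/S undefined")
    return(NA_real_)
  }
  round_half_away(ns / s, 2)
}
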