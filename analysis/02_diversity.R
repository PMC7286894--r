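#!/usr/bin/env Rscript
# Stage 2: diversity and differentiation statistics.
#
# Reads the simulated VCF back through the standard reader, classifies
# coding effects against the toy annotation, and writes windowed theta-pi /
# theta-w / Hudson F_ST (100 Kb windows), per-sample Hom/Het ratios, and
# the NS/S summary.

suppressMessages(library(pigpopgen))

sim <- "results/sim"; out <- "results/tables"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

gt <- read_vcf(file.path(sim, "variants.vcf"),
               metadata = file.path(sim, "samples.tsv"))
ref <- Biostrings::readDNAStringSet(file.path(sim, "reference.fa"))
names(ref) <- sub(" .*", "", names(ref))
feats <- read_gff3(file.path(sim, "annotation.gff3"))

gt$variants$effect <- classify_coding_effect(
  gt$variants$contig, gt$variants$pos, gt$variants$ref, gt$variants$alt,
  ref, feats)

div <- windowed_diversity(gt, 1e5, groups = c("CnSouth", "CnNorth"))
write.table(div, file.path(out, "diversity_windows.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

hh <- hom_het_ratio(gt)
write.table(hh, file.path(out, "hom_het.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

snp_eff <- gt$variants$effect[gt$variants$class == "SNP"]
omega <- suppressWarnings(ns_s_ratio(snp_eff))

auto <- div$contig == "chr1"
cat(sprintf("windows: %d | mean theta-pi %.2f/Kb, theta-w %.2f/Kb\n",
            nrow(div), mean(div$theta_pi_kb), mean(div$theta_w_kb)))
cat(sprintf("F_ST(CnSouth,CnNorth): autosome %.3f, X (carries the planted haplotype block) %.3f\n",
            mean(div$fst[auto], na.rm = TRUE),
            mean(div$fst[!auto], na.rm = TRUE)))
cat(sprintf("effects: %s\n",
            paste(names(table(snp_eff)), table(snp_eff), collapse = " ")))
cat(sprintf("NS/S ratio on simulated coding SNPs: %s\n", format(omega)))
cat(sprintf("Hom/Het ratios %.2f-%.2f\n",
            min(hh$hom_het_ratio[is.finite(hh$hom_het_ratio)]),
            max(hh$hom_het_ratio[is.finite(hh$hom_het_ratio)])))
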