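#!/usr/bin/env Rscript
# Attribute reads to loci, classify isomiRs into the seven variant
# classes, summarize end-nucleotide composition, and correlate isomiR
# abundance with locus abundance per genomic context.

source("analysis/00_common.R")
sim <- load_state("sim")
loci <- load_state("loci")
pass <- load_state("pass")

quant <- quantify_loci(loci, pass, sim$genome)
save_state(quant, "quant")

write_tsv(quant$isomirs, "isomirs.tsv")
cls <- strsplit(quant$isomirs$classes, ",")
comp <- end_composition(quant$isomirs$sequence, cls,
                        weights = quant$isomirs$count)
write_tsv(comp, "isomir_end_composition.tsv")

share <- sort(prop.table(tapply(quant$isomirs$count,
                                unlist(lapply(seq_along(cls), function(i)
                                  cls[[i]][1])), sum)),
              decreasing = TRUE)
cat("IsomiR class abundance shares:\n")
print(round(share, 3))

tiss <- tissue_mean_tpm(quant$expression, sim$lib_info)
tiss_iso <- tissue_mean_tpm(quant$isomir_expression, sim$lib_info)
corr <- isomir_context_correlation(tiss_iso, tiss, loci$context)
write_tsv(corr, "isomir_context_correlation.tsv")
cat("IsomiR vs locus abundance correlation per context:\n")
print(corr, row.names = FALSE)
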