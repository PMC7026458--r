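#!/usr/bin/env Rscript
# Tissue-specificity calling (modH < 1.8 bits, Zmax > 3) on replicate-
# mean TPM, and an exact-test differential-expression contrast between
# two tissues.

source("analysis/00_common.R")
sim <- load_state("sim")
loci <- load_state("loci")
quant <- load_state("quant")

tiss <- tissue_mean_tpm(quant$expression, sim$lib_info)
rownames(tiss) <- loci$locus
spec <- call_tissue_specific(tiss)
write_tsv(spec, "specificity.tsv")
save_state(tiss, "tissue_tpm")

m <- match(loci$mature, sim$loci$mature)
truth <- sim$loci$specific[m]
cat("Tissue-specific calls:", sum(spec$specific), "(planted one-hot:",
    sum(truth), ")\n")
agree <- spec$specific[truth] &
  spec$tissue[truth] == sim$loci$target_tissue[m][truth]
cat("One-hot loci called specific in the correct tissue:",
    sum(agree), "/", sum(truth), "\n")

de <- de_exact_test(tiss[, "tissue1"], tiss[, "tissue2"],
                    locus_id = rownames(tiss))
write_tsv(de, "de_tissue1_vs_tissue2.tsv")
cat("Differential loci (p < 0.01, |log2FC| >= 1) tissue1 vs tissue2:",
    sum(de$significant), "of", nrow(de), "\n")
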