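#!/usr/bin/env Rscript
# Collapse the 42 libraries, align with one mismatch allowed, TPM-
# normalize, and run the filtering cascade (size, structural RNA,
# abundance support, repetitiveness).

source("analysis/00_common.R")
sim <- load_state("sim")

reads <- collapse_reads(sim$libraries)
reads <- align_reads(reads, sim$genome)
reads <- tpm_normalize(reads)
reads <- filter_reads(reads, blacklist = sim$blacklist)

write_tsv(reads$attrition, "attrition.tsv")
save_state(reads, "reads")

cat("Distinct sequences:", length(reads$seq), "\n")
print(reads$attrition, row.names = FALSE)
planted <- match(sim$loci$mature, reads$seq)
cat("Planted matures passing every filter:",
    sum(reads$filter_status[planted] == "pass"), "/",
    nrow(sim$loci), "\n")
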