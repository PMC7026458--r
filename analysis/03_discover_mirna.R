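#!/usr/bin/env Rscript
# Discover miRNA loci from the filtered reads: strand-specific candidate
# windows, maximum-pairing hairpin folding, strand/abundance-bias and
# duplex gates, then the known/novel split against the reference set.

source("analysis/00_common.R")
sim <- load_state("sim")
reads <- load_state("reads")
pass <- passing_reads(reads)

loci <- discover_mirna(pass, sim$genome, reference = sim$reference)
ann <- sim$annotations
loci$context <- genomic_context(
  loci, ann[S4Vectors::mcols(ann)$type == "gene"],
  ann[S4Vectors::mcols(ann)$type == "transposable_element"])

write_tsv(loci[, setdiff(names(loci), "structure")], "mirna_loci.tsv")
save_state(loci, "loci")
save_state(pass, "pass")

lg <- GenomicRanges::GRanges(loci$chrom,
                             IRanges::IRanges(loci$start, loci$end))
tg <- GenomicRanges::GRanges(sim$loci$chrom,
                             IRanges::IRanges(sim$loci$start,
                                              sim$loci$end))
cat("Discovered", nrow(loci), "loci;",
    sum(GenomicRanges::countOverlaps(tg, lg) > 0), "/", nrow(sim$loci),
    "planted loci recovered;",
    sum(GenomicRanges::countOverlaps(lg, tg) == 0),
    "windows outside any planted locus\n")
print(table(status = loci$status, context = loci$context))
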