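#!/usr/bin/env Rscript
# Detect 21- and 24-nt PHAS loci with the hypergeometric phasing scan,
# assign miRNA triggers by complementarity, and apply the
# retrotransposon / easiRNA-trigger exclusion rule.

source("analysis/00_common.R")
sim <- load_state("sim")
pass <- load_state("pass")

phas <- rbind(detect_phas(pass, 21), detect_phas(pass, 24))
trig_set <- data.frame(id = sub("^ref_", "", names(sim$reference)),
                       seq = unname(sim$reference),
                       stringsAsFactors = FALSE)
trig <- lapply(seq_len(nrow(phas)), function(i)
  assign_trigger(phas[i, ], sim$genome, trig_set))
phas$trigger_id <- vapply(trig, function(t)
  if (is.null(t)) NA_character_ else t$id, character(1))
phas$trigger_length <- vapply(trig, function(t)
  if (is.null(t)) NA_integer_ else t$length, integer(1))
te <- sim$annotations[
  S4Vectors::mcols(sim$annotations)$type == "transposable_element"]
phas <- apply_exclusion(phas, te)

write_tsv(phas, "phas_loci.tsv")
save_state(phas, "phas")

cat("PHAS loci accepted at P < 1e-5:", sum(phas$cycle == 21), "x 21-nt,",
    sum(phas$cycle == 24), "x 24-nt (planted:", sum(sim$phas$cycle == 21),
    "+", sum(sim$phas$cycle == 24), ")\n")
cat("Triggers:", paste(names(table(phas$trigger_id)),
                       table(phas$trigger_id), collapse = ", "), "\n")
cat("Excluded as retrotransposon + easiRNA trigger:",
    sum(phas$excluded), "\n")
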