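# Shared setup for the numbered analysis scripts. Each script loads the
# state left by its predecessors from results/cache/ and appends its own.

library(srnascape)

RES_DIR <- "results"
CACHE <- file.path(RES_DIR, "cache")
dir.create(CACHE, recursive = TRUE, showWarnings = FALSE)

STUDY_SEED <- 101  # one seed for the whole analysis narrative

save_state <- function(object, name)
  saveRDS(object, file.path(CACHE, paste0(name, ".rds")))

load_state <- function(name) {
  f <- file.path(CACHE, paste0(name, ".rds"))
  if (!file.exists(f))
    stop("missing cached state '", name,
         "': run the earlier numbered scripts first")
  readRDS(f)
}

write_tsv <- function(x, name)
  write.table(x, file.path(RES_DIR, name), sep = "\t", quote = FALSE,
              row.names = FALSE)
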