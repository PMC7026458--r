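# shared small synthetic study (memoized: several test files reuse it)
.sim_cache <- new.env(parent = emptyenv())

small_sim_config <- function(seed = 7) {
  sim_config(seed = seed, n_mirna_loci = 20, n_tissue_specific = 5,
             n_phas21 = 3, n_phas24 = 3, n_tandem_pairs = 2,
             n_syntenic_pairs = 2, libraries_per_tissue = 2,
             depth_per_library = 2e5, contamination_fraction = 0,
             chrom_length = 200000)
}

get_small_sim <- function() {
  if (is.null(.sim_cache$sim))
    .sim_cache$sim <- generate_libraries(generate_genome(
      small_sim_config()))
  .sim_cache$sim
}

get_small_filtered <- function() {
  if (is.null(.sim_cache$pass)) {
    sim <- get_small_sim()
    reads <- collapse_reads(sim$libraries)
    reads <- align_reads(reads, sim$genome)
    reads <- tpm_normalize(reads)
    reads <- filter_reads(reads, blacklist = sim$blacklist)
    .sim_cache$reads <- reads
    .sim_cache$pass <- passing_reads(reads)
  }
  list(sim = get_small_sim(), reads = .sim_cache$reads,
       pass = .sim_cache$pass)
}

# tiny handmade genome with one planted hairpin, for discovery unit tests
hairpin_genome <- function(seed = 11) {
  withr::with_seed(seed, {
    hp <- srnascape:::.make_hairpin()
    pad5 <- srnascape:::.rand_dna(300)
    pad3 <- srnascape:::.rand_dna(300)
    genome <- c(chrA = paste0(pad5, hp$precursor, pad3))
    list(genome = genome, hp = hp, offset = 300)
  })
}
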