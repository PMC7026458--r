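test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_mirna_loci = -1), "nonnegative")
  expect_error(sim_config(n_mirna_loci = 5, n_tissue_specific = 6),
               "exceed")
  expect_error(sim_config(contamination_fraction = 1.2), "proportions")
  expect_error(sim_config(n_mirna_loci = 4, n_tissue_specific = 0,
                          n_tandem_pairs = 2, n_syntenic_pairs = 1),
               "pairs")
})

test_that("identical seeds give byte-identical outputs", {
  cfg <- sim_config(seed = 42, n_mirna_loci = 6, n_tissue_specific = 1,
                    n_phas21 = 1, n_phas24 = 1, n_tandem_pairs = 1,
                    n_syntenic_pairs = 1, n_tissues = 4,
                    libraries_per_tissue = 1, depth_per_library = 5e4,
                    contamination_fraction = 0.02,
                    n_frag_species = 2000, chrom_length = 150000)
  s1 <- generate_libraries(generate_genome(cfg))
  s2 <- generate_libraries(generate_genome(cfg))
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$loci, s2$loci)
  expect_identical(s1$libraries, s2$libraries)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  for (f in c("genome.fa", "annotations.gff3", "truth_loci.tsv",
              "synteny.tsv", "libraries/tissue1_rep1.tsv"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
})

test_that("degenerate configurations produce clean empty outputs", {
  cfg <- sim_config(n_mirna_loci = 0, n_tissue_specific = 0,
                    n_phas21 = 0, n_phas24 = 0, n_tandem_pairs = 0,
                    n_syntenic_pairs = 0, n_tissues = 2,
                    libraries_per_tissue = 1,
                    contamination_fraction = 0, chrom_length = 60000,
                    n_chromosomes = 1)
  sim <- generate_genome(cfg)
  expect_null(sim$loci)
  expect_null(sim$phas)
  expect_equal(nrow(sim$synteny), 0)
  expect_error(
    generate_genome(sim_config(n_mirna_loci = 400, n_chromosomes = 1,
                               n_tandem_pairs = 0, n_syntenic_pairs = 0,
                               n_tissue_specific = 0,
                               chrom_length = 90000)),
    "too short")
  expect_error(sim_config(n_chromosomes = 1), "two chromosomes")
})

test_that("tandem truth pairs sit under 200 kb on one chromosome", {
  sim <- get_small_sim()
  td <- sim$loci[sim$loci$dup_label == "tandem", ]
  expect_equal(nrow(td), 4)
  for (p in unique(pmin(td$locus, td$partner))) {
    pair <- td[td$locus == p | td$partner == p, ]
    expect_equal(length(unique(pair$chrom)), 1)
    gap <- max(pair$start) - min(pair$end) - 1
    expect_lt(gap, 200000)
    expect_gt(gap, 0)
  }
  sy <- sim$loci[sim$loci$dup_label == "syntenic", ]
  expect_true(all(table(sy$chrom) >= 0))
  # syntenic partners are mutually linked and inside declared blocks
  for (i in seq_len(nrow(sy))) {
    j <- match(sy$partner[i], sim$loci$locus)
    expect_equal(sim$loci$partner[j], sy$locus[i])
  }
})

test_that("library draws hit the exact configured depth", {
  sim <- get_small_sim()
  for (lib in sim$libraries)
    expect_equal(sum(lib$count), 2e5)
})

test_that("one-hot loci are expressed only in their target tissue", {
  sim <- get_small_sim()
  spec <- sim$loci[sim$loci$specific, ]
  for (i in seq_len(nrow(spec))) {
    m <- spec$mature[i]
    libs_with <- names(Filter(function(tab)
      m %in% tab$sequence, sim$libraries))
    tiss <- unique(sim$lib_info$tissue[
      sim$lib_info$library_id %in% libs_with])
    expect_equal(tiss, spec$target_tissue[i])
  }
})

test_that("every planted interval lies within the genome", {
  sim <- get_small_sim()
  for (tab in list(sim$loci, sim$phas)) {
    expect_true(all(tab$start >= 1))
    expect_true(all(tab$end <= sim$chrom_length[tab$chrom]))
  }
  # planted sequences are really in the genome
  for (i in seq_len(nrow(sim$loci)))
    expect_equal(substr(sim$genome[[sim$loci$chrom[i]]],
                        sim$loci$mature_start[i],
                        sim$loci$mature_start[i] +
                          nchar(sim$loci$mature[i]) - 1),
                 sim$loci$mature[i])
})

test_that("configured non-templated addition rate is recovered", {
  cfg <- sim_config(seed = 77, n_mirna_loci = 1, n_tissue_specific = 0,
                    n_phas21 = 0, n_phas24 = 0, n_tandem_pairs = 0,
                    n_syntenic_pairs = 0, n_tissues = 2,
                    libraries_per_tissue = 1, depth_per_library = 10000,
                    contamination_fraction = 0, star_fraction = 0,
                    isomir_rate = c(ntadd3 = 0.05),
                    chrom_length = 60000, n_chromosomes = 1)
  sim <- generate_libraries(generate_genome(cfg))
  iso_seq <- sim$species$seq[sim$species$kind == "isomir"]
  tab <- sim$libraries[[1]]
  n_iso <- sum(tab$count[tab$sequence %in% iso_seq])
  ci <- qbinom(c(0.005, 0.995), 10000, 0.05)
  expect_gte(n_iso, ci[1])
  expect_lte(n_iso, ci[2])
})

test_that("zero depth warns and yields empty libraries", {
  cfg <- sim_config(n_mirna_loci = 2, n_tissue_specific = 0,
                    n_phas21 = 0, n_phas24 = 0, n_tandem_pairs = 0,
                    n_syntenic_pairs = 0, n_tissues = 2,
                    libraries_per_tissue = 1, depth_per_library = 0,
                    contamination_fraction = 0, chrom_length = 60000,
                    n_chromosomes = 1)
  expect_warning(sim <- generate_libraries(generate_genome(cfg)),
                 "empty")
  expect_true(all(vapply(sim$libraries, nrow, integer(1)) == 0))
})

test_that("clean draws contain only planted exact species", {
  cfg <- sim_config(seed = 5, n_mirna_loci = 3, n_tissue_specific = 0,
                    n_phas21 = 1, n_phas24 = 0, n_tandem_pairs = 0,
                    n_syntenic_pairs = 0, n_tissues = 2,
                    libraries_per_tissue = 1, depth_per_library = 2e4,
                    contamination_fraction = 0, star_fraction = 0.1,
                    isomir_rate = c(ntadd3 = 0),
                    chrom_length = 80000, n_chromosomes = 1)
  sim <- generate_libraries(generate_genome(cfg))
  planted <- c(sim$loci$mature, sim$loci$star,
               sim$species$seq[sim$species$kind %in%
                                 c("phasirna", "phas_antisense")])
  for (tab in sim$libraries)
    expect_true(all(tab$sequence %in% planted))
})
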