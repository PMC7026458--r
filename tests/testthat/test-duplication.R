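test_that("genomic context uses PCG > TE > UI precedence", {
  pcg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 500))
  te <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 800),
                                                        c(500, 900)))
  loci <- data.frame(chrom = "chr1", start = c(200, 820, 2000),
                     end = c(300, 880, 2100))
  expect_equal(genomic_context(loci, pcg, te), c("PCG", "TE", "UI"))
  # a single shared base counts as overlap
  edge <- data.frame(chrom = "chr1", start = 500, end = 600)
  expect_equal(genomic_context(edge, pcg, te), "PCG")
})

test_that("conserved pairs follow the 2-mismatch rule", {
  # an aperiodic mature so shifted self-matches stay > 2 mismatches
  m <- withr::with_seed(61, srnascape:::.rand_dna(21))
  loci <- data.frame(
    locus = c("a", "b", "c", "d"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = c(1000, 151000, 5000, 9000),
    end = c(1135, 151135, 5135, 9135),
    mature = c(m, m, srnascape:::.inject_mismatches(m, c(2, 6)),
               srnascape:::.inject_mismatches(m, c(2, 6, 10, 14))),
    stringsAsFactors = FALSE)
  pairs <- find_conserved_pairs(loci)
  key <- paste(pairs$locus_a, pairs$locus_b)
  expect_true("a b" %in% key)
  expect_true("a c" %in% key)          # 2 substitutions: conserved
  expect_false(any(grepl("d", key) & grepl("a|b", key)))

  # genome re-alignment picks up an unannotated extra copy
  g <- c(chrZ = paste0(srnascape:::.rand_dna(100), m,
                       srnascape:::.rand_dna(100)))
  p2 <- find_conserved_pairs(loci[1, ], genome = g)
  expect_equal(nrow(p2), 1)
  expect_true(is.na(p2$locus_b))
  expect_equal(p2$chrom_b, "chrZ")
  expect_equal(p2$start_b, 101)
})

test_that("duplication mechanism follows distance and synteny rules", {
  m <- "ACGTACGTACGTACGTACGTA"
  loci <- data.frame(
    locus = c("t1", "t2", "f1", "f2", "s1", "s2", "solo"),
    chrom = c("chr1", "chr1", "chr2", "chr2", "chr3", "chr4", "chr5"),
    start = c(1000, 151000, 1000, 255000, 11000, 21000, 1000),
    end = c(1135, 151135, 1135, 255135, 11135, 21135, 1135),
    mature = c(m, m, "TTTTGGGGCCCCAAAATTTTG",
               "TTTTGGGGCCCCAAAATTTTG", "GATCGATCGATCGATCGATCG",
               "GATCGATCGATCGATCGATCG", "CCCCCAAAAATTTTTGGGGGC"),
    stringsAsFactors = FALSE)
  blocks <- data.frame(chrom_a = "chr3", start_a = 10000, end_a = 15000,
                       chrom_b = "chr4", start_b = 20000, end_b = 25000,
                       block_id = "blk1", stringsAsFactors = FALSE)
  pairs <- find_conserved_pairs(loci)
  dup <- classify_duplication(loci, pairs, blocks)
  get <- function(id) dup[dup$locus == id, ]
  expect_equal(get("t1")$mechanism, "tandem")        # gap ~150 kb
  expect_equal(get("t2")$status, "duplicate")
  expect_lt(get("t1")$distance, 200000)
  expect_equal(get("f1")$status, "singleton")        # gap ~254 kb
  expect_equal(get("s1")$mechanism, "syntenic")
  expect_equal(get("s2")$mechanism, "syntenic")
  expect_equal(get("solo")$status, "singleton")
})

test_that("synteny block files round-trip and reject malformed rows", {
  blocks <- data.frame(chrom_a = "chr1", start_a = 1, end_a = 1000,
                       chrom_b = "chr2", start_b = 51, end_b = 1050,
                       block_id = "b1", stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(blocks, f, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_synteny_blocks(f)
  expect_equal(got$block_id, "b1")
  expect_equal(got$start_b, 51)
  expect_equal(names(got), names(blocks))
  bad <- blocks
  bad$end_a <- 0
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_synteny_blocks(f), "line 2")
})

test_that("ratio test is 2x2 Pearson without continuity correction", {
  pcg <- ratio_chisq(112, 13, 305, 114, "PCG")
  expect_equal(pcg$ratio, 8.62)
  expect_equal(signif(pcg$p_value, 3), 9.68e-5)
  te <- ratio_chisq(92, 33, 305, 114, "TE")
  expect_equal(signif(te$p_value, 3), 0.858)
  flat <- ratio_chisq(61, 30, 305, 150)
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p_value, 1)
  expect_error(ratio_chisq(0, 0, 10, 5), "margin")
})

test_that("chi-square engine equals the brute-force Pearson statistic", {
  for (i in 1:500) {
    tab <- withr::with_seed(i, matrix(sample(1:400, 4), 2, 2))
    got <- ratio_chisq(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_equal(got$chi2, brute_chisq(tab), tolerance = 1e-10)
  }
})

test_that("pipeline duplication calls recover the planted labels", {
  fl <- get_small_filtered()
  loci <- discover_mirna(fl$pass, fl$sim$genome)
  loci$context <- genomic_context(
    loci,
    fl$sim$annotations[S4Vectors::mcols(fl$sim$annotations)$type ==
                         "gene"],
    fl$sim$annotations[S4Vectors::mcols(fl$sim$annotations)$type ==
                         "transposable_element"])
  pairs <- find_conserved_pairs(loci, genome = fl$sim$genome)
  dup <- classify_duplication(loci, pairs, blocks = fl$sim$synteny)
  # map discovered loci to truth by interval (duplicate-pair partners
  # share a mature sequence, so sequence matching is ambiguous)
  ov <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(loci$chrom,
                           IRanges::IRanges(loci$start, loci$end)),
    GenomicRanges::GRanges(fl$sim$loci$chrom,
                           IRanges::IRanges(fl$sim$loci$start,
                                            fl$sim$loci$end)))
  m <- rep(NA_integer_, nrow(loci))
  m[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)
  truth <- fl$sim$loci$dup_label[m]
  expect_identical(dup$mechanism[truth == "tandem"],
                   rep("tandem", sum(truth == "tandem")))
  expect_identical(dup$mechanism[truth == "syntenic"],
                   rep("syntenic", sum(truth == "syntenic")))
  expect_identical(dup$status[truth == "singleton"],
                   rep("singleton", sum(truth == "singleton")))
  # every locus gets exactly one context and one status
  expect_true(all(loci$context %in% c("PCG", "TE", "UI")))
  expect_true(all(dup$status %in% c("singleton", "duplicate")))
  # planted context labels are recovered through the annotations
  expect_identical(loci$context, fl$sim$loci$context[m])
})
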