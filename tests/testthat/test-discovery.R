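test_that("candidate clustering merges by gap and rejects long windows", {
  g <- c(chrA = withr::with_seed(21, srnascape:::.rand_dna(5000)))
  near1 <- substr(g, 1001, 1021)
  near2 <- substr(g, 1027, 1047)      # 5-nt gap from near1
  far <- substr(g, 1547, 1567)        # 500 nt downstream of near1
  r <- align_reads(collapse_reads(list(l = c(near1, near2, far))), g)
  cl <- cluster_candidates(r, c(chrA = 5000))
  expect_equal(nrow(cl$windows), 2)
  expect_equal(cl$discarded, 0)

  # a dense 400-nt cluster exceeds the 300-nt precursor cap
  spread <- vapply(seq(2001, 2381, by = 20), function(s)
    substr(g, s, s + 20), character(1))
  r2 <- align_reads(collapse_reads(list(l = spread)), g)
  cl2 <- cluster_candidates(r2, c(chrA = 5000))
  expect_equal(nrow(cl2$windows), 0)
  expect_equal(cl2$discarded, 1)
})

test_that("strand bias is the sense fraction of pooled raw counts", {
  g <- c(chrA = withr::with_seed(22, srnascape:::.rand_dna(2000)))
  sense <- substr(g, 1001, 1021)
  anti <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(g, 1031, 1051))))
  win <- data.frame(chrom = "chrA", start = 990, end = 1060,
                    strand = "+")
  mk <- function(cs, ca) {
    libs <- list(l = data.frame(sequence = c(sense, anti),
                                count = c(cs, ca)))
    align_reads(collapse_reads(libs), g)
  }
  expect_equal(strand_bias(mk(10L, 0L), win), 1.0)
  expect_equal(strand_bias(mk(9L, 1L), win), 0.9)
  expect_equal(strand_bias(mk(8L, 2L), win), 0.8)
})

test_that("canonical selection takes the most abundant sense read", {
  hg <- hairpin_genome()
  hp <- hg$hp
  mature <- hp$mature
  star <- hp$star
  libs <- list(l = data.frame(sequence = c(mature, star),
                              count = c(100L, 40L)))
  r <- align_reads(collapse_reads(libs), hg$genome)
  win <- data.frame(chrom = "chrA", start = hg$offset + 1,
                    end = hg$offset + nchar(hp$precursor), strand = "+")
  f <- fold_hairpin(hp$precursor)
  sel <- select_canonical(r, win, f$partner)
  expect_equal(r$seq[sel$mature$read], mature)
  expect_true(sel$star$observed)
  expect_equal(r$seq[sel$star$read], star)

  # tie at equal counts: the 5'-most read wins
  shifted <- substr(hp$precursor, hp$mature_ivl[1] - 2,
                    hp$mature_ivl[2] - 2)
  libs2 <- list(l = data.frame(sequence = c(mature, shifted),
                               count = c(100L, 100L)))
  r2 <- align_reads(collapse_reads(libs2), hg$genome)
  sel2 <- select_canonical(r2, win, f$partner)
  expect_equal(sel2$mature$p5, hp$mature_ivl[1] - 2)

  # no star read observed: star inferred from structure
  libs3 <- list(l = data.frame(sequence = mature, count = 50L))
  r3 <- align_reads(collapse_reads(libs3), hg$genome)
  sel3 <- select_canonical(r3, win, f$partner)
  expect_false(sel3$star$observed)
  expect_equal(sel3$star$p5, hp$star_ivl[1], tolerance = 0)
})

test_that("abundance bias is the attributable sense fraction", {
  hg <- hairpin_genome()
  hp <- hg$hp
  # an aligned but unrelated read inside the window: the padding region
  unrelated <- substr(hg$genome, hg$offset - 15, hg$offset + 5)
  win <- data.frame(chrom = "chrA", start = hg$offset - 20,
                    end = hg$offset + nchar(hp$precursor), strand = "+")
  libs <- list(l = data.frame(sequence = c(hp$mature, hp$star,
                                           unrelated),
                              count = c(60L, 15L, 25L)))
  r <- align_reads(collapse_reads(libs), hg$genome)
  wseq <- substr(hg$genome, win$start, win$end)
  f <- fold_hairpin(wseq)
  sel <- select_canonical(r, win, f$partner)
  ab <- abundance_bias(r, win, wseq, sel)
  expect_equal(ab, 0.75)
})

test_that("known/novel split uses the 2-mismatch conservation rule", {
  ref <- c("ACGTACGTACGTACGTACGTA")
  expect_equal(classify_known_novel("ACGTACGTACGTACGTACGTA", ref),
               "known")
  two <- srnascape:::.inject_mismatches(ref, c(3, 9))
  expect_equal(classify_known_novel(two, ref), "known")
  three <- srnascape:::.inject_mismatches(ref, c(3, 9, 15))
  expect_equal(classify_known_novel(three, ref), "novel")
  expect_equal(classify_known_novel(ref, character(0)), "novel")
  expect_equal(classify_known_novel(ref, NULL), "novel")
})

test_that("discovery recovers planted loci and rejects nothing else", {
  fl <- get_small_filtered()
  loci <- discover_mirna(fl$pass, fl$sim$genome,
                         reference = fl$sim$reference)
  truth <- fl$sim$loci
  lg <- GenomicRanges::GRanges(loci$chrom,
                               IRanges::IRanges(loci$start, loci$end))
  tg <- GenomicRanges::GRanges(truth$chrom,
                               IRanges::IRanges(truth$start, truth$end))
  expect_equal(sum(GenomicRanges::countOverlaps(tg, lg) > 0),
               nrow(truth))
  expect_equal(sum(GenomicRanges::countOverlaps(lg, tg) == 0), 0)
  # every accepted locus satisfies all gates
  expect_true(all(loci$strand_bias >= 0.9))
  expect_true(all(loci$abundance_bias >= 0.75))
  expect_true(all(loci$end - loci$start + 1 <= 300))
  expect_true(all(loci$duplex_mismatches <= 5))
  expect_true(all(loci$bulges <= 3))
  # mature is the locus's most abundant read and known/novel agrees
  m <- match(loci$mature, truth$mature)
  expect_true(all(!is.na(m)))
  expect_identical(loci$status == "known", truth$known[m])
})
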