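canon <- "TAGCTAGGATCAGGTCAATCA"           # 21 nt
f5 <- "GATTAC"
f3 <- "CGTGAA"

test_that("each variant class is recognized from sequence alone", {
  # canonical read: no class
  r0 <- classify_isomir(canon, canon, f5, f3)
  expect_true(r0$canonical)
  expect_length(r0$classes, 0)

  expect_equal(classify_isomir(substr(canon, 2, 21), canon, f5,
                               f3)$classes, "trim5")
  expect_equal(classify_isomir(paste0("C", canon), canon, f5,
                               f3)$classes, "add5")
  expect_equal(classify_isomir(substr(canon, 1, 20), canon, f5,
                               f3)$classes, "trim3")
  # genomic-template 3' base -> templated addition
  expect_equal(classify_isomir(paste0(canon, "C"), canon, f5,
                               f3)$classes, "add3")
  # non-template 3' base -> nt addition
  expect_equal(classify_isomir(paste0(canon, "A"), canon, f5,
                               f3)$classes, "ntadd3")
  # substitutions: position 4 is seed (2-8), position 15 is tail
  seedv <- srnascape:::.inject_mismatches(canon, 4)
  tailv <- srnascape:::.inject_mismatches(canon, 15)
  expect_equal(classify_isomir(seedv, canon, f5, f3)$classes,
               "seed_snp")
  expect_equal(classify_isomir(tailv, canon, f5, f3)$classes,
               "tail_snp")
  expect_equal(classify_isomir(seedv, canon, f5, f3)$substitutions, 4L)
})

test_that("classes combine and offsets carry sign conventions", {
  both <- paste0("C", substr(canon, 1, 20))   # 5' addition + 3' trim
  r <- classify_isomir(both, canon, f5, f3)
  expect_setequal(r$classes, c("add5", "trim3"))
  expect_equal(r$offset5, 1L)
  expect_equal(r$offset3, -1L)
  # trailing substitution is a tail SNP, not trimming plus nt-addition
  lastsub <- srnascape:::.inject_mismatches(canon, 21)
  expect_equal(classify_isomir(lastsub, canon, f5, f3)$classes,
               "tail_snp")
})

test_that("unattributable reads are excluded, classification is pure", {
  far <- srnascape:::.inject_mismatches(canon, c(3, 8, 12, 17))
  expect_false(classify_isomir(far, canon, f5, f3)$attributable)
  shifted <- paste0("CCCCCC", canon)           # +6 nt: beyond max offset
  expect_false(classify_isomir(shifted, canon, f5, f3)$attributable)
  a <- classify_isomir(substr(canon, 2, 21), canon, f5, f3)
  b <- classify_isomir(substr(canon, 2, 21), canon, f5, f3)
  expect_identical(a, b)
})

test_that("end composition is a per-class per-end distribution", {
  one <- end_composition("TAGCTAGGATCAGGTCAATCA", list("ntadd3"))
  expect_equal(one$freq[one$end == "3p"], 1)
  expect_equal(one$base[one$end == "3p"], "A")

  seqs <- c("AACCGGTTAACCGGTTAACCA", "AACCGGTTAACCGGTTAACCU",
            "GACCGGTTAACCGGTTAACCA")
  cls <- list("ntadd3", "ntadd3", c("trim5", "ntadd3"))
  comp <- end_composition(seqs, cls, weights = c(2, 1, 1))
  for (cl in unique(comp$class)) for (e in c("5p", "3p")) {
    s <- sum(comp$freq[comp$class == cl & comp$end == e])
    expect_equal(s, 1)
  }
  nt3 <- comp[comp$class == "ntadd3" & comp$end == "3p", ]
  expect_equal(nt3$freq[nt3$base == "A"], 0.75)

  empty <- end_composition(character(0), list())
  expect_equal(nrow(empty), 0)
})

test_that("planted isomiR classes are recovered exactly", {
  sim <- get_small_sim()
  iso <- sim$species[sim$species$kind == "isomir", ]
  for (i in seq_len(nrow(iso))) {
    li <- match(iso$locus[i], sim$loci$locus)
    chrseq <- sim$genome[[sim$loci$chrom[li]]]
    ms <- sim$loci$mature_start[li]
    L <- nchar(sim$loci$mature[li])
    got <- classify_isomir(iso$seq[i], sim$loci$mature[li],
                           substr(chrseq, ms - 6, ms - 1),
                           substr(chrseq, ms + L, ms + L + 5))
    expect_equal(got$classes, iso$class[i], info = iso$locus[i])
  }
})

test_that("context correlation is Pearson on per-context aggregates", {
  loc <- matrix(withr::with_seed(3, runif(5 * 10, 10, 100)), 5, 10)
  iso <- 0.5 * loc
  ctx <- c("PCG", "PCG", "TE", "TE", "UI")
  r <- isomir_context_correlation(iso, loc, ctx)
  expect_equal(r$r, rep(1, 3))

  # independent vectors: |r| small with overwhelming probability
  iso2 <- matrix(withr::with_seed(4, runif(2 * 100)), 2, 100)
  loc2 <- matrix(withr::with_seed(5, runif(2 * 100)), 2, 100)
  r2 <- isomir_context_correlation(iso2, loc2, c("PCG", "PCG"))
  expect_lt(abs(r2$r), 0.3)

  expect_error(isomir_context_correlation(iso[, 1:2], loc[, 1:2], ctx),
               "3 samples")
  expect_message(
    rc <- isomir_context_correlation(matrix(1, 1, 5), matrix(1, 1, 5),
                                     "TE"), "undefined")
  expect_true(is.na(rc$r))
})

test_that("attributed abundance decomposes into canonical plus isomiRs", {
  fl <- get_small_filtered()
  loci <- discover_mirna(fl$pass, fl$sim$genome)
  q <- quantify_loci(loci, fl$pass, fl$sim$genome)
  expect_true(all(q$isomir_expression <= q$expression + 1e-9))
  # locus totals dominated by the canonical mature
  expect_true(all(rowSums(q$isomir_expression) <
                    rowSums(q$expression)))
})
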