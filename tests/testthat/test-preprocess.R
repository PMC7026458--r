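test_that("collapsing counts distinct sequences per library", {
  r <- collapse_reads(list(lib1 = c("ACGUACGUACGUACG", "ACGUACGUACGUACG",
                                    "ACGAACGUACGUACG")))
  expect_equal(length(r$seq), 2)
  expect_setequal(as.integer(r$counts), c(2L, 1L))
  # U is unified to the DNA alphabet
  expect_true(all(!grepl("U", r$seq)))

  three <- collapse_reads(list(a = "ACGTACGTACGTACG",
                               b = "ACGTACGTACGTACG",
                               c = "ACGTACGTACGTACG"))
  expect_equal(length(three$seq), 1)
  expect_equal(as.integer(three$counts), c(1L, 1L, 1L))

  withn <- collapse_reads(list(a = c("ACGTNCGTACGTACG",
                                     "ACGTACGTACGTACG")))
  expect_equal(length(withn$seq), 1)
  expect_equal(withn$dropped_n, 1L)

  expect_warning(empty <- collapse_reads(list(a = character())),
                 "no reads")
  expect_equal(length(empty$seq), 0)
})

test_that("alignment reports every placement within one substitution", {
  g <- c(chrA = withr::with_seed(5, srnascape:::.rand_dna(4000)))
  exact <- substr(g, 1001, 1021)
  onemm <- srnascape:::.inject_mismatches(exact, 10)
  twomm <- srnascape:::.inject_mismatches(onemm, 15)
  minus <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(g, 2001, 2021))))
  r <- collapse_reads(list(l = c(exact, onemm, twomm, minus)))
  r <- align_reads(r, g)
  aln <- r$alignments
  get <- function(s) aln[aln$read == match(s, r$seq), , drop = FALSE]
  expect_equal(get(exact)$mismatches, 0)
  expect_equal(get(exact)$start, 1001)
  expect_equal(get(onemm)$mismatches, 1)
  expect_equal(nrow(get(twomm)), 0)
  expect_equal(r$n_hits[match(twomm, r$seq)], 0)
  expect_equal(get(minus)$strand, "-")
  expect_equal(get(minus)$start, 2001)
})

test_that("TPM normalization follows count * 1e6 / mapped total", {
  g <- c(chrA = withr::with_seed(6, srnascape:::.rand_dna(2000)))
  a <- substr(g, 101, 121)
  b <- substr(g, 201, 221)
  libs <- list(l1 = data.frame(sequence = c(a, b),
                               count = c(5L, 999995L)),
               l2 = data.frame(sequence = c(a, b),
                               count = c(10L, 1999990L)))
  r <- tpm_normalize(align_reads(collapse_reads(libs), g))
  i <- match(a, r$seq)
  expect_equal(unname(r$tpm[i, "l1"]), 5)
  expect_equal(unname(r$tpm[i, "l2"]), 5)
  expect_equal(unname(colSums(r$tpm)), c(1e6, 1e6))
  expect_equal(r$total_tpm[i], 10)
})

test_that("filter cascade assigns one status per read in fixed order", {
  g <- c(chrA = withr::with_seed(8, srnascape:::.rand_dna(9000)))
  short <- substr(g, 101, 117)            # 17 nt -> size
  struct_src <- substr(g, 301, 400)       # a planted structural gene
  struct_read <- substr(struct_src, 11, 32)
  rep_read <- substr(g, 501, 521)
  g <- c(g, chrB = paste(rep(rep_read, 25), collapse = ""))  # > 20 hits
  good <- substr(g[["chrA"]], 1001, 1021)
  weak <- substr(g[["chrA"]], 2001, 2021)
  off <- substr(g[["chrA"]], 3001, 3021)  # filler fixing mapped totals
  mk <- function(cg, cw, filler) data.frame(
    sequence = c(short, struct_read, rep_read, good, weak, off),
    count = c(50L, 40L, 200L, cg, cw, filler))
  # mapped totals ~1e6 per library so counts read as TPM directly
  libs <- list(l1 = mk(80L, 12L, 999690L), l2 = mk(80L, 2L, 999690L))
  r <- tpm_normalize(align_reads(collapse_reads(libs), g))
  r <- filter_reads(r, blacklist = c(sn1 = struct_src))
  st <- setNames(r$filter_status, r$seq)
  expect_equal(unname(st[short]), "size")
  expect_equal(unname(st[struct_read]), "structural")
  expect_equal(unname(st[rep_read]), "repetitive")
  # total ~160 TPM > 100 and max-library ~80 TPM > 10
  expect_equal(unname(st[good]), "pass")
  # total only ~14 TPM
  expect_equal(unname(st[weak]), "low_abundance")
  expect_true(all(r$filter_status %in% c(
    "pass", "size", "structural", "unaligned", "low_abundance",
    "repetitive")))
  expect_equal(nrow(r$attrition), 7)
  expect_equal(r$attrition$remaining[7], sum(r$filter_status == "pass"))

  # rerunning the cascade is idempotent
  r2 <- filter_reads(r, blacklist = c(sn1 = struct_src))
  expect_identical(r$filter_status, r2$filter_status)
})

test_that("abundance support needs both total and per-library TPM", {
  g <- c(chrA = withr::with_seed(9, srnascape:::.rand_dna(3000)))
  x <- substr(g, 101, 121)
  off <- substr(g, 2001, 2021)
  # 13 libraries at ~12 TPM each: total 156 > 100, max 12 > 10 -> pass
  libs <- lapply(1:13, function(i) data.frame(
    sequence = c(x, off), count = c(12L, 999988L)))
  names(libs) <- paste0("l", 1:13)
  r <- filter_reads(tpm_normalize(align_reads(collapse_reads(libs), g)))
  expect_equal(r$filter_status[match(x, r$seq)], "pass")
})

test_that("planted matures all pass filtering in a clean simulation", {
  fl <- get_small_filtered()
  idx <- match(fl$sim$loci$mature, fl$reads$seq)
  expect_true(all(!is.na(idx)))
  expect_true(all(fl$reads$filter_status[idx] == "pass"))
})

test_that("replicate means average TPM within each tissue", {
  tpm <- matrix(c(2, 4, 6, 8), 1, 4,
                dimnames = list(NULL, paste0("l", 1:4)))
  li <- data.frame(library_id = paste0("l", 1:4),
                   tissue = c("a", "a", "b", "b"))
  m <- tissue_mean_tpm(tpm, li)
  expect_equal(unname(m[1, ]), c(3, 7))
})
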