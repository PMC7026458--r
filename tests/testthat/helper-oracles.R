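# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: the folding oracle enumerates every nested
# structure, the chi-square oracle evaluates Pearson's formula directly,
# and the phasing oracle enumerates position subsets.

# exhaustive maximum base-pairing over all nested structures
brute_max_pairs <- function(seq) {
  v <- strsplit(gsub("U", "T", toupper(seq)), "")[[1]]
  can <- function(a, b) paste0(a, b) %in% c("AT", "TA", "GC", "CG",
                                            "GT", "TG")
  rec <- function(idx) {
    if (length(idx) < 2) return(0)
    i <- idx[1]
    rest <- idx[-1]
    best <- rec(rest)                       # i unpaired
    for (j in rest) {
      if (j - i > 3 && can(v[i], v[j])) {
        inside <- rest[rest < j]
        outside <- rest[rest > j]
        best <- max(best, 1 + rec(inside) + rec(outside))
      }
    }
    best
  }
  rec(seq_along(v))
}

# direct Pearson statistic on a 2x2 table
brute_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# exhaustive hypergeometric tail: draw `occupied` of `n` positions, count
# outcomes with at least `phased` of them on the register
brute_phasing_p <- function(n, slots, occupied, phased) {
  on_reg <- seq_len(slots)
  combs <- utils::combn(n, occupied)
  hits <- apply(combs, 2, function(s) sum(s %in% on_reg) >= phased)
  mean(hits)
}

# minimal aligned-reads object for scan-level tests: reads of width
# `cycle` with given plus-strand starts (1-based)
fake_phase_reads <- function(chrom, starts, cycle, strand = "+") {
  n <- length(starts)
  structure(list(
    seq = vapply(seq_len(n), function(i)
      paste(rep("A", cycle), collapse = ""), character(1)),
    counts = matrix(1L, n, 1, dimnames = list(NULL, "lib1")),
    alignments = data.frame(read = seq_len(n), chrom = chrom,
                            start = starts, strand = strand,
                            mismatches = 0L, stringsAsFactors = FALSE)),
    class = "srna_reads")
}
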