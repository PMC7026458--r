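#' Merge aligned reads into strand-specific candidate precursor windows
#'
#' Alignments of filter-passing reads are merged per chromosome and
#' strand when separated by at most \code{gap} nt, then extended by
#' \code{flank} nt on both sides and clipped to the chromosome. Windows
#' longer than \code{max_len} after extension (too long for a plausible
#' precursor) are discarded and tallied, as are windows too short to
#' fold.
#'
#' @param reads A filtered \code{srna_reads} object (pass only; use
#'   \code{\link{passing_reads}}).
#' @param genome_lengths Named integer vector of chromosome lengths.
#' @param gap Maximum merge gap between alignments (default 200 nt).
#' @param flank Extension on both sides (default 20 nt).
#' @param max_len Maximum window length (default 300 nt).
#' @param min_len Minimum window length (default 50 nt, the folding
#'   minimum).
#' @return List with \code{windows} (data.frame chrom / start / end /
#'   strand, 1-based inclusive) and \code{discarded} (tally of length-
#'   rejected clusters).
#' @export
cluster_candidates <- function(reads, genome_lengths, gap = 200,
                               flank = 20, max_len = 300, min_len = 50) {
  aln <- reads$alignments
  if (is.null(aln) || nrow(aln) == 0)
    return(list(windows = data.frame(chrom = character(),
                                     start = integer(), end = integer(),
                                     strand = character()),
                discarded = 0L))
  len <- nchar(reads$seq)[aln$read]
  gr <- GenomicRanges::GRanges(aln$chrom,
                               IRanges::IRanges(aln$start,
                                                aln$start + len - 1),
                               strand = aln$strand)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = gap + 1L)
  st <- pmax(1L, GenomicRanges::start(merged) - flank)
  en <- GenomicRanges::end(merged) + flank
  chrom <- as.character(GenomicRanges::seqnames(merged))
  en <- pmin(en, genome_lengths[chrom])
  w <- en - st + 1
  keep <- w <= max_len & w >= min_len
  list(windows = data.frame(chrom = chrom[keep], start = st[keep],
                            end = as.integer(en[keep]),
                            strand = as.character(
                              GenomicRanges::strand(merged))[keep],
                            stringsAsFactors = FALSE),
       discarded = sum(!keep))
}

# alignments of reads overlapping a window, with precursor coordinates
# for the sense-strand placements (position 1 = precursor 5' end)
.window_alignments <- function(reads, window) {
  aln <- reads$alignments
  len <- nchar(reads$seq)[aln$read]
  ov <- aln$chrom == window$chrom & aln$start <= window$end &
    (aln$start + len - 1) >= window$start
  aln <- aln[ov, , drop = FALSE]
  len <- len[ov]
  sense <- aln$strand == window$strand
  p5 <- ifelse(rep(window$strand == "+", nrow(aln)),
               aln$start - window$start + 1L,
               window$end - (aln$start + len - 1L) + 1L)
  data.frame(read = aln$read, sense = sense, p5 = p5, len = len,
             mismatches = aln$mismatches)
}

#' Strand bias of a candidate window
#'
#' Sense-strand read count divided by the total read count over both
#' strands, using raw counts pooled across libraries. Each distinct read
#' contributes once per strand on which it aligns in the window.
#'
#' @param reads A filtered \code{srna_reads} object.
#' @param window One-row window data.frame (chrom, start, end, strand).
#' @return Proportion in [0, 1]; NA for an empty window.
#' @export
strand_bias <- function(reads, window) {
  wa <- .window_alignments(reads, window)
  if (nrow(wa) == 0) return(NA_real_)
  tot <- rowSums(reads$counts)
  sense <- sum(tot[unique(wa$read[wa$sense])])
  anti <- sum(tot[unique(wa$read[!wa$sense])])
  if (sense + anti == 0) return(NA_real_)
  sense / (sense + anti)
}

#' Select the canonical mature and star of a window
#'
#' The most abundant sense read lying fully inside the window is the
#' canonical mature (ties: 5'-most read wins). The expected star
#' interval is derived from the folded structure with the 2-nt 3'
#' overhang convention; the most abundant sense read whose 5' start falls
#' within +/- \code{tol} of the expected star start is the observed star.
#' With no observed star read, the star is the structure-derived interval.
#'
#' @param reads A filtered \code{srna_reads} object.
#' @param window One-row window data.frame.
#' @param partner Pairing vector of the folded window sequence.
#' @param tol Star positioning tolerance (default 1 nt).
#' @return List with mature (read index, p5, len, seq), star (p5, len,
#'   seq or NA, observed flag), or NULL when the window has no usable
#'   sense read or the mature does not pair.
#' @export
select_canonical <- function(reads, window, partner, tol = 1) {
  wa <- .window_alignments(reads, window)
  wlen <- window$end - window$start + 1
  inside <- wa$sense & wa$p5 >= 1 & (wa$p5 + wa$len - 1) <= wlen
  wa <- wa[inside, , drop = FALSE]
  if (nrow(wa) == 0) return(NULL)
  tot <- rowSums(reads$counts)[wa$read]
  ord <- order(-tot, wa$p5)
  m <- wa[ord[1], ]
  mature_ivl <- c(m$p5, m$p5 + m$len - 1)
  exp_star <- star_from_structure(partner, mature_ivl, wlen)
  if (is.null(exp_star)) return(NULL)
  if (exp_star[1] <= mature_ivl[2] && mature_ivl[1] <= exp_star[2])
    return(NULL) # arms overlap: not a workable hairpin
  cand <- wa[abs(wa$p5 - exp_star[1]) <= tol &
               !(wa$p5 <= mature_ivl[2] &
                   (wa$p5 + wa$len - 1) >= mature_ivl[1]), , drop = FALSE]
  if (nrow(cand) > 0) {
    stot <- rowSums(reads$counts)[cand$read]
    s <- cand[order(-stot, cand$p5)[1], ]
    star <- list(p5 = s$p5, len = s$len, read = s$read, observed = TRUE)
  } else {
    star <- list(p5 = exp_star[1], len = exp_star[2] - exp_star[1] + 1,
                 read = NA_integer_, observed = FALSE)
  }
  list(mature = list(read = m$read, p5 = m$p5, len = m$len),
       star = star)
}

#' Abundance bias of a candidate window
#'
#' The fraction of sense-strand read counts attributable to the mature,
#' the star, or their isomiRs. Attribution uses the isomiR classifier
#' against both the mature and the star template.
#'
#' @param reads A filtered \code{srna_reads} object.
#' @param window One-row window data.frame.
#' @param precursor Window sequence (sense orientation).
#' @param sel Result of \code{\link{select_canonical}}.
#' @return Proportion in [0, 1]; NA when the window has no sense counts.
#' @export
abundance_bias <- function(reads, window, precursor, sel) {
  wa <- .window_alignments(reads, window)
  wa <- wa[wa$sense, , drop = FALSE]
  if (nrow(wa) == 0) return(NA_real_)
  tot <- rowSums(reads$counts)
  wa <- wa[!duplicated(wa$read), , drop = FALSE]
  sense_total <- sum(tot[wa$read])
  if (sense_total == 0) return(NA_real_)
  anchors <- list(c(sel$mature$p5, sel$mature$len))
  if (sel$star$observed) anchors <- c(anchors, list(c(sel$star$p5,
                                                      sel$star$len)))
  attributed <- vapply(seq_len(nrow(wa)), function(i) {
    rseq <- reads$seq[wa$read[i]]
    for (a in anchors) {
      canon <- substr(precursor, a[1], a[1] + a[2] - 1)
      f5 <- substr(precursor, max(1, a[1] - 6), a[1] - 1)
      f3 <- substr(precursor, a[1] + a[2],
                   min(nchar(precursor), a[1] + a[2] + 5))
      cl <- classify_isomir(rseq, canon, f5, f3,
                            offset5 = a[1] - wa$p5[i])
      if (cl$attributable) return(TRUE)
    }
    FALSE
  }, logical(1))
  sum(tot[wa$read[attributed]]) / sense_total
}

#' Classify a locus as previously annotated or novel
#'
#' Known iff the mature matches a reference mature with at most
#' \code{max_mm} substitutions (length differences count one mismatch per
#' overhanging base).
#'
#' @param mature Mature sequence.
#' @param reference Character vector (or DNAStringSet) of reference
#'   mature sequences; empty or NULL means every locus is novel.
#' @param max_mm Mismatch threshold (default 2, the conservation
#'   definition).
#' @return "known" or "novel".
#' @export
classify_known_novel <- function(mature, reference, max_mm = 2) {
  if (is.null(reference) || length(reference) == 0) return("novel")
  if (is(reference, "DNAStringSet")) reference <- as.character(reference)
  mature <- .as_dna(mature)
  d <- vapply(.as_dna(reference), function(r) .slide_dist(mature, r),
              numeric(1))
  if (min(d) <= max_mm) "known" else "novel"
}

#' Discover miRNA loci from filtered, aligned reads
#'
#' Runs the full gate cascade over candidate windows: strand bias >=
#' \code{min_strand_bias}, precursor folding, mature/star selection,
#' duplex gates (mismatches <= 5, asymmetric bulges <= 3), abundance
#' bias >= \code{min_abundance_bias}, and known/novel annotation.
#' Every accepted locus satisfies all gates.
#'
#' @param reads A filtered \code{srna_reads} object (only passing reads
#'   are used).
#' @param genome Named character vector or DNAStringSet.
#' @param reference Reference mature sequences for the known/novel split.
#' @param min_strand_bias,min_abundance_bias,max_precursor,max_duplex_mm,
#'   max_bulges Gate thresholds.
#' @param gap,flank Clustering parameters.
#' @return data.frame of accepted loci: locus id, interval, strand,
#'   mature/star sequences and precursor coordinates, arm, gate values,
#'   structure, status.
#' @export
discover_mirna <- function(reads, genome, reference = NULL,
                           min_strand_bias = 0.9,
                           min_abundance_bias = 0.75,
                           max_precursor = 300, max_duplex_mm = 5,
                           max_bulges = 3, gap = 200, flank = 20) {
  if (is(genome, "DNAStringSet")) genome <- as.character(genome)
  genome <- .as_dna(genome)
  pass <- if (!is.null(reads$filter_status)) passing_reads(reads) else reads
  cl <- cluster_candidates(pass, setNames(nchar(genome), names(genome)),
                           gap = gap, flank = flank,
                           max_len = max_precursor)
  loci <- list()
  for (i in seq_len(nrow(cl$windows))) {
    win <- cl$windows[i, ]
    sb <- strand_bias(pass, win)
    if (is.na(sb) || sb < min_strand_bias) next
    wseq <- substr(genome[[win$chrom]], win$start, win$end)
    if (win$strand == "-") wseq <- .revcomp(wseq)
    fold <- fold_hairpin(wseq)
    sel <- select_canonical(pass, win, fold$partner)
    if (is.null(sel)) next
    mat_ivl <- c(sel$mature$p5, sel$mature$p5 + sel$mature$len - 1)
    star_ivl <- c(sel$star$p5, sel$star$p5 + sel$star$len - 1)
    dup <- tryCatch(
      evaluate_duplex(fold$partner, mat_ivl, star_ivl,
                      max_mismatch = max_duplex_mm,
                      max_bulge = max_bulges),
      error = function(e) list(pass = FALSE, mismatches = NA, bulges = NA))
    if (!dup$pass) next
    ab <- abundance_bias(pass, win, wseq, sel)
    if (is.na(ab) || ab < min_abundance_bias) next
    mature_seq <- pass$seq[sel$mature$read]
    star_seq <- if (sel$star$observed) pass$seq[sel$star$read] else
      substr(wseq, star_ivl[1], star_ivl[2])
    loci[[length(loci) + 1]] <- data.frame(
      chrom = win$chrom, start = win$start, end = win$end,
      strand = win$strand,
      mature = mature_seq, star = star_seq,
      mature_p5 = sel$mature$p5, mature_len = sel$mature$len,
      star_p5 = sel$star$p5, star_len = sel$star$len,
      star_observed = sel$star$observed,
      arm = if (mean(mat_ivl) < mean(star_ivl)) "5p" else "3p",
      strand_bias = sb, abundance_bias = ab,
      duplex_mismatches = dup$mismatches, bulges = dup$bulges,
      structure = fold$structure,
      status = classify_known_novel(mature_seq, reference),
      stringsAsFactors = FALSE)
  }
  out <- if (length(loci) > 0) do.call(rbind, loci) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), mature = character(),
               star = character(), stringsAsFactors = FALSE)
  if (nrow(out) > 0)
    out <- cbind(locus = paste0("mir_", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}
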