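#' Hypergeometric phasing p-value
#'
#' Probability of observing at least \code{phased} of \code{occupied}
#' distinct sRNA start positions on the cycle register, when positions
#' are drawn uniformly without replacement from \code{n_positions}
#' window slots of which \code{phase_slots} lie on the register:
#' \deqn{p = \sum_{i=phased}^{\min(occupied, slots)}
#'   \frac{\binom{slots}{i}\binom{n-slots}{occupied-i}}{\binom{n}{occupied}}}
#'
#' @param n_positions Total candidate 5' positions in the window.
#' @param phase_slots Register positions among them.
#' @param occupied Distinct observed 5' positions.
#' @param phased Observed positions on the register.
#' @return Upper-tail probability.
#' @export
phasing_pvalue <- function(n_positions, phase_slots, occupied, phased) {
  if (phased > occupied || occupied > n_positions ||
      phase_slots > n_positions || phased > phase_slots ||
      any(c(n_positions, phase_slots, occupied, phased) < 0))
    stop("inconsistent phasing counts")
  phyper(phased - 1, phase_slots, n_positions - phase_slots, occupied,
         lower.tail = FALSE)
}

# adjusted 5' positions of cycle-length reads: sense reads at their
# leftmost coordinate, antisense reads shifted +2 (Dicer duplex overhang)
.phase_positions <- function(reads, cycle) {
  aln <- reads$alignments
  len <- nchar(reads$seq)[aln$read]
  sel <- len == cycle
  aln <- aln[sel, , drop = FALSE]
  pos <- ifelse(aln$strand == "+", aln$start, aln$start + 2L)
  unique(data.frame(chrom = aln$chrom, pos = pos,
                    stringsAsFactors = FALSE))
}

#' Scan for phased windows of a given cycle length
#'
#' Slides a window of \code{window_cycles} cycles anchored at each
#' distinct (register-adjusted) 5' position of cycle-length reads. Per
#' window, distinct 5' positions are tallied as occupied and those on
#' the anchor register as phased; windows with fewer than
#' \code{min_depth} phased positions are dropped. Because the anchor is
#' an occupied register position by construction, the reported p-value
#' is anchor-conditioned: the hypergeometric tail is taken over the
#' remaining positions and slots, which keeps the null well calibrated
#' when many anchors are scanned.
#'
#' @param reads A filtered \code{srna_reads} object (passing reads).
#' @param cycle Phasing cycle length (21 or 24 nt).
#' @param window_cycles Window size in cycles (default 10).
#' @param min_depth Minimum distinct phased positions (default 3).
#' @return data.frame of candidate windows with chrom, start, end,
#'   n_positions, phase_slots, occupied, phased, p_value.
#' @export
scan_phase_windows <- function(reads, cycle, window_cycles = 10,
                               min_depth = 3) {
  pos <- .phase_positions(reads, cycle)
  out <- list()
  wlen <- window_cycles * cycle
  for (chr in unique(pos$chrom)) {
    p <- sort(pos$pos[pos$chrom == chr])
    for (anchor in p) {
      inwin <- p[p >= anchor & p < anchor + wlen]
      phased <- sum((inwin - anchor) %% cycle == 0)
      if (phased < min_depth) next
      out[[length(out) + 1]] <- data.frame(
        chrom = chr, start = anchor, end = anchor + wlen - 1L,
        n_positions = wlen, phase_slots = window_cycles,
        occupied = length(inwin), phased = phased,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_positions = integer(),
                      phase_slots = integer(), occupied = integer(),
                      phased = integer(), p_value = numeric()))
  w <- do.call(rbind, out)
  # anchor conditioning: the window is anchored at an occupied register
  # position, so that position is phased by construction; the tail is
  # evaluated over the remaining positions to keep the null calibrated
  w$p_value <- mapply(phasing_pvalue, w$n_positions - 1L,
                      w$phase_slots - 1L, w$occupied - 1L,
                      w$phased - 1L)
  w
}

#' Detect PHAS loci of a given cycle length
#'
#' Accepts windows with phasing p below \code{p_max} and at least
#' \code{min_depth} phased positions, and merges overlapping accepted
#' windows into loci; a merged locus carries the minimum window p-value.
#'
#' @inheritParams scan_phase_windows
#' @param p_max Acceptance threshold on the phasing p-value (default
#'   1e-5).
#' @return data.frame of loci: locus, chrom, start, end, cycle,
#'   occupied, phased, p_value.
#' @export
detect_phas <- function(reads, cycle, window_cycles = 10, min_depth = 3,
                        p_max = 1e-5) {
  w <- scan_phase_windows(reads, cycle, window_cycles, min_depth)
  w <- w[w$p_value < p_max, , drop = FALSE]
  if (nrow(w) == 0)
    return(data.frame(locus = character(), chrom = character(),
                      start = integer(), end = integer(),
                      cycle = integer(), occupied = integer(),
                      phased = integer(), p_value = numeric()))
  gr <- GenomicRanges::GRanges(w$chrom, IRanges::IRanges(w$start, w$end))
  merged <- GenomicRanges::reduce(gr)
  hit <- GenomicRanges::findOverlaps(gr, merged)
  idx <- S4Vectors::subjectHits(hit)
  loci <- lapply(seq_along(merged), function(i) {
    rows <- w[idx == i, , drop = FALSE]
    best <- which.min(rows$p_value)
    data.frame(chrom = as.character(GenomicRanges::seqnames(merged))[i],
               start = GenomicRanges::start(merged)[i],
               end = GenomicRanges::end(merged)[i],
               cycle = cycle,
               occupied = rows$occupied[best],
               phased = max(rows$phased),
               p_value = min(rows$p_value), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, loci)
  cbind(locus = paste0("phas", cycle, "_", seq_len(nrow(out))), out)
}

#' Assign a miRNA trigger to a PHAS locus
#'
#' Scans both locus ends (+/- \code{flank_cycles} cycles) for a target
#' site complementary to a mature miRNA with at most \code{max_mispair}
#' mispairs, counting G.U pairs as half a mispair. The best-scoring
#' site wins; ties go to the 5'-most site.
#'
#' @param locus One-row PHAS locus data.frame (chrom, start, end, cycle).
#' @param genome Named character vector or DNAStringSet.
#' @param mirnas data.frame with columns \code{id} and \code{seq} of
#'   candidate trigger matures.
#' @param max_mispair Mispair budget (default 4).
#' @param flank_cycles Scan reach around each locus end, in cycles
#'   (default 2).
#' @return List with id, length, mispairs, position; or NULL when no
#'   site qualifies.
#' @export
assign_trigger <- function(locus, genome, mirnas, max_mispair = 4,
                           flank_cycles = 2) {
  if (is.null(mirnas) || nrow(mirnas) == 0) return(NULL)
  if (is(genome, "DNAStringSet")) genome <- as.character(genome)
  chrseq <- .as_dna(genome[[locus$chrom]])
  cyc <- locus$cycle
  reach <- flank_cycles * cyc
  regions <- rbind(c(locus$start - reach, locus$start + reach),
                   c(locus$end - reach, locus$end + reach))
  pair_cost <- c(AT = 0, TA = 0, GC = 0, CG = 0, GT = 0.5, TG = 0.5)
  best <- NULL
  for (k in seq_len(nrow(mirnas))) {
    mseq <- .as_dna(mirnas$seq[k])
    L <- nchar(mseq)
    mv <- strsplit(mseq, "")[[1]]
    for (r in seq_len(nrow(regions))) {
      lo <- max(1, regions[r, 1])
      hi <- min(nchar(chrseq) - L + 1, regions[r, 2])
      if (hi < lo) next
      rv <- strsplit(substr(chrseq, lo, hi + L - 1), "")[[1]]
      for (p in lo:hi) {
        sv <- rv[(p - lo + 1):(p - lo + L)]
        # miRNA 5'->3' pairs the site 3'->5'
        keys <- paste0(mv, rev(sv))
        cost <- pair_cost[keys]
        cost[is.na(cost)] <- 1
        sc <- sum(cost)
        if (sc <= max_mispair &&
            (is.null(best) || sc < best$mispairs ||
               (sc == best$mispairs && p < best$position))) {
          best <- list(id = mirnas$id[k], length = L, mispairs = sc,
                       position = p)
        }
      }
    }
  }
  best
}

#' Apply the retrotransposon / easiRNA-trigger exclusion rule
#'
#' A PHAS locus is excluded iff it overlaps a retrotransposon-class TE
#' AND its trigger is a 22-nt member of the excluded trigger set (the
#' easiRNA-associated miR170/miR171a).
#'
#' @param loci PHAS locus data.frame with trigger_id and trigger_length
#'   columns (NA when no trigger was assigned).
#' @param te GRanges of TE annotations with a \code{te_class} metadata
#'   column ("retrotransposon" marks the relevant class).
#' @param excluded_triggers Trigger ids subject to exclusion.
#' @return The loci data.frame with logical \code{excluded} and a
#'   \code{exclusion_reason} column.
#' @export
apply_exclusion <- function(loci, te,
                            excluded_triggers = c("miR170", "miR171a")) {
  if (nrow(loci) == 0) {
    loci$excluded <- logical(0)
    loci$exclusion_reason <- character(0)
    return(loci)
  }
  gr <- GenomicRanges::GRanges(loci$chrom,
                               IRanges::IRanges(loci$start, loci$end))
  retro <- te[!is.na(S4Vectors::mcols(te)$te_class) &
                S4Vectors::mcols(te)$te_class == "retrotransposon"]
  over <- GenomicRanges::countOverlaps(gr, retro) > 0
  trig <- !is.na(loci$trigger_id) &
    loci$trigger_id %in% excluded_triggers &
    !is.na(loci$trigger_length) & loci$trigger_length == 22
  loci$excluded <- over & trig
  loci$exclusion_reason <- ifelse(loci$excluded,
                                  "retrotransposon+easiRNA_trigger", "")
  loci
}

#' Conservation call for a pair of PHAS loci
#'
#' Conserved iff the two loci share a trigger and at least
#' \code{min_pairs} cross-locus phasiRNA pairs match with at most
#' \code{max_mm} substitutions.
#'
#' @param phasirna_a,phasirna_b Character vectors of phasiRNA sequences.
#' @param trigger_a,trigger_b Trigger ids (NA allowed).
#' @param max_mm Per-pair mismatch tolerance (default 2).
#' @param min_pairs Required number of similar pairs (default 2).
#' @return Logical.
#' @export
phas_conservation <- function(phasirna_a, phasirna_b, trigger_a,
                              trigger_b, max_mm = 2, min_pairs = 2) {
  if (is.na(trigger_a) || is.na(trigger_b) || trigger_a != trigger_b)
    return(FALSE)
  a <- .as_dna(phasirna_a); b <- .as_dna(phasirna_b)
  matched <- vapply(a, function(s)
    any(vapply(b, function(t) .hamming(s, t) <= max_mm, logical(1))),
    logical(1))
  sum(matched) >= min_pairs
}
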