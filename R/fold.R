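#' Fold a precursor sequence by maximum base pairing
#'
#' Computes a nested (pseudoknot-free) secondary structure maximizing the
#' number of base pairs (Watson-Crick plus G.U wobble) with a minimum
#' hairpin loop of 3 unpaired bases, by dynamic programming. The
#' traceback is deterministic: at equal pair count, pairing the opening
#' position with its smallest admissible partner is preferred.
#'
#' @param seq A single DNA/RNA string, 50-300 nt for precursor folding
#'   (shorter sequences are rejected unless \code{min_len} is lowered).
#' @param min_len Minimum length accepted (default 50).
#' @return List with \code{structure} (dot-bracket string),
#'   \code{partner} (integer vector, 1-based partner index or NA) and
#'   \code{n_pairs}.
#' @export
fold_hairpin <- function(seq, min_len = 50) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- .as_dna(seq)
  if (nchar(seq) < min_len)
    stop("sequence too short to fold (", nchar(seq), " < ", min_len, " nt)")
  partner0 <- .cpp_fold_maxpair(seq)
  partner <- ifelse(partner0 < 0, NA_integer_, partner0 + 1L)
  db <- rep(".", length(partner))
  paired <- which(!is.na(partner))
  db[paired[partner[paired] > paired]] <- "("
  db[paired[partner[paired] < paired]] <- ")"
  list(structure = paste(db, collapse = ""), partner = partner,
       n_pairs = sum(!is.na(partner)) / 2)
}

# raw maximum pair count without the precursor length guard (used by tests
# and short-sequence utilities)
max_pair_count <- function(seq) {
  seq <- .as_dna(seq)
  partner <- .cpp_fold_maxpair(seq)
  sum(partner >= 0) / 2
}

#' Evaluate the mature/star duplex of a folded precursor
#'
#' Walks the duplex between consecutive paired anchors of the mature and
#' star intervals. Unpaired mature positions facing unpaired star
#' positions count as mismatches; a maximal run of unpaired bases present
#' on only one side counts as one asymmetric bulge. Terminal unpaired
#' bases outside the first/last anchor pair (the 2-nt 3' overhangs of a
#' canonical duplex) are not counted. The duplex passes when mismatches
#' <= \code{max_mismatch} (default 5) and asymmetric bulges <=
#' \code{max_bulge} (default 3).
#'
#' @param partner Integer pairing vector from \code{\link{fold_hairpin}}
#'   (1-based partner or NA).
#' @param mature_ivl,star_ivl Integer length-2 vectors, 1-based inclusive
#'   positions of mature and star on the precursor.
#' @param max_mismatch,max_bulge Gate thresholds.
#' @return List with pass, mismatches, bulges.
#' @export
evaluate_duplex <- function(partner, mature_ivl, star_ivl,
                            max_mismatch = 5, max_bulge = 3) {
  m1 <- mature_ivl[1]; m2 <- mature_ivl[2]
  s1 <- star_ivl[1]; s2 <- star_ivl[2]
  stopifnot(m1 <= m2, s1 <= s2)
  if (m1 <= s2 && s1 <= m2) stop("mature and star arms overlap")
  in_star <- function(p) !is.na(p) & p >= s1 & p <= s2
  # anchors: mature positions paired into the star interval
  mpos <- m1:m2
  anch <- mpos[in_star(partner[mpos])]
  if (length(anch) == 0)
    return(list(pass = FALSE, mismatches = m2 - m1 + 1, bulges = 0))
  mism <- 0L
  bulg <- 0L
  for (k in seq_len(length(anch) - 1)) {
    i1 <- anch[k]; i2 <- anch[k + 1]
    j1 <- partner[i1]; j2 <- partner[i2]
    gap_m <- i2 - i1 - 1L
    gap_s <- abs(j1 - j2) - 1L
    mism <- mism + min(gap_m, gap_s)
    if (gap_m != gap_s) bulg <- bulg + 1L
  }
  # unpaired mature positions interior to the anchored region but whose
  # star-side counterpart region is exhausted are already covered above;
  # positions outside the anchored span are duplex overhangs
  list(pass = mism <= max_mismatch && bulg <= max_bulge,
       mismatches = as.integer(mism), bulges = as.integer(bulg))
}

# infer the star interval from structure with the canonical 2-nt 3'
# overhang geometry: the star spans the partners of the mature's paired
# positions, extended by 2 nt at its 3' end
star_from_structure <- function(partner, mature_ivl, precursor_len) {
  # the mature's own 2-nt 3' overhang does not pair into the star
  mpos <- mature_ivl[1]:max(mature_ivl[1], mature_ivl[2] - 2)
  p <- partner[mpos]
  p <- p[!is.na(p)]
  if (length(p) < 5) return(NULL) # mature essentially unpaired
  lo <- min(p); hi <- max(p)
  # the star is a sense read of the opposite arm, so its 3' end is its
  # high coordinate regardless of arm; extend it 2 nt for the overhang
  c(lo, min(hi + 2L, precursor_len))
}
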