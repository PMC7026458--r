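#' Genomic context of loci (PCG / TE / UI)
#'
#' A locus is PCG when its precursor shares at least one base with a
#' protein-coding gene annotation; otherwise TE when it overlaps a
#' transposable element; otherwise unclassified intergenic (UI). The
#' precedence PCG > TE > UI makes the three categories a partition.
#'
#' @param loci data.frame with chrom, start, end (1-based inclusive),
#'   or a GRanges.
#' @param pcg,te GRanges of PCG and TE annotations.
#' @return Character vector of context labels.
#' @export
genomic_context <- function(loci, pcg, te) {
  gr <- if (is(loci, "GRanges")) loci else
    GenomicRanges::GRanges(loci$chrom,
                           IRanges::IRanges(loci$start, loci$end))
  ctx <- rep("UI", length(gr))
  ctx[GenomicRanges::countOverlaps(gr, te) > 0] <- "TE"
  ctx[GenomicRanges::countOverlaps(gr, pcg) > 0] <- "PCG"
  ctx
}

#' Find conserved locus pairs by mature-sequence similarity
#'
#' All locus pairs whose mature sequences match with at most
#' \code{max_mm} substitutions (sliding the shorter sequence; overhangs
#' count one mismatch each), plus, optionally, extra genomic placements
#' of each mature (<= \code{max_mm} substitutions elsewhere in the
#' genome, outside every annotated locus), which act as anonymous
#' partners for distance-based duplication calling.
#'
#' @param loci Locus data.frame with locus, chrom, start, end, mature.
#' @param genome Optional named character vector / DNAStringSet; NULL
#'   skips the genome re-alignment step.
#' @param max_mm Conservation threshold (default 2).
#' @return data.frame of pairs: locus_a, locus_b (NA for an anonymous
#'   genomic site), chrom_a, start_a, end_a, chrom_b, start_b, end_b.
#' @export
find_conserved_pairs <- function(loci, genome = NULL, max_mm = 2) {
  pairs <- list()
  n <- nrow(loci)
  mat <- .as_dna(loci$mature)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (.slide_dist(mat[i], mat[j]) <= max_mm) {
        pairs[[length(pairs) + 1]] <- data.frame(
          locus_a = loci$locus[i], locus_b = loci$locus[j],
          chrom_a = loci$chrom[i], start_a = loci$start[i],
          end_a = loci$end[i], chrom_b = loci$chrom[j],
          start_b = loci$start[j], end_b = loci$end[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!is.null(genome)) {
    if (is(genome, "DNAStringSet")) genome <- as.character(genome)
    genome <- .as_dna(genome)
    lgr <- GenomicRanges::GRanges(loci$chrom,
                                  IRanges::IRanges(loci$start, loci$end))
    for (i in seq_len(n)) {
      pat <- Biostrings::DNAString(mat[i])
      for (chr in names(genome)) {
        subj <- Biostrings::DNAString(genome[[chr]])
        hits <- c(Biostrings::matchPattern(pat, subj,
                                           max.mismatch = max_mm),
                  Biostrings::matchPattern(
                    Biostrings::reverseComplement(pat), subj,
                    max.mismatch = max_mm))
        if (length(hits) == 0) next
        hgr <- GenomicRanges::GRanges(chr,
                                      IRanges::IRanges(
                                        Biostrings::start(hits),
                                        Biostrings::end(hits)))
        # hits may fall on chromosomes hosting no annotated locus
        outside <- suppressWarnings(
          GenomicRanges::countOverlaps(hgr, lgr) == 0)
        for (h in which(outside)) {
          pairs[[length(pairs) + 1]] <- data.frame(
            locus_a = loci$locus[i], locus_b = NA_character_,
            chrom_a = loci$chrom[i], start_a = loci$start[i],
            end_a = loci$end[i], chrom_b = chr,
            start_b = GenomicRanges::start(hgr)[h],
            end_b = GenomicRanges::end(hgr)[h],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(pairs) == 0)
    return(data.frame(locus_a = character(), locus_b = character(),
                      chrom_a = character(), start_a = integer(),
                      end_a = integer(), chrom_b = character(),
                      start_b = integer(), end_b = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, pairs)
}

#' Read a synteny block file
#'
#' Tab-separated, 1-based inclusive columns: chrom_a, start_a, end_a,
#' chrom_b, start_b, end_b, block_id.
#'
#' @param path File path.
#' @return data.frame of blocks.
#' @export
read_synteny_blocks <- function(path) {
  cols <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b",
            "end_b", "block_id")
  b <- tryCatch(
    read.table(path, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE),
    error = function(e) stop("malformed synteny file: ", conditionMessage(e)))
  if (!all(cols %in% names(b)))
    stop("synteny file must have columns: ", paste(cols, collapse = ", "))
  bad <- which(b$start_a > b$end_a | b$start_b > b$end_b)
  if (length(bad) > 0)
    stop("malformed synteny block at line ", bad[1] + 1,
         ": degenerate interval")
  b
}

# does the pair of points (as intervals) fall in the two intervals of one
# block (either orientation)?
.in_block <- function(pair, blocks) {
  inside <- function(chrom, s, e, bc, bs, be)
    chrom == bc & s >= bs & e <= be
  any(
    (inside(pair$chrom_a, pair$start_a, pair$end_a, blocks$chrom_a,
            blocks$start_a, blocks$end_a) &
       inside(pair$chrom_b, pair$start_b, pair$end_b, blocks$chrom_b,
              blocks$start_b, blocks$end_b)) |
      (inside(pair$chrom_a, pair$start_a, pair$end_a, blocks$chrom_b,
              blocks$start_b, blocks$end_b) &
         inside(pair$chrom_b, pair$start_b, pair$end_b, blocks$chrom_a,
                blocks$start_a, blocks$end_a)))
}

#' Classify loci as singletons, tandem or syntenic duplicates
#'
#' A conserved pair is tandem when both loci lie on one chromosome with
#' an inter-locus gap (nearest precursor ends) under \code{tandem_max}
#' bases; syntenic when the two loci fall in the paired intervals of one
#' synteny block. A locus in any qualifying pair is a duplicate
#' (mechanism tandem if any tandem pair exists, else syntenic); all
#' other loci are singletons.
#'
#' @param loci Locus data.frame (locus, chrom, start, end, mature).
#' @param pairs Output of \code{\link{find_conserved_pairs}}.
#' @param blocks Synteny blocks (data.frame as from
#'   \code{\link{read_synteny_blocks}}), or NULL.
#' @param tandem_max Tandem distance threshold (default 200000).
#' @return data.frame: locus, status (singleton/duplicate), mechanism
#'   (tandem/syntenic/none), partners (comma-separated ids), distance
#'   (smallest qualifying gap, NA otherwise).
#' @export
classify_duplication <- function(loci, pairs, blocks = NULL,
                                 tandem_max = 200000) {
  n <- nrow(loci)
  mech <- setNames(rep("none", n), loci$locus)
  partners <- setNames(vector("list", n), loci$locus)
  dist <- setNames(rep(NA_real_, n), loci$locus)
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      pr <- pairs[k, ]
      gap <- if (pr$chrom_a == pr$chrom_b)
        max(0, max(pr$start_a, pr$start_b) -
              min(pr$end_a, pr$end_b) - 1) else Inf
      tandem <- is.finite(gap) && gap < tandem_max
      syntenic <- !is.null(blocks) && nrow(blocks) > 0 && .in_block(pr, blocks)
      if (!tandem && !syntenic) next
      members <- c(pr$locus_a, pr$locus_b)
      for (m in members[!is.na(members)]) {
        other <- setdiff(members, m)
        partners[[m]] <- union(partners[[m]],
                               if (length(other) && !is.na(other)) other
                               else "genomic_site")
        if (tandem) {
          mech[m] <- "tandem"
          dist[m] <- min(dist[m], gap, na.rm = TRUE)
        } else if (mech[m] == "none") {
          mech[m] <- "syntenic"
        }
      }
    }
  }
  data.frame(locus = loci$locus,
             status = ifelse(mech == "none", "singleton", "duplicate"),
             mechanism = unname(mech),
             partners = vapply(partners, function(p)
               paste(p, collapse = ","), character(1)),
             distance = unname(dist), stringsAsFactors = FALSE)
}

#' Chi-square ratio test of singleton/duplicate counts
#'
#' Pearson chi-square on the 2x2 table of a category's
#' singleton/duplicate counts against reference (genome-wide) counts,
#' without continuity correction (df = 1). The singleton-to-duplicate
#' ratio is reported to two decimals.
#'
#' @param category_singletons,category_duplicates Category counts.
#' @param reference_singletons,reference_duplicates Reference counts.
#' @param label Category label carried into the output.
#' @return One-row data.frame: category, singletons, duplicates, ratio,
#'   chi2, p_value.
#' @export
ratio_chisq <- function(category_singletons, category_duplicates,
                        reference_singletons, reference_duplicates,
                        label = "category") {
  counts <- c(category_singletons, category_duplicates,
              reference_singletons, reference_duplicates)
  if (any(counts < 0)) stop("counts must be nonnegative")
  tab <- rbind(c(category_singletons, category_duplicates),
               c(reference_singletons, reference_duplicates))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin: chi-square expected counts undefined")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("zero expected cell")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  data.frame(category = label,
             singletons = category_singletons,
             duplicates = category_duplicates,
             ratio = round(category_singletons / category_duplicates, 2),
             chi2 = unname(ct$statistic),
             p_value = ct$p.value, stringsAsFactors = FALSE)
}
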