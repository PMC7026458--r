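#' Collapse raw small-RNA reads into a distinct-sequence table
#'
#' One record per distinct sequence with a per-library count matrix.
#' T and U are unified (internal representation is DNA); sequences
#' containing N are dropped and tallied.
#'
#' @param libraries Named list, one element per library: either a
#'   character vector of raw read sequences or a data.frame with columns
#'   \code{sequence} and \code{count} (an already-collapsed library).
#' @return An object of class \code{srna_reads}: a list with \code{seq}
#'   (distinct sequences), \code{counts} (integer matrix, reads x
#'   libraries) and \code{dropped_n} (number of distinct N-containing
#'   sequences removed).
#' @export
collapse_reads <- function(libraries) {
  stopifnot(is.list(libraries), length(libraries) > 0)
  lib_ids <- names(libraries)
  if (is.null(lib_ids)) lib_ids <- paste0("lib", seq_along(libraries))
  tabs <- lapply(libraries, function(x) {
    if (is.data.frame(x)) {
      stopifnot(all(c("sequence", "count") %in% names(x)))
      data.frame(sequence = .as_dna(x$sequence),
                 count = as.integer(x$count), stringsAsFactors = FALSE)
    } else {
      if (length(x) == 0)
        return(data.frame(sequence = character(), count = integer()))
      t <- table(.as_dna(x))
      data.frame(sequence = names(t), count = as.integer(t),
                 stringsAsFactors = FALSE)
    }
  })
  all_seq <- unique(unlist(lapply(tabs, `[[`, "sequence")))
  if (length(all_seq) == 0) {
    warning("no reads supplied; returning empty table")
    return(structure(list(seq = character(),
                          counts = matrix(0L, 0, length(lib_ids),
                                          dimnames = list(NULL, lib_ids)),
                          dropped_n = 0L), class = "srna_reads"))
  }
  has_n <- grepl("N", all_seq, fixed = TRUE)
  dropped <- sum(has_n)
  all_seq <- sort(all_seq[!has_n])
  counts <- matrix(0L, length(all_seq), length(lib_ids),
                   dimnames = list(NULL, lib_ids))
  for (j in seq_along(tabs)) {
    idx <- match(tabs[[j]]$sequence, all_seq)
    keep <- !is.na(idx)
    counts[idx[keep], j] <- counts[idx[keep], j] + tabs[[j]]$count[keep]
  }
  structure(list(seq = all_seq, counts = counts, dropped_n = dropped),
            class = "srna_reads")
}

#' @export
print.srna_reads <- function(x, ...) {
  cat("srna_reads:", length(x$seq), "distinct sequences,",
      ncol(x$counts), "libraries\n")
  if (!is.null(x$filter_status))
    print(table(x$filter_status))
  invisible(x)
}

#' Align collapsed reads to a genome with at most one substitution
#'
#' Every genomic placement on either strand with <= 1 substitution (no
#' indels) is recorded; reads with no placement are marked unaligned.
#'
#' @param reads An \code{srna_reads} object.
#' @param genome Named character vector or \code{Biostrings::DNAStringSet}
#'   of chromosome sequences.
#' @return The \code{srna_reads} object with \code{alignments} (a
#'   data.frame read / chrom / start / strand / mismatches; 1-based
#'   start) and \code{n_hits} added.
#' @export
align_reads <- function(reads, genome) {
  stopifnot(inherits(reads, "srna_reads"))
  if (is(genome, "DNAStringSet")) genome <- as.character(genome)
  if (is.null(names(genome))) stop("genome sequences must be named")
  aln <- .cpp_align_mm1(reads$seq, names(genome), unname(.as_dna(genome)))
  reads$alignments <- aln
  reads$n_hits <- tabulate(aln$read, nbins = length(reads$seq))
  reads
}

#' TPM-normalize a read table
#'
#' Per-library TPM is count x 1e6 / mapped-read total. By default the
#' mapped total counts aligned reads inside the retained size range only,
#' so length-outlier junk does not deflate the scale of real small RNAs;
#' set \code{denominator = "aligned"} to count every aligned read.
#'
#' @param reads An aligned \code{srna_reads} object.
#' @param min_len,max_len Retained size range used by the default
#'   denominator (18-26 nt).
#' @param denominator "size_aligned" (default) or "aligned".
#' @return The object with \code{tpm} (matrix), \code{total_tpm},
#'   \code{mapped_totals} added. Libraries with zero mapped reads get NA
#'   TPM and a warning.
#' @export
tpm_normalize <- function(reads, min_len = 18, max_len = 26,
                          denominator = c("size_aligned", "aligned")) {
  stopifnot(inherits(reads, "srna_reads"), !is.null(reads$n_hits))
  denominator <- match.arg(denominator)
  w <- nchar(reads$seq)
  use <- reads$n_hits > 0
  if (denominator == "size_aligned") use <- use & w >= min_len & w <= max_len
  totals <- colSums(reads$counts[use, , drop = FALSE])
  if (any(totals == 0))
    warning("libraries with zero mapped reads excluded from TPM: ",
            paste(names(totals)[totals == 0], collapse = ", "))
  scale <- ifelse(totals > 0, 1e6 / totals, NA_real_)
  reads$tpm <- sweep(reads$counts, 2, scale, `*`)
  reads$total_tpm <- rowSums(reads$tpm, na.rm = TRUE)
  reads$mapped_totals <- totals
  reads
}

#' Replicate-mean TPM per tissue
#'
#' @param reads A TPM-normalized \code{srna_reads} object (or a numeric
#'   matrix with library columns).
#' @param lib_info data.frame with columns \code{library_id} and
#'   \code{tissue}.
#' @return Matrix (reads x tissues) of replicate means.
#' @export
tissue_mean_tpm <- function(reads, lib_info) {
  tpm <- if (inherits(reads, "srna_reads")) reads$tpm else reads
  stopifnot(is.matrix(tpm), all(c("library_id", "tissue") %in%
                                  names(lib_info)))
  tissues <- unique(lib_info$tissue)
  out <- sapply(tissues, function(t) {
    libs <- lib_info$library_id[lib_info$tissue == t]
    rowMeans(tpm[, colnames(tpm) %in% libs, drop = FALSE], na.rm = TRUE)
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, tissues))
  colnames(out) <- tissues
  out
}

#' Apply the staged filtering cascade
#'
#' Statuses are assigned in a fixed order: size (outside 18-26 nt),
#' structural (<= 1-mismatch containment in a blacklist sequence),
#' unaligned (no genomic placement), low abundance, repetitive (> 20
#' genomic placements). A read is retained by the abundance stage iff
#' total TPM > \code{min_total_tpm} AND its maximum per-library TPM >
#' \code{min_lib_tpm}: both aggregate and single-library support are
#' required.
#'
#' @param reads An aligned, TPM-normalized \code{srna_reads} object.
#' @param blacklist Structural-RNA sequences (named character vector or
#'   DNAStringSet); NULL disables the structural stage.
#' @param min_len,max_len Retained length range (nt).
#' @param max_hits Maximum genomic placements before a read is called
#'   repetitive.
#' @param min_total_tpm,min_lib_tpm Abundance support thresholds.
#' @return The object with \code{filter_status} (one of pass, size,
#'   structural, unaligned, low_abundance, repetitive) and
#'   \code{attrition} (per-stage removal tally) added.
#' @export
filter_reads <- function(reads, blacklist = NULL, min_len = 18,
                         max_len = 26, max_hits = 20,
                         min_total_tpm = 100, min_lib_tpm = 10) {
  stopifnot(inherits(reads, "srna_reads"), !is.null(reads$tpm))
  n <- length(reads$seq)
  status <- rep("pass", n)
  w <- nchar(reads$seq)
  todo <- rep(TRUE, n)

  mark <- function(status, todo, bad, label) {
    hit <- todo & bad
    status[hit] <- label
    list(status = status, todo = todo & !hit, removed = sum(hit))
  }
  attr_rows <- list()

  st <- mark(status, todo, w < min_len | w > max_len, "size")
  attr_rows$size <- st$removed; status <- st$status; todo <- st$todo

  if (!is.null(blacklist) && length(blacklist) > 0) {
    if (is(blacklist, "DNAStringSet")) blacklist <- as.character(blacklist)
    bl_names <- names(blacklist)
    if (is.null(bl_names)) bl_names <- paste0("struct", seq_along(blacklist))
    idx <- which(todo)
    hits <- .cpp_align_mm1(reads$seq[idx], bl_names,
                           unname(.as_dna(blacklist)))
    is_struct <- rep(FALSE, n)
    is_struct[idx[unique(hits$read)]] <- TRUE
    st <- mark(status, todo, is_struct, "structural")
  } else {
    st <- mark(status, todo, rep(FALSE, n), "structural")
  }
  attr_rows$structural <- st$removed; status <- st$status; todo <- st$todo

  st <- mark(status, todo, reads$n_hits == 0, "unaligned")
  attr_rows$unaligned <- st$removed; status <- st$status; todo <- st$todo

  max_lib <- apply(reads$tpm, 1, function(z) suppressWarnings(
    max(z, na.rm = TRUE)))
  max_lib[!is.finite(max_lib)] <- 0
  low <- !(reads$total_tpm > min_total_tpm & max_lib > min_lib_tpm)
  st <- mark(status, todo, low, "low_abundance")
  attr_rows$low_abundance <- st$removed; status <- st$status; todo <- st$todo

  st <- mark(status, todo, reads$n_hits > max_hits, "repetitive")
  attr_rows$repetitive <- st$removed; status <- st$status; todo <- st$todo

  reads$filter_status <- status
  reads$attrition <- data.frame(
    stage = c("input", names(attr_rows), "pass"),
    removed = c(0L, unlist(attr_rows, use.names = FALSE), 0L),
    remaining = c(n, n - cumsum(unlist(attr_rows, use.names = FALSE)),
                  sum(status == "pass")),
    stringsAsFactors = FALSE)
  reads
}

#' Subset an \code{srna_reads} object to filter-passing records
#'
#' @param reads A filtered \code{srna_reads} object.
#' @return The object restricted to reads with status "pass" (alignments
#'   re-indexed).
#' @export
passing_reads <- function(reads) {
  stopifnot(!is.null(reads$filter_status))
  keep <- which(reads$filter_status == "pass")
  subset_reads(reads, keep)
}

# integer-index subset that keeps all parallel fields consistent
subset_reads <- function(reads, keep) {
  out <- reads
  out$seq <- reads$seq[keep]
  out$counts <- reads$counts[keep, , drop = FALSE]
  for (f in c("n_hits", "total_tpm", "filter_status"))
    if (!is.null(reads[[f]])) out[[f]] <- reads[[f]][keep]
  if (!is.null(reads$tpm)) out$tpm <- reads$tpm[keep, , drop = FALSE]
  if (!is.null(reads$alignments)) {
    aln <- reads$alignments[reads$alignments$read %in% keep, , drop = FALSE]
    aln$read <- match(aln$read, keep)
    rownames(aln) <- NULL
    out$alignments <- aln
  }
  out
}
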