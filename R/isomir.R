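#' Classify a read as an isomiR of a canonical mature
#'
#' Anchors the read against the canonical's genomic template (canonical
#' plus flanking sequence) and assigns one or more of seven variant
#' classes: 5' trimming, 5' addition, 3' trimming, 3' addition,
#' non-templated 3' addition, seed SNP, tail SNP. Trimming is a negative
#' end extension; addition is a positive extension matching the genomic
#' template; a 3' extension that does not match the template is a
#' non-templated addition. Internal substitutions fall in the seed class
#' when they hit canonical positions 2-8 (5'-anchored), else in the tail
#' class. Substituted bases inside a non-templated 3' extension are part
#' of that class, not extra SNPs.
#'
#' When \code{offset5} is not supplied, the placement is chosen by
#' parsimony: minimal internal substitutions, ties broken toward smaller
#' end offsets (end-offset classes are cheaper than substitutions).
#'
#' @param read Read sequence (sense strand of the locus).
#' @param canonical Canonical mature sequence.
#' @param flank5,flank3 Genomic template immediately 5' / 3' of the
#'   canonical (>= \code{max_offset} nt each for full sensitivity).
#' @param offset5 Optional known 5' extension of the read relative to the
#'   canonical (positive = read starts upstream), e.g. from a genomic
#'   alignment; bypasses the placement search.
#' @param seed Canonical positions forming the seed (default 2:8).
#' @param max_offset Maximum end offset considered (default 4 nt); larger
#'   shifts make the read a distinct sRNA, not an isomiR.
#' @param max_subs Maximum internal substitutions for an attributable
#'   read (default 2).
#' @return List with \code{classes} (character vector, empty for the
#'   canonical read), \code{canonical} flag, \code{attributable} flag,
#'   \code{offset5}, \code{offset3} (signed extensions) and
#'   \code{substitutions} (canonical-relative positions).
#' @export
classify_isomir <- function(read, canonical, flank5 = "", flank3 = "",
                            offset5 = NULL, seed = 2:8, max_offset = 4,
                            max_subs = 2) {
  read <- .as_dna(read); canonical <- .as_dna(canonical)
  flank5 <- .as_dna(flank5); flank3 <- .as_dna(flank3)
  template <- paste0(flank5, canonical, flank3)
  nf5 <- nchar(flank5)
  lc <- nchar(canonical); lr <- nchar(read)
  tv <- strsplit(template, "")[[1]]
  rv <- strsplit(read, "")[[1]]

  eval_placement <- function(ext5) {
    ext3 <- lr - lc - ext5
    rstart <- nf5 + 1 - ext5            # template position of read base 1
    tpos <- rstart:(rstart + lr - 1)
    inside <- tpos >= 1 & tpos <= length(tv)
    mism <- rep(TRUE, lr)
    mism[inside] <- rv[inside] != tv[tpos[inside]]
    ext3_region <- if (ext3 > 0) max(1, lr - ext3 + 1):lr else integer(0)
    internal <- setdiff(which(mism), ext3_region)
    list(ext5 = ext5, ext3 = ext3, n_internal = length(internal),
         internal = internal, tpos = tpos,
         nt3 = length(ext3_region) > 0 && any(mism[ext3_region]))
  }

  if (is.null(offset5)) {
    cands <- list()
    for (e5 in -max_offset:max_offset) {
      e3 <- lr - lc - e5
      if (abs(e3) > max_offset) next
      cands[[length(cands) + 1]] <- eval_placement(e5)
    }
    if (length(cands) == 0)
      return(list(classes = character(0), canonical = FALSE,
                  attributable = FALSE, offset5 = NA_integer_,
                  offset3 = NA_integer_, substitutions = integer(0)))
    cost <- vapply(cands, function(p)
      p$n_internal * 100 + abs(p$ext5) + abs(p$ext3), numeric(1))
    best <- cands[[which.min(cost)]]
  } else {
    best <- eval_placement(offset5)
  }

  attributable <- best$n_internal <= max_subs &&
    abs(best$ext5) <= max_offset && abs(best$ext3) <= max_offset
  if (!attributable)
    return(list(classes = character(0), canonical = FALSE,
                attributable = FALSE, offset5 = best$ext5,
                offset3 = best$ext3, substitutions = integer(0)))

  classes <- character(0)
  if (best$ext5 > 0) classes <- c(classes, "add5")
  if (best$ext5 < 0) classes <- c(classes, "trim5")
  if (best$ext3 > 0)
    classes <- c(classes, if (best$nt3) "ntadd3" else "add3")
  if (best$ext3 < 0) classes <- c(classes, "trim3")
  subs_cpos <- integer(0)
  if (best$n_internal > 0) {
    subs_cpos <- best$tpos[best$internal] - nf5  # canonical-relative
    classes <- c(classes,
                 unique(ifelse(subs_cpos %in% seed, "seed_snp", "tail_snp")))
  }
  is_canon <- length(classes) == 0
  list(classes = classes, canonical = is_canon, attributable = TRUE,
       offset5 = as.integer(best$ext5), offset3 = as.integer(best$ext3),
       substitutions = as.integer(subs_cpos))
}

#' Terminal-nucleotide composition of classified isomiRs
#'
#' Per class and per end, the frequency of the read's terminal
#' nucleotide, optionally abundance-weighted. Frequencies sum to 1 within
#' each class/end combination.
#'
#' @param sequences Read sequences.
#' @param classes List of class vectors (one element per read, as
#'   returned by \code{\link{classify_isomir}}).
#' @param weights Optional nonnegative weights (e.g. read counts).
#' @return data.frame with class, end (5p/3p), base (A/C/G/U), freq.
#' @export
end_composition <- function(sequences, classes, weights = NULL) {
  stopifnot(length(sequences) == length(classes))
  if (is.null(weights)) weights <- rep(1, length(sequences))
  keep <- lengths(classes) > 0
  if (!any(keep))
    return(data.frame(class = character(), end = character(),
                      base = character(), freq = numeric()))
  sequences <- .as_dna(sequences[keep])
  classes <- classes[keep]
  weights <- weights[keep]
  b5 <- substr(sequences, 1, 1)
  b3 <- substr(sequences, nchar(sequences), nchar(sequences))
  rows <- list()
  for (i in seq_along(sequences)) {
    for (cl in classes[[i]]) {
      rows[[length(rows) + 1]] <- data.frame(
        class = cl, end = c("5p", "3p"), base = c(b5[i], b3[i]),
        w = weights[i], stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(w ~ class + end + base, tab, sum)
  tot <- stats::aggregate(w ~ class + end, tab, sum)
  m <- merge(agg, tot, by = c("class", "end"),
             suffixes = c("", "_total"))
  m$freq <- m$w / m$w_total
  m$base <- gsub("T", "U", m$base)
  m[order(m$class, m$end, m$base),
    c("class", "end", "base", "freq")]
}

#' Correlation of isomiR and locus abundance within genomic contexts
#'
#' For each context class (PCG / TE / UI), sums isomiR abundance and
#' locus abundance over the loci of that context per sample, and returns
#' the Pearson correlation across samples.
#'
#' @param isomir_abund,locus_abund Numeric matrices, loci x samples.
#' @param context Character vector of per-locus context labels.
#' @return data.frame with context, r, n_samples; r is NA (with a
#'   message) when either aggregate is constant.
#' @export
isomir_context_correlation <- function(isomir_abund, locus_abund, context) {
  stopifnot(is.matrix(isomir_abund), is.matrix(locus_abund),
            all(dim(isomir_abund) == dim(locus_abund)),
            length(context) == nrow(locus_abund))
  if (ncol(locus_abund) < 3)
    stop("at least 3 samples required for correlation")
  out <- lapply(unique(context), function(cx) {
    sel <- context == cx
    x <- colSums(locus_abund[sel, , drop = FALSE])
    y <- colSums(isomir_abund[sel, , drop = FALSE])
    r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      message("constant abundance vector in context ", cx,
              "; correlation undefined")
      NA_real_
    } else cor(x, y)
    data.frame(context = cx, r = r, n_samples = ncol(locus_abund),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
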