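# reads attributable to a locus (mature/star/isomiR), by window
.attribute_reads <- function(reads, locus, genome) {
  win <- data.frame(chrom = locus$chrom, start = locus$start,
                    end = locus$end, strand = locus$strand,
                    stringsAsFactors = FALSE)
  wseq <- substr(genome[[locus$chrom]], locus$start, locus$end)
  if (locus$strand == "-") wseq <- .revcomp(wseq)
  wa <- .window_alignments(reads, win)
  wa <- wa[wa$sense & !duplicated(wa$read), , drop = FALSE]
  if (nrow(wa) == 0) return(list(reads = integer(0), classes = list()))
  anchors <- list(c(locus$mature_p5, locus$mature_len))
  if (isTRUE(locus$star_observed))
    anchors <- c(anchors, list(c(locus$star_p5, locus$star_len)))
  classes <- vector("list", nrow(wa))
  keep <- logical(nrow(wa))
  for (i in seq_len(nrow(wa))) {
    rseq <- reads$seq[wa$read[i]]
    for (k in seq_along(anchors)) {
      a <- anchors[[k]]
      canon <- substr(wseq, a[1], a[1] + a[2] - 1)
      f5 <- substr(wseq, max(1, a[1] - 6), a[1] - 1)
      f3 <- substr(wseq, a[1] + a[2], min(nchar(wseq), a[1] + a[2] + 5))
      cl <- classify_isomir(rseq, canon, f5, f3,
                            offset5 = a[1] - wa$p5[i])
      if (cl$attributable) {
        keep[i] <- TRUE
        # classes are reported relative to the mature anchor only
        classes[[i]] <- if (k == 1) cl$classes else character(0)
        break
      }
    }
  }
  list(reads = wa$read[keep], classes = classes[keep])
}

#' Per-locus expression and isomiR tables
#'
#' For every discovered locus, attributes sense reads to the mature,
#' star or an isomiR class and accumulates per-library TPM: locus
#' expression is the attributed total (mature + star + isomiRs), the
#' convention used for specificity calling and the tissue summaries.
#'
#' @param loci Output of \code{\link{discover_mirna}}.
#' @param reads A filtered, TPM-normalized \code{srna_reads} object
#'   (passing reads).
#' @param genome Named character vector or DNAStringSet.
#' @return List with \code{expression} (locus x library TPM matrix),
#'   \code{isomir_expression} (isomiR-only TPM matrix) and
#'   \code{isomirs} (read-level table: locus, sequence, classes,
#'   total count).
#' @export
quantify_loci <- function(loci, reads, genome) {
  if (is(genome, "DNAStringSet")) genome <- as.character(genome)
  genome <- .as_dna(genome)
  nlib <- ncol(reads$tpm)
  expr <- matrix(0, nrow(loci), nlib,
                 dimnames = list(loci$locus, colnames(reads$tpm)))
  iso_expr <- expr
  iso_rows <- list()
  for (i in seq_len(nrow(loci))) {
    att <- .attribute_reads(reads, loci[i, ], genome)
    if (length(att$reads) == 0) next
    expr[i, ] <- colSums(reads$tpm[att$reads, , drop = FALSE],
                         na.rm = TRUE)
    is_iso <- lengths(att$classes) > 0
    if (any(is_iso))
      iso_expr[i, ] <- colSums(reads$tpm[att$reads[is_iso], ,
                                         drop = FALSE], na.rm = TRUE)
    for (k in which(is_iso)) {
      iso_rows[[length(iso_rows) + 1]] <- data.frame(
        locus = loci$locus[i], sequence = reads$seq[att$reads[k]],
        classes = paste(att$classes[[k]], collapse = ","),
        count = sum(reads$counts[att$reads[k], ]),
        stringsAsFactors = FALSE)
    }
  }
  isomirs <- if (length(iso_rows) > 0) do.call(rbind, iso_rows) else
    data.frame(locus = character(), sequence = character(),
               classes = character(), count = integer())
  list(expression = expr, isomir_expression = iso_expr,
       isomirs = isomirs)
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes the stages in order: simulate, preprocess (collapse, align,
#' TPM, filter), discover, isomir, expression (specificity calling),
#' phas, duplication, summarize. Stage outputs are written as TSV under
#' \code{outdir} together with a provenance manifest; a rerun with an
#' identical configuration reproduces identical outputs.
#'
#' @param config A \code{\link{sim_config}}.
#' @param outdir Output directory; NULL keeps everything in memory.
#' @param stages Character vector of stages to run (simulation and
#'   preprocessing always run).
#' @return List with all stage results and the manifest.
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL,
                         stages = c("discover", "isomir", "expression",
                                    "phas", "duplication", "summarize")) {
  manifest <- list()
  note <- function(stage, status, rows = NA_integer_) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, status = status, rows = rows,
      stringsAsFactors = FALSE)
  }

  sim <- generate_libraries(generate_genome(config))
  note("simulate", "ok", length(sim$libraries))

  reads <- collapse_reads(sim$libraries)
  reads <- align_reads(reads, sim$genome)
  reads <- tpm_normalize(reads)
  reads <- filter_reads(reads, blacklist = sim$blacklist)
  pass <- passing_reads(reads)
  note("preprocess", "ok", length(pass$seq))

  ann <- sim$annotations
  pcg <- ann[S4Vectors::mcols(ann)$type == "gene"]
  te <- ann[S4Vectors::mcols(ann)$type == "transposable_element"]

  out <- list(config = config, sim = sim, reads = reads)

  loci <- NULL
  if ("discover" %in% stages) {
    loci <- discover_mirna(pass, sim$genome, reference = sim$reference)
    if (nrow(loci) > 0)
      loci$context <- genomic_context(loci, pcg, te)
    out$loci <- loci
    note("discover", "ok", nrow(loci))
  } else note("discover", "skipped")

  quant <- NULL
  if (!is.null(loci) && nrow(loci) > 0 &&
      any(c("isomir", "expression", "summarize") %in% stages)) {
    quant <- quantify_loci(loci, pass, sim$genome)
    out$quant <- quant
  }

  if ("isomir" %in% stages && !is.null(quant)) {
    cls <- strsplit(quant$isomirs$classes, ",")
    out$isomir_composition <- end_composition(
      quant$isomirs$sequence, cls, weights = quant$isomirs$count)
    tiss <- tissue_mean_tpm(quant$expression, sim$lib_info)
    tiss_iso <- tissue_mean_tpm(quant$isomir_expression, sim$lib_info)
    out$isomir_correlation <- isomir_context_correlation(
      tiss_iso, tiss, loci$context)
    note("isomir", "ok", nrow(quant$isomirs))
  } else note("isomir", "skipped")

  if ("expression" %in% stages && !is.null(quant)) {
    tiss <- tissue_mean_tpm(quant$expression, sim$lib_info)
    rownames(tiss) <- loci$locus
    out$expression <- tiss
    out$specificity <- call_tissue_specific(tiss)
    note("expression", "ok", nrow(out$specificity))
  } else note("expression", "skipped")

  if ("phas" %in% stages) {
    phas <- rbind(detect_phas(pass, 21), detect_phas(pass, 24))
    if (nrow(phas) > 0) {
      trig_set <- data.frame(id = sub("^ref_", "", names(sim$reference)),
                             seq = unname(sim$reference),
                             stringsAsFactors = FALSE)
      trig <- lapply(seq_len(nrow(phas)), function(i)
        assign_trigger(phas[i, ], sim$genome, trig_set))
      phas$trigger_id <- vapply(trig, function(t)
        if (is.null(t)) NA_character_ else t$id, character(1))
      phas$trigger_length <- vapply(trig, function(t)
        if (is.null(t)) NA_integer_ else t$length, integer(1))
      phas <- apply_exclusion(phas, te)
    }
    out$phas <- phas
    note("phas", "ok", nrow(phas))
  } else note("phas", "skipped")

  dup <- NULL
  if ("duplication" %in% stages && !is.null(loci) && nrow(loci) > 0) {
    pairs <- find_conserved_pairs(loci, genome = sim$genome)
    dup <- classify_duplication(loci, pairs, blocks = sim$synteny)
    out$duplication <- dup
    note("duplication", "ok", nrow(dup))
  } else note("duplication", "skipped")

  if ("summarize" %in% stages && !is.null(dup)) {
    out$summary <- summarize_run(loci, dup, out$expression,
                                 sim$lib_info)
    note("summarize", "ok", nrow(out$summary$by_context))
  } else note("summarize", "skipped")

  out$manifest <- do.call(rbind, manifest)
  if (!is.null(outdir)) .write_run(out, outdir)
  out
}

#' Context and tissue ratio-test summaries
#'
#' Builds the two headline summary tables of a run: per-context
#' singleton/duplicate counts with chi-square ratio tests against the
#' genome-wide counts, and per-tissue counts of expressed (replicate-
#' mean TPM >= \code{expressed_tpm}) singletons and duplicates with the
#' same test.
#'
#' @param loci Discovered loci with a \code{context} column.
#' @param dup Output of \code{\link{classify_duplication}}.
#' @param expression Locus x tissue replicate-mean TPM matrix (NULL
#'   skips the tissue table).
#' @param lib_info Library metadata (unused when expression is NULL).
#' @param expressed_tpm Expression threshold (default 1 TPM).
#' @return List with \code{by_context} and \code{by_tissue} data.frames.
#' @export
summarize_run <- function(loci, dup, expression = NULL, lib_info = NULL,
                          expressed_tpm = 1) {
  status <- dup$status[match(loci$locus, dup$locus)]
  ref_s <- sum(status == "singleton")
  ref_d <- sum(status == "duplicate")
  by_context <- do.call(rbind, lapply(
    sort(unique(loci$context)), function(cx) {
      s <- sum(status == "singleton" & loci$context == cx)
      d <- sum(status == "duplicate" & loci$context == cx)
      if (s == 0 || d == 0 || ref_d == 0)
        return(data.frame(category = cx, singletons = s, duplicates = d,
                          ratio = NA, chi2 = NA, p_value = NA))
      ratio_chisq(s, d, ref_s, ref_d, label = cx)
    }))
  by_context <- rbind(
    data.frame(category = "total", singletons = ref_s,
               duplicates = ref_d,
               ratio = round(ref_s / max(ref_d, 1), 2), chi2 = NA,
               p_value = NA), by_context)
  by_tissue <- NULL
  if (!is.null(expression)) {
    by_tissue <- do.call(rbind, lapply(
      colnames(expression), function(t) {
        expressed <- expression[, t] >= expressed_tpm
        s <- sum(expressed & status == "singleton")
        d <- sum(expressed & status == "duplicate")
        if (s == 0 || d == 0 || ref_d == 0)
          return(data.frame(category = t, singletons = s,
                            duplicates = d, ratio = NA, chi2 = NA,
                            p_value = NA))
        ratio_chisq(s, d, ref_s, ref_d, label = t)
      }))
  }
  list(by_context = by_context, by_tissue = by_tissue)
}

# write stage outputs and the provenance manifest
.write_run <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(x, f) if (!is.null(x)) write.table(
    x, file.path(outdir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wtsv(out$loci, "mirna_loci.tsv")
  wtsv(out$specificity, "specificity.tsv")
  wtsv(out$phas, "phas_loci.tsv")
  wtsv(out$duplication, "duplication.tsv")
  wtsv(out$reads$attrition, "attrition.tsv")
  if (!is.null(out$summary)) {
    wtsv(out$summary$by_context, "summary_by_context.tsv")
    wtsv(out$summary$by_tissue, "summary_by_tissue.tsv")
  }
  wtsv(out$manifest, "manifest.tsv")
  cfg <- out$config
  writeLines(paste0(names(cfg), "=",
                    vapply(cfg, function(v)
                      paste(format(v), collapse = ","), character(1))),
             file.path(outdir, "config.txt"))
  invisible(outdir)
}
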