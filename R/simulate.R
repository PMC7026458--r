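#' Configuration for the synthetic small-RNA study generator
#'
#' Defaults emulate a desk-scale version of a deeply sequenced 14-tissue
#' maize small-RNA study: 100 planted miRNA hairpin loci (20 of them
#' expressed in exactly one tissue), 10 phased loci per cycle length
#' (21 and 24 nt), 5 tandem and 5 syntenic duplicate pairs, 3 libraries
#' per tissue, and one million reads per library so that one read count
#' corresponds to about 1 TPM.
#'
#' @param seed Root seed; per-library streams are derived from it by
#'   fixed arithmetic so adding libraries does not perturb earlier ones.
#' @param n_chromosomes,chrom_length Genome shape.
#' @param n_tissues,libraries_per_tissue Study design.
#' @param n_mirna_loci Planted hairpin miRNA loci.
#' @param n_tissue_specific Loci given a one-hot tissue profile.
#' @param n_phas21,n_phas24 Phased loci per cycle length.
#' @param n_tandem_pairs,n_syntenic_pairs Duplicate pairs among the
#'   miRNA loci.
#' @param contamination_fraction Fraction of each library drawn from
#'   structural-RNA fragments and random degradation fragments.
#' @param isomir_rate Named per-class probabilities that a mature-arm
#'   draw is emitted as that isomiR class.
#' @param depth_per_library Exact total reads per library.
#' @param star_fraction Star abundance relative to the mature arm.
#' @param dirichlet_conc Concentration of the symmetric Dirichlet for
#'   broadly expressed locus profiles.
#' @param phas_share Library fraction allocated to phased loci.
#' @param known_fraction Fraction of miRNA loci whose matures go into
#'   the reference set (the known/novel truth).
#' @param n_struct_species,n_frag_species Sizes of the contaminant
#'   species pools.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1, n_chromosomes = 5, chrom_length = 300000,
                       n_tissues = 14, libraries_per_tissue = 3,
                       n_mirna_loci = 100, n_tissue_specific = 20,
                       n_phas21 = 10, n_phas24 = 10, n_tandem_pairs = 5,
                       n_syntenic_pairs = 5,
                       contamination_fraction = 0.05,
                       isomir_rate = c(seed_snp = 0.05, tail_snp = 0.04,
                                       trim3 = 0.03, trim5 = 0.02,
                                       add5 = 0.02, add3 = 0.02,
                                       ntadd3 = 0.02),
                       depth_per_library = 1e6, star_fraction = 0.1,
                       dirichlet_conc = 5, phas_share = 0.08,
                       known_fraction = 0.4, n_struct_species = 400,
                       n_frag_species = 30000) {
  cfg <- list(seed = seed, n_chromosomes = n_chromosomes,
              chrom_length = chrom_length, n_tissues = n_tissues,
              libraries_per_tissue = libraries_per_tissue,
              n_mirna_loci = n_mirna_loci,
              n_tissue_specific = n_tissue_specific,
              n_phas21 = n_phas21, n_phas24 = n_phas24,
              n_tandem_pairs = n_tandem_pairs,
              n_syntenic_pairs = n_syntenic_pairs,
              contamination_fraction = contamination_fraction,
              isomir_rate = isomir_rate,
              depth_per_library = depth_per_library,
              star_fraction = star_fraction,
              dirichlet_conc = dirichlet_conc, phas_share = phas_share,
              known_fraction = known_fraction,
              n_struct_species = n_struct_species,
              n_frag_species = n_frag_species)
  counts <- c("n_chromosomes", "chrom_length", "n_tissues",
              "libraries_per_tissue", "n_mirna_loci",
              "n_tissue_specific", "n_phas21", "n_phas24",
              "n_tandem_pairs", "n_syntenic_pairs", "depth_per_library")
  for (f in counts) if (cfg[[f]] < 0) stop(f, " must be nonnegative")
  props <- c(contamination_fraction, isomir_rate, star_fraction,
             phas_share, known_fraction)
  if (any(props < 0) || any(props > 1))
    stop("proportions must lie in [0, 1]")
  if (n_tissue_specific > n_mirna_loci)
    stop("n_tissue_specific must not exceed n_mirna_loci")
  if (2 * (n_tandem_pairs + n_syntenic_pairs) > n_mirna_loci)
    stop("duplicate pairs require 2 loci each; n_mirna_loci too small")
  if (n_syntenic_pairs > 0 && n_chromosomes < 2)
    stop("syntenic pairs require at least two chromosomes")
  structure(cfg, class = "sim_config")
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

.mutate_base <- function(base) sample(setdiff(c("A", "C", "G", "T"),
                                              base), 1)

# substitute positions pos of sequence s with random different bases
.inject_mismatches <- function(s, pos) {
  v <- strsplit(s, "")[[1]]
  for (p in pos) v[p] <- .mutate_base(v[p])
  paste(v, collapse = "")
}

# build a hairpin precursor: [arm5 | loop | revcomp(arm5)] with the
# mature planted at arm positions 21..41. The arms diverge at three
# positions spread across the mature (as real precursor arms do), which
# keeps the locus strand-separable: no mature-region read of one arm
# re-aligns to the other arm within one mismatch. The divergent sites
# are G.U wobbles (arm5 forced to G/T, the arm3 partner mutated to the
# wobble base), so the duplex still pairs fully and the planted loci
# pass the duplex gates by construction. n_mut adds extra substitutions
# outside the small-RNA region.
.make_hairpin <- function(arm_len = 60, loop_len = 15, mature_len = 21,
                          mature_off = 20, n_mut = 0) {
  arm5v <- strsplit(.rand_dna(arm_len), "")[[1]]
  guard5 <- mature_off + c(5, 12, 19)           # arm5 positions
  for (p in guard5)
    if (!arm5v[p] %in% c("G", "T")) arm5v[p] <- sample(c("G", "T"), 1)
  arm5 <- paste(arm5v, collapse = "")
  loop <- .rand_dna(loop_len)
  arm3v <- strsplit(.revcomp(arm5), "")[[1]]
  guard3 <- arm_len - guard5 + 1                # paired arm3 positions
  for (k in seq_along(guard5))                  # C->T or A->G wobble
    arm3v[guard3[k]] <- if (arm5v[guard5[k]] == "G") "T" else "G"
  arm3 <- paste(arm3v, collapse = "")
  if (n_mut > 0) {
    smallrna3 <- (arm_len - (mature_off + mature_len + 5) + 1):
      (arm_len - (mature_off - 4) + 1)
    free <- setdiff(seq_len(arm_len), c(guard3, smallrna3))
    arm3 <- .inject_mismatches(arm3, sample(free, min(n_mut,
                                                      length(free))))
  }
  pre <- paste0(arm5, loop, arm3)
  m1 <- mature_off + 1
  m2 <- mature_off + mature_len
  # star per canonical Dicer geometry: pairs mature[1..len-2], 2-nt 3'
  # overhang; with a perfect stem position i pairs 2*arm_len+loop_len+1-i
  pairpos <- function(i) 2 * arm_len + loop_len + 1 - i
  s1 <- pairpos(m2 - 2)
  s2 <- pairpos(m1) + 2
  list(precursor = pre, mature_ivl = c(m1, m2), star_ivl = c(s1, s2),
       mature = substr(pre, m1, m2), star = substr(pre, s1, s2))
}

# non-overlapping placement bookkeeping: occupied is a per-chromosome
# list of intervals; placement keeps a pad of clearance on both sides
.place_element <- function(occupied, chrom_length, len, chrom = NULL,
                           range = NULL, pad = 500, tries = 2000) {
  chroms <- names(occupied)
  for (t in seq_len(tries)) {
    ch <- if (is.null(chrom)) sample(chroms, 1) else chrom
    lo <- if (is.null(range)) 1 + pad else max(1 + pad, range[1])
    hi <- if (is.null(range)) chrom_length[ch] - len - pad else
      min(chrom_length[ch] - len - pad, range[2] - len)
    if (hi < lo) next
    start <- lo + sample.int(hi - lo + 1, 1) - 1
    iv <- c(start - pad, start + len - 1 + pad)
    occ <- occupied[[ch]]
    clash <- nrow(occ) > 0 &&
      any(occ[, 1] <= iv[2] & occ[, 2] >= iv[1])
    if (!clash) {
      occupied[[ch]] <- rbind(occ, iv)
      return(list(occupied = occupied, chrom = ch, start = start,
                  end = start + len - 1))
    }
  }
  stop("chromosome too short to host requested loci: could not place a ",
       len, "-nt element after ", tries, " attempts")
}

#' Generate the synthetic genome, annotations and ground truth
#'
#' Assembles a random genome and plants: hairpin miRNA precursors whose
#' arms are reverse-complementary apart from at most 3 injected
#' substitutions (so every planted locus passes the duplex gates by
#' construction), with tandem partners under 200 kb apart on one
#' chromosome and syntenic partners inside declared synteny-block
#' interval pairs; phased loci with a perfect register of the configured
#' cycle length and a perfectly complementary 22-nt trigger site at
#' their 5' end; structural-RNA genes backing the blacklist; and PCG/TE
#' annotation intervals realizing each locus's planted genomic context.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list (class \code{srna_sim}) with genome (named character),
#'   annotations (GRanges with type and te_class), blacklist, reference
#'   matures, truth tables (loci, phas, synteny, expression profiles)
#'   and lib_info.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  chrom_length <- setNames(rep(config$chrom_length,
                               config$n_chromosomes), chroms)
  genome <- setNames(vapply(chrom_length, .rand_dna, character(1)),
                     chroms)
  occupied <- setNames(lapply(chroms, function(x)
    matrix(numeric(0), 0, 2)), chroms)

  plant <- function(chrom, start, seqstr) {
    substr(genome[[chrom]], start, start + nchar(seqstr) - 1) <<- seqstr
  }

  n <- config$n_mirna_loci
  loci <- NULL
  synteny <- data.frame(chrom_a = character(), start_a = integer(),
                        end_a = integer(), chrom_b = character(),
                        start_b = integer(), end_b = integer(),
                        block_id = character(), stringsAsFactors = FALSE)
  if (n > 0) {
    hp <- lapply(seq_len(n), function(i)
      .make_hairpin(n_mut = sample(0:2, 1)))
    # duplicate pairs copy the partner's hairpin so matures are identical
    n_td <- config$n_tandem_pairs
    n_sy <- config$n_syntenic_pairs
    pair_second <- integer(0)
    dup_label <- rep("singleton", n)
    partner <- rep(NA_character_, n)
    idx <- 1
    pair_map <- list()
    for (k in seq_len(n_td)) {
      pair_map[[length(pair_map) + 1]] <- c(idx, idx + 1, 1)  # 1 = tandem
      idx <- idx + 2
    }
    for (k in seq_len(n_sy)) {
      pair_map[[length(pair_map) + 1]] <- c(idx, idx + 1, 2)  # 2 = syntenic
      idx <- idx + 2
    }
    for (pm in pair_map) hp[[pm[2]]] <- hp[[pm[1]]]

    rows <- vector("list", n)
    placed <- rep(FALSE, n)
    block_id <- 0
    for (pm in pair_map) {
      i <- pm[1]; j <- pm[2]
      L <- nchar(hp[[i]]$precursor)
      if (pm[3] == 1) { # tandem: same chromosome, gap < 200 kb
        gap_max <- min(150000, config$chrom_length - 60000)
        if (gap_max < 20000)
          stop("chromosome too short to host requested loci: tandem ",
               "pairs need chromosomes of at least 80 kb")
        gap <- 20000 + sample.int(gap_max - 20000 + 1, 1) - 1
        p1 <- .place_element(occupied, chrom_length, L,
                             range = c(1, config$chrom_length - gap -
                                         25000))
        occupied <- p1$occupied
        p2 <- .place_element(occupied, chrom_length, L,
                             chrom = p1$chrom,
                             range = c(p1$end + gap,
                                       p1$end + gap + 20000))
        occupied <- p2$occupied
        dup_label[c(i, j)] <- "tandem"
      } else { # syntenic: declared block pair on two chromosomes
        block_id <- block_id + 1
        cha <- sample(names(chrom_length), 1)
        chb <- sample(setdiff(names(chrom_length), cha), 1)
        block_len <- 20000
        pa <- .place_element(occupied, chrom_length, block_len,
                             chrom = cha)
        occupied <- pa$occupied
        pb <- .place_element(occupied, chrom_length, block_len,
                             chrom = chb)
        occupied <- pb$occupied
        # loci sit inside the block intervals
        off <- function() 2000 + sample.int(block_len - 4000 - L, 1) - 1
        p1 <- list(chrom = cha, start = pa$start + off())
        p1$end <- p1$start + L - 1
        p2 <- list(chrom = chb, start = pb$start + off())
        p2$end <- p2$start + L - 1
        synteny <- rbind(synteny, data.frame(
          chrom_a = cha, start_a = pa$start, end_a = pa$end,
          chrom_b = chb, start_b = pb$start, end_b = pb$end,
          block_id = paste0("block", block_id),
          stringsAsFactors = FALSE))
        dup_label[c(i, j)] <- "syntenic"
      }
      partner[i] <- paste0("locus_", j)
      partner[j] <- paste0("locus_", i)
      for (pp in list(list(k = i, p = p1), list(k = j, p = p2))) {
        plant(pp$p$chrom, pp$p$start, hp[[pp$k]]$precursor)
        rows[[pp$k]] <- data.frame(chrom = pp$p$chrom,
                                   start = pp$p$start,
                                   end = pp$p$start + L - 1,
                                   stringsAsFactors = FALSE)
        placed[pp$k] <- TRUE
      }
    }
    for (i in which(!placed)) {
      L <- nchar(hp[[i]]$precursor)
      p <- .place_element(occupied, chrom_length, L)
      occupied <- p$occupied
      plant(p$chrom, p$start, hp[[i]]$precursor)
      rows[[i]] <- data.frame(chrom = p$chrom, start = p$start,
                              end = p$end, stringsAsFactors = FALSE)
    }
    pos <- do.call(rbind, rows)
    # tissue-specific assignment: prefer non-duplicate loci so the
    # specificity and duplication axes stay independent
    singles <- which(dup_label == "singleton")
    spec_idx <- c(singles, setdiff(seq_len(n), singles))[
      seq_len(config$n_tissue_specific)]
    specific <- seq_len(n) %in% spec_idx
    target <- rep(NA_character_, n)
    tissues <- paste0("tissue", seq_len(config$n_tissues))
    target[spec_idx] <- tissues[(seq_along(spec_idx) - 1) %%
                                  config$n_tissues + 1]
    # planted genomic context: ~30/30/40 PCG/TE/UI
    ctx <- sample(rep(c("PCG", "TE", "UI"),
                      times = c(round(0.3 * n), round(0.3 * n), n)),
                  n)[seq_len(n)]
    known <- rep(FALSE, n)
    known[sample(n, round(config$known_fraction * n))] <- TRUE
    # duplicate partners share the mature, so the known flag (a property
    # of the mature sequence) must agree within a pair
    for (pm in pair_map) known[pm[2]] <- known[pm[1]]
    loci <- data.frame(
      locus = paste0("locus_", seq_len(n)), chrom = pos$chrom,
      start = pos$start, end = pos$end, strand = "+",
      mature = vapply(hp, `[[`, character(1), "mature"),
      star = vapply(hp, `[[`, character(1), "star"),
      mature_start = pos$start + vapply(hp, function(h)
        h$mature_ivl[1], numeric(1)) - 1,
      star_start = pos$start + vapply(hp, function(h)
        h$star_ivl[1], numeric(1)) - 1,
      context = ctx, specific = specific, target_tissue = target,
      known = known, dup_label = dup_label, partner = partner,
      stringsAsFactors = FALSE)
  }

  # phased loci: a perfect register of window_cycles cycles with a
  # perfectly complementary trigger site immediately upstream
  triggers <- data.frame(
    id = c("miR2118", "miR2275"), cycle = c(21, 24),
    seq = c(.rand_dna(22), .rand_dna(22)), stringsAsFactors = FALSE)
  phas <- NULL
  phas_rows <- list()
  for (cyc in c(21, 24)) {
    n_p <- if (cyc == 21) config$n_phas21 else config$n_phas24
    trig <- triggers[triggers$cycle == cyc, ]
    for (k in seq_len(n_p)) {
      L <- 10 * cyc
      p <- .place_element(occupied, chrom_length, L + 30)
      occupied <- p$occupied
      start <- p$start + 30  # room for the trigger site upstream
      plant(p$chrom, start - 22, .revcomp(trig$seq))
      phas_rows[[length(phas_rows) + 1]] <- data.frame(
        locus = paste0("true_phas", cyc, "_", k), chrom = p$chrom,
        start = start, end = start + L - 1, cycle = cyc,
        trigger_id = trig$id, trigger_len = nchar(trig$seq),
        stringsAsFactors = FALSE)
    }
  }
  if (length(phas_rows) > 0) phas <- do.call(rbind, phas_rows)

  # structural-RNA genes backing the blacklist (scaled to genome size)
  total_bp <- sum(chrom_length)
  n_bl <- max(4, min(30, total_bp %/% 50000))
  blacklist <- character(0)
  for (k in seq_len(n_bl)) {
    L <- sample(80:150, 1)
    p <- .place_element(occupied, chrom_length, L)
    occupied <- p$occupied
    s <- .rand_dna(L)
    plant(p$chrom, p$start, s)
    blacklist[paste0("structRNA_", k)] <- s
  }

  # annotations: context-realizing intervals plus unrelated background
  ann <- list()
  if (!is.null(loci)) {
    for (i in seq_len(nrow(loci))) {
      if (loci$context[i] == "PCG") {
        ann[[length(ann) + 1]] <- data.frame(
          chrom = loci$chrom[i], start = max(1, loci$start[i] - 300),
          end = loci$end[i] + 300, type = "gene",
          te_class = NA_character_, stringsAsFactors = FALSE)
      } else if (loci$context[i] == "TE") {
        ann[[length(ann) + 1]] <- data.frame(
          chrom = loci$chrom[i], start = max(1, loci$start[i] - 300),
          end = loci$end[i] + 300, type = "transposable_element",
          te_class = sample(c("dna_transposon", "retrotransposon"), 1),
          stringsAsFactors = FALSE)
      }
    }
  }
  for (k in seq_len(max(2, min(20, total_bp %/% 75000)))) {
    # background annotations away from any planted locus
    L <- sample(1000:4000, 1)
    p <- .place_element(occupied, chrom_length, L)
    occupied <- p$occupied
    ann[[length(ann) + 1]] <- data.frame(
      chrom = p$chrom, start = p$start, end = p$end,
      type = sample(c("gene", "transposable_element"), 1),
      te_class = NA_character_, stringsAsFactors = FALSE)
    if (ann[[length(ann)]]$type == "transposable_element")
      ann[[length(ann)]]$te_class <- sample(c("dna_transposon",
                                              "retrotransposon"), 1)
  }
  ann <- do.call(rbind, ann)
  annotations <- GenomicRanges::GRanges(
    ann$chrom, IRanges::IRanges(ann$start, ann$end), type = ann$type,
    te_class = ann$te_class)

  # expression profiles: one-hot for specific loci, symmetric Dirichlet
  # draws for broad loci and phased loci
  tissues <- paste0("tissue", seq_len(config$n_tissues))
  rdirichlet <- function(conc) {
    g <- rgamma(config$n_tissues, conc)
    g / sum(g)
  }
  profiles <- NULL
  if (!is.null(loci)) {
    profiles <- t(vapply(seq_len(nrow(loci)), function(i) {
      if (loci$specific[i]) {
        e <- rep(0, config$n_tissues)
        e[match(loci$target_tissue[i], tissues)] <- 1
        e
      } else rdirichlet(config$dirichlet_conc)
    }, numeric(config$n_tissues)))
    dimnames(profiles) <- list(loci$locus, tissues)
  }
  phas_profiles <- NULL
  if (!is.null(phas)) {
    phas_profiles <- t(vapply(seq_len(nrow(phas)), function(i)
      rdirichlet(config$dirichlet_conc), numeric(config$n_tissues)))
    dimnames(phas_profiles) <- list(phas$locus, tissues)
  }
  abundance <- if (!is.null(loci))
    setNames(exp(rnorm(nrow(loci), 0, 0.5)), loci$locus) else NULL
  phas_abundance <- if (!is.null(phas))
    setNames(exp(rnorm(nrow(phas), 0, 0.3)), phas$locus) else NULL

  reference <- character(0)
  if (!is.null(loci) && any(loci$known))
    reference <- setNames(loci$mature[loci$known],
                          paste0("ref_", loci$locus[loci$known]))
  reference <- c(reference, setNames(triggers$seq,
                                     paste0("ref_", triggers$id)))

  lib_info <- data.frame(
    library_id = paste0(rep(tissues, each = config$libraries_per_tissue),
                        "_rep",
                        rep(seq_len(config$libraries_per_tissue),
                            config$n_tissues)),
    tissue = rep(tissues, each = config$libraries_per_tissue),
    replicate = rep(seq_len(config$libraries_per_tissue),
                    config$n_tissues), stringsAsFactors = FALSE)

  structure(list(config = config, genome = genome,
                 chrom_length = chrom_length, annotations = annotations,
                 blacklist = blacklist, reference = reference,
                 triggers = triggers, loci = loci, phas = phas,
                 synteny = synteny, profiles = profiles,
                 phas_profiles = phas_profiles, abundance = abundance,
                 phas_abundance = phas_abundance, lib_info = lib_info),
            class = "srna_sim")
}

# isomiR species for one locus: sequence per configured class, built
# from the genomic template around the planted mature
.isomir_species <- function(sim, i) {
  loci <- sim$loci
  chrseq <- sim$genome[[loci$chrom[i]]]
  ms <- loci$mature_start[i]
  mature <- loci$mature[i]
  L <- nchar(mature)
  before <- substr(chrseq, ms - 1, ms - 1)
  after <- substr(chrseq, ms + L, ms + L)
  tmpl_pos4 <- substr(mature, 4, 4)
  tmpl_pos15 <- substr(mature, 15, 15)
  list(
    trim5 = substr(mature, 2, L),
    add5 = paste0(before, mature),
    trim3 = substr(mature, 1, L - 1),
    add3 = paste0(mature, after),
    ntadd3 = paste0(mature, .mutate_base(after)),
    seed_snp = .inject_mismatches(mature, 4),
    tail_snp = .inject_mismatches(mature, 15)
  )
}

#' Draw per-library read tables from a synthetic study
#'
#' Per tissue and replicate, reads are drawn as one multinomial of
#' exactly \code{depth_per_library} reads over the planted species:
#' canonical matures at the planted tissue profiles, stars at
#' \code{star_fraction} of the mature arm, isomiR variants at the
#' configured per-class rates, phased reads (sense plus a few antisense
#' partners at the 2-nt offset), structural-RNA fragments and random
#' degradation fragments (15-30 nt) at \code{contamination_fraction}.
#' All species are genome-templated except the non-templated 3'
#' addition isomiRs.
#'
#' @param sim Output of \code{\link{generate_genome}}.
#' @param config The same \code{\link{sim_config}} (defaults to the one
#'   stored in \code{sim}).
#' @return The sim object extended with \code{species} (truth-labelled
#'   species table), \code{weights} (species x tissue), and
#'   \code{libraries} (named list of collapsed data.frames sequence /
#'   count).
#' @export
generate_libraries <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "srna_sim"))
  set.seed(config$seed + 1L)
  tissues <- paste0("tissue", seq_len(config$n_tissues))
  rows <- list()
  wts <- list()
  add <- function(seq, kind, locus, class, w) {
    rows[[length(rows) + 1]] <<- data.frame(
      seq = seq, kind = kind, locus = locus, class = class,
      stringsAsFactors = FALSE)
    wts[[length(wts) + 1]] <<- w
  }

  r <- config$isomir_rate
  r <- r[r > 0]
  sf <- config$star_fraction
  if (!is.null(sim$loci)) {
    for (i in seq_len(nrow(sim$loci))) {
      lw <- sim$abundance[i] * sim$profiles[i, ]
      add(sim$loci$mature[i], "mature", sim$loci$locus[i], NA,
          lw * (1 - sum(r)))
      if (sf > 0)
        add(sim$loci$star[i], "star", sim$loci$locus[i], NA, lw * sf)
      if (length(r) > 0) {
        iso <- .isomir_species(sim, i)
        for (cl in names(r))
          add(iso[[cl]], "isomir", sim$loci$locus[i], cl, lw * r[[cl]])
      }
    }
  }
  n_mirna_rows <- length(rows)

  if (!is.null(sim$phas)) {
    for (i in seq_len(nrow(sim$phas))) {
      pw <- sim$phas_abundance[i] * sim$phas_profiles[i, ]
      cyc <- sim$phas$cycle[i]
      chrseq <- sim$genome[[sim$phas$chrom[i]]]
      for (k in 0:9) {
        s <- sim$phas$start[i] + k * cyc
        add(substr(chrseq, s, s + cyc - 1), "phasirna",
            sim$phas$locus[i], as.character(k), pw / 13)
      }
      for (k in c(2, 5, 8)) {
        s <- sim$phas$start[i] + k * cyc - 2
        add(.revcomp(substr(chrseq, s, s + cyc - 1)), "phas_antisense",
            sim$phas$locus[i], as.character(k), pw / 26)
      }
    }
  }

  # contaminants: fragments of the structural blacklist plus a large,
  # individually rare pool of random genome fragments (degradation)
  if (config$contamination_fraction > 0) {
    struct_w <- 0.4 * config$contamination_fraction
    frag_w <- 0.6 * config$contamination_fraction
    if (length(sim$blacklist) > 0 && config$n_struct_species > 0) {
      sw <- rgamma(config$n_struct_species, 1)
      sw <- sw / sum(sw)
      for (k in seq_len(config$n_struct_species)) {
        src <- sample(length(sim$blacklist), 1)
        bl <- sim$blacklist[[src]]
        L <- sample(18:30, 1)
        st <- sample(nchar(bl) - L + 1, 1)
        add(substr(bl, st, st + L - 1), "structural", NA, NA,
            rep(sw[k] * struct_w, config$n_tissues))
      }
    }
    if (config$n_frag_species > 0) {
      fw <- frag_w / config$n_frag_species
      chroms <- names(sim$genome)
      n_frag <- config$n_frag_species
      fr_chr <- sample(chroms, n_frag, replace = TRUE)
      fr_len <- sample(15:30, n_frag, replace = TRUE)
      fr_start <- vapply(seq_len(n_frag), function(k)
        sample(sim$chrom_length[fr_chr[k]] - fr_len[k], 1), numeric(1))
      fr_seq <- vapply(seq_len(n_frag), function(k)
        substr(sim$genome[[fr_chr[k]]], fr_start[k],
               fr_start[k] + fr_len[k] - 1), character(1))
      rows[[length(rows) + 1]] <- data.frame(
        seq = fr_seq, kind = "fragment", locus = NA, class = NA,
        stringsAsFactors = FALSE)
      wts[[length(wts) + 1]] <- matrix(fw, n_frag, config$n_tissues)
    }
  }

  species <- do.call(rbind, rows)
  W <- do.call(rbind, lapply(wts, function(w)
    if (is.matrix(w)) w else matrix(w, nrow = 1)))
  colnames(W) <- tissues

  # normalize block shares per tissue: miRNA + PHAS fill whatever the
  # contaminant fraction leaves
  contam <- species$kind %in% c("structural", "fragment")
  is_phas <- species$kind %in% c("phasirna", "phas_antisense")
  is_mir <- !contam & !is_phas
  contam_share <- if (any(contam)) config$contamination_fraction else 0
  phas_share <- if (any(is_phas)) config$phas_share else 0
  mir_share <- if (any(is_mir)) 1 - contam_share - phas_share else 0
  if (!any(is_mir)) {
    phas_share <- if (any(is_phas)) 1 - contam_share else 0
    if (!any(is_phas)) contam_share <- if (any(contam)) 1 else 0
  }
  for (t in tissues) {
    w <- W[, t]
    for (blk in list(list(sel = is_mir, share = mir_share),
                     list(sel = is_phas, share = phas_share),
                     list(sel = contam, share = contam_share))) {
      if (any(blk$sel) && sum(w[blk$sel]) > 0)
        w[blk$sel] <- w[blk$sel] / sum(w[blk$sel]) * blk$share
    }
    W[, t] <- w
  }

  libraries <- list()
  for (l in seq_len(nrow(sim$lib_info))) {
    lib <- sim$lib_info$library_id[l]
    child <- (config$seed * 48271 + 1000003 * l) %% 2147483563
    set.seed(child)
    if (config$depth_per_library == 0) {
      warning("depth_per_library is 0: library ", lib, " is empty")
      libraries[[lib]] <- data.frame(sequence = character(),
                                     count = integer())
      next
    }
    w <- W[, sim$lib_info$tissue[l]]
    if (sum(w) == 0) {
      libraries[[lib]] <- data.frame(sequence = character(),
                                     count = integer())
      next
    }
    cnt <- as.integer(rmultinom(1, config$depth_per_library, w))
    nz <- cnt > 0
    tab <- data.frame(sequence = species$seq[nz], count = cnt[nz],
                      stringsAsFactors = FALSE)
    # species sharing one sequence (duplicate-pair matures) collapse
    tab <- stats::aggregate(count ~ sequence, tab, sum)
    libraries[[lib]] <- tab[order(tab$sequence), ]
  }

  sim$species <- species
  sim$weights <- W
  sim$libraries <- libraries
  sim
}

#' Write a synthetic study to disk
#'
#' Emits genome FASTA, annotation GFF3 (1-based inclusive), blacklist
#' and reference FASTA, truth tables and synteny blocks as TSV, library
#' info, and one collapsed-read TSV per library (optionally FASTA with
#' count-encoded headers).
#'
#' @param sim Output of \code{\link{generate_libraries}}.
#' @param dir Output directory (created if needed).
#' @param fasta Also write per-library FASTA files.
#' @return \code{dir}, invisibly.
#' @export
write_simulation <- function(sim, dir, fasta = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome),
                              file.path(dir, "genome.fa"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$blacklist),
                              file.path(dir, "blacklist.fa"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$reference),
                              file.path(dir, "known_mirnas.fa"))
  gr <- sim$annotations
  S4Vectors::mcols(gr)$source <- "srnascape_sim"
  rtracklayer::export(gr, file.path(dir, "annotations.gff3"),
                      format = "gff3")
  wtsv <- function(x, f) write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$loci)) wtsv(sim$loci, "truth_loci.tsv")
  if (!is.null(sim$phas)) wtsv(sim$phas, "truth_phas.tsv")
  wtsv(sim$synteny, "synteny.tsv")
  wtsv(sim$lib_info, "lib_info.tsv")
  dir.create(file.path(dir, "libraries"), showWarnings = FALSE)
  for (lib in names(sim$libraries)) {
    wtsv(sim$libraries[[lib]], file.path("libraries",
                                         paste0(lib, ".tsv")))
    if (fasta) {
      tab <- sim$libraries[[lib]]
      if (nrow(tab) > 0) {
        seqs <- Biostrings::DNAStringSet(tab$sequence)
        names(seqs) <- sprintf("seq_%d_x%d", seq_len(nrow(tab)),
                               tab$count)
        Biostrings::writeXStringSet(seqs, file.path(
          dir, "libraries", paste0(lib, ".fa")))
      }
    }
  }
  invisible(dir)
}
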