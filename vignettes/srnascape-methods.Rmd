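---
title: "Methods and design of the srnascape pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the srnascape pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

srnascape implements an integrated multi-library small-RNA analysis of
the kind used for plant sRNA-seq compendia: annotation of miRNA genes
from many libraries at once, isomiR classification, exact small-count
differential expression, entropy-based tissue-specificity calling,
phased-siRNA (*PHAS*) locus detection, and singleton/duplicate
statistics. This vignette explains each model, the tunable parameters,
the numerical choices, and what the synthetic-data generator does and
does not emulate.

## Preprocessing model

Reads are collapsed to distinct sequences with a per-library count
matrix; the internal alphabet is DNA (U is mapped to T on input).
Alignment permits at most one substitution and no indels, on both
strands, and every placement is kept; a seed-and-verify index (exact
7-mers at both read ends, justified by the pigeonhole principle for
reads of at least 14 nt) makes this exact search fast in compiled code.

TPM is count × 10⁶ divided by the library's mapped-read total. By
default the denominator counts aligned reads inside the retained size
range (18–26 nt) only, so that length-outlier degradation products do
not deflate the scale of real small RNAs; `tpm_normalize()` exposes a
switch to count every aligned read instead. Replicate-mean TPM per
tissue is the expression unit used downstream.

The filter cascade runs in a fixed order — size, structural,
unaligned, low abundance, repetitive — so attrition tables are
reproducible. The low-abundance rule retains a read only when its
total TPM exceeds 100 **and** its best single-library TPM exceeds 10:
a removal rule phrased as one condition would either remove almost
everything (every read has *some* library at or below 10 TPM) or
almost nothing, so the implemented predicate demands both aggregate
and single-library support, which is the evident intent of the
original filter. Structural reads are identified by containment in a
blacklist sequence within one mismatch, mirroring the alignment rule.

## miRNA discovery

Candidate windows merge the placements of filter-passing reads per
chromosome and strand with a 200-nt gap and 20-nt flanks; the
precursor cap of 300 nt bounds any reasonable choice of these two
parameters, and both are arguments of `discover_mirna()`. Windows
shorter than 50 nt cannot form a scoreable hairpin and are dropped
with the over-long windows in the same tally.

Folding is a maximum-base-pairing dynamic program (Watson–Crick plus
G·U, minimum hairpin loop of 3, deterministic traceback that prefers
pairing the opening index with its smallest admissible partner). A
maximum-pairing objective, rather than a thermodynamic one, is
sufficient here because the downstream criterion is a pass/fail duplex
rule, not a free energy: the duplex evaluation walks the paired
anchors between mature and star, counting opposed unpaired bases as
mismatches (≤ 5 allowed) and one-sided unpaired runs as asymmetric
bulges (≤ 3 allowed), with terminal overhangs exempt. The folder is
verified against exhaustive enumeration of all nested structures for
short sequences.

The canonical mature is the most abundant sense read fully inside the
window, ties resolved toward the 5′-most read. The star is the most
abundant read whose 5′ end lies within ±1 nt of the position implied
by the 2-nt 3′-overhang geometry; if no such read exists the interval
implied by the structure is used. Strand bias uses raw counts pooled
across libraries (a TPM-weighted variant would change nothing for
clean loci and the raw-count form is the simpler estimand); abundance
bias attributes sense reads to the locus through the isomiR
classifier, run against both the mature and the observed star.

## IsomiR classification

A read is anchored to the canonical's genomic template (canonical plus
flanks). When the genomic placement is known the anchoring is taken
from the alignment; otherwise the placement minimizing internal
substitutions is chosen, with ties preferring smaller end offsets —
end-offset classes are cheaper than substitutions, so a read one base
short with a matching tail is "3′ trimming", not a shorter "tail SNP"
variant. Classes: negative end extensions are trimming; positive
extensions matching the template are additions; a 3′ extension that
mismatches the template is a non-templated addition (substituted bases
inside that extension belong to this class, not to the SNP classes);
internal substitutions are seed SNPs at canonical positions 2–8
(5′-anchored; the standard seed convention, overridable) and tail SNPs
elsewhere. End offsets beyond ±4 nt, or more than 2 internal
substitutions, make a read a distinct sRNA rather than an isomiR.
Reads shifted at both ends carry both end classes.

## Exact differential expression

The pointwise probability of observing counts *x* and *y* for the same
molecule in two equally sized libraries is the classical exact model
for digital tag counts; with both normalization totals set to 10⁶ the
conditional distribution of *x* given *y* is negative binomial with
p = ½, which provides the normalization identity (Σₓ P(x|y) = 1) used
as a numerical check to 10⁻¹². Evaluation is in log-gamma space. The
printed form is pointwise, so the two-sided p-value is a design
choice: twice the smaller of the lower and upper tail sums, capped at
one. TPM values are rounded to integers before use, since the formula
is defined on counts. The default significance rule for calling
differential loci (p < 0.01 and |log₂FC| ≥ 1) is exposed as arguments.

## Tissue specificity

H is Shannon entropy of relative expression in bits with 0·log 0 = 0.
modH follows the ROKU recipe: re-express the vector as absolute
deviations from a one-step Tukey biweight center (c = 5, ε = 10⁻⁴, the
expression-array convention) and take the entropy of the deviations.
Z scores use the sample (n−1) standard deviation, matching the default
of common statistical environments (a population-σ switch exists). A
locus is called specific when modH < 1.8 bits and Zmax > 3, with the
target tissue at argmax Z. For 14 tissues a one-hot vector yields
modH = 0 and Zmax = 13/√14 ≈ 3.474, comfortably above the threshold;
note Zmax can never exceed (n−1)/√n, so the Zmax > 3 rule needs at
least 11 samples to be satisfiable at all. Zmax is exactly invariant
to positive scaling of the expression vector; modH is invariant up to
the ε guard (relative effects below ~1% at realistic scales), and the
specificity call itself is scale-stable.

## PHAS detection

Reads of exactly the cycle length (21 or 24 nt) define candidate 5′
positions; antisense reads are projected onto the register with the
+2-nt offset implied by Dicer duplex geometry, so a dataset with
antisense reads at (sense − 2) positions phases identically to the
all-sense version. Windows of 10 cycles anchor at each occupied
position; `occupied` is the number of distinct positions in the
window and `phased` the number on the anchor's register. Windows need
at least 3 distinct phased positions (the minimum-depth rule applied
to distinct positions, the stricter of its possible readings).

Significance is the hypergeometric tail over distinct start positions
— the classic phasing p-value family. Because the anchor is itself an
occupied register position, the scan reports an anchor-conditioned
tail (window size − 1 positions, cycles − 1 register slots,
occupied − 1 draws, phased − 1 successes): without conditioning, a
scan over many anchors is anti-conservative and random placements
occasionally reach p < 10⁻⁵, while the conditioned form leaves 1,000
random ten-read windows with zero acceptances. Overlapping accepted
windows merge into one locus carrying the minimum window p.

Triggers are sought around both locus ends (± 2 cycles) as sites
complementary to a candidate mature with at most 4 mispairs, G·U
counted half; the best score wins, ties to the 5′-most site. The
exclusion rule removes loci that both overlap a retrotransposon-class
TE and are triggered by a 22-nt member of the miR170/miR171a set —
such loci produce easiRNAs rather than canonical phasiRNAs.

## Duplication statistics

Conserved pairs are locus pairs whose matures match within 2
substitutions (sliding the shorter sequence; overhangs count), plus
extra genomic placements of a mature outside all annotated loci, which
act as anonymous partners. Tandem means same chromosome with a gap
(nearest precursor ends, not midpoints) under 200 kb; syntenic means
the two loci fall in the paired intervals of one declared synteny
block; a locus in any qualifying pair is a duplicate, with tandem
taking precedence when both mechanisms apply. Genomic context uses the
precedence PCG > TE > UI so the three categories partition the loci.

The ratio test is a 2×2 Pearson χ² of a category's
singleton/duplicate counts against the genome-wide counts, without
continuity correction, df = 1. This construction reproduces the
published per-category and per-tissue p-values from their printed
counts to printed precision (verified in the test suite for nine
rows); one published tissue row (84 : 46 vs 305 : 114) is not
reproducible under this or any standard χ² construction we tried and
is treated as a probable erratum rather than a calibration target.
The χ² engine itself is checked against the direct Σ(O−E)²/E formula
on hundreds of random tables.

## The synthetic-data generator

`sim_config()` defaults define the study conditions used throughout
the tests and the acceptance script: 5 chromosomes × 300 kb, 14
tissues × 3 replicate libraries of exactly 10⁶ reads, 100 hairpin
loci (20 one-hot tissue-specific, 5 tandem and 5 syntenic duplicate
pairs), 10 phased loci per cycle length with an embedded perfectly
complementary 22-nt trigger site, a 30-gene structural-RNA blacklist,
and 5% contamination split between blacklist fragments and a large
pool of individually rare random genome fragments (15–30 nt). One
root seed drives everything; per-library streams derive from it by
fixed arithmetic so adding libraries does not perturb earlier ones,
and identical configurations reproduce byte-identical files.

Planted hairpins are inverted repeats whose arms diverge at three
wobble positions opposite the mature: the arm-5 bases there are forced
to G/T and the arm-3 partner is mutated to the G·U wobble base. The
duplex therefore still pairs fully (the loci pass the discovery gates
by construction) while the arms differ by ≥ 2 substitutions in every
alignable subwindow, so mature-region reads cannot re-align to the
opposite arm under the 1-mismatch rule — real precursor arms diverge
in exactly this way, and without it strand bias on a perfect inverted
repeat collapses to 0.5. Star abundance is fixed at 10% of the mature
arm, guaranteeing the abundance-bias gate for clean loci; isomiR reads
are emitted per class at configured per-class rates (a mature-arm draw
becomes class *c* with probability r_c, so observed class fractions
estimate r_c directly); expression profiles are one-hot for specific
loci and symmetric Dirichlet (concentration 5) for broad ones, making
specificity recovery unambiguous.

The generator does **not** emulate sequencing error beyond the planted
substitutions, quality scores, adapters, multi-branch precursors,
minus-strand loci, or abundance-versus-length biases of real
libraries. Passing tests therefore demonstrate the correctness of the
implemented rules under clean, well-separated signals — not robustness
to the full messiness of real sRNA-seq data.

## Problem sizes and determinism

The default synthetic study (42 × 10⁶ reads, ~31,000 distinct
sequences after collapsing) runs through the complete pipeline in
about half a minute on one CPU; the test suite uses a 20-locus variant
of the same design for the stage-level checks and the full default
design for the end-to-end recovery checks. All stochastic tests fix
their seeds; the folding and χ² engines are compared against
exhaustive or closed-form oracles rather than against themselves.

Known limitations worth repeating: the hairpin folder maximizes pair
count, not free energy, and handles a single stem-loop; the exact DE
test models no replicate-level dispersion (replicate means are tested
as counts); specificity calling needs enough tissues for Zmax > 3 to
be reachable; and the phasing statistic is a re-derivation of the
classic hypergeometric family, not a reimplementation of any specific
external tool's unpublished formula.
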