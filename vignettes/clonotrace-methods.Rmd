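---
title: "clonotrace: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clonotrace: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonotrace)
```

# The assay this package models

In barcoded Kras-G12D tumor models, every malignant clone is founded by a
single homology-directed-repair event that replaces the endogenous Kras
allele with an oncogenic G12D copy carrying a clone-specific set of
synonymous ("wobble") mutations. Because the barcode lives inside the
expressed coding sequence, targeted single-cell sequencing of the Kras
transcript reports three things at once, per cell:

* the founding clone (which barcode allele is expressed),
* the allelic configuration (the ratio of mutant to wildtype Kras
  transcripts, which becomes skewed when the wildtype allele is lost or the
  mutant allele amplified), and
* whether the cell is malignant at all (somatic cells express only
  wildtype Kras).

A companion targeted assay quantifies Kdm8 transcripts per cell; after
CRISPR editing of Kdm8, expression is bimodal and the positive fraction
estimates the proportion of cells that escaped editing. Finally, low-pass
single-cell whole-genome sequencing read-outs are binned into
equal-mappability windows to call chromosome-scale copy-number changes
(e.g., gain of the Kras-bearing chromosome).

# Barcode design space

The design template is the murine Kras codon 2--31 region (90 nt). Codons
3--8 are recoded synonymously (`GAGTATAAACTTGTGGTG` to
`GAATACAAGCTAGTAGTC`) so the knocked-in allele resists the sgRNA used to
cut the endogenous locus, and codon 12 carries GGT to GAT (G12D; the
single-nucleotide aspartate substitution). Both are fixed, not part of the
barcode.

The published library diversity is 2,359,296 = 2^18 x 3^2 distinct
synonymous variants, but the individual variable positions are not printed.
The calibrated set shipped in `inst/extdata/kras_barcode_design.tsv` is one
consistent solution: 20 variable codons (2, 9--11, 13--28), where the two
isoleucines (codons 21 and 24, which have exactly three synonymous codons
differing only at the wobble base) contribute a factor of 3 each and the
remaining 18 positions carry the wildtype codon plus one wobble variant.
Codons 29--31 were left fixed as the downstream homology junction. This is
a design choice, not a reconstruction of the original oligo pools; any set
with the same degeneracy product is equivalent for every algorithm in this
package.

```{r}
enumerate_diversity(kras_codon_template(), kras_variable_positions())
```

Note one arithmetic subtlety checked by the tests: of the six recoded
wobble bases across codons 3--8, five fall inside the 20-nt protospacer and
one (codon 8's wobble) sits just 3' of it, so the protospacer-aligned
mismatch count of every allele is at least 5 -- ample for sgRNA resistance,
where 2--3 seed mismatches usually abolish cutting.

# The synthetic tumor: what it emulates, and what it does not

`simulate_tumor()` draws a ground-truthed cell population:

* **Clone sizes** follow a truncated discrete power law (Zipf) with
  exponent `clone_size_alpha` (default 1.5): one parameter, heavy tail,
  matching the observation that a few large clones dominate. The true
  clone-size law in vivo is not printed; only the skew matters here.
* **Cell classes**: malignant cells carry exactly one barcode; somatic
  cells (default 20%) carry none; spike-in cells (default 2%) are foreign
  cells yielding no mouse Kras or Kdm8 transcripts.
* **Allelic imbalance**: a fraction `p_imbalanced` (default 0.15) of
  malignant cells draw their mutant-transcript fraction uniformly from
  [0.75, 1]; the rest draw it from Beta(100, 100) around 0.5 (sd about
  3.5%). The default is a deliberate choice: imbalance is a minority state
  in primary tumors (the published data show a minority of wildtype-skewed
  cells, 621/7,194, and mutant skew enriched only in hypoxic
  subpopulations). The Beta concentration keeps balanced cells well
  separated from the 0.75 decision threshold, which is what makes the
  recovery problem well-posed.
* **Kdm8**: cells are positive with probability `p_kdm8_positive`
  (default 0.114, the published positive fraction); positive cells draw at
  least one UMI, so the truth is exactly bimodal.
* **Depths**: per-cell Kras UMI totals are negative binomial (mean 20,
  size 10 by default; the published per-cell depth distribution is not
  printed, so these are exposed in the model object), transcriptome totals
  likewise (mean 5,000).

The read simulators add droplet structure (error-free 16-nt cell barcode +
10-nt UMI on read 1; cell-barcode correction is assumed upstream),
`rpois(reads_per_umi) + 1` PCR duplicates per UMI (so every true molecule
is observable and caller logic is isolated from dropout), and uniform
per-base substitution errors on read 2. Not emulated, deliberately:
ambient RNA, doublets, barcode swapping, chimeric PCR artifacts, and indel
sequencing errors. A green recovery test therefore establishes that the
calling logic inverts the stated generative model -- not that it is robust
to every artifact of real droplet data.

# The barcode caller

The caller mirrors the published pipeline stage by stage:

1. **Trimming** (`trim_krasbc()`): a required 5' anchor
   (`CTCTATCGTAGGGTCATA`) and an optional 3' anchor (`CATTTTCAGCAGGCCT`)
   are matched as contiguous windows allowing up to
   `floor(0.2 * length)` substitutions (the cutadapt `max_errors = 0.2`
   convention); the leftmost minimal-mismatch window wins; reads without
   the 5' anchor are dropped. Indels are not modelled (the simulators emit
   none).
2. **Assignment** (`assign_allele()`): minimal substitution distance
   against the wildtype-plus-alleles reference, accepted only if the
   distance is at most `ceiling(0.1 * length)` and the runner-up is at
   least one mismatch worse; ties are unassigned rather than guessed.
3. **UMI collapse** (`collapse_umis()`): one transcript per distinct
   (cell barcode, allele, UMI) triple -- the collapse key includes the
   allele, so a UMI observed under wildtype and under a barcode counts once
   under each.
4. **Barcode merging** (`merge_barcodes()`): within a cell, a barcode
   whose edit distance to a higher-count barcode is below 3 donates its
   UMIs to it. "Edit distance" is taken as Levenshtein (Hamming is a
   config option); the strict `< 3` is kept as printed. Merging is greedy
   from the highest pre-merge count with a lexicographic tie-break, so it
   is deterministic and conserves UMIs.
5. **Calling** (`call_clonotype()`): the dominant barcode is the unique
   argmax (a tie excludes the cell -- one HDR event per cell is the
   model's premise, so ties signal noise); cells with no barcode UMIs are
   somatic if they have at least two wildtype UMIs ("more than one copy")
   and excluded otherwise; Kras abundance is (wildtype + barcode UMIs) /
   transcriptome UMIs, scaled by the per-sample median transcriptome UMI
   count (one concrete reading of "scaled according to sequencing
   depths"; total-count scaling would differ by a constant factor only).
6. **Imbalance** (`classify_imbalance()`): with t = dominant + wildtype
   UMIs, cells with t < 4 are indeterminate; mutant fraction >= 0.75 is
   g12d-high, wildtype fraction >= 0.75 is wt-high, otherwise balanced.
   The 0.75/4 cutoffs are not published; they are defaults exposed in the
   API.

One honest caveat, quantified in the tests by a closed-form oracle: at a
mean depth of 20 UMIs per cell, binomial counting noise alone bounds the
expected per-cell imbalance label accuracy near 93--95% (balanced cells
produce about 2% false skew calls per tail; skewed cells drawn near the
0.75 boundary are missed about half the time). The *fraction* of skewed
cells is still recovered within binomial confidence bounds because the two
error modes nearly cancel at these defaults -- per-cell labels are noisier
than population fractions.

# The Kdm8 caller

Read 2 is trimmed positionally (first 26 bases), payloads are assigned to
the transcript when the best contiguous-window substitution distance is at
most 10% of the payload length, reads collapse to (cell barcode, UMI)
pairs, and -- the step that matters -- every cell of the experiment appears
in the output, with absent cells imputed to zero. "Detectable" is taken as
at least one collapsed UMI (the published cutoff is not stated; the
threshold is an argument, and the positive fraction is monotone
non-increasing in it). The bundled transcript FASTA is a synthetic
stand-in (the RefSeq record is not redistributed); only its role as
assignment target matters.

# Copy number

`build_binmap()` implements the equal-mappability construction
deterministically: a genome position is mappable iff its read-length k-mer
occurs exactly once in the genome counting both strands (this replaces the
published simulate-reads-and-realign procedure with its exact desk-scale
equivalent; a palindromic k-mer is never mappable). Mappable positions are
partitioned into bins of equal occupancy, within one position inside each
chromosome; bins never span chromosomes, and the bin count is apportioned
across chromosomes by largest remainder. Intervals tile each chromosome so
every read start falls in exactly one half-open bin.

`gc_correct()` fits expected count as a function of GC by a rolling median
over GC-sorted bins (window `max(21, n_bins/50)`), rescales by global
median / expected, and re-anchors the corrected median to the raw median.
The published pipeline says only that GC content was "accounted for"; the
rolling median is this package's choice (robust, parameter-light).

`estimate_cn()` makes three numerical choices worth recording:

* the exported `normalized_ratio` is mean-anchored (its genome-weighted
  mean is exactly 1), but the integer-CN track is scaled by the **median of
  per-chromosome medians**, because a plain genome-wide median or mean is
  inflated when a whole chromosome is amplified (one chromosome in three at
  CN 4 shifts the global median enough to miscall the gain as CN 3);
* the ratio track is smoothed by a within-chromosome rolling median
  (default window 37). This deviates from pure per-bin rounding
  deliberately: at 20 reads per bin, independent rounding of Poisson
  counts is correct for only ~73% of bins, so a per-bin estimator can
  never reach the 95% accuracy this package tests for. The window is
  sized so the smoothed ratio sits more than 3 sd from the rounding
  boundary at that depth. The default targets chromosome- and arm-level
  events (the analysis unit here); set `smooth_window = 1` for focal
  events, or use a dedicated segmentation method (out of scope, as are
  CBS/HMM, chromothripsis and non-diploid baselines);
* the smoothed ratios are self-calibrated to the integer lattice: a scale
  factor on a +/-10% grid around 1 minimises the squared distance of
  ratio x ploidy to the nearest integers. This absorbs the +/-3% sampling
  noise of the median normaliser, the same role ploidy-grid scaling plays
  in established single-cell CNV pipelines.

Coordinates are 0-based half-open throughout, BED-compatible on output.

# Annotation and exact statistics

`classify_locality()` measures the gap between a region interval and a TSS
point as the number of bases strictly between them (0 if the TSS lies
inside the region); regions at least 1 kb away are distal. The anchor is
the interval, not its midpoint (the conservative reading of "away from the
nearest TSS"), and equidistant genes tie-break lexicographically so the
result is order-invariant. `gene_region_table()` operationalises "gene
associated with a region" as nearest-gene assignment of TSS-proximal
regions of matching direction, the standard peak-annotation convention.

`fisher_exact_two_sided()` is built directly from the hypergeometric mass:
the p-value sums the probabilities of all tables with the observed margins
that are no more probable than the observed table, with a 1e-7 relative
tolerance on the comparison (the R/scipy convention; this reproduces the
printed p = 0.001 for the 0/13 vs 6/9 incidence table). Tests cross-check
it against full factorial enumeration and against `stats::fisher.test`.
`fraction_report()` rounds half-up to one decimal in exact integer
arithmetic (so 6.25% reports as 6.3, not banker's 6.2).

# Degenerate inputs and tie-breaks, in one place

* Trimming: absence of the 5' anchor, or an empty payload, drops the read
  (`NA`), never errors.
* Assignment: empty payloads and distance ties are unassigned.
* Merging: processing order is (count descending, name ascending); the
  result is independent of input order.
* Calling: zero transcriptome UMIs excludes the cell and leaves abundance
  undefined; dominant-barcode ties exclude.
* Binmap: `n_bins` above the mappable-position count is a capacity error;
  chromosomes without mappable positions get no bins.
* GC correction: all-zero counts return zeros with a warning; zero-count
  GC strata are left uncorrected.
* CN estimation: a zero genome median is an error, not a silent division.
* Locality: regions on chromosomes without genes are flagged, not dropped.

# Limitations

The package inverts its own stated generative model and reproduces the
published rule set and summary statistics; it does not align reads to a
genome, correct cell barcodes, call peaks, segment copy-number profiles,
or model amplification chemistry. The variable-position set is one
consistent solution to the printed diversity, not the study's oligo
design. All recovery guarantees quoted in the tests are statements about
synthetic data at stated depths and error rates.
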