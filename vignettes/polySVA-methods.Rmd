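---
title: "Methods: profiling epigenetic silencing of polymorphic SVA insertions"
author: "polySVA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling epigenetic silencing of polymorphic SVA insertions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polySVA)
```

## The problem

SVA elements are composite hominid retrotransposons: a `(CCCTCT)n` hexamer
head, an Alu-like region, a GC-rich VNTR, and a SINE-R region. Polymorphic
SVA insertions are present in some genomes but absent from the reference, so
every standard reference-based analysis -- alignment, annotation, methylation
calling -- is blind to them unless the reference itself is rewritten. The
paradigmatic case is X-linked dystonia parkinsonism (XDP), caused by an
antisense SVA inserted into an intron of *TAF1*; the insertion nucleates DNA
methylation and H3K9me3 heterochromatin, and its hexamer copy number tracks
disease severity.

polySVA implements the computational stages such a study needs as one tested
package: quality filtering of long-read insertion calls, construction of
insertion-augmented genomes with exact coordinate maps, spike-in-scaled
boundary profiling of repressive marks, aggregation of nanopore CpG calls
over elements, noise-tolerant hexamer copy-number estimation, and expression
summaries (intron retention, cis links, readthrough). A seeded synthetic
generator produces every input with a planted truth set, so each stage --
and the whole pipeline -- is validated by truth recovery rather than by
eyeballing.

## Insertion catalog

Calls arrive as TLDR-style tables. Three quality fields drive filtering:
`UnmapCover` (fraction of the inserted sequence covered by TE sequence),
`TEMatch` (similarity to the TE consensus) and `SpanReads` (supporting
reads). Defaults are `>= 0.80`, `>= 0.80` and `>= 3`, with elements retained
only when *longer than* 1 kbp -- the length cut is strict, so a 1,000-bp call
is rejected. Percentage columns are auto-detected per column (any value
above 1 flags a 0-100 scale) and normalized to fractions.

Cross-sample event matching (`shared_and_private()`) treats two calls as the
same insertion when chromosome and subfamily agree and start positions lie
within a tolerance, 50 bp by default. Long-read breakpoint estimates jitter
by tens of bases; no tolerance is prescribed by the data themselves, so 50 bp
was chosen once as a conservative bound well below the minimum spacing of
distinct SVA insertions and is exposed as a parameter.

## Genome augmentation and liftover

An insertion "at position p" splices the consensus before the 0-based
reference position p (after the 1-based base p). Applying insertions from
the end of each chromosome toward the start means earlier coordinates never
shift under later splices; the package records every splice in a
`coord_map`, making the operation exactly invertible:

* positions outside inserted segments project back uniquely;
* positions inside an inserted segment project to the insertion point and
  are flagged, since they have no reference equivalent.

Annotation liftover shifts features wholly downstream of k inserted bases by
k and *stretches* features that contain an insertion point -- an intronic
insertion makes the intron longer, it never splits the feature. This matches
what re-aligning reads to the augmented genome produces: reads spanning the
junction map contiguously through the inserted sequence. Two insertions at
one position are rejected outright; explicit failure beats an arbitrary
order.

```{r augment}
res <- augment_genome(c(chr1 = "ACGTACGTAC"),
                      data.frame(chrom = "chr1", position = 5,
                                 sequence = "TTT", label = "demo"))
res$genome
project_to_reference(res$map, "chr1", 6)
```

## Boundary profiling

Coverage is compared across samples after spike-in scaling: each sample's
track is multiplied by `1e4 / aligned spike-in reads`, so a doubling of
spike-in recovery halves the scale factor exactly and zero spike-in reads
are a hard error rather than a silent infinity.

`scale_regions_matrix()` builds the standard scale-regions profile: element
bodies rescaled to 1 kbp (length-weighted averaging), 10 kbp fixed flanks,
50-bp bins. The bin width is a package choice -- it divides both the body
and the flank evenly. Minus-strand rows are reversed so columns always run
5' to 3' of the element. Flank bins beyond a chromosome end become missing
values and are excluded from column means; inventing zeros there would
fabricate depletion. Only elements longer than 1 kbp receive rows, matching
the insertion-length cut.

`boundary_enrichment()` divides the mean signal within a window of each body
edge -- the outermost body bins plus the innermost flank bins -- by the mean
over the most distal flank bins. The flank-side bins are in raw genomic
units, so a boundary peak of fixed genomic width is captured undiluted even
when a long body is scaled down; using scaled body bins alone would dilute
the peak in proportion to element length. Elements with zero distal signal
return `NA`.

Alignment filtering for repeat quantification keeps primary, uniquely
mapping records with at most 0.03 mismatches per aligned base; the
comparison is inclusive, mirroring the "maximum allowed value" semantics of
aligner-side mismatch-rate flags.

## Methylation aggregation

Nanopore callers emit per-read, per-site log-likelihood ratios. Calls are
binarized with a symmetric dead zone: methylated at `LLR >= 2`, unmethylated
at `LLR <= -2`, discarded (and counted) in between. The 2.0 default is
common practice for nanopolish-style output; the threshold is exposed.
Element summaries average over retained calls (read-level averaging, the
natural analogue of methylation coverage displays); quarter means are
computed over four equal genomic sub-intervals ordered from the element's
own 5' end, so for a minus-strand element the "first quarter from the TSS"
is the last genomic quarter. Quarter means are call-weighted and always
average back to the element mean.

Group comparisons use a two-sided two-sample Student's t-test (equal
variances) on element-level summaries of either the full element or the
first quarter. With a single usable value in a group the difference is still
reported and the test is marked not applicable.

## Hexamer copy number

`column_consensus()` reduces a gapped read alignment by per-column
plurality over `{A, C, G, T, -}`: a gap plurality deletes the column,
sub-threshold depth emits `N`, ties break in the fixed order A < C < G < T <
gap.

`find_motif_run()` locates tandem motif runs by local wraparound dynamic
programming: the consensus is aligned against an unbounded repeat of the
motif with unit edit costs, a match scoring +1 and each edit costing
`(1 - max_noise) / max_noise`, so any positive-scoring segment has an edit
noise strictly below `max_noise` (default 20%). Matching is phase-agnostic
-- runs may start and end mid-motif, with partial terminal copies counted
fractionally. A segment must span at least two motif copies to count as
tandem, which keeps isolated chance matches in random sequence out of the
output; runs are extracted best-scoring first and reported 5' to 3'. The
headline copy number is the longest run's estimate rounded half-up
(`hexamer_report()`); whether published hexamer lengths count partial
terminal copies is not stated anywhere we could anchor to, so the rounding
rule is declared here and tested.

```{r hexamer}
find_motif_run(strrep("CCCTCT", 40), "CCCTCT")
```

## Expression summaries

TPM uses the annotated feature length as the effective length -- an
approximate TPM appropriate for per-feature bar plots, with no
fragment-length correction. Size factors follow the median-of-ratios
definition: per feature, the reference is the geometric mean across samples
(features with any zero excluded); per sample, the factor is the median of
count/reference. For an odd number of usable features this is exactly the
DESeq2 size factor, which serves as an independent cross-check in the test
suite. Note that scaling one sample's counts by c rescales the
geometric-mean reference by c^(1/S), so only *relative* factors are
equivariant under per-sample scaling -- the absolute factors of the other
samples shift by c^(-1/S); the tests assert the relative form. Differential
testing itself is out of scope; only the normalization is implemented.

Intron retention is summarized as per-group mean TPM of a target intron and
a downstream exon with between-group ratios; direction flags fire when the
ratios cross 1 in opposite directions. Cis linkage connects elements to
genes whose TSS lies 2-50 kbp from the nearest element edge (edge-to-TSS,
declared here; a midpoint convention would shift distances by half an
element length). Readthrough detection walks outward from the element
boundary on each strand, bridging coverage gaps up to 200 bp, and labels the
call antisense when the extended strand opposes the overlapped or nearest
gene.

## The synthetic generator

`sim_config()` fixes the study conditions: 3 chromosomes of 100 kbp, 6
fixed elements and 6 polymorphic insertions, element lengths 1.5-3 kbp
(all above the 1-kbp analysis cut), 30-50 hexamer copies, VNTR GC fraction
0.7, 5-fold boundary enrichment, methylation 0.9 (control) versus 0.1
(demethylated knockdown elements), a 2% read substitution rate and 10,000
spike-in reads. Each element is a hexamer head, a short A-rich spacer
(mirroring the non-repetitive junction before the Alu-like region, and
pinning the planted run to its exact copy number), and a GC-rich body with
20 CG dyads forced at even spacing so every element has enough CpG sites to
aggregate. Elements are placed with at least 12 kbp between neighbours so
that no element's distal profiling flank touches another's enriched
boundary window. Methylation calls are emitted with `|LLR| >= 2`, making
binarization unambiguous while the binarizer's dead zone is exercised by
dedicated unit fixtures. The count table plants a 3-fold intron-retention
increase and a 0.5-fold downstream-exon decrease in a double-knockdown
group over a stable background gene set, plus a 2-fold TE derepression.

What the generator does *not* emulate: read-level nanopore signal, indel
errors (substitutions only), subfamily-specific internal structure, mapping
ambiguity in repeats, or biological variance between replicates beyond
Poisson counting noise. Passing tests therefore demonstrate algorithmic
correctness on data with known truth -- exact splice arithmetic, unbiased
interval averaging, recovery of planted effects at realistic magnitudes --
not robustness to every artefact of real sequencing.

## Numerical choices and degenerate inputs

* Interval averaging is exact (length-weighted over the track's step
  function); equality with a per-base oracle is asserted to 1e-9.
* All-zero TPM columns stay zero; zero-count ratio denominators yield `NA`,
  never 0/0; zero spike-in reads and empty alignments are errors.
* Ties: consensus symbols break A < C < G < T < gap; equal-length motif
  runs report the 5'-most; insertions at identical positions are rejected.
* Problem sizes in tests and the acceptance script (100-kbp chromosomes,
  hundreds of positions per round-trip check, 1,000 null simulations for
  the t-test size) were chosen as the smallest sizes at which the measured
  quantities are statistically stable.

## Known limitations

Deletions, inversions and nested insertions are out of scope for the
coordinate map. The motif finder's greedy best-first extraction can, in
contrived cases, prefer a clean single-copy fragment over an overlapping
noisier multi-copy run. Read counting is accepted as an input table; the
package does not re-implement a read-to-feature assigner. Methylation
comparisons assume element-level summaries are exchangeable units; no
spatial autocorrelation along the genome is modelled.
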