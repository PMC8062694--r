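---
title: "Discovering noncoding-gene-encoded peptides and dark antigens with darkpep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering noncoding-gene-encoded peptides and dark antigens with darkpep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darkpep)
```

## The problem

Standard proteomic searches only see peptides present in the annotated
protein database, so translation products of regions conventionally
annotated as noncoding — pseudogenes, lncRNAs, UTRs, introns, alternative
reading frames, retroelements — are invisible to them. Proteogenomics
closes that gap by searching spectra against a customized database that
includes putative translation products of such regions. Because tumors
frequently de-repress these regions, their peptides are candidate
tumor antigens from outside the mutation space ("dark antigens").

`darkpep` implements that analysis as a tested pipeline: database
construction, class-specific false-discovery control for the novel
peptide class, genomic annotation and grouping into novel coding loci,
tumor/normal quantification, tissue-specificity classification, MHC
class I presentation screening, and orthogonal RNA-seq read support —
all exercised end-to-end on seeded synthetic data with known ground
truth.

## Search-database construction

Noncoding transcripts are translated in all three frames of their
spliced, strand-resolved sequence. Translations are split at stop codons
and segments of at least `min_segment_len` residues (default 7) are kept
as database entries; the default is the shortest length at which a fully
tryptic peptide of detectable size can arise, and it keeps the database
compact. Codons containing `N` translate to `X`, and `X` never matches
in peptide lookups.

Missense variants are applied to known proteins as single-residue
substitutions (indels and frameshifts are out of scope). Decoys are
full-protein reversals of every target entry — no pseudo-reversal at
K/R sites — and each decoy records the class of its source entry, which
matters for class-specific FDR below.

In-silico trypsin cleaves C-terminal to K or R except before P; the
tryptic index used for known-peptide matching enumerates up to two
missed cleavages and keeps peptides of 7–45 residues.

## Classifying peptides and class-specific FDR

A peptide is **known** if, after collapsing isoleucine to leucine (the
two are isobaric and indistinguishable in standard shotgun MS), it is a
contiguous substring of any known protein; **variant** if it instead
matches a variant entry; otherwise **novel**. Exact substring matching
under I/L collapse is the package's equivalent of a BLASTP
exact-identity filter; matching is a pure sequence property, so any
modifications must be stripped first.

False-discovery control happens *within the novel class*. Before
estimation, three groups are removed: target PSMs whose peptide
classifies known or variant; decoy PSMs whose reversed-read peptide
happens to be a known tryptic peptide; and decoy PSMs whose matched
entry originates from a non-noncoding class. The last rule is what
makes the estimate class-specific on the decoy side as well — the
surviving decoys mirror the novel-class search space, so the
decoy/target ratio estimates the error rate of the novel class rather
than being diluted (or swamped) by the abundant known class.

PSMs are collapsed to their best score per peptide (the pipeline
reports peptide counts; a PSM-level mode exists behind a flag). At each
target score $s$,

$$\widehat{\mathrm{FDR}}(s) = \frac{\#\{\text{decoy peptides} \ge s\}}
{\#\{\text{target peptides} \ge s\}},$$

capped at 1, with ties counting the decoy (conservative), and the
q-value is the minimum estimated FDR over all thresholds that would
accept the peptide. Peptides with $q \le \alpha$ (default 0.01) are
accepted. No +1 correction or $\pi_0$ estimation is applied — the plain
ratio is the estimator throughout.

Why class specificity matters is demonstrated, not asserted: in the
validation suite the same simulated search is evaluated both ways. In a
known-dominated regime (a large, high-scoring known class, decoy counts
set by database symmetry rather than spectrum counts) global 1% FDR
lets the mass of confident known identifications drag the acceptance
threshold into the null score range, inflating the realized
false-discovery proportion among the accepted *novel* peptides;
class-specific estimation at the same $\alpha$ keeps it near nominal.

## Genomic annotation and novel coding loci

Accepted novel peptides are placed back on the genome through the
residue-to-coordinate maps of their source transcripts; junction
spanning peptides produce multiple blocks whose lengths sum to three
times the peptide length, and multi-copy (repeat) peptides keep every
placement. Every placement re-translates from the genome to its peptide
— this round trip is asserted for all emitted locations.

Each placement receives exactly one origin category under a fixed
precedence:

pseudogene > lncRNA > retroelement > UTR > exonic (alternative frame) >
intron–exon boundary > intronic > upstream > downstream > intergenic.

Only the pseudogene-first rule is externally constrained; the rest of
the order is a documented, configurable package choice. Upstream and
downstream require the placement to fall within 1 kb of the nearest UTR
boundary of a coding gene. Exonic calls require a reading frame
different from the annotated CDS (same strand, same codon anchor means
same frame); same-frame overlap falls through to the remaining
categories, because a same-frame peptide would already have been
removed as known. A peptide whose placements all lie in annotated
repeat intervals is kept as a single retroelement assignment for its
family rather than discarded — multi-mapped peptides are evidence, not
noise.

Placements are grouped into **novel coding loci**: by noncoding gene
for pseudogene/lncRNA, by repeat family for retroelements, by (host
coding gene, category) for the gene-proximal categories, and by
single-linkage clustering within 10 kb (same chromosome and strand) for
intergenic placements. Host-gene grouping was chosen over pure
coordinate clustering for gene-proximal categories; the clustering
window is a parameter. Loci supported by fewer than
`k_min_peptides = 2` unique peptides are removed, and pseudogene loci
are tagged with their parental gene's function class from a
user-supplied lookup (missing keys become `"unannotated"`).

Coordinates are 1-based inclusive in all external formats (GFF3/TSV);
BED export is 0-based half-open; conversions live in one I/O layer.

## Quantification and differential expression

Label-free designs sum the log2 MS1 intensities of a locus's member
peptides per sample; the locus is missing only where all members are
missing. Isobaric designs compute peptide log2 ratios against the
internal reference channel (peptides with a missing or non-positive
reference are excluded with a warning) and summarize to the locus by
the median. Missing values are never imputed, and no cross-sample
renormalization is applied to the locus sums.

Matched designs use the paired t test on complete pairs (at least two
required); unmatched designs use the two-sided Welch t test with at
least two observations per group. Loci failing these minima are
reported untested rather than silently dropped. Degenerate cases are
flagged: identical tumor and normal values give effect 0 and p = 1; a
constant non-zero difference reports a p-value below the
machine-representable threshold with `degenerate = TRUE`. "Adjusted p"
means Benjamini–Hochberg across the tested loci. Fold change is
$2^{\overline{\log_2 T} - \overline{\log_2 N}}$ over non-missing
values.

Tissue specificity uses detection counts over a tissue panel, where
detection means at least one quantified member peptide in at least one
sample of that tissue (no intensity floor): one tissue is
tissue-specific, 2–14 nonspecific, and 15 or more ubiquitous. The
published bands overlap at 15; the package resolves the overlap in
favor of the verbatim ubiquitous rule ("at least 15") and makes both
thresholds configurable. Recurrence summaries bin each locus by its
per-dataset missing fraction on half-open intervals $[0,.25)$,
$[.25,.5)$, $[.5,.75)$, $[.75,1]$ — a locus missing in exactly half the
samples falls in the 50–75 bin — and cross-dataset overlap reports the
share of loci seen in at least two datasets, split pseudogene versus
non-pseudogene.

## Dark-antigen screening

All overlapping 9-mers of the translated segment of each surviving
locus are scored by three components — MHC binding, proteasomal
C-terminal cleavage, TAP transport — combined as

$$\text{combined} = \text{MHC} + 0.225 \times \text{cleavage} +
0.025 \times \text{TAP}.$$

The additive form with these weights follows the published convention
of the reference predictor the weights come from; a true normalized
weighted average is available behind `combine = "weighted_average"`
since the two readings of "weighted average" conflict and neither is
guessed silently. Enumerating from the full translated segment of loci
passing the two-peptide filter (rather than from detected peptides
only) is the package default.

The combined score is expressed as a percentile rank against a frozen
background: `background_size` (default 1000) 9-mer windows sampled
uniformly from a supplied natural proteome under a fixed seed and
scored identically. Rank = 100 × (background scores ≥ query)/size, so
ties raise the rank (conservative) and a score above the whole
background ranks 0. Candidates require rank ≤ 0.5% and a source-locus
tumor/normal fold change ≥ 1.5; the fold-change criterion applies only
where matched normals exist — loci without one pass on rank alone.
Identical 9-mers from different loci are reported per locus.

Scorers are pluggable: any function (or external table) mapping a 9-mer
and an allele tag to three reals in [0, 1] can replace the built-in
reference scorer, which is a deliberately simple deterministic stand-in
— an anchor-position (2 and 9) preference table for MHC, a C-terminal
residue lookup for cleavage, and scaled Kyte–Doolittle hydropathy for
TAP. It ignores the allele tag. It is *not* a trained predictor and its
scores have no immunological calibration; it exists so the screening
logic, rank arithmetic, and selection criteria are fully testable.

## Orthogonal RNA-seq support

A read supports a peptide placement if its reference span overlaps any
block by at least 1 bp and its edit distance (`NM` tag) is at most 1,
counted once per placement. Overlap with any single block suffices for
junction peptides by default (`require_all_blocks` exists), and reads
with no edit-distance tag fail the filter unless told otherwise —
conservative on both counts. Alignments are desk-scale SAM text; the
simulator emits fixed-length (100 nt) all-match records with per-base
substitution counts recorded in `NM`.

## What the synthetic data emulates — and what it does not

The generator builds a single toy chromosome carrying protein-coding
genes (UTRs, one intron, 1 kb flanks), pseudogenes that are
substitution-mutated copies of sampled parental CDS (5% per-nucleotide
divergence by default; an indel mode is deliberately off so frame
bookkeeping stays testable), two-exon lncRNAs whose spliced sequence
carries a junction-spanning ORF, and a family of identical LINE-1-like
repeat copies. All randomness flows from one root seed through named
substreams, so each stage is reproducible in isolation and identical
configurations give byte-identical outputs.

PSM simulation draws one continuous "search score" per PSM from
class-conditional Gaussians (defaults: known mean 5, correct-novel mean
2.5, incorrect/decoy mean 0, all sd 1); only rank behavior matters, not
any engine's score semantics. Incorrect matches and decoys share one
distribution, and with `decoy = NA` the decoy count is balanced so
noncoding-origin decoys match the number of incorrect novel-class
targets — the symmetry assumption underlying target-decoy estimation.
Quantification plants configurable log2 effects in tumor samples with
Gaussian noise (sd 0.25 by default) and missing-completely-at-random
cells.

What passing tests on these data do **not** show: real spectra
(fragment ions, retention time, isotope envelopes are all absent), real
score distributions (engine scores are neither Gaussian nor
homoscedastic), informative missingness (real MS missingness is
intensity-dependent), sequence homology structure beyond the planted
pseudogene/parent relationships, or trained epitope predictions. The
suite validates the *logic and calibration* of the pipeline, not the
biology of any particular dataset.

One interaction deserves emphasis: summed label-free locus values jump
when member-peptide availability changes across samples (a missing
peptide removes its entire baseline from the sum). With
missing-at-random injection this adds severe locus-level noise — a
property of summed quantification itself, not of the implementation.
The planted-effect recovery validation therefore runs at zero
missingness (73 loci, 11 planted at +1 log2, noise sd 0.25, 8 pairs),
where the paired test recovers essentially all planted loci; the
missingness machinery is exercised separately by the recurrence and
detection analyses.

## Validation problem sizes

The shipped validation uses: a standard world of 25 coding genes, 15
pseudogenes, 10 lncRNAs and 8 repeat copies; 20 replicate PSM
simulations of 1,000 novel-class PSMs for FDR calibration (realized
FDP ≤ 0.03 in at least 18 of 20 at α = 0.01); a 120-coding-gene,
known-dominated configuration for the class-specific versus global
contrast; 1,000 random instances per brute-force oracle (translation,
q-values, categories, percent rank, read counting); the 73-locus
differential design over 20 seeds; a 60-locus, 31-tissue panel; and a
planted-antigen fixture in which exactly one optimal 9-mer exists by
construction.

## Known limitations

Spliced alignment awareness is limited to reference-span arithmetic;
splice-graph enumeration, homology search beyond exact I/L-collapsed
matching, engine rescoring, reporter-ion normalization, batch
correction, and MHC class II are all out of scope. The intergenic
clustering window (10 kb) and the category precedence beyond
pseudogene-first are conventions, configurable but not externally
validated.
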