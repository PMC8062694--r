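# darkpep

Proteogenomic discovery of peptides translated from predicted noncoding
genes — pseudogenes, lncRNAs, retroelements, UTRs, introns and
alternative reading frames — and screening of those peptides as
candidate tumor "dark antigens".

Standard proteomic searches can only identify peptides present in the
annotated protein database. `darkpep` implements the proteogenomics
alternative as a tested R pipeline:

1. **Database construction** — three-frame translation of noncoding
   transcripts (segments split at stop codons), missense variant
   entries, and reversed-sequence decoys alongside the known proteome.
2. **Class-specific FDR** — peptides are classed known / variant /
   novel by I/L-collapsed sequence matching; known and variant matches
   are removed from both target and decoy sets, and decoy-based
   q-values are computed *within the novel class*:
   FDR(s) = #{decoys ≥ s} / #{targets ≥ s}, q(s) = min over
   thresholds ≤ s, acceptance at q ≤ 0.01.
3. **Genomic annotation** — accepted peptides map back to genomic
   blocks (junction- and multi-copy-aware), receive one origin
   category under a pseudogene-first precedence, and group into novel
   coding loci (≥ 2 unique peptides).
4. **Quantification** — summed log2 MS1 intensities (label-free) or
   median log2 reporter ratios vs an internal reference (isobaric);
   paired or two-sided t tests tumor vs normal; fold change
   2^(mean log2 difference); tissue-specificity classes
   (1 / 2–14 / ≥ 15 tissues); recurrence and cross-dataset overlap.
5. **Dark-antigen screening** — all 9-mers of surviving loci scored by
   pluggable MHC/cleavage/TAP components, combined as
   MHC + 0.225·cleavage + 0.025·TAP, ranked against a frozen
   background of 1000 random natural 9-mers; candidates need
   %-rank ≤ 0.5% and tumor/normal fold change ≥ 1.5.
6. **Orthogonal evidence** — RNA-seq reads support a peptide placement
   if they overlap a block by ≥ 1 bp with edit distance ≤ 1.

A first-class synthetic-data module generates a seeded toy genome,
annotation, search databases, PSM tables, quantification matrices and
SAM alignments with known ground truth, so the whole pipeline is
validated end-to-end at desk scale.

## Worked example

```r
library(darkpep)

world <- generate_world(sim_config(seed = 42))
world
#> synthetic_world: 130473 nt on 1 chromosome(s)
#>   transcripts: lncRNA=10, protein_coding=25, pseudogene=15, repeat=8
#>   known proteins: 25 | variant specs: 5 | true novel peptides: 442

run_demo(seed = 42, outdir = "demo_run")
#> darkpep pipeline manifest (seed 42 )
#>   simulate    transcripts=58, true_novel_peptides=442
#>   builddb     entries=722, targets=361
#>   psms        psms=3400, decoys=400
#>   fdr         novel_target_psms=1000, novel_decoy_psms=200, discarded_psms=2200, accepted_peptides=257
#>   annotate    placements=260, loci_all=26, loci_min_k=26
#>   quant       loci=26, tested=26, significant=3
#>   tissueclass nonspecific=9, tissue_specific=13, ubiquitous=4
#>   epitopes    nine_mers=2457, candidates=10, loci_with_candidate=8
#>   rnascan     reads=50, placements=5
```

Reading the manifest: of 3,400 simulated PSMs, the 2,200 that match the
known proteome, variant entries or out-of-class decoys are discarded
before novel-class FDR; 257 novel peptides pass at 1% class-specific
FDR and collapse onto 26 novel coding loci with at least two unique
peptides each. The quant stage plants tumor effects and tests them
(with 10% missing cells the summed label-free values are noisy, so
only a few loci reach significance — see the methods vignette); the
epitope stage scores 2,457 locus 9-mers and finds 10 passing the
0.5%-rank and 1.5-fold criteria; the rnascan stage confirms simulated
read support over the first placements. Every stage's tables are
written under `demo_run/`.

The methods vignette (`vignettes/darkpep-methods.Rmd`) documents the
model, every threshold and its default, the synthetic generator's
assumptions, and known limitations.

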