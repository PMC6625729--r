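---
title: "Scanning, scoring and rewriting pyrimidine-periodic SECReTE motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning, scoring and rewriting pyrimidine-periodic SECReTE motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secretescan)
```

## The motif and the model

mRNAs encoding secreted and membrane proteins (the secretome) are enriched,
across organisms from budding yeast to human, in a simple periodic sequence
signal: uninterrupted runs of nucleotide triplets that carry a pyrimidine
(C or U) at a fixed position of the triplet. In coding sequence the three
possible positions correspond to the codon positions, written YNN, NYN and
NNY. Runs at the second position are partly explained by the codon
composition of transmembrane domains (codons for Leu, Ile, Val and Phe all
carry U there), but third-position (NNY) runs are not reducible to any
protein-level feature, behave like a *cis*-regulatory element (SECReTE:
secretion-enhancing cis regulatory targeting element), and synonymous
mutations that strengthen or weaken them change protein secretion.

`secretescan` implements this analysis end to end:

* a **scanner** (`find_runs()`, `scan_transcript()`) for maximal
  triplet-periodic runs of a two-letter nucleotide class, with the SECReTE
  definition (class Y, at least 10 triplets) as the default and the other
  two-letter classes (R, K, M, S, W) available for specificity controls;
* **set statistics** (`fraction_with_motif()`, `chi2_enrichment()`,
  `threshold_sweep()`, `roc_auc()`, `bh_fdr()`) contrasting secretome
  against non-secretome gene sets;
* a **codon-shuffle permutation test** (`permutation_z()`) for whether a
  gene's signal exceeds what its codon usage alone produces;
* **masking** (`excise_protein_intervals()`, `rescan_after_excision()`) to
  remove TMD- and signal-peptide-coding codons before rescanning;
* descriptive statistics: motif distribution over regions and along the
  gene (`region_distribution()`, `positional_distribution()`), RRY purity
  (`rry_score()`) and pyrimidine content;
* a synonymous **recoder** (`plus_secrete()`, `minus_secrete()`,
  `recode_report()`) with CAI bookkeeping;
* a seeded **synthetic transcriptome generator**
  (`generate_transcriptome()`) so every stage is testable without any
  genome download, and a CLI (`secrete_cli()`).

## Scanner semantics

A run at phase $p \in \{0,1,2\}$ of a sequence $s$ is a maximal set of
consecutive checked positions $p, p+3, p+6, \dots$ (0-based) whose bases
all belong to the class. Key choices:

* **Maximality.** Each reported run cannot be extended by one triplet in
  either direction; sub-runs are never reported. The *count* of a
  transcript is the number of maximal runs at or above the threshold,
  summed over the configured regions and phases.
* **Frame anchoring.** CDS phases are anchored to the reading frame, so
  phase 2 is the third codon position (NNY). UTRs have no frame; each UTR
  is scanned at all three offsets from its own 5' end, and a poly-pyrimidine
  stretch therefore legitimately reports a run at every offset. A `FULL`
  mode concatenates 5'UTR + CDS + 3'UTR for whole-gene profiles; in
  per-region mode runs never cross region boundaries.
* **Ambiguity codes.** Input is normalized to A/C/G/T/N (U becomes T;
  other IUPAC codes become N). An N at a checked position breaks a run —
  the conservative reading, since an ambiguous base cannot be asserted to
  be a pyrimidine.
* **Coordinates.** Internally 0-based (`start_nt` is the start of the
  run's first triplet, so the first checked base is `start_nt + phase`);
  all emitted tables are 1-based inclusive and say so in their headers.
* **Degenerate inputs.** Empty regions yield no hits; CDSs whose length is
  not a multiple of 3 are excluded at assembly time (and counted), because
  codon-position analysis is undefined for them.
* The stop codon is part of the CDS as scanned (the coding region runs
  from start codon through stop codon).

The run-length threshold is a tunable (`min_triplets`, default 10,
unitless: number of triplets). Below 10, motif counts track gene length —
short runs arise by chance in proportion to sequence length — while at 10
and above the length dependence collapses and the secretome/non-secretome
separation (ROC AUC) peaks; `threshold_sweep()` reproduces exactly this
calibration on any labeled gene set and reports the argmax-AUC threshold.
The ROC score is the per-gene motif count at the evaluated threshold
(binary presence can be passed instead; the AUC is the tie-corrected
Mann–Whitney statistic either way, identical to the trapezoidal area under
the empirical curve).

## RRY purity

Because poly-pyrimidine sequence trivially satisfies NNY at every offset,
motifs are additionally scored against the stricter purine–purine–pyrimidine
template: each base scores 1 if it matches the cyclic R,R,Y pattern, the
mean is taken over the motif, and the maximum over the three template
offsets is reported. A perfect RRY repeat scores 1; poly-pyrimidine scores
exactly 1/3 (only the template-Y positions can match). CDS-resident motifs
tend toward high RRY scores, UTR motifs toward high pyrimidine content;
`rry_score()` and `pyrimidine_content()` quantify both.

## Permutation test

For each gene the codon order of the CDS is shuffled (default 1000 times;
the codon multiset, hence codon usage and GC content, is conserved), and

$$Z = \frac{\mathrm{observed} - \mathrm{mean}}{\mathrm{SD}}$$

over the shuffled values. The statistic is the length in triplets of the
longest run at the phase under test (`max_run_length`); the motif count at
the threshold is available as an alternative (`statistic =
"secrete_count"`), since either reading of "the motif signal per gene" is
defensible — the default is the run length, which is defined without
reference to a threshold. When every shuffle gives the same value
(e.g. a CDS whose third positions are all pyrimidines already), the SD is
zero; such genes are flagged `degenerate`, reported with $Z = 0$, and
excluded from `significant_fraction()` denominators by default. A fraction
of genes with $Z \ge 1.96$ well above what label-free sequences produce
(about 4% under the null at these settings — the statistic is discrete and
right-skewed, so the exceedance probability is not exactly the Gaussian
2.5%) indicates enrichment beyond codon usage.

Randomness is reproducible and order-independent: every gene draws from a
stream derived from `(seed, gene_id)`, so adding or reordering genes does
not change any other gene's result.

## Masking

TMD and signal-peptide annotations are residue intervals (1-based,
inclusive) on the encoded protein; excision removes whole codons,
concatenates the flanks, and rescans in excised-sequence coordinates.
Concatenation can in principle create a new run across the junction; the
scanner reports such runs as-is — whether they occur is a property of the
data, not a rule to enforce. Only the specified codons are removed; the
stop codon and UTRs are untouched.

## Recoding

`plus_secrete()` substitutes third-position A→T and G→C wherever the
substituted codon encodes the same amino acid; `minus_secrete()` applies
the reverse (T→A, C→G). The synonymy guard is the invariant: the protein
is never changed, substitutions that would change it are skipped and
counted, and stop codons are automatically untouched. Consequences worth
knowing:

* both directions are idempotent;
* only third codon positions ever differ between input and output;
* per-codon third-position pyrimidine coverage is monotone, and therefore
  so are motif *presence*, the longest run length, and the total number of
  triplets inside qualifying runs, at every threshold. The raw *count* of
  maximal runs is monotone at the working threshold in practice, but can
  move the "wrong" way at permissive thresholds: a (+) substitution that
  bridges two runs merges them (two runs become one longer run), and a (−)
  substitution can split one long run into two. This is a bookkeeping
  effect of maximality, not a loss of signal;
* (−) recoding cannot remove pyrimidines whose removal would change the
  protein, so some motifs survive — notably NYN-based runs, which the
  third-position rule does not address at all.

CAI is the geometric mean of relative adaptiveness $w = f/f_{\max}$ over
the codons of the CDS, excluding stops and single-codon amino acids (Met,
Trp), the standard convention. The package ships a clearly-labelled
*synthetic* usage table for examples; real analyses should supply an
organism table (`read_codon_usage()`). Under a flat table CAI is
identically 1, which makes the bookkeeping visible but not informative.
UTR recoding (`recode_utr()`) has no synonymy constraint and substitutes
unconditionally at every position, matching how a 3'UTR is rewritten when
planting the motif into a reporter construct. Secondary-structure free
energies are not computed; externally computed values can be carried
alongside reports.

## The synthetic generator: what it emulates, what it does not

`simulation_spec()` defaults define the study conditions used throughout
the tests and the acceptance script, chosen once as a desk-scale analogue
of a secretome contrast:

| parameter | default | rationale |
|---|---|---|
| genes | 400 secretome + 400 non-secretome | large enough for stable fractions/AUC, small enough to scan in seconds |
| CDS length | 200–600 codons | typical protein lengths |
| 5'UTR / 3'UTR | 20–150 / 50–300 nt | yeast-like UTR scales |
| background usage | uniform over the 61 sense codons | third-position pyrimidine probability ≈ 0.49, so chance SECReTE10 runs occur at realistic rates without importing an organism table |
| planted NNY motifs | 10–14 triplets in 85% of secretome; 5–9-triplet decoys in 25% of non-secretome | strong but imperfect class separation |
| planted TMDs | 18–28 residues in 50% / 20% of the classes | hydrophobic-stretch scale and prevalence |

CDS planting forces the third positions of a window to pyrimidines using
synonymous choices where the amino acid admits one, resampling the amino
acid from the pyrimidine-admitting set otherwise (Lys, Glu, Gln, Met and
Trp have no synonymous pyrimidine-ending codon, so exact planted lengths
are unattainable by synonymy alone); both flanking triplets are forced to
purines so each planted run is maximal at exactly its recorded length and
the truth table is exact. UTR planting substitutes checked positions
directly. TMD planting substitutes (rather than inserts) hydrophobic
codons, keeping lengths within the sampled range.

The generator emulates the statistical contrasts — class-dependent motif
prevalence, NYN signal from TMDs, NNY signal from third-position runs,
permutation-null behaviour — and deliberately not the biology it does not
need: no introns or isoforms, no organism codon bias by default, UTR base
composition uniform, signal-peptide regions annotated but not
compositionally distinct. Passing tests therefore demonstrate correctness
of the machinery on sequences with known ground truth, not genome-scale
effect sizes; on real data the non-secretome baseline, UTR motif density
and group fractions will differ. One visible consequence of the defaults:
with decoys in only a quarter of the negatives, thresholds 10 and 12
separate the classes almost equally well and the argmax-AUC threshold can
land on 12 — the sharp threshold-10 recovery requires the planted
contrast itself (all positives ≥ 10, all negatives ≤ 9), which is how the
calibration experiment is constructed.

## Numerical and design choices

* Chi-squared tests are Pearson, df = 1, without Yates continuity
  correction (gene-set sizes make the correction immaterial and the plain
  statistic is the conventional report); zero marginals are an error, not
  a silent NA. Families of tests (e.g. the six NNX classes) are corrected
  with Benjamini–Hochberg (`bh_fdr()`).
* AUC ties are handled by average ranks; `roc_auc()` errors on
  single-class input rather than returning 0.5.
* The Kolmogorov–Smirnov statistic accompanies ECDF comparisons of
  external per-gene values (`ecdf_compare()`) as the numeric summary of a
  plot-level comparison.
* Region densities normalize motif counts by the mean length of the
  region across genes; genes lacking a UTR are excluded from that UTR's
  mean and from UTR group comparisons.
* Motif tables are written with full double precision for scores, so
  write → read round trips are exact.
* Problem sizes in the test suite (10,000 sequences for scanner–oracle
  equivalence, 1,000 CDSs for recoding invariants, 500 genes × 200
  shuffles for permutation calibration) were chosen to make the checks
  statistically meaningful while keeping the whole suite comfortably
  under a minute per block on one CPU.

## Known limitations

* The scanner operates on provided sequences; it does not predict TMDs or
  signal peptides (they are inputs) and does not fold RNA.
* UTR scanning reports a poly-Y stretch at up to three offsets; when a
  per-gene "number of motifs" must not double-count offsets, restrict
  `phases` or deduplicate by interval downstream.
* The permutation null conserves the codon multiset only; dinucleotide
  composition across codon boundaries is not separately conserved.
* GFF3 ingestion assumes transcript-space, plus-strand feature
  coordinates on the supplied FASTA records.

## A worked example

```{r}
sim <- generate_transcriptome(simulation_spec(
  n_secretome = 40, n_non_secretome = 40, seed = 42))
labels <- vapply(sim$transcripts, function(t) t$is_secretome, logical(1))

sw <- threshold_sweep(sim$transcripts, labels,
                      cfg = scan_config(regions = "CDS"))
sw
attr(sw, "best_threshold")

tr <- sim$transcripts[[1]]
head(scan_transcript(tr, scan_config(min_triplets = 10)))

rp <- recode_report(tr, "minus", scan_config(phases = 2, regions = "CDS"))
rp
```
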