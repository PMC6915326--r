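---
title: "Methods: the CUIC motif, its structural context, and the interface-index"
author: "cuic package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CUIC motif, its structural context, and the interface-index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuic)
```

## Scope

Ribosomal-protein (RP) mRNAs share a short pyrimidine-rich element in their
5' UTRs — the cis-element upstream of the initiation codon (CUIC), consensus
`YYYYTTYC` — typically located within 100 nt of the start codon and exposed
in a single-stranded loop. This package implements the analysis chain around
that observation: motif scanning and positional classification, 5'-end and
TOP-like isoform calls, motif-anchored secondary-structure profiling,
CLIP-cluster binding-specificity scoring for RNA-binding proteins (RBPs),
the protein–rRNA interface-index, and the statistics that relate structural
position to transcript abundance. Every stage has a paired synthetic-data
generator with exact ground truth, so the full pipeline can be exercised and
validated without any external download.

## Coordinates and the motif model

All transcript coordinates are 0-based and half-open, matching BED
conventions. On a 5' UTR of length $L$, position $L$ is the first nucleotide
of the AUG; a motif hit $[s, e)$ therefore has

$$d = L - e$$

as its distance to the initiation codon, and $d = 0$ means the motif abuts
the start codon. The distance is measured from the motif *end* (the
motif edge nearest the AUG). This anchor choice is a genuine free parameter
— the alternative (motif start) shifts every distance by 8 nt — and
the scanning functions expose both the hit start and end so either
convention can be derived.

Scanning (`scan_cuic()`) is IUPAC-degenerate, case-insensitive, treats U and
T identically, and reports **all** matches including overlapping ones. A
transcript is called CUIC-positive (`classify_cuic_gene()`) when at least one
hit satisfies $d < 100$ — a strict inequality, following the element's
defining rule. The *best* hit per transcript is the one with minimal $d$,
ties resolved in favour of the 3'-most start, reflecting the biological
emphasis on motifs immediately upstream of the AUG. The characteristic
positional band, 20–80 nt upstream, is evaluated with inclusive ends
(`distance_band_fraction()`); the band endpoints are parameters.

The consensus `YYYYTTYC` admits $2^5 = 32$ of the $4^8 = 65{,}536$ possible
8-mers (`count_consensus_words()` computes the degeneracy product; the test
suite re-derives the count by exhaustive enumeration).

### 5'-end analysis and TOP-like classification

Observed transcript 5' termini are expressed as signed offsets to the best
hit's motif start (`relative_end_offsets()`); an isoform is called
*truncated at the CUIC region* when $|\text{offset}| \le 10$ nt. The 10-nt
tolerance is a default, not a measured quantity: the underlying data show 5'
ends concentrated at the motif but publish no numeric window, so the
parameter is exposed (`tol`).

A 5' end is TOP-like (`is_top_like()`) when the first nucleotide is C and
the first 5 nucleotides are all pyrimidines. This is the standard 5'
terminal oligopyrimidine definition from the TOP-mRNA literature (cap-adjacent
C followed by a pyrimidine run); the run length is configurable because
published definitions vary between 4 and 15.

## Secondary-structure profile

Dot-bracket structures are consumed as input (`parse_dotbracket()`,
`read_vienna()`); the package deliberately performs no thermodynamic
folding. Structures are restricted to the plain `(`, `)`, `.` alphabet —
pseudoknot alphabets are rejected rather than silently flattened, because a
pseudoknotted "paired" call does not mean the same thing in a profile.

`fold_maxpair()` is a deterministic Nussinov-style maximum-base-pairing
folder (AU/GC/GU pairs, minimum loop 3, traceback pairing each 5' base with
its largest admissible partner). It exists so that self-contained analyses
and tests can produce structures; it is a combinatorial optimum, not a
minimum-free-energy prediction, and the two can differ substantially. Its
pair counts are verified against exhaustive enumeration of all nested
structures for short sequences.

The profile (`paired_fraction_profile()`) aligns each motif-bearing
transcript at its anchor (default: motif start), averages the per-nucleotide
paired indicator at each offset in $-H..H$ ($H = 50$ by default), and then
applies a centered moving average of width 7 across offsets. Three numerical
choices matter:

* the per-offset denominator counts only transcripts whose UTR covers that
  offset, and these counts are reported alongside the means, so profile
  edges are interpretable;
* at the ends of the offset range the moving average uses the available
  neighbours only (no padding);
* `window = 1` disables smoothing exactly, which the tests exploit: on
  synthetic structures the unsmoothed profile is identically 0 over the
  planted motif footprint.

## CLIP specificity score

For one RBP, with $N$ CLIP clusters on RP transcripts and $n$ of them
overlapping their transcript's CUIC region,

$$\text{score} = n / N \in [0, 1].$$

The *CUIC region* is the motif footprint extended by a symmetric flank
(default 10 nt, clipped to the UTR). The flank default is a design choice —
the region's extent is not defined in the source analyses — so
`specificity_scores()` callers should report the flank used; scores are
monotone non-decreasing in the flank, which the suite checks. Intervals are
half-open and abutment is not overlap. Clusters are de-duplicated on
(rbp, transcript, start, end, dataset) before counting, all datasets of one
RBP are pooled, and RBPs with fewer than 5 clusters on RP transcripts are
excluded as unstable (a guard, also configurable). Ranking is by descending
score, then descending cluster support, then name (`rank_rbps()`).

## Interface-index

For a protein chain of the assembled ribosome with $R$ resolved residues of
which $I$ interface the rRNA,

$$\text{interface-index} = I / R .$$

Residues missing from the deposited model are excluded from the denominator
(only residues with at least one resolved heavy atom count). Two interface
criteria are provided:

* **dsasa** (default): a residue is interface when its solvent-accessible
  surface area on the isolated chain exceeds its SASA in the complex by
  more than 1.0 Å² — the buried-surface logic used by standard
  interface-residue tools. SASA is Shrake–Rupley: probe 1.4 Å, 960
  quasi-uniform points per atom (golden-section spiral), element radii
  C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Å, hydrogens ignored. The 960-point
  quadrature gives ~1% accuracy on a free atom, verified against the
  closed-form sphere area $4\pi(r + w)^2$.
* **contact**: any heavy atom within 5.0 Å of any partner heavy atom. This
  mode is exact and cutoff-transparent, and is the mode the synthetic
  fixtures validate exactly; it exists because the ΔSASA cutoffs used in the
  original structural analyses are not published, so dsasa results should be
  treated as cutoff-dependent.

Small-subunit proteins are scored against the 18S rRNA chain; large-subunit
proteins against 5S + 5.8S + 28S, via a user-supplied chain-role table
(`read_complex_pdb()`). Altloc conformers keep the highest occupancy. Chains
with index strictly above 0.6 are classified *penetrated* (core-embedded or
core-threading), the rest *surface*; the threshold is configurable and the
strictness at the boundary (0.6 itself is surface) is asserted in the tests.

Both modes are invariant under rigid-body motion of the whole complex. For
contact mode this is exact; for dsasa mode the residue *set* is stable
because quadrature noise (the sample sphere does not co-rotate) is far below
the 1.0 Å² cutoff for genuinely buried residues.

## Bias statistics

`abundance_bias()` splits RPs into abundant (FPKM strictly above 100, the
conventional cut for axonally abundant transcripts) and non-abundant groups
and reports: the group mean indices, a two-sample Kolmogorov–Smirnov test
between the two index *distributions* (not merely the means), Fisher's exact
test on the 2×2 table (high vs low index) × (abundant vs non-abundant), and
the fold depletion

$$\text{fold} = \frac{\Pr(\text{index} > 0.6 \mid \text{non-abundant})}
                      {\Pr(\text{index} > 0.6 \mid \text{abundant})},$$

with the non-abundant group as the reference (an `all`-RPs baseline is
available; the choice matters when the groups are very unbalanced). A zero
high-index fraction in the abundant group is reported as infinite with a
flag rather than an error, since it is a legitimate extreme of small tables.

The test engines are the standard ones: `ks.test` (asymptotic),
`wilcox.test` (tie-corrected normal approximation) and `fisher.test`
(conditional two-sided hypergeometric). For $n + m \le 12$ both the KS and
rank-sum tests switch to exact enumeration over all label assignments,
implemented in the package and verified against independent bitmask-style
enumeration oracles in the suite. All tests are two-sided. Stage-to-stage
abundance ratios use a pseudocount of 1.0 FPKM on both stages before the
log2 ratio, so zero-FPKM transcripts remain usable; with a zero pseudocount
a zero denominator is an error rather than an infinity.

FRAP recovery is the linear normalization
$R_x = (I_x - I_\text{post}) / (I_\text{pre} - I_\text{post})$ applied after
background subtraction; it requires $I_\text{pre} > I_\text{post}$.

## The synthetic benchmark

The generators emulate the statistical structure of the real analyses, with
defaults fixed once:

* **Transcripts** (`gen_transcripts()`): 80 RP and 200 non-RP UTRs of
  100–300 nt; the motif is planted in 70% of RP transcripts (the prevalence
  observed in RP-coding mRNAs) at a distance drawn uniformly from 20–80 nt
  (the observed positional band). The background is purine-only by default
  so the pyrimidine consensus has an exactly zero background hit rate and
  recovery can be asserted with zero error; `background = "uniform"` is the
  hard mode in which spurious matches occur and false-positive handling is
  exercised. FPKM values are log-normal, RP transcripts drawn ~10-fold more
  abundant.
* **Structures** (`gen_structures()`): the planted motif footprint is forced
  unpaired and enclosed by a nested stem over the flanking positions. These
  are *positional* constructions — pairing is imposed regardless of sequence
  complementarity — because their purpose is to carry an exact, known
  profile signal through the same code path that consumes externally folded
  structures; purine-only flanks could never form a sequence-consistent
  stem, and making the flanks complementary would change the motif-scanning
  ground truth.
* **CLIP** (`gen_clip()`): each cluster overlaps its transcript's CUIC
  region with probability ρ and is otherwise placed strictly outside it, so
  the expected specificity score equals ρ with a zero baseline; recovery is
  asserted within 3 binomial standard errors.
* **Toy complexes** (`gen_toy_complex()`): an RNA backbone of
  phosphate-spaced atoms (5.9 Å) and a peptide whose residues sit at 4 Å
  (interface) or 15 Å (non-interface), so contact-mode recovery of the
  planted fraction is exact, not approximate.
* **Abundance bias** (`gen_biased_abundance()`, `gen_depletion_groups()`):
  the logistic generator ties abundant-class membership to the centered
  index with strength β (β = 0 is the null); the depletion generator plants
  an expected fold depletion analytically — with $n_a$ abundant of $n$
  total and overall high fraction $h$, the abundant-group high probability
  is $q_a = nh / (n_a + f\,n_{\bar a})$ and the non-abundant probability
  $f q_a$ — under the study-scale conditions of 80 RPs, 30 abundant, 25%
  high-index.

Determinism: one global seed fans out to named per-generator substreams
(`substream_seed()`), so outputs are byte-identical for identical
configurations and adding a generator does not shift existing streams.

### Calibration replicates

Fisher's exact test is conservative: under the null its true rejection rate
at $\alpha = 0.05$ sits below the nominal level, close to the lower edge of
the calibration band the suite asserts ([0.03, 0.07]). At 2,000 Monte Carlo
replicates the standard error of the estimated rate (~0.004) is comparable
to the distance from that edge, so the calibration check uses 20,000
replicates, which makes the Monte Carlo error small relative to the band.
The power check (planted 5-fold depletion, Fisher p < 0.05 in at least 80%
of runs) uses 500 replicates as stated with the condition. Problem sizes
elsewhere in the suite — 1,000 random sequences for the scanning oracle,
sequences up to 12 nt for structure enumeration, all 2×2 tables with total
≤ 40 for the Fisher oracle, 200 simulated RBPs of 100 clusters — were chosen
to make the corresponding oracles exhaustive or tightly binding at desk
scale.

## What passing tests do and do not show

The synthetic data reproduce the *logical* structure of the real analyses
(planted signals, known effect sizes, exact ground truth), not their
biological texture: real UTRs have mixed base composition, real structures
come from thermodynamic ensembles rather than positional construction, real
CLIP clusters have variable widths and protocol biases, and a real ribosome
has ~80 chains with missing residues and modelled gaps. Green tests
therefore certify the correctness of the computations — scanning,
interval arithmetic, SASA, the statistics — and the recoverability of
planted effects at the stated sizes; they do not certify that the
biological conclusions transfer to any particular dataset. Dataset-level
numbers for the real biological system depend on a specific transcriptome
annotation, RNA-seq data and a deposited ribosome structure, and are not
recomputable without those inputs; the synthetic pipeline reproduces their
*pattern* at the generator's planted effect sizes (see
`scripts/acceptance.R`).

## Known limitations

* The dsasa interface criterion depends on unpublished upstream cutoffs;
  absolute indices from dsasa mode should be compared only within one
  parameter setting. Contact mode is the reproducible reference.
* `fold_maxpair()` maximizes pair count; it is not a substitute for
  free-energy folding when structure accuracy matters.
* The KS p value is asymptotic except at very small sizes; for $n + m$
  between 13 and ~30 it is conservative.
* Genome-coordinate scanning, motif discovery, and CLIP peak calling are out
  of scope; inputs are transcript-space.
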