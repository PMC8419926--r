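---
title: "Chromatin accessibility and strand-aware TF footprinting for fungal ATAC-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin accessibility and strand-aware TF footprinting for fungal ATAC-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatac)
library(tibble)
```

## The problem

ATAC-seq reads out chromatin accessibility: the Tn5 transposase inserts
sequencing adapters preferentially into open chromatin, so the genome-wide
density of insertion events maps accessible regulatory regions, and narrow
insertion-depleted intervals *inside* accessible regions mark DNA shielded
by a bound protein — transcription-factor footprints. In compact fungal
genomes (the motivating system is *Aspergillus niger*), promoters are short
and footprints cluster within a few hundred base pairs of the TSS, which
makes the assay a practical genome-wide screen for active cis-regulatory
elements.

The hard part is telling a *protein* footprint from a *pseudo* footprint
caused by Tn5's sequence preference. The discriminating signal this package
implements is strand asymmetry: around a genuinely bound, oriented motif,
the insertion-frequency profiles of the two strands are not mirror images
of each other, whereas deproteinised (naked) DNA — and the same sites in a
strain where the factor has been deleted — show mirror-symmetric profiles.
The package provides the full path from aligned fragments to that
criterion, plus a seeded simulator so every stage can be scored against
ground truth.

## Pipeline and models

### Insertion events

Each sequenced fragment is bounded by two Tn5 cuts. Because Tn5 inserts as
a dimer and duplicates 9 bp, read starts on the + strand are shifted by
+5 bp and read ends on the − strand by −5 bp, centring each event on the
insertion midpoint (`insertion_events()`, defaults `shift_plus = 5`,
`shift_minus = -5`; the ENCODE-style +4/−5 is available through the same
arguments). We take the − strand cut at the last covered base (`end − 1`)
before shifting. Duplicate fragments are collapsed on the exact
(chrom, start, end) key. Fragments are classified by length: < 100 bp
nucleosome-free (NFR), 180–247 bp mononucleosomal, > 247 bp
oligonucleosomal; lengths in [100, 180) are labelled ambiguous and excluded
from class-specific analyses because they cannot be attributed cleanly to
either class.

### Library QC

`length_histogram()` + `estimate_period()` quantify the nucleosomal
fragment-length ladder. The period is the lag of maximal autocorrelation of
the smoothed histogram after subtracting a 301-bin moving average (which
removes the overall exponential decay), searched over 120–300 bp. Two
numerical choices matter:

* only lengths ≥ 100 bp enter the autocorrelation — the large
  sub-nucleosomal peak otherwise contributes a spurious lag at the
  NFR-to-mononucleosome spacing (~160 bp) that can outweigh the true
  200 bp repeat;
* the autocorrelation uses unbiased (divide by `n − lag`) normalisation, so
  the shrinking overlap window does not bias the argmax towards small lags.

The confidence score is a z-score of the observed peak against the maximal
autocorrelation of 50 within-histogram shuffles passed through the same
smoothing/detrending; estimates below z = 3 (or from fewer than 100
fragments) are flagged unreliable. A white-noise histogram therefore flags
itself: its observed maximum is a draw from the same null.

`tss_matrix()` builds gene-by-offset insertion matrices oriented along the
gene (negative offsets upstream for both strands) and per-class mean
profiles; insertions in the flanks of two genes count for both rows — the
matrix is per-gene, not a partition. `sample_correlation()` computes
Spearman correlations of 1-kb-binned genome-wide insertion counts, the
standard replicate diagnostic.

### Peak calling

`call_peaks()` scans fixed 200 bp windows (step 50) and tests each
combined-strand count against a Poisson null whose rate is the maximum of
the genome-wide insertion rate and the local rates in 5 kb and 10 kb
neighbourhoods — the dynamic local-lambda device that makes the test robust
to broad coverage differences. Window p-values are BH-adjusted genome-wide;
windows with q ≤ 0.05 are merged across gaps ≤ 100 bp, merged peaks
shorter than 100 bp are dropped, and the summit is the maximum of the
50 bp-smoothed insertion density. Peaks are annotated by summit position
with precedence promoter > TTS > exon > intron > intergenic, where the
promoter is the 1 kb window upstream of a TSS (gene-strand aware) and the
TTS window is ±300 bp (the source analyses do not state a width; 300 bp is
a conventional choice). Peak-set comparisons (`overlap_sets()`) report
common counts on each side because overlaps need not be one-to-one; a flag
marks disagreement between the two sides.

### Differential accessibility

`differential_accessibility()` takes an insertions-per-consensus-peak count
matrix, scales counts to a common library size, and tests each peak with a
negative-binomial likelihood-ratio test at a common dispersion shared
across peaks. For fixed dispersion the NB mean MLE is the sample mean, so
the LRT is closed-form; the dispersion is a pooled ratio-of-sums moment
estimator, `sum(s² − m) / sum(m²)` over peaks and groups, falling back to
Poisson when non-positive (e.g. single-replicate groups). Log2 fold changes
use a pseudocount of 1 on the CPM scale; BH controls the FDR. The
calibration suite simulates 2 vs 2 designs with 2000 peaks, per-peak means
lognormal around 200 counts and biological CV 0.2 — representative of
replicate fungal ATAC libraries at routine depth — and checks both the
type-I error at nominal 0.05 and the recovery of planted 4-fold changes.

### Footprint detection

`score_candidate()` implements the strand-aware binomial depletion test.
For a candidate window FP of odd size `s` centred at `c` with shoulders of
35 bp: the forward component asks whether + strand cuts in FP are depleted
relative to the upstream shoulder (binomial lower tail with
`n = x(US,+) + x(FP,+)`, `p0 = s/(s+35)`), the reverse component mirrors
this with the downstream shoulder and − strand cuts, and the combined score
is `log10 max(p_fwd, p_rev)` — both strands must be depleted, which is the
property that distinguishes protein protection from sequence-preference
artefacts. We use the plain binomial rather than a beta-binomial because no
dispersion parameterisation is published for this setting; the conservative
max-combination compensates in practice, and the empirical-FDR mode
(threshold chosen on a strand-and-position-shuffled track so that shuffled
yield ≤ 1% of real yield) offers a calibration that makes no distributional
assumption at all.

`detect_footprints()` scores every position of every peak at sizes 11–31 bp
(odd), keeps the best score per position, and selects non-overlapping
footprints greedily in ascending score order down to the −10 threshold,
breaking ties towards smaller sizes and leftmost positions. Candidates
whose window (footprint + shoulders) would leave the peak are skipped.

### The strand-asymmetry criterion

`strand_profiles()` aggregates per-base + and − strand insertion counts
over ±100 bp around motif instances in the motif frame: offsets increase
towards the motif's 3′ end, and minus-strand matches contribute with
offsets negated and strand labels swapped. Motif-body offsets are included
by default (the reference profiles span the motif). The statistic is

S = ½ · Σₓ | g₊(x) − g₋(−x) |,

the total-variation distance between the + profile and the offset-mirrored
− profile, each normalised to a probability distribution over offsets. S is
scale-free, lies in [0, 1], and is exactly 0 under the reverse-complement
symmetry that holds in expectation for naked DNA *regardless of Tn5
sequence preference* — sequence bias is reverse-complement symmetric, so it
cancels in the mirror comparison. Protein binding at an oriented motif is
the one mechanism in this system that breaks the symmetry.

The significance test (`permutation_test()`) flips each instance's
orientation with probability ½ and recomputes S. This null preserves every
instance's total signal and positional clustering, destroying only the
coupling between strand and motif orientation — precisely the quantity the
criterion isolates. `p = (1 + #{S_null ≥ S_obs}) / (n_perm + 1)`. A site
set is called **bound** only when the permutation test rejects *and* S
exceeds the 95th bootstrap percentile of every supplied control condition
(TF-deletion, naked DNA), mirroring the three-panel comparison the
criterion derives from; disagreement between controls yields
`indeterminate`. `compare_conditions()` reports S differences with
instance-level bootstrap CIs. Profiles are reported as per-instance means;
per-library normalisation would only rescale both strands and S is
invariant to that.

### Motif scanning and expression integration

`scan_motif()` does exact IUPAC consensus matching on both strands via
`Biostrings::vmatchPattern(fixed = FALSE)`, with gap shorthand
(`CGG-N8-MGG`) and `(C/A)`-style alternatives normalised first; palindromic
double-hits are reported once on the + strand. Enrichment
(`motif_enrichment()`) is interval-level — hit/no-hit per interval with a
hypergeometric upper tail — because that makes the null exact; the
published passing rule (fold > 5 and p below threshold) is applied to
per-bp hit densities. Instances are assigned to genes whose promoter
(1 kb upstream, gene-strand aware) contains the instance midpoint; an
instance between divergent genes counts for both, as divergent promoters
are common in compact fungal genomes. `integrate_expression()` crosses
target genes with differential-expression tables using the standard DEG
rule (|log2FC| ≥ 1, p < 0.05, direction-selected) and a hypergeometric
overlap test over the expression-table universe.

## The synthetic-data generator

`make_genome()` + `simulate_condition()` generate the study conditions every
calibration in this package runs under. The generator emulates:

* **fragment-length structure** — a mixture of a truncated-exponential
  sub-nucleosomal class (scale 40 bp, < 100 bp; weight 0.55, the dominant
  class in these libraries) and Gaussian modes at k·200 bp (sd 20·√k bp,
  k = 1..3, weights 0.55/0.29/0.16 of the remainder), reproducing the
  decaying nucleosomal ladder;
* **promoter NFRs** — insertion weight ×8 in TSS ± 150 bp for
  sub-nucleosomal cuts; nucleosomal-class cuts are suppressed there
  (×0.15), because a mononucleosomal fragment requires a nucleosome;
* **nucleosome protection** — 147 bp cores on a 200 bp lattice jittered
  with sd 10 bp outside NFRs, insertion weight ×0.15 inside cores;
* **bound footprints** — motif instances planted in promoter NFRs; each is
  bound with probability `occupancy`, and bound instances block insertion
  across the motif ± 7 bp (a bound factor protects more than its core
  motif; ~20 bp total is typical);
* **strand asymmetry at bound sites** — Tn5 integration is enhanced at the
  protein-DNA boundary in a strand-specific way: on the motif's 5′ flank
  the oriented + strand weight is multiplied by `exp(kappa)`, on the 3′
  flank the oriented − strand by `exp(kappa · bias_ratio)` (default ratio
  0.5), over 75 bp flanks and for sub-nucleosomal cuts only. The
  attenuation of the 3′ boost is essential: were the two flank
  perturbations exact mirror images, the profiles would retain
  reverse-complement symmetry and S would stay at its null value no matter
  how strong the bias. A bound protein-DNA complex is structurally
  asymmetric, so unequal perturbation of its two faces is also the
  physically sensible model;
* **conditions** — `naked` removes all protection and bias (uniform
  insertion); `TF-deleted:<motif>` zeroes one motif's occupancy and leaves
  everything else identical to WT.

Fragments are generated by drawing the left cut from the strand-specific
weight vector, a length from the mixture, and accepting the implied right
cut with probability proportional to its weight; rejection sampling tops
the count up to exactly `n_fragments`. Fragments are emitted as
`[p1 − 5, p2 + 6)` so that the downstream +5/−5 shift recovers the
simulated insertion centres exactly. All randomness flows from one seed
(`with_seed()` confines it; nothing touches the caller's RNG state).

What the generator does **not** emulate: Tn5 hexamer sequence preference
(the asymmetry criterion is constructed to be insensitive to it, so
synthetic tests cannot probe that insensitivity empirically), sequencing
error and base quality, mappability structure, PCR duplication beyond a
uniform rate, organellar contamination, and GC-dependent coverage. Passing
the synthetic suites therefore demonstrates correctness of the statistics
under the stated generative model, not robustness to every artefact of
real libraries.

### Reference study conditions

The calibration suites and the acceptance script use one fixed design:
2 chromosomes × 100 kb with 120 genes (500–1000 bp bodies, ≥ 500 bp gaps —
a deliberately gene-dense scale model of a compact fungal genome), 300
target-motif instances (`CCGHCGG`, occupancy 0.9, kappa 2) and 60 decoy
instances (occupancy 0) planted in promoter NFRs, and 10⁵ fragments per
condition. At this depth a protected footprint's shoulders carry ~70–150
cuts per strand, which is what the binomial depletion test needs to reach
the −10 score threshold; the problem sizes keep the whole test suite and
the acceptance script in the minutes range.

## Worked example

```{r example, eval = FALSE}
library(fatac)

genome <- make_genome(2, 100000, 120, seed = 11,
                      gene_length_range = c(500, 1000), min_gene_gap = 500,
                      motifs = tibble(motif = "PrtT", consensus = "CCGHCGG",
                                      n_instances = 300))
cfg <- simulation_config(
  n_fragments = 1e5,
  footprint_spec = tibble(motif = "PrtT", occupancy = 0.9, kappa = 2)
)
wt <- simulate_condition(genome, cfg, "WT", seed = 5)
naked <- simulate_condition(genome, cfg, "naked", seed = 3)

track <- track_from_fragments(wt$fragments, genome)
peaks <- call_peaks(track)
fps <- detect_footprints(track, peaks)

inst <- genome$motif_instances
ctrl <- strand_profiles(track_from_fragments(naked$fragments, genome), inst)
res <- permutation_test(track, inst, n_perm = 999, seed = 1, controls = ctrl)
tidy(res)
autoplot(strand_profiles(track, inst))
```

## Known limitations

* The footprint score assumes cut counts are binomial given the shoulder
  totals; overdispersion from local sequence preference is only addressed
  through the conservative two-strand max and the optional empirical-FDR
  threshold.
* The common-dispersion NB test is designed for the small-replicate
  regimes typical of these experiments; with many samples a per-peak
  dispersion (as in edgeR/DESeq2) would be more powerful.
* `call_peaks()` uses fixed windows on insertion counts; it does not model
  fragment pileup shape, and translation invariance holds exactly only for
  shifts that are multiples of the window step.
* Condition calls from `permutation_test()` require well-matched controls;
  library-depth differences between test and control affect bootstrap
  percentiles only weakly (S is scale-free) but extreme sparsity makes the
  call conservative (`unbound`).
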