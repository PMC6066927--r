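---
title: "rloopshift: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rloopshift: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope and scientific setting

R-loops are three-stranded structures — an RNA:DNA hybrid plus a displaced
single strand — that form co-transcriptionally. Strand-specific R-loop
mapping (DRIPc-seq) reads out the RNA moiety, so signal on a gene's
annotated strand reports template-strand R-loops. When topoisomerase I is
acutely depleted, R-loop signal shifts in both directions: long, highly
expressed genes in gene-poor, lamina-proximal territory gain R-loops over
their bodies, while genes whose promoters and terminators sit on early,
active replication origins lose them.

`rloopshift` implements the full comparative analysis as a reusable,
tested pipeline: HMM peak calling on strand-specific binned coverage,
negative-binomial differential testing of union-peak counts, gene
classification into R-loop gain (RLG) and loss (RLL) classes,
matched-control Monte-Carlo enrichment against chromatin features,
fold-change-binned covariate analyses, strand-aware profiling, and OK-seq
replication-fork-directionality (RFD) segmentation — together with a
synthetic-data generator that plants all of this structure with known
ground truth, so every stage is testable without any external download.

# Coordinates and containers

Interval data live in Bioconductor `GRanges` objects (1-based, closed),
the standard container in this ecosystem; BED and bedGraph files
(0-based, half-open) are converted at the file boundary, exactly as
`rtracklayer` does, and GTF input (1-based, closed) is taken as is.
Round trips through `write_bed()`/`read_bed()` and
`write_bedgraph()`/`read_bedgraph()` are exact.

Coverage is held in a `binned_track`: one value per fixed-width bin per
chromosome (default 100 bp — fine enough to resolve promoter-scale
features on a desk-scale genome), a logical exclusion mask, and the
sample's mapped-read total. Blacklist exclusion (`exclude_regions()`)
masks a bin on any 1-bp overlap — matching the wholesale exclusion of
contamination-prone regions in the assay — and masked bins both break the
HMM chain and are dropped from counting. Depth normalization scales by
`reference / mapped_read_total` with the geometric mean of totals as the
reference: symmetric in the samples and philosophically aligned with the
median-of-ratios normalization used downstream.

# Peak calling

A two-state hidden Markov model (background, peak) with negative-binomial
emissions on raw bin counts is fitted per strand per sample by
Baum-Welch (`fit_hmm()`); NB emissions match the counting noise of the
assay and of the simulator, and a Gaussian-on-log1p fallback is
available. States are identified by ordering (peak mean > background
mean); an all-zero or constant track is a degenerate-fit error.
Forward-backward and Viterbi recursions are in compiled code; Viterbi
ties break toward background, so ambiguous bins are never called peaks.

`decode_peaks()` has two modes:

* **standard** — maximal runs of Viterbi peak-state bins;
* **high sensitivity** — bins with posterior peak probability at least
  `p_core` (0.9), or called by Viterbi, seed peaks; seeds are extended
  outward through contiguous bins with posterior at least `p_tail` (0.5).
  This is this package's explicit interpretation of a "higher sensitivity
  for lower and trailing signal" decoder; the original modification is
  not published in detail.

Runs closer than `merge_gap` (500 bp) are merged and runs shorter than
`min_peak_length` (300 bp) dropped, in both modes. Because seeds include
all Viterbi bins, every standard-mode peak is contained in a
high-sensitivity peak, so high-sensitivity coverage can never be smaller.

One empirical subtlety is worth recording: for a two-state chain the
posterior-0.5 crossing generically trails the Viterbi switch point by
only a couple of bins, because the posterior at the Viterbi boundary is
close to 0.5 by construction. Substantial tail capture (hundreds of bp
over low trailing shoulders) therefore requires `p_tail` below 0.5; the
test suite demonstrates a 700 bp extension at `p_tail = 0.3` on a
deterministic shoulder construction. Defaults are unchanged — the
sensitivity/precision trade-off belongs to the user.

`union_peaks()` merges peaks present in at least one sample, per strand,
recording contributing samples — the peak universe for testing.

# Differential testing ("NB-lite")

The reference analysis used a standard NB count-testing framework; this
package re-implements a documented, simplified version rather than
wrapping it, so the statistical surface is fully owned and testable:

* **Counting** — `count_in_peaks()` sums raw (un-normalized) strand-
  matched bin counts per union peak per sample.
* **Size factors** — median-of-ratios over rows with all-positive
  counts, renormalized to geometric mean one.
* **Dispersion** — per-row method-of-moments
  `max(0, (s2 - mu) / mu^2)` on normalized counts with within-condition
  variances, a least-squares trend `alpha(mu) = a1/mu + a0` across rows,
  and log-scale shrinkage of (trend-winsorized) raw estimates toward the
  trend with fixed weight 0.7. Winsorizing to `[trend/8, trend*8]` keeps
  zero raw estimates finite and tames outliers.
* **Wald test** — per-row NB GLM with log link, log size factors as
  offsets and one condition coefficient, fitted by IRLS vectorized across
  rows; two-sided p from the standard normal; shrinkage-free log2 fold
  change. The squared standard error carries a finite-sample inflation
  `(m + 1)/m` (m = samples): without it the plain plug-in Wald test is
  measurably liberal at 2 vs 2 (null p < 0.05 fraction near 0.075 at
  peak-scale counts), with it the test sits inside the nominal band.
  This is the same spirit as degrees-of-freedom moderation in
  moderated-t frameworks.
* **Multiplicity** — Benjamini-Hochberg (the de facto default of this
  analysis family; the procedure is not named in the reference).

Calls use the assay's thresholds: a peak is a **gain** iff padj < 0.1
and fold change > 1.25, a **loss** iff padj < 0.1 and fold change < 0.8.
RNA-level differential expression uses the same machinery at 1.5-fold
and padj < 0.05.

This NB-lite will not numerically equal the reference implementation;
the accepted surface is calibration (null p uniformity, false-call rate)
and recovery (planted effects, planted depth factors), which the
acceptance tests check directly.

# Gene classification

Peaks are assigned to every gene whose flank-extended extent
(`TSS - 2 kb` to `PAS + 2 kb`, strand-matched) they overlap; the flank
acknowledges that promoter/terminator R-loop signal extends beyond gene
boundaries, and its exact size is configurable because the reference
never defines its compartment widths. Genes shorter than 5 kb are
excluded. A gene is **RLG** iff gains outnumber losses at least 5:1 with
at least one gain (so 5 gains : 1 loss qualifies), **RLL** for the
mirror image, **none** with no called peaks, otherwise **mixed**.
Compartment annotation for enrichment analyses uses promoter = TSS ± 2 kb,
terminator = PAS ± 2 kb, body = the remainder, with precedence
promoter > terminator > body.

# Matched-control enrichment

Chromatin enrichment of RLG/RLL peak sets is judged against control
peaks from genes unaffected by the perturbation (class none or mixed),
matched per target on genic compartment and, within 0.5 log2 units, on
gene length, gene expression and peak length (tolerances are unstated in
the reference; 0.5 log2 controls confounding while keeping matches
findable on a toy genome, and every relaxation — stepwise doubling, at
most four times — is logged per target). Promoter and terminator
controls are re-positioned to the target's exact offset from the control
gene's TSS/PAS, preserving position within the compartment.

`overlap_enrichment()` reports the observed share of targets overlapping
the feature by at least 1 bp (a minimum-overlap fraction is not used, as
none is stated), the expected share over `n_mc = 249` Monte-Carlo
control sets (one control per target per set, resampled from the 10
matches), their ratio, and `p = (1 + b) / (1 + n_mc)` per direction,
two-sided by doubling. With 124 randomizations the attainable floor is
1/125 = 0.008 — the significance floor the reference reports; 249 gives
finer resolution at trivial cost. The star annotation reflects absolute
observed overlap: below 10% none, 10-25% `*`, 25-50% `**`, above 50%
`***`.

Distances (`distance_to_nearest()`) are edge-to-edge gaps, zero when
overlapping, strand-agnostic, computed by a per-chromosome sorted sweep
(checked against a brute-force oracle in the tests). Distance sets are
compared by a two-sided Mann-Whitney test with tie and continuity
correction, exact by full enumeration when both sides have at most eight
observations. Fold-change binning sorts peaks by log2 fold change (ties
broken by a stable sort on peak id, for determinism), cuts equal-
occupancy bins (sizes differing by at most one) and correlates per-bin
medians (Pearson). Replication-timing phase assignment takes the argmax
of depth-normalized mean phase signal over the peak, ties to the earlier
phase, and compares per-phase fractions against matched controls with
the same Monte-Carlo machinery.

# Profiles

Scaled-gene metagenes divide each gene into 40 bins (minus-strand genes
flipped) and count peak overlaps per bin, normalized by genes per length
category. Signal metaplots extract depth-normalized coverage in a 20 kb
window centered on the TSS or PAS — symmetric about the anchor bin
(2·half + 1 positions), which makes mirror-genome invariance exact at
bin resolution — with template strand defined as track strand equal to
gene strand. Summaries are median (spread SD) or mean (spread SE).
Promoter density around LAD boundaries is signed (negative inside the
LAD) and split by whether the gene transcribes away from or toward the
LAD interior. The RNAP pausing index is the mean ChIP density over
TSS −50..+300 divided by the mean over TSS +300..PAS (windows follow the
common convention; the reference defers to prior work without printing
them), with categories low-expressed (below an expression threshold),
paused (index ≥ 2) and non-paused; a zero body with TSS signal is an
infinite index, paused. TSS ratio profiles divide group-mean depleted by
group-mean control signal with a pseudocount of 0.5 normalized units in
both numerator and denominator to stabilize sparse bins.

# RFD segmentation

`compute_rfd()` forms RFD = (C − W)/(C + W) per bin from OK-seq
Crick/Watson fragment counts, NA below `min_count = 10` fragments (which
bounds the variance of the ratio). `segment_rfd()` smooths the profile
with a 7-bin running mean, differences it, and decodes a three-state HMM
on the increments — ascending (+mu), descending (−mu), flat (0), with
fixed means and a single EM-estimated variance; the referenced original
configuration is not printed, so this fixed-mean drift HMM is this
package's explicit, fully parameterized interpretation. `mu = 0.01` per
1 kb bin was set from the operating-point analysis: it detects both the
canonical planted ramps (slope 0.04/bin) and gentle 200-bin ramps (slope
0.008/bin) while keeping per-bin noise log-odds negative. NA bins break
the chain; ascending runs of at least 5 bins become initiation zones.

Two symmetry subtleties are handled explicitly. First, Viterbi's
tie-break toward the lower state index is not equivariant under the
AS/DS relabeling, and score-neutral boundary bins do occur with discrete
count data (including at float-residue level), so boundary bins whose
emissions tie within 1e-9 log units are canonically reassigned — to flat
when a flat run adjoins, else to the left-hand run; both rules commute
with negation, making "negating the profile swaps AS and DS labels"
hold exactly. Second, full genome mirroring (coordinates reversed and
strands — hence the RFD sign — swapped) preserves the slope sign:
initiation zones map onto mirrored initiation zones, they do not become
termination zones; negation alone, or coordinate reversal alone, is what
swaps AS and DS. The tests assert the mathematically correct statements.

# The synthetic world

`sim_config()` states one toy world and the tests never tune it
per-outcome: 2 chromosomes × 10 Mb with a gene-density gradient, 500
genes (10% RLG, 15% RLL, 25% mixed, the rest invariant — ordinally
matching the observed predominance of mixed/invariant genes), log-normal
gene lengths (median 15 kb; RLG 3× longer, echoing the reported ~2.7-fold
contrast) and expression (RLG 2.5×, within the reported 1.5-3.5×),
two replicates per condition, NB bin counts with dispersion 0.05,
background mean 2 per 100 bp bin, peak signal-to-noise 10, planted gain
and loss effects of ±1 log2 unit (comfortably beyond the 1.25×/0.8× call
gates), and log-normal depth factors (sd 0.15 in log). Gains sit only on
gene-body peaks on the template strand; losses on promoter/terminator
peaks of origin-proximal genes; mixed genes carry exactly one of each. A
30% fraction of gain peaks receives a 1 kb decaying 3' tail — the
trailing signal the high-sensitivity decoder targets.

Chromatin context is planted, not emergent: RLG genes are isolated
(30-60 kb gaps) on the gene-poor chromosome and carry an H3K9me3 patch
(80%) and/or a LAD (50%, with every RLG gene guaranteed at least one of
the two) whose 3' edge sits at the promoter or reaches into the gene
body; RLL genes sit in dense territory with an origin on their promoter
or terminator; a baseline rate (15%) of control-pool genes receives the
same features so matched-control overlap is non-degenerate, with
baseline features kept off the immediate neighbourhood of RLL genes and
baseline LADs confined to gene-poor chromosomes (lamina-associated
chromatin is gene-poor). OK-seq zones ramp RFD linearly from −0.8 to
+0.8 over ±20 kb around origin centers with ~50 Poisson fragments per
1 kb bin; Repli-seq phase is distance-to-origin banded (150 kb per
phase); RNAP ChIP amplifies the promoter-proximal window of paused genes
(index 6) with further TSS accumulation (×1.5) under depletion.

What a green test does establish: the pipeline recovers structure it was
designed to detect, at realistic counting noise, with calibrated error
rates. What it does not establish: performance on real genomes —
sequence-driven artifacts, mappability, copy-number structure, GC skew
and absolute genomic distances (the toy geometry compresses LAD
distances far below the ~200 kb medians seen in real data; only ordinal
relationships are emulated) are all out of scope. Accordingly, the
direction tests assert only the paper-stated contrasts: gains proximal
to H3K9me3/LADs and origin-depleted, losses H3K9me3-distal and
origin-enriched. The loss-versus-LAD distance contrast is not asserted —
the reference makes no such claim, and in the toy world it is not
structurally forced.

# Determinism and numerical policy

Every stochastic step takes a seed and derives independent substreams
from it (`derive_seed()` keeps everything below 2^31); RNG state is
always restored. EM log-likelihoods are monotone up to tolerance with
best-so-far fallback and a warning on non-convergence. Degenerate inputs
error early and loudly: all-zero or constant tracks, empty distance
samples, constant fold changes, missing LADs, fewer than two replicates,
fewer than three usable chromosomes for the density correlation.
Benjamini-Hochberg, median-of-ratios and the exact Mann-Whitney are
checked against independent oracles (`stats::p.adjust`, hand
computation, `stats::wilcox.test`/enumeration) in the test suite; the
compiled Viterbi is checked against exhaustive path enumeration.
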