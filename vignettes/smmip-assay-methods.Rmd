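---
title: "Models and methods behind smmipkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smmipkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smmipkit)
```

smmipkit implements the analysis chain of a targeted screening assay
built on single-molecule molecular inversion probes (smMIPs). This
vignette documents the models, the assumptions behind them, the
defaults, and the places where a design choice was genuinely open —
and why we resolved it the way we did.

## The assay in brief

Each smMIP carries two targeting arms flanking a fixed-length capture
target (110 bp by default) and a 5-base random tag (unique molecular
barcode, UMB) in its backbone. Adjacent probes of an exon tile overlap
by 20–40 bp. After capture, PCR and sequencing, reads sharing a
(probe, UMB) key are PCR copies of one captured molecule; collapsing
them to a single representative makes coverage count molecules. A
5-base tag can distinguish at most 4^5 = 1024 molecules per probe, so
deduplicated per-probe coverage is hard-bounded at 1024.

## Coordinates and panel validation

All coordinates are 0-based half-open internally and in the panel TSV;
BED export is native, and a 1-based inclusive dialect is converted
only at the reader boundary (`read_panel(coords = "one_based")`). A
single internal convention avoids the off-by-one class of CNV exon
bugs.

`validate_tiling()` treats violations as *data*, not exceptions: a
target length different from the panel's capture length and
adjacent-probe overlaps outside [min, max] are reported per probe. A
positive gap between consecutive targets starts a new tile — probes
tile exons, and inter-exon gaps are expected — so gaps are
informational, never violations. Arm-pair uniqueness, by contrast, is
a construction-time error: read assignment keys on arms, so a panel
with duplicate arm pairs cannot be processed meaningfully at all.

Coding coverage is a per-base intersection of the merged probe
footprint with each gene's coding intervals. Reported percentages are
always computed from the inputs; the package never reconciles them
against externally stated values.

## Read structure, assignment and deduplication

The layout of arms and tag on each mate is not standardized across
smMIP library designs. The package (and its simulator) use:

* R1 = extension arm + insert (5'→3')
* R2 = UMB (5 bases) + ligation arm + reverse-complemented insert

Assignment compares both arms positionally (Hamming distance, no
indels) with at most `max_arm_mismatch` (default 1) mismatches per
arm; arms are primer-grade sequences, so positional matching is
adequate and fast at desk scale. Among multiple candidates the
fewest-total-mismatch probe wins; exact ties fall to panel order
(deterministic, and essentially impossible with unique arms). Reads
too short to contain arm + tag are unassigned, not errors. An aligned
SAM/BAM intake (`assignments_from_sam()`) accepts externally mapped
reads, resolving probes by maximal overlap of the alignment span and
recovering the tag from a `name#UMB` read-name suffix — the delimiter
is configurable because upstream pipelines differ.

Deduplication keeps exactly one read per (probe, UMB) group, chosen
uniformly at random under a caller-supplied seed; consensus collapse
is a documented extension point, not the default, to match the
random-discard semantics the assay defines. UMBs containing N cannot
define a molecule: they are excluded from grouping and counted
separately. Identical inputs and seed give byte-identical outputs; the
RNG state of the caller is never disturbed.

Because tags are finite, two distinct molecules can draw the same UMB.
With m molecules over K = 4^5 tags the expected number of distinct
tags is K(1 − (1 − 1/K)^m): at m = 200 this is ≈ 181.6, a ~9% loss
that the tests account for explicitly rather than hiding in loose
tolerances.

## Pool rebalancing

Against the uniform expectation of 1/n reads per probe for an n-probe
pool, a probe is *under*-performing when its proportion falls below
1e-4 **or** its deduplicated reads fall below a strict 30-read floor —
either signal alone triggers the boost; requiring both would leave
marginal probes unrescued, and assay completeness argues for the
conservative OR. A probe is *over*-performing above 1e-2. Proportions
are computed on deduplicated counts by default (raw counts are a
configuration switch): molecules, not PCR copies, measure capture
efficiency. Note the published cut-offs bracket a ~900-probe pool's
uniform expectation by roughly 0.1× / 9×; for much smaller pools the
caller should scale them accordingly (they are plain arguments).

The recipe: under-performers get a 10× phosphorylated concentration
(1.0 µM over the 0.1 µM base); over-performers keep their base
concentration and receive an equimolar *unphosphorylated* competitor,
which cannot ligate and so dilutes effective capture. How strongly the
competitor suppresses capture is not quantified anywhere we know of;
the simulator models it as a 50% effective-capture reduction
(`competitor_factor`, a named parameter that lives only in the
simulator, never in the analysis path).

## Exon CNV calling

The caller is a read-depth method in the ExomeDepth/DECoN family,
re-implemented from its published model structure with every constant
surfaced in `cnv_params()`.

**Aggregation.** Per-probe deduplicated counts are summed into exons,
each probe mapped to exactly one exon by maximal overlap (ties to the
first exon in order; with 20-bp flanks and ≥150-bp introns ties do not
arise in practice). Exon-level windows match how calls are reviewed
and reported (single- and multi-exon events). Exons with zero counts
in more than half the samples are masked and excluded from
normalization, emissions and calls. Batch normalization needs batch
structure: fewer than 17 samples is an error by default
(`enforce_min_batch = FALSE` exists for toy runs, and is used in the
package's own small examples).

**Reference selection.** Candidate references are the other batch
samples ranked by Pearson correlation with the test profile. Walking
down that ranking, the aggregated reference's expected fractions are
recomputed at each prefix and the test-vs-reference beta-binomial
overdispersion ρ re-estimated; the prefix minimizing ρ is kept —
equivalently, accumulation stops once adding samples only increases
it. Two numerical points matter. First, ρ is estimated by method of
moments on the *median* per-exon chi-square statistic (rescaled by the
χ²₁ median) rather than the mean: a test sample's own CNV exons are a
minority, and a mean-based estimate would let them inflate ρ and
flatten the very emissions needed to call them. Second, prefixes are
compared on the *unclamped* estimate (which may be negative —
exon counts are mildly under-dispersed because tag-space saturation
shrinks high counts); ties, which occur in degenerate cases such as
identical clone profiles, prefer the larger reference. At least one
sample is always selected. When the panel contains X-chromosome exons,
reference candidates are restricted to samples of the test's stated
sex (male and female X coverage differ two-fold); without sex
metadata the caller warns and proceeds with all samples.

**Ratios.** Expected fraction per exon φ = reference exon sum /
reference total; the per-exon ratio is observed / (φ × test total).
For a diploid sample the mean ratio is ≈1 by construction. The
plotted `log_norm_cov` is log2 of the size-factor-normalized count
(+1), with size factors from sample totals over unmasked exons.

**HMM.** Three states — deletion, diploid, duplication — along each
gene's exons in order. Emissions are beta-binomial on (observed, test
total) with state-scaled success probability p_s = sφ / (sφ + 1 − φ)
for s = 0.5 / 1 / 1.5: scaling the exon's *odds* keeps p_s a proper
probability and makes a heterozygous deletion halve the exon's
expected share relative to everything else. Entering a CNV state costs
1e-4 per step; staying in one, 0.5 (geometric segment length, mean 2
exons — emissions dominate at realistic depths, so this prior is
deliberately weak). The Viterbi decode is exact; a brute-force
enumeration over all 3^n paths (n ≤ 6) is the test oracle. Calls are
maximal non-diploid segments, scored by the summed log-likelihood
ratio of the segment state against diploid; copy estimates come from
the segment's mean ratio (below 0.25 → 0 copies, else 1; duplications
report "3+"). Single-exon calls are permitted — the point of the
17-sample batch design.

**What the caller can and cannot promise.** Homozygous deletions leave
zero molecules, so their boundaries are recovered exactly.
Heterozygous events are statistical: detection is reliable from ~200×
deduplicated coverage with ≥2 probes per exon, but a boundary exon
whose draw lands high can be dropped from the called segment. Events
spanning a large fraction of the panel inflate the sample's own
normalization total and compress their apparent ratio — irrelevant for
a 23-gene panel, visible on a 2-gene toy. Balanced events, inversions
and gene–pseudogene rearrangements are invisible to read depth by
construction.

## qPCR relative quantification

The assay states the RQ↔copies correspondence (0.5 / 1 / 1.5 ↔ 1 / 2 /
3) but not the Ct→RQ formula; we adopt the standard comparative-Ct
form RQ = E^−ΔΔCt with ΔΔCt = (Ct_target − Ct_reference)_sample −
(Ct_target − Ct_reference)_calibrator and perfect-doubling efficiency
E = 2 by default (E is an exposed parameter for calibrated assays). RQ
is strictly decreasing in ΔΔCt and RQ(0) = 1 exactly. Copy calls use
half-open nearest bands — [0.25, 0.75) → 1, [0.75, 1.25) → 2,
[1.25, 1.75) → 3 — so the bands partition (0.25, 1.75) and the
boundary 0.75 maps to 2 copies; anything outside is `unclassified`
rather than forced into a band.

## Case status, yield and concordance

A case is *diagnosed* when pathogenic/likely-pathogenic variants
satisfy the gene's inheritance model (autosomal recessive: homozygous,
≥2 heterozygous, homozygous CNV, or het SNV + het CNV in the same
gene; X-linked: hemizygous or homozygous). Exactly one AR het P/LP
variant is *partial*; VUS are never diagnostic — classification is
input metadata, not computed, because pathogenicity assessment is out
of scope. Compound heterozygotes are assumed in trans when unphased
and flagged (`phase_assumed`), since phasing data is typically absent.
Yield tables carry exact Clopper–Pearson 95% intervals
(`stats::binom.test`). Concordance requires every truth variant of a
case to be recovered; extra findings never break it. A missed truth
variant lying outside the panel footprint is annotated
`uncovered_target` — a panel-design gap, not a pipeline failure. The
module tallies whatever case table it is given and does not arbitrate
inconsistencies in externally provided denominators.

## The simulator: what it emulates, and what it does not

`sim_config()` defines the study conditions: per-probe capture
efficiency is log-normal(0, σ = 0.3) with an optional fraction of
"poor" probes scaled by `poor_factor` — this reproduces the skewed
coverage distribution and low-coverage tail real pools show, and gives
the rebalancing loop its substrate (the generative form of the skew is
our choice; only the skew itself is observed). Molecules per probe are
Poisson(depth × efficiency × concentration multiplier × copy scale)
with copy scale 0 / 0.5 / 1 / 1.5 from the CNV genotype; each molecule
draws a UMB uniformly and a geometric PCR duplicate count (mean
`pcr_dup_mean`, single-parameter by design); heterozygous SNVs are
Bernoulli(1/2) per molecule; sequencing errors are uniform per base.
Defaults (depth 200, duplicates 2×, error 1e-3, 5-base tag) sit in the
range a practitioner would call typical for this assay class.
Everything is deterministic under the seed, down to FASTQ bytes.

`simulate_counts()` exposes the molecule layer directly (including
tag-collision thinning) so batch-scale CNV experiments need not write
FASTQ; the FASTQ path and the count path agree by construction, which
the full-loop tests verify on small cohorts.

Not emulated: real genome sequence content and low-complexity regions,
pseudogene homology (and hence the capture dropouts it causes),
GC bias, quality-score error profiles, indels, and structural variants
other than exon-level dosage. Passing simulation tests therefore
demonstrates the *pipeline's* correctness under its stated model, not
robustness to those real-data phenomena.

## Problem sizes in the test suite

The packaged experiments use toy genomes of 2–4 genes with 3–14 exons
(~50–110 probes), 17-sample batches at 200× molecule depth, 20-batch
recall/specificity sweeps for the CNV caller, and 50 random geometries
for the panel designer — sizes chosen so the full suite documents the
method's behaviour in minutes on a laptop while keeping every
statistical margin analysable in closed form.

## Known limitations

* Arm matching is Hamming-only; an indel in an arm unassigns the read.
* The pileup SNV caller is a deliberate desk-scale stand-in (no
  realignment, no indels, no quality model) for end-to-end testing;
  production SNV calling belongs to a dedicated caller downstream of
  alignment.
* Overdispersion is a single panel-wide ρ; exon-specific dispersion
  (e.g. from pseudogene cross-capture) is not modelled.
* The rebalancing loop models one round; iterative multi-round
  schedules are out of scope.
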