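---
title: "Classifying DSB repair outcomes and calling drug-screen hits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying DSB repair outcomes and calling drug-screen hits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repairchoice)
```

## The problem

A CRISPR nuclease cut is repaired by one of several competing pathways, and
each pathway leaves a recognizable scar in amplicon sequencing reads:
non-homologous end joining (NHEJ) produces small insertions — typically 1 bp
— and deletions without junction homology; microhomology-mediated end
joining (MMEJ) produces deletions whose junctions carry two or more bases of
exact flanking identity; homology-directed repair (HDR) incorporates the
intended donor substitution precisely; and reads carrying both the donor
edit and an indel form a "mix" class. Counting these per condition turns a
drug-treatment plate into a multidimensional readout — HDR, NHEJ, MMEJ and
cell survival fold-changes against the solvent control — from which
repurposable pathway modulators can be called. `repairchoice` implements
that whole computational path, plus the viability and dose-response
analytics used for synthetic-lethality follow-up, and a seeded generator
that fabricates every input so the pipeline is testable end to end.

## Read classification

Each read is aligned end to end against the wild-type amplicon (and, when a
donor is defined, against the donor-edited sequence) with an affine-gap
Needleman–Wunsch kernel (match +2, mismatch −1, gap open 10, gap extend 1
per base; all configurable). Similarity is matched columns over total
alignment columns, gaps included; `N` never counts as a match. The decision
cascade uses two similarity thresholds and a quantification window:

1. reads below 70% similarity to both references are discarded (as are
   reads with more than 10% `N`);
2. indels count only when they overlap a 20 bp window centred on the
   predicted cut site (Cas9: 3 bp from the PAM-proximal protospacer end);
   substitutions count only at intended-edit positions — any other
   substitution is disregarded as potential sequencing error;
3. no window indel and no intended edit: *unmodified*;
4. all intended edits present, no window indel, and at least 95% similarity
   to the donor-edited sequence: *HDR*;
5. window indel plus all intended edits: *mix*;
6. window indel without the intended edits: *MMEJ* when the read carries
   exactly one window deletion with at least 2 bp of junction microhomology
   and no window insertion, otherwise *NHEJ*.

Two rules deserve comment because the underlying conventions are genuinely
open:

**Window anchor.** A "20 bp window surrounding the gRNA" can be anchored on
the protospacer span, its midpoint, or the cut. We centre it on the
predicted cut site (±10 bp): indels from end-joining arise at the cut, and
this anchor behaves identically for guides of different lengths. The anchor
and width are configuration (`guide_spec()`), not constants.

**Reads that carry the donor edit but fail the 95% bar, with no window
indel.** The cascade above leaves this case undefined. We call it
*unmodified*: substitutions are otherwise disregarded as sequencing error,
and promoting a read to HDR on a noisy background would inflate precise-edit
counts exactly where the evidence is weakest.

**Mix stays separate.** Mix reads are reported as their own class and do not
contribute to the NHEJ or MMEJ metrics; they do count as indel-bearing reads
for the insertion/deletion share.

### Canonical lesion placement and junction microhomology

A deletion inside a repeat can be placed at several alignment-equivalent
positions. All lesions are therefore canonicalized to their leftmost
equivalent placement before any rule fires. For a deletion
`[s, e)` the junction microhomology is the longer of the two exact matches
across the junction — deleted prefix versus retained sequence after the
junction, and deleted suffix versus retained sequence before it — capped at
the deletion length (`microhomology_length()`).

This per-interval quantity is *not* invariant across equivalent placements:
shifting a placement one base right turns `(k_left, k_right)` into
`(k_left + 1, k_right − 1)`. Only the leftmost placement, where
`k_left = 0`, attains the maximum over all placements — which is why the
classifier computes microhomology on the canonical placement. The property
suite verifies on enumerated repeat constructions that the canonical value
equals the maximum over all equivalent placements, so the MMEJ/NHEJ split
never depends on which placement an aligner happened to emit.

Multi-indel reads are attributed to NHEJ: "deletions with microhomology"
describes a single junction, and a read with several window indels has no
single junction to attribute. This is the conservative reading; the 2 bp
cutoff (`mh_min`) is configurable.

## Screen analytics

Per plate, every metric is divided by the mean of that plate's mock (DMSO)
wells; survival comes from blank-corrected resazurin fluorescence,
`(F − blank)/(F_mock − blank)`. Conditions at or below 1000 retained reads
are dropped before any hit calling — low-depth shares are unstable and
would generate false hits.

Hit categories are directional quartile rules. Q1 and Q3 are
linear-interpolation quantiles (type 7 of `stats::quantile()`; the
convention is fixed and exposed) of each mock-relative metric across all
retained drug conditions, pooled over concentrations. A pathway enhancer
must raise its own metric above Q3 while the other two editing metrics stay
at or below Q3; inhibitors mirror this below Q1; the survival-enhancer rule
uses survival alone, as printed. The joint conditions are the point of the
design: a generally toxic drug depresses everything and trips no category,
and a drug that lifts everything is not a pathway hit either. A condition
may satisfy several rules (all are reported; we do not force exclusivity),
and an empty set means neutral.

Relative MMEJ is additionally reported on a detection-limit scale: genetic
ablation of the MMEJ pathway still leaves a residual relative MMEJ of 0.74,
because NHEJ- and MMEJ-derived deletions cannot be scored perfectly and
baseline MMEJ is low while NHEJ is active. Values below 1 are rescaled
linearly so 0.74 maps to 0 (full inhibition) and 1 maps to 1, clamped at 0;
values above 1 pass through unchanged.

Top-hit lists keep each drug once at its best concentration (stable sort,
ties broken by drug id, default top 30). Target-class enrichment compares
the class share among top drugs with the library share, reporting only
classes hit by at least two distinct top drugs. The PCA is a standard
SVD on z-scored metrics with deterministic sign (largest-magnitude loading
positive). For dose-response follow-up, each category's members are ranked
by their defining metric and the shortlist is extended until it contains at
least four non-toxic drugs — relative survival strictly above 0.79, the
survival Q1 of the screen; the threshold can be recomputed from the data —
and follow-up concentrations are the 0.2/0.5/1/2/5-fold ladder around the
screening concentration.

## Viability and dose-response

Survival curves are fitted with the four-parameter logistic
`S(c) = bottom + (top − bottom)/(1 + (c/EC50)^h)` by Levenberg–Marquardt
least squares in log-concentration space, with five starts on an EC50 grid
spanning the dose range and box bounds (`0 ≤ bottom`, `top ≤ 1.5`,
`0.2 ≤ h ≤ 10`) to stabilize sparse designs; the best converged start by
residual sum of squares wins, and survival ranges under 0.05 are flagged
degenerate rather than fitted. Whether published sigmoidal fits constrain
the asymptotes is rarely stated; our bounds are documented and exposed.

EC75 is anchored to an *absolute* surviving fraction of 0.75 relative to
mock — "the concentration that induces 25% cell death" — not 75% of the
fitted span, and is obtained by inverting the fitted curve analytically
(`ec_x()`, any death fraction). The genotype contrast flags synthetic
lethality at doses where the control survives (within 0.15 of 1) while the
repair-deficient genotype's survival ratio falls below 0.7; both tolerances
are arguments.

## What the generator emulates — and what it does not

`simulate_amplicon()` draws a random amplicon (default 150 bp, one MiSeq
read; GC 0.5) with the cut at the midpoint and a donor transversion 4 bp
right of the cut, redrawing until a ≥2 bp repeat pair flanks the cut so
MMEJ alleles exist by construction. `simulate_reads()` draws reads from a
multinomial over generative kinds — MMEJ deletions between repeat copies
(junction microhomology ≥2 bp guaranteed), NHEJ deletions rejection-sampled
to junction microhomology <2 at the canonical placement, 1 bp insertions at
the cut, HDR and mix alleles — then applies uniform per-base substitution
errors. The default outcome mixture (unmodified 30, NHEJ 45, HDR 10, MMEJ
10, mix 5, as percentages) reflects an efficiently edited iPSC target where
NHEJ dominates and MMEJ is low while NHEJ is active.

`simulate_screen()` works at metric level by default (shares drawn
directly; per-read simulation of thousands of conditions adds nothing to
the analytics under test). Its drug library has four strata: *planted*
drugs (4 per category) with clean 2-fold effects on their defining metric;
*inert nulls* (10%) carrying only measurement noise (CV 10%, lognormal);
*background* drugs with per-metric lognormal effects (sdlog 0.6) modelling
the real heterogeneity of a bioactive library — this dispersion was chosen
to reproduce a screen-wide survival Q1 near 0.8, the regime the quartile
rules were designed for; and a strongly *toxic* subset (10% of background,
survival ×U(0.02, 0.5)) whose editing metrics co-reduce with survival
(×√survival) and whose read counts (Poisson, mean 15000 × survival) fall
into the depth filter when toxicity is deep. Fluorescence is
blank + gain × survival + gaussian noise. The default is a single 10 µM
concentration; with a dose ladder, log-effects scale with concentration
relative to the top dose. Sensitivity and specificity of category recovery
are scored on the planted and inert strata; background drugs carry real but
unlabelled effects and are deliberately excluded from both.

The generator does *not* emulate quality-dependent or indel sequencing
errors, PCR chimeras, large deletions beyond the amplicon, or library-size
artifacts — so green tests say the analytics are correct under the stated
generative model, not that the model captures every failure mode of real
amplicon data.

### Problem sizes used by the test suite

The suite verifies the microhomology oracle on 10,000 random intervals,
round-trips five 10,000-read mixtures at per-base error 0 and 0.1%,
recovers planted categories on a 200-drug single-dose screen, and fits 200
noisy dose-response data sets (8 doses × 3 replicates, 2% gaussian noise).
These sizes give binomial margins far tighter than the thresholds being
checked while keeping the whole suite around two minutes on one core.

## Interface notes

The package is an R library: the pipeline entry points are
`run_pipeline()` (configuration-driven, YAML or list),
`classify_experiment()` and `run_screen_pipeline()`, which write
deterministic, byte-reproducible TSV outputs plus a JSON run manifest with
reconciled record counts; a shell wrapper would add nothing beyond
`Rscript -e`. Coordinates are 0-based half-open everywhere, matching the
conventions of the sequence-analysis tools this package sits between; every
function that takes coordinates says so.

## Known limitations

Reads are assumed to span the full amplicon in reference orientation
(paired-end merging, trimming and demultiplexing are upstream concerns;
minus-strand reads must be reverse-complemented first). The classifier
disregards all unexpected substitutions, so it cannot distinguish true
point-mutation byproducts from sequencing error. Quartile-rule hit calling
is relative by construction: categories depend on the screened library's
own distribution, so the same drug can change category between screens with
different composition. The 0.74 MMEJ floor and the 0.79 non-toxicity cutoff
are empirical constants of the assay that produced them; both are arguments
with those defaults, and the survival Q1 can be recomputed from the data at
hand.
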