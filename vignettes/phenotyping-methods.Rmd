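---
title: "Methods: multi-modal phenotyping analytics for amyloid mouse models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-modal phenotyping analytics for amyloid mouse models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fadpheno)
```

`fadpheno` implements the computational layers of a deep-phenotyping study
of an amyloid transgenic mouse line (TG vs wild-type littermates, both
sexes, several ages): EEG sleep staging and spike-wave-discharge (SWD)
detection, whole-brain plaque density mapping, PET SUVR analysis,
behavioral and frailty scoring, and a per-gene sex-by-genotype expression
model compared against human co-expression module signatures. Because the
raw recordings of such a study are large and external, every stage is
paired with a seeded synthetic-data generator that emulates the statistical
structure the stage assumes and returns its ground truth, so the whole
pipeline is verifiable at desk scale.

## EEG sleep staging

Recordings carry EEG and neck EMG at 500 Hz plus 1 Hz activity and
temperature channels and a 12:12 light/dark schedule. Preprocessing applies
a zero-phase 4th-order Butterworth band-pass (0.5--80 Hz) with a 2nd-order
60 Hz notch to the EEG and a 10--100 Hz band-pass to the EMG; zero-phase
filtering is chosen so spike morphology is not distorted for the SWD
detector downstream.

The recording is scored in fixed epochs (default 10 s, the common scoring
convention; the epoch length is configurable). Per epoch, band powers are
integrated from the FFT periodogram over delta (0.5--4 Hz), theta (4--8 Hz)
and the total analysis band (0.5--80 Hz), with left-open/right-closed band
membership so the shared 4 Hz edge belongs to delta only. Two ratio
features drive staging:

* **delta ratio** = delta power / total power (a fraction, consistent with
  its 0.4 threshold), and
* **theta ratio** = theta power / delta power (can exceed 1, consistent
  with its threshold of 3).

The denominators are a design choice: the scoring convention states the
thresholds but not the normalizations, and these are the only pairings for
which the thresholds are dimensionally sensible. Classification gates on
muscle tone first: an epoch whose EMG RMS reaches the per-animal threshold
(default 40 uV, the midpoint of the usual 30--50 uV calibration range) or
that has any activity counts is WAKE. Among inactive epochs, theta ratio
strictly above 3 gives paradoxical (REM) sleep, otherwise delta ratio
strictly above 0.4 gives slow-wave sleep; inactive epochs failing both
tests are scored as quiet wake rather than inventing a fourth stage. Under
these definitions the two sleep criteria are mutually exclusive: theta
ratio above 3 forces the delta fraction below 1/4. Sleep architecture is
summarized by run-length encoding the hypnogram into episodes, split at
light/dark transitions, reporting per period the minutes, episode counts
and mean episode durations per stage.

## Spike-wave-discharge detection

The detector mirrors the standard rodent screening criteria: dynamic
threshold 3--20 times baseline (default 6, the sensitive end, not the
midpoint, and configurable), spike width 1--200 ms, inter-spike interval
0.05--0.6 s, minimum train duration 0.5 s (measured first-to-last spike),
trains closer than 1 s joined, minimum four spikes per train. The baseline
estimator is unspecified in the screening convention; we use the rolling
median absolute amplitude over 60 s, floored at 1 uV so flat signal cannot
produce a zero threshold. Supra-threshold excursions separated by less than
the minimum inter-spike interval are merged into a single spike complex
before the width test: the two lobes of one biphasic spike are one spike,
not two, and without this merge the minimum-four-spikes rule would be
applied to lobes rather than spikes. Train assembly is greedy
left-to-right grouping by the inter-spike-interval window followed by
join-interval merging; the implementation is checked against an
independent enumeration oracle on small inputs.

The synthetic generator renders SWD events as trains of biphasic 20 ms
transients (width configurable within the 1--200 ms acceptance window)
whose amplitude is a chosen multiple of the realized median absolute EEG
amplitude; no quantitative amplitude distribution is established for such
events, so the multiplier is an explicit free parameter. One property of
the Gaussian background model is worth stating: the median-absolute
baseline equals 0.674 sigma, so events rendered near 5x baseline sit within
about one noise SD of any admissible threshold that still controls chance
spike-chains, and event-level precision/recall of 0.95 is not reachable
there. The recovery suite therefore runs at the generator default of 8x
amplitude with the default 6x threshold (where precision and recall are
both 1.0 on 110 events) and separately asserts that recall degrades
monotonically as the amplitude multiplier falls toward the threshold.

## Plaque density mapping

The plaque channel (ch3) is cleaned of autofluorescent background by
scaled channel subtraction against ch1 (`max(ch3 - scale*ch1, 0)`, scale
default 1), then a single global intensity threshold, held constant across
all sections and subjects of a run, produces the plaque mask. We read the
source procedure's "local threshold-based segmentation" as this exact
chain: the *local* part is the background removal, the threshold itself is
global. Negative differences are clamped to zero; no smoothing is applied
before thresholding (an optional Gaussian pre-blur and a minimum-object
size filter exist but default off, since the procedure states neither).

Atlas labels are categorical, so resampling to imaging resolution is
nearest-neighbor. Density is fractional area: per region, masked and
region pixel counts are pooled over *all* sections first and divided once
-- a ratio of pooled counts, not a mean of per-section ratios (the two
differ whenever section areas differ). Aggregation to major regions pools
the counts over each major region's descendant set in the region
hierarchy, which makes the whole-forest density independent of where the
hierarchy is cut. Regions with zero pixels are reported as missing rather
than zero. The synthetic generator places disc-shaped plaques wholly
inside their regions at requested densities over a smooth background with
channel leak; its truth table is measured from the rendered masks, so
recovery tests compare the pipeline against what was actually drawn.

## PET SUVR analysis

Regional uptake is normalized per subject to the cerebellum
(SUVR = R/C), cancelling injected dose and global calibration; the
reference region itself is identically 1 and is excluded from the PCA
below as a zero-variance column. Lateralized regions named `<stem>_left` /
`<stem>_right` are averaged into bilateral volumes first; midline regions
pass through.

Consensus regions are selected by PCA. We use correlation-mode PCA
(centered, unit-scaled columns) because SUVR ranges differ across regions.
The minimal set of leading components whose cumulative explained variance
reaches the 80% target is retained (never fewer than one), and per
retained component the regions whose absolute loading is at least half
that component's maximum absolute loading are selected; the union over
components is the consensus set. The loading-magnitude rule is our design
choice -- reproducible and parameter-light -- since no canonical mapping
from components to "consensus regions" exists; the half-max fraction is
configurable. Selection is deterministic and invariant to component sign
flips. Genotype and age effects are then tested per region with a two-way
fixed-effects ANOVA with interaction at p < 0.05, uncorrected across
regions by default (a BH option exists but is off, matching the convention
of reporting raw p-values here); balanced designs reduce to the classical
sum-of-squares decomposition, which the tests verify against a hand-coded
oracle at 1e-10.

## Behavioral and frailty scoring

*Spontaneous alternation*: a triad is a window of three consecutive arm
entries visiting all three Y-maze arms; windows slide by one entry;
opportunities are entries minus 2 (the standard convention -- the source
does not define the denominator numerically) and percent alternation is
100 * triads / opportunities. Sequences shorter than three entries return
a flagged null result rather than an error, matching a QC-exclusion
workflow. An agent that never re-enters its current arm and chooses
uniformly between the two others alternates at 50% chance level; the
simulated generator exposes this as a triad-completion probability.

*Frailty*: 26 named aging traits each scored 0 / 0.5 / 1; the frailty
index is their sum (maximum 26); cohort trait prevalence is the percent of
subjects scoring above zero. *Open field*: samples are binned into twelve
5-minute intervals over 60 minutes with a totals row; binning conserves
grand totals. *Wheel running*: 1-minute epochs are tiled into 30-minute
periods from session start; running time is the count of epochs with
nonzero distance (the "running" criterion is a design choice). *Rotarod*:
trials flagged as falls before acceleration score 0 s, latencies cap at
300 s, and the aggregate across the three trials is the mean (the
aggregate is unstated at source; per-trial values are preserved). *Assay
panels*: values strictly below the lower limit of detection are replaced
by half the LLOD and flagged.

## Transcriptome layer

Genes with zero counts in more than 75% of samples are removed (a gene at
exactly 75% is kept -- the rule is "more than"). TPM values are
upper-quantile normalized: each sample is divided by its 75th percentile
of nonzero TPM and rescaled by the global mean of those quantiles, then
transformed as log2(x + 1); the +1 offset and the nonzero restriction are
design choices where the procedure is silent. The per-gene model on log2
expression is

E = b0 + b1 Sex + b2 Genotype + b12 Sex.Genotype + eps

with 0/1 coding, the WT male as reference, fitted by ordinary least
squares separately within each age group. Negative-binomial differential
expression and variance-stabilizing transforms are deliberately out of
scope: this linear model on log2 values is the implemented analysis. The
model-level F-test p-value is BH-adjusted across the genes of one age
stratum (the adjustment family is our choice; the source does not state
it). Candidates satisfy q < 0.25 and R^2 > 0.3, both strict; within
candidates, per-term gene lists are read at p < 0.05. Mouse log2 fold
changes are TG-minus-WT means within a sex-by-age stratum (strata are kept
separate rather than pooled). Correlation against human module signatures
is Pearson on the shared-gene intersection per module, two-sided p from
`cor.test`, BH across all supplied module cells, and the display value is
blanked where the adjusted p exceeds 0.05; modules sharing fewer than
three genes are skipped with a warning.

The chimeric reference builder appends human transgene sequences (e.g.
hAPP, hPSEN1) to a genome as separate records named by their assigned
chromosome labels ("21", "22") and emits one gene plus one exon annotation
row per transgene spanning its full length, written as FASTA/GTF.

## Synthetic-data generators

All generators are seeded and bitwise-reproducible. The study design is
fully crossed: 2 genotypes x 2 sexes x 3 ages (4, 6, 12 months) x
`n_per_cell` replicates; 6 per cell gives the 72-sample transcriptome
layout. EEG stage sequences follow a semi-Markov process (exponential
dwell times truncated at one epoch), which produces the run-length
structure needed for episode-duration tests; per-epoch EEG is synthesized
in the frequency domain (constant amplitude per band, random phases) so
the periodogram band ratios equal the stage targets exactly, with targets
margined at least 0.15 beyond the staging thresholds; EMG is band-limited
10--100 Hz noise at the stage tone. Expression counts follow a rounded
log-normal rather than a negative binomial -- stated openly as a
simplification, since the downstream model operates on log2 values. Effect
sizes throughout are order-of-magnitude realistic only; the generators
make no attempt to mimic any particular cohort's effect sizes, and passing
recovery tests demonstrates correctness of the computations, not
performance on real recordings (real EEG has artifacts and non-stationary
spectra; real sections have uneven illumination and registration error;
real counts are overdispersed).

## Numerical choices and problem sizes

Strict inequalities are used wherever a rule says "above" or "below"
(staging thresholds, gene filter, candidate thresholds, LLOD). Degenerate
inputs return missing values or flagged nulls rather than silent zeros
(zero-pixel regions, constant ANOVA responses, sub-3-entry sequences).
Stage seeds in the pipeline are derived by hashing (global seed, stage
name) so inserting a stage does not reshuffle the randomness of the
others. The packaged verification suites run at desk scale -- e.g. 20
minutes of synthetic EEG for staging recovery, 110 injected SWD events,
ten 80x80 sections, 2000-gene null simulations -- sizes chosen so the
whole suite completes in a few minutes while keeping Monte-Carlo standard
errors well inside the asserted bounds.

This package is an analysis library rather than a shell tool: its
command-line surface is the exported `run_pipeline()` / `render_report()`
pair driven by a validated YAML configuration, plus the
`scripts/acceptance.R` entry point.

## Known limitations

Atlas registration, PET/MRI reconstruction and co-registration, read
alignment and quantification, and negative-binomial DE models are out of
scope; inputs are assumed pre-registered/pre-quantified. The SWD detector
has no video confirmation of behavioral arrest. The staging rules assume
the ratio-denominator conventions above; other scoring software may
normalize differently. The generators' noise models are Gaussian/log-normal
simplifications of real physiology.
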