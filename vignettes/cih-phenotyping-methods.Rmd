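---
title: "Methods: cardiorespiratory and microbiome phenotyping for CIH rodent studies"
author: "cihpheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiorespiratory and microbiome phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cihpheno)
```

# Scope and model of the data

`cihpheno` implements the quantification pipeline used to phenotype
cardiorespiratory function in rodent models of chronic intermittent hypoxia
(CIH), together with the compositional summary statistics applied to caecal
metagenome count tables, over a 2x2 exposure-by-diet design
(Sham/CIH x vehicle/prebiotic). Animal recordings are not required: a
synthetic-data module generates every input with known ground truth (planted
respiratory events, planted RR spectral content, planted taxon fold changes),
so each stage of the pipeline is verifiable at desk scale.

# The synthetic-data generator

## Respiratory flow

A flow trace is a train of stereotyped breaths at a set respiratory frequency
`f_R` (default 80 breaths/min, the resting rat scale), sampled at 200 Hz.
Inspiration is a negative half-sine lobe lasting `ti_fraction x T_tot`
(default 1/3, giving the T_i < T_e asymmetry typical of resting rats) and
expiration is a positive exponential-decay lobe (time constant T_e/4,
shifted to land exactly on zero at the cycle end). Each lobe is normalised so
its sampled integral equals the tidal volume `V_T` (default 2.1 ml for a
~300 g rat, i.e. 0.7 ml/100 g). Additive Gaussian noise is scaled as a
fraction of peak inspiratory flow (default 0.02).

Planted events:

* **Sighs** scale a whole breath by `sigh_gain` (default 2.5, comfortably
  beyond the 2x detection criterion).
* **Apnoeas** replace scheduled breaths with zero flow (plus the noise
  floor), with no amplitude taper, so the pause boundaries are unambiguous
  ground truth. An apnoea is parameterised by the full inter-onset interval
  it creates, in multiples of T_tot; a `post_sigh` flag makes the breath
  opening the pause a sigh.
* **Artifacts** replace the signal with high-amplitude broadband noise
  (movement/sniffing).

The event log records each planted event once, sorted by onset; overlapping
events are rejected at construction with the offending pair named. One master
seed drives a study; per-subject streams derive from it by fixed offsets
(`child_seed`), so datasets are bit-reproducible while subjects stay
independent.

Default sampling rates (200 Hz flow, 1 kHz pressure) are free parameters of
the generator: they are at least 50x the highest rat HF band edge (3 Hz) and
ample for beat detection. The plethysmograph sampling rate and
breath-acceptance settings of commercial systems are not standardised, so
these defaults are the package's own choice.

## Arterial pressure

Beat-to-beat intervals are `RR_i = mean_rr + sum_j a_j sin(2 pi f_j t_i) +
jitter`, with the default mean RR at the anaesthetised-rat scale (~150 ms,
~400 beats/min). Each beat is a stylised pulse: a quarter-sine systolic
upstroke to SBP over 30% of the cycle, then an exponential decay rescaled to
land exactly on DBP, so per-beat SBP/DBP are exact by construction and a
planted sinusoid of amplitude `a` ms contributes power `a^2/2` ms^2 to the RR
spectrum. Component frequencies at or above the beat-rate Nyquist are
rejected.

## Gas fractions and counts

Gas traces are steady-state flow-through fractions obtained by algebraic
inversion of `VO2 = flow (FiO2_in - FiO2_out)` and
`VCO2 = flow (FiCO2_out - FiCO2_in)`; the metabolic computation therefore
recovers planted rates to machine precision on noiseless traces.

Count tables are Dirichlet-multinomial: per sample a composition is drawn
from `Dirichlet(base_proportions / dispersion)` and counts from a multinomial
at a uniformly drawn library size. A planted effect multiplies one taxon's
base proportion by `2^log2fc` in one level of one design factor before
renormalisation. As `dispersion -> 0` compositions converge on the base.

## What the generator does not emulate

No chamber gas-mixing dynamics, temperature/humidity corrections or
barometric volume calibration; no pulse-waveform morphology beyond the
stylised pulse; no baseline drift, electrode noise or movement artifacts in
pressure; no phylogenetic correlation structure in counts. Passing tests
therefore demonstrate correctness of the *scoring rules and statistics* under
controlled conditions, not robustness to every failure mode of real
recordings.

# Breath scoring

Breaths are delimited by inspiratory onsets found on a 10 ms moving-average
smoothed signal with a hysteresis band of +/-2% of the epoch peak flow
(inspiration negative; a sign flip is available). Two refinements matter in
noise:

* the onset is walked back from the hysteresis crossing to the preceding
  raw-signal zero crossing, removing the crossing-delay bias;
* a candidate onset is accepted only if the smoothed signal reaches below
  15% of the epoch peak within 100 ms (a *depth guard*): a genuine
  inspiration plunges immediately, while noise excursions during an apnoeic
  pause do not. Without this guard, a long pause occasionally yields a
  noise-triggered onset whose "inspiratory phase" swallows the next real
  breath.

T_i is the inspiratory (negative) phase; T_e is the remainder of the
inter-onset interval, so expiratory pauses accrue to T_e up to the apnoea
criterion; V_T is the magnitude of the integrated flow over inspiration.
Sub-threshold cycles (T_i < 30 ms or V_T < 0.05 ml) are dropped and their
time folds into the preceding breath's interval. On noiseless traces the
round trip recovers planted f_R, V_T, T_i and T_e within 1%; at the default
noise level, timing errors stay within a few percent (one smoothing window).

Artifact rejection flags breaths overlapping declared artifact windows, with
T_tot outside [100, 3000] ms, or with V_T above 5x the epoch median; rules
are recomputed from scratch on each call (the V_T median is taken over
breaths not hit by this call's window/timing rules), which makes flagging
idempotent. Flagged breaths are retained but excluded from all summaries.
Note the T_tot upper bound also catches long apnoeic gaps: event scoring
therefore assesses every breath as a potential gap regardless of its own
flag, and uses flags only to clean the local baseline.

Epoch summaries are means over unflagged breaths in a window; V_T, V_I and
V_T/T_i are normalised per 100 g body mass, and V_I is defined as
f_R x V_T from the window means so the identity holds exactly. Baseline
epoch boundaries are user inputs (how the three baseline epochs were
delimited in time is not standardised).

Poincare variability uses the population-variance lagged-pair forms
SD1 = sqrt(Var(x_n - x_(n+1))/2), SD2 = sqrt(Var(x_n + x_(n+1))/2) — the
ellipse-fitting definitions; the difference from sample variance is
negligible for n >= 100 and the identity SD1^2 + SD2^2 = Var(x_n) +
Var(x_(n+1)) holds to machine precision.

# Sigh and apnoea scoring

A **sigh** is an augmented breath with V_T at least double (configurable) the
prevailing average V_T, estimated as a rolling mean over the surrounding 50
unflagged breaths excluding the breath itself. Detection runs two passes:
candidates found in pass one are excluded from the baseline in pass two, so a
large sigh cannot hide a nearby borderline one by inflating the local mean.

An **apnoea** is a pause greater than two consecutive missed breaths. The
operationalisation: a breath's full inter-onset interval qualifies iff it
exceeds `(1 + miss_multiple)` times the local mean T_tot, with
`miss_multiple = 2` by default — one expected breath plus two missed. A gap
of 3.5 local cycles is an apnoea; 2.5 is not (the strict "greater than two"
reading). Whether the original analyses used > 2 or >= 2, and the averaging
window for the prevailing V_T, are not printed anywhere we know of; both are
exposed as parameters. The local mean is taken over the preceding 10
unflagged, non-sigh, non-apnoeic breaths (tracking slow rate drift without
being distorted by the event itself), and gaps before the first full window
are not scored. An apnoea whose opening breath falls within one breath of a
sigh (configurable lag) is post-sigh, otherwise spontaneous; the classes
partition the events, and the apnoea index (events/hour) is their combined
rate over the analysed duration.

# Haemodynamics and HRV

Beats are delimited by upward mid-level crossings of the pressure waveform;
SBP/DBP are the per-cycle extrema, MAP the per-cycle time average of the
waveform (a formula fallback is unnecessary since the waveform is always
available here), and RR the inter-systolic-peak interval.

Time-domain metrics follow the standard definitions (SDRR as the sample SD;
RMSSD as the root mean square of successive differences). SDSD uses the
population SD of successive differences so that RMSSD = SDSD exactly when
the mean successive difference is zero; SD1/SD2 reuse the Poincare module.

Spectral metrics: the RR series is cubic-spline interpolated to a uniform
20 Hz grid at its beat times, linearly detrended (slow drift would otherwise
leak into VLF), and the PSD estimated by Welch's method (Hann window, 50%
overlap, ~30 s segments — at least 6 cycles of the 0.2 Hz LF edge per
segment). Band powers integrate the one-sided PSD over the rodent
conventions VLF < 0.2 Hz, LF 0.2–0.75 Hz, HF 0.75–3 Hz (configurable; the
published rat literature varies and the bands consistent with ~400 beats/min
are used). Normalised units are LF/(LF+HF) and HF/(LF+HF) x 100, which sum
to 100 exactly. The estimator recovers a planted sinusoid's `a^2/2` power
within a few percent, and the summed band powers agree with the total
estimated power within 10% for band-limited inputs. Published group tables
of HRV cannot be reproduced without raw recordings, so verification is
property-based against planted spectra.

# Challenge, drug and metabolic quantification

Two windowing conventions are implemented exactly as specified by the study
design:

* **Plethysmography mode**: the response is the mean over the final 5 min of
  the challenge epoch (allowing chamber gas mixing), the baseline is the
  unweighted mean of the per-epoch means of the baseline epochs (epochs of
  unequal length contribute equally — deliberately not a pooled mean), and
  absolute change is reported.
* **Anaesthetised mode**: mean of the last 1 min of the challenge against the
  1 min immediately pre-challenge, reported as percent change.

Windows track epoch definitions sample-for-sample — no hidden snapping.

Drug responses bin the series into 3 or 5 s bins post-injection (a per-drug
choice; which bin width matched which drug originally is unspecified, so it
is a parameter) and take the bin with maximum absolute deviation from the
1 min pre-injection baseline within a 60 s search window (covering the fast
chemoreflex and vasoactive responses while excluding recovery drift); the
signed percent change falls out of the same rule for pressor and depressor
responses. The pulmonary chemoreflex (PBG) apnoea and subsequent tachypnoea
are durations normalised to the mean breath cycle of the 30 s pre-injection
baseline; tachypnoea is a contiguous run of at least 3 breaths with T_tot
below the baseline mean minus 2 SD (the period is named but not bounded in
the source literature, so the boundary is a documented package choice).

Metabolism: VO2 and VCO2 from mean inlet/outlet fraction differences times
chamber flow, per 100 g; the ventilatory equivalent V_I/VCO2 is computed with
both terms per 100 g so the mass normalisation cancels. No STPD/BTPS
corrections are applied; flows are treated as instrument-reported. Small
utilities cover the oedema index 100 (wet - dry)/wet and
analyte:internal-standard ratio quantification.

# Microbiome summaries

Filtering removes features present in 5% or fewer samples; a second mask
marks features reaching 0.5% relative abundance in at least one sample as
eligible for differential testing (the rest remain in the composition).

The centred log-ratio transform adds a pseudocount of 0.5 (the common
convention; the value is configurable since zero handling is rarely printed)
and expresses each log count relative to the sample's geometric mean. CLR
sample vectors sum to zero and are scale-invariant; Euclidean distance
between them is the Aitchison distance.

Alpha diversity uses bias-corrected Chao1, Shannon entropy in nats, and the
Gini–Simpson index 1 - sum(p^2) (the variant consistent with box plots
compressed near 1; inverse Simpson is a trivial transform if needed).
Ordination is PCA of the centred CLR matrix.

PERMANOVA uses pseudo-F = (SS_between/(g-1))/(SS_within/(n-g)) on Aitchison
distances with p = (1 + #{F_perm >= F_obs})/(1 + n_perm) — the observed
labelling counts, guaranteeing p > 0 and exactness — with 1000 permutations
by default and a pairwise mode over group pairs. For small two-group
problems an exact mode enumerates every distinct assignment.

Differential abundance is a single CLR-space two-sample test per eligible
feature — Welch's t when both groups pass the Shapiro-Wilk gate, Wilcoxon
otherwise — with Benjamini-Hochberg adjustment at FDR 10%. This deliberately
replaces Dirichlet Monte-Carlo instance averaging (as in ALDEx2-style
pipelines) with one test on one pseudocounted CLR instance; the FDR property
is verified by simulation instead. A known limitation is compositional
closure: a large one-sided shift concentrated on abundant taxa moves the
geometric mean and hence every CLR coordinate, which any CLR-based test
(including the replaced one) reads as widespread change; the FDR simulations
therefore plant balanced effects on mid-abundance taxa, which is also the
regime where such tests are trusted in practice.

Functional modules (gut-brain/gut-metabolic style) are ordered steps of
alternative KEGG orthologues: step abundance is the sum of its alternatives,
module coverage the fraction of steps with nonzero abundance, and module
abundance the median over steps when coverage reaches 0.66 (the aggregation
convention of the standard module framework; rule and threshold are
configurable).

# Statistical harness

For each metric over the 2x2 design: the parametric path (two-way ANOVA with
interaction, then Fisher's LSD as unadjusted pairwise t-tests restricted to
the four planned comparisons) is taken iff every cell passes Shapiro-Wilk
normality and Levene's variance-homogeneity test at the 0.05 gate
(conventional; the gate level is not printed in the source literature);
otherwise Kruskal-Wallis followed by pairwise Mann-Whitney U. The four
planned comparisons are Sham+VEH v CIH+VEH, CIH+VEH v CIH+PREB, Sham+PREB v
CIH+PREB and Sham+VEH v Sham+PREB, judged against the Bonferroni-adjusted
alpha 0.05/4 = 0.0125. Whether pairwise testing was originally gated on the
omnibus is not stated; both behaviours sit behind `require_omnibus`
(default off, since the Bonferroni correction already bounds the family-wise
error, which the null simulations confirm). Box-plot (1.5 IQR) outliers are
counted and reported but never removed — no removal rule is documented, so
the harness refuses to invent one.

The correlation screen is flat all-against-all Spearman with BH adjustment at
q < 0.1: deliberately not a hierarchical (HAllA-style) procedure, and
labelled as such in its output metadata. Constant vectors are skipped with a
flag rather than propagating undefined correlations.

# Numerical choices and problem sizes

Permutation p-values include the observed statistic (+1 convention). BH
wraps `stats::p.adjust` and is property-tested against a brute-force step-up
oracle. The test suite and the acceptance script size their simulations for
a desktop run: 100 seeded 10-min traces for event recovery, 200 null
replicates at 999 permutations for PERMANOVA calibration, 100
null-plus-planted tables (100 features, 5 planted, 12 samples/group) for FDR
control, 1000 random series for the Poincare closed forms; the complete run
takes on the order of a minute.

# Known limitations

* Breath timing quantisation is one flow sample (5 ms at the default rate);
  T_i/T_e accuracy statements assume the planted timing sits near the grid.
* Beat detection assumes a pulsatile waveform with one systolic peak per
  cycle; dicrotic notches larger than the mid-level band would need a
  minimum-separation rule the stylised simulator does not require.
* The CLR differential test inherits compositional closure sensitivity (see
  above) and, like its Monte-Carlo counterpart, weakens for features whose
  Dirichlet concentration is below ~1.
* Obstructive versus central apnoea cannot be distinguished from flow alone
  and is not attempted.
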