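---
title: "Methods: copy-number profiling and the THYT1 signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number profiling and the THYT1 signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyt1)
```

# The analysis

Papillary thyroid carcinomas that seed distant metastases (DM) differ
from non-metastatic controls in their somatic copy-number landscape.
The pipeline in this package reproduces the analytical chain of such a
case-control SNP-array study: probe-level log-R ratio (LRR) and
B-allele frequency (BAF) profiles are segmented, segments are
classified into copy-number event classes, per-sample burden and
arm/locus alteration flags are derived, per-position alteration
frequencies are compared between groups, the three-feature THYT1
signature (Chr1q duplication, TERT-locus duplication on 5p, TERT
promoter mutation) is scored, and its association with metastasis and
overall survival is tested. Because the original probe-level arrays
and survival dates are not public, every stage is exercised against a
synthetic cohort generator that plants the published group-level
frequencies; the pipeline also ingests SEG-format segment tables for
real data.

# Segmentation model

Each chromosome's LRR vector is modelled as a hidden Markov chain over
$K = 5$ copy-number levels with Gaussian emissions. The state means
default to $(-1.5, -0.45, 0, 0.3, 0.9)$ — the centres of the
homozygous-deletion, deletion, neutral, duplication and amplification
calling bands — and a shared emission standard deviation is estimated
per sample as $\hat\sigma = \mathrm{mad}(\Delta \mathrm{LRR})/\sqrt2$,
which is robust to the (sparse) true breakpoints and self-calibrates
to the sample's noise level. The transition matrix is uniform with
per-probe state-change probability $p = 10^{-7}$ (self-transition
$1 - p(K-1)$). The commercial segmenter the study used exposes a
"significance threshold" of $10^{-7}$; the closest published reading
of that knob is a per-probe breakpoint prior, which is what we use,
and it is configurable (`seg_params(breakpoint_prior = )`). Whether
the original software applied it per probe or per candidate breakpoint
is not decidable from the publication; the monotonicity property
(fewer segments as the prior shrinks) holds either way and is tested.

The Viterbi path is decoded in C++ and run-length encoded. Runs
shorter than `min_probes` (default 10) are *merged* into the flanking
state whose mean is closer to the run's observed mean, rather than
deleted, so the segments always partition the probe grid — a property
the tests enforce. Segment means are recomputed from member probes, so
a sub-minimum event merged into a long neutral segment does not leak
its shift into the calls.

## Wave correction

FFPE array data show long-range intensity waves; the study applied a
quadratic correction before segmentation. A naive least-squares
quadratic per chromosome is *wrong* in the presence of arm-level
events: fitting the trend to the raw LRR absorbs up to half of a
50%-of-chromosome duplication into the trend and pushes the corrected
signal below the calling band (we measured exactly this failure on
planted 1q duplications). `wave_correct()` therefore estimates the
copy-number signal and the trend jointly: it alternates (i) Viterbi
decoding of the current detrended signal and (ii) least-squares
quadratic fitting of the state-mean-subtracted residuals, for at most
five iterations. On trend-only input the first Viterbi pass is all
neutral and the procedure reduces exactly to the plain least-squares
fit (an exact quadratic is annihilated to numerical precision); on
event-bearing input the planted-event recall is unchanged relative to
wave-free data, which is tested as a paired comparison. The profile
median is re-centred to zero afterwards; BAF is untouched.

## Allelic imbalance and LOH

The per-probe allelic ratio is $r = |2\,\mathrm{BAF} - 1|$, computed
on germline-heterozygous probes. The publication states its thresholds
(0.4 for heterozygous imbalance; 85% of probes above 0.8 in ≥ 500 kb
for LOH) without defining "allele ratio"; $r$ is chosen because the
stated cuts then correspond to natural BAF splits (0.3/0.7 and
0.1/0.9). Segments without informative probes get `NA` flags rather
than `FALSE`.

# Calling, burden, and flags

Segment means are classified by half-open bands: amplification
$> 0.7$, duplication $(0.1, 0.7]$, neutral $[-0.15, 0.1]$, deletion
$[-1.1, -0.15)$, homozygous deletion $< -1.1$. The published
thresholds are strict inequalities on both sides, which leaves
boundary points ambiguous; the half-open orientation here makes the
classes exhaustive and mutually exclusive. Burden is the per-class
altered length as a percentage of the covered *autosomal* genome
(sex chromosomes are excluded by default to avoid gender-driven
artifacts; the publication is silent on this and the choice is
configurable), plus per-class event counts; amplifications are not
double-counted inside duplications.

Arm-level flags (Chr1q duplication, Chr9q loss) require segments of
the class set to cover at least 50% of the arm — a binary arm call
needs an operational coverage rule, and 50% reflects that the
differential signal spans the arm; the fraction is a parameter. Locus
flags (TERT duplication) require ≥ 1 bp overlap. The published
results call the 9q event a "homozygous loss", but the same table's
homozygous-deletion burden is ~0.002% of the genome, which excludes a
whole homozygously-deleted arm; the generator therefore plants the 9q
analogue as a hemizygous deletion and the loss flag tests
{del, homdel}.

# Differential regions

For each probe, samples are cross-tabulated as (altered, not altered)
× (DM, control), where "altered" means the sample's call at that
probe belongs to the direction's class set (gain = {dup, amp},
loss = {del, homdel}); gains and losses are tested in separate passes
as in the study's frequency plots. Two-sided Fisher exact tests are
BH-adjusted across probes. A probe passes when the adjusted p is
below 0.05 and the between-group difference is at least 15 percentage
points — the two criteria the study's figure legend attaches to its
significance bars. The study also states a 25% "frequency threshold
for calling in the overall sample"; that number cannot have gated
differential regions, because the study's own 5p region runs at
23.5% in the metastatic group (and its 1q region pools to 14.7%), so
here it parameterizes the aggregate calling track: probes whose
alteration frequency reaches 25% in the more frequent group are
annotated as cohort-level aggregate calls alongside, not instead of,
the differential test. Passing probes are merged into regions
tolerating one
failing probe (a single-probe dropout should not split an arm), never
across chromosome boundaries. The original software's exact statistic
and adjustment are undocumented; equivalence with the original region
list is not claimed — the tests instead verify FDR control under the
null and exact recovery of planted regions.

# Signature, MSI, and variant filtering

THYT1 is positive when any of the three features is present. Missing
is distinct from absent: a sample with no positive feature and at
least one unassessed feature is *indeterminate*, not negative
(tumor-profile matrices mark unavailable assays explicitly, and
collapsing them to negative would bias specificity upward). Variant
support requires both strands, ≥ 10 supporting reads and ≥ 5% variant
fraction. MSI is MSS with zero unstable markers, MSI-H at ≥ 30%
unstable, MSI-L between; the defaults use the study's 13-marker panel.

# Survival statistics

Kaplan–Meier estimation, the log-rank test, and Cox proportional
hazards regression are delegated to the survival package behind thin,
validated interfaces. Ties use the Efron approximation by default —
the modern default — with Breslow exposed because the study's
statistical software defaults to it; on tied data the two differ
slightly and both are tested. The multivariate model adjusts for
stage (ordinal I–IV), histological variant and gender, as in the
study. Complete separation (e.g. zero deaths in one arm of a small
group) triggers a warning and a flagged estimate rather than an
error.

The two-sided Fisher p-value is defined by the "probability at most
that of the observed table" convention of mainstream implementations;
the publication names the test but not the sidedness rule. The test
suite verifies the implementation against an independent
hypergeometric-enumeration oracle for every 2×2 table with
$N \le 40$.

# The synthetic cohort generator

The generator *is* the study conditions. Group sizes default to the
SNP-array denominators (34 DM, 61 controls). Signature-feature
probabilities default to the published frequencies (Chr1q duplication
35.3%/3.3%, TERT duplication 23.5%/0%, TERT promoter mutation
40.6%/3.4%, BRAF V600E 35.4%/55%). Chr9q loss is drawn only among
Chr1q-duplicated samples with probability 0.85 plus a 1% leak: the
publication reports the coupling as "strict", with a single sample
carrying 9q loss alone, and 0.85 + leak reproduces roughly one
uncoupled sample per cohort. The three THYT1 features are otherwise
sampled independently per feature; the study reports co-occurrence
frequencies but no dependence model. TERT promoter mutations split
between C228T and C250T at 80%/17% per group (the published variant
ratios). MSI panels are all-stable in DM and occasionally unstable in
controls (2.2% one marker, 1.1% four markers), matching the observed
three unstable controls.

LRR class shifts default to +0.3 (dup), +0.9 (amp), −0.45 (del),
−1.5 (homdel): centred inside the calling bands rather than at ideal
log2 ratios, emulating FFPE signal compression, and constrained by
validation so planted events remain recoverable. Heterozygous BAF
sits at 0.5 / {1/3, 2/3} / {1/4, 3/4} / {0, 1} under neutral /
duplication / amplification / deletion-or-cnLOH; homozygous-deletion
probes have uniform BAF (no allelic signal). Probe noise is Gaussian
(LRR sd 0.2, BAF sd 0.03, 30% heterozygous probes). Random background
events (means of 6 per DM and 4 per control sample, ~1.9 Mb mean
length, 70% duplications) provide non-signature burden; at the
desk-scale probe spacing the study's typical sub-100 kb events are
not representable, so the absolute burden percentages of the
simulated cohorts run higher than the published means — comparisons
between groups, not absolute burden levels, are the tested quantity.

Survival is exponential with administrative censoring at 240 months
and a light random-censoring hazard (0.001/month); the publication
gives hazard ratios but no survival-time distribution. The baseline
hazard (0.002/month) puts THYT1-negative 20-year mortality near 40%,
and the THYT1-positive hazard is multiplied by 7.29, the published
univariate hazard ratio. One global seed drives everything through a
documented counter scheme (`sub_seed`), so any single sample is
reproducible in isolation.

What the generator does *not* emulate: FFPE artifacts beyond
Gaussian noise and quadratic waves, probe-specific response, GC waves
correlated across samples, tumor purity/ploidy shifts, subclonality,
germline CNVs, and read-level sequencing. Passing tests therefore
demonstrate correctness of the analytical chain under the stated
noise model, not performance on raw clinical arrays.

# Numerical and scale choices

The default "desk" genome is 300 Mb over six chromosomes (analogues
of 1, 5, 9, 17 plus two fillers) with TERT at 1.25–1.30 Mb on the 5p
analogue, probed at 10 kb mean spacing (~30,000 probes) with ±40%
jitter; an hg19-like 24-chromosome preset is available. The
publication never states probe counts or spacing; 10 kb on 300 Mb
keeps a full 95-sample pipeline run around ten seconds while leaving
arm events thousands of probes long. Property-style tests use a 50 kb
grid and the null-FDR simulation a 400-probe single chromosome — the
statistical properties under test are scale-free, and these sizes
keep the suite's total runtime in minutes. Differential-region
recovery is additionally verified with the published group
frequencies at enlarged cohorts (120–300 DM vs 220–540 controls at
the study's 1:1.8 ratio): the 5p analogue is planted at 23.5%, within
sampling noise of the 15% frequency-difference gate at n = 34, and
concentrating the frequencies separates the gate's correctness from
the coin flip of a single binomial draw. At the study's own n, 5p
recovery tracks exactly whether the realized truth frequency clears
the gate, which is asserted as such. Coordinates are 0-based
half-open internally; SEG is read and written 1-based inclusive and
BED 0-based half-open, matching each format's dominant dialect, and
chromosome names are normalized ("chr" stripped) because public SEG
files mix dialects.

Breakpoint accuracy is assessed against the exact least-squares
changepoint on the same data. At the default noise (shift 0.3, sd
0.2) the *data* limit boundary localization: the least-squares oracle
itself misses the true breakpoint by more than 5 probes in ~2.5% of
boundaries, while the HMM boundary stays within 5 probes of the
oracle essentially always. Truth-referenced localization is reported
descriptively (median 0, 90th percentile ≈ 4 probes).

# Known limitations

No tumor-purity or ploidy deconvolution (ASCAT-style), no joint
multi-sample segmentation, no GISTIC-style peak deconvolution, no
gene-ontology enrichment, and no germline CNV filtering. The
segmentation is a faithful, tested HMM segmenter of the same family
as the study's proprietary tool, but identity of output with that
tool is neither expected nor claimed.
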