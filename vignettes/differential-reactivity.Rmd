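---
title: "Detecting differentially reactive regions in RNA structure-probing data"
author: "DRRscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differentially reactive regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DRRscan)
```

## The problem

Chemical and enzymatic structure-probing experiments (SHAPE, DMS-based
Structure-Seq, PARS) measure a per-nucleotide *reactivity* that reflects
each nucleotide's structural context: flexible/unpaired nucleotides react
strongly with SHAPE/DMS reagents, and the V1/S1 nuclease pair of PARS
reports pairing evidence directly. Comparing reactivity profiles between
two conditions — with and without a ligand, a bound protein, a sequence
variant — can reveal *differentially reactive regions* (DRRs): contiguous
stretches whose reactivity pattern changes more between the groups than
biological replicates vary within them.

The statistical difficulty is that a reactivity pattern is a geometric
feature. It cannot be summarised as "higher" or "lower" in one group, and
replicate profiles disagree substantially even under identical
conditions. DRRscan addresses this by turning pattern disagreement into a
per-nucleotide dissimilarity score and asking, region by region, whether
between-group dissimilarity exceeds within-group dissimilarity.

## The dissimilarity score

For a nucleotide with reactivities $r_1,\dots,r_m$ across $m$ samples,
with sample mean $\mu$ and sample standard deviation $\sigma$ (the $n-1$
denominator), the d score is

$$d = \frac{2}{\pi}\arctan\!\left(\frac{\sigma}{|\mu|}\right),$$

i.e. a bounded transform of the absolute coefficient of variation. For
$m = 2$ this reduces to
$d = \tfrac{2}{\pi}\arctan\big(\sqrt{2}\,|r_1-r_2|/|r_1+r_2|\big)$, which
is why the $n-1$ convention is used: the paired special case holds
exactly. The arctan matters because $\sigma/|\mu|$ explodes as
$\mu \to 0$ (routine for signed PARS scores), and unbounded values would
dominate the averages taken downstream. Conventions at the boundaries:

* all values identical: $d = 0$;
* $\mu = 0$ with $\sigma > 0$: $d = 1$ (for PARS this means the samples
  actively disagree about pairing);
* all values exactly zero ($0/0$): $d$ is **undefined** and treated as
  missing — zero reactivities can be genuine signal or no information at
  all, and counting them as perfect agreement produces erroneous calls.

The d score is a redefinition of the replicate signal-to-noise ratio
$SNR = |\mu|/\sigma$: `snrFromD()` inverts the transform,
$SNR = 1/\tan(\pi d/2)$, so $d = 0.5$ corresponds to $SNR = 1$ and
$d = 0.2$ to $SNR \approx 3$. Those two points anchor the quality
thresholds below.

## The three analysis steps

**Step 1 — variation profiles.** With $m_A$ and $m_B$ replicates, the
subset size is $m = \max(m_A, m_B)$. All size-$m$ subsets of the pooled
samples are formed; subsets drawn from a single group are *homogeneous*,
the rest *heterogeneous*, and among the heterogeneous ones only those
with maximal heterogeneity $g_A g_B/m^2$ are kept. If the retained
subsets are unbalanced ($g_A \neq g_B$), $m$ is reduced in steps of 1 —
never below 3 — until balance is reached; the floor applies only when the
starting $m$ exceeds 3, so a 2-vs-1 design uses $m = 2$. Averaging each
nucleotide's d score over homogeneous and heterogeneous subsets yields
`dWithin` and `dBetween`. Design choices the method description leaves
open, resolved here:

* after a reduction, *all* size-$m$ single-group subsets are used (not
  just the two unreduced ones), which uses replicate information
  symmetrically;
* the decrement stops at the **first** $m$ achieving balance (a 5-vs-4
  design stops at $m = 4$ rather than continuing to 3);
* a subset's d score at a nucleotide is computed only when all of its
  samples are observed there; subsets with a missing or undefined d are
  dropped from that nucleotide's average, and a 1-vs-1 design is refused
  outright since no within-group information exists;
* with only one replicate in a group (1-vs-2, common in practice), that
  group cannot contribute within-group information — the cost is a
  stricter quality threshold below.

**Step 2 — candidate construction (de novo mode).**
$\Delta d = d_{between} - d_{within}$ is the per-nucleotide evidence of
differential reactivity. Before screening, $\Delta d$ is masked at
nucleotides where every sample has $|r| < 0.1$ (changes among very low
reactivities are not meaningful; the mask is applied on the analysis
scale as given, including signed PARS scores). The masked profile is
smoothed with a centered rolling mean of the user's search length $l$;
windows are truncated at transcript ends so coordinates map 1:1, missing
values inside a window are ignored, and an all-missing window stays
missing. Candidates are maximal runs of strictly positive smoothed
$\Delta d$ of length $\ge l$ (a missing smoothed value breaks a run; no
post-hoc merging is done — joined regions arise only from the smoothing
itself). Runs of length $\ge 11$ are trimmed at their edges of
nucleotides below the 0.1 threshold in all samples; shorter runs are not
trimmed, as that costs power. A run must contain non-missing $\Delta d$
at $\ge 5$ nucleotides if $l > 5$, or $\ge l - 1$ if $l \le 5$. Finally,
the *minimum quality threshold* requires the region's mean $d_{within}$
to be below 0.5 when $\min(m_A, m_B) \ge 2$ and below 0.2 when a group
has a single replicate (strict inequalities); these are the $SNR = 1$
and $SNR \approx 3$ quality levels.

**Step 3 — testing.** For each surviving region, the paired
$(d_{within}, d_{between})$ values are compared with a one-sided
Wilcoxon signed-rank test of the alternative that
$d_{between} - d_{within}$ is shifted positive. The smoothed profile
plays no role here. P values from **all** regions of **all** transcripts
form one Benjamini–Hochberg family; DRRs are regions with $q < \alpha$
(default 0.05). An optional pooled mode concatenates all candidate pairs
of a transcript into a single transcript-level test; its output is
transcript-level evidence and is labelled as such.

Test conventions: pairs with a missing side are dropped; zero differences
are dropped before ranking (standard signed-rank practice — the method
description is silent); tied absolute differences get average ranks. The
exact null distribution of the positive-rank sum is computed by a
generating-function recursion (valid with average ranks) up to 25 pairs;
beyond that a tie-corrected normal approximation with continuity
correction is used, and the switch point is configurable. A region whose
pairs all vanish is untestable and reported with missing p and q,
contributing nothing to the BH family. Note the test's natural
alternative is a location shift (a median statement), while the stated
alternative concerns the mean of $\Delta d$; the standard one-sided
signed-rank test is used and this distinction is simply documented. An
immediate consequence of exactness: with all differences positive,
$p = 2^{-n}$, so no region with fewer than 5 informative pairs can reach
$p < 0.05$ — differential signal confined to fewer than 5 nucleotides is
invisible to the test.

In **guided mode** the user supplies candidate coordinates and step 2 is
skipped (no masking or smoothing). The same quality threshold applies,
and additionally the median of the region's $\Delta d$ must be positive
for the region to be called a DRR; regions failing the median rule are
still tested and reported, flagged non-significant.

```{r example}
set.seed(7)
base <- rlnorm(60, -1, 0.6)
alt <- base
alt[21:40] <- rlnorm(20, 0.7, 0.4)    # altered block in group B
jitter <- function(x) pmax(x + rnorm(60, 0, 0.05), 0.001)
rs <- ReactivitySet(list(tx = cbind(A1 = jitter(base), A2 = jitter(base),
                                    B1 = jitter(alt), B2 = jitter(alt))))
runDStruct(rs, l = 11)
```

## Reactivity calculation utilities

For count-based protocols the package computes reactivities the standard
way: detection rates are counts over local coverage (zero coverage gives
a missing rate); raw reactivity is
$\max\big((r^+ - r^-)/(1 - r^-),\, 0\big)$, clamped where background
exceeds signal; base-selective reagents (DMS) mask the unprobed bases;
and profiles are 2–8% normalized — the top 2% of non-missing values are
set aside as outliers and the mean of the next 8% is the normalization
constant. Band sizes are `ceiling(0.02 n)` and `ceiling(0.08 n)` over
the $n$ non-missing values sorted descending; the ceiling rule is this
package's choice (it is deterministic, keeps the bands non-empty for any
$n \ge 1$, and reproduces the textbook 100-value example with
$f = \bar{x}_{(91..98)} = 94.5$). Normalization is per sample; for
transcriptome-wide data all transcripts of a sample should be pooled
before normalizing, which is what the simulator and file pipeline do,
while single-RNA analyses can normalize per transcript. PARS scores are
$\log_2((V1+5)/(S1+5))$, and a propagated standard error
$(1/f)\sqrt{r^+/C^+ + r^-/C^-}$ is provided for workflows that need
per-nucleotide uncertainty.

## The simulator

`generateDataset()` produces correlated replicate datasets with known
truth, emulating a two-group transcriptome-wide probing experiment. Its
defaults are the study conditions used by the acceptance checks and were
chosen once, on the following reasoning.

*Structure ensembles.* RNAs adopt ensembles of conformations, and
reactivity averages over the ensemble. Each transcript (150 nt by
default) is tiled with independent folding domains of 50–75 nt — the
usual search range for structured regions — and each domain receives an
ensemble of 30 unique pairing-state vectors from a toy sampler that
drops hairpin helices (stems 3–7 nt, loops 3–8 nt) into free intervals
until a typical pairing density (40–65%) is reached; placement into
fully free intervals guarantees valid, non-crossing structures without a
thermodynamic model. Externally computed structures can be supplied as
dot-bracket strings instead (`ensembleFromDotBracket()`). One structure
per ensemble is designated MFE-like; giving it the same weight in both
groups pulls the groups together, which is the between-group correlation
control.

*Weights and the planted signal.* Up to 5 dominant structures per group
receive a total ensemble weight drawn from U(0.33, 0.66) of the
non-MFE budget, the remainder being spread randomly over the infrequent
structures. In a planted DRR domain the dominant sets of the two groups
are disjoint — the groups differ because their ensembles differ, not
through injected noise — and the replicate weights are perturbed with
multiplicative lognormal noise (scale 0.35) to create within-group
ensemble variation. The truth table records each planted domain and the
span over which the two groups' top dominant structures differ in
pairing state. Outside planted domains both groups share one weight
vector: the null hypothesis is true there by construction.

*Emission and measurement.* Per-structure reactivity profiles are drawn
from lognormal paired/unpaired distributions (medians 0.1 and 1, log-sd
0.8 — an explicit, configurable stand-in for mixture models fitted to
real data) and combined as the ensemble-weighted average; replicates
share the per-structure profiles, which is what makes them correlated.
Measurement noise is then generated at the *count* level: each
replicate's profile is scaled to a transcript hit rate (mean treated
modification rate 0.03 per probed nucleotide), the untreated background
rate (mean 0.0025, position-variable) is added, treated and untreated
counts are drawn binomially at finite local coverage, and reactivities
are recomputed through the standard pipeline above, with G/U masked in
DMS mode and 2–8% normalization pooled per sample. Coverage is
heterogeneous at both levels (lognormal sd 1 across transcripts and
across positions, median 700), and transcripts hosting planted DRRs are
drawn from the top 20% of the coverage distribution, since regions are
planted only into well-covered transcripts. Count-level noise reproduces
the features of real libraries that matter for calibration — zeros,
discreteness, noise scaling with coverage, independence between
nucleotides — and in particular keeps the null $\Delta d$ profile
essentially uncorrelated (lag-1 autocorrelation near 0), which the
testing step implicitly assumes.

`backCalculateCounts()` exposes the profile-to-counts inversion
separately: raw reactivities are recovered as $r_k h_t / \sum_k r_k$
with $h_t$ the transcript hit rate, untreated rates are added, and
multiplication by treated coverage plus rounding gives integer counts.
Because this recipe adds rates without the $1/(1-r^-)$ background
factor, the forward pipeline reproduces the input exactly only when the
untreated rate is constant along the transcript (the factor is then
absorbed by normalization) or zero; the round-trip tests use those
conditions.

*What the simulator does not emulate.* Real sequence-dependent folding
(ensembles come from a toy sampler), reverse-transcriptase sequence
biases, correlated coverage profiles between samples sharing a library
batch, and the length/abundance distributions of a real structurome.
Passing the synthetic checks therefore demonstrates correct behaviour of
the statistics under realistic noise structure, not performance on any
particular organism's data. The default problem size for the
transcriptome-scale checks — 300 transcripts of 150 nt with 100 planted
DRRs, analysed at search length 11 — was fixed as a desk-scale design
point, with power reported rather than benchmarked.

## The riboSNitch scorer

For PARS trio data (mother/father/child, no replicates), variant-centred
structural change is scored pairwise. V1 and S1 counts are smoothed as
5-nt pseudocounted window sums,
$\bar r_i = \log_2\!\sum_{j=i-2}^{i+2}\frac{V1_j+5}{5} -
\log_2\!\sum_{j=i-2}^{i+2}\frac{S1_j+5}{5}$ (edges undefined), the two
individuals' profiles are compared as
$\Delta\bar r_i = |\bar r_{i,1} - \bar r_{i,2}|$, and the change score
at variant site $k$ is $v_{SNV} = \tfrac15\sum_{i=k-2}^{k+2}
\Delta\bar r_i$. Significance comes from permuting the *non-zero*
$\Delta\bar r$ values 1000 times (zeros and undefined edges stay in
place), recomputing the score at the variant window, and taking the
fraction of null scores strictly greater than the observed one; BH
adjustment runs across all variants. A region is flagged a riboSNitch
only if every criterion holds: $p$ and $q$ significant (defaults 0.05
and 0.1), $v_{SNV} > 1$, and adequate window coverage and signal. The
coverage/signal thresholds default to a mean 11-nt window count of 10
(the same rule as the variant pre-filter) and a mean absolute smoothed
score of 0.1 — explicit package choices, since no canonical numbers
exist for "high". Candidate variants are pre-filtered by collapsing
duplicates at one genomic locus with identical count windows (isoform
duplicates) and excluding variants whose mean $(V1+S1)$ over the
centred 11-nt window falls below 10 in any cell line.

A caveat worth demonstrating (and covered by a test): smoothing makes
neighbouring $\Delta\bar r$ values correlated, but permutation destroys
that correlation, so the permutation null is systematically *narrower*
than the true sampling distribution of $v_{SNV}$ under the null — the
permutation p values are anti-conservative on smoothed data. The
two-group d-score framework above, run in guided mode on the same
regions, does not share this defect and is the recommended analysis
when replicates (or surrogate replicates, such as allelically identical
individuals) are available.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `l` | 11 nt | search length; minimum reportable region length, smoothing window. Results depend on it and no automatic selection is attempted. |
| `alpha` | 0.05 | q-value cutoff defining DRRs. |
| `maxDWithin` | 0.5 / 0.2 | minimum quality threshold on mean within-group d (SNR 1; SNR ~3 when a group has one replicate). |
| `signalThreshold` | 0.1 | reactivity magnitude below which a nucleotide counts as uninformative for screening/trimming. |
| `exactLimit` | 25 pairs | switch from the exact signed-rank distribution to the corrected normal approximation. |

## Known limitations

The search length is user-chosen and results vary with it; regions
dominated by zero or very low reactivities are invisible; reported
boundaries favour the longest contiguous stretch and may join nearby
regions separated by less than about twice the search length; isolated
single-nucleotide changes are diluted away by windowing, and the exact
test cannot flag regions with fewer than 5 informative nucleotides;
normalization quality is the user's responsibility, although the quality
threshold filters regions with poor replicate agreement. Computing
$d_{within}$ from only the less-variable group (useful when one group is
known to be far noisier) is exposed as a stub flag but is not validated
here. Differentially *structured* regions that swap pairing partners
while remaining paired do not change reactivity and cannot be seen by
any reactivity-based method.
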