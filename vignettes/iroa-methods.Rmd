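---
title: "Dual-label isotopologue pair analysis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-label isotopologue pair analysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iroapairs)
```

## The experimental design this package analyses

Isotopic ratio outlier analysis (IROA) grows treatment and control cultures
in media whose carbon sources are uniformly 95:5 ^12^C:^13^C labeled, so
every biosynthesized metabolite carries ~5% ^13^C per carbon atom. A second
set of "standard" cultures — grown under *both* conditions in 5:95-labeled
media and pooled at harvest — provides an internal standard (IS) that
contains a ~95% ^13^C isotope of every metabolite produced under either
condition. The pooled IS is spiked into each sample before extraction, so
each run contains two isotopic populations of every metabolite.

Three consequences drive the whole pipeline:

1. **Metabolites appear as peak pairs.** The light population's monoisotopic
   ion is the all-^12^C species; the heavy population's is the all-^13^C
   species. Their m/z gap is $n \cdot \Delta / z$ with
   $\Delta = 1.0033548$ Da, so the gap reads out the carbon count $n$
   directly, and any signal without an isotopic twin (solvent clusters,
   plasticizers, electronic noise) is excluded as non-biological.
2. **The IS cancels nuisance variation.** Quantities are the ratio of
   sample-channel to IS-channel area; extraction and injection effects
   divide out, and scaling all IS areas of a metabolite leaves
   treatment-versus-control fold changes unchanged.
3. **On/off metabolites remain measurable.** Because the IS pools both
   conditions, a metabolite whose production is *initiated* (absent from
   control) or *terminated* (absent from treatment) still has an IS
   denominator in every run; only its sample channel is missing, which is
   exactly the evidence the regulation classifier uses.

## Envelope model

Under uniform labeling each carbon is independently ^13^C with probability
$p$, so the number of ^13^C atoms in an $n$-carbon metabolite is
$\mathrm{Binomial}(n, p)$ and the isotopologue envelope over $k = 0..n$ is
the binomial pmf (`carbon_isotopologue_envelope()`). Natural-abundance
contributions of H, N, O and S are ignored: the enforced 5% / 95% carbon
labeling dominates the envelope shape. Sulfur- or chlorine-rich patterns are
out of scope. For $p > 0.5$ the envelope is computed as the reversed
light-side pmf so the mirror identity
$E(n, p)_k = E(n, 1-p)_{n-k}$ holds to machine precision. Note the mode of
the light envelope is $\lfloor (n+1)p \rfloor$ — the all-^12^C ion itself
only up to $n = 18$ at $p = 0.05$ — but the all-^12^C member is always
within a factor ~2.8 of the mode and is always emitted.

## Detection: clustering, channel calls, pairing

**Clustering** chains centroid peaks of one run greedily in m/z order: a
peak extends a cluster when it sits one spacing $\Delta/z$ above the last
member within the ppm tolerance and co-elutes with the cluster apex.

**Channel classification** scores each cluster envelope by cosine similarity
against binomial templates over candidate carbon counts: light templates
anchored at the low-m/z end (sample channel) and heavy templates anchored at
the high-m/z end (IS channel). Two numerical guards matter:

* *Coverage gate.* A candidate $n$ is scored only when the observed window
  covers ≥ 90% of the template's probability mass. A short window of a long
  template can mimic almost any shape (a flat doublet matches the first two
  members of a 12-carbon light template at cosine 0.96); clusters emitted
  above the 0.5% centroid floor always cover > 97% of their true template,
  so the gate costs nothing on real signals.
* *Joint clusters.* For small carbon counts (roughly $n \le 5$) the light
  and heavy envelopes of one metabolite overlap on the shared m/z grid
  $\mathrm{mono12} + k\Delta$ and centroiding merges them into a single
  chained cluster. Such clusters are recognized by a nonnegative
  two-template mixture fit (closed-form 2×2 least squares, clamped); the fit
  also apportions the cluster area between the channels, and the cluster
  yields a peak pair directly. Without this path every 2–5-carbon metabolite
  would be undetectable.

**Pairing** searches, for each sample-channel cluster, IS-channel clusters
that co-elute and whose monoisotopic gap (IS top minus sample base) is an
integer number of spacings for some $n$ in the allowed range (default
2–36; $n_{\min} = 2$ suppresses spurious one-carbon gaps). The ppm
tolerance is applied *on the m/z scale*: adjacent carbon counts differ by
~2500 ppm of m/z at 400 Th, so carbon misassignment would require a gross
mass error, whereas a tolerance expressed in ppm *of the gap* would be
violated by ordinary instrument noise (two 3-ppm errors on 400 Th ions are
hundreds of ppm of a small gap). The residual is still reported in ppm of
the gap for diagnostics. Both partners must additionally fit the
gap-implied $n$'s channel template at cosine ≥ 0.95 (`consistency_min`):
intact envelopes score ~0.999 while cluster fragments created when mass
noise breaks a chain link top out near 0.93 against any wrong-$n$ template,
so this threshold blocks fragment mispairs without costing true pairs.
Cross-channel pairs require ≥ 2 member peaks per cluster, which excludes
single-peak artifacts that could otherwise satisfy a gap-plus-retention-time
coincidence. Candidates are ranked (pair score, gap residual, co-elution,
IS area) and matched one-to-one greedily; everything unpaired is discarded.

**Alignment** across runs is greedy centroid matching per polarity (carbon
count must match exactly; m/z within the ppm tolerance of the running-mean
centroid; retention time within a window twice the within-run tolerance,
since between-run drift exceeds co-elution spread). Two consolidation
passes follow: co-located rows with equal carbon counts are merged (a noisy
run can split a metabolite over two rows under pure greedy assignment), and
where co-located rows disagree on the carbon count the better-supported row
wins — one feature, one carbon count.

## Quantitation, imputation, regulation

Each cell is `area_sample / area_is` when both areas reach the limit of
quantitation (LOQ), otherwise missing. Areas are summed over the emitted
envelope members of a channel, which is robust across carbon counts; a
monoisotopic-only variant is not offered because envelope truncation at the
LOQ would bias it. A row whose IS is below the LOQ in at least half of the
runs *in which the pair was detected* is flagged unquantifiable — the
denominator cannot be trusted. (Counting over all runs instead would flag
every initiated/terminated metabolite, which by design is detected in only
one group's runs.)

Missing cells are imputed as half the row's minimum observed ratio, a
standard left-censoring surrogate; the pre-imputation missingness mask is
preserved. Fold changes are $\log_2$ of the ratio of arithmetic group means
(matching how mean fold changes are usually reported for $n = 4$ designs); a
geometric-mean option exists. Regulation classes: *initiated* when every
control cell was imputed while the metabolite was observed under treatment;
*terminated* mirrored; otherwise *up-/downregulated* at
$|\log_2 FC| \ge 1$ and $p \le 0.001$ (both configurable, mirroring the
common two-fold / 0.001 cut), else *unchanged*. Requiring only one observed
expressed-channel cell (rather than a majority) follows from the design:
the control channel of an initiated metabolite cannot produce a pair at
all, so any treatment observation against an all-missing control is already
the defining evidence.

## Statistics

Row-wise unpaired Student $t$ tests (pooled variance; Welch available) run
on $\log_2$ ratios by default, since ratios are right-skewed. Raw p-values
are the primary filter — mirroring common practice in this design — with
Benjamini–Hochberg q-values reported alongside. Zero pooled variance is
handled explicitly ($p = 1$ for equal means, $p \to 0$ otherwise, flagged).
PCA runs on autoscaled $\log_2$ ratios via `prcomp`, with component signs
fixed so each loading vector's largest-magnitude entry is positive
(determinism) and constant metabolites dropped under autoscaling. The random
forest (via the randomForest package: bootstrap per tree, $\sqrt{m}$
candidate features per split, Gini impurity) reports out-of-bag error,
unscaled permutation importance — the operational definition of mean
decrease accuracy; "removal" of a variable is operationalized as permuting
it, as is standard — the tree-proximity matrix, and a classical MDS
embedding of $1 - \mathrm{proximity}$. All stochastic steps are seeded
through function arguments; identical seeds give identical results.

## Formula identification

With the carbon count fixed by the pair, molecular-formula enumeration
reduces to a small grid over N and O (S and P are available but default to
zero, matching the CHNO-dominant compound classes of actinomycete primary
metabolism): the hydrogen count is pinned by the residual mass, and
candidates are filtered by non-negativity, $H \le 2C + 2 + N$, and a
non-negative integer ring-and-double-bond equivalent. The default match
tolerance is 10 ppm; a documented worked case (carbon count 16 with a
printed $[M+H]^+$ of 385.1761) sits ~11 ppm from the theoretical mass of
C~16~H~24~N~4~O~7~, so that example requires 15 ppm — the tolerance is
widened rather than any constant adjusted. Standards-library identification
requires simultaneous agreement of carbon count, adduct m/z, retention time
and polarity. Electron mass is folded into the proton adduct delta once and
used consistently.

## The synthetic-study generator

`simulate_iroa_study()` emulates the dual-label design so every stage is
testable without instrument data: 200 metabolites by default, drawn from a
bundled pool of plausible CHNO formulas spanning 2–36 carbons (realistic
masses and valences rather than random element counts); 4 + 4 replicates;
category fractions 10% up, 10% down, 5% on, 5% off with effect
$|\log_2 FC| = 2$; lognormal base abundances (meanlog 12, sdlog 1, area
units); multiplicative replicate noise at CV 0.10 on both channels;
Gaussian m/z noise of 3 ppm (1 sd); retention-time jitter of 2 s (1 sd);
LOQ 1000 area units; and unpaired artifact peaks at 10% of the metabolite
count per run (30% in the stress configuration used by the acceptance
checks). The replicate sizes, labeling fractions and carbon range are the
stated study conditions; the remaining values are fixed, field-typical
choices — a Q-Exactive-class instrument motivates the 3 ppm noise and the
10 ppm matching tolerance, and UHPLC peak stability the 2 s jitter.

The IS abundance of each metabolite is the pooled mean of the two group
means, constant across runs up to measurement noise — it is one physical
mixture. "On" metabolites have zero control-channel abundance but a present
IS channel, and mirrored for "off". Envelope members below 0.5% of the
channel maximum are not emitted (centroid realism); coincident grid
positions of the two channels are summed, which is what creates the merged
joint clusters the classifier must handle.

Two stated simplifications bound what passing tests mean for real data.
First, the generator emits *chromatographically resolved* features: two
metabolites whose isotopologue grids coincide within instrument accuracy
(isomers, or masses differing by an integer number of ^13^C spacings) are
kept ≥ 30 s apart. Real isobaric co-elution exists, cannot be
disambiguated from centroid data by any pairing algorithm, and has no
well-defined per-metabolite ground truth. Second, no chromatographic peak
shapes, adduct multiplicity or electronic noise models are simulated:
recovery rates on synthetic data are an upper bound on real-data behavior,
while the *relative* statements (artifact exclusion, carbon-count accuracy,
IS cancellation) transfer.

## Problem sizes and numerical choices

The validation suite runs detection on one 200-metabolite, 8-run study
(~1600 emitted features per run), type-I-error simulation on 10,000 null
rows, brute-force formula cross-checks on 50 random cases up to 500 Da, and
a 500-tree forest; these sizes keep the whole suite near two minutes while
leaving the binomial confidence bands tight enough to be informative. The
random-forest "perfect separator" check is constructed at 10 + 10 samples
with `mtry` equal to the number of metabolites: with 4 + 4 samples a
pure-noise metabolite separates a bootstrap perfectly with probability
~0.2, ties the Gini gain and randomly roots trees, so zero OOB error would
hold only with ~85–90% probability; at 20 samples the probability of such a
tie is ~10^-5^ and the expected outcome is certain for any seed.

Degenerate inputs are handled explicitly: empty peak lists yield empty
tables at every stage; zero IS areas never divide; fully missing and
unquantifiable rows are dropped with messages; ties in pairing and ranking
are broken deterministically (gap residual, co-elution, IS area, row id).

## Known limitations

* Charge states beyond 2 and adduct series other than
  $[M+H]^+ / [M-H]^- / [M+Na]^+$ are not grouped or deconvolved.
* Isobaric co-eluting metabolites on a shared isotopologue grid are merged
  or resolved by support, not deconvolved.
* The imputation rule is a fixed censoring surrogate; it biases fold
  changes of rows with many missing cells toward the observed minimum.
* Formula enumeration scores candidates by mass error only; isotope-pattern
  intensities beyond the carbon constraint and MS² evidence are out of
  scope.
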