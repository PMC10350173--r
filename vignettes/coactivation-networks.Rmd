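---
title: "Brain-wide c-Fos co-activation networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-wide c-Fos co-activation networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coactnet)
```

# The analysis problem

Whole-brain activity mapping counts c-Fos positive cells per anatomical
region in each animal after a behavioural assay (for instance the
resident-intruder test, which separates aggressive residents, AGG, from
non-aggressive ones, NON). The scientific questions this package addresses
are:

1. Which groups of regions are *co-activated* across animals — i.e. form
   modules of a correlation network?
2. Which regions are *hubs* inside a module (highly connected to the other
   members)?
3. Do subjects of different groups (sexes, phenotypes, chemogenetic arms)
   *express* a module more or less strongly?
4. Is a module found in one group's network *preserved* in another group's
   network?
5. Which individual regions differ in raw c-Fos counts between groups?

A companion arm analyses fibre-photometry recordings of a region's calcium
activity during behaviour: baseline-normalised, control-corrected traces
aligned to behavioural bout onsets, with bouts classified by their temporal
context (investigation that precedes an attack vs investigation in
isolation; attack with vs without prior investigation).

Everything is driven by a synthetic-data generator, so each stage is
testable end-to-end without any raw imaging data.

# Network model

Let $s_{ij}$ be the Pearson correlation of region $i$ and $j$ count
profiles across the subjects of one group (`correlation_matrix()`;
Spearman selectable). The soft-thresholded adjacency is

$$a_{ij} = |s_{ij}|^\beta,$$

(`adjacency_power()`, unsigned mode; a signed-hybrid mode that zeroes
negative correlations is available). Raising to the power $\beta$
suppresses weak, potentially spurious correlations while keeping the edge
weight in $[0,1]$. The default $\beta = 6$ is the customary unsigned
default; `pick_soft_power()` alternatively selects the smallest candidate
whose connectivity distribution is approximately scale-free (log–log
regression $R^2 > 0.8$ with negative slope), falling back with a warning.
On networks of some tens of regions the scale-free criterion is erratic —
pure noise networks can satisfy it at high powers because a handful of
extreme correlations then dominates the connectivity distribution — which
is why the fixed default is preferred here.

The topological overlap measure combines the direct edge with the shared
neighbourhood:

$$\omega_{ij} = \frac{\ell_{ij} + a_{ij}}
  {\min(k_i, k_j) + 1 - a_{ij}}, \qquad
  \ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}, \quad
  k_i = \sum_{j \ne i} a_{ij},$$

with $\omega_{ii} = 1$ (`topological_overlap()`). The denominator
normalises $\omega_{ij}$ into $[0,1]$; `tests/` verify the bound on random
adjacencies and equality with a brute-force triple loop to $10^{-10}$.

## Module detection

`detect_modules()` clusters regions by average-linkage hierarchical
clustering of the *log-scale* overlap dissimilarity $-\log \omega_{ij}$ and
cuts the tree at a configurable fraction (default 0.4) of the way between
the lowest and highest merge. Working on the log scale is a deliberate
design choice: the soft power $\beta$ acts on $-\log\omega$ approximately
as a multiplicative constant, so a *relative* cut behaves consistently
whichever power produced the adjacency. A classic static cut of
$1-\omega$ is kept as `cut = "absolute"`, but on region-scale networks the
absolute TOM magnitudes shrink rapidly with $\beta$ (with tens of regions
every merge can sit above 0.9), making any fixed absolute height unusable
across powers — this motivated the relative log-scale rule.

Two refinement passes make the cut robust on noisy networks, both using
only the TOM:

* *Consolidation*: every region is reassigned to the module with the
  smallest mean log-dissimilarity to its members, provided that attachment
  is below the cut height; otherwise it becomes unassigned. This re-adds
  genuine members the initial cut split off and releases loosely attached
  ones.
* *Attachment-gap pruning*: within each module, member attachments are
  sorted and the module is pruned above the largest gap when that gap
  exceeds 8% of the dendrogram height range. Passenger regions that merged
  into a module by chance attach far above the genuine members, separated
  by a visible gap; genuine members form a continuum.

Clusters smaller than `min_module_size` (default 3) are sent to the
reserved `"unassigned"` label. Modules are named by colour in decreasing
size order with lexicographic tie-breaks, so labelling is deterministic.
These defaults were frozen after validating recovery of planted modules
(4 modules of 8–15 regions, within-correlation 0.6, 40 subjects) on two
independent 40-replicate batches across powers 4–12.

## Module expression and hubs

`module_expression()` standardises each member region across subjects and
takes the singular value decomposition of the subject-by-region submatrix
$X = U D V^\top$: the leading left singular vector $u_1$ gives one score
per subject (the module eigengene) and $\sigma_1^2 / \sum_k \sigma_k^2$
the proportion of variance explained. Scores are sign-oriented to
correlate positively with the mean standardised profile, so results do not
depend on the sign indeterminacy of the decomposition. A variant applying
the SVD to the module's TOM submatrix is available via `input = "tom"` for
audits; it cannot yield per-subject scores (a region-by-region matrix has
no subject dimension), which is why the eigengene construction is the
default for group comparisons.

`connectivity_profile()` reports, per member region, the intramodular
connectivity kIM (sum of adjacency to the other members), the module
membership kME (correlation of the region's standardised profile with the
module scores), and the maximum adjacency ratio
$\mathrm{MAR}_i = \sum_j a_{ij}^2 / \sum_j a_{ij}$ over same-module
partners — equal to the mean edge weight under equal weights and
approaching the strongest weight under concentration. kIM and MAR are
computed within-module, the natural scope for label-permutation
preservation. `rank_hubs()` orders members by kIM (lexicographic
tie-break) and reports the mean within-module edge weight.

## Module preservation

`module_preservation()` asks whether a module defined in a *reference*
network retains its connectivity and density in a *test* network. Nine
base statistics are computed (`preservation_base_statistics()`):
connectivity — correlations, between reference and test, of kIM, kME,
kME-of-all-regions, the vectorised within-module correlation submatrix
(cor.cor), and MAR; density — the variance explained by the module's
leading singular pair in the test data, the sign-aware mean correlation
$\mathrm{mean}\,\mathrm{sign}(s^{ref})\,s^{test}$, the mean within-module
test adjacency, and the mean test MAR. The permutation null redraws the
module's label set uniformly over all test-network regions (size
preserved) and recomputes *all* statistics jointly per draw; each
$Z = (\text{observed} - \overline{\text{perm}})/\mathrm{sd}(\text{perm})$.
Degenerate permutation distributions yield a flagged infinite Z rather
than a silent number. `preservation_summary()` offers a median-of-Z
aggregate per module — a convention of this package, not a standard
composite.

A quantitative caveat documented here deliberately: connectivity
statistics that are correlations over the module's $m$ regions have a
permutation null with standard deviation of order $1/\sqrt{m-3}$ — about
0.27 at $m = 15$ — so their Z values are bounded by roughly 3–4 no matter
how perfectly a small module is preserved. Large Z values for small
modules can only come from the density statistics (whose nulls concentrate
sharply; simulated preserved modules reach $Z \approx 10$–40) — the
connectivity correlations become powerful only for modules with hundreds
of members, as in transcriptomic applications. The package therefore
reports both families and the tests judge disruption primarily by the
density Z's dropping to the null.

## Region-wise count statistics

`fit_region_nb()` models one region's counts as negative binomial with a
log link, intercept plus a 0/1 group dummy, variance
$\mu + \mu^2/\theta$. Coefficients and dispersion are jointly maximised by
iteratively reweighted least squares (Fisher scoring with weights
$\mu/(1+\mu/\theta)$) alternated with maximum-likelihood updates of
$\theta$ on the log scale, until the log-likelihood stabilises. The
reported $z$ is the group coefficient over its expected-information
standard error; $p$ is two-sided normal. Tests verify agreement with joint
brute-force likelihood maximisation to $10^{-4}$ and with the standard
glm.nb implementation. Degenerate inputs (an all-zero group) return a
flagged sentinel and are excluded from multiple-testing adjustment with a
warning, keeping the screen deterministic. `run_region_screen()` applies
the fit to every region and adjusts p-values with Benjamini–Hochberg
(`bh_adjust()`, backed by `p.adjust`); the q < 0.05 convention is the
caller's threshold, not baked in. The model is intercept + group only —
no further covariates are assumed — with dispersion estimated per region.
At 15 subjects per group the normal approximation is mildly
anti-conservative (null rejection rates around 0.06–0.09 at nominal 0.05);
calibration tests therefore use 30 per group, where the rate sits inside
the three-sigma Monte-Carlo band of 0.05.

# Photometry model

`preprocess()` implements the signal pipeline: the 415 nm control channel
is subtracted from the 470 nm signal channel as a raw difference (the
literal pipeline; a least-squares rescaled subtraction is available via
`control_fit = "regress"`); $F_0$ is the mean corrected fluorescence over
the final 60 s of the pre-stimulus baseline window;
$\Delta F/F = (\text{corrected} - F_0)/F_0$; the result is z-scored over
the whole session (a baseline-scoped variant via
`zscore_scope = "baseline"`, since the wording of session-level z-scoring
is ambiguous in common protocols). $F_0 \le 0$ and zero-variance traces
are explicit errors — the algebra is undefined, not silently patched.
The z-scored output is invariant to affine rescaling of raw fluorescence
units (property-tested to $10^{-10}$).

`classify_bouts()` labels each investigation bout by whether an attack
starts within a configurable gap (default 2 s — the gap is not a measured
quantity, so it is exposed and reported in outputs) after the bout ends,
and each attack by whether an investigation ends within the gap before its
onset. `peri_event()` cuts the trace into onset-aligned trials (windows of
4 s before/after by default, 2 s for odour-style analyses), excluding and
counting trials whose window leaves the recording. `pre_post_stats()` and
`compare_classes()` summarise per-trial pre/post means with
Wilcoxon tests; single-trial classes are descriptive only.

# The synthetic-data generator

`simulate_counts()` draws, per subject, a latent standard normal vector
with a one-factor-per-module block structure — member $i$ of module $m$
has $z_i = \lambda_i f_m + \sqrt{1-\lambda_i^2}\,\varepsilon_i$ with
$\lambda_i = \sqrt{\rho}$, so within-module latent correlation is exactly
$\rho$ — maps it through the normal CDF and takes negative binomial
quantiles (Gaussian copula). This is the simplest mechanism that produces
correlated, overdispersed counts marginally matching the NB model the
region screen assumes, making the network and regression stages jointly
testable. Three optional realism features:

* a length-2 `rho = c(lo, hi)` grades the loadings linearly, giving the
  module the connectivity gradient (hub structure) real co-activation
  modules display;
* `hub_multiplier` doubles (or scales) the first member's loading, the
  planted-hub benchmark;
* `background_rho` adds a weak global factor shared by all regions,
  emulating brain-wide state covariation.

Background regions are independent NB noise — the null that module
detection must reject. Group-by-module effects multiply the NB mean.
Defaults: `nb_mean = 100`, `nb_dispersion = 10` (coefficient of variation
about 0.33 at the default mean, typical of between-animal c-Fos counts;
per-region count distributions are not published, so these are chosen for
test power, not fitted realism).

`simulate_photometry()` produces two channels at 40 Hz: signal =
baseline × single-exponential bleach + difference-of-exponentials
transients (rise 0.2 s, decay 1.5 s, peak-normalised) + white noise;
control = the same bleach scaled by `control_scale` (default 0.8 —
autofluorescence is dimmer than the calcium-dependent baseline; 1 makes
the channels identical in the noiseless transient-free case) + independent
noise. The control scale keeps the control-subtracted baseline positive,
as the $F_0 > 0$ contract requires. The pipeline must be robust to, not
dependent on, these particular shapes.

What the generator does *not* emulate: anatomical spatial autocorrelation,
count heteroscedasticity across regions, registration/segmentation errors
upstream of the count table, photometry motion artifacts that differ
between channels, and bout-annotation noise. Passing tests therefore
demonstrate the pipeline's correctness and statistical behaviour under the
stated model, not robustness to those artefacts.

# Orchestration and reproducibility

`pipeline_config()` collects every tunable named above;
`run_network_arm()` builds the reference network, transfers its module
labels to the test group's network by region identity (modules always
originate in the designated reference network), computes expression, hub
rankings, preservation and the region screen; `run_photometry_arm()`
preprocesses sessions, classifies bouts and pools per-class summaries,
skipping unreadable sessions with a logged error. All outputs are
delimited text stamped with the seed; a single top-level seed drives every
stage, and rerunning an identical configuration reproduces outputs byte
for byte (asserted in the test suite). A thin command-line wrapper with
`simulate` / `network` / `screen` / `photometry` / `run-all` subcommands
over a YAML config ships in `inst/scripts/coactnet-cli.R`; the exported
functions are the primary interface.

Problem sizes used by the test-suite simulations — 60-region brains with
4 planted modules for recovery, 200-region universes for preservation,
200-region screens for calibration, 100 replicates for hub ranking — were
chosen as the smallest sizes at which the statistical claims stabilise.

# Known limitations

* Which subjects enter each network (pooling sexes or not) and the
  contrast used for the region screen are configuration, not opinion; the
  package defaults pool whatever subjects the caller selects.
* Module detection tie-breaks (equal-size modules, equal attachments) are
  lexicographic by region id — deterministic but arbitrary.
* The preservation permutation reshuffles region sets of fixed size; no
  quality (within-network reproducibility) or cross-tabulation statistics
  are provided.
* No spatial smoothing, atlas-ontology rollups, consensus networks across
  cohorts, or spike deconvolution.
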