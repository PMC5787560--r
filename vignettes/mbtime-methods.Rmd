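---
title: "Methods and modelling choices in mbtime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modelling choices in mbtime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbtime)
```

`mbtime` is a headless toolkit for longitudinal microbiome analysis: one
subject (or environment) sampled repeatedly over time, summarized as a
taxa-by-timepoint abundance matrix. This vignette explains the statistical
machinery behind each workflow, the tunable parameters and their defaults,
what the synthetic generators do and do not emulate, and the numerical
decisions that were genuinely open.

## Data model and ingestion

The central container (`mbtime_dataset`) holds a non-negative taxa × time
matrix for a single source, strictly increasing time stamps, a condition
label per time point, optional greengenes-style lineage strings, and a
normalization flag. Two input dialects are parsed: the QIIME-classic OTU
table (header `#OTU ID` or `#OTU_ID`, taxonomy column named
`Consensus Lineage` or `taxonomy`) and plain TSV with row identifiers in
the first column. Metadata requires `sample_id`, `source`, `time`,
`condition`.

Time stamps are treated as **ordinal positions** by every algorithm (DTW,
Granger regressions, the Dickey-Fuller regression): the actual spacing is
recorded and carried through, but unevenly spaced series are *not*
resampled, and a warning is raised when spacing is non-uniform. This is the
simplest defensible treatment when no sampling-interval model is available;
users with strongly irregular designs should interpolate to a regular grid
before analysis.

Ties in time within a source are rejected rather than averaged, because
every downstream method assumes one observation per time point.
Aggregation to a taxonomic level sums rows sharing the lineage prefix;
blank or missing ranks join an `Unclassified` group at that rank, and
column totals are conserved exactly.

## Normalization

Two normalizations are supported, mirroring common practice:

* **relative** — columns scaled to proportions; all-zero columns are left
  at zero with a warning rather than producing NaNs;
* **rarefaction** — each column subsampled *without replacement*
  (multivariate hypergeometric, implemented by shuffling the expanded read
  vector) to an even depth; columns below the depth are dropped with a
  warning. The seed is an explicit argument: rarefaction is the one
  stochastic preprocessing step, and reruns with the same
  (data, depth, seed) are bit-identical.

Rarefaction curves report mean observed richness over a configurable
number of replicate subsamples (default 10) per depth; at full depth the
curve equals the observed richness exactly, which the tests assert, and at
intermediate depths it tracks the closed-form hypergeometric expectation
$\sum_i \left(1 - \binom{N-c_i}{d}\big/\binom{N}{d}\right)$.

Both normalized views remain compositional: a real change in one abundant
taxon induces apparent changes in all others. None of the analyses below
correct for compositionality (no CLR/ILR transforms are provided), so
correlation- and causality-style outputs should be read with that caveat.

## Diversity and prevalence classes

Richness is the count of taxa with abundance strictly greater than zero;
no minimum-count presence filter is applied. Diversity is the Shannon
index $H = -\sum_i p_i \ln p_i$ with natural logarithm, computed over the
positive proportions of each column; it is invariant to rescaling and
bounded by $\ln R$ at richness $R$.

Prevalence classes use two per-taxon statistics: *prevalence* (fraction of
time points present) and the *longest-run fraction* (longest consecutive
presence run ÷ number of presence points). The rules, with all four
thresholds user-overridable:

* **core** — present at every time point;
* **persistent** — prevalence > 0.20 and run fraction ≥ 0.90;
* **transient** — prevalence ≥ 0.60 and run fraction ≤ 0.75;
* **other** — anything else.

"X% of the observations being consecutive" is formalized as the
longest-run fraction — the simplest reading that makes the persistent and
transient rules graded versions of "one solid block" versus "scattered
visits". The rule regions can overlap for unusual threshold choices, so
precedence core > persistent > transient is applied; with the defaults a
taxon with run fraction strictly between 0.75 and 0.90 falls through to
*other*, which is intended (it is neither clearly blocked nor clearly
scattered).

## Stationarity screening

Each taxon's series is tested for a unit root with an augmented
Dickey-Fuller regression

$$\Delta y_t = \alpha + \rho\, y_{t-1} + \sum_{i=1}^{p} \phi_i\,
\Delta y_{t-i} + \varepsilon_t,$$

optionally with a linear trend term. The statistic is the $t$-ratio of
$\hat\rho$; more negative values reject the unit-root null more strongly.
Because no unit-root test ships with the package's dependencies, the
regression, the AIC lag search (candidates $0..p_{max}$ compared on a
common sample, $p_{max} = \lfloor (n-1)^{1/3} \rfloor$ by default, then
the chosen order refit on the full sample) and the MacKinnon (1994)
response-surface p-value approximation are implemented directly; unit
tests pin statistics and p-values to an independent reference
implementation to 10 decimal places.

Decisions and defaults:

* deterministic terms: constant only. Relative-abundance series have no a
  priori trend; a `constant_trend` option exists.
* `alpha = 0.05` for the stationary/non-stationary call, on **raw**
  p-values (one decision per taxon, as screening tools usually report); a
  Benjamini-Hochberg adjusted column is emitted alongside for cautious
  readers.
* constant series are reported as *untestable* (NA with a note), never as
  stationary.
* `transform = "log10"` runs the test on `log10` abundances. The
  Dickey-Fuller regression is linear and its null distribution is not
  preserved under strongly convex transforms; for heavy-tailed
  (log-normal-like) abundance data the log scale is the appropriate one.
  The default remains `"none"` so the user's normalization choice is
  respected.

A note on planted-mixture expectations: with two planted random walks in a
dataset, the probability that *both* survive a 5%-level test is at most
$0.95^2 \approx 0.90$ even for a perfectly calibrated test, so exact
recovery of the planted non-stationary set is asserted in the test suite
at `alpha = 0.01`, alongside the sharper properties that non-stationary
calls are only ever planted walks and that the walks carry the two largest
p-values.

## Temporal-shape similarity

Dynamic time warping aligns two series with the standard
match/insert/delete step pattern and local cost $|x_i - y_j|$; a
Sakoe-Chiba band of half-width $w$ (default $\max(10, \lceil 0.1T
\rceil)$, the classical 10% convention) restricts the dynamic program to
$|i-j| \le w$. The kernel is implemented in C++ (two rolling rows); the
test suite checks it exactly against an exhaustive enumeration of all
warping paths on short series, banded and unbanded.

The bounded distance used for clustering adds two steps:

1. z-normalize each series with the population SD (constant series are
   rejected, not imputed), making the index shift- and scale-invariant;
2. divide the banded DTW distance by the mean of each normalized series'
   sum of absolute differences from its mirror image $-\tilde s$ — the
   pointwise-dissimilarity scale of a shape against its own reflection —
   and clip at 1.

For a 2-point alternation the ratio is exactly 1; warping can re-align
longer alternations against their mirrors, so values near 1 indicate
shapes that stay maximally dissimilar *even after* warping. The DTW cost
is **not** path-length-normalized before division (recorded in output
metadata); with the band default the alignment lengths of same-length
series differ little, and the clip guards the residual pathological cases
(clips are rare: none occurred in a 1000-pair Gaussian battery).

Pearson correlation is offered as the fast linear alternative
(distance $1-r$, raw $r$ retained for heatmaps). Hierarchical clustering
uses average linkage by default and exports Newick trees with branch
lengths from merge heights.

## Causality networks

Pairwise Granger causality compares nested least-squares fits of
$y_t$ on its own lag(s), with and without the lag(s) of $x$, via the
standard F statistic; the implementation is a direct nested-QR
computation, cross-checked in tests against an independent library
implementation to $10^{-8}$. The multivariate alternative fits, for each
target taxon, an L1-penalized regression of its present on the lag-stacked
past of *all* taxa (each series z-standardized so the shared penalty is
scale-fair), with the penalty chosen by 5-fold cross-validation on a
deterministic fold assignment and the one-standard-error rule — the
parsimonious choice, which in the planted-support simulations recovers all
true edges with almost no false ones. An edge $i \to j$ survives when any
lag of $i$ keeps a nonzero coefficient ($|\beta| > 10^{-8}$) in $j$'s
model.

Network assembly filters rare taxa first (default prevalence cutoff 0.5),
then keeps pairwise edges whose Benjamini-Hochberg-adjusted p-values pass
`alpha` (raw p-values are exported too), lasso support edges, or their
intersection — the conservative option that in simulations has precision
at least that of either method alone. Node attributes carry the
stationarity flags so non-stationary taxa can be highlighted in downstream
renderings. Series are *not* differenced before testing, matching the
screening character of the tool; the run metadata records this, and
Granger edges should be read as statistical predictability, not
mechanistic causation — a common-cause taxon can induce edges between its
children.

`transform = "log10"` is available here for the same reason as in the
stationarity screen: the linear VAR machinery is dominated by the largest
values on raw heavy-tailed abundances. In the package's own simulations
(log-normal marginals by construction) support recovery collapses on the
raw scale and is essentially perfect on the log scale; real count data is
typically analysed log- or rank-transformed for the same reason.

## Community states

Time points are compared by Jensen-Shannon divergence between their
compositions, $\mathrm{JSD}(P,Q) = \tfrac12 KL(P\|M) + \tfrac12 KL(Q\|M)$
with $M = (P+Q)/2$, natural log (consistent with the Shannon index),
zero-probability terms contributing 0, hence values in $[0, \ln 2]$. The
square root of JSD is a metric, which the tests verify on random triples.

Clustering is K-medoids in its classic PAM form: a greedy BUILD phase and
best-improvement SWAP passes whose objective (total distance to nearest
medoid) is non-increasing by construction — the implementation exposes the
objective trace so this is asserted, and its final objective is checked
against the reference PAM implementation in the test suite. Given the
distance matrix, the algorithm is fully deterministic (ties break to the
lowest index); the `seed` argument exists only for interface symmetry.
`k` is a user choice (default 2); an advisory silhouette table over
$k = 2..6$ is emitted rather than any automatic selection.

Driver taxa are ranked by between-state contrast — the range of per-state
mean relative abundances — which puts taxa that distinguish states first;
"most dominant" alone would rank ubiquitous abundant taxa that do not
separate states.

## Two-window differential abundance

For two non-overlapping windows of at least 3 points each (selected by
inclusive index pairs or by condition label), each taxon gets window
means, a log2 fold change $\log_2\frac{m_2 + c}{m_1 + c}$ with pseudocount
$c$ = half the smallest nonzero abundance (so zeros are representable
without dominating), a two-sided Wilcoxon rank-sum test (exact for
windows ≤ 20 without ties, normal approximation with tie/continuity
correction otherwise; identical windows short-circuit to $p = 1$),
Benjamini-Hochberg correction across taxa, and an `eliminated` flag for
taxa present before and absent after. Swapping the windows negates every
fold change and preserves every p-value exactly.

## Synthetic generators

All generators are pure functions of their seed and write, on request, the
abundance/metadata/ground-truth files consumed by the command-line
workflows. Latent dynamics are Gaussian and abundances are obtained by
exponentiation (log-normal marginals) — deliberately, because truncating
negatives to zero would inject spurious zero-inflation into the prevalence
logic. Default problem sizes (≤ 20 taxa, ≤ 300 time points) keep the whole
battery at desk scale.

* `simulate_var` — stable VAR(1) latent dynamics with a planted edge list
  (stability enforced via the spectral radius). Power/size studies use the
  planted coefficient 0.8 (pair) and a 10-taxon, 3-edge, coefficient-0.7
  design over 300 points.
* `simulate_unit_root_mix` — white-noise taxa plus random walks with
  innovations scaled to 0.25 so exponentiated levels stay numerically
  tame.
* `simulate_two_states` — Dirichlet draws (precision 100) around two
  state compositions, default blocks of 30 + 30; the centres used in the
  tests (uniform vs two taxa at 0.3) are clearly separated but noisy.
* `simulate_shape_groups` — two sinusoidal shape groups in antiphase plus
  noise, for clustering recovery.
* `make_prevalence_fixture` — eight hand-constructed presence patterns
  whose classes under the default thresholds were derived by hand and
  stored as ground truth.

What these generators do **not** emulate: sequencing-depth variation and
count noise, sparsity/zero-inflation, compositional closure of real
libraries, irregular sampling, and taxonomic correlation structure.
Passing the planted-structure tests therefore demonstrates that the
algorithms recover the signals they model, at realistic desk-scale sizes —
not that those signals are recoverable from any particular real dataset.

## Numerical and degenerate-input decisions

* Log scaling is base 10 with pseudocount 1 for counts and half the
  smallest nonzero value for proportions.
* Quartile segregation ranks by mean abundance over time (ties broken by
  row order, deterministically) and splits the ranking at its quartiles.
* Moving averages are trailing (no look-ahead), with shorter prefixes at
  the start.
* All-zero columns: warned and left zero by relative normalization,
  an error in JSD (a time point with no observations has no composition),
  `NA` with a warning in the Shannon index.
* The acceptance script and every stochastic test derive their seeds from
  a single integer; reruns are byte-identical, including all command-line
  workflow outputs (asserted by hashing).

## Known limitations

No compositional transforms; no handling of irregular sampling beyond a
warning; Granger and ADF assume linear dynamics on the chosen scale; no
paired or mixed-model differential testing; `k` for community states is
user-chosen; DTW is univariate per taxon pair and single-threaded.
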