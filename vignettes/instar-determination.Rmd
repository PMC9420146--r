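---
title: "Determining larval instars from head-capsule widths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining larval instars from head-capsule widths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(instarmix)
library(dplyr)
```

## The problem

Insect larvae grow through a fixed number of instars separated by moults.
The sclerotized head capsule does not grow within an instar, so its width
(HCW) is essentially constant within an instar and jumps at each moult. A
sample of field-collected larvae of mixed ages therefore shows a
multi-modal HCW frequency distribution with one mode per instar, and the
classical instar-determination problem is to decide how many modes the
distribution has and where to cut it.

`instarmix` treats the sample as a univariate Gaussian mixture: instar $i$
contributes a weighted normal component $w_i\,N(x \mid \mu_i, \sigma_i)$,
with $\sum_i w_i = 1$. The analysis pipeline is:

1. fit mixtures with $k = k_{\min}, \dots, k_{\max}$ components by maximum
   likelihood (EM) and pick $k$ by BIC;
2. place the boundary between adjacent instars at the width where the two
   weighted normal curves intersect;
3. assign every larva to an instar and validate the partition with the
   standard morphometric criteria (coefficient of variation, Brooks' index,
   Crosby's growth rule);
4. check Dyar's rule by regressing $\ln(\text{mean HCW})$ on instar number.

## Model and estimation

### Mixture fit

The default fit maximises the raw-data likelihood with EM. Historically
this analysis is often done by fitting a sum of Gaussian curves to the
binned frequency histogram in interactive software; that procedure depends
on the (usually unreported) bin width. Maximum likelihood on the raw values
is bin-independent and statistically more efficient, which is why it is the
default here. A `fit_mode = "histogram"` option is provided for fidelity to
the curve-fitting tradition: it performs nonlinear least squares of a sum of
amplitude-parameterised Gaussians against the bin counts and then converts
amplitudes to mixing weights via component areas ($w_j \propto A_j
\sigma_j$). Whether a histogram-based fit constrains areas or amplitudes is
ambiguous in most published analyses; we fit amplitudes and normalise.

EM details:

* **Initialisation.** Component means start at the $k$ interior quantiles
  of the data (probabilities $(j - 1/2)/k$), SDs at the pooled
  $\mathrm{sd}(x)/k$, weights equal. This is deterministic; the seed only
  matters when a restart is needed.
* **Degeneracy.** A component whose SD collapses to the floor while
  carrying almost no posterior mass triggers a restart from jittered means
  (seeded, up to 10 restarts), then an error. The SD floor is 1 µm —
  below the precision of stereo-microscope measurements, so it never binds
  on real data.
* **Convergence.** Iteration stops when the log-likelihood increment falls
  below `tol` (default 1e-8) or after `max_iter` (default 1000) iterations.
  The log-likelihood trace is stored; EM guarantees it is non-decreasing,
  and the test suite asserts that on every fit it runs.
* **Model selection.** BIC $= -2\hat\ell + (3k - 1)\log n$, minimised over
  the candidate range, ties broken toward smaller $k$. The per-$k$ table is
  attached to the result so the automatic choice can be compared with a
  visual peak count.

### Instar boundaries

The dividing point between instars $i$ and $i+1$ is the solution of
$w_i N(x \mid \mu_i, \sigma_i) = w_{i+1} N(x \mid \mu_{i+1}, \sigma_{i+1})$
that lies strictly between the two means. On the log scale this is a
quadratic in $x$ (linear when the SDs are equal), solved in closed form;
the root strictly between the means is kept, and if both quadratic roots
were interior the one nearer the equal-density midpoint would be kept (a
guard — with crossing densities and distinct means only one interior root
occurs). With extreme weight imbalance no interior crossing may exist; that
raises an informative error rather than silently placing a boundary. A
`boundary_mode = "unweighted"` flag intersects the unit-weight curves
instead, since published descriptions of "the intersection of adjacent
normal curves" often leave the weighting ambiguous; weighted is the default
because it is the Bayes-optimal cut between components.

Assignment uses open-left/closed-right intervals: a larva exactly on a
boundary joins the lower instar. The tie rule is arbitrary but fixed and
documented; with continuous measurements ties have probability zero.

### Validation criteria

For instar means $\bar x_n$, Brooks' index is $b_n = \bar x_n / \bar
x_{n-1}$ (defined from the 2nd instar) and Crosby's index is $(b_n -
b_{n-1}) / b_{n-1}$ (defined from the 3rd). The pipeline's criteria are the
conventional ones: every within-instar CV strictly below 15% and every
Crosby index strictly below 0.1 **in magnitude**. The magnitude reading
matters: a healthy partition can give a negative Crosby index (growth ratio
slightly decreasing with instar), and only $|$Crosby$|$ makes the criterion
informative in that case. Both thresholds are configuration defaults, not
constants. CV and SE use the sample ($n-1$) SD, the convention for small
morphometric samples.

### Dyar's rule

Dyar's rule says HCW grows by a roughly constant factor per moult, so
$\ln \bar x_n$ is linear in $n$. `dyar_regression()` fits that line by OLS
and reports slope (log growth ratio), $R^2$, and the overall $F$ with its
p-value. With $k = 3$ instars the $F$ test has $(1, 1)$ degrees of freedom
and carries almost no information, so the p-value is reported but never
used as a gate.

## The synthetic generator

No raw per-larva HCW data are publicly deposited for the reference study
this pipeline is benchmarked against, so recovery testing uses a synthetic
stand-in. `spec_from_table1()` encodes the published per-instar summary of
that sample: counts 65/145/191 (n = 401), means 365.0/473.7/578.0 µm, and
CVs 5.30/5.26/4.38% converted to SDs of 19.345/24.917/25.316 µm, with
observable widths truncated to the reported 300–650 µm range.

Generator design choices:

* **Exact stratified counts** per component by default (matching the fixed
  published per-instar n and removing one noise source from recovery
  tests); a `multinomial = TRUE` mode randomises the split.
* **Truncation by rejection**, not clipping: clipping would pile mass on
  the window edges, distort component SDs and bias mixture recovery. The
  window excluding more than 99% of a component's mass is an error. Whether
  the published 300–650 µm range is a hard truncation or just observed
  extrema is unknowable; truncation is optional in `simulation_spec()` for
  that reason, and at these parameters it trims well under 1% of any
  component's mass.
* **Single seeded stream**, consumed component-by-component in
  ascending-mean order, so identical spec + seed give identical data
  regardless of how the call is embedded.

What the generator does *not* emulate: measurement rounding, seasonal or
site structure in the sample, within-instar growth of non-sclerotized
parts, or misidentified individuals. Passing recovery tests therefore shows
the estimator works when the mixture-of-normals model is true, not that
field data satisfy that model.

## Numerical and interface choices

* Histogram bins are half-open $[a, b)$ with a closed last bin, anchored at
  the minimum observation rounded down to the bin width; the default width
  is the Freedman–Diaconis rule with a 5 µm floor. The default fit never
  uses the histogram; it is presentation (and the optional histogram fit
  mode).
* Widths are always micrometres. The reader converts mm → µm only when
  told to (`unit = "mm"`); units are never inferred from headers.
* Invalid rows (non-numeric, non-positive) are fatal by default;
  `strict = FALSE` downgrades them to a warning and drops them.
* Serialised tables and text reports round numbers to 4 decimal places;
  JSON keeps full precision and is the lossless interchange format.
* All stochastic entry points take an explicit integer seed and are
  bit-reproducible under it.
* The pipeline isolates stages: if, say, only one instar is found, the
  Dyar regression is skipped with a recorded reason and all upstream
  results are kept.

## Worked example

```{r example}
d <- simulate_hcw(spec_from_table1(), seed = 1)
res <- run_analysis(d, analysis_config(k_min = 1, k_max = 5, seed = 1))
res
```

The BIC table behind the selection:

```{r bic}
res$bic_table
```

Tidy accessors and plots:

```{r tidy}
tidy(res)
glance(res)
```

```{r plots, fig.width = 7, fig.height = 4.5}
autoplot(res)
autoplot(res$dyar)
```

## Problem sizes used in the test suite

Recovery checks in the package's tests use 200 replicate datasets (n = 401
each) for the BIC selection rate, 50 replicates for averaged parameter
recovery, and counts scaled ×1000 (pooled over 3 seeds) for the generator's
moment-convergence check. These sizes give Monte-Carlo error comfortably
below the asserted tolerances while keeping the full suite around a minute
on one CPU.

## Limitations

* Components are univariate normals; skewed or heavy-tailed within-instar
  variation (measurement rounding, pooled sexes or populations) is not
  modelled and can inflate the selected $k$.
* BIC selection assumes the candidate range contains the truth; heavily
  overlapping adjacent instars (Brooks index near 1) may be merged, and
  the CV/Crosby criteria are then the operative safeguard.
* The intersection boundary minimises overall misclassification under the
  fitted model but is not a per-individual probability statement; larvae
  near a boundary are genuinely ambiguous.
* With 3 instars the Dyar regression has one residual degree of freedom;
  its $R^2$ is descriptive and its $F$/p should not be over-read.
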