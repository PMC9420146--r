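# instarmix

Determine the number of larval instars of an insect from head-capsule-width
(HCW) measurements.

The head capsule is sclerotized: its width stays fixed within an instar and
jumps at each moult, so a mixed-age field sample of larvae shows a
multi-modal HCW frequency distribution with one mode per instar. Deciding
how many instars a species has — and where one instar ends and the next
begins — is a routine but error-prone task in insect biology and pest
management. `instarmix` automates it for entomologists and applied
ecologists working from a flat table of per-larva widths.

## Method

The sample is modelled as a univariate Gaussian mixture,
`f(x) = Σ_i w_i N(x | μ_i, σ_i)`, one component per instar:

* the mixture is fitted by maximum likelihood (EM) on the raw widths and
  the number of components k is chosen by BIC over a user-set range
  (an optional histogram-curve-fit mode is included);
* the boundary between adjacent instars is the width where the two weighted
  normal curves intersect — solved in closed form from the quadratic the
  equality defines on the log scale;
* the partition is validated by the standard morphometric criteria:
  within-instar coefficient of variation below 15%, Brooks' index
  `b_n = x̄_n / x̄_{n−1}` and Crosby's index `(b_n − b_{n−1}) / b_{n−1}`
  below 0.1 in magnitude;
* Dyar's rule is checked by OLS regression of `ln(mean HCW)` on instar
  number.

A seedable synthetic generator (`simulation_spec()`, `simulate_hcw()`)
produces labelled HCW datasets with known mixture structure for
parameter-recovery studies, including a preset (`spec_from_table1()`)
emulating a published three-instar reference sample (n = 401, means
365.0/473.7/578.0 µm).

## Worked example

```r
library(instarmix)

d <- simulate_hcw(spec_from_table1(), seed = 1)   # 401 synthetic larvae
res <- run_analysis(d, analysis_config(k_min = 1, k_max = 5, seed = 1))
res
```

```
Instar determination: 3 instar(s) selected (BIC over k = 1..5)
  n = 401 larvae, fit: em
  boundaries (um): 406.7887, 527.9708

  instar n     mean+/-SE (um) CV(%)    Brooks   Crosby
  1      64      366.9 +/- 2.0  4.4177
  2      150     474.8 +/- 2.1  5.2966   1.2939
  3      187     580.0 +/- 1.7  3.9931   1.2217   -0.0558
  criteria (CV < 15%, |Crosby| < 0.1): PASS
  Dyar regression: slope = 0.2290, R2 = 0.9948, F = 190.49, p = 0.0460
```

Three instars are selected; the two boundaries at ≈406.8 and ≈528.0 µm cut
the sample into groups of 64/150/187 larvae. Every within-instar CV is far
below 15%, the growth ratios (Brooks ≈1.29 and ≈1.22) change by less than
10% (Crosby −0.0558), and log mean width is almost perfectly linear in
instar number (R² = 0.995) — all consistent with a clean three-instar
partition. `tidy(res)`, `glance(res)` and `autoplot(res)` give the tibble
and ggplot views; `render_report(res, "json")` serialises everything.

Real data enter through `read_hcw_table("larvae.csv", column = "hcw_um")`.
A thin command-line wrapper is installed as `exec/instarmix`
(`instarmix analyze --input larvae.csv`, `instarmix simulate --preset
table1 --seed 1 --out fixture.csv`).

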