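---
title: "Modelling breast-milk caloric intake: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling breast-milk caloric intake: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkintake)
```

## The model

`milkintake` estimates the caloric intake a healthy, full-term,
breastfed infant obtains from breast milk, normalised to body weight
and expressed on two scales: per feeding and per day. Age is stratified
into seven groups of completed months — 0–1, 1–3, 3–6, 6–9, 9–12,
12–18, 18–24 — with half-open intervals `[start, end)` so no age is
counted twice. The neonatal month is kept separate because both milk
composition and feeding behaviour change fastest there.

One simulated infant-day draws four independent inputs and combines
them arithmetically:

- daily feeding frequency **F** (feeds/day), triangular — appropriate
  when only a minimum, most-likely and maximum can be supported by the
  literature;
- volume per feed **V** (mL), Beta-PERT — smoother than the triangular
  and less sensitive to the elicited extremes, suited to a wide and
  asymmetric quantity;
- milk caloric density **D** (kcal/dL), normal or Beta-PERT depending
  on the heterogeneity of the pooled evidence (below);
- infant weight **W** (kg), uniform between the WHO median (P50)
  weight-for-age of girls (lower bound) and boys (upper bound) —
  a deliberately narrow, reference-based band rather than a
  population-weight distribution.

The outcomes are `per_feed = V · (D/100) / W` (the division by 100
converts kcal/dL to kcal/mL) and `per_day = F · per_feed`. Milk mass
and volume are treated as equivalent (milk density ≈ 1.03 g/mL is not
corrected for).

Each group is simulated for 5000 iterations by default, 35,000 for the
seven default groups together. "Second-order" stratification here means
exactly this per-group structure; there is no nested
uncertainty-vs-variability loop, since a single flat loop per group
reproduces the published summary table (a genuinely two-dimensional
design is not described anywhere in the source material for the model
and would change the interpretation of the quartiles).

## Evidence pooling for caloric density

Caloric density is the one input supported by study-level means and
SDs, so it is pooled per age group by random-effects inverse-variance
meta-analysis. Per-study standard errors are `sd / sqrt(n)`; the
between-study variance τ² uses the DerSimonian–Laird moment estimator —
the canonical "random-effects with inverse-variance weighting" method
and the default of common online meta-analysis calculators, which is
what the original analysis used. Whether that tool used DL or another
τ² estimator (REML, Paule–Mandel) is not documented; DL is the most
defensible reading and is what the package implements and tests.
Heterogeneity is reported as Cochran's Q, τ² and I²; a single-study
group pools to itself with Q = τ² = I² = 0 rather than erroring,
because some strata genuinely rest on one study.

The pooled estimate becomes a distribution by a documented rule
(`density_spec_from_pooled()`): below an I² threshold (default 75%, the
conventional "high heterogeneity" cutoff) the density is
normal(μ = pooled mean, σ = CI width / (2·1.96)); at or above it, PERT
with the CI limits as range and the pooled mean as mode. The boundary
value itself takes the PERT branch — with I² exactly at the cutoff the
evidence is already highly heterogeneous, and the PERT is the more
conservative (wider-bodied) choice. The shipped `default_config()` does
not re-run this rule: it hard-codes the published per-group choices
(normal for 3–6 and 6–9 months, PERT elsewhere), which are
authoritative over any threshold. The two normal σ values, 0.76 and
0.79 kcal/dL, are exactly the CI back-computations of the 3–6 and
6–9-month pooled intervals, which the acceptance suite verifies.

One default parameter deserves a note: the 0–1-month density maximum is
stored as 65.31 kcal/dL, the upper CI bound of the pooled estimate,
where the distribution table prints the truncated 65.3; the CI value is
taken as the authoritative one.

## Distribution internals and numerical choices

- **Beta-PERT** is the standard construction: a Beta variate with
  shapes `α₁ = 1 + λ(m−a)/(b−a)`, `α₂ = 1 + λ(b−m)/(b−a)` rescaled to
  `[a, b]`, with shape weight λ = 4. λ = 4 is the classic PERT
  convention (mean `(a + 4m + b)/6`) and is the value consistent with
  the pooled means being the PERT modes of the density inputs; λ is a
  spec field so variants remain testable. Bit-level agreement with the
  spreadsheet engine behind the original analysis is not claimable, and
  is not needed at the model's stochastic tolerances.
- **Triangular** sampling uses the inverse-CDF transform of a single
  uniform, so the draw sequence is a deterministic function of the
  uniform stream.
- **Normal** density draws are untruncated; a guard resamples the
  (practically impossible at the default μ/σ of ~62/0.8) event of a
  non-positive draw, with a warning, so downstream arithmetic can never
  see negative calories while the distribution is not measurably
  distorted.
- **Quantiles** use linear interpolation between order statistics
  (`stats::quantile` type 7, the spreadsheet-percentile rule). No
  convention is named in the source material; at n = 5000 the choice
  moves quartiles by well under 0.1%, but it must be pinned for exact
  regression tests. SD uses the n−1 denominator, for the same reason.
- **Seeding**: one master seed; each (age group, variable) pair draws
  from a substream whose seed is a deterministic 31-bit hash of the
  master seed and the pair's labels. Consequences, both tested:
  identical seeds give byte-identical outputs end-to-end, and a group's
  results do not depend on which other groups are simulated or in what
  order. All derived seeds stay below 2³¹.
- **Degenerate inputs**: the bounded families require `a < b`
  (a zero-width range is rejected at validation); point-mass behaviour
  is recovered in the limit of a narrow interval, which the test suite
  checks at width 2·10⁻⁹.

## Convergence monitoring

`convergence_trace()` records the running mean and quartiles at
checkpoints `step, 2·step, …, n_iter`; `is_converged()` declares
stability when, over the trailing 20% of checkpoints, mean and all
three quartiles each stay within 0.5% of their final value. Both knobs
(`rel_tol = 0.005`, `window_frac = 0.2`) are arguments. At the default
5000 iterations every default group converges by this criterion; at a
few hundred iterations the report flags instability, which is the
intended behaviour of the check rather than a defect.

## Scenario bands

Simulated intake is classified against the quartiles of its own
distribution: at or below Q1 is low caloric intake (LCI), at or above
Q3 is high (HCI), strictly between is medium (MCI). The band edges are
assigned to the outer bands by convention — the source defines the
bands only as the quartile values themselves — so `classify_intake()`
partitions the real line with no gaps.

## The synthetic study generator

`synth_studies()` exists to test the pooling stage with known truth:
study means are drawn from
`normal(true_mean, sqrt(tau² + within_sd²/n))`, i.e. a correctly
specified random-effects world with shared within-study SD and sample
size. Parameter-recovery tests use k = 20 studies of n = 50 with
within-study SD 4 kcal/dL — study counts and sizes typical of the milk
composition literature — at τ = 0 (expect an unbiased pooled mean and
I² near zero) and τ = 10 (expect I² > 75% in most replicates). What it
does not emulate: unequal study sizes and SDs, non-normal study
effects, correlated or rounded reporting, and publication bias. Passing
these tests therefore shows the estimator is implemented correctly, not
that real pooled milk-density tables are free of such artefacts —
indeed the shipped density inputs are taken as trusted published values
precisely because the underlying per-study appendix data are not
reproduced here.

## Problem sizes and verification

The suite checks the implementation at three scales, chosen so the full
run stays fast on a single CPU:

- moment checks of every default distribution at 10⁵ draws against the
  closed-form mean/variance, within 4 Monte-Carlo standard errors;
- the full 7-group simulation at the study's own 5000
  iterations/group, compared to the published summary table (means and
  quartiles within 2%, SDs within 5% — roughly 3–4 MC standard errors
  at that n);
- the analytic oracle `expected_intake()` —
  `E[per_day] = E[F]·E[V]·(E[D]/100)·E[1/W]` with
  `E[1/W] = log(b/a)/(b−a)` for uniform weight — against simulated
  means at 10⁶ iterations per group;
- 1000 randomized pooling fixtures against an independently written
  brute-force DerSimonian–Laird oracle (agreement to 10 significant
  digits), plus a cross-check against `metafor::rma(method = "DL")`.

## Known limitations

- The four inputs are sampled independently. The literature reports an
  inverse relation between feeding frequency and volume per feed
  (r² ≈ 0.44 in early infancy); modelling it would narrow the per-day
  distribution but departs from the reproduced design, so it is left as
  an extension hook rather than a default.
- Weight is a uniform band between two reference medians, so the model
  underrepresents weight variability; intake per kg is correspondingly
  tight in W.
- Inputs derive from studies in mostly high- and middle-income
  settings; maternal nutritional status, infant illness and cultural
  feeding patterns are outside the model.
- The model stops at milk: complementary-food energy after 6 months and
  WHO energy-requirement comparisons are interpretation, not
  computation, and are not implemented.
- Outputs are research estimates of population-level intake
  distributions, not clinical feeding guidance for an individual
  infant.
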