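---
title: "Linguistic interval-valued q-rung orthopair MABAC: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linguistic interval-valued q-rung orthopair MABAC: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlmabac)
```

## The representation model

Experts judge alternatives on an ordered linguistic scale
$\{J_0, \dots, J_\tau\}$. The 2-tuple representation model makes that
scale continuous: any real $\xi \in [0, \tau]$ is written as
$(J_k, \upsilon)$ with $k = \mathrm{round}(\xi)$ and
$\upsilon = \xi - k \in [-0.5, 0.5)$, so aggregation results keep full
precision while remaining interpretable as "a bit above $J_3$". `tl_delta()`
and `tl_delta_inv()` implement the two directions; the package computes on
the numeric $[0, \tau]$ scale throughout and re-encodes as 2-tuples only at
reporting boundaries (`as_two_tuples()`, `format_tlivq()`), which avoids
accumulating rounding.

Two conventions here were genuinely open and are fixed as follows:

- **Term indexing is 0-based** ($J_0 \dots J_\tau$, hence $\tau + 1$
  terms). The case study's 9-label scale with $\tau = 8$ only makes sense
  this way.
- **Rounding at half-way points goes up** ($\Delta(4.5) = (J_5, -0.5)$),
  which is what keeps $\upsilon$ in the half-open interval $[-0.5, 0.5)$;
  at the top of the scale $\Delta(\tau) = (J_\tau, 0)$.

An evaluation (one cell of a decision matrix) is an interval-valued
q-rung orthopair fuzzy number on that scale: a membership interval
$[r, t]$ and a non-membership interval $[u, y]$, all four endpoints in
$[0, \tau]$, with the rung constraint
$(t/\tau)^q + (y/\tau)^q \le 1$. Larger $q$ admits more orthopairs:
$q = 1$ is the intuitionistic case, $q = 2$ the Pythagorean case. In
tibbles the four endpoints are the columns `mu_lo`, `mu_hi`, `nu_lo`,
`nu_hi`, which is what lets every operation be an ordinary vectorized
data-frame verb.

## Scalar summaries, on the unit scale

The score and accuracy of an evaluation, with $a, b, c, d$ the four
$\tau$-normalized endpoints, are

$$K = \tfrac14\big[(1 + a^q - c^q) + (1 + b^q - d^q)\big], \qquad
  F = \tfrac14\big(a^q + b^q + c^q + d^q\big).$$

Both live in $[0, 1]$, and the score satisfies $K(R) + K(R^c) = 1$ where
$R^c$ swaps the two intervals. The formulas are sometimes printed with an
extra $\Delta(\tau \cdot \,)$ wrapper that would place them on $[0, \tau]$;
all published tables we reproduce are on $[0, 1]$, so the unit scale is the
primary convention here and the term-scale 2-tuple form is available via
`as_two_tuple = TRUE`. Comparison (`fz_compare()`) orders by score and
breaks ties by accuracy, with an absolute tie tolerance of $10^{-9}$ —
tight enough never to merge genuinely different evaluations on a
$\tau \le 10$ scale, loose enough to absorb floating-point noise.

## Operational laws and aggregation

The algebra is the standard q-rung orthopair t-norm/t-conorm pair applied
endpoint-wise on the unit scale: addition combines membership by the
probabilistic sum under the $q$-power transform,
$(a_1^q + a_2^q - a_1^q a_2^q)^{1/q}$, and multiplies non-membership;
multiplication is its complement-dual; the scalar law
$\varepsilon R$ maps membership to $(1 - (1-a^q)^\varepsilon)^{1/q}$ and
non-membership to $c^\varepsilon$; the power law $R^\varepsilon$ is its
dual. Other t-norm families (Dombi, Hamacher) are out of scope.

The weighted averaging operator (WA) and weighted geometric operator (WG)
are implemented in closed form,

$$\mathrm{WA}: \Big(1 - \prod_j (1 - a_j^q)^{w_j}\Big)^{1/q}
  \;/\; \prod_j c_j^{w_j}, \qquad
  \mathrm{WG}: \prod_j a_j^{w_j} \;/\;
  \Big(1 - \prod_j (1 - c_j^q)^{w_j}\Big)^{1/q},$$

and also as literal folds of the operational laws
($\oplus_j w_j R_j$, $\otimes_j R_j^{w_j}$; `method = "fold"`). The two
routes agreeing to $10^{-9}$ on randomized inputs is the module's central
numerical check, exercised in the test suite on a thousand random
instances alongside idempotency, monotonicity, boundedness, permutation
invariance and the WA/WG complement duality.

**Weight-sum policy.** The theory requires $\sum w_j = 1$, but published
weight vectors do not always comply (the embedded case study's expert
weights sum to 0.8162). `resolve_weights()` therefore supports three
policies: `"as-given"` (default — use the weights verbatim and warn on
deviation, since silently altering published inputs is worse than
surfacing the discrepancy), `"renormalize"`, and `"strict"`. Zero weights
are allowed and verifiably inert. Closed form and fold agree for any
weights, normalized or not.

## The MABAC pipeline

`mabac()` runs: expert aggregation by WA → benefit/cost normalization
(cost columns are complemented) → attribute weighting by the scalar law →
border approximation area $g_j$ = equal-weight geometric mean (exponent
$1/\alpha$) of each weighted column → signed normalized Hamming distances
$d_{ij} = \pm\, d(W\!N_{ij}, g_j)$, with the sign from the
score-then-accuracy comparison and an exact zero inside the $10^{-9}$ tie
band → cumulative values $S_i = \sum_j d_{ij}$ → descending stable
ranking (ties keep input order; no published tie exists, so the rule is a
determinism guarantee, not a modelling claim). Every intermediate is
stored on the result and is bit-for-bit reproducible from its stored
predecessor, which the tests assert.

The pipeline can be entered either at the raw per-expert cube or at a
precomputed aggregated matrix. The second entry point exists for a
substantive reason: in the embedded case study, re-aggregating the expert
matrices with the published expert weights does **not** reproduce the
published aggregated matrix — not verbatim (max endpoint deviation
$\approx 0.83$ terms) and not renormalized ($\approx 0.29$) — and the
weights or procedure actually used upstream are not recoverable from the
published record. Rather than guess, the package anchors all downstream
reproduction on the published aggregated matrix and reports the upstream
gap through `fz_matrix_deviation()`. From that anchor, the weighted
matrix, its scores, the border elements and their scores, the signed
distances and the cumulative values all reproduce to within
$5 \times 10^{-4}$ per endpoint / $2 \times 10^{-4}$ per cumulative value
(the residual is the 4-decimal rounding of the published inputs), and the
final ranking is exact.

One published labelling quirk is worth documenting: the case study's
border-area table labels its scalar column $F(g)$, but the values are the
score $K$, not the accuracy (e.g. $g_1 \mapsto 0.3538 = K(g_1)$). The
package compares border elements by score, consistent with the rest of
the method.

**Rung sensitivity.** `mabac_sweep()` reruns the pipeline across a set of
rungs and reports cumulative values and rankings per rung, with
validation relaxed to warning level because real data sets (including the
embedded one) violate the rung constraint for $q < 1$. Published per-rung
values for the case study are not exactly reproducible — whether each rung
was rerun from the raw cube or from the $q = 6$ aggregated matrix is not
stated — so the sweep is compared qualitatively (the top alternative is
stable across moderate-to-large rungs), and no numeric agreement is
asserted.

## Numerical choices

- All operational laws run on $\tau$-normalized probabilities with
  `log1p()`/`expm1()` for every $1 - \prod(1-x)^w$ form. The naive form
  loses about half the significant digits for small endpoints (a term
  index of 1 on $\tau = 8$ at $q = 6$ gives $a^q \approx 2 \times 10^{-16}$),
  which is visible as $\varepsilon = 1$ failing to be an identity; the
  log-space form keeps all identities below $10^{-12}$ on the term scale.
- Zero-weight terms are dropped from log-space sums (so a degenerate
  endpoint of 1 with weight 0 cannot produce $0 \cdot (-\infty)$), and
  $0^0 = 1$ in weighted products; intermediate probabilities are clamped
  to $[0, 1]$ before roots.
- Degenerate point intervals (`mu_lo == mu_hi`, `nu_lo == nu_hi`) need no
  special casing: every law acts endpoint-wise, so the interval algebra
  collapses to the single-valued one automatically.
- Constraint validation defaults to `"warn"` rather than `"strict"`
  because legitimate analyses (rung sweeps below $q = 1$) visit
  parameter regions where published data violate the constraint.

## The instance generator

`generate_cube()` draws rectangular expert × alternative × attribute
cubes. Defaults mirror the study conditions: scale $\tau = 8$, rung
$q = 6$, crisp term indices (experts elicit whole terms; the continuous
mode exists for stress-testing the algebra), endpoints uniform over the
scale with interval ordering by sorting, and rejection sampling until the
rung constraint holds (`constraint = "enforce"`), with an explicit
infeasibility error when a rung is so small that no non-trivial
evaluation passes. Draws are deterministic under a seed.

What the generator does *not* emulate: inter-expert correlation,
attribute-specific response styles, or any relationship between
membership and non-membership beyond the constraint. Passing property
tests on generated cubes therefore demonstrates algebraic and pipeline
correctness, not calibration to real elicitation behaviour; the embedded
case study is the realism anchor.

Test problem sizes were chosen to keep the default suite quick while
still exercising the combinatorics: property tests use cubes up to
$5 \times 20 \times 10$ (1000 cells) and operator checks run on a few
hundred random instances per identity, with the closed-form-vs-fold
equivalence at 1000 instances.

## Known limitations

- The upstream expert-aggregation stage of the embedded case study is not
  reproducible from its published inputs (see above); the package reports
  the deviation rather than matching it.
- Only the WA/WG operator pair is provided — no ordered-weighted, power,
  or Bonferroni variants, and no alternative ranking back-ends
  (TOPSIS/CODAS/EDAS/WASPAS).
- Expert and attribute weights are inputs; the package does not elicit or
  derive them.
- The CSV dialect carries crisp terms only; full-precision exchange is
  JSON.
- A ranking is a mathematical summary of the supplied judgements, not a
  clinical recommendation.
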