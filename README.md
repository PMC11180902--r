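# tlmabac

Multi-attribute group decision making with 2-tuple linguistic
interval-valued q-rung orthopair fuzzy numbers and the MABAC ranking
method.

## The problem

Committees of experts frequently have to rank a handful of alternatives
(treatments, suppliers, designs) against several conflicting attributes,
using qualitative judgements rather than hard numbers. `tlmabac` targets
that setting. Experts rate each alternative on an ordered linguistic scale
`{J0, ..., Jτ}` (for example J0 = "Immaterial" up to J8 = "Trustable"),
and each rating is an *interval-valued q-rung orthopair fuzzy number whose
endpoints are linguistic 2-tuples*:

- a **2-tuple** `(Jk, υ)` with symbolic translation `υ ∈ [-0.5, 0.5)`
  represents any real `ξ = k + υ` on the term scale, so aggregation
  results need not be rounded to a term (the Δ / Δ⁻¹ conversions);
- an evaluation carries a membership interval `[r, t]` and a
  non-membership interval `[u, y]` on that scale, constrained by
  `(t/τ)^q + (y/τ)^q ≤ 1` — the rung `q` widens the admissible region, so
  experts can be simultaneously quite satisfied and quite dissatisfied.

The package implements the full algebra of these numbers (operational
laws ⊕, ⊗, εR, R^ε; score `K = ¼[(1 + a^q − c^q) + (1 + b^q − d^q)]` and
accuracy `F = ¼(a^q + b^q + c^q + d^q)` on τ-normalized endpoints;
normalized Hamming distance `d = ¼ Σ |x₁^q − x₂^q|`), the weighted
averaging (WA) and weighted geometric (WG) aggregation operators in both
closed form and operational-law fold form, and the extended **MABAC**
(multi-attributive border approximation area comparison) pipeline:

1. experts' matrices are pooled with the WA operator (expert weights ω′);
2. cost attributes are complemented so every column is benefit-oriented;
3. attribute weights ϖ are applied through the scalar law;
4. the **border approximation area** `g_j` is the geometric mean of each
   weighted column over the α alternatives (exponent 1/α);
5. each cell gets a signed Hamming distance to its border element
   (positive above the border by score comparison, negative below);
6. row sums `S_i = Σ_j d_ij` rank the alternatives (larger is better).

Everything is tidyverse-shaped: evaluations live in tibbles with columns
`mu_lo`, `mu_hi`, `nu_lo`, `nu_hi` (plus id columns), every stage is a
data-frame-in / tibble-out verb, results have `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example: the breast-cancer case study

The package embeds a published case study: seven treatment options
(G1 lumpectomy, G2 mastectomy, G3 chemotherapy, G4 hormone therapy,
G5 targeted therapy, G6 immunotherapy, G7 clinical trials) rated by four
experts on four attributes (T1 cancer stage/subtype, T2 patient
preferences, T3 resource availability, T4 expected outcomes) on a 9-term
scale with `q = 6`.

```r
library(tlmabac)

case <- case_breast_cancer()
res <- mabac(aggregated = case$aggregated, config = case$config)
res
#> <mabac_result> 7 alternatives x 4 attributes (q = 6, tau = 8)
#>   ranking: G6 > G4 > G1 > G5 > G2 > G3 > G7
#>   cumulative values: G1 = 0.0234, G2 = -0.0184, G3 = -0.0289, G4 = 0.0569,
#>     G5 = 0.0043, G6 = 0.1539, G7 = -0.1199
```

Immunotherapy (G6) sits furthest above the border approximation area
(S = 0.1539) and is ranked best; clinical trials (G7) sit furthest below
(S = −0.1199). A single weighted evaluation and its score:

```r
x <- tlivq(3.4154, 4.1953, 5.2148, 6.0315, tau = 8)
format_tlivq(x, tau = 8)
#> "([(J3, 0.4154), (J4, 0.1953)], [(J5, 0.2148), (J6, 0.0315)])"
fz_score(x, q = 6, tau = 8)
#> 0.4416197
```

How sensitive is the ranking to the rung?

```r
mabac_sweep(aggregated = case$aggregated, config = case$config,
            q_values = c(0.5, 3, 6, 9))
#> <mabac_sweep> 4 rungs, 7 alternatives
#>   q = 0.5    G7 > G3 > G5 > G2 > G4 > G6 > G1
#>   q = 3      G6 > G4 > G5 > G1 > G3 > G2 > G7
#>   q = 6      G6 > G4 > G1 > G5 > G2 > G3 > G7
#>   q = 9      G6 > G4 > G1 > G5 > G2 > G3 > G7
```

The top choice is stable for moderate and large rungs; at `q = 0.5` the
data violate the rung constraint (the run records a validation warning)
and the ordering is not meaningful.

A command-line interface wraps the same functions:

```sh
mabac=$(Rscript -e 'cat(system.file("exec", "mabac", package = "tlmabac"))')
Rscript "$mabac" fixtures --case breast-cancer --out-prefix /tmp/bc
Rscript "$mabac" run --input /tmp/bc_cube.json --config /tmp/bc_config.json \
        --entry-stage experts --out /tmp/result.json
```

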