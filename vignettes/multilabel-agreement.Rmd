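---
title: "Measuring agreement when raters may tick more than one category"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring agreement when raters may tick more than one category}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multikappa)
```

## The setting

Classic chance-corrected agreement coefficients assume *mutually
exclusive* categories: Cohen's kappa handles two raters, Fleiss' kappa
(Fleiss, 1971) several, but each rater must place each subject in exactly
one category. Many real classification tasks are multi-label: clinicians
record several diagnoses per case, coders attach several codes to a text
fragment, teachers tick several feedback items on an exam answer.
`multikappa` implements a chance-corrected coefficient for that setting —
`I` subjects, `J` raters, `C` categories, with the indicator
`x_ijc = 1` when rater `j` put subject `i` into category `c` — together
with weighting, category hierarchies, varying rater panels, bootstrap
benchmarking, and the four alternative methods found in the literature.

## The coefficient

All quantities are built from the *agreement table* `X` with entries
`x_ic = sum_j x_ijc`. Agreement is counted pairwise per category: two
raters agree on category `c` for subject `i` when both selected it *or*
both did not. Pooling over subjects,

$$Po_c = \frac{\sum_i \left[\binom{x_{ic}}{2} + \binom{s_{ic}-x_{ic}}{2}\right]}
              {\sum_i \binom{s_{ic}}{2}},$$

where `s_ic` is the number of raters for whom category `c` was available
for subject `i` (for a fixed panel without hierarchy, `s_ic = J`
everywhere). Chance agreement uses the overall selection proportion
`p_c = sum_i x_ic / sum_i s_ic`:

$$Pe_c = p_c^2 + (1-p_c)^2 = 2p_c^2 - 2p_c + 1 \in [0.5, 1].$$

The per-category `kappa_c = (Po_c - Pe_c)/(1 - Pe_c)` is reported for
diagnosis but not pooled directly. Instead the coefficient pools the
beyond-chance terms:

$$\kappa = \frac{\sum_c w_c\,\phi_c\,(Po_c - Pe_c)}
                {\sum_c w_c\,\phi_c\,(1 - Pe_c)},$$

with importance weights `w_c` (default 1; any positive rescaling leaves
`kappa` unchanged) and hierarchy scale factors
`phi_c = sum_i s_ic / sum_i j_ic` (1 for every main category). On
mutually exclusive, equally weighted, non-hierarchical data this reduces
*exactly* to Fleiss' kappa; the test suite verifies the equality to ten
significant digits over a thousand random tables against an independent
implementation of the classic formulas.

### Varying numbers of raters

When subject `i` was rated by `j_i` raters (or, less desirably, when even
the per-category availability varies, `j_ic`), the same two formulas
apply with `s_ic = j_i` (or `j_ic`). `rater_availability()` expresses all
three designs; a per-subject vector is verified in the tests to be
exactly the matching per-cell special case. Availability is normally
derived from the roster of rated (subject, rater) pairs, which is also
how "rated but selected nothing" is kept distinct from "did not rate" —
an all-zero rating is real data and counts raters into `j_i`.

### Hierarchies

In hierarchical codebooks some categories are selectable only under a
condition on the rater's *other* selections. Rules are boolean
expressions over category identifiers (`"1 and 3"`, `"4"`,
`"(a or b) and not c"`); `s_ic` counts the raters of subject `i` whose
own selections satisfy the rule of category `c`. For a plain parent-child
rule this gives `s_ic' = x_ip` — the child was selectable exactly for the
raters who ticked the parent. The general definition — counting raters
whose own selection vector satisfies an arbitrary acyclic predicate — is
this package's formalization; the literature describes the parent-child
case and gestures at inclusion–exclusion for complex graphs without
fixing an algorithm. Predicates over *other raters'* selections are
deliberately unsupported. Rules referencing their own category, or
forming a cycle, are rejected at construction.

Why `phi_c`? `Po_c` and `Pe_c` are already computed on the right pair
counts, but a subcategory available only a handful of times would
otherwise enter the pooled ratio with the same force as a main category
available `I * J` times; one noisy, rarely-available item could drag the
coefficient down. `phi_c` scales each category's contribution by its
share of possible classifications.

### Weights from checkbox scores

For score-carrying checklists, `checkbox_weights()` maps item scores to
weights via

$$w_c = \frac{|\mathrm{score}_c| + \max_k |\mathrm{score}_k|}
             {2\,\max_k |\mathrm{score}_k|} \in [0.5, 1],$$

so a score-neutral item still weighs 0.5 (its presence changes the
feedback a student receives) and the largest-scoring item weighs 1.
Absolute values make a deduction count like a bonus of the same size.

## Premises, paradoxes, corrections

**Non-selection is agreement.** Two raters who both leave category `c`
unticked agree about `c` just as much as two raters who both tick it.
This is a philosophical premise, not a theorem; users should check it
fits their context. The comparator methods below make the opposite
choice (ignoring agreement on non-selection) and the bundled examples
show both choices can misbehave.

**Unused categories are invisible.** An unused category has
`Po_c = Pe_c = 1`, hence zero contribution — the coefficient cannot be
inflated by padding the codebook. Symmetrically, a category ticked by
*every* rater for *every* subject also contributes nothing, although it
represents maximal agreement — the *always-selected-category paradox*.
The three `table1_ex*` fixtures isolate this: an unused pair of
categories, a maximally split table, and an always-selected pair all
produce the same `kappa = -0.333`, the minimum possible with four
raters. The opt-in correction (`correct =`) sets `Pe_c = 0` for chosen
categories, adding their full agreement to both sides of the ratio; on
the third example it yields 0.733, separating genuine unanimity from
noise. It is never applied automatically, and may also be applied to
unused categories where a context warrants it.

**Prevalence.** A category selected almost always (or almost never) has
`Pe_c` near 1, so a couple of disagreements produce a low `kappa_c` —
inspect the per-category table before reading the pooled value. The
worked math-exam item 1 (`Po = 0.889`, `Pe = 0.802`, `kappa = 0.438`)
is exactly this effect.

**Range.** For a fixed panel, unweighted and non-hierarchical,
`kappa` lies in `[-1/(J-1), 1]`; the lower bound is attained by the
even-split pattern (`x_ic = J/2` everywhere) and, as for Fleiss' kappa,
by maximal dispersion when `J <= C`. The property suite checks the
bounds on random tables.

**Degenerate categories.** A category with no rater pairs at all
(`sum_i s_ic (s_ic - 1) = 0`) has no defined `Po_c`; it contributes
exactly zero and is flagged `skipped_no_pairs`, consistent with the
unused-category behaviour. `kappa_c` is `NaN` (flagged, never an error)
whenever `Pe_c = 1`. If *every* category is degenerate the pooled
denominator is 0 and the coefficient is reported as undefined with
diagnostics — no silent default.

## Benchmarking with interval membership probabilities

Comparing a point estimate against the Landis & Koch (1977) scale
ignores how precisely the coefficient was estimated. Following Gwet's
benchmarking idea, the package instead bootstraps the coefficient —
resampling *subjects* with replacement, `n = I` per replicate, 10,000
replicates by default — and reports, per scale level, the probability
mass of replicates in that level (the IMP) plus the cumulative mass from
the top level down. The *final level* at significance `alpha` (default
0.05, i.e. confidence `1 - alpha`) is the highest level whose cumulative
IMP reaches `1 - alpha`. Replicates with an undefined coefficient are
excluded and counted, never silently dropped. Levels are half-open
intervals `(lower, upper]`: a replicate belongs to "Almost perfect" when
`kappa > 0.8`, matching how the scale is quoted at two decimals (0.81 to
1.00); the scale is user-replaceable via `benchmark_scale()`.

Two resampling designs are offered. The default, `design = "bundle"`,
resamples each subject's whole row bundle — counts `x_i.`, availability
`j_i.`, and hierarchy-derived `s_i.` travel together — so every
replicate is a coherent dataset; this is the statistically sound scheme,
since `s_i.` is a function of that subject's own raters' selections.
`design = "fixed"` resamples only the rows of `X` while the
possible-classification matrix, availability and scale factors stay at
their observed values. Exact enumeration of the 6-subject worked example
shows the two designs differ dramatically under hierarchy (with fixed
design a resampled count row can even exceed the possible
classifications it is paired with), and that the published benchmarking
table for that example — 77% mass above 0.8 around a point estimate of
0.69 — is reproducible only under the fixed design, whose replicate
distribution the acceptance tests match within Monte-Carlo error. Treat
`"fixed"` as conditioning on the observed selectability design when
comparability with those reference tables is wanted; use the default for
inference. For the non-hierarchical psychiatric example the two designs
nearly coincide, and the default reproduces the reference confidence of
99.4% for at-least-Fair agreement.

## The comparator methods

Four literature methods are provided for side-by-side reporting
(`compare_methods()`); none supports weights or hierarchies.

* **Averaged / pooled Cohen's kappa** (two raters only): one 2x2
  Cohen's kappa per category; the average is undefined as soon as one
  category's kappa is (e.g. a category neither rater used), while
  pooling mean `Po` and mean `Pe` first stays defined — the reason
  pooling is generally preferred (De Vries et al., 2008).
* **Proportional overlap** (Mezzich et al., 1981): per pair of raters,
  `|A ∩ B| / |A ∪ B|` of their selection sets. An empty selection set
  admits no overlap: every pair involving one is excluded and counted,
  and a subject with no computable pair drops out of `Po`. The chance
  term averages the overlap over *all* pairs of rated units — including
  same-rater pairs, as the classical description loops over all
  `choose(I*J, 2)` combinations; `exclude_same_rater = TRUE` is offered
  for sensitivity analysis.
* **Chance-corrected intraclass correlation**: per subject, a one-way
  ANOVA intraclass coefficient of the raters' binary vectors with
  *categories as groups and raters as observations*
  (`(MSB - MSW)/(MSB + (k-1) MSW)`, `k` raters), averaged for `Po`; the
  same estimator over all vectors pooled gives `Pe`. The literature
  names only "a one-way ANOVA", which fixes neither the grouping nor
  the treatment of degenerate subjects; this package's choices —
  categories as groups, and a constant matrix (zero variance, e.g. a
  subject for which every rater ticked everything) scoring 0 with a
  `degenerate` flag — are validated empirically by reproducing the
  reference values of both bundled examples to the printed precision,
  and should be read as an estimator convention, not the only possible
  one.
* **Chance-corrected rank correlation** (Kraemer, 1980): raters rank
  their selected categories (ties allowed); unselected categories share
  the mean leftover rank. Agreement between two rank vectors is
  Spearman correlation; `Po`/`Pe` pool pairs as in the overlap method.
  The default `method = "classic"` applies Spearman's difference
  formula `1 - 6\sum d^2 / (n(n^2-1))` directly to the tied vectors,
  which is what the reference analyses use; `method = "pearson"` gives
  the tie-corrected product-moment version, which yields a visibly
  smaller value on the psychiatric data (0.356 vs 0.379) — a reminder
  that tie handling is a reportable choice. Pairs with a constant
  vector are excluded with a count under either method.

On the psychiatric example our recomputation of the proportional
overlap from the printed diagnosis table gives 0.276 under exactly the
conventions that reproduce the other example's value of 0.602; the
commonly quoted figure for these data is 0.27. The acceptance test
allows for this one-point-in-the-second-decimal gap rather than hiding
it.

## The synthetic generator

`simulate_ratings()` exists so that properties can be tested on data
with a known agreement mechanism: each subject owns a latent label set
(per-category prevalence, default 0.3 — a typical multi-label density);
each rater copies each latent label with probability `fidelity`
(default 0.8, a strong but imperfect panel) and otherwise draws
independently from prevalence; hierarchy rules are enforced per rater in
topological order, so `x <= s` holds by construction. `fidelity = 1`
forces `kappa = 1`; `fidelity = 0` concentrates `kappa` near 0; mean
agreement is monotone in fidelity — all verified in the tests. The
mechanism is deliberately stylised: it has exchangeable raters, no
rater-specific bias or leniency, no subject difficulty gradient, and no
correlation between categories beyond the hierarchy. Passing tests on
generated data therefore demonstrate the *arithmetic* of the
coefficient, not robustness on real panels.

## Numerical and scale choices

All internal computation is in double precision with no rounding;
printed tables round half away from zero to three decimals, matching the
convention of the reference tables (machine-readable exports keep full
precision). Test comparisons against printed values use half a unit in
the last printed decimal. The test suite runs the Fleiss-equivalence
property at 1,000 random tables, the remaining invariants at 50-200
random instances, and both bootstrap reproductions at the advised
`B = 10,000` (a few seconds each); the acceptance script uses the same
sizes. Seeds are explicit everywhere randomness occurs — the bootstrap
and the generator refuse to run without one.

## Limitations

No analytic standard error or power analysis is provided — the
large-sample variance of the coefficient has not been derived, which is
exactly why benchmarking is bootstrap-based. The hierarchy engine
evaluates per-rater boolean predicates only; cross-rater conditions and
alternative partial-weighting schemes across hierarchy levels are out of
scope. The comparator implementations are faithful to their classical
descriptions but those descriptions underdetermine some conventions
(ICC estimator variant, overlap pair universe, tie handling); the
choices here are documented above and pinned by tests against published
values.
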