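---
title: "Extent-analysis fuzzy AHP: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extent-analysis fuzzy AHP: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(extentahp)
library(dplyr)
```

## The problem

Health-system planners routinely have to rank qualitative criteria — here,
the factors affecting the development of military hospital beds — using
nothing more objective than expert judgment. The analytic hierarchy process
(AHP) structures that judgment as pairwise comparisons over a criterion
hierarchy; its fuzzy variant replaces crisp ratio judgments with triangular
fuzzy numbers (TFNs) so that the vagueness of linguistic answers
("moderately more important") is carried through the arithmetic instead of
being discarded at data entry.

`extentahp` implements the extent-analysis (Chang-style) variant of fuzzy
AHP end to end: linguistic judgments → fuzzy pairwise comparison matrices →
group aggregation across an expert panel → per-node weight vectors → dense
priority ranks over a two-level hierarchy. The package also ships a
synthetic expert-panel generator with known ground truth, because the case
study it reproduces — a 22-expert prioritization of 8 factors and 54
subfactors — published only its final scores and priorities, not the raw
questionnaires: everything upstream of the printed tables must be validated
on simulated panels.

## Judgments and their arithmetic

A TFN $(l, m, u)$, $l \le m \le u$, has membership rising linearly from $l$
to the mode $m$ and falling to $u$. The package uses the standard
componentwise operations

$$M_1 \oplus M_2 = (l_1{+}l_2,\; m_1{+}m_2,\; u_1{+}u_2), \qquad
  M_1 \otimes M_2 = (l_1 l_2,\; m_1 m_2,\; u_1 u_2), \qquad
  M^{-1} = (1/u,\; 1/m,\; 1/l),$$

with $\otimes$ and inversion restricted to strictly positive support. The
product and inverse are the usual triangular approximations; no alpha-cut
exact product is attempted because extent analysis is defined in terms of
the componentwise rules.

Judgments are entered on a nine-rung ladder (`fuzzy_scale()`): five pure
grades at odd intensities 1, 3, 5, 7, 9 and four intermediate grades at the
even intensities. The forward TFN of rung $k$ has mode $k$. The published
scale also prints two-decimal reciprocal triples; the package treats those
as reference data only and always derives reciprocals analytically as
$(1/u, 1/m, 1/l)$. Half-up rounding of the analytic reciprocals reproduces
the printed triples on eight of the nine rungs; the ninth — the upper
component of the $(7,9,9)$ rung, printed 0.13 where $1/7$ rounds to 0.14 —
is a rounding slip in the printed table that we document rather than
hard-code.

```{r scale}
fuzzy_scale()
```

## From a matrix to weights

For an $n \times n$ fuzzy comparison matrix $M$ the synthetic extent of row
$k$ is

$$S_k = \sum_{j=1}^{n} M_{kj} \;\otimes\; \Big[ \sum_{i=1}^{n}\sum_{j=1}^{n} M_{ij} \Big]^{-1}.$$

The modal components of $S_1, \dots, S_n$ sum to exactly 1 — an algebraic
identity the test suite checks on hundreds of random matrices. Extents are
compared by the possibility degree

$$V(M_1 \ge M_2) =
  \begin{cases}
  1 & m_1 \ge m_2,\\[2pt]
  0 & u_1 \le l_2,\\[2pt]
  \dfrac{u_1 - l_2}{(u_1 - l_2) + (m_2 - m_1)} & \text{otherwise,}
  \end{cases}$$

the height of the intersection of the two membership triangles. Note the
fraction: the intersection height is the ratio of $u_1 - l_2$ to
$(u_1 - l_2) + (m_2 - m_1)$; quoting the numerator and denominator side by
side without the bar (as the source tables of this method family sometimes
do) yields an unbounded expression, so the bounded standard form is what is
implemented. When the supports merely touch ($u_1 = l_2$ with $m_1 < m_2$)
the intersection height is zero and the degree is defined as 0, which also
avoids a 0/0. The suite cross-checks this closed form against a grid-search
maximisation of the min-membership on a thousand random TFN pairs.

The non-normalised weight of item $i$ is the min-aggregated degree
$W'(x_i) = \min_{k \ne i} V(S_i \ge S_k)$, and reported weights are
$W = W' / \sum_i W'(x_i)$. The study this package reproduces does not state
whether (or how) it normalised $W'$; since all of its printed score blocks
sum to $\approx 1$, sum-normalisation is adopted as the obvious reading. An
all-zero $W'$ (conceivable only in degenerate inputs) raises an explicit
error instead of silently returning uniform weights.

```{r worked}
m <- as_pcm(data.frame(item_i = c("a", "b"), item_j = c("b", "a"),
                       l = c(1, 0.2), m = c(3, 0.33), u = c(5, 1)))
compute_weights(m)
```

## Group aggregation

The reference study aggregated 22 experts but does not say how. The package
default is the componentwise geometric mean of the experts' matrices,
chosen because it is the only common rule that preserves reciprocal
symmetry exactly (the geometric mean of reciprocals is the reciprocal of
the geometric mean), so the aggregated matrix is again a valid judgment
matrix. A componentwise arithmetic mean is available behind
`aggregate_judgments(method = "arithmetic")` for sensitivity analysis; it
breaks reciprocity slightly and downstream validation must be relaxed
accordingly. Aggregation always happens on judgments, before extent
analysis, matching the single-matrix form of the weighting equations.

## Hierarchy and ranking

Criteria live in a two-level tree: goal → factors → subfactors. Local
weights are derived per node; global leaf weights are the product of leaf
and parent local weights. Priorities are assigned by *dense* descending
ranking — tied scores share a priority and the next distinct score takes
the next integer — because that is the convention evidenced by the
published subfactor table (a block ranks its items 5, 5, 6 where
competition ranking would print 5, 5, 7). Ties are decided by exact
equality on stored values; published fixtures are stored at their printed
three decimals, so printed ties tie.

One caution on the shipped fixtures: the published subfactor block F7 sums
to 0.959 rather than $\approx 1$ (every other block sums to
$0.999\text{–}1.001$), apparently a typo in one printed score.
Demonstrations that compose global weights from the printed tables
therefore use a sibling-sum tolerance of 0.05; exact-sum invariants are
tested on computed, unrounded weights instead.

```{r rank}
tabs <- hospital_bed_tables()
add_priorities(tabs$factors[c("code", "label", "score")])
```

## The synthetic panel generator

`generate_panel()` emulates the questionnaire study: a ground-truth weight
vector per node implies, for each item pair, an ideal ladder judgment
(half-up rounded ratio $w_i / w_j$, clipped to $[1, 9]$; ratios below 1
encode as the reciprocal cell), and each simulated expert reports that
judgment after ladder noise — every upper-triangle cell independently moves
±1 rung with probability `step_probability`, up to `max_steps` times,
clipped to the ladder. Reciprocal cells are derived analytically, so every
generated matrix is valid by construction. Defaults are the study
conditions where stated (22 experts) and package conventions where not:
`step_probability = 0.2` with `max_steps = 1` as a moderate
disagreement level (the study reports nothing about inter-expert
variability), and a symmetric Dirichlet truth sampler with
`concentration = 1` (a flat prior over the simplex).

Two restrictions are applied to sampled truths, both derived from the
instrument rather than from the method under test. Consecutively ranked
weights closer than one ladder rung (ratio < 1.5) are pushed one rung
apart: such items round to "equally important" everywhere and are
unidentifiable from any questionnaire on this scale. And weights more than
a factor 9 below the top are collapsed onto that floor as exact ties: the
ladder saturates at ratio 9, so finer distinctions down there are likewise
inexpressible. `sample_true_weights(min_ratio = 1, max_spread = Inf)`
disables both and gives the plain Dirichlet draw.

What the generator does *not* emulate: correlated experts (panel members
who talk to each other), systematic individual biases (an expert who
always inflates by a rung), missing answers, and intransitive judgment
sets beyond what ladder noise produces. Passing recovery tests therefore
show that the pipeline inverts its own generative model at realistic noise,
not that the published study's panel behaved this way.

## What recovery experiments show — and the method's limits

`recovery_experiment()` repeatedly samples a truth, simulates a panel,
aggregates and re-derives weights, and compares recovered to true rankings
(Spearman correlation and exact dense-rank agreement). Problem sizes in the
shipped tests are 50 replicates per zero-noise condition at $n \in \{4,8\}$
and 200 replicates for the noisy condition at $n = 8$ with 22 experts —
desk-scale runs that complete in seconds.

Two structural limits of extent analysis surface immediately and are worth
understanding before trusting its output:

* **Zero-weight degeneracy.** $W'$ is exactly 0 for any item whose extent's
  support lies entirely left of a competitor's lower bound. All
  sufficiently dominated items therefore tie at weight 0 — distinct true
  ranks collapse. This is visible already at zero noise: with ladder-capped
  truths the suite's zero-noise condition recovers the exact dense ranking
  in only about two-thirds of seeds at $n = 4$ and almost never at $n = 8$,
  where a one-rung-separated truth necessarily spans a ratio of
  $1.5^{7} \approx 17$ and the bottom items zero out. The corresponding
  acceptance assertion states the full exact-recovery bar and fails
  honestly; the noisy Spearman criterion (median $\ge 0.9$) passes because
  rank correlation is barely harmed by a tie among the weakest items.
  Practitioners who need strictly positive discrimination among dominated
  criteria should treat zero weights as "indistinguishably unimportant",
  not as measured zeros.

* **Ladder quantisation.** Truths with adjacent ratios under 1.5 are
  invisible to the scale regardless of method — the published factor
  weights themselves (0.249 down to 0.040, adjacent ratios 1.09–1.35)
  could not be exactly recovered from their own ideal questionnaire.

A related observation: with several experts, geometric-mean aggregation of
*noisy* panels softens both effects — independent one-rung errors dither
the quantisation, pulling aggregated entries off the saturated rungs — so
heavy noise does not necessarily degrade mean recovery relative to zero
noise. The monotone noise-hurts property holds cleanly for single-expert
panels, and that is how the suite tests it.

## Numerical conventions

* Internal arithmetic is never rounded; half-up rounding to the printed
  precision (2 decimals for the scale, 3 for score tables) is applied only
  when comparing against or writing published-style output.
* Reciprocity validation uses a per-component absolute tolerance of 0.01 so
  that judgments typed from the two-decimal printed reciprocals validate;
  generated and aggregated matrices satisfy reciprocity to machine
  precision.
* All randomness flows through explicit `seed` arguments (restored via
  `withr`, so callers' RNG streams are untouched); identical configurations
  produce byte-identical outputs, and `run_*` writers record the seed,
  aggregation rule and a configuration hash in `run_metadata.json`.
* `min_possibility` and `compute_weights` are deterministic, closed-form
  computations; there is no iteration, initialisation or tie-breaking
  randomness anywhere in the weighting path.

## Known limitations

Beyond the method-level limits above: the hierarchy container supports the
two criterion levels the case study uses (no alternatives layer, no deeper
nesting); no consistency-ratio machinery is provided (that belongs to
eigenvector AHP, out of scope here); and expert weighting, consensus
measures and imputation of partial questionnaires are deliberately not
implemented.
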