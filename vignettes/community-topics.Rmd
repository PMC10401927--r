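---
title: "Community types from microbiome count data: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community types from microbiome count data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microtopics)
```

## The model and its assumptions

`microtopics` models a genus-level count table the way LDA models a text
corpus: a sample is a document, a genus is a term, and a *community type*
is a topic — a probability distribution over genera that tends to occur
together. Each sample has fractional membership θ_d across the K
communities (Dirichlet(α) a priori); each read belongs to one community.
The assumptions this buys, and their price:

- **Mixed membership.** A sample is a blend of communities rather than one
  enterotype. This matches the motivating biology (dysbiosis as a shift in
  community *prevalence*, not the wholesale replacement of a flora).
- **Bag of reads.** Counts are exchangeable within a sample; library size
  carries no biological meaning. Consequently all downstream inference is
  compositional, which is why the differential-abundance stage carries an
  explicit bias correction.
- **Topics are cohort-level.** β is shared across samples; real
  strain-level variation within a community is absorbed into the
  multinomial noise.

Inference is variational EM. The per-document variational family is a
Dirichlet γ_d over topic proportions and multinomial responsibilities φ for
every observed genus; the E-step fixed point is

φ_dvk ∝ β_kv · exp(ψ(γ_dk)),  γ_dk = α + Σ_v n_dv φ_dvk,

and the M-step re-estimates β (with Dirichlet smoothing η) and optionally α
(Newton with step-halving). The recorded objective is the ELBO plus the η
log-prior on β, which makes the trace provably non-decreasing up to the
E-step tolerance — a property the test suite asserts on every fit.

## Parameters that matter

| parameter | default | meaning / why this value |
|---|---|---|
| `K` | chosen by `select_topic_number()` | number of community types; the study-scale analogue used 30, desk-scale simulations use 6–10 |
| `alpha_init` | 50/K | the `topicmodels`-style VEM starting value; α is then estimated unless `estimate_alpha = FALSE` |
| `eta` | 0.1 | Dirichlet smoothing on β; keeps every genus at positive probability so held-out genera never produce −∞ likelihoods; small enough not to blur block structure |
| `tol` | 1e-4 (relative ELBO) | outer EM stop; `e_tol` 1e-8 on mean |γ| change stops the inner fixed point |
| `n_starts` | 1 | random restarts; determinism contract is (seed, n_starts) — the best final objective wins |
| `filter threshold` | 1e-5 | overall relative abundance (feature total / grand total); the per-sample bases are available as `basis = "mean"|"max"` because the original rule's basis is ambiguous |
| `cosine threshold` | 0.80 | a topic pair at or above it counts as the same community type in two cohorts; matching is deliberately many-to-many |
| `pseudocount` | 0.5 | added before log2 relative abundance in the DA stage |
| `winsorization` | 0.97 quantile, genera only | damps single-sample blooms; topic tables are left unwinsorized, mirroring the convention of the LinDA-style analysis this reproduces |
| dual rule | p ≤ 0.05 ∧ q ≤ 0.25 | boundary-inclusive; q is BH step-up |

## What the simulator emulates — and what it does not

`generate_topics()` builds disjoint-block topics: each community places
`dominance` (default 0.9) of its mass uniformly on its own block of genera
and the rest uniformly elsewhere, so pairwise topic cosines have a closed
form and are small (≈0.008 for 5-genus blocks in V = 150).
`generate_cohort()` then follows the LDA generative process exactly —
θ ~ Dirichlet(per-group α), library sizes log-normal (default median 2×10⁴,
σ_log 0.7, floored at 100, spanning roughly 10³–10⁵), counts multinomial.
Group effects are encoded in the Dirichlet concentrations, *not* as
post-hoc count multipliers, so parameter recovery is a fair test of the
fitted model family. `generate_paired_cohorts()` emulates the
exploratory/validation design: cohort B's topics are Dirichlet-jittered
copies (concentration β_A/ε, exact copies at ε = 0) and a fraction of
genera is renamed cohort-private to emulate partially overlapping
vocabularies (the real cohorts retained 175 vs 160 genera).

A green test on these data therefore establishes that the *inference and
decision machinery* behaves: topics are recoverable when they exist, the
matching logic finds truly shared types and rejects unrelated ones, the DA
stage is calibrated under the null and powered under a planted effect. It
does **not** establish anything about real stool samples: the simulator has
no sequencing error, no ASV-level structure, no phylogenetic correlation,
no zero-inflation beyond the multinomial, and its topics are cleanly
block-separated in a way real communities are not.

The default paired profile (used by `run_pipeline(simulate = "paired")`)
is: K_true = 10 block topics of 8 genera in V = 160, dominance 0.9, base
α = 1.5 with topic 1's concentration tripled in the disease group,
25 samples per arm per cohort, ε = 0.01, vocabulary overlap 0.95. Two of
these values deserve their rationale spelled out. Base α = 1.5 keeps
per-sample memberships mixed but bounded away from the simplex corners;
with α ≤ 1 many samples carry θ_k ≈ 0, and log2 topic proportions become so
heavy-tailed that no realistic arm size detects the planted contrast — a
property of the log-linear test, not of the pipeline. Vocabulary overlap
0.95 (not lower) keeps the *true* cross-cohort cosines of shared topics
above the 0.80 threshold; at 0.90 with 8-genus blocks the renaming alone
pushes truly identical topics below threshold, i.e. the scenario would
contradict its own premise of shared community types.

## Numerical choices

- **ELBO bookkeeping.** Because φ is the exact conditional given γ, the
  z- and w-terms of the per-document bound collapse to
  Σ_v n_v(log Z_v − ψ(Σ_k γ_k)) with Z = E[θ]·β in exp-digamma form; the
  recorded trace and the exported `elbo()` recomputation agree to 1e-6.
- **α Newton safeguard.** Steps that leave the positive domain or decrease
  the α-objective are halved (up to 30 times); with K = 1 the objective is
  flat and α is returned unchanged.
- **Arun metric flooring.** Both distributions are floored at 1e-12 before
  the logs, so disjoint supports give large finite divergences rather than
  ∞.
- **Ties.** K-selection ties break to the smallest K (parsimony); `top_terms`
  probability ties break alphabetically; the chosen K is the
  round-half-to-even mean of the per-metric per-cohort argmins.
- **Degenerate DA inputs.** A single-feature table cannot anchor the bias
  mode: the corrected effect is set to 0 and p to 1, flagged `degenerate`.
  Zero-variance features get p = 1 likewise. Constant vectors have no rank
  correlation: network edges involving them are skipped and listed.
- **Fractional counts** are accepted everywhere (the assigned-read tables
  are fractional by construction); the multinomial likelihood generalizes by
  weighting, and an optional largest-remainder rounding provides integer
  tables whose rows still sum exactly to the library size.

## Known limitations

- The Arun2010 curve separates over-fitting sharply (it jumps once K
  exceeds the true topic number) but is nearly flat under-fitting, so its
  argmin on a finite grid is seed-sensitive; averaging it with CaoJuan2009,
  as the selection procedure does, mitigates but does not remove this.
  Treat `chosen_k` as a starting point, not an oracle.
- The DA stage is a two-group OLS contrast; covariates (age, sex),
  longitudinal designs and the cited method's small-sample refinements are
  out of scope.
- Cross-cohort matching aligns vocabularies by genus *name* on the union
  with zero fill; synonymy or rank-level disagreements between taxonomies
  must be resolved upstream.
- VEM finds local optima; use `n_starts` > 1 for anything you intend to
  interpret, and expect topic *labels* to be arbitrary across fits.
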