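# microtopics

Topic modeling of gut-microbiome count data for **community-type
discovery**: instead of testing genera one at a time, `microtopics` treats
each sample as a *document* and each genus as a *term*, infers latent
bacterial communities (topics) with latent Dirichlet allocation (LDA), and
asks which communities differ between a disease group and controls and
whether the same communities re-appear in an independent cohort.

It is aimed at microbiome researchers with genus-level 16S count tables
(TSV/CSV/BIOM) and a two-level sample label (e.g. relapsing-remitting
multiple-sclerosis patients vs healthy controls), and at methodologists who
want a fully tested, self-contained R implementation of the workflow —
including a Dirichlet-multinomial cohort simulator, so every stage runs and
is validated without any external data.

## The model

LDA places a distribution over K latent topics on every sample. With
symmetric Dirichlet priors,

- θ_d ~ Dirichlet(α) — sample d's topic proportions ("fractional
  membership" of a stool sample across communities),
- β_k — topic k's distribution over genera (rows of the K×V topic-term
  matrix),
- each read draws a topic z ~ Multinomial(θ_d) and a genus w ~
  Multinomial(β_z).

Inference is mean-field **variational EM**: per-sample variational
Dirichlet parameters γ_d and per-term responsibilities
φ_dv ∝ β_kv·exp(ψ(γ_dk)) are iterated to a fixed point (E-step), then β is
re-estimated with Dirichlet smoothing η and α by Newton's method (M-step),
monotonically increasing the evidence lower bound (ELBO).

Around the engine sit the workflow stages:

| stage | function | statistic |
|---|---|---|
| prevalence filter | `filter_low_prevalence()` | overall relative abundance < 1e-5 removed |
| choose K | `select_topic_number()` | CaoJuan2009 (mean pairwise topic cosine) and Arun2010 (symmetric KL of singular values vs weighted topic mass), both minimized |
| read assignment | `assign_reads()` | γ_norm × library size per sample |
| cross-cohort validation | `topic_cosine_matrix()`, `match_topics()` | topic pairs with cosine ≥ 0.80, union-aligned vocabularies |
| differential abundance | `linda_fit()` | OLS on log2 relative abundance, compositional bias removed as the mode of the coefficient density, BH-FDR, significant iff p ≤ 0.05 **and** q ≤ 0.25 |
| co-occurrence networks | `topic_network()` | Spearman correlations among a topic's genera |

## Worked example

```r
library(microtopics)

# a simulated 50-sample cohort: 4 ground-truth communities, topic 1's
# Dirichlet concentration tripled in the RRMS group
beta_true <- generate_topics(K = 4, V = 60, dominant_per_topic = 8,
                             dominance = 0.9)
sim <- generate_cohort(beta_true,
         alpha_by_group = list(HC = rep(1.5, 4),
                               RRMS = c(4.5, 1.5, 1.5, 1.5)),
         group_sizes = c(HC = 25, RRMS = 25), seed = 1)
sim$table
#> count_table: 50 samples x 60 features
#> groups: HC=25, RRMS=25
#> total reads: 1,383,117

fit <- fit_lda(sim$table, K = 4, seed = 1, n_starts = 3)
fit
#> lda_model: K = 4 topics, 50 samples, 60 terms
#> alpha = 0.2337, objective = -4760315.8817 after 17 iterations

evaluate_recovery(fit, sim$truth)$matches   # fitted vs true topics
#>   true_topic fitted_topic    cosine
#> 1    topic_1      topic_1 0.9944487
#> 2    topic_4      topic_2 0.9896749
#> 3    topic_2      topic_3 0.9896052
#> 4    topic_3      topic_4 0.9794746

da <- linda_fit(assign_reads(fit, sim$table))  # topic-level DA
print(da[, c("feature", "effect_log2", "se", "p", "q", "significant")],
      digits = 3)
#>   feature effect_log2   se        p        q significant
#> 1 topic_1       7.290 1.27 5.95e-07 2.38e-06        TRUE
#> 2 topic_2       0.505 1.51 7.40e-01 8.35e-01       FALSE
#> 3 topic_3      -1.412 1.44 3.32e-01 6.63e-01       FALSE
#> 4 topic_4       0.266 1.27 8.35e-01 8.35e-01       FALSE
```

All four planted communities are recovered (cosine ≥ 0.98), and the
community whose prevalence was raised in the disease group is the one — and
the only one — called differentially abundant (positive `effect_log2` =
enriched in RRMS relative to the alphabetically-first reference level, HC).

The full two-cohort workflow (filter → fit → assign → match → DA → networks)
is one call:

```r
res <- run_pipeline(list(simulate = "paired", seed = 1, k = 10, starts = 3))
res$summary   # validated community types with direction in both cohorts
```

or, from a config file and real data,
`run_pipeline("config.yaml", out_dir = "run1")` (see `?run_pipeline` for
the keys) or the CLI wrapper `inst/cli/microtopics run --config config.yaml`.

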