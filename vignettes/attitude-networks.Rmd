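---
title: "Detecting opinion-based groups with attitude networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting opinion-based groups with attitude networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opinionets)
```

## The problem

Opinion-based groups are social factions defined by shared attitudes
rather than by pre-existing categories. When they emerge — around a
referendum, a pandemic, a crisis — mean-level analyses can miss them
entirely: two factions moving in opposite directions leave item averages
nearly flat. The network view makes the sorting visible. Each survey wave
is cast as a bipartite graph of persons and attitude items; its two
unipartite projections show, respectively, which people agree with each
other across the battery, and which attitudes are held together or in
opposition across people. Watching the participant projection across
waves turns "polarization" into a concrete observable: a connected
agreement network that splits, with ever fewer edges bridging the parts.

## The pipeline and its assumptions

1. **Stances.** `binarize()` trichotomizes each Likert response at its
   scale midpoint: above → +1, below → −1, exactly at it → 0, missing
   stays missing. Agreement means *same stance sign*, not equal raw
   values — the weakest rule that realizes agree/disagree edge semantics.
   Scales spanning an odd number of steps (1–4) admit no neutral stance;
   1–7 scales map the central response to 0. Custom cutpoints are
   pluggable (`rule = "custom"`) for batteries where the substantive
   neutral point is off-centre.
2. **Participant projection.** `project_participants()` weights each pair
   by the proportion of attitudes shared, `shared / compared`, counting
   only items where both stances are non-neutral and non-missing. Pairs
   comparing fewer than `min_overlap = 5` items get no edge (a proportion
   estimated from 2 items is noise), nor do pairs below the agreement
   `threshold = 0.75`. Both are configuration keys, never hard-coded
   downstream; 0.75 demands substantially more agreement than the ~0.5
   two random respondents would share, while 5 of 11 items still lets
   panels with item nonresponse in.
3. **Attitude projection.** `project_attitudes()` uses the majority
   verdict per item pair: sign(C − D) with weight |C − D|, where C counts
   sign-concordant and D sign-discordant persons. The raw support C + D
   is retained on every edge for audit; exact ties (C = D) yield no edge,
   since the data then carry no majority signal. Neutral stances count
   for neither side: a midpoint response is neither trust nor distrust.
4. **Factions.** `faction_components()` takes connected components of the
   thresholded participant projection, numbered by decreasing size (ties
   broken by the smallest contained participant id, making labels
   deterministic), with nodes outside the `top` largest components left
   unassigned. Components are the minimal formalization of "clusters
   joined by few edges"; they are deliberately *not* a
   modularity-maximizing community search, which would find structure
   even in unpolarized data. `kmeans_partition()` (standard k-means,
   best-of-`n_restarts`, seeded) provides the confirmatory partition from
   the raw responses — raw, not standardized, because the attitude items
   share one 1–4 scale; a `standardize` flag covers mixed batteries.
   `compare_partitions()` quantifies correspondence with a Pearson χ²
   test (no continuity correction by default, the large-sample
   convention; a flag adds it) and the adjusted Rand index in its
   permutation-model closed form.
5. **Semantic labels.** `label_factions()` names the cluster with the
   higher mean stance on the anchor items (trust in science and in
   scientists) the *trusters*, the other the *sceptics*. An exact tie is
   an error demanding manual labels rather than a silent coin flip.
6. **Polarization observables.** `bridging_edge_count()` counts edges
   joining different factions; `threshold_edges()` is monotone (raising
   the threshold never adds edges), so bridging counts are non-increasing
   in the threshold for fixed labels.

## Survey bookkeeping

`read_wave()`/`write_wave()` round-trip per-wave CSVs with validation
that names the offending row, item and value. Attention checks are
exact-match single items (`apply_attention_exclusions()`); a missing
attention response counts as a failure. `match_waves()` reduces all waves
to the id intersection in a common order and reports the unmatched ids
per wave. Scale scoring (`score_scale()`) uses the mean of available
(non-missing) items per participant, while Cronbach's α uses complete
cases only, with the complete-case count reported — the two conventions
common in survey practice; both item-order invariant. `describe()`
reports M and SD with the n−1 denominator, matching conventional
reporting.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` plants the structure the analysis is meant to
detect, so every stage is testable without a real panel:

- Two fixed factions (default fractions 0.6/0.4 of n = 300, mirroring
  the relative sizes opinion clusters show in practice) answer 11 trust
  items on 1–4 scales.
- Seven *shared* items carry a positive template for everyone; four
  *contested* items (science, scientists, government, journalists) carry
  a positive template for faction 0, while each faction-1 respondent's
  template is negative with probability d_t. The default ramp
  d = (0.2, 0.5, 0.9) makes the between-faction divergence grow across
  the three waves. Templates are drawn per respondent-item-wave so the
  divergence grows smoothly in d_t rather than jumping item-wise.
- Each stance matches its template with probability c
  (`consensus_strength = 0.85`); otherwise it falls in the neutral region
  with probability `neutral_rate` (inert on the 1–4 items, which have no
  attainable midpoint) and is opposite otherwise. The integer response is
  uniform over the template-consistent half of the scale — the simplest
  model preserving sign structure, which is all the network stage
  consumes.
- Compliance and clarity items (1–7) come from a person-level latent
  score plus item noise, with between-person SDs chosen so the
  three-item scales land at α ≈ 0.7 (typical of short behavioural
  batteries) and anchored near the top of the scale as such measures are
  in practice; faction 1 is shifted down by `outcome_effect_d = 0.3`
  standard deviations of the scale score, i.e. a planted η² ≈ .02.
- Attrition (0.05/wave, permanent) and attention-check failures (0.01)
  exercise the exclusion bookkeeping. Everything is reproducible
  bit-for-bit from `config$seed`.

What it does **not** emulate: real panels have correlated stances within
respondents beyond the faction template (ideological consistency),
item-specific difficulty and popularity, gradual opinion *change*
mechanisms rather than planted schedules, non-random attrition, and item
nonresponse. Passing tests on this generator therefore demonstrate that
the pipeline recovers structure of the planted kind at realistic sizes —
not that any particular real dataset contains such structure.

## Numerical choices

- η² confidence intervals invert the noncentral-F distribution with
  `uniroot` (tolerance 1e-10, bracket doubled until it spans the root),
  converting noncentrality to η² via λ / (λ + df₁ + df₂ + 1); the
  alternative λ / (λ + N) convention differs only in unbalanced-design
  bookkeeping and is isolated in one helper should a user need to swap
  it. The lower bound floors at 0, and both bounds are 0 when F is small
  enough — the usual one-sided behaviour near the null. A 2000-replicate
  simulation in the test suite checks 90% intervals cover the true η² at
  0.90 ± 0.02 on three-group designs of n = 60.
- `wilks_manova()` assembles the E and H cross-product matrices
  explicitly and applies Rao's F approximation; with one outcome it
  reduces *exactly* to the one-way ANOVA, and the test suite checks it
  against `stats::manova` and against a label-permutation oracle.
  Repeated-measures designs are handled by the multivariate route:
  `difference_scores()` builds successive-wave contrasts, a group test on
  which is the time-by-group interaction; a group test on per-subject
  wave means is the group main effect. A singular error matrix raises an
  error suggesting fewer outcomes or more cases.
- `logistic_fit()` wraps the IRLS fit (`stats::glm`, tolerance 1e-8),
  reports Wald intervals from the *unrounded* coefficients — note that
  published OR intervals occasionally fail to re-round from the printed
  two-decimal B and SE for exactly this reason — and turns
  quasi-perfect separation into an explicit error naming the worst
  predictor rather than returning absurd standard errors.
- All p-values are two-sided and uncorrected for multiplicity, matching
  how such analyses are conventionally reported; users wanting
  family-wise control can apply `p.adjust` to the collected p-values.
- Layouts (`layout_graph()`) are Fruchterman–Reingold with
  weight-proportional attraction, seeded for exact reproducibility;
  disagreement (negative) edges enter with vanishing attraction since FR
  requires positive weights. A single node is placed at the origin.
- GEXF export is written directly (igraph writes GraphML but not GEXF);
  both formats and the CSV edge list round-trip node and edge attributes
  exactly, which the test suite asserts.

## Problem sizes

The test suite and the acceptance script run the full pipeline on 20
generator seeds at the default n = 300 × 3 waves (a few seconds each),
projection-oracle equivalence on 50 random 20 × 8 stance matrices
against naive double-loop references, and the coverage simulation at
2000 replicates — sizes chosen so the whole suite completes in well under
a minute while keeping Monte-Carlo error far below the asserted margins.

## Known limitations

- **Component-based faction recovery is brittle to bridging noise.** A
  single surviving between-faction edge merges two components. At the
  default consensus c = 0.85, the expected pairwise agreement between
  same-faction respondents is c² + (1−c)² ≈ 0.745 — *below* the 0.75
  edge threshold — so within-faction edges arise from favourable item
  draws, and enough between-faction pairs clear the threshold (even at
  full divergence) that the wave-3 graph typically remains one giant
  component at n = 300. Exact component separation requires near-perfect
  within-faction consensus, far higher than the planted 0.85. The
  bridging-edge count is the robust polarization observable at realistic
  noise — it falls by roughly a factor of four across the default ramp
  regardless — and users wanting clean partitions at moderate consensus
  should raise the threshold, or treat the component rule as a
  visualization aid and rely on `kmeans_partition()` for assignment.
- The multivariate η² convention 1 − Λ^(1/s) equals 1 − Λ only for
  two-group (s = 1) designs; published multivariate effect sizes for
  higher-order interactions can follow software-specific conventions that
  differ, so cross-study comparison of those values needs care.
- The attitude projection's net-count weight conflates "many people,
  small majority" with "few people, unanimous"; the `support` attribute
  is retained on every edge precisely so users can distinguish them.
- The generator plants structure; it does not model influence dynamics,
  so it cannot be used to study *why* factions emerge — only whether a
  pipeline would detect them once they have.
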