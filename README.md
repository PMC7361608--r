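# opinionets

Attitude networks and opinion-based group detection for longitudinal
Likert survey panels.

During rapid societal change, people can sort themselves into
*opinion-based groups* — factions defined by what their members believe
rather than by demographics or party. A mean-level trend line cannot show
this: two groups drifting apart can leave every item average flat.
`opinionets` implements the network approach to detecting such factions as
they emerge: each survey wave becomes a bipartite person–attitude graph,
its projections expose who agrees with whom (and which attitudes travel
together), and the wave-by-wave thinning of edges between clusters
quantifies the schism. A synthetic cohort generator with a planted,
ramping two-faction structure makes the whole pipeline testable without
access to any real panel.

## The model

For wave *t*, responses are trichotomized at each item's scale midpoint
into stances *s* ∈ {+1, 0, −1} (agree / neutral / disagree; missing stays
missing). The bipartite graph has a signed edge for every non-neutral
stance. Two projections follow:

- **Participant projection.** For persons *i*, *j*, let *compared* be the
  number of items on which both hold a non-neutral stance and *shared* the
  compared items with equal sign. The edge weight is the proportion of
  attitudes shared, *w_ij* = shared / compared, kept when
  compared ≥ `min_overlap` and *w_ij* ≥ `threshold`.
- **Attitude projection.** For items *a*, *b*, with *C* persons agreeing
  in sign and *D* disagreeing, the edge carries sign(*C* − *D*) and weight
  |*C* − *D*| (support *C* + *D*): blue majority-agreement edges, red
  majority-disagreement edges.

Factions are connected components of the thresholded participant
projection (cross-validated with k-means on the raw responses; agreement
is reported as a χ² test plus adjusted Rand index), labelled
truster/sceptic by their mean stance on trust-in-science anchor items.
Polarization is tracked by the count of *bridging edges* — edges joining
different factions.

The statistics layer covers the group comparisons such studies report,
as auditable formulas: partial η² = F·df₁ / (F·df₁ + df₂) with a
noncentral-F confidence interval (λ / (λ + df₁ + df₂ + 1) convention),
Wilks Λ = det(E) / det(E + H) with Rao's F approximation and
η² = 1 − Λ^(1/s), binary logistic regression with Wald odds-ratio
intervals, Pearson χ² association, correlations, and Cronbach's α for
scale scoring.

## Worked example

```r
library(opinionets)

cfg <- cohort_config(seed = 7)           # planted 60/40 schism, 3 waves
cohort <- generate_cohort(cfg)

# attention-check exclusions + longitudinal panel matching
screened <- lapply(cohort$waves, apply_attention_exclusions,
                   attention_item = "attention_check", expected = 4L)
panel <- match_waves(lapply(screened, `[[`, "matrix"))$waves

# stance networks per wave
stances <- lapply(panel, function(w) binarize(subset_items(w, block = "attitude")))
nets <- lapply(stances, project_participants, min_overlap = 5, threshold = 0.75)
nets[[3]]
#> <projection_graph (participant): 250 nodes, 6669 edges>

# bridging edges against the planted factions: the schism widens
truth <- cohort$truth$faction_of
sapply(nets, bridging_edge_count, assignment = truth)
#> [1] 5002 3433 1080

# compliance gap between factions at the final wave
comp <- score_scale(panel[[3]], paste0("compliance_", 1:3), "compliance")
comp
#> <scale_score 'compliance': 3 items, alpha = 0.668 (250 complete cases)>
f <- truth[panel[[3]]$participants]
oneway_anova(split(comp$per_participant_mean, f))
#> F(1, 248) = 7.792, p = 0.005657, eta_sq = 0.0305, 90% CI [0.0051, 0.0733]
```

The bridging-edge counts fall from 5002 to 1080 across the ramp — the
between-faction agreement network thins out as contested attitudes
polarize — and the faction gap in behavioural compliance is a small but
significant effect (η² ≈ .03), the magnitude such opinion-based groups
typically show.

Graphs export to GraphML/GEXF/CSV (`export_graph()`, with deterministic
force-directed layouts from `layout_graph()`), and `wave_panel()` renders
the wave-by-wave schism as a multi-panel figure.

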