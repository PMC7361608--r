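test_that("midpoint binarization trichotomizes correctly and propagates NA", {
  items <- c(lapply(c("a7", "b7"), item_spec, scale = likert_scale(1, 7)),
             lapply(c("c4"), item_spec, scale = likert_scale(1, 4)))
  vals <- cbind(a7 = c(4L, 5L, NA), b7 = c(1L, 7L, 4L), c4 = c(3L, 2L, 1L))
  rm <- response_matrix(vals, items, c("x", "y", "z"), "T1")
  st <- binarize(rm)
  expect_equal(unname(st$stances[, "a7"]), c(0L, 1L, NA))
  expect_equal(unname(st$stances[, "b7"]), c(-1L, 1L, 0L))
  # no attainable midpoint on 1-4: 3 -> +1, 2 -> -1
  expect_equal(unname(st$stances[, "c4"]), c(1L, -1L, -1L))
})

test_that("custom cutpoints must cover every item", {
  rm <- tiny_wave(cbind(c(2L, 6L), c(3L, 5L)))
  st <- binarize(rm, rule = "custom", cutpoints = c(q1 = 2, q2 = 5))
  expect_equal(unname(st$stances[, "q1"]), c(0L, 1L))
  expect_error(binarize(rm, rule = "custom", cutpoints = c(q1 = 2)), "q2")
})

test_that("the bipartite graph has one signed edge per non-neutral stance", {
  st <- stance_fixture(rbind(c(1, 1, 1), c(1, 1, 1)))
  g <- build_bipartite(st)
  expect_equal(igraph::ecount(g), 6)
  expect_true(all(igraph::E(g)$sign == 1))
  expect_true(igraph::is_bipartite(g))
  # every edge joins a person to an item
  el <- igraph::as_edgelist(g)
  types <- setNames(igraph::V(g)$type, igraph::V(g)$name)
  expect_true(all(types[el[, 1]] != types[el[, 2]]))

  # all-neutral person stays as an isolate
  st2 <- stance_fixture(rbind(c(1, -1, 1), c(0, 0, 0)))
  g2 <- build_bipartite(st2)
  expect_equal(igraph::ecount(g2), 3)
  expect_equal(unname(igraph::degree(g2)["p02"]), 0)
  expect_equal(sort(unique(igraph::E(g2)$sign)), c(-1, 1))
})

test_that("participant projection weights follow shared/compared", {
  # identical non-neutral rows: w = 1
  st <- stance_fixture(rbind(c(1, -1, 1, 1, -1), c(1, -1, 1, 1, -1)))
  g <- project_participants(st, min_overlap = 1, threshold = 0)
  expect_equal(g$edges$weight, 1)
  expect_equal(g$edges$support, 5)

  # exactly opposite rows: w = 0, no edge at any positive threshold
  st2 <- stance_fixture(rbind(c(1, 1, -1), c(-1, -1, 1)))
  g2 <- project_participants(st2, min_overlap = 1, threshold = 0)
  expect_equal(g2$edges$weight, 0)
  expect_equal(nrow(project_participants(st2, 1, 0.01)$edges), 0L)

  # hand-enumerated pair: compared 4, shared 3 -> w = 0.75
  st3 <- stance_fixture(rbind(c(1, 1, -1, 0, 1), c(1, -1, -1, 1, 1)))
  g3 <- project_participants(st3, min_overlap = 1, threshold = 0)
  expect_equal(g3$edges$weight, 0.75)
  expect_equal(g3$edges$support, 4)
  expect_equal(g3$edges$sign, 1L)
})

test_that("pairs with too little overlap produce no edge", {
  st <- stance_fixture(rbind(c(1, 0, 0), c(1, 0, 0), c(0, 0, 0)))
  g <- project_participants(st, min_overlap = 2, threshold = 0)
  expect_equal(nrow(g$edges), 0L)
  g2 <- project_participants(st, min_overlap = 1, threshold = 0)
  expect_equal(nrow(g2$edges), 1L)  # only the pair that compared anything
})

test_that("attitude projection carries net sign, weight and support", {
  # unanimity: 10 persons +1 on both items
  st <- stance_fixture(matrix(1L, 10, 2))
  g <- project_attitudes(st)
  expect_equal(g$edges$weight, 10)
  expect_equal(g$edges$sign, 1L)
  expect_equal(g$edges$support, 10)

  # exact cancellation: 5 concordant, 5 discordant -> no edge
  st2 <- stance_fixture(rbind(matrix(c(1, 1), 5, 2, byrow = TRUE),
                              matrix(c(1, -1), 5, 2, byrow = TRUE)))
  expect_equal(nrow(project_attitudes(st2)$edges), 0L)

  # listed 6-person table: C = 4, D = 1, one neutral pair
  st3 <- stance_fixture(rbind(c(1, 1), c(1, 1), c(-1, -1), c(-1, -1),
                              c(1, -1), c(0, 1)))
  g3 <- project_attitudes(st3)
  expect_equal(g3$edges$weight, 3)
  expect_equal(g3$edges$sign, 1L)
  expect_equal(g3$edges$support, 5)
  # brute-force person-by-person count agrees
  expect_equal(sort_edges(g3$edges), sort_edges(naive_project_attitudes(st3)))
})

test_that("both projections agree exactly with naive double-loop references", {
  set.seed(123)
  for (rep in 1:10) {
    st <- random_stance(12, 6)
    g <- project_participants(st, min_overlap = 2, threshold = 0.5)
    expect_equal(sort_edges(g$edges),
                 sort_edges(naive_project_participants(st, 2, 0.5)))
    ga <- project_attitudes(st)
    expect_equal(sort_edges(ga$edges), sort_edges(naive_project_attitudes(st)))
  }
})

test_that("permuting participants yields an isomorphic projection", {
  set.seed(77)
  st <- random_stance(15, 6)
  g1 <- project_participants(st, min_overlap = 1, threshold = 0)
  perm <- sample(nrow(st$stances))
  st2 <- st
  st2$stances <- st$stances[perm, ]
  st2$participants <- st$participants[perm]
  g2 <- project_participants(st2, min_overlap = 1, threshold = 0)
  expect_equal(sort(g1$edges$weight), sort(g2$edges$weight))
  key <- function(e) sort(paste(pmin(e$u, e$v), pmax(e$u, e$v), e$weight))
  expect_equal(key(g1$edges), key(g2$edges))
})

test_that("thresholding retains nodes and is monotone in the edge count", {
  set.seed(5)
  st <- random_stance(15, 8)
  g <- project_participants(st, min_overlap = 1, threshold = 0)
  expect_equal(nrow(threshold_edges(g, 0)$edges), nrow(g$edges))
  thr <- seq(0, 1, by = 0.1)
  counts <- sapply(thr, function(t) nrow(threshold_edges(g, t)$edges))
  expect_true(all(diff(counts) <= 0))
  empty <- threshold_edges(g, max(g$edges$weight) + 0.1)
  expect_equal(nrow(empty$edges), 0L)
  expect_equal(empty$nodes, g$nodes)

  # forced count: weights {0.5, 0.8, 1.0}, threshold 0.8 -> 2 survive
  gg <- g
  gg$edges <- gg$edges[1:3, ]
  gg$edges$weight <- c(0.5, 0.8, 1.0)
  expect_equal(nrow(threshold_edges(gg, 0.8)$edges), 2L)
})

test_that("bridging edges are counted across faction labels", {
  st <- stance_fixture(rbind(c(1, 1), c(1, 1), c(-1, -1), c(-1, -1)))
  g <- project_participants(st, min_overlap = 1, threshold = 0)
  expect_equal(nrow(g$edges), 6L)  # complete graph on 4 nodes
  labels <- setNames(c(1L, 1L, 2L, 2L), st$participants)
  expect_equal(bridging_edge_count(g, labels), 4L)
  expect_equal(bridging_edge_count(g, setNames(rep(1L, 4), st$participants)), 0L)
  # perfect separation: labels = components
  g2 <- threshold_edges(g, 1)
  fa <- faction_components(g2)
  expect_equal(bridging_edge_count(g2, fa), 0L)
  expect_error(bridging_edge_count(g, labels[1:2]), "without a faction label")
})

test_that("bridging count is non-increasing in the threshold", {
  set.seed(9)
  st <- random_stance(20, 8)
  g <- project_participants(st, min_overlap = 1, threshold = 0)
  labels <- setNames(rep(1:2, each = 10), st$participants)
  counts <- sapply(seq(0, 1, 0.1), function(t)
    bridging_edge_count(threshold_edges(g, t), labels))
  expect_true(all(diff(counts) <= 0))
})

test_that("within-faction agreement exceeds between-faction agreement per wave", {
  for (s in 1:3) {
    co <- generate_cohort(cohort_config(n_participants = 300, seed = s))
    f <- co$truth$faction_of
    gap <- sapply(co$waves, function(w) {
      st <- binarize(subset_items(w, block = "attitude"))
      g <- project_participants(st, min_overlap = 1, threshold = 0)
      within <- f[g$edges$u] == f[g$edges$v]
      mean(g$edges$weight[within]) - mean(g$edges$weight[!within])
    })
    expect_true(all(gap > 0))
    expect_true(all(diff(gap) > 0))  # schism widens with the ramp
  }
})
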