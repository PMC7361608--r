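faction_assignment <- function(labels, method, k, semantic = NULL) {
  structure(
    list(labels = labels, method = method, k = as.integer(k),
         semantic = semantic),
    class = "faction_assignment"
  )
}

#' @export
print.faction_assignment <- function(x, ...) {
  sizes <- table(x$labels, useNA = "no")
  cat(sprintf("<faction_assignment (%s): k = %d, sizes %s%s%s>\n",
              x$method, x$k, paste(sizes, collapse = "/"),
              if (anyNA(x$labels)) sprintf(", %d unassigned", sum(is.na(x$labels))) else "",
              if (!is.null(x$semantic)) paste0(", ", paste(names(x$semantic),
                x$semantic, sep = "=", collapse = ", ")) else ""))
  invisible(x)
}

#' Detect factions as connected components
#'
#' Labels each node of a (typically thresholded) participant projection by
#' its connected component, numbered by decreasing size with ties broken by
#' the smallest contained participant id. When `top` is given, nodes
#' outside the `top` largest components are marked unassigned (`NA`),
#' reflecting the convention that opinion-based groups are the dominant
#' clusters and stragglers stay unlabelled.
#'
#' @param graph A `projection_graph`.
#' @param top Optional number of largest components to keep as factions.
#' @return A `faction_assignment` with `method = "components"`.
#' @export
faction_components <- function(graph, top = NULL) {
  stopifnot(inherits(graph, "projection_graph"))
  if (!length(graph$nodes)) stop("graph has no nodes", call. = FALSE)
  comp <- igraph::components(as_igraph(graph))
  memb <- comp$membership
  # order components by (-size, smallest contained id)
  first_id <- vapply(seq_len(comp$no), function(i)
    min(names(memb)[memb == i]), character(1))
  ord <- order(-comp$csize, first_id)
  relabel <- integer(comp$no)
  relabel[ord] <- seq_len(comp$no)
  labels <- relabel[memb]
  names(labels) <- names(memb)
  labels <- labels[graph$nodes]
  names(labels) <- graph$nodes
  k <- comp$no
  if (!is.null(top)) {
    labels[labels > top] <- NA_integer_
    k <- min(top, comp$no)
  }
  faction_assignment(labels, "components", k)
}

#' Cluster participants with k-means on raw Likert responses
#'
#' Standard k-means (squared Euclidean distance, best of `n_restarts` by
#' within-cluster sum of squares, seeded RNG stream) on the raw responses
#' to the given items, restricted to complete cases. Clusters are numbered
#' by decreasing size, ties broken by the smallest contained participant
#' id. No standardization is applied by default since attitude items share
#' one scale; set `standardize = TRUE` otherwise.
#'
#' @param matrix A [response_matrix()].
#' @param item_ids Items to cluster on.
#' @param k Number of clusters.
#' @param seed RNG seed.
#' @param n_restarts Random restarts.
#' @param standardize Scale columns to unit variance first.
#' @return A `faction_assignment` with `method = "kmeans"`; participants
#'   with incomplete responses are absent from `labels`.
#' @export
kmeans_partition <- function(matrix, item_ids, k = 2, seed = 1,
                             n_restarts = 10, standardize = FALSE) {
  stopifnot(inherits(matrix, "response_matrix"), k >= 1)
  x <- subset_items(matrix, item_ids)$values
  cc <- stats::complete.cases(x)
  x <- x[cc, , drop = FALSE]
  if (nrow(x) < k) {
    stop(sprintf("only %d complete cases for k = %d", nrow(x), k),
         call. = FALSE)
  }
  if (standardize) x <- scale(x)
  set.seed(seed)
  fit <- stats::kmeans(x, centers = k, nstart = n_restarts, iter.max = 100)
  labels <- fit$cluster
  sizes <- tabulate(labels, k)
  first_id <- vapply(seq_len(k), function(i)
    min(rownames(x)[labels == i]), character(1))
  ord <- order(-sizes, first_id)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- stats::setNames(relabel[labels], rownames(x))
  faction_assignment(labels, "kmeans", k)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected partition agreement under the permutation model:
#' 1 for identical partitions (up to relabelling), about 0 for independent
#' ones.
#'
#' @param a,b Label vectors of equal length (ids aligned).
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Quantify correspondence between two faction assignments
#'
#' Cross-tabulates the two labelings over their (identical) id sets and
#' reports the Pearson chi-square independence test (no continuity
#' correction by default, matching large-sample usage) and the adjusted
#' Rand index. Ids unassigned (`NA`) in either partition are dropped first.
#'
#' @param a,b `faction_assignment` objects (or named label vectors) over
#'   the same ids.
#' @param correct Apply Yates continuity correction.
#' @return A `partition_agreement`: `contingency`, `chi_square`
#'   (`statistic`, `df`, `p`), `ari`, `n`.
#' @export
compare_partitions <- function(a, b, correct = FALSE) {
  la <- if (inherits(a, "faction_assignment")) a$labels else a
  lb <- if (inherits(b, "faction_assignment")) b$labels else b
  ids_a <- names(la)[!is.na(la)]
  ids_b <- names(lb)[!is.na(lb)]
  if (!setequal(ids_a, ids_b)) {
    stop("partitions cover different id sets (after dropping unassigned)",
         call. = FALSE)
  }
  ids <- sort(ids_a)
  la <- la[ids]; lb <- lb[ids]
  tab <- table(a = la, b = lb)
  chi <- chi_square_independence(tab, correct = correct)
  structure(
    list(contingency = tab, chi_square = chi,
         ari = adjusted_rand_index(la, lb), n = length(ids)),
    class = "partition_agreement"
  )
}

#' @export
print.partition_agreement <- function(x, ...) {
  cat(sprintf("<partition_agreement: n = %d, X2(%d) = %.2f, p = %.3g, ARI = %.3f>\n",
              x$n, x$chi_square$df, x$chi_square$statistic, x$chi_square$p,
              x$ari))
  print(x$contingency)
  invisible(x)
}

#' Attach truster/sceptic labels to a two-faction assignment
#'
#' The cluster with the higher mean stance on the anchor items (by default
#' trust in science and in scientists) is labelled `truster`, the other
#' `sceptic`. An exact tie is an error demanding explicit manual labels.
#'
#' @param assignment A `faction_assignment` with two (labelled) clusters.
#' @param stance A [binarize()]d stance matrix covering the labelled ids.
#' @param anchor_items Items anchoring the truster pole.
#' @return The assignment with its `semantic` field filled
#'   (cluster -> `"truster"`/`"sceptic"`).
#' @export
label_factions <- function(assignment, stance,
                           anchor_items = c("trust_science",
                                            "trust_scientists")) {
  stopifnot(inherits(assignment, "faction_assignment"),
            inherits(stance, "stance_matrix"))
  labels <- assignment$labels[!is.na(assignment$labels)]
  clusters <- sort(unique(labels))
  if (length(clusters) != 2L) {
    stop("semantic labelling requires exactly 2 clusters", call. = FALSE)
  }
  absent <- setdiff(anchor_items, stance$item_ids)
  if (length(absent)) {
    stop("anchor item(s) absent: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  ids <- intersect(names(labels), stance$participants)
  anchor_mean <- vapply(clusters, function(cl) {
    mean(stance$stances[ids[labels[ids] == cl], anchor_items], na.rm = TRUE)
  }, numeric(1))
  if (abs(diff(anchor_mean)) < .Machine$double.eps^0.5) {
    stop("anchor stances tie across clusters; supply manual semantic labels",
         call. = FALSE)
  }
  semantic <- ifelse(anchor_mean == max(anchor_mean), "truster", "sceptic")
  names(semantic) <- as.character(clusters)
  assignment$semantic <- semantic
  assignment
}
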