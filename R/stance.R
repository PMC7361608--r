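#' Trichotomize Likert responses into stances
#'
#' Maps each response to a stance: agree (+1) above the cutpoint, disagree
#' (-1) below it, neutral (0) exactly at it, missing stays missing. Under
#' the default midpoint rule the cutpoint is the scale midpoint, so scales
#' spanning an odd number of steps (1--4) admit no neutral stance while
#' 1--7 scales map the central response to 0.
#'
#' @param matrix A [response_matrix()].
#' @param rule `"midpoint"` or `"custom"`.
#' @param cutpoints Named numeric vector of per-item cutpoints, required
#'   when `rule = "custom"` and it must cover every item.
#' @return An object of class `stance_matrix`: `wave_id`, `participants`,
#'   `item_ids`, `stances` (integer matrix over -1/0/+1/`NA`), `rule`.
#' @export
binarize <- function(matrix, rule = c("midpoint", "custom"), cutpoints = NULL) {
  stopifnot(inherits(matrix, "response_matrix"))
  rule <- match.arg(rule)
  ids <- names(matrix$items)
  if (rule == "midpoint") {
    cut <- vapply(matrix$items, function(it) it$scale$midpoint, numeric(1))
  } else {
    if (is.null(cutpoints)) stop("custom rule needs 'cutpoints'", call. = FALSE)
    absent <- setdiff(ids, names(cutpoints))
    if (length(absent)) {
      stop("cutpoints missing for item(s): ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
    cut <- cutpoints[ids]
  }
  st <- sign(sweep(matrix$values, 2, cut, `-`))
  storage.mode(st) <- "integer"
  structure(
    list(wave_id = matrix$wave_id, participants = matrix$participants,
         item_ids = ids, stances = st,
         rule = list(rule = rule, cutpoints = cut)),
    class = "stance_matrix"
  )
}

#' @export
print.stance_matrix <- function(x, ...) {
  tab <- table(factor(x$stances, levels = c(-1, 0, 1)))
  cat(sprintf(
    "<stance_matrix wave '%s': %d participants x %d items (-1: %d, 0: %d, +1: %d, NA: %d)>\n",
    x$wave_id, length(x$participants), length(x$item_ids),
    tab[["-1"]], tab[["0"]], tab[["1"]], sum(is.na(x$stances))))
  invisible(x)
}

#' Build the bipartite person-attitude graph
#'
#' One node per participant and per item; one signed edge per non-neutral,
#' non-missing stance. Persons with only neutral or missing stances remain
#' as isolated nodes. Edges never connect two persons or two items.
#'
#' @param stance A [binarize()]d stance matrix.
#' @return An [igraph::igraph] bipartite graph; vertex attribute `type` is
#'   `FALSE` for persons and `TRUE` for items, edge attribute `sign` is
#'   +1 or -1.
#' @export
build_bipartite <- function(stance) {
  stopifnot(inherits(stance, "stance_matrix"))
  idx <- which(!is.na(stance$stances) & stance$stances != 0L, arr.ind = TRUE)
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(stance$participants),
                            name = stance$participants, type = FALSE)
  g <- igraph::add_vertices(g, length(stance$item_ids),
                            name = stance$item_ids, type = TRUE)
  if (nrow(idx)) {
    ends <- rbind(stance$participants[idx[, 1]], stance$item_ids[idx[, 2]])
    g <- igraph::add_edges(g, as.vector(ends),
                           sign = stance$stances[idx])
  }
  g <- igraph::set_graph_attr(g, "wave_id", stance$wave_id)
  g
}

projection_graph <- function(kind, nodes, edges, params = list()) {
  stopifnot(kind %in% c("participant", "attitude"))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  structure(
    list(kind = kind, nodes = nodes, edges = edges, params = params),
    class = "projection_graph"
  )
}

#' @export
print.projection_graph <- function(x, ...) {
  cat(sprintf("<projection_graph (%s): %d nodes, %d edges>\n",
              x$kind, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Project the bipartite graph onto participants
#'
#' For every participant pair, `compared` counts the items on which both
#' hold a non-neutral, non-missing stance and `shared` the compared items
#' with equal stance sign. The edge weight is the proportion of attitudes
#' shared, `shared / compared`; an edge is emitted when at least
#' `min_overlap` items were compared and the weight reaches `threshold`.
#'
#' @param stance A [binarize()]d stance matrix.
#' @param min_overlap Minimum number of compared items for an edge.
#' @param threshold Minimum agreement weight in `[0, 1]` for an edge.
#' @return A `projection_graph` of kind `"participant"`; edges carry
#'   `u`, `v`, `weight`, `sign` (always +1), `support` (= compared count).
#' @export
project_participants <- function(stance, min_overlap = 5, threshold = 0.75) {
  stopifnot(inherits(stance, "stance_matrix"),
            min_overlap >= 1, threshold >= 0, threshold <= 1)
  s <- stance$stances
  s[is.na(s)] <- 0L
  # crossprod identities: compared = <|s_i|, |s_j|>, shared - opposed = <s_i, s_j>
  compared <- tcrossprod(abs(s))
  shared <- (compared + tcrossprod(s)) / 2
  w <- ifelse(compared > 0, shared / compared, NA_real_)
  keep <- upper.tri(compared) & compared >= min_overlap &
    !is.na(w) & w >= threshold
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(
    u = stance$participants[idx[, 1]],
    v = stance$participants[idx[, 2]],
    weight = w[keep],
    sign = rep(1L, nrow(idx)),
    support = compared[keep],
    stringsAsFactors = FALSE
  )
  projection_graph("participant", stance$participants, edges,
                   params = list(rule = stance$rule$rule,
                                 min_overlap = min_overlap,
                                 threshold = threshold,
                                 wave_id = stance$wave_id))
}

#' Project the bipartite graph onto attitudes
#'
#' For every item pair, `C` counts persons whose stances on the two items
#' share a sign (agreement) and `D` those with opposite signs
#' (disagreement); neutral and missing stances count for neither. The edge
#' carries the majority verdict: sign of `C - D`, weight `|C - D|`, support
#' `C + D`. Pairs with `C = D` produce no edge.
#'
#' @param stance A [binarize()]d stance matrix.
#' @return A `projection_graph` of kind `"attitude"`.
#' @export
project_attitudes <- function(stance) {
  stopifnot(inherits(stance, "stance_matrix"))
  s <- stance$stances
  s[is.na(s)] <- 0L
  net <- crossprod(s)            # C - D
  support <- crossprod(abs(s))   # C + D
  keep <- upper.tri(net) & net != 0
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(
    u = stance$item_ids[idx[, 1]],
    v = stance$item_ids[idx[, 2]],
    weight = abs(net[keep]),
    sign = as.integer(sign(net[keep])),
    support = support[keep],
    stringsAsFactors = FALSE
  )
  projection_graph("attitude", stance$item_ids, edges,
                   params = list(rule = stance$rule$rule,
                                 wave_id = stance$wave_id))
}

#' Retain only edges at or above a weight threshold
#'
#' Nodes are always retained, so thresholding can only disconnect, never
#' shrink, the graph.
#'
#' @param graph A `projection_graph`.
#' @param threshold Minimum edge weight to keep (same units as the graph's
#'   weights: a proportion for participant projections, a person count for
#'   attitude projections).
#' @return A `projection_graph` with the filtered edge set.
#' @export
threshold_edges <- function(graph, threshold) {
  stopifnot(inherits(graph, "projection_graph"), threshold >= 0)
  out <- graph
  out$edges <- graph$edges[graph$edges$weight >= threshold, , drop = FALSE]
  rownames(out$edges) <- NULL
  out$params$threshold <- max(threshold, graph$params$threshold %||% 0)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count edges bridging different factions
#'
#' The paper-facing polarization observable: the number of edges whose
#' endpoints carry different cluster labels. Few bridging edges indicate
#' schism.
#'
#' @param graph A `projection_graph`.
#' @param assignment A `faction_assignment` (or a named label vector)
#'   covering every node incident to an edge.
#' @return Integer count.
#' @export
bridging_edge_count <- function(graph, assignment) {
  stopifnot(inherits(graph, "projection_graph"))
  labels <- if (inherits(assignment, "faction_assignment")) {
    assignment$labels
  } else {
    assignment
  }
  ends <- unique(c(graph$edges$u, graph$edges$v))
  unlabelled <- ends[!ends %in% names(labels) | is.na(labels[ends])]
  if (length(unlabelled)) {
    stop("node(s) without a faction label: ",
         paste(utils::head(unlabelled, 5), collapse = ", "), call. = FALSE)
  }
  sum(labels[graph$edges$u] != labels[graph$edges$v])
}

#' Convert a projection graph to igraph
#'
#' @param graph A `projection_graph`.
#' @return An [igraph::igraph] with `weight`, `sign`, `support` edge
#'   attributes and all (also isolated) nodes.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "projection_graph"))
  igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                vertices = data.frame(name = graph$nodes))
}
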