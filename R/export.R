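#' Deterministic force-directed layout
#'
#' Fruchterman-Reingold spring-electrical placement with edge weights as
#' attraction strengths, seeded so identical `(graph, seed, iterations)`
#' always yield identical coordinates. A single node is placed at the
#' origin. For attitude projections, negative (disagreement) edges do not
#' attract: their weight enters as zero.
#'
#' @param graph A `projection_graph`.
#' @param seed RNG seed.
#' @param iterations Number of layout iterations.
#' @return A `layout_result`: `coordinates` (nodes x 2 matrix),
#'   `algorithm`, `seed`, `iterations`.
#' @export
layout_graph <- function(graph, seed = 1, iterations = 500) {
  stopifnot(inherits(graph, "projection_graph"))
  if (!length(graph$nodes)) stop("graph has no nodes", call. = FALSE)
  g <- as_igraph(graph)
  if (length(graph$nodes) == 1L) {
    xy <- matrix(0, 1, 2)
  } else {
    w <- NULL
    if (nrow(graph$edges)) {
      w <- graph$edges$weight * graph$edges$sign
      # FR needs strictly positive weights; repulsive (negative) edges get a
      # vanishing attraction instead
      floor_w <- if (any(w > 0)) min(w[w > 0]) * 1e-6 else 1e-6
      w[w <= 0] <- floor_w
    }
    set.seed(seed)
    xy <- igraph::layout_with_fr(g, niter = iterations, weights = w)
  }
  dimnames(xy) <- list(graph$nodes, c("x", "y"))
  structure(
    list(coordinates = xy, algorithm = "fruchterman-reingold",
         seed = seed, iterations = iterations),
    class = "layout_result"
  )
}

attach_attrs <- function(graph, layout = NULL, assignment = NULL) {
  g <- as_igraph(graph)
  g <- igraph::set_graph_attr(g, "kind", graph$kind)
  if (!is.null(layout)) {
    xy <- layout$coordinates[igraph::V(g)$name, , drop = FALSE]
    g <- igraph::set_vertex_attr(g, "x", value = xy[, 1])
    g <- igraph::set_vertex_attr(g, "y", value = xy[, 2])
  }
  if (!is.null(assignment)) {
    labels <- assignment$labels[igraph::V(g)$name]
    g <- igraph::set_vertex_attr(g, "faction", value = as.numeric(labels))
    if (!is.null(assignment$semantic)) {
      sem <- assignment$semantic[as.character(labels)]
      sem[is.na(sem)] <- "unassigned"
      g <- igraph::set_vertex_attr(g, "semantic", value = unname(sem))
    }
  }
  g
}

#' Export a projection graph
#'
#' Writes GraphML (via igraph), GEXF 1.3, or a plain edge-list CSV
#' (`u,v,weight,sign,support`). Node faction/semantic labels and layout
#' coordinates are carried along when supplied; all three formats
#' re-import losslessly via [import_graph()].
#'
#' @param graph A `projection_graph`.
#' @param path Output file path.
#' @param format `"graphml"`, `"gexf"` or `"edge_csv"`.
#' @param layout Optional `layout_result`.
#' @param assignment Optional `faction_assignment`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path,
                         format = c("graphml", "gexf", "edge_csv"),
                         layout = NULL, assignment = NULL) {
  stopifnot(inherits(graph, "projection_graph"))
  format <- match.arg(format)
  if (format == "edge_csv") {
    utils::write.csv(graph$edges, path, row.names = FALSE)
    return(invisible(path))
  }
  g <- attach_attrs(graph, layout, assignment)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    write_gexf(g, path)
  }
  invisible(path)
}

# minimal GEXF 1.3 writer: node attributes besides label, edge
# weight/sign/support as attvalues
write_gexf <- function(g, path) {
  doc <- xml2::xml_new_root("gexf",
    xmlns = "http://gexf.net/1.3", version = "1.3")
  graph_node <- xml2::xml_add_child(doc, "graph",
    defaultedgetype = "undirected")
  vattrs <- setdiff(igraph::vertex_attr_names(g), "name")
  nattrs <- xml2::xml_add_child(graph_node, "attributes", class = "node")
  for (i in seq_along(vattrs)) {
    xml2::xml_add_child(nattrs, "attribute", id = as.character(i - 1),
                        title = vattrs[i],
                        type = if (is.numeric(igraph::vertex_attr(g, vattrs[i])))
                          "double" else "string")
  }
  eattrs <- xml2::xml_add_child(graph_node, "attributes", class = "edge")
  edge_fields <- setdiff(igraph::edge_attr_names(g), "weight")
  for (i in seq_along(edge_fields)) {
    xml2::xml_add_child(eattrs, "attribute", id = as.character(i - 1),
                        title = edge_fields[i], type = "double")
  }
  nodes <- xml2::xml_add_child(graph_node, "nodes")
  for (v in seq_len(igraph::vcount(g))) {
    nd <- xml2::xml_add_child(nodes, "node",
                              id = igraph::V(g)$name[v],
                              label = igraph::V(g)$name[v])
    if (length(vattrs)) {
      av <- xml2::xml_add_child(nd, "attvalues")
      for (i in seq_along(vattrs)) {
        xml2::xml_add_child(av, "attvalue", `for` = as.character(i - 1),
                            value = as.character(igraph::vertex_attr(g, vattrs[i], v)))
      }
    }
  }
  edges <- xml2::xml_add_child(graph_node, "edges")
  el <- igraph::as_edgelist(g)
  for (e in seq_len(igraph::ecount(g))) {
    ed <- xml2::xml_add_child(edges, "edge", id = as.character(e - 1),
                              source = el[e, 1], target = el[e, 2],
                              weight = as.character(igraph::E(g)$weight[e]))
    if (length(edge_fields)) {
      av <- xml2::xml_add_child(ed, "attvalues")
      for (i in seq_along(edge_fields)) {
        xml2::xml_add_child(av, "attvalue", `for` = as.character(i - 1),
                            value = as.character(igraph::edge_attr(g, edge_fields[i], e)))
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  attr_defs <- function(klass) {
    nodes <- xml2::xml_find_all(doc, sprintf(
      "//g:attributes[@class='%s']/g:attribute", klass), ns)
    stats::setNames(xml2::xml_attr(nodes, "title"), xml2::xml_attr(nodes, "id"))
  }
  vdefs <- attr_defs("node")
  edefs <- attr_defs("edge")
  node_els <- xml2::xml_find_all(doc, "//g:nodes/g:node", ns)
  nodes <- data.frame(name = xml2::xml_attr(node_els, "id"),
                      stringsAsFactors = FALSE)
  for (id in names(vdefs)) {
    nodes[[vdefs[[id]]]] <- vapply(node_els, function(nd) {
      v <- xml2::xml_find_first(nd, sprintf(".//g:attvalue[@for='%s']", id), ns)
      xml2::xml_attr(v, "value")
    }, character(1))
  }
  edge_els <- xml2::xml_find_all(doc, "//g:edges/g:edge", ns)
  edges <- data.frame(u = xml2::xml_attr(edge_els, "source"),
                      v = xml2::xml_attr(edge_els, "target"),
                      weight = as.numeric(xml2::xml_attr(edge_els, "weight")),
                      stringsAsFactors = FALSE)
  for (id in names(edefs)) {
    edges[[edefs[[id]]]] <- as.numeric(vapply(edge_els, function(ed) {
      v <- xml2::xml_find_first(ed, sprintf(".//g:attvalue[@for='%s']", id), ns)
      xml2::xml_attr(v, "value")
    }, character(1)))
  }
  list(nodes = nodes, edges = edges)
}

#' Re-import an exported graph
#'
#' @param path File written by [export_graph()].
#' @param format Format it was written in.
#' @return A list with `nodes` (data frame of node attributes) and `edges`
#'   (data frame with `u`, `v`, `weight` and any further attributes).
#' @export
import_graph <- function(path, format = c("graphml", "gexf", "edge_csv")) {
  format <- match.arg(format)
  if (format == "edge_csv") {
    edges <- utils::read.csv(path, stringsAsFactors = FALSE)
    return(list(nodes = data.frame(name = unique(c(edges$u, edges$v)),
                                   stringsAsFactors = FALSE),
                edges = edges))
  }
  if (format == "gexf") return(read_gexf(path))
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_edgelist(g)
  edges <- data.frame(u = el[, 1], v = el[, 2], stringsAsFactors = FALSE)
  for (a in igraph::edge_attr_names(g)) edges[[a]] <- igraph::edge_attr(g, a)
  nodes <- data.frame(name = igraph::V(g)$name, stringsAsFactors = FALSE)
  for (a in setdiff(igraph::vertex_attr_names(g), "name")) {
    nodes[[a]] <- igraph::vertex_attr(g, a)
  }
  list(nodes = nodes, edges = edges)
}

#' Plot one panel per wave of a projection-graph sequence
#'
#' Renders the wave-by-wave schism: one force-directed panel per wave with
#' faction-coloured nodes (truster white, sceptic gold, unassigned grey by
#' convention).
#'
#' @param graphs List of `projection_graph` objects, one per wave.
#' @param layouts List of matching `layout_result` objects.
#' @param out Output PNG path.
#' @param assignments Optional list of `faction_assignment` objects (one
#'   per wave) for node colouring.
#' @param colors Named colour map for semantic labels.
#' @param width,height Panel device size in pixels.
#' @return `out`, invisibly.
#' @export
wave_panel <- function(graphs, layouts, out, assignments = NULL,
                       colors = c(truster = "white", sceptic = "gold",
                                  unassigned = "grey70"),
                       width = 480 * length(graphs), height = 480) {
  if (length(graphs) != length(layouts)) {
    stop("graphs and layouts differ in length", call. = FALSE)
  }
  if (!is.null(assignments) && length(assignments) != length(graphs)) {
    stop("assignments and graphs differ in length", call. = FALSE)
  }
  grDevices::png(out, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(1, length(graphs)), mar = c(1, 1, 2, 1))
  for (i in seq_along(graphs)) {
    g <- as_igraph(graphs[[i]])
    xy <- layouts[[i]]$coordinates[igraph::V(g)$name, , drop = FALSE]
    col <- "grey70"
    if (!is.null(assignments)) {
      a <- assignments[[i]]
      sem <- rep("unassigned", igraph::vcount(g))
      if (!is.null(a$semantic)) {
        lab <- a$labels[igraph::V(g)$name]
        s <- a$semantic[as.character(lab)]
        sem[!is.na(s)] <- s[!is.na(s)]
      }
      col <- colors[sem]
    }
    igraph::plot.igraph(g, layout = xy, vertex.size = 4,
                        vertex.label = NA, vertex.color = col,
                        edge.color = grDevices::adjustcolor("steelblue", 0.4),
                        main = graphs[[i]]$params$wave_id %||% paste("wave", i))
  }
  invisible(out)
}
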