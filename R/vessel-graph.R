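# The vessel_graph container: a planar geometric graph of lumen centrelines.
# Nodes are junctions/endpoints (positions in micrometres, image frame:
# x = column, y = row). Each edge carries an ordered centreline polyline,
# per-point inscribed-circle radii, arc length and a vascular-bed label.

VESSEL_BEDS <- c("artery", "vein", "capillary", "sprouting_front", "unassigned")

#' Construct a vessel graph
#'
#' @param nodes Data frame with columns `id` (integer), `x`, `y` (um).
#' @param edges List of edge records; each is a list with `id`, `node_a`,
#'   `node_b`, `polyline` (n x 2 matrix, um), `radii` (length-n vector, um),
#'   `length` (um, computed if missing) and `bed` (one of artery, vein,
#'   capillary, sprouting_front, unassigned).
#' @param domain Optional c(width, height) of the imaged domain, um.
#' @param roots Optional named list of special node ids (e.g. `artery`,
#'   `vein` trunk roots) used for default flow boundary conditions.
#' @param validate Check structural invariants (default TRUE).
#' @return Object of class `vessel_graph`.
#' @export
vessel_graph <- function(nodes, edges, domain = NULL, roots = NULL,
                         validate = TRUE) {
  nodes <- as.data.frame(nodes)
  stop_if_not(all(c("id", "x", "y") %in% names(nodes)),
              "nodes must have columns id, x, y")
  nodes$id <- as.integer(nodes$id)
  stop_if_not(!anyDuplicated(nodes$id), "duplicate node ids")
  edges <- lapply(edges, function(e) {
    e$id <- as.integer(e$id)
    e$node_a <- as.integer(e$node_a)
    e$node_b <- as.integer(e$node_b)
    e$polyline <- as.matrix(e$polyline)
    e$bed <- e$bed %||% "unassigned"
    e$length <- e$length %||% polyline_length(e$polyline)
    e
  })
  g <- structure(list(nodes = nodes, edges = edges,
                      domain = domain, roots = roots),
                 class = "vessel_graph")
  if (validate) validate_vessel_graph(g)
  g
}

validate_vessel_graph <- function(g, tol = 1e-6) {
  pos <- g$nodes
  for (e in g$edges) {
    stop_if_not(e$node_a %in% pos$id && e$node_b %in% pos$id,
                sprintf("edge %d references unknown node", e$id))
    stop_if_not(nrow(e$polyline) >= 2,
                sprintf("edge %d: polyline needs >= 2 points", e$id))
    stop_if_not(length(e$radii) == nrow(e$polyline),
                sprintf("edge %d: radii/polyline length mismatch", e$id))
    stop_if_not(all(e$radii > 0), sprintf("edge %d: nonpositive radius", e$id))
    pa <- unlist(pos[pos$id == e$node_a, c("x", "y")])
    pb <- unlist(pos[pos$id == e$node_b, c("x", "y")])
    stop_if_not(vec_norm(e$polyline[1, ] - pa) < tol,
                sprintf("edge %d: polyline start is off node %d", e$id, e$node_a))
    stop_if_not(vec_norm(e$polyline[nrow(e$polyline), ] - pb) < tol,
                sprintf("edge %d: polyline end is off node %d", e$id, e$node_b))
    chord <- vec_norm(pb - pa)
    stop_if_not(e$length >= chord - 1e-6,
                sprintf("edge %d: arc length below chord", e$id))
    stop_if_not(!(e$node_a == e$node_b && e$length <= tol),
                sprintf("edge %d: zero-length self-loop", e$id))
    stop_if_not(e$bed %in% VESSEL_BEDS,
                sprintf("edge %d: unknown bed '%s'", e$id, e$bed))
  }
  invisible(g)
}

#' Summarize vessel-graph edges as a data frame
#'
#' @param g A `vessel_graph`.
#' @return Data frame with one row per edge: id, node_a, node_b, length_um,
#'   mean_radius_um, bed.
#' @export
edge_table <- function(g) {
  do.call(rbind, lapply(g$edges, function(e)
    data.frame(id = e$id, node_a = e$node_a, node_b = e$node_b,
               length_um = e$length, mean_radius_um = mean(e$radii),
               bed = e$bed)))
}

# igraph view of the topology (vertex names are node ids as characters).
as_igraph_vg <- function(g) {
  verts <- data.frame(name = as.character(g$nodes$id))
  ed <- data.frame(
    from = vapply(g$edges, function(e) as.character(e$node_a), ""),
    to = vapply(g$edges, function(e) as.character(e$node_b), ""))
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = verts)
}

#' Node degrees of a vessel graph
#'
#' @param g A `vessel_graph`.
#' @return Named integer vector (names = node ids).
#' @export
node_degrees <- function(g) {
  deg <- stats::setNames(integer(nrow(g$nodes)), as.character(g$nodes$id))
  for (e in g$edges) {
    deg[as.character(e$node_a)] <- deg[as.character(e$node_a)] + 1L
    deg[as.character(e$node_b)] <- deg[as.character(e$node_b)] + 1L
  }
  deg
}

#' Number of connected components of a vessel graph
#' @param g A `vessel_graph`.
#' @return Integer count.
#' @export
graph_components <- function(g) {
  igraph::count_components(as_igraph_vg(g))
}

#' Total centreline length of a vessel graph
#' @param g A `vessel_graph`.
#' @return Length in um.
#' @export
total_length <- function(g) sum(vapply(g$edges, `[[`, numeric(1), "length"))

#' @export
print.vessel_graph <- function(x, ...) {
  deg <- node_degrees(x)
  cat(sprintf("vessel_graph: %d nodes, %d edges, total length %.0f um\n",
              nrow(x$nodes), length(x$edges), total_length(x)))
  cat(sprintf("  junctions (deg >= 3): %d; endpoints (deg 1): %d\n",
              sum(deg >= 3), sum(deg == 1)))
  beds <- table(vapply(x$edges, `[[`, "", "bed"))
  cat("  beds:", paste(sprintf("%s=%d", names(beds), beds), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.vessel_graph <- function(object, ...) {
  et <- edge_table(object)
  cat(sprintf("vessel_graph with %d nodes / %d edges\n",
              nrow(object$nodes), nrow(et)))
  print(stats::aggregate(cbind(length_um, mean_radius_um) ~ bed, et,
                         function(v) round(mean(v), 2)))
  invisible(et)
}

# Nearest graph node to a point (x, y) in um.
nearest_node <- function(g, point) {
  d2 <- (g$nodes$x - point[1])^2 + (g$nodes$y - point[2])^2
  g$nodes$id[which.min(d2)]
}
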