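# Steady Poiseuille/Kirchhoff flow on the vessel graph.
#
# Each edge is treated as a tube of (possibly varying) circular cross-section;
# its hydraulic resistance is the arc-length integral of 8*mu/(pi*R^4).
# Pressures solve Kirchhoff's current law at interior nodes; wall shear
# stress follows the Poiseuille wall formula tau = 4*mu*|Q|/(pi*R^3).
# Units: um, s, Pa throughout (conductance um^3/(s*Pa)).

#' Blood viscosity by the Pries in-vitro law
#'
#' Apparent viscosity of blood flowing in a narrow tube as a function of
#' tube radius and discharge hematocrit (Fahraeus-Lindqvist effect),
#' relative viscosity scaled by plasma viscosity.
#'
#' @param radius_um Tube radius in um.
#' @param hematocrit Discharge hematocrit (default 0.45).
#' @param plasma_viscosity_pa_s Plasma viscosity, Pa s (default 1.2e-3).
#' @return Viscosity in Pa s (vectorized over radius).
#' @export
pries_viscosity <- function(radius_um, hematocrit = 0.45,
                            plasma_viscosity_pa_s = 1.2e-3) {
  d <- 2 * radius_um
  mu45 <- 220 * exp(-1.3 * d) + 3.2 - 2.44 * exp(-0.06 * d^0.645)
  frac <- 1 / (1 + 1e-11 * d^12)
  cc <- (0.8 + exp(-0.075 * d)) * (-1 + frac) + frac
  rel <- 1 + (mu45 - 1) * ((1 - hematocrit)^cc - 1) / ((1 - 0.45)^cc - 1)
  rel * plasma_viscosity_pa_s
}

# Per-point viscosity along an edge under the chosen rheology model.
edge_viscosity <- function(radii, viscosity_pa_s, model = "constant",
                           hematocrit = 0.45) {
  if (model == "pries") pries_viscosity(radii, hematocrit)
  else rep(viscosity_pa_s, length(radii))
}

#' Hydraulic conductance of a vessel segment
#'
#' Series (Poiseuille) composition along the centreline:
#' G = \[ integral of 8 mu / (pi R(s)^4) ds \]^-1, evaluated by the
#' trapezoidal rule over the polyline's per-point radii. A uniform tube
#' reduces to the closed form G = pi R^4 / (8 mu L).
#'
#' @param edge A vessel-graph edge record (`polyline`, `radii`, `id`).
#' @param viscosity_pa_s Dynamic viscosity, Pa s.
#' @param model `"constant"` or `"pries"` (radius-dependent viscosity).
#' @param hematocrit Hematocrit for the Pries model.
#' @return Conductance in um^3/(s Pa).
#' @export
segment_conductance <- function(edge, viscosity_pa_s = 3.5e-3,
                                model = c("constant", "pries"),
                                hematocrit = 0.45) {
  model <- match.arg(model)
  if (any(edge$radii <= 0))
    stop(sprintf("edge %d has nonpositive radius", edge$id), call. = FALSE)
  stop_if_not(polyline_length(edge$polyline) > 0,
              sprintf("edge %d has zero length", edge$id))
  mu <- edge_viscosity(edge$radii, viscosity_pa_s, model, hematocrit)
  integrand <- 8 * mu / (pi * edge$radii^4)
  ds <- sqrt(rowSums(diff(edge$polyline)^2))
  resistance <- sum(ds * (integrand[-1] + integrand[-length(integrand)]) / 2)
  1 / resistance
}

#' Boundary conditions for the flow solve
#'
#' @param node Node ids.
#' @param kind `"fixed_pressure"` or `"no_flow"` per node.
#' @param pressure_pa Pressure for fixed-pressure nodes (NA otherwise).
#' @return Data frame of class `boundary_conditions`.
#' @export
boundary_conditions <- function(node, kind, pressure_pa = NA_real_) {
  bc <- data.frame(node = as.integer(node), kind = kind,
                   pressure_pa = pressure_pa)
  stop_if_not(all(bc$kind %in% c("fixed_pressure", "no_flow")),
              "kind must be fixed_pressure or no_flow")
  stop_if_not(all(is.finite(bc$pressure_pa[bc$kind == "fixed_pressure"])),
              "fixed_pressure nodes need a finite pressure")
  stop_if_not(sum(bc$kind == "fixed_pressure") >= 2,
              "need at least two fixed-pressure nodes (an inlet and an outlet)")
  class(bc) <- c("boundary_conditions", "data.frame")
  bc
}

#' Default boundary conditions from graph roots
#'
#' Fixes the artery root at `inlet_pressure_pa` and the vein root at 0 Pa;
#' every other terminal (degree-1) node is blind-ended (no flow).
#'
#' @param g A `vessel_graph` whose `roots` name `artery` and `vein` nodes.
#' @param inlet_pressure_pa Arterial inlet pressure above the venous
#'   reference, Pa.
#' @return A `boundary_conditions` object.
#' @export
default_boundary <- function(g, inlet_pressure_pa = 2500) {
  stop_if_not(!is.null(g$roots) && !is.null(g$roots$artery) &&
                !is.null(g$roots$vein),
              "graph has no artery/vein roots; supply boundary_conditions()")
  deg <- node_degrees(g)
  term <- as.integer(names(deg)[deg == 1])
  term <- setdiff(term, c(g$roots$artery, g$roots$vein))
  boundary_conditions(
    node = c(g$roots$artery, g$roots$vein, term),
    kind = c("fixed_pressure", "fixed_pressure", rep("no_flow", length(term))),
    pressure_pa = c(inlet_pressure_pa, 0, rep(NA_real_, length(term))))
}

#' Solve nodal pressures on the hydraulic network
#'
#' Assembles the weighted graph Laplacian with edge conductances and solves
#' flow conservation at every non-fixed node (no-flow terminals are the
#' natural boundary condition), as a sparse symmetric linear system.
#'
#' @param g A `vessel_graph`.
#' @param conductances Numeric vector, one per edge (same order as
#'   `g$edges`).
#' @param boundary A `boundary_conditions` object; every connected component
#'   must contain at least one fixed-pressure node.
#' @return Named numeric vector of node pressures (Pa), names = node ids.
#' @export
solve_nodal_pressures <- function(g, conductances, boundary) {
  ids <- g$nodes$id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), as.character(ids))
  fixed <- boundary$node[boundary$kind == "fixed_pressure"]
  stop_if_not(all(fixed %in% ids), "boundary references unknown node")
  comp <- igraph::components(as_igraph_vg(g))$membership
  fixed_comp <- unique(comp[as.character(fixed)])
  if (!all(unique(comp) %in% fixed_comp))
    stop("connected component without a fixed-pressure node: system underdetermined",
         call. = FALSE)
  ia <- vapply(g$edges, function(e) idx[[as.character(e$node_a)]], integer(1))
  ib <- vapply(g$edges, function(e) idx[[as.character(e$node_b)]], integer(1))
  L <- Matrix::sparseMatrix(
    i = c(ia, ib, ia, ib), j = c(ib, ia, ia, ib),
    x = c(-conductances, -conductances, conductances, conductances),
    dims = c(n, n))
  p <- stats::setNames(rep(NA_real_, n), as.character(ids))
  p[as.character(fixed)] <-
    boundary$pressure_pa[boundary$kind == "fixed_pressure"]
  free <- which(is.na(p))
  if (length(free)) {
    A <- L[free, free, drop = FALSE]
    b <- -L[free, -free, drop = FALSE] %*% p[-free]
    sol <- tryCatch(Matrix::solve(A, b),
                    error = function(e) stop("singular hydraulic system: ",
                                             conditionMessage(e), call. = FALSE))
    p[free] <- as.numeric(sol)
  }
  p
}

#' Edge flows and wall shear stress from solved pressures
#'
#' Q = G * (P_a - P_b), signed positive from node_a to node_b. Pointwise
#' WSS along each polyline is tau = 4 mu |Q| / (pi R^3); the edge value is
#' its arc-length-weighted mean. The flow direction field is the polyline
#' tangent oriented from high to low pressure.
#'
#' @param g A `vessel_graph`.
#' @param pressures Named pressures from [solve_nodal_pressures()].
#' @param viscosity_pa_s Viscosity, Pa s.
#' @param model,hematocrit Rheology model as in [segment_conductance()].
#' @param conductances Optional precomputed conductances.
#' @return Object of class `flow_solution`: list with `node_pressure`,
#'   `edges` (data frame: id, conductance, flow_um3_s, wss_pa, reversed),
#'   `viscosity_pa_s`, `model`.
#' @export
segment_flows_and_wss <- function(g, pressures, viscosity_pa_s = 3.5e-3,
                                  model = "constant", hematocrit = 0.45,
                                  conductances = NULL) {
  if (is.null(conductances))
    conductances <- vapply(g$edges, segment_conductance, numeric(1),
                           viscosity_pa_s = viscosity_pa_s, model = model,
                           hematocrit = hematocrit)
  rows <- lapply(seq_along(g$edges), function(i) {
    e <- g$edges[[i]]
    q <- conductances[i] * (pressures[[as.character(e$node_a)]] -
                              pressures[[as.character(e$node_b)]])
    mu <- edge_viscosity(e$radii, viscosity_pa_s, model, hematocrit)
    tau_pt <- 4 * mu * abs(q) / (pi * e$radii^3)
    ds <- sqrt(rowSums(diff(e$polyline)^2))
    w <- c(ds / 2, 0) + c(0, ds / 2)      # trapezoidal point weights
    data.frame(id = e$id, conductance = conductances[i], flow_um3_s = q,
               wss_pa = sum(w * tau_pt) / sum(w), reversed = q < 0)
  })
  structure(list(node_pressure = pressures, edges = do.call(rbind, rows),
                 viscosity_pa_s = viscosity_pa_s, model = model,
                 hematocrit = hematocrit),
            class = "flow_solution")
}

#' Solve steady network flow on a vessel graph
#'
#' Convenience wrapper: conductances, nodal pressures and per-edge
#' flow/WSS in one call.
#'
#' @inheritParams segment_flows_and_wss
#' @param boundary A `boundary_conditions` object, or `NULL` to use
#'   [default_boundary()] with `inlet_pressure_pa`.
#' @param inlet_pressure_pa Inlet pressure for the default boundary.
#' @return A `flow_solution`.
#' @export
solve_flow <- function(g, viscosity_pa_s = 3.5e-3, boundary = NULL,
                       inlet_pressure_pa = 2500, model = c("constant", "pries"),
                       hematocrit = 0.45) {
  model <- match.arg(model)
  if (is.null(boundary)) boundary <- default_boundary(g, inlet_pressure_pa)
  cond <- vapply(g$edges, segment_conductance, numeric(1),
                 viscosity_pa_s = viscosity_pa_s, model = model,
                 hematocrit = hematocrit)
  p <- solve_nodal_pressures(g, cond, boundary)
  fl <- segment_flows_and_wss(g, p, viscosity_pa_s, model, hematocrit,
                              conductances = cond)
  fl$boundary <- boundary
  fl
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("flow_solution: %d nodes, %d edges (viscosity %.3g Pa s, %s)\n",
              length(x$node_pressure), nrow(x$edges), x$viscosity_pa_s,
              x$model))
  cat(sprintf("  pressure range: %.3g .. %.3g Pa\n",
              min(x$node_pressure), max(x$node_pressure)))
  cat(sprintf("  WSS: median %.3g Pa, max %.3g Pa\n",
              stats::median(x$edges$wss_pa), max(x$edges$wss_pa)))
  invisible(x)
}

#' Net flow imbalance at interior nodes
#'
#' Sum of signed flows at every node without a boundary condition other
#' than no-flow terminals excluded; used to verify mass conservation.
#'
#' @param g A `vessel_graph`.
#' @param flow A `flow_solution` with a `boundary` element.
#' @return Named vector of absolute net flows (um^3/s) at interior nodes.
#' @export
node_flow_imbalance <- function(g, flow) {
  fixed <- flow$boundary$node[flow$boundary$kind == "fixed_pressure"]
  net <- stats::setNames(numeric(nrow(g$nodes)), as.character(g$nodes$id))
  for (i in seq_along(g$edges)) {
    e <- g$edges[[i]]
    q <- flow$edges$flow_um3_s[i]
    net[as.character(e$node_a)] <- net[as.character(e$node_a)] - q
    net[as.character(e$node_b)] <- net[as.character(e$node_b)] + q
  }
  abs(net[!(names(net) %in% as.character(fixed))])
}

# --- spatial sampling of the flow field -------------------------------------

#' Build a spatial index of graph polylines
#'
#' Buckets polyline vertices on a uniform grid for fast nearest-point
#' queries; used when sampling WSS at many nucleus positions.
#'
#' @param g A `vessel_graph`.
#' @param cell_um Grid cell size (um); default chosen from vertex spacing.
#' @return Opaque index object for [wss_vector_at_point()].
#' @export
polyline_index <- function(g, cell_um = NULL) {
  pts <- do.call(rbind, lapply(g$edges, function(e) {
    cbind(e$polyline, edge = e$id, pt = seq_len(nrow(e$polyline)))
  }))
  if (is.null(pts) || nrow(pts) == 0) stop("graph has no edges", call. = FALSE)
  if (is.null(cell_um)) {
    sp <- max(vapply(g$edges, function(e) {
      if (nrow(e$polyline) < 2) return(0)
      max(sqrt(rowSums(diff(e$polyline)^2)))
    }, numeric(1)))
    cell_um <- max(sp * 2, 4)
  }
  gx <- floor(pts[, 1] / cell_um)
  gy <- floor(pts[, 2] / cell_um)
  key <- paste(gx, gy)
  list(pts = pts, cell = cell_um, buckets = split(seq_len(nrow(pts)), key),
       edge_of = pts[, 3], pt_of = pts[, 4])
}

# Nearest point on any edge polyline to `point`; exact segment projection on
# candidate edges found through the vertex grid. Ties broken by lower edge id,
# then smaller arc position. Returns NULL if nothing within max_dist.
nearest_polyline_point <- function(g, point, max_dist, index) {
  cand <- integer(0)
  reach <- ceiling((max_dist + index$cell) / index$cell)
  cx <- floor(point[1] / index$cell); cy <- floor(point[2] / index$cell)
  for (dx in -reach:reach) for (dy in -reach:reach) {
    b <- index$buckets[[paste(cx + dx, cy + dy)]]
    if (!is.null(b)) cand <- c(cand, b)
  }
  if (!length(cand)) return(NULL)
  edges <- sort(unique(index$edge_of[cand]))
  best <- NULL
  for (eid in edges) {
    e <- g$edges[[match(eid, vapply(g$edges, `[[`, integer(1), "id"))]]
    p <- e$polyline
    a <- p[-nrow(p), , drop = FALSE]
    d <- p[-1, , drop = FALSE] - a
    len2 <- rowSums(d^2)
    t <- ((point[1] - a[, 1]) * d[, 1] + (point[2] - a[, 2]) * d[, 2]) /
      pmax(len2, 1e-300)
    t <- pmin(pmax(t, 0), 1)
    px <- a[, 1] + t * d[, 1]; py <- a[, 2] + t * d[, 2]
    dist <- sqrt((point[1] - px)^2 + (point[2] - py)^2)
    k <- which.min(dist)
    if (dist[k] <= max_dist &&
        (is.null(best) || dist[k] < best$dist - 1e-9)) {
      best <- list(edge = e, seg = k, t = t[k], dist = dist[k],
                   point = c(px[k], py[k]))
    }
  }
  best
}

#' Sample the WSS vector at a point
#'
#' Finds the nearest centreline point across all edges; if it lies within
#' `max_dist` of `point`, returns the pointwise WSS magnitude there and the
#' flow-oriented unit tangent. Ties between equidistant edges break
#' deterministically to the lower edge id.
#'
#' @param flow A `flow_solution`.
#' @param g The `vessel_graph` the flow was solved on.
#' @param point c(x, y) in um.
#' @param max_dist Maximum sampling distance, um.
#' @param index Optional prebuilt [polyline_index()].
#' @return List with `wss_pa`, `flow_dir` (unit 2-vector), `edge_id`,
#'   `dist_um`; or `NULL` if no vessel lies within `max_dist`.
#' @export
wss_vector_at_point <- function(flow, g, point, max_dist = 20, index = NULL) {
  stop_if_not(max_dist > 0, "max_dist must be positive")
  if (is.null(index)) index <- polyline_index(g)
  hit <- nearest_polyline_point(g, point, max_dist, index)
  if (is.null(hit)) return(NULL)
  e <- hit$edge
  row <- flow$edges[flow$edges$id == e$id, ]
  mu <- edge_viscosity(e$radii, flow$viscosity_pa_s, flow$model,
                       flow$hematocrit %||% 0.45)
  r <- (1 - hit$t) * e$radii[hit$seg] + hit$t * e$radii[hit$seg + 1]
  mu_loc <- (1 - hit$t) * mu[hit$seg] + hit$t * mu[hit$seg + 1]
  tau <- 4 * mu_loc * abs(row$flow_um3_s) / (pi * r^3)
  tang <- e$polyline[hit$seg + 1, ] - e$polyline[hit$seg, ]
  tang <- tang / vec_norm(tang)
  if (row$reversed) tang <- -tang
  list(wss_pa = tau, flow_dir = tang, edge_id = e$id, dist_um = hit$dist,
       bed = e$bed)
}
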