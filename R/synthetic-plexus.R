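# Synthetic retinal-style plexus generator.
#
# Ground truth for validating the whole pipeline: an artery trunk and a vein
# trunk bridged by a jittered capillary lattice with random edge dropout and
# blind-ended sprouts at the distal margin; flow is solved on the true graph
# and endothelial cells are placed on centrelines with axial-polarity angles
# drawn from a von Mises distribution centred anti-parallel to local flow,
# whose concentration rises sigmoidally with wall shear stress around a
# threshold tau0.

#' Parameters of the synthetic plexus geometry
#'
#' @param domain_size c(width, height) of the tissue domain, um.
#' @param pixel_size Rasterization scale, um per pixel.
#' @param artery_radius,vein_radius Trunk radii at the root, um (trunks taper
#'   linearly to 75\% of the root radius at the distal end).
#' @param capillary_radius_mean,capillary_radius_sd Capillary radius
#'   distribution (normal, truncated at 1 um), um.
#' @param mesh_spacing Capillary lattice spacing, um.
#' @param edge_dropout_prob Probability of removing each capillary edge;
#'   draws that disconnect the network are rejected and resampled.
#' @param n_sprouts Number of blind-ended sprouts on the distal margin.
#' @param jitter_sd Positional jitter of interior lattice nodes, um.
#' @param seed Integer seed; the whole geometry is deterministic given it.
#' @return Object of class `plexus_params`.
#' @export
plexus_params <- function(domain_size = c(480, 360), pixel_size = 1,
                          artery_radius = 12, vein_radius = 14,
                          capillary_radius_mean = 4, capillary_radius_sd = 0.8,
                          mesh_spacing = 60, edge_dropout_prob = 0.15,
                          n_sprouts = 8, jitter_sd = 6, seed = 1) {
  p <- list(domain_size = as.numeric(domain_size), pixel_size = pixel_size,
            artery_radius = artery_radius, vein_radius = vein_radius,
            capillary_radius_mean = capillary_radius_mean,
            capillary_radius_sd = capillary_radius_sd,
            mesh_spacing = mesh_spacing,
            edge_dropout_prob = edge_dropout_prob,
            n_sprouts = as.integer(n_sprouts), jitter_sd = jitter_sd,
            seed = as.integer(seed))
  stop_if_not(length(p$domain_size) == 2 && all(p$domain_size > 0),
              "domain_size must be positive (width, height)")
  stop_if_not(p$pixel_size > 0, "pixel_size must be > 0")
  stop_if_not(p$artery_radius > 0 && p$vein_radius > 0 &&
                p$capillary_radius_mean > 0 && p$capillary_radius_sd >= 0,
              "radii must be positive")
  stop_if_not(p$mesh_spacing > 0, "mesh_spacing must be > 0")
  stop_if_not(p$edge_dropout_prob >= 0 && p$edge_dropout_prob < 1,
              "edge_dropout_prob must lie in [0, 1)")
  stop_if_not(p$n_sprouts >= 0 && p$jitter_sd >= 0, "invalid sprout/jitter")
  class(p) <- "plexus_params"
  p
}

#' Parameters of the shear-threshold polarity response
#'
#' Cells polarize against the flow with a strength that rises sigmoidally
#' with local wall shear stress: the von Mises concentration is
#' kappa(tau) = kappa_max / (1 + exp(-(tau - tau0)/slope_s)).
#'
#' @param tau0 WSS threshold, Pa (sigmoid midpoint).
#' @param slope_s Sigmoid width, Pa.
#' @param kappa_max Concentration ceiling (dimensionless; 0 = never
#'   polarized, i.e. uniform angles at any shear).
#' @param polarity_len_mean,polarity_len_sd Nucleus-to-Golgi distance
#'   (log-normal, natural-scale mean and sd), um.
#' @param cells_per_100um Linear nucleus density along centrelines.
#' @param seed Integer seed for cell placement and angle noise.
#' @return Object of class `polarity_response_params`.
#' @export
polarity_response_params <- function(tau0 = 4, slope_s = 1, kappa_max = 4,
                                     polarity_len_mean = 7,
                                     polarity_len_sd = 2,
                                     cells_per_100um = 10, seed = 1) {
  p <- list(tau0 = tau0, slope_s = slope_s, kappa_max = kappa_max,
            polarity_len_mean = polarity_len_mean,
            polarity_len_sd = polarity_len_sd,
            cells_per_100um = cells_per_100um, seed = as.integer(seed))
  stop_if_not(p$tau0 >= 0, "tau0 must be >= 0")
  stop_if_not(p$slope_s > 0, "slope_s must be > 0")
  stop_if_not(p$kappa_max >= 0, "kappa_max must be >= 0")
  stop_if_not(p$polarity_len_mean > 0 && p$polarity_len_sd >= 0,
              "polarity length parameters invalid")
  stop_if_not(p$cells_per_100um > 0, "cells_per_100um must be > 0")
  class(p) <- "polarity_response_params"
  p
}

#' von Mises concentration as a function of wall shear stress
#'
#' kappa(tau) = kappa_max / (1 + exp(-(tau - tau0)/slope_s)): a logistic
#' threshold response, monotone non-decreasing in tau, reaching half its
#' ceiling at tau = tau0.
#'
#' @param tau WSS magnitude(s), Pa (>= 0).
#' @param params A `polarity_response_params`.
#' @return Concentration value(s), dimensionless.
#' @export
polarity_concentration <- function(tau, params) {
  stop_if_not(all(tau >= 0), "tau must be >= 0")
  params$kappa_max / (1 + exp(-(tau - params$tau0) / params$slope_s))
}

# Closed-form node/edge counts of the undropped lattice, for tests.
lattice_counts <- function(nc, nr) {
  list(nodes = nc * nr + 2L * nr + 4L,
       edges = 2L * (nr + 1L) + nr * (nc + 1L) + nc * (nr - 1L))
}

#' Generate a synthetic vascular plexus graph
#'
#' Builds a planar geometric graph with an artery trunk on the left, a vein
#' trunk on the right, an interior capillary lattice with positional jitter
#' and random edge dropout, and blind-ended sprouts on the distal (top)
#' margin labelled `sprouting_front`. Dropout draws that disconnect the
#' network are rejected and resampled (bounded retries). Deterministic for a
#' fixed seed.
#'
#' @param params A `plexus_params`.
#' @param max_tries Resampling budget for the dropout rejection loop.
#' @return A `vessel_graph` with `roots` naming the artery and vein root
#'   nodes and `domain` set to the domain size.
#' @export
generate_graph <- function(params, max_tries = 100) {
  stopifnot(inherits(params, "plexus_params"))
  with_seed(params$seed, generate_graph_impl(params, max_tries))
}

generate_graph_impl <- function(params, max_tries) {
  W <- params$domain_size[1]; H <- params$domain_size[2]
  s <- params$mesh_spacing
  ax <- s; vx <- W - s
  stop_if_not(vx - ax >= 2 * s, "domain too narrow for the trunk spacing")
  nc <- max(1L, as.integer(round((vx - ax) / s)) - 1L)
  nr <- max(2L, as.integer(floor(H / s)) - 1L)
  dx <- (vx - ax) / (nc + 1)
  dy <- H / (nr + 1)
  xs <- ax + seq_len(nc) * dx
  ys <- seq_len(nr) * dy

  # nodes: trunk ends (4), trunk taps (2*nr), mesh (nc*nr)
  nodes <- data.frame(id = integer(0), x = numeric(0), y = numeric(0))
  nid <- 0L
  add_node <- function(x, y) {
    nid <<- nid + 1L
    nodes[nrow(nodes) + 1L, ] <<- list(nid, x, y)
    nid
  }
  y_top <- dy / 2; y_bot <- H - dy / 2
  a_root <- add_node(ax, y_top); a_end <- add_node(ax, y_bot)
  v_root <- add_node(vx, y_top); v_end <- add_node(vx, y_bot)
  a_tap <- vapply(ys, function(y) add_node(ax, y), integer(1))
  v_tap <- vapply(ys, function(y) add_node(vx, y), integer(1))
  mesh <- matrix(0L, nr, nc)
  for (j in seq_len(nr)) for (i in seq_len(nc)) {
    jit <- stats::rnorm(2, 0, params$jitter_sd)
    mesh[j, i] <- add_node(xs[i] + jit[1], ys[j] + jit[2])
  }

  cap_radius <- function(n) pmax(1, stats::rnorm(
    n, params$capillary_radius_mean, params$capillary_radius_sd))

  edges <- list(); eid <- 0L
  add_edge <- function(na, nb, radii_ends, bed) {
    eid <<- eid + 1L
    pa <- unlist(nodes[nodes$id == na, c("x", "y")])
    pb <- unlist(nodes[nodes$id == nb, c("x", "y")])
    pl <- make_polyline(pa, pb, step = 2)
    t <- if (nrow(pl) > 1) polyline_arcpos(pl) / polyline_length(pl) else 0
    radii <- radii_ends[1] + t * (radii_ends[2] - radii_ends[1])
    edges[[eid]] <<- list(id = eid, node_a = na, node_b = nb, polyline = pl,
                          radii = radii, length = polyline_length(pl),
                          bed = bed)
    eid
  }

  # trunks: root -> taps -> end, radius tapering to 75% at the distal end
  trunk <- function(root, taps, end, r0, bed) {
    chain <- c(root, taps, end)
    yy <- nodes$y[match(chain, nodes$id)]
    tfrac <- (yy - min(yy)) / diff(range(yy))
    rr <- r0 * (1 - 0.25 * tfrac)
    for (k in seq_len(length(chain) - 1))
      add_edge(chain[k], chain[k + 1], rr[k:(k + 1)], bed)
  }
  trunk(a_root, a_tap, a_end, params$artery_radius, "artery")
  trunk(v_root, v_tap, v_end, params$vein_radius, "vein")

  # capillary lattice: horizontal rows (artery tap .. mesh .. vein tap),
  # vertical links between rows; subject to dropout with connectivity check
  cap_pairs <- list()
  for (j in seq_len(nr)) {
    row_nodes <- c(a_tap[j], mesh[j, ], v_tap[j])
    for (k in seq_len(length(row_nodes) - 1))
      cap_pairs[[length(cap_pairs) + 1L]] <- c(row_nodes[k], row_nodes[k + 1])
  }
  for (i in seq_len(nc)) for (j in seq_len(nr - 1))
    cap_pairs[[length(cap_pairs) + 1L]] <- c(mesh[j, i], mesh[j + 1, i])

  n_cap <- length(cap_pairs)
  trunk_pairs <- t(vapply(edges, function(e) c(e$node_a, e$node_b), integer(2)))
  keep <- NULL
  for (try in seq_len(max_tries)) {
    cand <- stats::runif(n_cap) >= params$edge_dropout_prob
    pairs <- rbind(trunk_pairs,
                   do.call(rbind, cap_pairs[cand]))
    gg <- igraph::graph_from_edgelist(
      cbind(as.character(pairs[, 1]), as.character(pairs[, 2])),
      directed = FALSE)
    all_ids <- as.character(nodes$id)
    present <- all_ids %in% igraph::V(gg)$name
    connected <- all(present) && igraph::is_connected(gg)
    if (connected) { keep <- cand; break }
  }
  if (is.null(keep))
    stop(sprintf(
      "edge dropout (p = %.2f) disconnected the plexus in %d resamples",
      params$edge_dropout_prob, max_tries), call. = FALSE)
  for (k in which(keep)) {
    r <- cap_radius(1)
    add_edge(cap_pairs[[k]][1], cap_pairs[[k]][2], c(r, r), "capillary")
  }

  # blind-ended sprouts on the distal (top, y ~ min) margin
  if (params$n_sprouts > 0) {
    attach <- mesh[1, ((seq_len(params$n_sprouts) - 1L) %% nc) + 1L]
    ang <- -90 + seq(-25, 25, length.out = max(params$n_sprouts, 2))[
      seq_len(params$n_sprouts)]
    for (k in seq_len(params$n_sprouts)) {
      base <- unlist(nodes[nodes$id == attach[k], c("x", "y")])
      len <- 0.4 * s
      tip <- base + len * c(cos(deg2rad(ang[k])), sin(deg2rad(ang[k])))
      tipid <- add_node(tip[1], tip[2])
      r <- cap_radius(1)
      add_edge(attach[k], tipid, c(r, max(1, 0.8 * r)), "sprouting_front")
    }
  }

  vessel_graph(nodes, edges, domain = c(W, H),
               roots = list(artery = a_root, vein = v_root))
}

#' Rasterize a vessel graph into a binary lumen mask
#'
#' Foreground is the union of stadium shapes: each polyline sub-segment
#' dilated by its linearly interpolated local radius. The image covers the
#' graph's domain (or its padded bounding box) at `pixel_size` um/pixel;
#' pixel centres sit at (index + 0.5) * pixel_size with 0-based indices.
#'
#' @param g A `vessel_graph`.
#' @param pixel_size um per pixel; every radius must be >= 1 pixel.
#' @return Integer matrix (rows = y, cols = x) of 0/1, class `vessel_mask`,
#'   with attribute `pixel_size`.
#' @export
rasterize_mask <- function(g, pixel_size = 1) {
  stop_if_not(pixel_size > 0, "pixel_size must be > 0")
  for (e in g$edges) {
    if (any(e$radii < pixel_size))
      stop(sprintf("edge %d has sub-pixel radius (%.3g um < %.3g um/px)",
                   e$id, min(e$radii), pixel_size), call. = FALSE)
  }
  dom <- g$domain
  if (is.null(dom)) {
    allp <- do.call(rbind, lapply(g$edges, `[[`, "polyline"))
    rmax <- if (length(g$edges)) max(vapply(g$edges, function(e) max(e$radii),
                                            numeric(1))) else 0
    dom <- c(max(allp[, 1]) + rmax + pixel_size,
             max(allp[, 2]) + rmax + pixel_size)
  }
  nx <- as.integer(ceiling(dom[1] / pixel_size))
  ny <- as.integer(ceiling(dom[2] / pixel_size))
  m <- matrix(0L, nrow = ny, ncol = nx)
  for (e in g$edges) {
    p <- e$polyline
    for (k in seq_len(nrow(p) - 1)) {
      a <- p[k, ]; b <- p[k + 1, ]
      r0 <- e$radii[k]; r1 <- e$radii[k + 1]
      rmax <- max(r0, r1)
      c0 <- max(1L, floor((min(a[1], b[1]) - rmax) / pixel_size) + 1L)
      c1 <- min(nx, ceiling((max(a[1], b[1]) + rmax) / pixel_size) + 1L)
      r0i <- max(1L, floor((min(a[2], b[2]) - rmax) / pixel_size) + 1L)
      r1i <- min(ny, ceiling((max(a[2], b[2]) + rmax) / pixel_size) + 1L)
      if (c1 < c0 || r1i < r0i) next
      cx <- ((c0:c1) - 0.5) * pixel_size
      cy <- ((r0i:r1i) - 0.5) * pixel_size
      px <- matrix(cx, nrow = length(cy), ncol = length(cx), byrow = TRUE)
      py <- matrix(cy, nrow = length(cy), ncol = length(cx))
      d <- b - a
      len2 <- sum(d^2)
      t <- if (len2 > 0) ((px - a[1]) * d[1] + (py - a[2]) * d[2]) / len2 else 0
      t <- pmin(pmax(t, 0), 1)
      qx <- a[1] + t * d[1]; qy <- a[2] + t * d[2]
      rad <- r0 + t * (r1 - r0)
      hit <- (px - qx)^2 + (py - qy)^2 <= rad^2
      blk <- m[r0i:r1i, c0:c1]
      blk[hit] <- 1L
      m[r0i:r1i, c0:c1] <- blk
    }
  }
  structure(m, pixel_size = pixel_size, class = c("vessel_mask", "matrix"))
}

#' Place endothelial cells on a perfused plexus
#'
#' Nuclei are spaced evenly along each segment's centreline at the stated
#' linear density. Each cell's angle to flow is 180 degrees plus von Mises
#' noise with concentration kappa(local WSS); its Golgi lies at
#' nucleus + polarity vector, whose magnitude is log-normal. Zero-flow
#' segments get kappa evaluated at tau = 0 (near-uniform orientation).
#'
#' @param g A `vessel_graph`.
#' @param flow A `flow_solution` solved on `g`.
#' @param params A `polarity_response_params` (carries the seed).
#' @return Data frame with one row per cell: `nucleus_x_um`, `nucleus_y_um`,
#'   `golgi_x_um`, `golgi_y_um`, `true_angle_deg` (angle to flow actually
#'   drawn), `true_wss_pa`, `true_kappa`, `segment_id`, `bed`.
#' @export
place_cells <- function(g, flow, params) {
  stopifnot(inherits(params, "polarity_response_params"))
  with_seed(params$seed, place_cells_impl(g, flow, params))
}

place_cells_impl <- function(g, flow, params) {
  sdlog <- sqrt(log(1 + (params$polarity_len_sd / params$polarity_len_mean)^2))
  meanlog <- log(params$polarity_len_mean) - sdlog^2 / 2
  out <- list()
  for (i in seq_along(g$edges)) {
    e <- g$edges[[i]]
    n <- as.integer(floor(e$length * params$cells_per_100um / 100 + 0.5))
    if (n == 0L) next
    srow <- flow$edges[flow$edges$id == e$id, ]
    arc <- polyline_arcpos(e$polyline)
    spos <- (seq_len(n) - 0.5) / n * e$length
    seg <- pmin(findInterval(spos, arc), nrow(e$polyline) - 1L)
    t <- (spos - arc[seg]) / pmax(arc[seg + 1] - arc[seg], 1e-12)
    nx <- (1 - t) * e$polyline[seg, 1] + t * e$polyline[seg + 1, 1]
    ny <- (1 - t) * e$polyline[seg, 2] + t * e$polyline[seg + 1, 2]
    rr <- (1 - t) * e$radii[seg] + t * e$radii[seg + 1]
    mu <- edge_viscosity(rr, flow$viscosity_pa_s, flow$model,
                         flow$hematocrit %||% 0.45)
    tau <- 4 * mu * abs(srow$flow_um3_s) / (pi * rr^3)
    tang <- e$polyline[seg + 1, , drop = FALSE] - e$polyline[seg, , drop = FALSE]
    tang <- tang / sqrt(rowSums(tang^2))
    if (srow$reversed) tang <- -tang
    flow_ang <- rad2deg(atan2(tang[, 2], tang[, 1]))
    kap <- polarity_concentration(tau, params)
    theta <- vapply(kap, function(k) rvonmises(1, 180, k), numeric(1))
    len <- stats::rlnorm(n, meanlog, sdlog)
    abs_ang <- deg2rad(flow_ang + theta)
    out[[length(out) + 1L]] <- data.frame(
      nucleus_x_um = nx, nucleus_y_um = ny,
      golgi_x_um = nx + len * cos(abs_ang),
      golgi_y_um = ny + len * sin(abs_ang),
      true_angle_deg = fold_angle(theta), true_wss_pa = tau,
      true_kappa = kap, segment_id = e$id, bed = e$bed)
  }
  if (!length(out))
    stop("no cells placed: density too low for every segment", call. = FALSE)
  do.call(rbind, out)
}

#' Generate a complete synthetic scene
#'
#' Chains [generate_graph()], [rasterize_mask()], [solve_flow()] and
#' [place_cells()], recording all ground truth and generating parameters.
#'
#' @param plexus A `plexus_params`.
#' @param response A `polarity_response_params`.
#' @param viscosity_pa_s Blood viscosity, Pa s.
#' @param inlet_pressure_pa Arterial inlet pressure above venous 0, Pa.
#' @param model Rheology model, `"constant"` or `"pries"`.
#' @return Object of class `scene`: list with `graph`, `mask`, `flow`,
#'   `cells`, `params`.
#' @export
generate_scene <- function(plexus = plexus_params(),
                           response = polarity_response_params(),
                           viscosity_pa_s = 3.5e-3,
                           inlet_pressure_pa = 2500,
                           model = c("constant", "pries")) {
  model <- match.arg(model)
  g <- generate_graph(plexus)
  mask <- rasterize_mask(g, plexus$pixel_size)
  flow <- solve_flow(g, viscosity_pa_s = viscosity_pa_s,
                     inlet_pressure_pa = inlet_pressure_pa, model = model)
  cells <- place_cells(g, flow, response)
  structure(list(graph = g, mask = mask, flow = flow, cells = cells,
                 params = list(plexus = plexus, response = response,
                               hemo = list(viscosity_pa_s = viscosity_pa_s,
                                           inlet_pressure_pa = inlet_pressure_pa,
                                           model = model))),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat("Synthetic plexus scene\n")
  print(x$graph)
  cat(sprintf("  mask: %d x %d px at %.2g um/px\n", nrow(x$mask), ncol(x$mask),
              attr(x$mask, "pixel_size")))
  cat(sprintf("  cells: %d (tau0 = %.3g Pa, kappa_max = %.3g)\n",
              nrow(x$cells), x$params$response$tau0,
              x$params$response$kappa_max))
  invisible(x)
}
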