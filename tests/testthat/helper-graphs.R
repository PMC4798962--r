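# Small hand-built graphs and geometry helpers shared across tests.

# Straight horizontal tube from (x0, y) to (x0 + length, y).
tube_graph <- function(length_um = 100, radius_um = 5, x0 = 20, y = 50,
                       n_pts = 11) {
  t <- seq(0, 1, length.out = n_pts)
  pl <- cbind(x0 + t * length_um, rep(y, n_pts))
  vessel_graph(
    nodes = data.frame(id = 1:2, x = c(x0, x0 + length_um), y = c(y, y)),
    edges = list(list(id = 1L, node_a = 1L, node_b = 2L, polyline = pl,
                      radii = rep(radius_um, n_pts), bed = "capillary")),
    domain = c(x0 * 2 + length_um, y * 2))
}

tube_boundary <- function(p_in = 100, p_out = 0) {
  boundary_conditions(node = c(1L, 2L), kind = rep("fixed_pressure", 2),
                      pressure_pa = c(p_in, p_out))
}

# Diamond: 1 -> {2, 3} -> 4 plus crossbar 2-3; per-edge constant radii.
diamond_graph <- function(radii = c(5, 4, 4, 5, 3)) {
  xy <- rbind(c(0, 50), c(50, 0), c(50, 100), c(100, 50))
  pair <- rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4), c(2, 3))
  edges <- lapply(seq_len(nrow(pair)), function(i) {
    a <- xy[pair[i, 1], ]; b <- xy[pair[i, 2], ]
    pl <- make_polyline_t(a, b, 11)
    list(id = i, node_a = pair[i, 1], node_b = pair[i, 2], polyline = pl,
         radii = rep(radii[i], nrow(pl)), bed = "capillary")
  })
  vessel_graph(nodes = data.frame(id = 1:4, x = xy[, 1], y = xy[, 2]),
               edges = edges)
}

make_polyline_t <- function(a, b, n) {
  t <- seq(0, 1, length.out = n)
  cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
}

# "Y": junction at centre with three straight branches.
y_vessel_graph <- function(branch_len = c(50, 50, 50), radius = 3) {
  ctr <- c(60, 60)
  dirs <- rbind(c(0, -1), c(-sqrt(3) / 2, 0.5), c(sqrt(3) / 2, 0.5))
  nodes <- data.frame(id = 1L, x = ctr[1], y = ctr[2])
  edges <- list()
  for (k in 1:3) {
    tip <- ctr + branch_len[k] * dirs[k, ]
    nodes <- rbind(nodes, data.frame(id = k + 1L, x = tip[1], y = tip[2]))
    pl <- make_polyline_t(ctr, tip, 9)
    edges[[k]] <- list(id = k, node_a = 1L, node_b = k + 1L, polyline = pl,
                       radii = rep(radius, nrow(pl)), bed = "capillary")
  }
  vessel_graph(nodes, edges, domain = c(160, 160))
}

# Rigid rotation of a vessel graph about `center` by `theta_deg` CCW.
rotate_vg <- function(g, theta_deg, center = c(0, 0)) {
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- function(m) sweep(sweep(m, 2, center) %*% t(R), 2, center, `+`)
  xy <- rot(cbind(g$nodes$x, g$nodes$y))
  g$nodes$x <- xy[, 1]; g$nodes$y <- xy[, 2]
  g$edges <- lapply(g$edges, function(e) {
    e$polyline <- rot(e$polyline)
    e
  })
  g$domain <- NULL
  g
}

rotate_pts <- function(m, theta_deg, center = c(0, 0)) {
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(sweep(as.matrix(m), 2, center) %*% t(R), 2, center, `+`)
}

with_seed_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# Angular difference folded to [-180, 180).
ang_diff <- function(a, b) ((a - b + 180) %% 360) - 180

# Clean axis-aligned 3x3 lattice parameters (no dropout, no jitter).
clean_lattice_params <- function(seed = 1, n_sprouts = 0, jitter_sd = 0) {
  plexus_params(domain_size = c(360, 270), edge_dropout_prob = 0,
                n_sprouts = n_sprouts, jitter_sd = jitter_sd, seed = seed)
}

# Extraction round trip with roots carried over from the generating graph.
extract_with_roots <- function(scene) {
  g <- extract_network(scene$mask, attr(scene$mask, "pixel_size"),
                       reference = scene$graph)
  truth <- scene$graph
  for (r in names(truth$roots)) {
    p <- unlist(truth$nodes[truth$nodes$id == truth$roots[[r]], c("x", "y")])
    g$roots[[r]] <- vesselpol:::nearest_node(g, p)
  }
  g
}
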