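# Poiseuille/Kirchhoff network solver: conductances, pressures, flows, WSS,
# and point sampling of the flow field.

test_that("segment conductance matches the closed form and series composition", {
  mu <- 3.5e-3
  tube <- tube_graph(length_um = 200, radius_um = 6)
  G <- segment_conductance(tube$edges[[1]], mu)
  expect_equal(G, pi * 6^4 / (8 * mu * 200), tolerance = 1e-10)

  # two equal tubes in series halve the conductance
  half <- tube_graph(length_um = 100, radius_um = 6)
  G_half <- segment_conductance(half$edges[[1]], mu)
  expect_equal(G, G_half / 2, tolerance = 1e-10)

  # stepped tube: R1 = 5 over L1 = 80, R2 = 3 over L2 = 40 (hand series sum)
  s_step <- c(seq(0, 80, length.out = 41), 80 + 1e-8,
              seq(80 + 2e-8, 120, length.out = 21))
  pl <- cbind(s_step, rep(0, length(s_step)))
  radii <- ifelse(s_step <= 80, 5, 3)
  edge <- list(id = 1L, polyline = pl, radii = radii)
  G_step <- segment_conductance(edge, mu)
  R_hand <- (8 * mu / pi) * (80 / 5^4 + 40 / 3^4)
  expect_equal(1 / G_step, R_hand, tolerance = 1e-4)

  bad <- tube_graph()$edges[[1]]
  bad$radii[3] <- -1
  expect_error(segment_conductance(bad, mu), "edge 1")
})

test_that("single perfused tube obeys Q = G dP and the Poiseuille wall formula", {
  mu <- 3.5e-3
  g <- tube_graph(length_um = 100, radius_um = 5)
  fl <- solve_flow(g, viscosity_pa_s = mu, boundary = tube_boundary(100, 0))
  G <- segment_conductance(g$edges[[1]], mu)
  expect_equal(fl$edges$flow_um3_s, 100 * G, tolerance = 1e-12)
  tau_exact <- 4 * mu * abs(fl$edges$flow_um3_s) / (pi * 5^3)
  expect_equal(fl$edges$wss_pa, tau_exact, tolerance = 1e-9)
  # unit check: mu = 1, R = 1, Q = pi/4 gives tau = 1 Pa
  expect_equal(4 * 1 * (pi / 4) / (pi * 1^3), 1)
  # cubic scaling: doubling R at fixed Q divides tau by 8
  expect_equal((4 * mu * 1 / (pi * 2^3)) / (4 * mu * 1 / (pi * 1^3)), 1 / 8)
})

test_that("diamond-network pressures match a hand-assembled 2x2 system", {
  mu <- 3.5e-3
  g <- diamond_graph(radii = c(5, 4, 4, 5, 3))
  G <- vapply(g$edges, segment_conductance, numeric(1), viscosity_pa_s = mu)
  bc <- boundary_conditions(node = c(1L, 4L), kind = rep("fixed_pressure", 2),
                            pressure_pa = c(100, 0))
  p <- solve_nodal_pressures(g, G, bc)
  # unknowns p2, p3; conservation: (G1+G3+G5) p2 - G5 p3 = G1*100, etc.
  A <- rbind(c(G[1] + G[3] + G[5], -G[5]),
             c(-G[5], G[2] + G[4] + G[5]))
  b <- c(G[1] * 100, G[2] * 100)
  p_hand <- solve(A, b)
  expect_equal(unname(p[c("2", "3")]), p_hand, tolerance = 1e-10)
})

test_that("symmetric H-network carries no crossbar flow and flow is conserved", {
  g <- diamond_graph(radii = c(5, 5, 5, 5, 3))   # symmetric arms
  fl <- solve_flow(g, boundary = boundary_conditions(
    node = c(1L, 4L), kind = rep("fixed_pressure", 2), pressure_pa = c(50, 0)))
  expect_lt(abs(fl$edges$flow_um3_s[5]), 1e-10 * max(abs(fl$edges$flow_um3_s)))
  imb <- node_flow_imbalance(g, fl)
  expect_lt(max(imb), 1e-8 * max(abs(fl$edges$flow_um3_s)))
})

test_that("reversing the boundary pressures negates flows and keeps WSS", {
  g <- diamond_graph()
  fwd <- solve_flow(g, boundary = boundary_conditions(
    node = c(1L, 4L), kind = rep("fixed_pressure", 2), pressure_pa = c(80, 0)))
  rev <- solve_flow(g, boundary = boundary_conditions(
    node = c(1L, 4L), kind = rep("fixed_pressure", 2), pressure_pa = c(0, 80)))
  expect_equal(rev$edges$flow_um3_s, -fwd$edges$flow_um3_s, tolerance = 1e-10)
  expect_equal(rev$edges$wss_pa, fwd$edges$wss_pa, tolerance = 1e-10)
  expect_equal(rev$edges$reversed, !fwd$edges$reversed)
})

test_that("flows and WSS scale linearly with the driving pressure", {
  g <- diamond_graph()
  f1 <- solve_flow(g, boundary = boundary_conditions(
    node = c(1L, 4L), kind = rep("fixed_pressure", 2), pressure_pa = c(100, 0)))
  f3 <- solve_flow(g, boundary = boundary_conditions(
    node = c(1L, 4L), kind = rep("fixed_pressure", 2), pressure_pa = c(300, 0)))
  expect_equal(f3$edges$flow_um3_s, 3 * f1$edges$flow_um3_s, tolerance = 1e-10)
  expect_equal(f3$edges$wss_pa, 3 * f1$edges$wss_pa, tolerance = 1e-10)
})

test_that("components without a fixed-pressure node are rejected", {
  g <- tube_graph()
  # add a disconnected second tube
  g2 <- vessel_graph(
    nodes = rbind(g$nodes, data.frame(id = 3:4, x = c(0, 50), y = c(200, 200))),
    edges = c(g$edges, list(list(id = 2L, node_a = 3L, node_b = 4L,
                                 polyline = make_polyline_t(c(0, 200), c(50, 200), 5),
                                 radii = rep(3, 5), bed = "capillary"))))
  G <- vapply(g2$edges, segment_conductance, numeric(1), viscosity_pa_s = 3.5e-3)
  expect_error(solve_nodal_pressures(g2, G, tube_boundary()),
               "fixed-pressure")
})

test_that("WSS sampling returns the flow-oriented tangent and honours max_dist", {
  g <- tube_graph(length_um = 100, radius_um = 5, x0 = 20, y = 50)
  fl <- solve_flow(g, boundary = tube_boundary(100, 0))
  hit <- wss_vector_at_point(fl, g, c(60, 50), max_dist = 10)
  expect_equal(hit$flow_dir, c(1, 0), tolerance = 1e-12)
  expect_equal(hit$wss_pa, fl$edges$wss_pa[1], tolerance = 1e-9)
  # against the pressure gradient the tangent flips
  fl_rev <- solve_flow(g, boundary = tube_boundary(0, 100))
  hit_rev <- wss_vector_at_point(fl_rev, g, c(60, 50), max_dist = 10)
  expect_equal(hit_rev$flow_dir, c(-1, 0), tolerance = 1e-12)
  # out of range
  expect_null(wss_vector_at_point(fl, g, c(60, 80), max_dist = 10))
})

test_that("equidistant edges tie-break deterministically to the lower edge id", {
  # two parallel horizontal tubes at y = 40 and y = 60; query at y = 50
  pl1 <- make_polyline_t(c(0, 40), c(100, 40), 11)
  pl2 <- make_polyline_t(c(0, 60), c(100, 60), 11)
  g <- vessel_graph(
    nodes = data.frame(id = 1:4, x = c(0, 100, 0, 100), y = c(40, 40, 60, 60)),
    edges = list(
      list(id = 1L, node_a = 1L, node_b = 2L, polyline = pl1,
           radii = rep(4, 11), bed = "artery"),
      list(id = 2L, node_a = 3L, node_b = 4L, polyline = pl2,
           radii = rep(4, 11), bed = "vein")))
  bc <- boundary_conditions(node = c(1L, 2L, 3L, 4L),
                            kind = rep("fixed_pressure", 4),
                            pressure_pa = c(10, 0, 10, 0))
  fl <- solve_flow(g, boundary = bc)
  h1 <- wss_vector_at_point(fl, g, c(50, 50), max_dist = 15)
  h2 <- wss_vector_at_point(fl, g, c(50, 50), max_dist = 15)
  expect_equal(h1$edge_id, 1L)
  expect_identical(h1, h2)
})

test_that("Pries viscosity rises steeply in narrow tubes and feeds the solver", {
  # Fahraeus-Lindqvist: minimum near 7 um diameter, steep rise below it
  expect_gt(pries_viscosity(1.5), pries_viscosity(3.5))
  # large tubes approach bulk blood viscosity (well above plasma)
  expect_gt(pries_viscosity(100), 2.5e-3)
  g <- tube_graph(radius_um = 4)
  f_const <- solve_flow(g, boundary = tube_boundary(), model = "constant")
  f_pries <- solve_flow(g, boundary = tube_boundary(), model = "pries")
  expect_false(isTRUE(all.equal(f_const$edges$flow_um3_s,
                                f_pries$edges$flow_um3_s)))
})
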