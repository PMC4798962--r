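# Synthetic plexus generator: lattice combinatorics, determinism, sprouts,
# rasterization, the logistic shear response and cell placement.

test_that("undropped 3x3 lattice matches closed-form node and edge counts", {
  g <- generate_graph(clean_lattice_params(seed = 2))
  # domain 360 x 270 at spacing 60: nc = 3 columns, nr = 3 rows
  cnt <- vesselpol:::lattice_counts(3, 3)
  expect_equal(nrow(g$nodes), cnt$nodes)
  expect_equal(length(g$edges), cnt$edges)
  deg <- node_degrees(g)
  expect_equal(sum(deg >= 3), 3 * 3 + 2 * 3)   # mesh nodes + trunk taps
  expect_equal(sum(deg == 1), 4)               # four trunk ends
  expect_equal(graph_components(g), 1L)
})

test_that("generation is deterministic for a fixed seed", {
  p <- plexus_params(seed = 9)
  g1 <- generate_graph(p)
  g2 <- generate_graph(p)
  expect_identical(g1, g2)
  g3 <- generate_graph(plexus_params(seed = 10))
  expect_false(identical(g1, g3))
})

test_that("sprouts appear as labelled blind-ended degree-1 nodes", {
  g <- generate_graph(clean_lattice_params(seed = 3, n_sprouts = 5))
  deg <- node_degrees(g)
  sprout_edges <- Filter(function(e) e$bed == "sprouting_front", g$edges)
  expect_length(sprout_edges, 5)
  tips <- vapply(sprout_edges, `[[`, integer(1), "node_b")
  expect_true(all(deg[as.character(tips)] == 1L))
  # beyond the 4 lattice trunk endpoints
  expect_equal(sum(deg == 1), 4 + 5)
})

test_that("dropout never disconnects the plexus; impossible dropout errors", {
  for (seed in 1:5) {
    g <- generate_graph(plexus_params(edge_dropout_prob = 0.3, seed = seed))
    expect_equal(graph_components(g), 1L)
  }
  expect_error(
    generate_graph(plexus_params(edge_dropout_prob = 0.97, seed = 1),
                   max_tries = 5),
    "disconnected")
})

test_that("parameter validation rejects out-of-range inputs", {
  expect_error(plexus_params(edge_dropout_prob = 1), "dropout")
  expect_error(plexus_params(pixel_size = 0), "pixel_size")
  expect_error(polarity_response_params(slope_s = 0), "slope_s")
  expect_error(polarity_response_params(kappa_max = -1), "kappa_max")
})

test_that("logistic shear response has the midpoint, limit and monotonicity", {
  pr <- polarity_response_params(tau0 = 4, slope_s = 1, kappa_max = 6)
  expect_equal(polarity_concentration(4, pr), 3)
  pr_far <- polarity_response_params(tau0 = 50, slope_s = 1, kappa_max = 6)
  expect_lt(polarity_concentration(0, pr_far), 1e-10)
  tau <- seq(0, 12, by = 0.25)
  expect_true(all(diff(polarity_concentration(tau, pr)) >= 0))
  expect_error(polarity_concentration(-1, pr), "tau")
})

test_that("stadium rasterization has the analytic area and empty graphs rasterize empty", {
  g <- tube_graph(length_um = 100, radius_um = 10, x0 = 30, y = 40)
  m <- rasterize_mask(g, pixel_size = 1)
  area_exact <- 2 * 10 * 100 + pi * 10^2
  expect_lt(abs(sum(m) - area_exact) / area_exact, 0.05)

  empty <- vessel_graph(nodes = data.frame(id = integer(0), x = numeric(0),
                                           y = numeric(0)),
                        edges = list(), domain = c(50, 40))
  m0 <- rasterize_mask(empty, 1)
  expect_equal(sum(m0), 0)
  expect_equal(dim(m0), c(40L, 50L))

  thin <- tube_graph(radius_um = 0.4)
  expect_error(rasterize_mask(thin, pixel_size = 1), "sub-pixel")
})

test_that("cell placement hits the stated density and respects kappa limits", {
  g <- tube_graph(length_um = 500, radius_um = 5, x0 = 20, y = 40)
  fl <- solve_flow(g, boundary = tube_boundary(100, 0))
  pr <- polarity_response_params(cells_per_100um = 1, kappa_max = 2, seed = 4)
  cells <- place_cells(g, fl, pr)
  expect_equal(nrow(cells), 5L)
  expect_true(all(cells$nucleus_y_um == 40))

  # kappa -> infinity proxy at kappa = 500 (circular sd ~ 2.6 deg): the bulk
  # of angles sits within 5 degrees of anti-parallel
  pr_hi <- polarity_response_params(tau0 = 0, slope_s = 0.01, kappa_max = 500,
                                    cells_per_100um = 20, seed = 5)
  cells_hi <- place_cells(g, fl, pr_hi)
  dev_hi <- abs(ang_diff(cells_hi$true_angle_deg, 180))
  expect_lt(stats::quantile(dev_hi, 0.9), 5)
  # and at kappa = 5000 (sd ~ 0.8 deg) every angle is within 5 degrees
  pr_vhi <- polarity_response_params(tau0 = 0, slope_s = 0.01,
                                     kappa_max = 5000,
                                     cells_per_100um = 20, seed = 5)
  dev_vhi <- abs(ang_diff(place_cells(g, fl, pr_vhi)$true_angle_deg, 180))
  expect_true(all(dev_vhi < 5))

  # kappa_max = 0: orientations indistinguishable from uniform
  pr0 <- polarity_response_params(kappa_max = 0, cells_per_100um = 200, seed = 6)
  cells0 <- place_cells(g, fl, pr0)
  expect_gte(nrow(cells0), 1000)
  expect_gt(rayleigh_test(cells0$true_angle_deg)$p_value, 0.05)
})

test_that("zero-flow segments place cells with near-uniform orientation, no error", {
  g <- tube_graph(length_um = 300, radius_um = 5)
  fl <- solve_flow(g, boundary = boundary_conditions(
    node = 1:2, kind = rep("fixed_pressure", 2), pressure_pa = c(0, 0)))
  expect_equal(fl$edges$flow_um3_s, 0)
  pr <- polarity_response_params(tau0 = 4, kappa_max = 8,
                                 cells_per_100um = 10, seed = 7)
  cells <- place_cells(g, fl, pr)
  expect_equal(unique(cells$true_wss_pa), 0)
  expect_equal(unique(cells$true_kappa),
               polarity_concentration(0, pr))
})

test_that("scenes are reproducible, lie on the mask, and respond to tau0", {
  pp <- clean_lattice_params(seed = 8)
  pr <- polarity_response_params(seed = 8)
  sc1 <- generate_scene(pp, pr)
  sc2 <- generate_scene(pp, pr)
  expect_identical(sc1$cells, sc2$cells)
  expect_identical(sc1$mask, sc2$mask)

  # every nucleus lies on mask foreground
  px <- attr(sc1$mask, "pixel_size")
  rows <- floor(sc1$cells$nucleus_y_um / px) + 1
  cols <- floor(sc1$cells$nucleus_x_um / px) + 1
  expect_true(all(sc1$mask[cbind(rows, cols)] == 1L))

  # lower threshold => larger overall anti-aligned fraction (same seeds)
  sc_lo <- generate_scene(pp, polarity_response_params(tau0 = 2, seed = 8))
  sc_hi <- generate_scene(pp, polarity_response_params(tau0 = 8, seed = 8))
  expect_gt(antialigned_fraction(sc_lo$cells$true_angle_deg),
            antialigned_fraction(sc_hi$cells$true_angle_deg))
})
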