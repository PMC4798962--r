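# Polarity records: vectors, angle convention, scalar products, bed
# assignment, dataset assembly and its invariances.

test_that("axial polarity vector is Golgi minus nucleus with Euclidean norm", {
  v <- axial_polarity_vector(c(0, 0), c(3, 4))
  expect_equal(v$vec, c(3, 4))
  expect_equal(v$magnitude, 5)
  v2 <- axial_polarity_vector(c(1, 1), c(1, 2))
  expect_equal(v2$vec, c(0, 1))
  expect_equal(v2$magnitude, 1)
  v3 <- axial_polarity_vector(c(3, 4), c(0, 0))
  expect_equal(v3$vec, -v$vec)
  expect_error(axial_polarity_vector(c(1, 1), c(1, 1)), "degenerate")
})

test_that("angle to flow uses the CCW convention on [0, 360)", {
  expect_equal(angle_to_flow(c(1, 0), c(1, 0)), 0)
  expect_equal(angle_to_flow(c(-1, 0), c(1, 0)), 180)
  expect_equal(angle_to_flow(c(0, 1), c(1, 0)), 90)
  expect_equal(angle_to_flow(c(0, -1), c(1, 0)), 270)
  expect_error(angle_to_flow(c(0, 0), c(1, 0)), "zero vector")
})

test_that("scalar product combines magnitude, WSS and angle with sign", {
  expect_equal(cell_scalar_product(2, 3, 180), -6)
  expect_equal(cell_scalar_product(2, 3, 90), 0)
  expect_equal(cell_scalar_product(2, 3, 0), 6)
})

test_that("vascular beds assign by nearest labelled edge within range", {
  g <- generate_graph(clean_lattice_params(seed = 5))
  idx <- polyline_index(g)
  artery_edge <- Filter(function(e) e$bed == "artery", g$edges)[[1]]
  mid <- artery_edge$polyline[ceiling(nrow(artery_edge$polyline) / 2), ]
  expect_equal(assign_vascular_bed(mid, g, max_dist = 10, index = idx),
               "artery")
  expect_equal(assign_vascular_bed(c(-100, -100), g, max_dist = 10,
                                   index = idx), "unassigned")
})

test_that("the dataset joins cells to flow and reports exclusions", {
  g <- tube_graph(length_um = 200, radius_um = 5, x0 = 20, y = 50)
  fl <- solve_flow(g, boundary = tube_boundary(100, 0))
  cells <- data.frame(
    nucleus_x_um = c(60, 100, 60, 60, NA),
    nucleus_y_um = c(50, 50, 200, 50, 50),
    golgi_x_um = c(55, 104, 62, 60, 61),
    golgi_y_um = c(50, 53, 205, 50, 51))
  # row 4 degenerate, row 5 malformed -> dropped with a warning
  expect_warning(rec <- build_polarity_dataset(cells, g, fl, max_dist = 15),
                 "dropped 2")
  expect_equal(nrow(rec), 3)
  expect_equal(attr(rec, "dropped_rows"), c(4L, 5L))
  # cell 1 points against flow (flow is +x)
  expect_equal(rec$angle_deg[1], 180)
  expect_lt(rec$scalar_product[1], 0)
  # cell 3 is far from the vessel: flow fields missing, kept with polarity
  expect_false(rec$flow_found[3])
  expect_true(is.na(rec$wss_pa[3]))
  expect_equal(rec$polarity_len_um[3], sqrt(2^2 + 5^2))
  # scalar-product identity holds record-wise
  ok <- rec$flow_found
  expect_equal(rec$scalar_product[ok],
               rec$polarity_len_um[ok] * rec$wss_pa[ok] *
                 cospi(rec$angle_deg[ok] / 180), tolerance = 1e-12)
  expect_error(build_polarity_dataset(cells[0, ], g, fl), "empty")
  expect_error(build_polarity_dataset(data.frame(a = 1), g, fl), "lacks")
})

test_that("row order permutations permute rows only", {
  g <- tube_graph(length_um = 200, radius_um = 5, x0 = 20, y = 50)
  fl <- solve_flow(g, boundary = tube_boundary(100, 0))
  set.seed(14)
  n <- 20
  cells <- data.frame(nucleus_x_um = runif(n, 30, 210),
                      nucleus_y_um = runif(n, 48, 52),
                      golgi_x_um = runif(n, 30, 210),
                      golgi_y_um = runif(n, 44, 56))
  rec <- build_polarity_dataset(cells, g, fl, max_dist = 15)
  perm <- sample(n)
  rec_p <- build_polarity_dataset(cells[perm, ], g, fl, max_dist = 15)
  rownames(rec) <- rownames(rec_p) <- NULL
  expect_equal(rec_p, rec[perm, ], ignore_attr = TRUE)
})

test_that("angles and scalar products are invariant under rigid rotation", {
  g <- diamond_graph()
  bc <- boundary_conditions(node = c(1L, 4L), kind = rep("fixed_pressure", 2),
                            pressure_pa = c(200, 0))
  fl <- solve_flow(g, boundary = bc)
  set.seed(15)
  n <- 30
  cells <- data.frame(nucleus_x_um = runif(n, 0, 100),
                      nucleus_y_um = runif(n, 0, 100),
                      golgi_x_um = runif(n, 0, 100),
                      golgi_y_um = runif(n, 0, 100))
  rec <- build_polarity_dataset(cells, g, fl, max_dist = 8)

  theta <- 37
  g_rot <- rotate_vg(g, theta, center = c(50, 50))
  fl_rot <- solve_flow(g_rot, boundary = bc)
  nuc <- rotate_pts(cells[, 1:2], theta, c(50, 50))
  gol <- rotate_pts(cells[, 3:4], theta, c(50, 50))
  cells_rot <- data.frame(nucleus_x_um = nuc[, 1], nucleus_y_um = nuc[, 2],
                          golgi_x_um = gol[, 1], golgi_y_um = gol[, 2])
  rec_rot <- build_polarity_dataset(cells_rot, g_rot, fl_rot, max_dist = 8)
  ok <- rec$flow_found & rec_rot$flow_found
  expect_gt(sum(ok), 5)
  expect_lt(max(abs(ang_diff(rec_rot$angle_deg[ok], rec$angle_deg[ok]))), 1e-9)
  expect_equal(rec_rot$scalar_product[ok], rec$scalar_product[ok],
               tolerance = 1e-9)
})

test_that("flow reversal shifts every angle by 180 and negates scalar products", {
  g <- tube_graph(length_um = 200, radius_um = 5, x0 = 20, y = 50)
  set.seed(16)
  n <- 15
  cells <- data.frame(nucleus_x_um = runif(n, 40, 200),
                      nucleus_y_um = rep(50, n),
                      golgi_x_um = runif(n, 40, 200),
                      golgi_y_um = runif(n, 45, 55))
  fwd <- build_polarity_dataset(cells, g,
                                solve_flow(g, boundary = tube_boundary(100, 0)),
                                max_dist = 15)
  bwd <- build_polarity_dataset(cells, g,
                                solve_flow(g, boundary = tube_boundary(0, 100)),
                                max_dist = 15)
  expect_lt(max(abs(ang_diff(bwd$angle_deg, fwd$angle_deg + 180))), 1e-9)
  expect_equal(bwd$scalar_product, -fwd$scalar_product, tolerance = 1e-9)
})

test_that("synthetic cells carry their ground-truth bed through the dataset", {
  sc <- generate_scene(clean_lattice_params(seed = 6, n_sprouts = 3),
                       polarity_response_params(seed = 6))
  rec <- build_polarity_dataset(sc$cells, sc$graph, sc$flow, max_dist = 20)
  expect_gte(mean(rec$bed == sc$cells$bed), 0.99)
})
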