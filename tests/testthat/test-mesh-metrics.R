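test_that("scaled Jacobian normalisation: regular tet 1, degenerate 0", {
  expect_equal(scaled_jacobian(regular_tet()), 1, tolerance = 1e-12)
  coplanar <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                             c(1, 1, 0)), matrix(1:4, 1))
  expect_equal(scaled_jacobian(coplanar), 0)
  repeated <- tet_mesh(rbind(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0),
                             c(0, 0, 1)), matrix(1:4, 1))
  expect_warning(sj <- scaled_jacobian(repeated), "repeated")
  expect_equal(sj, 0)
})

test_that("scaled Jacobian matches an independent determinant formula", {
  mesh <- random_tet_mesh(n_tets = 100, n_points = 60, seed = 9,
                          with_fields = FALSE)
  # brute-force oracle: sqrt(2) * det / max corner edge-length product
  oracle <- apply(mesh$tets, 1, function(t4) {
    p <- mesh$points[t4, ]
    jac <- det(rbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ]))
    prods <- sapply(1:4, function(c0) {
      others <- setdiff(1:4, c0)
      prod(sapply(others, function(o) sqrt(sum((p[o, ] - p[c0, ])^2))))
    })
    max(min(sqrt(2) * jac / max(prods), 1), -1)
  })
  expect_equal(scaled_jacobian(mesh), oracle, tolerance = 1e-12)
})

test_that("scaled Jacobian is invariant under rigid motion and scaling", {
  mesh <- random_tet_mesh(n_tets = 30, seed = 3, with_fields = FALSE)
  sj0 <- scaled_jacobian(mesh)
  R <- rotation_matrix_axis_angle(c(20, 35, 50))
  moved <- mesh
  moved$points <- sweep(2.5 * mesh$points %*% t(R), 2, c(5, -3, 7), `+`)
  expect_equal(scaled_jacobian(moved), sj0, tolerance = 1e-10)
})

test_that("divergence-theorem volume: cube, sphere, orientation errors", {
  # unit cube = 1 mm^3 = 0.001 mL
  pts <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  tri <- rbind(
    c(1, 3, 2), c(2, 3, 4),      # z = 0 (outward -z)
    c(5, 6, 7), c(6, 8, 7),      # z = 1
    c(1, 2, 5), c(2, 6, 5),      # y = 0
    c(3, 7, 4), c(4, 7, 8),      # y = 1
    c(1, 5, 3), c(3, 5, 7),      # x = 0
    c(2, 4, 6), c(4, 8, 6))      # x = 1
  expect_equal(cavity_volume_stokes(pts, tri), 0.001, tolerance = 1e-12)

  sph <- uv_sphere(radius = 10)
  v_ml <- cavity_volume_stokes(sph$points, sph$triangles)
  expect_lt(abs(v_ml - 4 / 3 * pi * 1000 / 1000) / (4 / 3 * pi), 0.01)

  flipped <- sph$triangles[, c(1, 3, 2)]
  expect_error(cavity_volume_stokes(sph$points, flipped), "orientation")
  expect_error(cavity_volume_stokes(pts, tri[-1, , drop = FALSE]),
               "not closed")
})

test_that("divergence volume equals signed tetrahedral decomposition", {
  tm <- tpl8()
  surf <- rbind(tm$meta$surfaces$LV$wall, tm$meta$surfaces$LV$cap)
  v_stokes <- cavity_volume_stokes(tm$points, surf)
  # oracle: signed tets to the origin
  p1 <- tm$points[surf[, 1], ]; p2 <- tm$points[surf[, 2], ]
  p3 <- tm$points[surf[, 3], ]
  v_tet <- sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
               p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
               p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6 / 1000
  expect_equal(v_stokes, v_tet, tolerance = 1e-8)
})

test_that("edge length statistics over the unique undirected edge set", {
  es <- edge_length_stats(regular_tet())
  expect_equal(es$mean, 1, tolerance = 1e-12)
  expect_equal(es$sd, 0)
  expect_equal(es$n_edges, 6)

  big <- regular_tet(edge = 2)
  expect_equal(edge_length_stats(big)$mean, 2, tolerance = 1e-12)

  # two tets sharing a face: 9 unique edges
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
               c(1, 1, 1))
  two <- tet_mesh(pts, rbind(1:4, c(2, 3, 4, 5)))
  expect_equal(edge_length_stats(two)$n_edges, 9)
})

test_that("lumped anatomy matches a hemispherical-shell analytic oracle", {
  shell <- build_template(resolution = 4,
                          lv = list(a = 25, b = 25, c = 25, h = 10, k = 0),
                          rv = list(a = 25, b = 25, c = 25, h = 5, k = 0))
  an <- lumped_anatomy(shell)
  lv <- an[an$ventricle == "LV", ]
  wall_analytic <- (2 / 3) * pi * (35^3 - 25^3) / 1000
  expect_lt(abs(lv$wall_volume - wall_analytic) / wall_analytic, 0.02)
  edv_analytic <- (2 / 3) * pi * 25^3 / 1000
  expect_lt(abs(lv$edv - edv_analytic) / edv_analytic, 0.02)
  # mass = wall volume x 1.05 g/mL
  expect_equal(lv$mass, lv$wall_volume * 1.05, tolerance = 1e-12)
})

test_that("cavity volume scales with the cube of a uniform scaling", {
  tm <- tpl8()
  an0 <- lumped_anatomy(tm)
  scaled <- deform_template(tm, anatomy_params(scale = 1.3))
  an1 <- lumped_anatomy(scaled)
  expect_equal(an1$edv, an0$edv * 1.3^3, tolerance = 1e-6)
})
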