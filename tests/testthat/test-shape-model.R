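test_that("rigid alignment recovers rotations and translations exactly", {
  tm <- tpl8()
  R <- rotation_matrix_axis_angle(c(10, 25, 40))
  moved <- tm
  moved$points <- sweep(tm$points %*% t(R), 2, c(12, -8, 30), `+`)
  al <- rigid_align(list(m = moved), tm)
  expect_lt(al$rmsd$rmsd[1], 1e-9)
  # the de-rotation applied by the alignment equals the applied rotation
  ang <- acos(pmin(1, (sum(diag(al$transforms$m$R %*% t(R))) - 1) / 2))
  expect_lt(ang, 1e-6)
})

test_that("alignment is rigid-only: size differences survive", {
  tm <- tpl8()
  scaled <- tm
  scaled$points <- tm$points * 1.2
  al <- rigid_align(list(m = scaled), tm)
  R <- al$transforms$m$R
  expect_equal(crossprod(R), diag(3), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(det(R), 1, tolerance = 1e-10)
  expect_gt(al$rmsd$rmsd[1], 1)   # residual reflects the size difference
})

test_that("alignment rejects topology mismatch", {
  tm <- tpl8()
  other <- random_tet_mesh(10, seed = 1, with_fields = FALSE)
  expect_error(rigid_align(list(a = other), tm), "topology")
})

test_that("PCA model: mode count, orthonormality, exact reconstruction", {
  model <- ssm19()
  n <- length(model$case_names)
  expect_equal(ncol(model$modes), n - 1)
  gram <- crossprod(model$modes)
  expect_equal(gram, diag(n - 1), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(model$explained_variance_ratio) <= 1e-12))
  expect_equal(sum(model$explained_variance_ratio), 1, tolerance = 1e-10)

  # every cohort member reconstructs from its own weights
  al <- rigid_align(cohort19()$meshes, tpl8())
  for (i in c(2, 11)) {
    rec <- reconstruct_shape(model$subject_weights[i, ], model)
    expect_lt(max(abs(rec$points - al$meshes[[i]]$points)), 1e-9)
  }
  # zero weights give the average mesh
  avg <- reconstruct_shape(numeric(n - 1), model)
  expect_equal(avg$points, model$mean_points, tolerance = 1e-12)
})

test_that("variance is conserved between cohort displacements and modes", {
  model <- ssm19()
  al <- rigid_align(cohort19()$meshes, tpl8())
  X <- t(sapply(al$meshes, function(m) as.numeric(m$points)))
  total <- sum(scale(X, scale = FALSE)^2) / (nrow(X) - 1)
  expect_equal(sum(model$mode_sds^2), total, tolerance = 1e-8)
})

test_that("noiseless two-factor cohort is recovered by the first two modes", {
  tm <- tpl8()
  co <- sample_cohort(cohort_spec(n_cases = 10, latent_sds = c(0.1, 0.05),
                                  node_noise_sd = 0, seed = 3), tm)
  # the generator applies no rotation for these factors, so the meshes
  # share a frame and the SSM can be fitted directly
  model <- fit_ssm(co$meshes)
  expect_gte(sum(model$explained_variance_ratio[1:2]), 0.999)

  # span recovery: principal angles between fitted modes and the true
  # displacement span are ~0
  X <- t(sapply(co$meshes, function(m) {
    as.numeric(m$points) - as.numeric(tm$points)
  }))
  true_basis <- svd(X)$v[, 1:2]
  sv <- svd(crossprod(true_basis, model$modes[, 1:2]))$d
  expect_lt(max(abs(sv - 1)), 1e-6)
})

test_that("projection is the orthogonal projector onto the mode span", {
  model <- ssm19()
  out_of_span <- tpl8()
  set.seed(4)
  out_of_span$points <- model$mean_points +
    matrix(rnorm(length(model$mean_points), 0, 0.5),
           ncol = 3)
  w <- project_shape(out_of_span, model)
  rec <- reconstruct_shape(w, model)
  resid <- as.numeric(out_of_span$points) - as.numeric(rec$points)
  expect_lt(max(abs(crossprod(model$modes, resid))), 1e-8)
  expect_error(reconstruct_shape(w[-1], model), "does not match")
})

test_that("modes_for_threshold uses cumulative explained variance", {
  fake <- structure(list(explained_variance_ratio = c(0.5, 0.3, 0.2)),
                    class = "shape_model")
  expect_equal(modes_for_threshold(fake, 0.9), 3)
  expect_equal(modes_for_threshold(fake, 0.8), 2)
  expect_equal(modes_for_threshold(fake, 1.0), 3)
  model <- ssm19()
  expect_equal(modes_for_threshold(model, 1.0),
               length(model$explained_variance_ratio))
  # at least the five injected latent factors are needed for 90% variance
  expect_gte(modes_for_threshold(model, 0.9), 5)
})

test_that("extreme cohort: counts, naming, exact single-mode projections", {
  model <- ssm19()
  ex <- make_extreme_cohort(model, modes = 1:9, multipliers = c(-3, 3))
  expect_length(ex$meshes, 18)
  expect_equal(nrow(ex$manifest), 18)

  w <- project_shape(ex$meshes[["mode04_+3sd"]], model)
  expected <- numeric(ncol(model$modes))
  expected[4] <- 3 * model$mode_sds[4]
  expect_lt(max(abs(w - expected)), 1e-9)

  avg <- make_extreme_cohort(model, modes = 1, multipliers = 0)
  expect_equal(avg$meshes[[1]]$points, model$mean_points,
               tolerance = 1e-12)
})

test_that("scaled cohort yields a size-dominant first mode", {
  tm <- tpl8()
  set.seed(8)
  scales <- 1 + rnorm(8, 0, 0.1)
  meshes <- lapply(scales, function(s) {
    deform_template(tm, anatomy_params(scale = s))
  })
  names(meshes) <- paste0("s", seq_along(meshes))
  model <- fit_ssm(rigid_align(meshes, tm)$meshes)
  vols <- sapply(meshes, function(m) sum(tet_volumes(m)))
  expect_gt(abs(cor(vols, model$subject_weights[, 1])), 0.99)
})

test_that("tidy and glance summarise the model", {
  model <- ssm19()
  td <- tidy(model)
  expect_equal(nrow(td), ncol(model$modes))
  expect_equal(td$cumulative_variance[nrow(td)], 1, tolerance = 1e-10)
  gl <- glance(model)
  expect_equal(gl$n_subjects, 19)
})
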