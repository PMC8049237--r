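# Shared fixtures, memoised per test session ------------------------------------

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# coarse template used by most tests (faster than the default resolution)
tpl8 <- function() fixture("tpl8", function() build_template(resolution = 8))

tpl_default <- function() fixture("tpl6", function() build_template())

# study-sized cohort: 19 cases, 5 latent factors, node noise
cohort19 <- function() {
  fixture("cohort19", function() {
    sample_cohort(cohort_spec(n_cases = 19, seed = 11), tpl8())
  })
}

ssm19 <- function() {
  fixture("ssm19", function() {
    al <- rigid_align(cohort19()$meshes, tpl8())
    fit_ssm(al$meshes)
  })
}

# template beat at default surrogate parameters
template_beat <- function() {
  fixture("template_beat", function() {
    tm <- tpl_default()
    an <- lumped_anatomy(tm)
    act <- simulate_activation(tm)
    list(mesh = tm, anatomy = an, act = act,
         beat = simulate_beat(an, activation_triggers(act, tm)))
  })
}

regular_tet <- function(edge = 1) {
  pts <- rbind(c(0, 0, 0), c(edge, 0, 0), c(edge / 2, edge * sqrt(3) / 2, 0),
               c(edge / 2, edge * sqrt(3) / 6, edge * sqrt(2 / 3)))
  tet_mesh(pts, matrix(1:4, 1))
}

random_tet_mesh <- function(n_tets = 50, n_points = 40, seed = 1,
                            with_fields = TRUE) {
  set.seed(seed)
  pts <- matrix(runif(3 * n_points, 0, 50), ncol = 3)
  tets <- t(replicate(n_tets, sample.int(n_points, 4)))
  unit_rows <- function(m) m / sqrt(rowSums(m^2))
  uvc <- cbind(runif(n_points), runif(n_points, -pi, pi),
               runif(n_points), sample(c(-1, 1), n_points, TRUE))
  uvc[1:5, ] <- -10  # sentinel block outside the ventricular myocardium
  tet_mesh(pts, tets,
           cell_labels = if (with_fields) sample(1:2, n_tets, TRUE),
           fibre_dir = if (with_fields)
             unit_rows(matrix(rnorm(3 * n_tets), ncol = 3)),
           sheet_dir = if (with_fields)
             unit_rows(matrix(rnorm(3 * n_tets), ncol = 3)),
           uvc = if (with_fields) uvc,
           name = "random_fixture")
}

# lat-long triangulated sphere (outward-oriented), for volume oracles
uv_sphere <- function(radius = 10, n_theta = 40, n_phi = 80) {
  theta <- seq(0, pi, length.out = n_theta + 1)[2:n_theta]
  phi <- 2 * pi * (0:(n_phi - 1)) / n_phi
  ring <- function(th) cbind(radius * sin(th) * cos(phi),
                             radius * sin(th) * sin(phi),
                             radius * cos(th))
  pts <- rbind(c(0, 0, radius), do.call(rbind, lapply(theta, ring)),
               c(0, 0, -radius))
  id <- function(i, j) 1 + (i - 1) * n_phi + (j %% n_phi) + 1
  north <- do.call(rbind, lapply(0:(n_phi - 1), function(j)
    c(1, id(1, j), id(1, j + 1))))
  south_start <- nrow(pts)
  south <- do.call(rbind, lapply(0:(n_phi - 1), function(j)
    c(south_start, id(n_theta - 1, j + 1), id(n_theta - 1, j))))
  bands <- do.call(rbind, lapply(1:(n_theta - 2), function(i) {
    do.call(rbind, lapply(0:(n_phi - 1), function(j) {
      rbind(c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
            c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
    }))
  }))
  list(points = pts, triangles = rbind(north, bands, south))
}

# independent single-source shortest path (Bellman-Ford) over weighted edges
bellman_ford <- function(n_nodes, edges, weights, sources) {
  dist <- rep(Inf, n_nodes)
  dist[sources] <- 0
  for (iter in seq_len(n_nodes)) {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]; w <- weights[k]
      if (dist[a] + w < dist[b]) { dist[b] <- dist[a] + w; changed <- TRUE }
      if (dist[b] + w < dist[a]) { dist[a] <- dist[b] + w; changed <- TRUE }
    }
    if (!changed) break
  }
  dist
}

# collinear "chain" mesh: consecutive tets over points spaced `spacing` mm
# along x, so shortest-path distance equals euclidean distance
chain_mesh <- function(n_nodes = 12, spacing = 1) {
  pts <- cbind((0:(n_nodes - 1)) * spacing, 0, 0)
  tets <- t(sapply(1:(n_nodes - 3), function(i) i:(i + 3)))
  tet_mesh(pts, tets, name = "chain")
}
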