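ns <- asNamespace("boldpatch")

make_unit_run <- function(mesh, t_len = 6, seed = 1) {
  set.seed(seed)
  v2 <- 2L * n_vertices(mesh)
  structure(list(subject = "sub-001",
                 data = matrix(stats::runif(v2 * t_len, -1, 1), v2, t_len),
                 tr = 3, state = "unit"),
            class = "bold_run")
}

test_that("make_compromised zeroes exactly the masked rows", {
  m <- mesh_level1()
  run <- make_unit_run(m)
  empty <- vertex_mask(m, integer(0))
  expect_identical(make_compromised(run, empty, m)$data, run$data)
  full <- vertex_mask(m, seq_len(n_vertices(m)))
  full_rh <- full; full_rh$hemisphere <- "rh"
  both <- make_compromised(make_compromised(run, full, m), full_rh, m)
  expect_true(all(both$data == 0))
  single <- vertex_mask(m, 7L)
  out <- make_compromised(run, single, m)
  expect_true(all(out$data[7, ] == 0))
  expect_identical(out$data[-7, ], run$data[-7, ])
})

test_that("latent search keeps the best-observed z and preserves intact vertices", {
  model <- tiny_trained_model()
  m <- build_icosphere(0)           # 12 vertices/hemisphere on the 16x16 raster
  map <- flatten_pair(m, 16, 16)
  mask <- vertex_mask(m, c(1L, 5L))
  frame <- stats::runif(map$n_vertices, -1, 1)
  search <- latent_search_spec(iterations = 40, lr = 0.05, optimizer = "adam",
                               seed = 2)
  res <- reconstruct_frame_gan(model, frame, mask, map, m, search)

  rows <- mask_run_rows(mask, m)
  expect_identical(res$frame[-rows], frame[-rows])  # bit-exact intact region

  # final loss <= loss of the seeded initialization
  img <- frame_to_image(frame, map)
  intact_pix <- rep(TRUE, 256)
  intact_pix[vertex_pixel_index(map)[rows]] <- FALSE
  set.seed(ns$frame_seed(as.numeric(img), search$seed, 1L))
  z0 <- stats::runif(8, -1, 1)
  loss0 <- sum(((gan_sample(model, z0) - as.numeric(img)) * intact_pix)^2)
  expect_lte(res$loss, loss0 + 1e-12)
  expect_true(is.finite(res$loss) && res$loss >= 0)

  expect_error(reconstruct_frame_gan(model, frame * 4, mask, map, m, search),
               "normalized")
})

test_that("run reconstruction is frame-wise independent and order-invariant", {
  model <- tiny_trained_model()
  m <- build_icosphere(0)
  map <- flatten_pair(m, 16, 16)
  mask <- geodesic_mask(m, 2, 0.2)
  run <- make_unit_run(m, t_len = 5, seed = 3)
  search <- latent_search_spec(iterations = 10, lr = 0.05, optimizer = "adam",
                               seed = 4, chunk = 2)
  rec <- reconstruct_run_gan(model, run, mask, map, m, search)
  expect_identical(ncol(rec$run$data), 5L)
  rows <- mask_run_rows(mask, m)
  expect_identical(rec$run$data[-rows, ], run$data[-rows, ])

  perm <- c(4L, 2L, 5L, 1L, 3L)
  shuffled <- run
  shuffled$data <- run$data[, perm]
  rec_shuf <- reconstruct_run_gan(model, shuffled, mask, map, m, search)
  # equal up to BLAS accumulation order, which depends on batch composition
  expect_equal(rec_shuf$run$data[, order(perm)], rec$run$data, tolerance = 1e-12)
  expect_equal(rec_shuf$loss[order(perm)], rec$loss, tolerance = 1e-12)
})

test_that("diffusion filling matches its local-mean contract", {
  m <- mesh_level1()
  run <- make_unit_run(m, t_len = 3, seed = 5)
  # single masked vertex takes the mean of its neighbors
  single <- vertex_mask(m, 9L)
  rec <- reconstruct_diffusion(run, single, m)
  expect_equal(rec$run$data[9, ],
               colMeans(run$data[m$adjacency[[9]], ]), tolerance = 1e-14)
  expect_identical(rec$run$data[-9, ], run$data[-9, ])
  # constant field fills with the constant
  const <- run
  const$data[] <- 0.25
  big <- geodesic_mask(m, 1, 0.5)
  filled <- reconstruct_diffusion(const, big, m)
  expect_equal(unique(as.vector(filled$run$data)), 0.25, tolerance = 1e-12)
  expect_error(reconstruct_diffusion(run, vertex_mask(m, seq_len(n_vertices(m))), m),
               "intact")
})

# independent oracle: igraph distances define the layers; plain loops fill
diffusion_oracle <- function(x, masked, adjacency) {
  gr <- igraph::graph_from_edgelist(
    do.call(rbind, lapply(seq_along(adjacency), function(v) {
      nb <- adjacency[[v]][adjacency[[v]] > v]
      cbind(rep(v, length(nb)), nb)
    })), directed = FALSE)
  d_all <- igraph::distances(gr, v = which(!seq_along(adjacency) %in% masked))
  layer <- apply(d_all, 2, min)
  vals <- x
  for (l in sort(unique(layer[layer > 0]))) {
    prev <- vals
    for (v in which(layer == l)) {
      nb <- adjacency[[v]]
      nb <- nb[layer[nb] < l]
      vals[v, ] <- colMeans(prev[nb, , drop = FALSE])
    }
  }
  vals
}

test_that("diffusion filling equals the independent BFS-layer oracle", {
  skip_if_not_installed("igraph")
  m <- mesh_level1()
  v <- n_vertices(m)
  for (s in 1:10) {
    set.seed(s)
    masked <- sample.int(v, round(0.3 * v))
    run <- make_unit_run(m, t_len = 4, seed = 100 + s)
    mask <- vertex_mask(m, masked)
    got <- reconstruct_diffusion(run, mask, m)$run$data[seq_len(v), ]
    want <- diffusion_oracle(run$data[seq_len(v), ], masked, m$adjacency)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("diffusion filling is equivariant under vertex relabeling", {
  m <- mesh_level1()
  v <- n_vertices(m)
  set.seed(17)
  perm <- sample.int(v)            # new label of each old vertex
  m_perm <- m
  m_perm$vertices <- m$vertices[order(perm), ]
  m_perm$adjacency <- lapply(order(perm), function(old) sort(perm[m$adjacency[[old]]]))
  run <- make_unit_run(m, t_len = 3, seed = 18)
  run_perm <- run
  run_perm$data <- rbind(run$data[seq_len(v), ][order(perm), ],
                         run$data[v + seq_len(v), ][order(perm), ])
  masked <- which(geodesic_mask(m, 4, 0.3)$mask)
  rec <- reconstruct_diffusion(run, vertex_mask(m, masked), m)
  rec_perm <- reconstruct_diffusion(run_perm, vertex_mask(m_perm, sort(perm[masked])), m_perm)
  expect_equal(rec_perm$run$data[seq_len(v), ][perm, ],
               rec$run$data[seq_len(v), ], tolerance = 1e-12)
})

test_that("diffusion recovers smooth fields better than high-frequency ones", {
  m <- mesh_level2()
  v <- n_vertices(m)
  mask <- geodesic_mask(m, 30, 0.15)
  smooth_field <- m$vertices[, 1]              # a first-order spherical harmonic
  set.seed(19)
  rough_field <- stats::runif(v, -1, 1)
  err <- function(field) {
    run <- structure(list(subject = "s", data = matrix(rep(field, 2), ncol = 1),
                          tr = 3, state = "unit"), class = "bold_run")
    comp <- make_compromised(run, mask, m)
    rec <- reconstruct_diffusion(comp, mask, m)
    mean(abs(rec$run$data[which(mask$mask), 1] - field[which(mask$mask)]))
  }
  expect_lt(err(smooth_field), err(rough_field))
})

test_that("amplitude-contrast detection recovers known compromised regions", {
  m <- mesh_level1()
  run <- make_unit_run(m, t_len = 200, seed = 20)
  # identical runs: nothing flagged
  none <- detect_dbs_mask(run, run, m)
  expect_identical(sum(none$mask), 0L)
  # exactly zeroed region: recovered exactly
  region <- geodesic_mask(m, 6, 0.25)
  zeroed <- make_compromised(run, region, m)
  got <- detect_dbs_mask(run, zeroed, m)
  expect_identical(got$mask, region$mask)
  # simulated implantation pair at attenuation 0.3: near-exact recovery
  sp <- cohort_spec(n_subjects = 1, n_frames = 1500, seed = 21)
  pair <- make_dbs_pair(sp, m, region, 0.3)
  det <- detect_dbs_mask(pair$pre, pair$post, m, ratio_threshold = 0.8)
  jaccard <- sum(det$mask & region$mask) / sum(det$mask | region$mask)
  expect_gte(jaccard, 0.9)
})
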