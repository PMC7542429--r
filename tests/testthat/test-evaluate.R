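unit_run <- function(data) {
  structure(list(subject = "s", data = data, tr = 3, state = "unit"),
            class = "bold_run")
}

test_that("time-series accuracy matches the textbook correlation formula", {
  m <- mesh_level1()
  v2 <- 2L * n_vertices(m)
  set.seed(1)
  a <- unit_run(matrix(stats::rnorm(v2 * 50), v2))
  mask <- geodesic_mask(m, 3, 0.12)
  rows <- mask_run_rows(mask, m)

  expect_equal(timeseries_accuracy(a, a, mask, m)$r, rep(1, length(rows)),
               tolerance = 1e-12)
  neg <- a; neg$data <- -a$data
  expect_equal(timeseries_accuracy(a, neg, mask, m)$mean, -1, tolerance = 1e-12)

  b <- unit_run(matrix(stats::rnorm(v2 * 50), v2))
  got <- timeseries_accuracy(a, b, mask, m)$r
  for (j in seq_along(rows))
    expect_equal(got[j], oracle_pearson(a$data[rows[j], ], b$data[rows[j], ]),
                 tolerance = 1e-12)

  flat <- b; flat$data[rows[1], ] <- 2
  res <- timeseries_accuracy(a, flat, mask, m)
  expect_identical(res$n_flagged, 1L)
  expect_identical(res$r[1], 0)
  short <- unit_run(a$data[, 1:10])
  expect_error(timeseries_accuracy(a, short, mask, m), "shape")
})

test_that("FC maps are Fisher-z transformed brute-force correlation maps", {
  m <- mesh_level1()
  v2 <- 2L * n_vertices(m)
  set.seed(2)
  run <- unit_run(matrix(stats::rnorm(v2 * 40), v2))
  fm <- fc_map(run, 10)
  # brute-force oracle
  for (v in sample(v2, 15)) {
    r <- oracle_pearson(run$data[10, ], run$data[v, ])
    expect_equal(fm$z[v], atanh(min(max(r, -1 + 1e-7), 1 - 1e-7)),
                 tolerance = 1e-10)
  }
  # r = 0.5 -> z = atanh(0.5)
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  # self-entry is finite (clipped), not infinite
  expect_true(is.finite(fm$z[10]))
  # symmetric generation: FC(a)[b] == FC(b)[a]
  fb <- fc_map(run, 25)
  expect_equal(fm$z[25], fc_map(run, 10)$z[25], tolerance = 1e-12)
  expect_equal(fm$z[25], fb$z[10], tolerance = 1e-10)
  # affine invariance of the underlying correlation
  scaled <- unit_run(0.2 * run$data + 3)
  expect_equal(fc_map(scaled, 10)$z, fm$z, tolerance = 1e-9)
  # degenerate seed
  degen <- run; degen$data[4, ] <- 1
  expect_error(fc_map(degen, 4), "degenerate")
})

test_that("FC-map similarity behaves like a correlation over non-seed vertices", {
  m <- mesh_level1()
  v2 <- 2L * n_vertices(m)
  set.seed(3)
  run_a <- unit_run(matrix(stats::rnorm(v2 * 40), v2))
  run_b <- unit_run(matrix(stats::rnorm(v2 * 40), v2))
  map_a <- fc_map(run_a, 5)
  map_b <- fc_map(run_b, 5)
  expect_equal(fc_accuracy(map_a, map_a), 1, tolerance = 1e-12)
  # oracle on the excluded-seed vectors
  keep <- setdiff(seq_len(v2), 5)
  expect_equal(fc_accuracy(map_a, map_b),
               oracle_pearson(map_a$z[keep], map_b$z[keep]), tolerance = 1e-12)
  # derangements of one map decorrelate it: distribution centered on 0
  set.seed(4)
  perms <- replicate(100, {
    mp <- map_b
    mp$z[keep] <- mp$z[sample(keep)]
    fc_accuracy(map_a, mp)
  })
  expect_lt(abs(mean(perms)), 0.05)
  expect_lt(max(abs(perms)), 0.5)
  expect_error(fc_accuracy(map_a, fc_map(run_b, 6)), "seeds")
})

test_that("MSI identifies the fingerprint-matched training subject", {
  m <- mesh_level1()
  sp <- cohort_spec(n_subjects = 8, n_frames = 500, seed = 6)
  co <- make_cohort(sp, m, runs_per_subject = 2, return_truth = FALSE)
  seeds <- mask_run_rows(geodesic_mask(m, 11, 0.25), m)
  training <- lapply(co$runs, `[[`, 1)

  # a training set containing the test subject's own data picks itself
  self <- msi(training[[3]], training, seeds)
  expect_identical(self$msi, 3L)
  expect_gt(self$similarity, 0.99)
  # single candidate
  expect_identical(msi(training[[2]], training[1], seeds)$msi, 1L)
  expect_error(msi(training[[1]], training, integer(0)), "empty")

  # independent second runs: MSI finds the same individual, which is also
  # the subject at the smallest fingerprint (loading-matrix) distance
  hits <- 0L
  for (s in seq_len(8)) {
    got <- msi(co$runs[[s]][[2]], training, seeds)$msi
    fp_dist <- vapply(co$loadings, function(w)
      sum((w - co$loadings[[s]])^2), numeric(1))
    expect_identical(which.min(fp_dist), s)  # own fingerprint is closest
    if (got == s) hits <- hits + 1L
  }
  expect_gte(hits, 7L)
})

test_that("specificity analysis ranks own connectivity first for perfect reconstructions", {
  m <- mesh_level1()
  sp <- cohort_spec(n_subjects = 6, n_frames = 300, seed = 7)
  co <- make_cohort(sp, m, return_truth = FALSE)
  runs <- lapply(co$runs, `[[`, 1)
  seeds <- mask_run_rows(geodesic_mask(m, 2, 0.2), m)
  # reconstruction == original, test subjects absent from training
  rep_ <- specificity_analysis(runs[5:6], runs[5:6], runs[1:4], seeds)
  expect_equal(unname(rep_$mean["own"]), 1, tolerance = 1e-10)
  expect_true(all(rep_$per_subject[, "own"] >= rep_$per_subject[, "group"] - 1e-10))
  expect_true(all(rep_$per_subject[, "own"] >= rep_$per_subject[, "msi"] - 1e-10))
  # degenerate consistency: a 1-subject training cohort is its own group average
  one <- specificity_analysis(runs[5], runs[5], runs[1], seeds)
  expect_equal(unname(one$per_subject[1, "group"]),
               unname(one$per_subject[1, "msi"]), tolerance = 1e-12)
})

test_that("amplitude recovery is a percentage of the reference amplitude", {
  m <- mesh_level1()
  set.seed(8)
  v2 <- 2L * n_vertices(m)
  pre <- unit_run(matrix(stats::rnorm(v2 * 100), v2))
  mask <- geodesic_mask(m, 9, 0.2)
  expect_equal(amplitude_recovery(pre, pre, mask, m), 100, tolerance = 1e-12)
  half <- pre; half$data <- 0.5 * pre$data
  expect_equal(amplitude_recovery(pre, half, mask, m), 50, tolerance = 1e-12)
  zero <- pre; zero$data[] <- 0
  expect_error(amplitude_recovery(zero, pre, mask, m), "degenerate")

  # implantation pair at attenuation 0.3: matches the generator's closed form
  sp <- cohort_spec(n_subjects = 1, n_frames = 2000, seed = 9)
  pair <- make_dbs_pair(sp, m, mask, 0.3)
  v_eta <- 1 / (1 - sp$ar_phi^2)
  rows <- pair$region_rows
  struct_var <- rowSums(pair$loadings[rows, , drop = FALSE]^2) * v_eta
  expected <- 100 * mean(sqrt(0.3^2 * struct_var + (1 - 0.3^2) * sp$noise_sd^2)) /
    mean(sqrt(struct_var + sp$noise_sd^2))
  got <- amplitude_recovery(pair$pre, pair$post, mask, m)
  expect_equal(got, expected, tolerance = 0.05 * expected)
})

test_that("the mask-size sweep returns one point per fraction and flags degenerate fields", {
  m <- mesh_level1()
  run <- unit_run(matrix(stats::runif(2 * n_vertices(m) * 30, -1, 1),
                         2 * n_vertices(m)))
  sw <- mask_size_sweep(NULL, run, m, NULL, centers = c(1, 20),
                        method = "diffusion")
  expect_identical(nrow(sw), 6L)
  expect_identical(sw$fraction, seq(0.1, 0.6, by = 0.1))
  expect_true(all(is.finite(sw$mean_fc_r)))
  # constant field: FC undefined, flagged as NA with a warning
  const <- unit_run(matrix(0.4, 2 * n_vertices(m), 30))
  expect_warning(
    swc <- mask_size_sweep(NULL, const, m, NULL, centers = 1,
                           fractions = 0.2, method = "diffusion"),
    "degenerate")
  expect_true(is.na(swc$mean_fc_r))
  expect_error(mask_size_sweep(NULL, run, m, NULL, centers = 1, fractions = c(0, 0.5)),
               "fractions")
})
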