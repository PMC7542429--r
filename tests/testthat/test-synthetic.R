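test_that("cohorts are bit-reproducible from the master seed and extensible", {
  m <- mesh_level1()
  sp <- cohort_spec(n_subjects = 3, n_frames = 30, seed = 42)
  a <- make_cohort(sp, m)
  b <- make_cohort(sp, m)
  expect_identical(a$runs[[2]][[1]]$data, b$runs[[2]][[1]]$data)
  expect_identical(a$loadings, b$loadings)
  # adding subjects does not reshuffle existing ones (counter-derived seeds)
  bigger <- make_cohort(cohort_spec(n_subjects = 5, n_frames = 30, seed = 42), m)
  expect_identical(bigger$runs[[3]][[1]]$data, a$runs[[3]][[1]]$data)
})

test_that("parcels partition each hemisphere into edge-connected pieces", {
  m <- mesh_level2()
  co <- make_cohort(cohort_spec(n_subjects = 1, n_frames = 10, seed = 3), m,
                    return_truth = FALSE)
  v <- n_vertices(m)
  for (hemi_rows in list(seq_len(v), v + seq_len(v))) {
    assign <- co$parcel[hemi_rows]
    expect_true(all(assign %in% seq_len(co$spec$n_parcels)))
    for (p in unique(assign)) {
      members <- which(assign == p)
      seen <- members[1]; frontier <- members[1]
      while (length(frontier)) {
        nb <- setdiff(intersect(unique(unlist(m$adjacency[frontier])), members), seen)
        seen <- c(seen, nb); frontier <- nb
      }
      expect_setequal(seen, members)
    }
  }
})

test_that("a noiseless single-network cohort has perfectly correlated vertices", {
  m <- mesh_level1()
  sp <- cohort_spec(n_subjects = 1, n_frames = 50, n_parcels = 1, n_networks = 1,
                    loading = 1, indiv_sd = 0, noise_sd = 0, seed = 5)
  run <- make_cohort(sp, m, return_truth = FALSE)$runs[[1]][[1]]
  cc <- stats::cor(t(run$data))
  expect_true(all(abs(cc - 1) < 1e-12))
})

test_that("within-network correlation matches the closed-form model value", {
  # independent oracle: under x = l*eta + e with var(eta) = 1/(1-phi^2),
  # corr(x_i, x_j) = l^2 v / (l^2 v + sigma^2) for same-network vertices
  m <- mesh_level1()
  l <- 0.8; phi <- 0.4; sigma <- 1
  v_eta <- 1 / (1 - phi^2)
  r_theory <- l^2 * v_eta / (l^2 * v_eta + sigma^2)
  sp <- cohort_spec(n_subjects = 4, n_frames = 1000, loading = l,
                    indiv_sd = 0, ar_phi = phi, noise_sd = sigma, seed = 8)
  co <- make_cohort(sp, m, return_truth = FALSE)
  net_of_vertex <- co$network[co$parcel]
  rs <- c()
  for (s in 1:4) {
    cc <- stats::cor(t(co$runs[[s]][[1]]$data))
    same <- outer(net_of_vertex, net_of_vertex, `==`) & upper.tri(cc)
    rs <- c(rs, mean(cc[same]))
  }
  expect_equal(mean(rs), r_theory, tolerance = 0.03)
})

test_that("empirical FC converges to the ground-truth FC as T grows", {
  m <- mesh_level1()
  mad_at <- function(t_len) {
    sp <- cohort_spec(n_subjects = 1, n_frames = t_len, seed = 21)
    co <- make_cohort(sp, m)
    emp <- stats::cor(t(co$runs[[1]][[1]]$data))
    mean(abs(emp - co$fc_truth[[1]]))
  }
  expect_lt(mad_at(4000), mad_at(250))
})

test_that("ground-truth FC is a symmetric unit-diagonal correlation matrix", {
  m <- mesh_level1()
  co <- make_cohort(cohort_spec(n_subjects = 2, n_frames = 10, seed = 2), m)
  fc <- co$fc_truth[[1]]
  expect_equal(fc, t(fc), tolerance = 1e-12)
  expect_equal(diag(fc), rep(1, nrow(fc)), tolerance = 1e-12)
  expect_true(all(abs(fc) <= 1 + 1e-12))
})

test_that("within-subject FC similarity exceeds between-subject similarity", {
  m <- mesh_level1()
  sp <- cohort_spec(n_subjects = 6, n_frames = 400, seed = 13)
  co <- make_cohort(sp, m, runs_per_subject = 2, return_truth = FALSE)
  fc_vec <- function(run) {
    cc <- stats::cor(t(run$data))
    cc[upper.tri(cc)]
  }
  v1 <- lapply(co$runs, function(rs) fc_vec(rs[[1]]))
  v2 <- lapply(co$runs, function(rs) fc_vec(rs[[2]]))
  within <- vapply(1:6, function(s) stats::cor(v1[[s]], v2[[s]]), numeric(1))
  between <- c()
  for (s in 1:6) for (t in setdiff(1:6, s))
    between <- c(between, stats::cor(v1[[s]], v2[[t]]))
  expect_gt(mean(within), mean(between))
  expect_gt(min(within), max(between) - 0.2)  # separation is systematic, not a fluke
})

test_that("the pre/post implantation pair degrades the region as specified", {
  m <- mesh_level1()
  sp <- cohort_spec(n_subjects = 1, n_frames = 2000, seed = 31)
  region <- geodesic_mask(m, 10, 0.2)
  expect_error(make_dbs_pair(sp, m, region, 1), "< 1")
  empty <- vertex_mask(m, integer(0))
  expect_error(make_dbs_pair(sp, m, empty, 0.5), "empty")

  # factor 0: the region carries pure measurement noise
  pair0 <- make_dbs_pair(sp, m, region, 0)
  region_sd <- apply(pair0$post$data[pair0$region_rows, ], 1, stats::sd)
  expect_equal(mean(region_sd), sp$noise_sd, tolerance = 0.05)

  # factor f: amplitude ratio matches the generator's closed form
  f <- 0.3
  pair <- make_dbs_pair(sp, m, region, f)
  rows <- pair$region_rows
  v_eta <- 1 / (1 - sp$ar_phi^2)
  struct_var <- rowSums(pair$loadings[rows, , drop = FALSE]^2) * v_eta
  sd_pre_th <- sqrt(struct_var + sp$noise_sd^2)
  sd_post_th <- sqrt(f^2 * struct_var + (1 - f^2) * sp$noise_sd^2)
  ratio_th <- mean(sd_post_th) / mean(sd_pre_th)
  amp <- function(x) rowMeans(abs(x))
  ratio_obs <- mean(amp(pair$post$data[rows, ])) / mean(amp(pair$pre$data[rows, ]))
  expect_equal(ratio_obs, ratio_th, tolerance = 0.05)

  # outside the region the two runs share their FC structure
  outside <- setdiff(seq_len(nrow(pair$pre$data)), rows)[1:30]
  fc_pre <- stats::cor(t(pair$pre$data[outside, ]))
  fc_post <- stats::cor(t(pair$post$data[outside, ]))
  expect_gt(stats::cor(fc_pre[upper.tri(fc_pre)], fc_post[upper.tri(fc_post)]), 0.9)
})
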