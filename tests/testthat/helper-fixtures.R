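# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, fixture_env)) assign(name, build(), fixture_env)
  get(name, fixture_env)
}

mesh_level1 <- function() fixture("mesh1", function() build_icosphere(1))
mesh_level2 <- function() fixture("mesh2", function() build_icosphere(2))

# tiny GAN spec used by several smoke tests (16x16 raster, narrow channels)
tiny_gan_spec <- function(seed = 7L, max_epochs = 1L, ...) {
  gan_spec(latent_dim = 8L, height = 16L, width = 16L,
           g_channels = c(16L, 8L, 8L, 4L), d_channels = c(4L, 8L, 8L, 16L),
           batch_size = 16L, holdout = 8L, max_epochs = max_epochs,
           seed = seed, ...)
}

# undirected edge list of a mesh (for igraph-based oracles)
mesh_edges <- function(mesh) {
  do.call(rbind, lapply(seq_along(mesh$adjacency), function(v) {
    nb <- mesh$adjacency[[v]][mesh$adjacency[[v]] > v]
    cbind(rep(v, length(nb)), nb)
  }))
}

# a tiny trained model on smooth random frames, cached across tests
tiny_trained_model <- function() {
  fixture("tiny_model", function() {
    set.seed(99)
    base <- matrix(stats::runif(256 * 4, -1, 1), 256, 4)
    mix <- matrix(stats::runif(4 * 120), 4, 120)
    frames <- tanh(base %*% mix)
    gan_train(frames, tiny_gan_spec(max_epochs = 3L))
  })
}

# independent per-vertex Pearson correlation, textbook formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}
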