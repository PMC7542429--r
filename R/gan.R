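# DCGAN for flattened BOLD frames.
#
# Generator: learned projection of a uniform latent vector to a small spatial
# representation, then four fractionally-strided convolutions (ReLU hidden
# activations, batch normalization on all layers except the output, tanh
# output). Discriminator: four strided convolutions (leaky ReLU, batch
# normalization on all layers except the first) into a single sigmoid unit.
# Training is the two-player minimax game with sigmoid cross-entropy losses,
# Adam for both players, one discriminator update and two generator updates
# per iteration, stopping when held-out discriminator accuracy settles at
# chance level.

#' Specify a DCGAN
#'
#' Defaults follow the architecture and optimizer the method was built with:
#' a 100-dimensional uniform latent space, Adam at learning rate 0.0002
#' (betas 0.5/0.999), batch size 64 with batch normalization, two generator
#' updates per iteration, and early stopping when held-out discriminator
#' accuracy stays at chance level (0.5 within `eps_acc`) over `window`
#' iterations. The raster defaults to 128 x 128; any size divisible by 16
#' (four halvings) is accepted.
#'
#' @param latent_dim latent dimension (default 100).
#' @param height,width raster size in pixels; both divisible by 16.
#' @param g_channels four channel widths: initial projection then the first
#'   three up-convolutions (the fourth up-convolution outputs 1 channel).
#' @param d_channels four channel widths of the strided down-convolutions.
#' @param lr Adam learning rate for both networks (default 0.0002).
#' @param beta1,beta2 Adam moment decays (default 0.5, 0.999).
#' @param batch_size minibatch size (default 64; must be >= 2 for batch
#'   normalization).
#' @param g_updates generator updates per iteration (default 2).
#' @param max_epochs hard cap on training epochs.
#' @param window early-stop window in iterations (default 200).
#' @param eps_acc chance-level tolerance for held-out discriminator accuracy
#'   (default 0.05).
#' @param holdout number of real frames held out for the accuracy probe.
#' @param eval_every iterations between accuracy probes (default 5).
#' @param loss generator loss: `"non-saturating"` (default; maximize
#'   log D(G(z))) or `"minimax"` (literal descent on log(1 - D(G(z)))).
#' @param seed training seed.
#' @return an object of class `gan_spec`.
#' @export
gan_spec <- function(latent_dim = 100L, height = 128L, width = 128L,
                     g_channels = c(512L, 256L, 128L, 64L),
                     d_channels = c(64L, 128L, 256L, 512L),
                     lr = 2e-4, beta1 = 0.5, beta2 = 0.999,
                     batch_size = 64L, g_updates = 2L,
                     max_epochs = 20L, window = 200L, eps_acc = 0.05,
                     holdout = 64L, eval_every = 5L,
                     loss = c("non-saturating", "minimax"), seed = 1L) {
  latent_dim <- check_count(latent_dim, "latent_dim", lower = 1L)
  height <- check_count(height, "height", lower = 16L)
  width <- check_count(width, "width", lower = 16L)
  if (height %% 16L != 0L || width %% 16L != 0L)
    stop_arg("raster size must be divisible by 16 (four stride-2 stages)")
  if (length(g_channels) != 4L || length(d_channels) != 4L)
    stop_arg("g_channels and d_channels must each have length 4")
  batch_size <- check_count(batch_size, "batch_size", lower = 2L)
  structure(
    list(latent_dim = latent_dim, height = height, width = width,
         g_channels = as.integer(g_channels), d_channels = as.integer(d_channels),
         lr = lr, beta1 = beta1, beta2 = beta2,
         batch_size = batch_size, g_updates = check_count(g_updates, "g_updates", 1L),
         max_epochs = check_count(max_epochs, "max_epochs", 1L),
         window = check_count(window, "window", 1L), eps_acc = eps_acc,
         holdout = check_count(holdout, "holdout", 2L),
         eval_every = check_count(eval_every, "eval_every", 1L),
         loss = match.arg(loss), seed = check_count(seed, "seed")),
    class = "gan_spec"
  )
}

#' Build the generator network
#'
#' @param spec a [gan_spec()].
#' @param seed weight-initialization seed (default derived from the spec's
#'   training seed).
#' @return an object of class `gan_generator`.
#' @export
build_generator <- function(spec, seed = derive_seed(spec$seed, 11L)) {
  stopifnot(inherits(spec, "gan_spec"))
  set.seed(seed)
  bh <- spec$height %/% 16L
  bw <- spec$width %/% 16L
  ch <- spec$g_channels
  layers <- list(
    layer_dense(spec$latent_dim, ch[1] * bh * bw),
    layer_bn(ch[1], bh * bw),
    layer_act("relu"),
    layer_tconv(ch[1], bh, bw, ch[2]),
    layer_bn(ch[2], 4L * bh * bw),
    layer_act("relu"),
    layer_tconv(ch[2], 2L * bh, 2L * bw, ch[3]),
    layer_bn(ch[3], 16L * bh * bw),
    layer_act("relu"),
    layer_tconv(ch[3], 4L * bh, 4L * bw, ch[4]),
    layer_bn(ch[4], 64L * bh * bw),
    layer_act("relu"),
    layer_tconv(ch[4], 8L * bh, 8L * bw, 1L),
    layer_act("tanh")
  )
  structure(list(layers = layers, latent_dim = spec$latent_dim,
                 height = spec$height, width = spec$width),
            class = "gan_generator")
}

#' Build the discriminator network
#'
#' @inheritParams build_generator
#' @return an object of class `gan_discriminator` mapping a raster to the
#'   probability that it is a real frame.
#' @export
build_discriminator <- function(spec, seed = derive_seed(spec$seed, 12L)) {
  stopifnot(inherits(spec, "gan_spec"))
  set.seed(seed)
  h <- spec$height
  w <- spec$width
  ch <- spec$d_channels
  layers <- list(
    layer_conv(1L, h, w, ch[1]),
    layer_act("lrelu"),
    layer_conv(ch[1], h %/% 2L, w %/% 2L, ch[2]),
    layer_bn(ch[2], (h %/% 4L) * (w %/% 4L)),
    layer_act("lrelu"),
    layer_conv(ch[2], h %/% 4L, w %/% 4L, ch[3]),
    layer_bn(ch[3], (h %/% 8L) * (w %/% 8L)),
    layer_act("lrelu"),
    layer_conv(ch[3], h %/% 8L, w %/% 8L, ch[4]),
    layer_bn(ch[4], (h %/% 16L) * (w %/% 16L)),
    layer_act("lrelu"),
    layer_dense(ch[4] * (h %/% 16L) * (w %/% 16L), 1L)
  )
  structure(list(layers = layers, height = h, width = w),
            class = "gan_discriminator")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# forward pass of the generator; z is (latent_dim x n)
generator_forward <- function(gen, z, training = FALSE) {
  net_forward(gen, z, training)
}

# discriminator probability for images (pixels x n)
discriminator_prob <- function(disc, x, training = FALSE) {
  f <- net_forward(disc, x, training)
  list(p = as.numeric(sigmoid(f$out)), caches = f$caches, net = f$net)
}

#' Draw latent points uniformly in `[-1, 1]`
#' @param latent_dim latent dimension.
#' @param n number of points.
#' @return a `latent_dim x n` matrix.
#' @export
sample_latent <- function(latent_dim, n) {
  matrix(stats::runif(latent_dim * n, -1, 1), latent_dim, n)
}

#' Sigmoid cross-entropy losses of the minimax game
#'
#' Discriminator loss `-(mean log D(x) + mean log(1 - D(G(z))))` and
#' generator loss (non-saturating `-mean log D(G(z))`, or minimax
#' `mean log(1 - D(G(z)))`), computed from the two probability batches.
#' Exposed so the training losses can be checked against hand-computed
#' values.
#'
#' @param p_real discriminator probabilities on real frames.
#' @param p_fake discriminator probabilities on generated frames.
#' @param loss generator-loss form.
#' @return list with `d_loss` and `g_loss`.
#' @export
gan_losses <- function(p_real, p_fake, loss = c("non-saturating", "minimax")) {
  loss <- match.arg(loss)
  eps <- 1e-12
  d_loss <- -(mean(log(pmax(p_real, eps))) + mean(log(pmax(1 - p_fake, eps))))
  g_loss <- if (loss == "non-saturating") -mean(log(pmax(p_fake, eps)))
            else mean(log(pmax(1 - p_fake, eps)))
  list(d_loss = d_loss, g_loss = g_loss)
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (i in seq_along(a)) {
    if (is.null(a[[i]])) next
    for (nm in names(a[[i]])) a[[i]][[nm]] <- a[[i]][[nm]] + b[[i]][[nm]]
  }
  a
}

#' Train the DCGAN on flattened BOLD frames
#'
#' Alternating optimization of the two-player minimax value function with
#' sigmoid cross-entropy: per iteration, one discriminator update on a real
#' and a generated batch, then `g_updates` generator updates. Training stops
#' at `max_epochs` or as soon as the held-out discriminator accuracy stays
#' within `eps_acc` of chance (0.5) over the early-stop window. Fully seeded
#' and bit-reproducible; input frames are never mutated.
#'
#' @param frames numeric matrix of flattened frames (`height*width` x
#'   n_frames), values in `[-1, 1]`.
#' @param spec a [gan_spec()].
#' @param verbose print progress every 20 iterations.
#' @return an object of class `gan_model`: list with `generator`,
#'   `discriminator`, `spec`, and `history` (per-iteration losses plus the
#'   held-out accuracy trace).
#' @export
gan_train <- function(frames, spec, verbose = FALSE) {
  stopifnot(inherits(spec, "gan_spec"), is.matrix(frames))
  if (nrow(frames) != spec$height * spec$width)
    stop_arg("frames have ", nrow(frames), " pixels; spec raster is ",
             spec$height, "x", spec$width)
  if (max(abs(frames)) > 1 + 1e-9)
    stop_arg("frames must be normalized to [-1, 1]")
  n <- ncol(frames)
  if (n < spec$batch_size + spec$holdout)
    stop_arg("need at least batch_size + holdout = ",
             spec$batch_size + spec$holdout, " frames, got ", n)
  set.seed(derive_seed(spec$seed, 1L))
  hold_idx <- sample.int(n, spec$holdout)
  x_hold <- frames[, hold_idx, drop = FALSE]
  x_train <- frames[, -hold_idx, drop = FALSE]
  n_train <- ncol(x_train)

  gen <- build_generator(spec)
  disc <- build_discriminator(spec)
  g_state <- adam_init(gen)
  d_state <- adam_init(disc)

  iter <- 0L
  hist_d <- numeric(0); hist_g <- numeric(0)
  acc_iter <- integer(0); acc_val <- numeric(0)
  n_acc_window <- max(1L, spec$window %/% spec$eval_every)
  stopped_early <- FALSE

  for (epoch in seq_len(spec$max_epochs)) {
    perm <- sample.int(n_train)
    n_batches <- n_train %/% spec$batch_size
    for (b in seq_len(n_batches)) {
      iter <- iter + 1L
      idx <- perm[((b - 1L) * spec$batch_size + 1L):(b * spec$batch_size)]
      x_real <- x_train[, idx, drop = FALSE]

      # --- discriminator update ---
      z <- sample_latent(spec$latent_dim, spec$batch_size)
      gf <- generator_forward(gen, z, training = TRUE)
      gen <- gf$net
      x_fake <- gf$out
      dr <- discriminator_prob(disc, x_real, training = TRUE)
      disc <- dr$net
      bw_r <- net_backward(disc, dr$caches,
                           matrix((dr$p - 1) / spec$batch_size, 1L))
      df <- discriminator_prob(disc, x_fake, training = TRUE)
      disc <- df$net
      bw_f <- net_backward(disc, df$caches,
                           matrix(df$p / spec$batch_size, 1L))
      d_grads <- add_grads(bw_r$grads, bw_f$grads)
      upd <- adam_step(disc, d_grads, d_state, spec$lr, spec$beta1, spec$beta2)
      disc <- upd$net
      d_state <- upd$state
      losses <- gan_losses(dr$p, df$p, spec$loss)
      hist_d <- c(hist_d, losses$d_loss)

      # --- generator updates ---
      g_loss <- NA_real_
      for (u in seq_len(spec$g_updates)) {
        z <- sample_latent(spec$latent_dim, spec$batch_size)
        gf <- generator_forward(gen, z, training = TRUE)
        gen <- gf$net
        dg <- discriminator_prob(disc, gf$out, training = TRUE)
        dlogit <- if (spec$loss == "non-saturating") {
          (dg$p - 1) / spec$batch_size
        } else {
          -dg$p / spec$batch_size
        }
        bw_d <- net_backward(dg$net, dg$caches, matrix(dlogit, 1L))
        bw_g <- net_backward(gen, gf$caches, bw_d$dx)
        upd <- adam_step(gen, bw_g$grads, g_state, spec$lr, spec$beta1, spec$beta2)
        gen <- upd$net
        g_state <- upd$state
        g_loss <- gan_losses(dg$p, dg$p, spec$loss)$g_loss
      }
      hist_g <- c(hist_g, g_loss)

      # --- held-out accuracy probe ---
      if (iter %% spec$eval_every == 0L) {
        z <- sample_latent(spec$latent_dim, spec$holdout)
        fake_h <- generator_forward(gen, z, training = FALSE)$out
        p_r <- discriminator_prob(disc, x_hold, training = FALSE)$p
        p_f <- discriminator_prob(disc, fake_h, training = FALSE)$p
        acc <- (mean(p_r > 0.5) + mean(p_f <= 0.5)) / 2
        acc_iter <- c(acc_iter, iter)
        acc_val <- c(acc_val, acc)
        if (verbose && iter %% 20L == 0L)
          message(sprintf("iter %d  d_loss %.3f  g_loss %.3f  holdout acc %.3f",
                          iter, losses$d_loss, g_loss, acc))
        # stop only once an *optimized* discriminator has fallen back to
        # chance: it must first have clearly beaten 0.5 on the held-out set
        if (length(acc_val) >= n_acc_window &&
            max(acc_val) >= 0.5 + 2 * spec$eps_acc &&
            abs(mean(utils::tail(acc_val, n_acc_window)) - 0.5) <= spec$eps_acc) {
          stopped_early <- TRUE
          break
        }
      }
    }
    if (stopped_early) break
  }

  structure(
    list(generator = gen, discriminator = disc, spec = spec,
         history = list(
           iterations = iter,
           d_loss = hist_d, g_loss = hist_g,
           holdout_acc = data.frame(iteration = acc_iter, accuracy = acc_val),
           stopped_early = stopped_early)),
    class = "gan_model"
  )
}

#' @export
print.gan_model <- function(x, ...) {
  cat(sprintf("gan_model: %dx%d raster, latent %d, %d iterations%s\n",
              x$spec$height, x$spec$width, x$spec$latent_dim,
              x$history$iterations,
              if (x$history$stopped_early) " (early stop at chance-level accuracy)" else ""))
  invisible(x)
}

#' Generate rasters from latent points
#'
#' Deterministic forward pass in evaluation mode (batch-normalization
#' statistics frozen).
#'
#' @param model a `gan_model` (or a bare `gan_generator`).
#' @param z latent matrix (`latent_dim` x n) or a single latent vector.
#' @return a `height*width` x n matrix of generated rasters, values in
#'   `(-1, 1)`.
#' @export
gan_sample <- function(model, z) {
  gen <- if (inherits(model, "gan_model")) model$generator else model
  stopifnot(inherits(gen, "gan_generator"))
  if (is.null(dim(z))) z <- matrix(z, ncol = 1L)
  if (nrow(z) != gen$latent_dim)
    stop_arg("z has ", nrow(z), " dimensions; generator expects ", gen$latent_dim)
  generator_forward(gen, z, training = FALSE)$out
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is a single RDS archive holding spec, parameters, training
#' history and seed.
#' @param model a `gan_model`.
#' @param path file path.
#' @return `path` (save) or the restored `gan_model` (load).
#' @export
save_gan <- function(model, path) {
  stopifnot(inherits(model, "gan_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_gan
#' @export
load_gan <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "gan_model"))
  model
}
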