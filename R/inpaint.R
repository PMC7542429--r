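# Frame-by-frame reconstruction of compromised regions.
#
# GAN route: for each frame, search the generator's latent space for the
# point whose generated raster best matches the frame over the intact region
# (masked reconstruction loss L = sum over intact pixels of (x - G(z))^2),
# then splice G(z) into the compromised vertices. Diffusion route: fill the
# region from its perimeter inwards, each vertex taking the mean of its
# already-assigned neighbors. Both methods are strict identities on intact
# vertices.

#' Specify the latent-space search
#'
#' Defaults follow the reconstruction recipe: 500 plain gradient-descent
#' iterations at learning rate 0.000002. The fixed step is tied to the loss
#' scale of a full-size raster; for small rasters the `"adam"` optimizer
#' (step-size adaptive) is provided and recommended. The best-observed `z`
#' across all iterations and restarts is returned, so the final loss never
#' exceeds the initial one.
#'
#' @param iterations gradient iterations per restart (default 500).
#' @param lr learning rate (default 0.000002 for `"gd"`; a typical `"adam"`
#'   value is 0.05).
#' @param restarts number of random restarts (default 1).
#' @param optimizer `"gd"` (plain gradient descent, default) or `"adam"`.
#' @param clip_z clip `z` to `[-1, 1]` after each step (default `FALSE`;
#'   only the initialization range is constrained).
#' @param seed restart seed; per-frame initializations derive from it and
#'   from the frame content, so reconstruction is a pure per-frame function
#'   (identical regardless of frame order or batching).
#' @param chunk frames optimized per batch (memory/speed trade-off).
#' @return an object of class `latent_search_spec`.
#' @export
latent_search_spec <- function(iterations = 500L, lr = 2e-6, restarts = 1L,
                               optimizer = c("gd", "adam"), clip_z = FALSE,
                               seed = 1L, chunk = 64L) {
  iterations <- check_count(iterations, "iterations", lower = 1L)
  check_scalar_number(lr, "lr", lower = 1e-300)
  structure(
    list(iterations = iterations, lr = lr,
         restarts = check_count(restarts, "restarts", lower = 1L),
         optimizer = match.arg(optimizer), clip_z = isTRUE(clip_z),
         seed = check_count(seed, "seed"),
         chunk = check_count(chunk, "chunk", lower = 1L)),
    class = "latent_search_spec"
  )
}

#' Zero the signal inside a compromised region
#'
#' @param run a `bold_run` on the two-hemisphere template.
#' @param mask a `region_mask`.
#' @param mesh the template `cortical_mesh`.
#' @return the run with masked vertices set to 0 at all frames; all other
#'   values bit-identical.
#' @export
make_compromised <- function(run, mask, mesh) {
  stopifnot(inherits(run, "bold_run"))
  rows <- mask_run_rows(mask, mesh)
  if (nrow(run$data) != 2L * n_vertices(mesh))
    stop_arg("run has ", nrow(run$data), " rows; template implies ",
             2L * n_vertices(mesh))
  run$data[rows, ] <- 0
  run
}

# content-derived per-frame seed so reconstruction is order-invariant
frame_seed <- function(frame, seed, restart) {
  h <- sum(abs(frame) * seq_along(frame)) + sum(frame)
  derive_seed(seed, restart, abs(floor(h * 1e6)) %% 2147480000)
}

# core batched latent search: images (pixels x T), intact_pix logical
latent_inpaint <- function(gen, images, intact_pix, search) {
  t_all <- ncol(images)
  d <- gen$latent_dim
  best_z <- matrix(0, d, t_all)
  best_loss <- rep(Inf, t_all)
  w_int <- as.numeric(intact_pix)
  for (start in seq(1L, t_all, by = search$chunk)) {
    cols <- start:min(start + search$chunk - 1L, t_all)
    x <- images[, cols, drop = FALSE]
    tt <- length(cols)
    for (r in seq_len(search$restarts)) {
      z <- vapply(seq_len(tt), function(j) {
        set.seed(frame_seed(x[, j], search$seed, r))
        stats::runif(d, -1, 1)
      }, numeric(d))
      z <- matrix(z, d, tt)
      bz <- z
      bl <- rep(Inf, tt)
      if (search$optimizer == "adam") {
        m <- z * 0; v <- z * 0
      }
      for (it in seq_len(search$iterations + 1L)) {
        gf <- generator_forward(gen, z, training = FALSE)
        diff <- (gf$out - x) * w_int
        loss <- colSums(diff * diff)
        improved <- loss < bl
        if (any(improved)) {
          bl[improved] <- loss[improved]
          bz[, improved] <- z[, improved]
        }
        if (it > search$iterations) break
        dz <- net_backward(gen, gf$caches, 2 * diff)$dx
        if (search$optimizer == "adam") {
          m <- 0.9 * m + 0.1 * dz
          v <- 0.999 * v + 0.001 * dz * dz
          mh <- m / (1 - 0.9^it)
          vh <- v / (1 - 0.999^it)
          z <- z - search$lr * mh / (sqrt(vh) + 1e-8)
        } else {
          z <- z - search$lr * dz
        }
        if (search$clip_z) z <- pmin(pmax(z, -1), 1)
      }
      take <- bl < best_loss[cols]
      if (any(take)) {
        best_loss[cols][take] <- bl[take]
        best_z[, cols[take]] <- bz[, take]
      }
    }
  }
  gen_out <- generator_forward(gen, best_z, training = FALSE)$out
  list(z = best_z, loss = best_loss, generated = gen_out)
}

#' Reconstruct one compromised frame by latent-space optimization
#'
#' Minimizes `L = sum over intact pixels of (x - G(z))^2` over the latent
#' point `z` (initialized uniformly in `[-1, 1]`), keeps the best-observed
#' `z`, and composes the output frame: input values on intact vertices,
#' `G(z)` values on masked vertices.
#'
#' @param model a trained `gan_model`.
#' @param frame per-vertex values (length `2V`), normalized to `[-1, 1]`.
#' @param mask a `region_mask`.
#' @param map the `vertex_pixel_map` the model was trained with.
#' @param mesh the template `cortical_mesh`.
#' @param search a [latent_search_spec()].
#' @return list with `frame` (reconstructed), `loss` (final best loss) and
#'   `z` (best latent point).
#' @export
reconstruct_frame_gan <- function(model, frame, mask, map, mesh,
                                  search = latent_search_spec()) {
  stopifnot(inherits(model, "gan_model"), inherits(map, "vertex_pixel_map"))
  if (length(frame) != map$n_vertices)
    stop_arg("frame length does not match the flattening map")
  if (max(abs(frame)) > 1 + 1e-9)
    stop_arg("frame must be normalized to [-1, 1]")
  rows <- mask_run_rows(mask, mesh)
  pix_idx <- vertex_pixel_index(map)
  intact_pix <- rep(TRUE, map$height * map$width)
  intact_pix[pix_idx[rows]] <- FALSE
  img <- matrix(as.numeric(frame_to_image(frame, map)), ncol = 1L)
  res <- latent_inpaint(model$generator, img, intact_pix, search)
  out <- frame
  out[rows] <- res$generated[pix_idx[rows], 1L]
  list(frame = out, loss = res$loss, z = res$z[, 1L])
}

#' Reconstruct a whole run by frame-wise latent optimization
#'
#' Applies the latent search to every frame independently (no temporal
#' information is shared between frames) and reassembles the time series.
#' Per-frame initializations derive from the restart seed and the frame
#' content, so the result does not depend on frame order or batching.
#'
#' @inheritParams reconstruct_frame_gan
#' @param run a `bold_run` normalized to `[-1, 1]`.
#' @return an object of class `reconstruction_result`: list with `run`
#'   (reconstructed `bold_run`), `loss` (per-frame final loss), `z`
#'   (latent points, `latent_dim x T`), `mask`, `method = "gan"`.
#' @export
reconstruct_run_gan <- function(model, run, mask, map, mesh,
                                search = latent_search_spec()) {
  stopifnot(inherits(run, "bold_run"))
  if (max(abs(run$data)) > 1 + 1e-9)
    stop_arg("run must be normalized to [-1, 1] (see normalize_session)")
  rows <- mask_run_rows(mask, mesh)
  pix_idx <- vertex_pixel_index(map)
  intact_pix <- rep(TRUE, map$height * map$width)
  intact_pix[pix_idx[rows]] <- FALSE
  images <- matrix(0, map$height * map$width, ncol(run$data))
  images[pix_idx, ] <- run$data
  res <- latent_inpaint(model$generator, images, intact_pix, search)
  out <- run
  out$data[rows, ] <- res$generated[pix_idx[rows], , drop = FALSE]
  structure(list(run = out, loss = res$loss, z = res$z, mask = mask,
                 method = "gan"),
            class = "reconstruction_result")
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat(sprintf("reconstruction_result (%s): %d frames, mean final loss %.4g\n",
              x$method, ncol(x$run$data), mean(x$loss)))
  invisible(x)
}

#' Reconstruct a compromised region by boundary diffusion
#'
#' Compromised vertices are layered by graph distance to the nearest intact
#' vertex; layers are processed from the perimeter inwards, each vertex
#' taking the mean of its already-assigned neighbors (intact or earlier
#' layer). Assignments within a layer are synchronous (pre-layer values
#' only). Applied independently to every frame; deterministic.
#'
#' @param run a `bold_run`.
#' @param mask a `region_mask`.
#' @param mesh the template `cortical_mesh`.
#' @return a `reconstruction_result` with `method = "diffusion"`.
#' @export
reconstruct_diffusion <- function(run, mask, mesh) {
  stopifnot(inherits(run, "bold_run"), inherits(mask, "region_mask"),
            inherits(mesh, "cortical_mesh"))
  v <- n_vertices(mesh)
  if (all(mask$mask)) stop_arg("no intact vertices on the masked hemisphere")
  offset <- if (mask$hemisphere == "rh") v else 0L
  x <- run$data[offset + seq_len(v), , drop = FALSE]
  # multi-source BFS layering from the intact set
  layer <- rep(NA_integer_, v)
  layer[!mask$mask] <- 0L
  frontier <- which(!mask$mask)
  d <- 0L
  while (anyNA(layer)) {
    d <- d + 1L
    nxt <- unique(unlist(mesh$adjacency[frontier], use.names = FALSE))
    nxt <- nxt[is.na(layer[nxt])]
    if (length(nxt) == 0L) break
    layer[nxt] <- d
    frontier <- nxt
  }
  for (l in seq_len(max(layer, na.rm = TRUE))) {
    members <- which(layer == l)
    new_vals <- lapply(members, function(vv) {
      nb <- mesh$adjacency[[vv]]
      nb <- nb[layer[nb] < l]
      colMeans(x[nb, , drop = FALSE])
    })
    # synchronous: all layer-l values computed from pre-layer state
    x[members, ] <- do.call(rbind, new_vals)
  }
  out <- run
  out$data[offset + seq_len(v), ] <- x
  structure(list(run = out, loss = rep(NA_real_, ncol(run$data)), z = NULL,
                 mask = mask, method = "diffusion"),
            class = "reconstruction_result")
}

#' Detect a compromised region from pre/post amplitude contrast
#'
#' Computes the per-vertex mean absolute amplitude of the pre- and
#' post-implantation runs, normalizes each map to `[0, 1]` by its maximum,
#' and flags vertices whose post/pre normalized amplitude ratio falls below
#' `ratio_threshold`. Vertices with pre-normalized amplitude below
#' `amplitude_floor` are never flagged (their ratio is unstable).
#'
#' @param pre,post `bold_run`s on the same template.
#' @param ratio_threshold flag vertices with post/pre ratio below this value,
#'   in `(0, 1)` (default 0.5).
#' @param hemisphere hemisphere whose mask is returned (default `"lh"`).
#' @param mesh the template `cortical_mesh`.
#' @param amplitude_floor pre-amplitude floor (default 0.01).
#' @return a `region_mask` over the requested hemisphere.
#' @export
detect_dbs_mask <- function(pre, post, mesh, ratio_threshold = 0.5,
                            hemisphere = c("lh", "rh"),
                            amplitude_floor = 0.01) {
  stopifnot(inherits(pre, "bold_run"), inherits(post, "bold_run"))
  hemisphere <- match.arg(hemisphere)
  if (!identical(dim(pre$data)[1], dim(post$data)[1]))
    stop_arg("pre/post runs have different vertex counts")
  check_scalar_number(ratio_threshold, "ratio_threshold", lower = 1e-12,
                      upper = 1 - 1e-12)
  amp_pre <- rowMeans(abs(pre$data))
  amp_post <- rowMeans(abs(post$data))
  amp_pre <- amp_pre / max(amp_pre)
  amp_post <- amp_post / max(amp_post)
  flagged <- (amp_pre >= amplitude_floor) &
    (amp_post / pmax(amp_pre, amplitude_floor) < ratio_threshold)
  v <- nrow(pre$data) %/% 2L
  block <- if (hemisphere == "rh") v + seq_len(v) else seq_len(v)
  out <- vertex_mask(mesh, which(flagged[block]))
  out$hemisphere <- hemisphere
  out
}
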