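# End-to-end desk-scale experiments.
#
# recovery_experiment() runs the full study loop at a scale a single CPU
# handles in minutes: synthesize a cohort, preprocess, train the DCGAN on
# the training subjects' flattened frames, compromise a region in the test
# subjects, reconstruct by latent optimization and by diffusion, and score
# recovery, FC-map similarity, subject specificity, and the mask-size sweep.
# The default sizes are the package's reference desk-scale conditions:
# level-2 mesh (162 vertices/hemisphere), 32x32 rasters, 20 training + 5
# test subjects, 240 frames smoothed by 4, a 10% geodesic mask, and a
# 100-iteration latent search.

#' Run the scaled-down end-to-end recovery experiment
#'
#' @param seed master seed for the whole experiment.
#' @param level icosphere subdivision level (default 2).
#' @param raster raster side in pixels (default 32; both hemispheres side by
#'   side in one image).
#' @param n_train,n_test training/test subjects (default 20/5).
#' @param n_frames frames per run before smoothing (default 240).
#' @param smooth_window temporal-smoothing window (default 4).
#' @param mask_fraction compromised fraction of the left hemisphere
#'   (default 0.1).
#' @param mask_center center vertex of the compromised region (default 1).
#' @param g_channels,d_channels desk-scale channel widths.
#' @param max_epochs training epoch cap (default 56).
#' @param stop_window,eps_acc early-stop window (iterations) and chance-level
#'   tolerance.
#' @param search_iterations latent-search iterations per frame (default 100).
#' @param search_lr latent-search Adam learning rate (default 0.05).
#' @param sweep run the mask-size sweep (default TRUE).
#' @param n_sweep_centers mask centers in the sweep (default 2).
#' @param sweep_frames frames used per sweep reconstruction (default 40).
#' @param verbose print stage progress.
#' @return an object of class `recovery_experiment`: list with the trained
#'   `model`, per-stage results (`timeseries`, `fc`, `specificity`,
#'   `sweep`), and the experiment configuration.
#' @export
recovery_experiment <- function(seed = 1L, level = 2L, raster = 32L,
                                n_train = 20L, n_test = 5L, n_frames = 240L,
                                smooth_window = 4L,
                                mask_fraction = 0.1, mask_center = 1L,
                                g_channels = c(128L, 64L, 32L, 16L),
                                d_channels = c(16L, 32L, 64L, 128L),
                                max_epochs = 56L, stop_window = 200L,
                                eps_acc = 0.05,
                                search_iterations = 100L, search_lr = 0.05,
                                sweep = TRUE, n_sweep_centers = 2L,
                                sweep_frames = 40L, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  mesh <- build_icosphere(level)
  map <- flatten_pair(mesh, raster, raster)

  say("simulating cohort (%d subjects)", n_train + n_test)
  spec <- cohort_spec(n_subjects = n_train + n_test, n_frames = n_frames,
                      seed = derive_seed(seed, 1L))
  cohort <- make_cohort(spec, mesh, return_truth = FALSE)
  prep <- lapply(cohort$runs, function(rs) {
    r <- normalize_session(rs[[1]])
    if (smooth_window > 1L) r <- temporal_smooth(r, smooth_window)
    r
  })
  train_runs <- prep[seq_len(n_train)]
  test_runs <- prep[n_train + seq_len(n_test)]

  pix_idx <- vertex_pixel_index(map)
  frames <- do.call(cbind, lapply(train_runs, function(r) {
    f <- matrix(0, raster * raster, ncol(r$data))
    f[pix_idx, ] <- r$data
    f
  }))

  say("training DCGAN on %d frames", ncol(frames))
  gspec <- gan_spec(height = raster, width = raster,
                    g_channels = g_channels, d_channels = d_channels,
                    max_epochs = max_epochs, window = stop_window,
                    eps_acc = eps_acc, seed = derive_seed(seed, 2L))
  model <- gan_train(frames, gspec, verbose = verbose)

  mask <- geodesic_mask(mesh, mask_center, mask_fraction)
  rows <- mask_run_rows(mask, mesh)
  search <- latent_search_spec(iterations = search_iterations, lr = search_lr,
                               optimizer = "adam", seed = derive_seed(seed, 3L))

  say("reconstructing %d test subjects (%d masked vertices)",
      n_test, length(rows))
  rec_gan <- vector("list", n_test)
  rec_diff <- vector("list", n_test)
  ts_r <- list()
  fc_gan <- numeric(n_test)
  fc_diff <- numeric(n_test)
  for (i in seq_len(n_test)) {
    compromised <- make_compromised(test_runs[[i]], mask, mesh)
    rec_gan[[i]] <- reconstruct_run_gan(model, compromised, mask, map, mesh, search)
    rec_diff[[i]] <- reconstruct_diffusion(compromised, mask, mesh)
    ts <- timeseries_accuracy(test_runs[[i]], rec_gan[[i]]$run, mask, mesh)
    ts_r[[i]] <- ts$r
    z_orig <- fc_maps_for_seeds(test_runs[[i]], rows)
    fc_gan[i] <- mean_fc_similarity(z_orig,
                                    fc_maps_for_seeds(rec_gan[[i]]$run, rows),
                                    rows, nrow(test_runs[[i]]$data))
    fc_diff[i] <- mean_fc_similarity(z_orig,
                                     fc_maps_for_seeds(rec_diff[[i]]$run, rows),
                                     rows, nrow(test_runs[[i]]$data))
    say("  subject %d: ts r %.3f, FC r gan %.3f / diffusion %.3f",
        i, mean(ts$r), fc_gan[i], fc_diff[i])
  }
  all_r <- unlist(ts_r)
  timeseries <- list(
    r = all_r, mean = mean(all_r),
    ci = bootstrap_ci_mean(all_r, seed = derive_seed(seed, 4L)))
  fc <- list(gan = fc_gan, diffusion = fc_diff,
             mean_gan = mean(fc_gan), mean_diffusion = mean(fc_diff),
             diff_ci = bootstrap_ci_mean(fc_gan - fc_diff,
                                         seed = derive_seed(seed, 5L)))

  say("specificity analysis")
  specificity <- specificity_analysis(test_runs,
                                      lapply(rec_gan, `[[`, "run"),
                                      train_runs, rows,
                                      ci_seed = derive_seed(seed, 6L))

  sweep_out <- NULL
  if (sweep) {
    set.seed(derive_seed(seed, 7L))
    centers <- sample.int(n_vertices(mesh), n_sweep_centers)
    say("mask-size sweep (%d centers x 6 fractions, %d frames)",
        n_sweep_centers, sweep_frames)
    short <- test_runs[[1]]
    short$data <- short$data[, seq_len(min(sweep_frames, ncol(short$data))), drop = FALSE]
    sweep_df <- mask_size_sweep(model, short, mesh, map, centers,
                                search = search)
    sweep_out <- list(
      curve = sweep_df,
      spearman = stats::cor(sweep_df$fraction, sweep_df$mean_fc_r,
                            method = "spearman"))
  }

  structure(
    list(model = model, mask = mask, timeseries = timeseries, fc = fc,
         specificity = specificity, sweep = sweep_out,
         config = list(seed = seed, level = level, raster = raster,
                       n_train = n_train, n_test = n_test,
                       n_frames = n_frames, smooth_window = smooth_window,
                       mask_fraction = mask_fraction,
                       search_iterations = search_iterations)),
    class = "recovery_experiment"
  )
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat("recovery_experiment\n")
  cat(sprintf("  mean within-mask time-series r: %.3f (95%% CI %.3f..%.3f)\n",
              x$timeseries$mean, x$timeseries$ci["lower"], x$timeseries$ci["upper"]))
  cat(sprintf("  mean within-mask FC-map r: GAN %.3f, diffusion %.3f\n",
              x$fc$mean_gan, x$fc$mean_diffusion))
  cat(sprintf("  specificity: own %.3f vs group %.3f\n",
              x$specificity$mean["own"], x$specificity$mean["group"]))
  if (!is.null(x$sweep))
    cat(sprintf("  mask-size sweep Spearman rho: %.3f\n", x$sweep$spearman))
  invisible(x)
}

#' Effect of temporal smoothing on temporal SNR
#'
#' Generates seeded synthetic runs and compares each run's mean tSNR before
#' and after block smoothing (window 4 by default). Smoothing averages away
#' white measurement noise, so tSNR should rise in nearly all replicates.
#'
#' @param n_reps replicates (default 100).
#' @param seed master seed.
#' @param level mesh level of the replicate runs (default 2).
#' @param n_frames frames per run (default 240).
#' @param window smoothing window (default 4).
#' @return list with `improved` (logical per replicate), `fraction_improved`,
#'   and `mean_ratio` (smoothed / raw mean tSNR).
#' @export
tsnr_smoothing_experiment <- function(n_reps = 100L, seed = 1L, level = 2L,
                                      n_frames = 240L, window = 4L) {
  mesh <- build_icosphere(level)
  ratios <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    spec <- cohort_spec(n_subjects = 1L, n_frames = n_frames,
                        seed = derive_seed(seed, i))
    run <- make_cohort(spec, mesh, return_truth = FALSE)$runs[[1]][[1]]
    run <- normalize_session(run)
    ratios[i] <- tsnr(temporal_smooth(run, window))$mean / tsnr(run)$mean
  }
  list(improved = ratios > 1, fraction_improved = mean(ratios > 1),
       mean_ratio = mean(ratios))
}
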