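# Accuracy and specificity metrics: per-vertex time-series recovery,
# seed-based Fisher-z FC maps and their similarity, most-similar-individual
# fingerprinting, group-average comparison, amplitude recovery, and the
# mask-size sweep.

#' Per-vertex time-series recovery inside a region
#'
#' Pearson correlation between original and reconstructed series at every
#' masked vertex; the region value is the mean over masked vertices.
#' Zero-variance vertices yield r = 0 and are counted in `n_flagged`.
#'
#' @param original,reconstructed `bold_run`s of equal shape.
#' @param mask a `region_mask`.
#' @param mesh the template `cortical_mesh`.
#' @return list with `r` (per masked vertex), `mean`, `sd`, `n_flagged`.
#' @export
timeseries_accuracy <- function(original, reconstructed, mask, mesh) {
  stopifnot(inherits(original, "bold_run"), inherits(reconstructed, "bold_run"))
  if (!all(dim(original$data) == dim(reconstructed$data)))
    stop_arg("original and reconstructed runs differ in shape")
  rows <- mask_run_rows(mask, mesh)
  r <- rowwise_cor(original$data[rows, , drop = FALSE],
                   reconstructed$data[rows, , drop = FALSE])
  n_flagged <- sum(is.na(r))
  r[is.na(r)] <- 0
  list(r = r, mean = mean(r), sd = stats::sd(r), n_flagged = n_flagged)
}

#' Seed-based Fisher-z functional connectivity map
#'
#' Pearson correlation of the seed vertex's series against every vertex in
#' both hemispheres, clipped to `±(1 - 1e-7)` and Fisher-transformed
#' (`z = atanh(r)`). The self-entry is retained in the vector but excluded
#' from all downstream similarity computations.
#'
#' @param run a `bold_run` with at least 3 frames.
#' @param seed 1-based seed vertex index (into the `2V` run rows).
#' @return an object of class `fc_map`: list with `seed`, `z` (length `2V`),
#'   `n_vertices`.
#' @export
fc_map <- function(run, seed) {
  stopifnot(inherits(run, "bold_run"))
  x <- run$data
  if (ncol(x) < 3L) stop_arg("FC needs >= 3 frames")
  seed <- check_count(seed, "seed", lower = 1L)
  if (seed > nrow(x)) stop_arg("seed index out of range")
  s <- x[seed, ]
  if (stats::sd(s) == 0) stop_arg("degenerate seed: zero-variance series")
  sc <- s - mean(s)
  xc <- x - rowMeans(x)
  den <- sqrt(rowSums(xc * xc)) * sqrt(sum(sc * sc))
  r <- as.numeric(xc %*% sc)
  r <- ifelse(den > 0, r / den, 0)
  z <- atanh(clip_cor(r))
  structure(list(seed = seed, z = z, n_vertices = nrow(x)), class = "fc_map")
}

#' Similarity between two FC maps
#'
#' Pearson correlation of the Fisher-z vectors over all vertices except the
#' seed and any explicitly excluded set.
#'
#' @param map_a,map_b `fc_map`s with the same seed and vertex count.
#' @param exclude optional vertex indices to drop from the comparison.
#' @return Pearson correlation (scalar).
#' @export
fc_accuracy <- function(map_a, map_b, exclude = integer(0)) {
  stopifnot(inherits(map_a, "fc_map"), inherits(map_b, "fc_map"))
  if (map_a$seed != map_b$seed) stop_arg("FC maps have different seeds")
  if (map_a$n_vertices != map_b$n_vertices)
    stop_arg("FC maps cover different vertex counts")
  keep <- setdiff(seq_len(map_a$n_vertices), c(map_a$seed, exclude))
  stats::cor(map_a$z[keep], map_b$z[keep])
}

# FC maps for every seed in a vertex set; returns z matrix (2V x n_seeds)
fc_maps_for_seeds <- function(run, seeds) {
  vapply(seeds, function(s) fc_map(run, s)$z, numeric(nrow(run$data)))
}

# mean over seed vertices of the FC-vector correlation between two z matrices
mean_fc_similarity <- function(za, zb, seeds, n_vertices) {
  vals <- vapply(seq_along(seeds), function(j) {
    keep <- setdiff(seq_len(n_vertices), seeds[j])
    stats::cor(za[keep, j], zb[keep, j])
  }, numeric(1))
  mean(vals)
}

#' Most similar individual (MSI)
#'
#' For each training subject, averages over the masked seed vertices the
#' correlation between the test subject's FC vectors and the training
#' subject's; returns the arg-max subject. Ties break to the lowest subject
#' index.
#'
#' @param test_run the test subject's `bold_run`.
#' @param training_runs list of training subjects' `bold_run`s.
#' @param seeds vertex indices (into `2V` rows) of the combined mask set.
#' @return list with `msi` (training subject index), `similarity` (its mean
#'   correlation), and `all` (per-training-subject similarity).
#' @export
msi <- function(test_run, training_runs, seeds) {
  if (length(seeds) == 0L) stop_arg("empty mask seed set")
  if (length(training_runs) == 0L) stop_arg("need at least one training subject")
  z_test <- fc_maps_for_seeds(test_run, seeds)
  nv <- nrow(test_run$data)
  sims <- vapply(training_runs, function(tr) {
    z_tr <- fc_maps_for_seeds(tr, seeds)
    mean_fc_similarity(z_test, z_tr, seeds, nv)
  }, numeric(1))
  best <- which.max(sims)  # which.max takes the first (lowest index) on ties
  list(msi = best, similarity = sims[best], all = sims)
}

#' Specificity of reconstructed connectivity
#'
#' Per test subject, mean over masked seed vertices of the correlation
#' between the reconstructed FC map and (i) the subject's own original FC
#' map, (ii) the training-cohort group-average FC map (mean of the training
#' subjects' Fisher-z maps), and (iii) the most similar training individual's
#' FC map. A subject-specific reconstruction shows own > group-average.
#'
#' @param originals list of test subjects' original `bold_run`s.
#' @param reconstructions list of matching reconstructed `bold_run`s.
#' @param training_runs list of training subjects' `bold_run`s.
#' @param seeds vertex indices of the combined mask set.
#' @param ci_seed seed of the bootstrap confidence intervals.
#' @return an object of class `specificity_report`: per-subject triple plus
#'   means, sds and 95% bootstrap CIs.
#' @export
specificity_analysis <- function(originals, reconstructions, training_runs,
                                 seeds, ci_seed = 1L) {
  stopifnot(length(originals) == length(reconstructions))
  nv <- nrow(originals[[1]]$data)
  z_train <- lapply(training_runs, fc_maps_for_seeds, seeds = seeds)
  z_group <- Reduce(`+`, z_train) / length(z_train)
  rows <- lapply(seq_along(originals), function(i) {
    z_rec <- fc_maps_for_seeds(reconstructions[[i]], seeds)
    z_orig <- fc_maps_for_seeds(originals[[i]], seeds)
    own <- mean_fc_similarity(z_rec, z_orig, seeds, nv)
    grp <- mean_fc_similarity(z_rec, z_group, seeds, nv)
    sims <- vapply(z_train, function(zt) mean_fc_similarity(z_rec, zt, seeds, nv),
                   numeric(1))
    c(own = own, group = grp, msi = max(sims), msi_id = which.max(sims))
  })
  tab <- do.call(rbind, rows)
  mk_ci <- function(col, k) bootstrap_ci_mean(tab[, col], seed = derive_seed(ci_seed, k))
  structure(
    list(per_subject = tab,
         mean = colMeans(tab[, 1:3, drop = FALSE]),
         sd = apply(tab[, 1:3, drop = FALSE], 2, stats::sd),
         ci = rbind(own = mk_ci("own", 1L), group = mk_ci("group", 2L),
                    msi = mk_ci("msi", 3L)),
         diff_own_group = mean(tab[, "own"] - tab[, "group"]),
         diff_ci = bootstrap_ci_mean(tab[, "own"] - tab[, "group"],
                                     seed = derive_seed(ci_seed, 4L))),
    class = "specificity_report"
  )
}

#' @export
print.specificity_report <- function(x, ...) {
  cat("specificity_report (mean FC-map similarity of reconstructions):\n")
  cat(sprintf("  vs own original:   %.3f +/- %.3f\n", x$mean["own"], x$sd["own"]))
  cat(sprintf("  vs group average:  %.3f +/- %.3f\n", x$mean["group"], x$sd["group"]))
  cat(sprintf("  vs MSI:            %.3f +/- %.3f\n", x$mean["msi"], x$sd["msi"]))
  cat(sprintf("  own - group: %.3f (95%% CI %.3f..%.3f)\n",
              x$diff_own_group, x$diff_ci["lower"], x$diff_ci["upper"]))
  invisible(x)
}

#' Amplitude recovery relative to a reference run
#'
#' `100 * (mean over masked vertices of mean |amplitude| in other) /
#' (the same quantity in pre)`.
#'
#' @param pre reference `bold_run` (e.g. pre-operative).
#' @param other comparison `bold_run`.
#' @param mask a `region_mask`.
#' @param mesh the template `cortical_mesh`.
#' @return percentage (scalar).
#' @export
amplitude_recovery <- function(pre, other, mask, mesh) {
  stopifnot(inherits(pre, "bold_run"), inherits(other, "bold_run"))
  rows <- mask_run_rows(mask, mesh)
  ref <- mean(rowMeans(abs(pre$data[rows, , drop = FALSE])))
  if (ref == 0) stop_arg("degenerate reference: zero pre-amplitude in region")
  100 * mean(rowMeans(abs(other$data[rows, , drop = FALSE]))) / ref
}

#' Reconstruction accuracy as a function of mask size
#'
#' For each center x fraction, grows a geodesic mask, zeroes it, reconstructs
#' with the GAN (or diffusion), and computes the mean within-mask FC-map
#' similarity to the original run. Returns the per-fraction mean and sd over
#' centers.
#'
#' @param model a trained `gan_model` (ignored for `method = "diffusion"`).
#' @param run the original `bold_run` (normalized for the GAN route).
#' @param mesh the template `cortical_mesh`.
#' @param map the `vertex_pixel_map` (GAN route).
#' @param centers vertex indices serving as mask centers.
#' @param fractions mask coverages, default `seq(0.1, 0.6, by = 0.1)`.
#' @param search a [latent_search_spec()] (GAN route).
#' @param method `"gan"` or `"diffusion"`.
#' @return data.frame with `fraction`, `mean_fc_r`, `sd_fc_r`.
#' @export
mask_size_sweep <- function(model, run, mesh, map, centers,
                            fractions = seq(0.1, 0.6, by = 0.1),
                            search = latent_search_spec(),
                            method = c("gan", "diffusion")) {
  method <- match.arg(method)
  if (any(fractions <= 0 | fractions > 1))
    stop_arg("fractions must lie in (0, 1]")
  acc <- matrix(NA_real_, length(centers), length(fractions))
  for (ci in seq_along(centers)) {
    for (fi in seq_along(fractions)) {
      mask <- geodesic_mask(mesh, centers[ci], fractions[fi])
      compromised <- make_compromised(run, mask, mesh)
      rec <- if (method == "gan") {
        reconstruct_run_gan(model, compromised, mask, map, mesh, search)
      } else {
        reconstruct_diffusion(compromised, mask, mesh)
      }
      seeds <- mask_run_rows(mask, mesh)
      acc[ci, fi] <- tryCatch({
        z_orig <- fc_maps_for_seeds(run, seeds)
        z_rec <- fc_maps_for_seeds(rec$run, seeds)
        mean_fc_similarity(z_orig, z_rec, seeds, nrow(run$data))
      }, error = function(e) {
        warning("FC accuracy undefined at center ", centers[ci], ", fraction ",
                fractions[fi], ": ", conditionMessage(e), call. = FALSE)
        NA_real_
      })
    }
  }
  data.frame(fraction = fractions,
             mean_fc_r = colMeans(acc),
             sd_fc_r = apply(acc, 2, stats::sd))
}
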