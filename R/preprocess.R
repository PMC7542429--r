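# Preprocessing arithmetic: session normalization to [-1,1], global signal
# regression, block temporal smoothing, and temporal signal-to-noise ratio.

#' Normalize a session to unit range
#'
#' Divides every value by the single session-wide maximum absolute value
#' (one scalar per run), bringing the run into `[-1, 1]` — the input range
#' the generative model is trained on — while preserving the spatial
#' amplitude pattern within each frame. Idempotent.
#'
#' @param run a `bold_run`.
#' @return the run with values scaled and `state = "unit"`.
#' @export
normalize_session <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  m <- max(abs(run$data))
  if (!is.finite(m) || m == 0) stop_arg("degenerate session: all values zero")
  run$data <- run$data / m
  run$state <- "unit"
  run
}

#' Regress out the global signal
#'
#' For each vertex, removes the least-squares projection of its time series
#' onto an intercept and the global mean time course (mean over all vertices,
#' both hemispheres). The residual series are orthogonal to the global
#' course. A linear projection: applying it twice equals applying it once.
#'
#' @param run a `bold_run` with at least 3 frames.
#' @return the run with residual series in `data`.
#' @export
regress_global_signal <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  x <- run$data
  if (ncol(x) < 3L) stop_arg("global signal regression needs >= 3 frames")
  g <- colMeans(x)
  if (stats::sd(g) < 1e-12) {
    # an (almost) zero global course means the run is already global-mean
    # free (e.g. GSR applied twice); a constant nonzero course is degenerate
    if (mean(abs(g)) > 1e-10)
      stop_arg("degenerate regressor: global signal is constant")
    run$data <- x - rowMeans(x)
    return(run)
  }
  q <- qr(cbind(1, g))
  run$data <- t(qr.resid(q, t(x)))
  run
}

#' Temporal smoothing by block averaging
#'
#' Averages non-overlapping blocks of `window` consecutive frames (default 4,
#' the smoothing used to trade temporal resolution for temporal
#' signal-to-noise); output length is `floor(T / window)`, the trailing
#' partial block is dropped. TR is scaled accordingly.
#'
#' @param run a `bold_run`.
#' @param window block length in frames, `>= 1`.
#' @return the run with `floor(T/window)` frames.
#' @export
temporal_smooth <- function(run, window = 4L) {
  stopifnot(inherits(run, "bold_run"))
  window <- check_count(window, "window", lower = 1L)
  x <- run$data
  t_out <- ncol(x) %/% window
  if (t_out < 1L) stop_arg("run shorter than the smoothing window")
  if (window == 1L) return(run)
  keep <- x[, seq_len(t_out * window), drop = FALSE]
  blocks <- (outer(seq_len(t_out * window), seq_len(t_out),
                   function(i, j) (i - 1) %/% window + 1 == j)) / window
  run$data <- keep %*% blocks
  run$tr <- run$tr * window
  run
}

#' Temporal signal-to-noise ratio
#'
#' Per-vertex tSNR = 1 / (sample standard deviation of that vertex's series);
#' the summary is the mean over vertices. Zero-variance vertices are excluded
#' from the mean and counted in `n_excluded`.
#'
#' @param run a `bold_run` with at least 2 frames.
#' @return an object of class `tsnr_summary`: list with `per_vertex`
#'   (`NA` for excluded vertices), `mean`, and `n_excluded`.
#' @export
tsnr <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  x <- run$data
  if (ncol(x) < 2L) stop_arg("tSNR needs >= 2 frames")
  sds <- sqrt(rowSums((x - rowMeans(x))^2) / (ncol(x) - 1))
  per_vertex <- ifelse(sds > 0, 1 / sds, NA_real_)
  n_excluded <- sum(sds == 0)
  if (n_excluded > 0)
    warning(n_excluded, " zero-variance vertices excluded from tSNR mean")
  structure(list(per_vertex = per_vertex,
                 mean = mean(per_vertex, na.rm = TRUE),
                 n_excluded = n_excluded),
            class = "tsnr_summary")
}

#' @export
print.tsnr_summary <- function(x, ...) {
  cat(sprintf("tsnr_summary: mean %.4g over %d vertices (%d excluded)\n",
              x$mean, sum(is.finite(x$per_vertex)), x$n_excluded))
  invisible(x)
}

#' Mean tSNR over the runs of a cohort
#'
#' @param cohort a `bold_cohort`.
#' @param normalize normalize each session to unit range first (default
#'   `TRUE`, matching tSNR computed after preprocessing); set `FALSE` for raw
#'   amplitude units.
#' @param window optional temporal smoothing window applied first
#'   (`NULL` = none).
#' @return mean over runs and subjects of each run's vertex-mean tSNR.
#' @export
cohort_tsnr <- function(cohort, normalize = TRUE, window = NULL) {
  stopifnot(inherits(cohort, "bold_cohort"))
  vals <- unlist(lapply(cohort$runs, function(subject_runs) {
    vapply(subject_runs, function(r) {
      if (normalize) r <- normalize_session(r)
      if (!is.null(window)) r <- temporal_smooth(r, window)
      tsnr(r)$mean
    }, numeric(1))
  }))
  mean(vals)
}
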