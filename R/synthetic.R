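# Synthetic surface-BOLD cohorts.
#
# The generator emulates the statistical structure the reconstruction method
# relies on in real resting-state data: a shared network parcellation, stable
# per-subject functional connectivity with individual-specific variation
# (perturbed loading matrices, so "most similar individual" has a continuous
# ground truth), temporally autocorrelated network time courses (AR(1)), and
# additive white measurement noise. Runs stack left-hemisphere vertices
# (1..V) above right-hemisphere vertices (V+1..2V) on the shared template.

#' Specify a synthetic cohort
#'
#' Defaults follow the study layout the package is exercised against:
#' 240 frames per run at TR = 3 s, network-structured signal with AR(1)
#' temporal autocorrelation (phi = 0.4), within-network vertex loading 0.9,
#' white-noise standard deviation 0.8 (within-network vertex-pair correlation
#' about 0.6, typical of clean resting-state surface data), and
#' individual-variation magnitude 0.25 on the loading matrix.
#'
#' @param n_subjects number of subjects.
#' @param n_frames frames per run (default 240).
#' @param tr frame interval in seconds (default 3).
#' @param n_parcels parcels per hemisphere (default 6); parcels are
#'   edge-connected and partition each hemisphere.
#' @param n_networks number of networks the parcels are assigned to
#'   (default 3); networks span both hemispheres.
#' @param loading within-network vertex loading in `[0, 1]` (default 0.9).
#' @param indiv_sd standard deviation of the per-subject perturbation of the
#'   loading matrix — the individual fingerprint magnitude (default 0.25).
#' @param ar_phi AR(1) coefficient of the network time courses, in `[0, 1)`
#'   (default 0.4).
#' @param noise_sd white measurement-noise standard deviation (default 0.8).
#' @param seed master seed; all subject- and run-level draws derive from it
#'   via [derive_seed()] so cohorts are extensible without reshuffling.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20L, n_frames = 240L, tr = 3,
                        n_parcels = 6L, n_networks = 3L,
                        loading = 0.9, indiv_sd = 0.25,
                        ar_phi = 0.4, noise_sd = 0.8, seed = 1L) {
  n_subjects <- check_count(n_subjects, "n_subjects", lower = 1L)
  n_frames <- check_count(n_frames, "n_frames", lower = 2L)
  check_scalar_number(tr, "tr", lower = 1e-9)
  n_parcels <- check_count(n_parcels, "n_parcels", lower = 1L)
  n_networks <- check_count(n_networks, "n_networks", lower = 1L)
  if (n_parcels %% n_networks != 0L)
    stop_arg("n_parcels must be divisible by n_networks")
  check_scalar_number(loading, "loading", lower = 0, upper = 1)
  check_scalar_number(indiv_sd, "indiv_sd", lower = 0)
  check_scalar_number(ar_phi, "ar_phi", lower = 0, upper = 1 - 1e-9)
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  structure(
    list(n_subjects = n_subjects, n_frames = n_frames, tr = as.numeric(tr),
         n_parcels = n_parcels, n_networks = n_networks, loading = loading,
         indiv_sd = indiv_sd, ar_phi = ar_phi, noise_sd = noise_sd,
         seed = check_count(seed, "seed")),
    class = "cohort_spec"
  )
}

# edge-connected partition of one hemisphere into P parcels: seeded k-means on
# vertex coordinates, then reassignment of any vertex disconnected from its
# parcel's main component to a neighboring parcel (deterministic)
parcellate_hemisphere <- function(mesh, n_parcels, seed) {
  set.seed(seed)
  km <- stats::kmeans(mesh$vertices, centers = n_parcels, nstart = 5,
                      iter.max = 200, algorithm = "Lloyd")
  assign <- km$cluster
  # enforce edge-connectedness of each parcel
  repeat {
    changed <- FALSE
    for (p in seq_len(n_parcels)) {
      members <- which(assign == p)
      if (length(members) == 0L) next
      # BFS over parcel-internal edges from the lowest-index member
      comp <- logical(length(assign))
      comp[members[1]] <- TRUE
      frontier <- members[1]
      while (length(frontier)) {
        nb <- unique(unlist(mesh$adjacency[frontier], use.names = FALSE))
        nb <- nb[assign[nb] == p & !comp[nb]]
        comp[nb] <- TRUE
        frontier <- nb
      }
      stray <- members[!comp[members]]
      for (s in stray) {
        nb_parcels <- assign[mesh$adjacency[[s]]]
        nb_parcels <- nb_parcels[nb_parcels != p]
        if (length(nb_parcels)) {
          assign[s] <- min(nb_parcels)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  assign
}

# group-template loading matrix over both hemispheres (2V x N)
template_loadings <- function(mesh, spec) {
  v <- n_vertices(mesh)
  assign_lh <- parcellate_hemisphere(mesh, spec$n_parcels, derive_seed(spec$seed, 101L))
  assign_rh <- parcellate_hemisphere(mesh, spec$n_parcels, derive_seed(spec$seed, 102L))
  # parcels cycle through networks so each network spans both hemispheres
  network_of_parcel <- ((seq_len(spec$n_parcels) - 1L) %% spec$n_networks) + 1L
  w <- matrix(0, 2L * v, spec$n_networks)
  w[cbind(seq_len(v), network_of_parcel[assign_lh])] <- spec$loading
  w[cbind(v + seq_len(v), network_of_parcel[assign_rh])] <- spec$loading
  list(loadings = w,
       parcel = c(assign_lh, assign_rh),
       network = network_of_parcel)
}

subject_loadings <- function(template, spec, subject) {
  set.seed(derive_seed(spec$seed, 200L, subject))
  template$loadings + spec$indiv_sd *
    matrix(stats::rnorm(length(template$loadings)), nrow(template$loadings))
}

# AR(1) courses with unit innovation variance, stationary start
ar1_courses <- function(n_networks, n_frames, phi, seed) {
  set.seed(seed)
  eta <- matrix(stats::rnorm(n_networks * n_frames), n_networks, n_frames)
  if (phi > 0) {
    eta[, 1] <- eta[, 1] / sqrt(1 - phi^2)
    for (t in 2:n_frames) eta[, t] <- phi * eta[, t - 1] + eta[, t]
  }
  eta
}

new_bold_run <- function(subject, data, tr, state = "raw") {
  structure(list(subject = subject, data = data, tr = tr, state = state),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("bold_run: subject %s, %d vertices x %d frames, TR %.3g s, %s\n",
              as.character(x$subject), nrow(x$data), ncol(x$data), x$tr, x$state))
  invisible(x)
}

simulate_run <- function(w, spec, run_seed) {
  eta <- ar1_courses(spec$n_networks, spec$n_frames, spec$ar_phi,
                     derive_seed(run_seed, 1L))
  set.seed(derive_seed(run_seed, 2L))
  noise <- spec$noise_sd * matrix(stats::rnorm(nrow(w) * spec$n_frames),
                                  nrow(w), spec$n_frames)
  w %*% eta + noise
}

# closed-form ground-truth correlation implied by loadings w under the model
truth_fc_from_loadings <- function(w, spec) {
  var_eta <- if (spec$ar_phi > 0) 1 / (1 - spec$ar_phi^2) else 1
  cov <- var_eta * tcrossprod(w)
  diag(cov) <- diag(cov) + spec$noise_sd^2
  stats::cov2cor(cov)
}

#' Generate a synthetic surface-BOLD cohort
#'
#' Runs the generative model: (i) parcellate each hemisphere by seeded
#' k-means on vertex coordinates with connectivity repair; (ii) per subject,
#' draw network loading weights = group template + subject-seeded Gaussian
#' perturbation scaled by `indiv_sd`; (iii) simulate network time courses as
#' AR(1) with unit innovation variance; (iv) vertex signal = loadings x
#' courses + white noise. Bit-reproducible from the master seed; runs of one
#' subject share that subject's loadings.
#'
#' @param spec a [cohort_spec()].
#' @param mesh the template `cortical_mesh` (shared by both hemispheres).
#' @param runs_per_subject number of runs per subject (default 1).
#' @param return_truth if `TRUE` (default), include per-subject ground-truth
#'   FC matrices (closed form under the generative model).
#' @return an object of class `bold_cohort`: list with `runs` (list of lists
#'   of `bold_run`, one inner list per subject), `fc_truth` (list of 2V x 2V
#'   correlation matrices or `NULL`), `loadings` (list of 2V x N fingerprint
#'   matrices), `parcel` (parcel assignment over 2V vertices), `spec`, `mesh`.
#' @examples
#' co <- make_cohort(cohort_spec(n_subjects = 2, n_frames = 40),
#'                   build_icosphere(1))
#' dim(co$runs[[1]][[1]]$data)  # 84 x 40
#' @export
make_cohort <- function(spec, mesh, runs_per_subject = 1L, return_truth = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(mesh, "cortical_mesh"))
  runs_per_subject <- check_count(runs_per_subject, "runs_per_subject", lower = 1L)
  template <- template_loadings(mesh, spec)
  runs <- vector("list", spec$n_subjects)
  loadings <- vector("list", spec$n_subjects)
  fc_truth <- if (return_truth) vector("list", spec$n_subjects) else NULL
  for (s in seq_len(spec$n_subjects)) {
    w <- subject_loadings(template, spec, s)
    loadings[[s]] <- w
    if (return_truth) fc_truth[[s]] <- truth_fc_from_loadings(w, spec)
    runs[[s]] <- lapply(seq_len(runs_per_subject), function(k) {
      new_bold_run(sprintf("sub-%03d", s),
                   simulate_run(w, spec, derive_seed(spec$seed, 300L, s, k)),
                   spec$tr)
    })
  }
  structure(
    list(runs = runs, fc_truth = fc_truth, loadings = loadings,
         parcel = template$parcel, network = template$network,
         spec = spec, mesh = mesh),
    class = "bold_cohort"
  )
}

#' @export
print.bold_cohort <- function(x, ...) {
  cat(sprintf("bold_cohort: %d subjects x %d run(s), %d vertices x %d frames\n",
              x$spec$n_subjects, length(x$runs[[1]]),
              nrow(x$runs[[1]][[1]]$data), x$spec$n_frames))
  invisible(x)
}

#' Simulate a pre/post implantation run pair with regional signal loss
#'
#' Generates two runs sharing one subject fingerprint. In the post run the
#' structured (network) signal inside `attenuation_region` is multiplied by
#' `attenuation_factor` and the noise there is refreshed at standard deviation
#' `sqrt(1 - attenuation_factor^2) * noise_sd`, so at factor 0 the region
#' carries pure noise at the model's noise variance and functional
#' connectivity inside the region degrades with the factor. Outside the
#' region both runs follow the same ground-truth FC.
#'
#' @param spec a [cohort_spec()] (its first subject's fingerprint is used).
#' @param mesh the template `cortical_mesh`.
#' @param attenuation_region a `region_mask` marking the affected vertices.
#' @param attenuation_factor multiplier on the structured signal inside the
#'   region, in `[0, 1)`.
#' @return list with `pre` and `post` (`bold_run`s), `region_rows` (row
#'   indices into the run matrices), and `loadings`.
#' @export
make_dbs_pair <- function(spec, mesh, attenuation_region, attenuation_factor) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(mesh, "cortical_mesh"),
            inherits(attenuation_region, "region_mask"))
  check_scalar_number(attenuation_factor, "attenuation_factor", lower = 0)
  if (attenuation_factor >= 1)
    stop_arg("attenuation_factor must be < 1")
  rows <- mask_run_rows(attenuation_region, mesh)
  if (length(rows) == 0L) stop_arg("attenuation region is empty")
  template <- template_loadings(mesh, spec)
  w <- subject_loadings(template, spec, 1L)
  pre <- new_bold_run("sub-001", simulate_run(w, spec, derive_seed(spec$seed, 400L, 1L)),
                      spec$tr)
  # post run: fresh courses/noise, same fingerprint
  eta <- ar1_courses(spec$n_networks, spec$n_frames, spec$ar_phi,
                     derive_seed(spec$seed, 401L, 1L))
  set.seed(derive_seed(spec$seed, 402L, 1L))
  noise <- spec$noise_sd * matrix(stats::rnorm(nrow(w) * spec$n_frames),
                                  nrow(w), spec$n_frames)
  post_data <- w %*% eta + noise
  f <- attenuation_factor
  set.seed(derive_seed(spec$seed, 403L, 1L))
  fresh <- matrix(stats::rnorm(length(rows) * spec$n_frames),
                  length(rows), spec$n_frames)
  post_data[rows, ] <- f * (w[rows, , drop = FALSE] %*% eta) +
    sqrt(1 - f^2) * spec$noise_sd * fresh
  list(pre = pre,
       post = new_bold_run("sub-001", post_data, spec$tr),
       region_rows = rows, loadings = w)
}
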