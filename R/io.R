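# Cohort storage and GIFTI import/export.
#
# The canonical interchange is a versioned directory layout: a JSON manifest
# (spec, mesh level, layout version, creating command) plus one RDS matrix
# per run and per ground-truth object — lossless and R-native. GIFTI
# (ASCII-encoded XML) is provided for exchanging single runs, masks and
# surfaces with surface-analysis tool chains.

COHORT_LAYOUT_VERSION <- "1"

#' Write a cohort to the documented directory layout
#'
#' Creates `path/manifest.json` plus `path/sub-XXX/run-K.rds`,
#' `fc_truth.rds` and `loadings.rds` per subject. The manifest records the
#' layout version, the generating spec and the mesh level, so the cohort can
#' be re-read (or regenerated) exactly.
#'
#' @param cohort a `bold_cohort`.
#' @param path target directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "bold_cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    layout_version = COHORT_LAYOUT_VERSION,
    created_by = "boldpatch::write_cohort",
    spec = unclass(cohort$spec),
    mesh_level = cohort$mesh$level,
    n_subjects = cohort$spec$n_subjects,
    runs_per_subject = length(cohort$runs[[1]]),
    has_truth = !is.null(cohort$fc_truth)
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(cohort$parcel, file.path(path, "parcel.rds"))
  saveRDS(cohort$network, file.path(path, "network.rds"))
  for (s in seq_along(cohort$runs)) {
    sdir <- file.path(path, sprintf("sub-%03d", s))
    dir.create(sdir, showWarnings = FALSE)
    for (k in seq_along(cohort$runs[[s]])) {
      saveRDS(cohort$runs[[s]][[k]], file.path(sdir, sprintf("run-%d.rds", k)))
    }
    if (!is.null(cohort$fc_truth))
      saveRDS(cohort$fc_truth[[s]], file.path(sdir, "fc_truth.rds"))
    saveRDS(cohort$loadings[[s]], file.path(sdir, "loadings.rds"))
  }
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path cohort directory.
#' @return a `bold_cohort`.
#' @export
read_cohort <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop_arg("no cohort manifest at ", mf)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(as.character(manifest$layout_version), COHORT_LAYOUT_VERSION))
    stop_arg("unsupported cohort layout version '", manifest$layout_version,
             "' (this build reads version ", COHORT_LAYOUT_VERSION, ")")
  spec <- do.call(cohort_spec, manifest$spec[names(formals(cohort_spec))])
  mesh <- build_icosphere(manifest$mesh_level)
  runs <- vector("list", manifest$n_subjects)
  loadings <- vector("list", manifest$n_subjects)
  fc_truth <- if (isTRUE(manifest$has_truth)) vector("list", manifest$n_subjects) else NULL
  for (s in seq_len(manifest$n_subjects)) {
    sdir <- file.path(path, sprintf("sub-%03d", s))
    runs[[s]] <- lapply(seq_len(manifest$runs_per_subject), function(k)
      readRDS(file.path(sdir, sprintf("run-%d.rds", k))))
    loadings[[s]] <- readRDS(file.path(sdir, "loadings.rds"))
    if (!is.null(fc_truth))
      fc_truth[[s]] <- readRDS(file.path(sdir, "fc_truth.rds"))
  }
  structure(
    list(runs = runs, fc_truth = fc_truth, loadings = loadings,
         parcel = readRDS(file.path(path, "parcel.rds")),
         network = readRDS(file.path(path, "network.rds")),
         spec = spec, mesh = mesh),
    class = "bold_cohort"
  )
}

# ---- GIFTI --------------------------------------------------------------

gifti_data_array <- function(doc, values, intent, datatype, dims) {
  da <- xml2::xml_add_child(doc, "DataArray",
    Intent = intent, DataType = datatype,
    ArrayIndexingOrder = "RowMajorOrder",
    Dimensionality = as.character(length(dims)),
    Encoding = "ASCII", Endian = "LittleEndian",
    ExternalFileName = "", ExternalFileOffset = "")
  for (i in seq_along(dims))
    xml2::xml_attr(da, paste0("Dim", i - 1L)) <- as.character(dims[i])
  fmt <- if (datatype == "NIFTI_TYPE_INT32") "%d" else "%.9g"
  xml2::xml_add_child(da, "Data", paste(sprintf(fmt, values), collapse = " "))
  invisible(da)
}

#' Export a run (or any vertices x time matrix) as a GIFTI functional file
#'
#' One ASCII-encoded `NIFTI_INTENT_TIME_SERIES` data array per frame
#' (values stored at float32-like precision, 9 significant digits).
#'
#' @param run a `bold_run` or a numeric matrix (vertices x time).
#' @param path output `.func.gii` path.
#' @return `path`, invisibly.
#' @export
write_gifti_func <- function(run, path) {
  x <- if (inherits(run, "bold_run")) run$data else as.matrix(run)
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = as.character(ncol(x)))
  for (t in seq_len(ncol(x)))
    gifti_data_array(doc, x[, t], "NIFTI_INTENT_TIME_SERIES",
                     "NIFTI_TYPE_FLOAT32", nrow(x))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a GIFTI functional file written by [write_gifti_func()]
#'
#' @param path `.func.gii` path.
#' @return numeric matrix (vertices x time).
#' @export
read_gifti_func <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  cols <- lapply(arrays, function(da) {
    txt <- xml2::xml_text(xml2::xml_find_first(da, ".//Data"))
    as.numeric(strsplit(trimws(txt), "\\s+")[[1]])
  })
  do.call(cbind, cols)
}

#' Export a mesh as a GIFTI surface file
#'
#' Pointset (vertex coordinates) and triangle (0-based face indices) arrays,
#' ASCII-encoded.
#'
#' @param mesh a `cortical_mesh`.
#' @param path output `.surf.gii` path.
#' @return `path`, invisibly.
#' @export
write_gifti_surface <- function(mesh, path) {
  stopifnot(inherits(mesh, "cortical_mesh"))
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0", NumberOfDataArrays = "2")
  gifti_data_array(doc, as.numeric(t(mesh$vertices)), "NIFTI_INTENT_POINTSET",
                   "NIFTI_TYPE_FLOAT32", dim(mesh$vertices))
  gifti_data_array(doc, as.integer(t(mesh$faces)) - 1L, "NIFTI_INTENT_TRIANGLE",
                   "NIFTI_TYPE_INT32", dim(mesh$faces))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Export a region mask as a GIFTI label file
#'
#' Per-vertex 0/1 labels (1 = compromised), ASCII-encoded.
#'
#' @param mask a `region_mask`.
#' @param path output `.label.gii` path.
#' @return `path`, invisibly.
#' @export
write_gifti_label <- function(mask, path) {
  stopifnot(inherits(mask, "region_mask"))
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0", NumberOfDataArrays = "1")
  gifti_data_array(doc, as.integer(mask$mask), "NIFTI_INTENT_LABEL",
                   "NIFTI_TYPE_INT32", length(mask$mask))
  xml2::write_xml(doc, path)
  invisible(path)
}
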