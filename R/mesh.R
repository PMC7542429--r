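# Icosphere surface substrate.
#
# The cortical template used downstream is a subdivided icosahedron: the
# level-4 sphere has 2562 vertices per hemisphere, the resolution the BOLD
# data are sampled at after downsampling. Levels 0-3 give 12/42/162/642
# vertices and serve as desk-scale stand-ins.

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  list(vertices = v, faces = f)
}

# one 4-to-1 subdivision step; midpoint vertices are shared across faces
subdivide_once <- function(vertices, faces) {
  nv <- nrow(vertices)
  e1 <- cbind(faces[, 1], faces[, 2])
  e2 <- cbind(faces[, 2], faces[, 3])
  e3 <- cbind(faces[, 3], faces[, 1])
  edges <- rbind(e1, e2, e3)
  key <- pmin(edges[, 1], edges[, 2]) * (nv + 1) + pmax(edges[, 1], edges[, 2])
  ukey <- unique(key)
  mid_id <- nv + match(key, ukey)
  ue <- edges[match(ukey, key), , drop = FALSE]
  mids <- (vertices[ue[, 1], , drop = FALSE] + vertices[ue[, 2], , drop = FALSE]) / 2
  mids <- mids / sqrt(rowSums(mids^2))
  nf <- nrow(faces)
  m12 <- mid_id[seq_len(nf)]
  m23 <- mid_id[nf + seq_len(nf)]
  m31 <- mid_id[2 * nf + seq_len(nf)]
  new_faces <- rbind(
    cbind(faces[, 1], m12, m31),
    cbind(faces[, 2], m23, m12),
    cbind(faces[, 3], m31, m23),
    cbind(m12, m23, m31)
  )
  list(vertices = rbind(vertices, mids), faces = new_faces)
}

#' Build an icosphere hemisphere template
#'
#' Constructs a closed triangulated sphere by recursive 4-to-1 subdivision of
#' the icosahedron, the substrate standing in for one registered cortical
#' hemisphere. Level `k` has `10 * 4^k + 2` vertices; level 4 reproduces the
#' 2562-vertex resolution of the downsampled surface template.
#'
#' @param level subdivision level, an integer in `[0, 6]`.
#' @param hemisphere hemisphere label, `"lh"` or `"rh"`.
#' @return an object of class `cortical_mesh`: a list with `hemisphere`,
#'   `vertices` (V x 3 unit-norm coordinates), `faces` (F x 3, 1-based),
#'   `adjacency` (list of neighbor index vectors) and `level`.
#' @examples
#' m <- build_icosphere(2)
#' n_vertices(m)  # 162
#' @export
build_icosphere <- function(level, hemisphere = c("lh", "rh")) {
  hemisphere <- match.arg(hemisphere)
  level <- check_count(level, "level")
  if (level > 6L) stop_arg("level must be <= 6 (10*4^6+2 = 40962 vertices)")
  ico <- icosahedron()
  for (i in seq_len(level)) ico <- subdivide_once(ico$vertices, ico$faces)
  v <- nrow(ico$vertices)
  edges <- unique(rbind(
    cbind(pmin(ico$faces[, 1], ico$faces[, 2]), pmax(ico$faces[, 1], ico$faces[, 2])),
    cbind(pmin(ico$faces[, 2], ico$faces[, 3]), pmax(ico$faces[, 2], ico$faces[, 3])),
    cbind(pmin(ico$faces[, 3], ico$faces[, 1]), pmax(ico$faces[, 3], ico$faces[, 1]))
  ))
  adj <- split(c(edges[, 2], edges[, 1]), factor(c(edges[, 1], edges[, 2]), levels = seq_len(v)))
  adj <- lapply(adj, function(x) sort(unname(x)))
  faces <- ico$faces
  storage.mode(faces) <- "integer"
  structure(
    list(hemisphere = hemisphere, vertices = ico$vertices, faces = faces,
         adjacency = adj, level = level),
    class = "cortical_mesh"
  )
}

#' @export
print.cortical_mesh <- function(x, ...) {
  cat(sprintf("cortical_mesh: level-%d icosphere, hemisphere %s\n  %d vertices, %d faces\n",
              x$level, x$hemisphere, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Number of vertices of a mesh
#' @param mesh a `cortical_mesh`.
#' @return integer vertex count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' Grow a geodesic region mask on a hemisphere mesh
#'
#' Grows an edge-connected region from a center vertex in breadth-first rings
#' over the mesh adjacency graph until `round(fraction * V)` vertices are
#' covered; within the last, partial ring vertices are admitted in ascending
#' vertex-index order, making the mask fully deterministic. Geodesic masks of
#' a given vertex count stand in for atlas-derived cortical regions with the
#' same coverage.
#'
#' @param mesh a `cortical_mesh`.
#' @param center 1-based center vertex index.
#' @param fraction target covered fraction of the hemisphere, in `(0, 1]`.
#' @return an object of class `region_mask`: list with `hemisphere`,
#'   `mask` (logical over the hemisphere's vertices), `fraction`
#'   (achieved covered fraction) and `center`.
#' @examples
#' m <- build_icosphere(2)
#' rm <- geodesic_mask(m, center = 1, fraction = 0.10)
#' sum(rm$mask)      # round(0.10 * 162) = 16
#' rm$fraction       # 16/162
#' @export
geodesic_mask <- function(mesh, center, fraction) {
  stopifnot(inherits(mesh, "cortical_mesh"))
  v <- n_vertices(mesh)
  center <- check_count(center, "center", lower = 1L)
  if (center > v) stop_arg("center must be a valid vertex index (1..", v, ")")
  check_scalar_number(fraction, "fraction")
  if (fraction <= 0 || fraction > 1) stop_arg("fraction must be in (0, 1]")
  target <- max(1L, as.integer(round(fraction * v)))
  selected <- logical(v)
  selected[center] <- TRUE
  n_sel <- 1L
  frontier <- center
  while (n_sel < target) {
    ring <- sort(unique(unlist(mesh$adjacency[frontier], use.names = FALSE)))
    ring <- ring[!selected[ring]]
    if (length(ring) == 0L) break  # cannot happen on a closed mesh before full cover
    take <- min(length(ring), target - n_sel)
    admitted <- ring[seq_len(take)]  # ascending index order within partial ring
    selected[admitted] <- TRUE
    n_sel <- n_sel + take
    frontier <- ring  # full ring defines the next frontier, keeping rings geodesic
  }
  structure(
    list(hemisphere = mesh$hemisphere, mask = selected,
         fraction = n_sel / v, center = center),
    class = "region_mask"
  )
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("region_mask: %d/%d vertices (%.1f%%) on hemisphere %s\n",
              sum(x$mask), length(x$mask), 100 * x$fraction, x$hemisphere))
  invisible(x)
}

#' Build a region mask from an explicit vertex set
#'
#' @param mesh a `cortical_mesh`.
#' @param vertices 1-based vertex indices to mark as compromised.
#' @return a `region_mask`.
#' @export
vertex_mask <- function(mesh, vertices) {
  stopifnot(inherits(mesh, "cortical_mesh"))
  v <- n_vertices(mesh)
  vertices <- as.integer(vertices)
  if (length(vertices) && (min(vertices) < 1L || max(vertices) > v))
    stop_arg("vertex indices out of range 1..", v)
  m <- logical(v)
  m[vertices] <- TRUE
  structure(list(hemisphere = mesh$hemisphere, mask = m,
                 fraction = sum(m) / v, center = NA_integer_),
            class = "region_mask")
}

#' Map a per-hemisphere mask to row indices of a two-hemisphere run matrix
#'
#' Runs stack the left hemisphere's vertices first (`1..V`) and the right
#' hemisphere's second (`V+1..2V`), both on the shared template mesh.
#'
#' @param mask a `region_mask`.
#' @param mesh the template `cortical_mesh` shared by both hemispheres.
#' @return integer row indices into the `2V x T` run matrix.
#' @export
mask_run_rows <- function(mask, mesh) {
  stopifnot(inherits(mask, "region_mask"), inherits(mesh, "cortical_mesh"))
  v <- n_vertices(mesh)
  if (length(mask$mask) != v) stop_arg("mask/mesh vertex counts differ")
  offset <- if (mask$hemisphere == "rh") v else 0L
  which(mask$mask) + offset
}

#' Write a region mask as a plain-text vertex list
#'
#' One 1-based vertex index per line, preceded by a `#` header carrying the
#' hemisphere label.
#' @param mask a `region_mask`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask_text <- function(mask, path) {
  stopifnot(inherits(mask, "region_mask"))
  writeLines(c(sprintf("# hemisphere=%s n=%d", mask$hemisphere, sum(mask$mask)),
               as.character(which(mask$mask))), path)
  invisible(path)
}

#' Read a region mask written by [write_mask_text()]
#' @param mesh the `cortical_mesh` the mask refers to.
#' @param path file path.
#' @return a `region_mask`.
#' @export
read_mask_text <- function(mesh, path) {
  lines <- readLines(path)
  header <- lines[1]
  hemi <- sub(".*hemisphere=(\\w+).*", "\\1", header)
  idx <- as.integer(lines[-1])
  out <- vertex_mask(mesh, idx)
  out$hemisphere <- hemi
  out
}
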