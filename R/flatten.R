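# Deterministic vertex <-> pixel flattening.
#
# Each hemisphere sphere is unrolled onto a raster by an azimuthal-equidistant
# projection from the north pole (polar angle maps to radius, azimuth to
# direction), scaled anisotropically so the disc fills the target rectangle.
# Rounding collisions are resolved by moving the later-indexed vertex to the
# nearest free pixel (deterministic outward spiral), so the assignment is a
# fixed bijection between vertices and covered pixels — the only property the
# inpainting method needs from a flattening.

# pixel offsets sorted by (distance, row, col), excluding (0,0)
spiral_offsets <- function(max_radius) {
  d <- -max_radius:max_radius
  g <- expand.grid(dr = d, dc = d)
  g <- g[!(g$dr == 0 & g$dc == 0), ]
  dist <- g$dr^2 + g$dc^2
  g <- g[order(dist, g$dr, g$dc), ]
  as.matrix(g)
}

#' Flatten a hemisphere mesh onto a pixel raster
#'
#' Assigns every vertex a distinct pixel through an azimuthal-equidistant
#' projection from the pole, rounded to the grid; colliding vertices (the
#' later-indexed of each pair) are moved to the nearest free pixel by a
#' deterministic spiral search. The result is an exact, invertible lookup.
#'
#' @param mesh a `cortical_mesh`.
#' @param height,width raster dimensions in pixels.
#' @return an object of class `vertex_pixel_map`: list with `height`, `width`,
#'   `pixel` (V x 2 matrix of 1-based row/col), `lookup` (height x width
#'   integer matrix; 0 = uncovered pixel), `n_vertices`, and `n_moved`
#'   (vertices displaced by collision resolution).
#' @examples
#' m <- build_icosphere(0)
#' vp <- flatten_map(m, 64, 64)
#' nrow(unique(vp$pixel))  # 12 distinct pixels
#' @export
flatten_map <- function(mesh, height = 128L, width = 128L) {
  stopifnot(inherits(mesh, "cortical_mesh"))
  height <- check_count(height, "height", lower = 2L)
  width <- check_count(width, "width", lower = 2L)
  v <- mesh$vertices
  nv <- nrow(v)
  if (height * width < nv)
    stop_arg("raster (", height, "x", width, ") too small for ", nv, " vertices")
  theta <- acos(pmin(pmax(v[, 3], -1), 1))   # polar distance from +z pole
  phi <- atan2(v[, 2], v[, 1])
  # anisotropic radius so the projected disc fills the rectangle
  ry <- (height - 1) / 2
  rx <- (width - 1) / 2
  row <- as.integer(round((height + 1) / 2 + (theta / pi) * ry * sin(phi)))
  col <- as.integer(round((width + 1) / 2 + (theta / pi) * rx * cos(phi)))
  row <- pmin(pmax(row, 1L), height)
  col <- pmin(pmax(col, 1L), width)
  lookup <- matrix(0L, height, width)
  pixel <- matrix(NA_integer_, nv, 2)
  offsets <- NULL
  n_moved <- 0L
  max_radius <- max(height, width)
  for (i in seq_len(nv)) {
    r <- row[i]; cc <- col[i]
    if (lookup[r, cc] != 0L) {
      if (is.null(offsets)) offsets <- spiral_offsets(max_radius)
      placed <- FALSE
      for (k in seq_len(nrow(offsets))) {
        r2 <- r + offsets[k, 1]; c2 <- cc + offsets[k, 2]
        if (r2 >= 1 && r2 <= height && c2 >= 1 && c2 <= width &&
            lookup[r2, c2] == 0L) {
          r <- r2; cc <- c2; placed <- TRUE
          break
        }
      }
      if (!placed)
        stop_arg("could not resolve pixel collisions; use a larger raster")
      n_moved <- n_moved + 1L
    }
    lookup[r, cc] <- i
    pixel[i, ] <- c(r, cc)
  }
  structure(
    list(height = height, width = width,
         pixel = pixel, lookup = lookup, n_vertices = nv, n_moved = n_moved),
    class = "vertex_pixel_map"
  )
}

#' Flatten both hemispheres side by side into one raster
#'
#' Places the left hemisphere's disc in columns `1..width/2` and the right
#' hemisphere's in `width/2+1..width` of a single raster, so each image frame
#' carries both hemispheres and the generative model can exploit contralateral
#' structure. Vertex indices run `1..V` (left) then `V+1..2V` (right),
#' matching the row order of run matrices.
#'
#' @param mesh the template `cortical_mesh` shared by both hemispheres.
#' @param height raster height in pixels.
#' @param width raster width in pixels (must be even).
#' @return a `vertex_pixel_map` over `2V` vertices.
#' @export
flatten_pair <- function(mesh, height = 128L, width = 128L) {
  height <- check_count(height, "height", lower = 2L)
  width <- check_count(width, "width", lower = 4L)
  if (width %% 2L != 0L) stop_arg("width must be even for a side-by-side pair")
  half <- width %/% 2L
  left <- flatten_map(mesh, height, half)
  right <- flatten_map(mesh, height, half)
  nv <- left$n_vertices
  pixel <- rbind(left$pixel, cbind(right$pixel[, 1], right$pixel[, 2] + half))
  lookup <- cbind(left$lookup, right$lookup)
  lookup[lookup != 0L & col(lookup) > half] <-
    lookup[lookup != 0L & col(lookup) > half] + nv
  structure(
    list(height = height, width = width, pixel = pixel, lookup = lookup,
         n_vertices = 2L * nv, n_moved = left$n_moved + right$n_moved),
    class = "vertex_pixel_map"
  )
}

#' @export
print.vertex_pixel_map <- function(x, ...) {
  cat(sprintf("vertex_pixel_map: %d vertices on a %dx%d raster (%d moved by collision resolution)\n",
              x$n_vertices, x$height, x$width, x$n_moved))
  invisible(x)
}

#' Render a per-vertex frame onto the raster
#'
#' @param frame numeric vector of per-vertex values (length `n_vertices` of
#'   the map).
#' @param map a `vertex_pixel_map`.
#' @param background value for pixels not covered by any vertex.
#' @return a `height x width` numeric matrix.
#' @export
frame_to_image <- function(frame, map, background = 0) {
  stopifnot(inherits(map, "vertex_pixel_map"))
  if (length(frame) != map$n_vertices)
    stop_arg("frame length ", length(frame), " != map vertex count ", map$n_vertices)
  img <- matrix(background, map$height, map$width)
  img[cbind(map$pixel[, 1], map$pixel[, 2])] <- frame
  img
}

#' Recover a per-vertex frame from a raster image
#'
#' Exact inverse of [frame_to_image()] on covered pixels.
#'
#' @param image a `height x width` numeric matrix (or a vector of length
#'   `height*width` in column-major order).
#' @param map a `vertex_pixel_map`.
#' @return numeric vector of per-vertex values.
#' @export
image_to_frame <- function(image, map) {
  stopifnot(inherits(map, "vertex_pixel_map"))
  if (length(image) != map$height * map$width)
    stop_arg("image size does not match map raster")
  img <- matrix(image, map$height, map$width)
  img[cbind(map$pixel[, 1], map$pixel[, 2])]
}

#' Linear (column-major) pixel indices of a map's vertices
#'
#' Convenience for working with flattened image vectors: element `i` is the
#' position of vertex `i` in `as.vector(frame_to_image(...))`.
#' @param map a `vertex_pixel_map`.
#' @return integer vector of length `n_vertices`.
#' @export
vertex_pixel_index <- function(map) {
  (map$pixel[, 2] - 1L) * map$height + map$pixel[, 1]
}
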