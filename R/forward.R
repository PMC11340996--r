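#' Construct a triangulated cortical surface with region labels
#'
#' @param vertices n x 3 matrix of coordinates (mm).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param region_of_vertex Region id per vertex (length n).
#' @return Object of class `tri_surface`.
#' @export
tri_surface <- function(vertices, triangles, region_of_vertex) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3,
            length(region_of_vertex) == nrow(vertices))
  if (any(triangles < 1) || any(triangles > nrow(vertices)))
    stop("triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles,
                 region_of_vertex = region_of_vertex),
            class = "tri_surface")
}

#' Construct an SEEG sensor array
#'
#' @param positions n x 3 matrix of contact coordinates (mm).
#' @param names Unique channel labels.
#' @return Object of class `sensor_array`.
#' @export
sensor_array <- function(positions, names = NULL) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, all(is.finite(positions)))
  if (is.null(names)) names <- paste0("S", seq_len(nrow(positions)))
  if (anyDuplicated(names)) stop("sensor names must be unique")
  structure(list(positions = positions, names = names),
            class = "sensor_array")
}

.triangle_areas <- function(surface) {
  v <- surface$vertices; tr <- surface$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Per-vertex surface areas
#'
#' Each vertex receives one third of the area of every incident triangle,
#' so vertex areas sum exactly to the total mesh area. Degenerate
#' zero-area triangles contribute nothing.
#'
#' @param surface A [tri_surface()].
#' @return Numeric vector of per-vertex areas (mm^2).
#' @export
vertex_areas <- function(surface) {
  stopifnot(inherits(surface, "tri_surface"))
  ta <- .triangle_areas(surface)
  if (any(ta == 0)) message(sum(ta == 0), " degenerate triangle(s) ignored")
  areas <- numeric(nrow(surface$vertices))
  third <- rep(ta / 3, 3)
  idx <- as.vector(surface$triangles)
  for (k in seq_along(idx)) areas[idx[k]] <- areas[idx[k]] + third[k]
  areas
}

.sensor_distances <- function(surface, sensors) {
  v <- surface$vertices; s <- sensors$positions
  d2 <- outer(rowSums(v^2), rep(1, nrow(s))) +
        outer(rep(1, nrow(v)), rowSums(s^2)) - 2 * v %*% t(s)
  sqrt(pmax(d2, 0))
}

#' Inverse-square gain matrix from regions to SEEG sensors
#'
#' `g[j, k] = sum over vertices i of region j of a_i / d(i, k)^2`, where
#' `a_i` is the vertex area and `d` the Euclidean vertex-sensor distance.
#'
#' @param surface A [tri_surface()].
#' @param sensors A [sensor_array()].
#' @return Object of class `gain_matrix`: `values` (regions x sensors),
#'   `region_ids`, `sensor_names`.
#' @export
compute_gain <- function(surface, sensors) {
  d <- .sensor_distances(surface, sensors)
  if (any(d == 0)) {
    bad <- which(d == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("sensor %d coincides with vertex %d", bad[2], bad[1]))
  }
  a <- vertex_areas(surface)
  regions <- sort(unique(surface$region_of_vertex))
  g <- matrix(0, length(regions), nrow(sensors$positions),
              dimnames = list(as.character(regions), sensors$names))
  contrib <- a / d^2                     # vertices x sensors
  for (r in seq_along(regions)) {
    rows <- surface$region_of_vertex == regions[r]
    g[r, ] <- colSums(contrib[rows, , drop = FALSE])
  }
  structure(list(values = g, region_ids = regions,
                 sensor_names = sensors$names),
            class = "gain_matrix")
}

#' Sensor-to-source matrix from nearest-vertex inverse distances
#'
#' For each (region, sensor) pair, the 60 vertices of the region closest
#' to the sensor are selected (all of them when the region has fewer,
#' normalizing by the actual count; distance ties broken by vertex index)
#' and their inverse distances averaged.
#'
#' @inheritParams compute_gain
#' @param n_closest Number of closest vertices per region (default 60).
#' @return Object of class `sensor_to_source`: `values`
#'   (regions x sensors), `region_ids`, `sensor_names`.
#' @export
compute_sensor_to_source <- function(surface, sensors, n_closest = 60) {
  d <- .sensor_distances(surface, sensors)
  if (any(d == 0)) stop("sensor coincides with a vertex (zero distance)")
  regions <- sort(unique(surface$region_of_vertex))
  w <- matrix(0, length(regions), nrow(sensors$positions),
              dimnames = list(as.character(regions), sensors$names))
  for (r in seq_along(regions)) {
    rows <- which(surface$region_of_vertex == regions[r])
    for (k in seq_len(ncol(d))) {
      dk <- d[rows, k]
      ord <- order(dk, rows)             # ties -> lowest vertex index
      sel <- ord[seq_len(min(n_closest, length(rows)))]
      w[r, k] <- mean(1 / dk[sel])
    }
  }
  structure(list(values = w, region_ids = regions,
                 sensor_names = sensors$names),
            class = "sensor_to_source")
}

#' Project source activity to SEEG sensors
#'
#' Sensor signals are the matrix product of the gain matrix (transposed)
#' with the source fast-variable time series.
#'
#' @param traj A `source_trajectory` (or a regions x times matrix).
#' @param gain A `gain_matrix`.
#' @return Matrix of sensor signals (sensors x times).
#' @export
project_sources_to_sensors <- function(traj, gain) {
  x <- if (inherits(traj, "source_trajectory")) traj$x else as.matrix(traj)
  g <- gain$values
  if (nrow(g) != nrow(x))
    stop("region count mismatch between gain matrix and sources")
  out <- t(g) %*% x
  rownames(out) <- gain$sensor_names
  out
}

#' Read / write sensor coordinate tables
#'
#' TSV with columns `name`, `x`, `y`, `z` (mm).
#'
#' @param path File path.
#' @export
read_sensors <- function(path) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  sensor_array(as.matrix(d[, c("x", "y", "z")]), d$name)
}

#' @rdname read_sensors
#' @param sensors A `sensor_array`.
#' @export
write_sensors <- function(sensors, path) {
  d <- data.frame(name = sensors$names, sensors$positions)
  names(d) <- c("name", "x", "y", "z")
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
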