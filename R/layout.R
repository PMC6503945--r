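#' Sensor layout on a spherical cap
#'
#' Deterministic quasi-uniform sensor layout: `n` points placed on a
#' spherical cap (head-like coverage) by a Fibonacci lattice, with an
#' azimuthal-equidistant 2D projection used for spatial adjacency. This
#' gives a nontrivial neighbor graph without real sensor geometry.
#'
#' Conventions: +x right, +y anterior, +z superior; "posterior" sensors have
#' low y.
#'
#' @param n number of sensors.
#' @param capAngle angular radius of the cap, degrees (default 75).
#' @param labels channel labels (default `CH001`, ...).
#' @return matrix with columns `x, y, z, layout2d_x, layout2d_y`, one row
#'   per sensor, rownames = labels.
#' @examples
#' pos <- sensorLayout(30)
#' @export
sensorLayout <- function(n, capAngle = 75,
                         labels = sprintf("CH%03d", seq_len(n))) {
  stopifnot(n >= 1, length(labels) == n)
  i <- seq_len(n)
  theta <- (capAngle * pi / 180) * sqrt((i - 0.5) / n)  # colatitude
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  x <- sin(theta) * cos(phi)
  y <- sin(theta) * sin(phi)
  z <- cos(theta)
  pos <- cbind(x = x, y = y, z = z,
               layout2d_x = theta * cos(phi), layout2d_y = theta * sin(phi))
  rownames(pos) <- labels
  pos
}

#' Spatial adjacency from sensor positions
#'
#' Builds a symmetric neighbor structure by k-nearest neighbors in the 2D
#' layout projection (union-symmetrized), the standard construction for
#' planar sensor neighbourhoods.
#'
#' @param positions matrix from [sensorLayout()] (or any matrix with
#'   `layout2d_x`/`layout2d_y` columns, else the first two columns are
#'   used); rownames are the channel labels.
#' @param k number of nearest neighbors before symmetrization (default 6).
#' @return a [SensorAdjacency-class] object.
#' @export
sensorAdjacency <- function(positions, k = 6) {
  n <- nrow(positions)
  stopifnot(n >= 2, k >= 1)
  labels <- rownames(positions)
  if (is.null(labels)) labels <- sprintf("CH%03d", seq_len(n))
  cols <- if (all(c("layout2d_x", "layout2d_y") %in% colnames(positions)))
    c("layout2d_x", "layout2d_y") else 1:2
  xy <- positions[, cols, drop = FALSE]
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  k <- min(k, n - 1)
  nb <- lapply(seq_len(n), function(i) sort(order(d[i, ])[seq_len(k)]))
  # union-symmetrize
  for (i in seq_len(n)) for (j in nb[[i]])
    if (!(i %in% nb[[j]])) nb[[j]] <- sort(c(nb[[j]], i))
  new("SensorAdjacency", neighbors = stats::setNames(nb, labels),
      labels = labels)
}

#' Build a SensorAdjacency from explicit neighbor lists
#'
#' @param neighbors named list of character vectors (labels of neighbors
#'   per channel). Must be symmetric and self-loop free.
#' @return a [SensorAdjacency-class] object.
#' @export
adjacencyFromList <- function(neighbors) {
  labels <- names(neighbors)
  idx <- lapply(neighbors, function(nb) {
    i <- match(nb, labels)
    if (anyNA(i)) stop("neighbor label not found among channel names")
    sort(i)
  })
  new("SensorAdjacency", neighbors = stats::setNames(idx, labels),
      labels = labels)
}

#' Read / write adjacency as JSON neighbor lists
#'
#' @param adjacency a [SensorAdjacency-class] object.
#' @param path JSON file path.
#' @return `readAdjacency` returns a [SensorAdjacency-class] object;
#'   `writeAdjacency` returns `path` invisibly.
#' @export
writeAdjacency <- function(adjacency, path) {
  jsonlite::write_json(neighborList(adjacency), path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeAdjacency
#' @export
readAdjacency <- function(path) {
  nb <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(nb)) nb <- as.list(nb)
  nb <- lapply(nb, as.character)
  adjacencyFromList(nb)
}
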