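#' Build a triangulated mesh for SPDE fields
#'
#' Constructs the piecewise-linear finite-element mesh that discretizes the
#' latent Gaussian fields.  Candidate vertices are the supplied locations,
#' thinned greedily in input order so that no two retained vertices are
#' closer than `cutoff_km` (the minimum-distance convention used when
#' meshing survey domains).  A ring of boundary vertices of width
#' `extension_km` is added around the data hull to push boundary effects of
#' the SPDE approximation away from the domain, and the union is Delaunay
#' triangulated.
#'
#' @param locations Two-column matrix / data frame of planar km coordinates
#'   (columns `x_km`, `y_km` recognized by name).
#' @param cutoff_km Minimum distance between mesh vertices (km).
#' @param extension_km Width of the outer extension ring (km).  Choose this
#'   on the order of 1-1.5 times the expected correlation range; the default
#'   is `5 * cutoff_km`.
#'
#' @return An object of class `spat_mesh`: list with `loc` (n x 2 node
#'   coordinates), `tri` (m x 3 vertex indices), `interior` (logical, TRUE
#'   for nodes from the data region), `cutoff_km`, `extension_km`.
#' @examples
#' set.seed(1)
#' m <- build_mesh(cbind(runif(50, 0, 90), runif(50, 0, 90)), cutoff_km = 10)
#' m
#' @export
build_mesh <- function(locations, cutoff_km, extension_km = 5 * cutoff_km) {
  pts <- as_points(locations)
  stopifnot(cutoff_km > 0, extension_km >= 0)
  if (nrow(pts) < 3) stop("need at least 3 locations")
  diam <- max(stats::dist(pts))
  if (cutoff_km > diam)
    stop("`cutoff_km` (", cutoff_km, " km) exceeds the domain diameter (",
         round(diam, 2), " km); no usable mesh can be built")

  keep <- greedy_thin(pts, cutoff_km)
  interior_loc <- pts[keep, , drop = FALSE]

  ring_loc <- extension_ring(interior_loc, cutoff_km, extension_km)
  ## thin ring points against the accepted set so the global minimum
  ## distance invariant holds
  all_loc <- interior_loc
  for (i in seq_len(nrow(ring_loc))) {
    d2 <- (all_loc[, 1] - ring_loc[i, 1])^2 + (all_loc[, 2] - ring_loc[i, 2])^2
    if (min(d2) >= cutoff_km^2) all_loc <- rbind(all_loc, ring_loc[i, ])
  }
  n_int <- nrow(interior_loc)

  tm <- tryCatch(
    interp::tri.mesh(all_loc[, 1], all_loc[, 2]),
    error = function(e) stop("triangulation failed (collinear vertices?): ",
                             conditionMessage(e)))
  tri <- unname(interp::triangles(tm)[, 1:3, drop = FALSE])

  structure(list(
    loc = unname(all_loc),
    tri = tri,
    interior = seq_len(nrow(all_loc)) <= n_int,
    cutoff_km = cutoff_km,
    extension_km = extension_km
  ), class = "spat_mesh")
}

## greedy thinning: accept a point only if >= cutoff from all accepted ones
greedy_thin <- function(pts, cutoff_km) {
  n <- nrow(pts)
  keep <- logical(n)
  acc_x <- numeric(0); acc_y <- numeric(0)
  c2 <- cutoff_km^2
  for (i in seq_len(n)) {
    if (length(acc_x) == 0L ||
        min((acc_x - pts[i, 1])^2 + (acc_y - pts[i, 2])^2) >= c2) {
      keep[i] <- TRUE
      acc_x <- c(acc_x, pts[i, 1]); acc_y <- c(acc_y, pts[i, 2])
    }
  }
  keep
}

## graded concentric rings of boundary vertices around the data centroid:
## ring gaps (and in-ring spacing) start near the interior cutoff and grow
## geometrically outward, so triangle size increases smoothly into the
## extension.  A mild deterministic radial modulation avoids cocircular
## degeneracies.
extension_ring <- function(loc, cutoff_km, extension_km) {
  if (extension_km <= 0) return(matrix(numeric(0), 0, 2))
  ctr <- colMeans(loc)
  rmax <- sqrt(max((loc[, 1] - ctr[1])^2 + (loc[, 2] - ctr[2])^2))
  gap <- 1.5 * cutoff_km
  radii <- numeric(0)
  r <- rmax
  while (r < rmax + extension_km) {
    r <- r + gap
    radii <- c(radii, min(r, rmax + extension_km))
    gap <- gap * 1.4
  }
  out <- NULL
  for (j in seq_along(radii)) {
    r <- radii[j]
    spacing <- if (j == 1) 1.5 * cutoff_km else radii[j] - radii[j - 1]
    m <- max(8L, ceiling(2 * pi * r / spacing))
    th <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)] + 0.31 * j
    rr <- r * (1 + 0.015 * sin(3 * th + 0.7 * j))
    out <- rbind(out, cbind(ctr[1] + rr * cos(th), ctr[2] + rr * sin(th)))
  }
  out
}

#' @export
print.spat_mesh <- function(x, ...) {
  cat(sprintf("SPDE mesh: %d nodes (%d interior), %d triangles, cutoff %g km, extension %g km\n",
              nrow(x$loc), sum(x$interior), nrow(x$tri),
              x$cutoff_km, x$extension_km))
  invisible(x)
}

#' Write / read a mesh as plain-text tables
#'
#' Serializes a mesh to two CSV files, `<prefix>_nodes.csv` (id, x_km,
#' y_km, interior) and `<prefix>_triangles.csv` (v1, v2, v3), and reads it
#' back.
#'
#' @param mesh A `spat_mesh`.
#' @param prefix File path prefix.
#' @return `read_mesh` returns the reconstructed `spat_mesh`.
#' @export
write_mesh <- function(mesh, prefix) {
  stopifnot(inherits(mesh, "spat_mesh"))
  nodes <- data.frame(id = seq_len(nrow(mesh$loc)),
                      x_km = mesh$loc[, 1], y_km = mesh$loc[, 2],
                      interior = as.integer(mesh$interior))
  tris <- data.frame(v1 = mesh$tri[, 1], v2 = mesh$tri[, 2], v3 = mesh$tri[, 3])
  utils::write.csv(nodes, paste0(prefix, "_nodes.csv"), row.names = FALSE)
  utils::write.csv(tris, paste0(prefix, "_triangles.csv"), row.names = FALSE)
  ## cutoff/extension ride along in a small header file
  writeLines(c(paste0("cutoff_km,", mesh$cutoff_km),
               paste0("extension_km,", mesh$extension_km)),
             paste0(prefix, "_meta.csv"))
  invisible(prefix)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(prefix) {
  nodes <- utils::read.csv(paste0(prefix, "_nodes.csv"))
  tris <- utils::read.csv(paste0(prefix, "_triangles.csv"))
  meta <- utils::read.csv(paste0(prefix, "_meta.csv"), header = FALSE,
                          row.names = 1)
  structure(list(
    loc = unname(cbind(nodes$x_km, nodes$y_km)),
    tri = unname(as.matrix(tris)),
    interior = nodes$interior == 1L,
    cutoff_km = meta["cutoff_km", 1],
    extension_km = meta["extension_km", 1]
  ), class = "spat_mesh")
}

#' Projection matrix from mesh nodes to locations
#'
#' Builds the sparse matrix of piecewise-linear basis weights (barycentric
#' coordinates of the containing triangle) that interpolates node values of
#' a latent field to arbitrary locations.  Each row is non-negative and
#' sums to one; a location coinciding with a node gets weight 1 on that
#' node.
#'
#' @param mesh A `spat_mesh`.
#' @param locations Points inside the (extended) mesh.
#' @return A sparse `dgCMatrix`, `nrow(locations)` x `nrow(mesh$loc)`.
#' @export
project <- function(mesh, locations) {
  stopifnot(inherits(mesh, "spat_mesh"))
  pts <- as_points(locations)
  n <- nrow(pts)
  tri <- mesh$tri
  loc <- mesh$loc
  row_i <- integer(0); col_j <- integer(0); val <- numeric(0)
  unassigned <- seq_len(n)
  tol <- -1e-9
  for (t in seq_len(nrow(tri))) {
    if (!length(unassigned)) break
    v <- tri[t, ]
    p1 <- loc[v[1], ]; p2 <- loc[v[2], ]; p3 <- loc[v[3], ]
    det <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p3[1] - p1[1]) * (p2[2] - p1[2])
    if (abs(det) < 1e-12) next
    dx <- pts[unassigned, 1] - p1[1]
    dy <- pts[unassigned, 2] - p1[2]
    w2 <- ((p3[2] - p1[2]) * dx - (p3[1] - p1[1]) * dy) / det
    w3 <- (-(p2[2] - p1[2]) * dx + (p2[1] - p1[1]) * dy) / det
    w1 <- 1 - w2 - w3
    inside <- w1 >= tol & w2 >= tol & w3 >= tol
    if (any(inside)) {
      idx <- unassigned[inside]
      W <- cbind(pmax(w1[inside], 0), pmax(w2[inside], 0), pmax(w3[inside], 0))
      W <- W / rowSums(W)
      row_i <- c(row_i, rep(idx, 3L))
      col_j <- c(col_j, rep(v, each = length(idx)))
      val <- c(val, as.vector(W))
      unassigned <- unassigned[!inside]
    }
  }
  if (length(unassigned))
    stop("locations outside the mesh (rows: ",
         paste(utils::head(unassigned, 10), collapse = ", "),
         if (length(unassigned) > 10) ", ..." else "", ")")
  Matrix::sparseMatrix(i = row_i, j = col_j, x = val,
                       dims = c(n, nrow(loc)))
}
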