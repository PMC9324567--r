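# Euclidean 3-space primitives: vectors, rigid poses (unit quaternions),
# tile shapes, connector geometry, obstruction tests and the Brownian
# displacement applied to mobile objects each iteration.
#
# Length unit convention: 1 unit = one tile edge length.

#' Create a 3D vector
#'
#' @param x,y,z Finite numeric components (length unit: one tile edge).
#' @return A numeric vector of length 3 with class `vec3`.
#' @examples
#' vec3(1, 2, 3)
#' @export
vec3 <- function(x, y, z) {
  v <- c(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (!all(is.finite(v))) {
    stop("vec3 components must be finite", call. = FALSE)
  }
  class(v) <- "vec3"
  v
}

vnorm <- function(v) sqrt(sum(v * v))

#' Create a rigid-body pose
#'
#' A pose is a position plus an orientation stored as a unit quaternion
#' `(w, x, y, z)`. The identity quaternion is `c(1, 0, 0, 0)`.
#'
#' @param position Numeric length-3 position.
#' @param quaternion Numeric length-4 unit quaternion (w, x, y, z);
#'   must have unit norm within 1e-9.
#' @return An object of class `pose`.
#' @examples
#' pose(c(0, 0, 0))
#' pose(c(1, 0, 0), quat_axis_angle(c(0, 0, 1), pi / 2))
#' @export
pose <- function(position = c(0, 0, 0), quaternion = c(1, 0, 0, 0)) {
  position <- as.numeric(position)
  quaternion <- as.numeric(quaternion)
  stopifnot(length(position) == 3, length(quaternion) == 4)
  if (!all(is.finite(position)) || !all(is.finite(quaternion))) {
    stop("pose components must be finite", call. = FALSE)
  }
  if (abs(vnorm(quaternion) - 1) > 1e-9) {
    stop("pose orientation must be a unit quaternion (|q| = 1 within 1e-9)",
         call. = FALSE)
  }
  structure(list(position = position, quaternion = quaternion),
            class = "pose")
}

#' Quaternion from axis and angle
#'
#' @param axis Numeric length-3 rotation axis (need not be normalised).
#' @param angle Rotation angle in radians.
#' @return Unit quaternion (w, x, y, z).
#' @export
quat_axis_angle <- function(axis, angle) {
  axis <- as.numeric(axis)
  n <- vnorm(axis)
  if (n == 0) stop("rotation axis must be nonzero", call. = FALSE)
  axis <- axis / n
  c(cos(angle / 2), sin(angle / 2) * axis)
}

# 3x3 rotation matrix of a unit quaternion.
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Map local coordinates to world coordinates under a pose
#'
#' Applies the rigid transform of `pose`: rotation then translation.
#' Accepts a single point (length-3) or an n x 3 matrix of points.
#'
#' @param pose A [pose()].
#' @param p Length-3 numeric point, or an n x 3 matrix of row points, in
#'   the local frame.
#' @return Point(s) in world coordinates, same shape as `p`.
#' @examples
#' to_world(pose(c(1, 0, 0)), c(0, 0, 0))
#' @export
to_world <- function(pose, p) {
  if (!inherits(pose, "pose")) stop("`pose` must be a pose object", call. = FALSE)
  R <- quat_to_matrix(pose$quaternion)
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3)
    sweep(p %*% t(R), 2, -pose$position)
  } else {
    as.numeric(R %*% as.numeric(p)) + pose$position
  }
}

#' Tile shape: planar polygon or rod segment
#'
#' Shapes live in the tile's local frame. Polygons are simple planar
#' polygons with >= 3 coplanar vertices; by convention the polygon
#' normal is +z and the first vertex lies on the +x axis. Rods have
#' exactly two distinct endpoints.
#'
#' @param kind `"polygon2D"` or `"rod1D"`.
#' @param vertices n x 3 numeric matrix of local vertices (n >= 3
#'   coplanar for polygons, n = 2 for rods).
#' @return An object of class `tile_shape`.
#' @examples
#' tile_shape_regular_polygon(8)   # octagon with unit edge
#' tile_shape("rod1D", rbind(c(0, 0, 0), c(1, 0, 0)))
#' @export
tile_shape <- function(kind = c("polygon2D", "rod1D"), vertices) {
  kind <- match.arg(kind)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  stopifnot(ncol(vertices) == 3, all(is.finite(vertices)))
  if (kind == "rod1D") {
    if (nrow(vertices) != 2) stop("rod1D needs exactly 2 vertices", call. = FALSE)
    if (vnorm(vertices[2, ] - vertices[1, ]) <= 0) {
      stop("rod length must be > 0", call. = FALSE)
    }
  } else {
    if (nrow(vertices) < 3) stop("polygon2D needs >= 3 vertices", call. = FALSE)
    if (max(abs(vertices[, 3])) > 1e-9) {
      stop("polygon2D vertices must be coplanar (z = 0) within 1e-9",
           call. = FALSE)
    }
  }
  structure(list(kind = kind, vertices = vertices), class = "tile_shape")
}

#' Regular polygon tile shape with unit edge length
#'
#' Centred at the origin in the z = 0 plane, first vertex rotated so the
#' shape is symmetric about +x.
#'
#' @param n Number of edges (>= 3).
#' @param edge Edge length (default 1 unit).
#' @return A `tile_shape` of kind `"polygon2D"`.
#' @export
tile_shape_regular_polygon <- function(n, edge = 1) {
  stopifnot(n >= 3)
  r <- edge / (2 * sin(pi / n))
  ang <- 2 * pi * (seq_len(n) - 1) / n
  tile_shape("polygon2D", cbind(r * cos(ang), r * sin(ang), 0))
}

#' Connector on a tile boundary
#'
#' A connector is a point or segment on the tile boundary covered with a
#' glue; two connectors can bond iff their glues match under the model's
#' glue relation. `attach_angle` is the dihedral angle (radians) at which
#' an incoming tile is oriented relative to the host tile plane.
#'
#' @param site Length-3 point, or 2 x 3 matrix segment, in the tile local
#'   frame, on the tile boundary.
#' @param glue Character glue label.
#' @param attach_angle Dihedral attachment angle in `[0, 2*pi)`.
#' @return An object of class `connector`.
#' @export
connector <- function(site, glue, attach_angle = pi) {
  if (!is.matrix(site)) site <- matrix(as.numeric(site), nrow = 1)
  stopifnot(ncol(site) == 3, is.character(glue), length(glue) == 1)
  if (attach_angle < 0 || attach_angle >= 2 * pi) {
    stop("attach_angle must lie in [0, 2*pi)", call. = FALSE)
  }
  structure(list(site = site, glue = glue, attach_angle = attach_angle),
            class = "connector")
}

# Sampled surface points of a placed shape, for distance queries.
# Polygons: vertices + edge midpoints + centroid; rods: endpoints + midpoint.
shape_points <- function(shape, pose) {
  v <- shape$vertices
  if (shape$kind == "polygon2D") {
    mids <- (v + v[c(2:nrow(v), 1), ]) / 2
    pts <- rbind(v, mids, colMeans(v))
  } else {
    pts <- rbind(v, colMeans(v))
  }
  to_world(pose, pts)
}

#' Obstruction test between two placed shapes
#'
#' Tiles are obstructive, solid objects: a placement is blocked when two
#' shapes come closer than `clearance`. The test is a symmetric minimal
#' point-set distance over sampled boundary points (vertices, edge
#' midpoints and centroids), adequate at the tile granularity used here.
#'
#' @param shape_a,shape_b `tile_shape` objects.
#' @param pose_a,pose_b Their [pose()]s.
#' @param clearance Non-negative minimal allowed separation
#'   (default 0.01 tile-edge units).
#' @return `TRUE` iff the minimal sampled distance is `< clearance`.
#' @export
overlap <- function(shape_a, pose_a, shape_b, pose_b, clearance = 0.01) {
  stopifnot(clearance >= 0)
  pa <- shape_points(shape_a, pose_a)
  pb <- shape_points(shape_b, pose_b)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  min_d <- sqrt(max(0, min(d2)))
  min_d < clearance
}

#' One Brownian displacement
#'
#' Moves a point by exactly `step` units in a direction uniform on the
#' sphere. If `bounds` is given (a 2 x 3 matrix of lower/upper box
#' limits), the result is reflected back into the box so no object is
#' lost through the boundary.
#'
#' @param p Length-3 point or n x 3 matrix of points.
#' @param step Displacement length (>= 0); one value or one per point.
#' @param bounds Optional 2 x 3 matrix `rbind(lower, upper)`.
#' @return Displaced point(s), same shape as `p`.
#' @export
brownian_step <- function(p, step, bounds = NULL) {
  single <- !is.matrix(p)
  if (single) p <- matrix(as.numeric(p), nrow = 1)
  stopifnot(all(step >= 0))
  n <- nrow(p)
  dir <- matrix(stats::rnorm(3 * n), ncol = 3)
  nrm <- sqrt(rowSums(dir^2))
  nrm[nrm == 0] <- 1
  q <- p + dir / nrm * step
  if (!is.null(bounds)) q <- reflect_into_box(q, bounds)
  if (single) as.numeric(q) else q
}

# Reflect points into an axis-aligned box (handles multiple bounces).
reflect_into_box <- function(p, bounds) {
  lo <- bounds[1, ]; hi <- bounds[2, ]
  for (j in 1:3) {
    w <- hi[j] - lo[j]
    x <- p[, j] - lo[j]
    x <- x %% (2 * w)
    x <- ifelse(x > w, 2 * w - x, x)
    p[, j] <- x + lo[j]
  }
  p
}

# Uniform points inside an axis-aligned box; m x 3 matrix.
runif_box <- function(m, bounds) {
  cbind(stats::runif(m, bounds[1, 1], bounds[2, 1]),
        stats::runif(m, bounds[1, 2], bounds[2, 2]),
        stats::runif(m, bounds[1, 3], bounds[2, 3]))
}
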