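#' Active-zone polygon
#'
#' Constructs a simple (non-self-intersecting) polygon representing the outline
#' of a presynaptic active zone (AZ) fractured onto a membrane replica.
#' Vertices are given in nm; the polygon is implicitly closed and stored
#' counterclockwise (clockwise input is reversed). The area is computed with
#' the shoelace formula and reported in both nm^2 and um^2.
#'
#' @param vertices_nm numeric matrix (or coercible) with two columns, the
#'   ordered (x, y) vertex coordinates in nm; at least 3 rows.
#' @return An object of class `az_polygon` with elements `vertices_nm`
#'   (counterclockwise matrix), `area_nm2` and `area_um2`.
#' @examples
#' sq <- az_polygon(rbind(c(0, 0), c(300, 0), c(300, 300), c(0, 300)))
#' sq$area_um2  # 0.09
#' @export
az_polygon <- function(vertices_nm) {
  v <- as.matrix(vertices_nm)
  if (!is.numeric(v) || ncol(v) != 2L || nrow(v) < 3L) {
    stop("vertices_nm must be a numeric matrix with 2 columns and >= 3 rows")
  }
  if (anyNA(v)) stop("polygon vertices contain missing values")
  # drop an explicit closing vertex if present
  if (nrow(v) > 3L && all(v[1L, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  if (!.is_simple_polygon(v)) stop("polygon is not simple (edges self-intersect)")
  a <- .signed_area(v)
  if (a < 0) {
    v <- v[nrow(v):1L, , drop = FALSE]
    a <- -a
  }
  if (a <= 0) stop("polygon has zero area")
  structure(
    list(vertices_nm = unname(v), area_nm2 = a, area_um2 = a / NM2_PER_UM2),
    class = "az_polygon"
  )
}

#' @export
print.az_polygon <- function(x, ...) {
  cat(sprintf(
    "az_polygon: %d vertices, area %.4g um^2 (%s)\n",
    nrow(x$vertices_nm), x$area_um2,
    if (.is_convex(x$vertices_nm)) "convex" else "non-convex"
  ))
  invisible(x)
}

# Shoelace signed area; positive for counterclockwise orientation.
.signed_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  j <- c(seq_len(nrow(v))[-1L], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

.is_convex <- function(v) {
  n <- nrow(v)
  if (n < 4L) return(TRUE)
  nxt <- c(2:n, 1L)
  e <- v[nxt, , drop = FALSE] - v
  cr <- e[, 1L] * e[nxt, 2L] - e[, 2L] * e[nxt, 1L]
  all(cr >= -1e-9 * max(abs(cr), 1)) || all(cr <= 1e-9 * max(abs(cr), 1))
}

# O(n^2) pairwise test of non-adjacent edges for proper/improper intersection.
.is_simple_polygon <- function(v) {
  n <- nrow(v)
  nxt <- c(2:n, 1L)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (share a vertex)
      if (j == i || nxt[i] == j || nxt[j] == i) next
      if (.segments_cross(
        v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ]
      )) {
        return(FALSE)
      }
    }
  }
  TRUE
}

.orient <- function(p, q, r) {
  val <- (q[1L] - p[1L]) * (r[2L] - p[2L]) - (q[2L] - p[2L]) * (r[1L] - p[1L])
  scale <- max(abs(c(p, q, r)), 1)
  if (abs(val) < 1e-12 * scale * scale) 0 else sign(val)
}

.on_segment_collinear <- function(p, q, r) {
  # assumes collinear; is q within the bounding box of p--r?
  q[1L] <= max(p[1L], r[1L]) + 1e-12 && q[1L] >= min(p[1L], r[1L]) - 1e-12 &&
    q[2L] <= max(p[2L], r[2L]) + 1e-12 && q[2L] >= min(p[2L], r[2L]) - 1e-12
}

.segments_cross <- function(p1, p2, p3, p4) {
  o1 <- .orient(p1, p2, p3); o2 <- .orient(p1, p2, p4)
  o3 <- .orient(p3, p4, p1); o4 <- .orient(p3, p4, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  if (o1 == 0 && .on_segment_collinear(p1, p3, p2)) return(TRUE)
  if (o2 == 0 && .on_segment_collinear(p1, p4, p2)) return(TRUE)
  if (o3 == 0 && .on_segment_collinear(p3, p1, p4)) return(TRUE)
  if (o4 == 0 && .on_segment_collinear(p3, p2, p4)) return(TRUE)
  FALSE
}

#' Point-in-polygon test (closed polygon convention)
#'
#' Boundary points count as inside, matching the convention used for gold
#' particles digitized on the AZ perimeter.
#'
#' @param points_nm numeric matrix with columns (x, y) in nm (a single point
#'   may be given as a length-2 vector).
#' @param polygon an [az_polygon()].
#' @param tol absolute tolerance (nm) for the boundary test.
#' @return logical vector, one entry per point.
#' @export
point_in_polygon <- function(points_nm, polygon, tol = 1e-9) {
  stopifnot(inherits(polygon, "az_polygon"))
  p <- .as_points(points_nm)
  if (nrow(p) == 0L) return(logical(0))
  v <- polygon$vertices_nm
  inside <- .ray_cast(p[, 1L], p[, 2L], v[, 1L], v[, 2L])
  # boundary rescue: even-odd ray casting is ambiguous exactly on edges
  amb <- which(!inside)
  if (length(amb)) {
    scale <- max(abs(v), 1)
    onb <- vapply(
      amb,
      function(i) .dist_to_boundary(p[i, 1L], p[i, 2L], v) <= tol * scale,
      logical(1L)
    )
    inside[amb[onb]] <- TRUE
  }
  inside
}

.as_points <- function(points_nm) {
  if (is.null(points_nm) || length(points_nm) == 0L) {
    return(matrix(numeric(0), ncol = 2L))
  }
  if (is.null(dim(points_nm))) points_nm <- matrix(points_nm, ncol = 2L)
  p <- as.matrix(points_nm)
  if (ncol(p) != 2L || !is.numeric(p) || anyNA(p)) {
    stop("points must be a numeric matrix with 2 columns and no missing values")
  }
  unname(p)
}

.ray_cast <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

.dist_to_boundary <- function(px, py, v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  ax <- v[, 1L]; ay <- v[, 2L]
  bx <- v[j, 1L]; by <- v[j, 2L]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / pmax(len2, 1e-300)))
  qx <- ax + t * dx; qy <- ay + t * dy
  sqrt(min((px - qx)^2 + (py - qy)^2))
}

.poly_diameter <- function(polygon) {
  v <- polygon$vertices_nm
  max(stats::dist(v))
}

#' Gold-particle point pattern inside an active zone
#'
#' Bundles 2-D gold-particle coordinates (nm) with the enclosing AZ polygon.
#' Every point must lie inside or on the polygon boundary.
#'
#' @param points_nm numeric matrix with columns (x, y) in nm; may have 0 rows.
#' @param polygon an [az_polygon()].
#' @param az_id identifier for the AZ.
#' @return Object of class `point_pattern` with elements `az_id`, `points_nm`,
#'   `polygon` and `n_points`.
#' @export
point_pattern <- function(points_nm, polygon, az_id = "AZ1") {
  stopifnot(inherits(polygon, "az_polygon"))
  p <- .as_points(points_nm)
  if (nrow(p) > 0L) {
    ok <- point_in_polygon(p, polygon)
    if (!all(ok)) {
      bad <- which(!ok)[1L]
      stop(sprintf(
        "point (%.6g, %.6g) of AZ '%s' lies outside its polygon",
        p[bad, 1L], p[bad, 2L], az_id
      ))
    }
  }
  structure(
    list(az_id = az_id, points_nm = p, polygon = polygon, n_points = nrow(p)),
    class = "point_pattern"
  )
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf(
    "point_pattern '%s': %d points in a %.4g um^2 AZ\n",
    x$az_id, x$n_points, x$polygon$area_um2
  ))
  invisible(x)
}
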