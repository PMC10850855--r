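# Core geometric data types: cell meshes, contours, midlines.
#
# A cell mesh is an n x 4 matrix (x_left, y_left, x_right, y_right) pairing
# corresponding points on the two sides of a rod-shaped cell outline; the
# first and last rows are the cell poles. Coordinates are 0-based pixel
# centers, x = column axis, y = row axis, subpixel values allowed.

#' Construct and validate a cell mesh
#'
#' @param x Numeric matrix with 4 columns `(x_left, y_left, x_right,
#'   y_right)` and at least 4 rows; the row order runs pole to pole.
#'   Pole rows may have zero width (left equal to right).
#' @param validate_contour Check that the derived outline is a simple
#'   (non-self-intersecting) closed polygon. Defaults to `TRUE`.
#' @return The matrix with class `cell_mesh`.
#' @export
cell_mesh <- function(x, validate_contour = TRUE) {
  x <- as.matrix(x)
  if (ncol(x) != 4L) {
    stop_validation("a cell mesh must have exactly 4 columns (x_left, y_left, x_right, y_right)")
  }
  if (nrow(x) < 4L) {
    stop_validation(sprintf("a cell mesh needs at least 4 rows, got %d", nrow(x)))
  }
  if (!all(is.finite(x))) {
    stop_validation("cell mesh coordinates must all be finite")
  }
  storage.mode(x) <- "double"
  dimnames(x) <- list(NULL, c("x_left", "y_left", "x_right", "y_right"))
  if (validate_contour) {
    pts <- mesh_outline_points(x)
    if (nrow(pts) < 3L || !is_simple_polygon(pts)) {
      stop_validation("mesh outline is degenerate or self-intersecting")
    }
  }
  structure(x, class = c("cell_mesh", "matrix", "array"))
}

#' Test for a cell mesh
#' @param x Object to test.
#' @return `TRUE` for objects created by [cell_mesh()].
#' @export
is_cell_mesh <- function(x) inherits(x, "cell_mesh")

#' Construct and validate a closed contour
#'
#' A contour is an ordered list of subpixel `(x, y)` vertices describing a
#' simple closed polygon. Orientation is normalized to counter-clockwise
#' (positive shoelace area) on construction.
#'
#' @param xy Numeric matrix with 2 columns; the closing edge from the last
#'   vertex back to the first is implicit (a duplicated closing vertex is
#'   dropped).
#' @return The vertex matrix with class `cell_contour`, CCW-oriented.
#' @export
contour <- function(xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L) stop_validation("a contour must have exactly 2 columns (x, y)")
  storage.mode(xy) <- "double"
  if (!all(is.finite(xy))) stop_validation("contour coordinates must all be finite")
  xy <- drop_consecutive_duplicates(xy)
  if (nrow(xy) < 3L) stop_validation("a contour needs at least 3 distinct vertices")
  if (!is_simple_polygon(xy)) stop_validation("contour is self-intersecting")
  if (polygon_signed_area(xy) < 0) xy <- xy[nrow(xy):1L, , drop = FALSE]
  dimnames(xy) <- list(NULL, c("x", "y"))
  structure(xy, class = c("cell_contour", "matrix", "array"))
}

#' Test for a contour
#' @param x Object to test.
#' @return `TRUE` for objects created by [contour()].
#' @export
is_contour <- function(x) inherits(x, "cell_contour")

# ordered outline: left side pole->pole then right side pole->pole reversed,
# with consecutive duplicates (coincident poles) collapsed
mesh_outline_points <- function(m) {
  pts <- rbind(m[, 1:2, drop = FALSE], m[nrow(m):1L, 3:4, drop = FALSE])
  drop_consecutive_duplicates(unname(pts))
}

drop_consecutive_duplicates <- function(xy, tol = 1e-9) {
  n <- nrow(xy)
  if (n < 2L) return(xy)
  keep <- c(TRUE, rowSums(abs(xy[-1L, , drop = FALSE] - xy[-n, , drop = FALSE])) > tol)
  xy <- xy[keep, , drop = FALSE]
  # drop a closing vertex equal to the first
  n <- nrow(xy)
  if (n > 1L && sum(abs(xy[n, ] - xy[1L, ])) <= tol) xy <- xy[-n, , drop = FALSE]
  xy
}

#' Signed polygon area (shoelace)
#' @param xy Vertex matrix, closing edge implicit.
#' @return Signed area; positive for counter-clockwise traversal.
#' @export
polygon_signed_area <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

# Simplicity test: no two non-adjacent edges of the closed polygon intersect.
# O(n^2) vectorized segment-intersection; fine for contours of a few hundred
# vertices.
is_simple_polygon <- function(xy, tol = 1e-12) {
  n <- nrow(xy)
  if (n < 3L) return(FALSE)
  p1 <- xy
  p2 <- xy[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    j <- seq.int(i + 2L, n)
    if (i == 1L) j <- j[j != n]  # edge n is adjacent to edge 1
    if (!length(j)) next
    if (any(segments_intersect(p1[i, ], p2[i, ],
                               p1[j, , drop = FALSE], p2[j, , drop = FALSE],
                               tol))) {
      return(FALSE)
    }
  }
  TRUE
}

# does segment a1-a2 properly intersect any of the segments b1[k,]-b2[k,]
segments_intersect <- function(a1, a2, b1, b2, tol = 1e-12) {
  ax <- a2[1L] - a1[1L]; ay <- a2[2L] - a1[2L]
  d1 <- ax * (b1[, 2L] - a1[2L]) - ay * (b1[, 1L] - a1[1L])
  d2 <- ax * (b2[, 2L] - a1[2L]) - ay * (b2[, 1L] - a1[1L])
  bx <- b2[, 1L] - b1[, 1L]; by <- b2[, 2L] - b1[, 2L]
  d3 <- bx * (a1[2L] - b1[, 2L]) - by * (a1[1L] - b1[, 1L])
  d4 <- bx * (a2[2L] - b1[, 2L]) - by * (a2[1L] - b1[, 1L])
  proper <- (d1 * d2 < -tol) & (d3 * d4 < -tol)
  if (any(proper)) return(TRUE)
  # collinear overlap / touching interior: treat exact touching of
  # non-adjacent edges as non-simple too
  touch <- (abs(d1) <= tol & on_segment_pt(a1, a2, b1, tol)) |
    (abs(d2) <= tol & on_segment_pt(a1, a2, b2, tol)) |
    (abs(d3) <= tol & on_segment(b1, b2, a1, tol)) |
    (abs(d4) <= tol & on_segment(b1, b2, a2, tol))
  any(touch)
}

on_segment <- function(s1, s2, p, tol) {
  # p scalar point, s1/s2 row matrices
  (p[1L] >= pmin(s1[, 1L], s2[, 1L]) - tol) & (p[1L] <= pmax(s1[, 1L], s2[, 1L]) + tol) &
    (p[2L] >= pmin(s1[, 2L], s2[, 2L]) - tol) & (p[2L] <= pmax(s1[, 2L], s2[, 2L]) + tol)
}
on_segment_pt <- function(a1, a2, p, tol) {
  # p row matrix, a1/a2 scalar points
  (p[, 1L] >= min(a1[1L], a2[1L]) - tol) & (p[, 1L] <= max(a1[1L], a2[1L]) + tol) &
    (p[, 2L] >= min(a1[2L], a2[2L]) - tol) & (p[, 2L] <= max(a1[2L], a2[2L]) + tol)
}

#' Derive the closed contour of a cell mesh
#'
#' The contour is the left-side points from pole to pole followed by the
#' right-side points in reverse, with coincident pole duplicates collapsed.
#'
#' @param mesh A [cell_mesh()].
#' @return A [contour()].
#' @export
contour_from_mesh <- function(mesh) {
  if (!is_cell_mesh(mesh)) mesh <- cell_mesh(mesh)
  pts <- mesh_outline_points(mesh)
  tryCatch(contour(pts), cellcurator_validation_error = function(e) {
    stop_validation(paste0("mesh does not yield a simple contour: ", conditionMessage(e)))
  })
}

#' Build a cell mesh from a closed contour
#'
#' The two mutually farthest contour vertices are taken as the cell poles
#' (ties broken toward the lowest vertex index); the contour is split into
#' two pole-to-pole sides, each side is resampled at `n_rows` arc-length
#' uniform positions, and corresponding samples are paired into mesh rows.
#' Rows 1 and `n_rows` are the (coincident) pole points on both sides.
#'
#' @param ctr A [contour()] (or 2-column vertex matrix).
#' @param n_rows Number of mesh rows, at least 4.
#' @return A [cell_mesh()].
#' @export
mesh_from_contour <- function(ctr, n_rows) {
  if (!is_contour(ctr)) ctr <- contour(ctr)
  n_rows <- as.integer(n_rows)
  if (n_rows < 4L) stop_validation("n_rows must be at least 4")
  n <- nrow(ctr)
  if (n < 4L) stop_validation("contour too small to mesh (need at least 4 vertices)")

  poles <- farthest_vertex_pair(ctr)
  a <- poles[1L]; b <- poles[2L]
  idx <- c(seq_len(n), seq_len(n))  # unrolled cyclic index
  side1 <- ctr[idx[a:(if (b >= a) b else b + n)], , drop = FALSE]
  side2 <- ctr[idx[b:(if (a >= b) a else a + n)], , drop = FALSE]
  side2 <- side2[nrow(side2):1L, , drop = FALSE]  # both sides run a -> b

  left <- resample_polyline(side1, n_rows)
  right <- resample_polyline(side2, n_rows)
  cell_mesh(cbind(left, right))
}

farthest_vertex_pair <- function(xy) {
  n <- nrow(xy)
  d2 <- as.matrix(stats::dist(xy))^2
  best <- which(d2 == max(d2), arr.ind = TRUE)
  best <- best[best[, 1L] < best[, 2L], , drop = FALSE]
  best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
  c(best[1L, 1L], best[1L, 2L])
}

# resample an open polyline at k arc-length-uniform positions (endpoints kept)
resample_polyline <- function(xy, k) {
  seg <- sqrt(rowSums((xy[-1L, , drop = FALSE] - xy[-nrow(xy), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) {
    return(matrix(rep(xy[1L, ], each = k), nrow = k))
  }
  at <- seq(0, total, length.out = k)
  cbind(stats::approx(s, xy[, 1L], xout = at, ties = "ordered")$y,
        stats::approx(s, xy[, 2L], xout = at, ties = "ordered")$y)
}

#' Midline of a cell mesh
#'
#' The polyline of per-row midpoints between the left and right mesh sides;
#' summing its segment lengths gives the cell length.
#'
#' @param mesh A [cell_mesh()].
#' @return Numeric matrix (`n_rows` x 2) of midpoint coordinates.
#' @export
midline_from_mesh <- function(mesh) {
  if (!is_cell_mesh(mesh)) mesh <- cell_mesh(mesh)
  cbind(x = (mesh[, 1L] + mesh[, 3L]) / 2,
        y = (mesh[, 2L] + mesh[, 4L]) / 2)
}
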