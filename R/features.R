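# Extraction of the 26 per-cell features from a cell mesh and its
# (inverted, background-subtracted) phase-contrast frame.

#' Manifest of the 26 extracted features
#'
#' Single source of truth for feature names, order and units. Lengths are
#' in micrometers when `pixel_size` is calibrated (default 1.0 leaves
#' everything in pixel units); intensities are arbitrary units of the
#' inverted, background-subtracted phase-contrast image.
#'
#' @return Tibble with columns `name`, `unit`, `description` (26 rows).
#' @export
feature_manifest <- function() {
  tibble::tribble(
    ~name, ~unit, ~description,
    "cell_length", "um", "sum of midpoint-to-midpoint step lengths along the mesh",
    "cell_width", "um", "mean of the top one-third of the segment widths",
    "cell_area", "um^2", "shoelace area of the cell contour",
    "cell_volume", "um^3", "per-segment cylinder volumes (trapezoidal rule), summed",
    "cell_surface_area", "um^2", "per-segment lateral cylinder surfaces, summed",
    "max_contour_curvature", "1/um", "maximum signed curvature along the contour",
    "min_contour_curvature", "1/um", "minimum signed curvature along the contour",
    "mean_contour_curvature", "1/um", "mean signed curvature along the contour",
    "cell_perimeter", "um", "closed-loop sum of consecutive contour vertex distances",
    "circularity", "dimensionless", "4*pi*area / perimeter^2",
    "compactness", "dimensionless", "perimeter^2 / area",
    "sphericity", "dimensionless", "2*sqrt(pi*area) / perimeter",
    "total_phaco_intensity", "a.u.", "sum of preprocessed intensities inside the contour",
    "max_phaco_intensity", "a.u.", "maximum preprocessed intensity inside the contour",
    "mean_phaco_intensity", "a.u.", "mean preprocessed intensity inside the contour",
    "phaco_contour_intensity_peaks", "count", "local maxima of the contour intensity profile",
    "max_contour_intensity", "a.u.", "maximum intensity along the contour",
    "min_contour_intensity", "a.u.", "minimum intensity along the contour",
    "mean_contour_intensity", "a.u.", "mean intensity along the contour",
    "max_contour_intensity_variability", "a.u.", "max rolling (window 10) std of contour intensity",
    "mean_contour_intensity_variability", "a.u.", "mean rolling (window 10) std of contour intensity",
    "midline_intensity_skewness", "dimensionless", "skewness of intensities along the midline",
    "midline_intensity_kurtosis", "dimensionless", "excess kurtosis of intensities along the midline",
    "max_expanded_contour_intensity", "a.u.", "max intensity along the contour expanded by 2 px",
    "mean_expanded_contour_intensity", "a.u.", "mean intensity along the contour expanded by 2 px",
    "mean_cell_edge_gradient", "a.u.", "mean intensity drop from eroded to expanded contour (+/-2 px)"
  )
}

#' Feature names in canonical order
#' @return Character vector of the 26 feature names.
#' @export
feature_names <- function() feature_manifest()$name

# -- image preprocessing ----------------------------------------------------

#' Invert and background-subtract a phase-contrast frame
#'
#' The image is inverted (`max(image) - image`, so dark cell interiors
#' become bright) and the mean inverted intensity outside the union of all
#' filled cell contours of the frame is subtracted. With no meshes the
#' background is the mean of the whole inverted image.
#'
#' @param image Numeric matrix (raw frame).
#' @param meshes List of [cell_mesh()] for every cell detected in this
#'   frame (may be empty).
#' @return Object of class `preprocessed_frame`: list with `intensity`
#'   (numeric matrix) and `background` (scalar, the subtracted mean).
#' @export
preprocess_frame <- function(image, meshes = list()) {
  image <- as.matrix(image)
  if (!all(is.finite(image))) stop_validation("frame image has non-finite values")
  inv <- max(image) - image
  mask <- matrix(FALSE, nrow(image), ncol(image))
  for (m in meshes) {
    ctr <- contour_from_mesh(m)
    mask <- mask | rasterize_polygon(ctr, dim(image))
  }
  if (all(mask)) stop_validation("cell masks cover the entire frame; background undefined")
  background <- mean(inv[!mask])
  structure(list(intensity = inv - background, background = background),
            class = "preprocessed_frame")
}

# logical mask of pixels whose centers fall inside (or on) the polygon
rasterize_polygon <- function(xy, dims) {
  mask <- matrix(FALSE, dims[1L], dims[2L])
  # pixel (row r, col c), 1-based indices, has center (x = c-1, y = r-1)
  cmin <- max(1L, floor(min(xy[, 1L])) + 1L)
  cmax <- min(dims[2L], ceiling(max(xy[, 1L])) + 1L)
  rmin <- max(1L, floor(min(xy[, 2L])) + 1L)
  rmax <- min(dims[1L], ceiling(max(xy[, 2L])) + 1L)
  if (cmin > cmax || rmin > rmax) return(mask)
  cols <- cmin:cmax; rows <- rmin:rmax
  px <- rep(cols - 1, each = length(rows))
  py <- rep(rows - 1, times = length(cols))
  inside <- points_in_polygon(px, py, xy)
  mask[cbind(rep(rows, times = length(cols)), rep(cols, each = length(rows)))] <- inside
  mask
}

#' Point-in-polygon test (boundary inclusive)
#'
#' Even-odd crossing-number test; points lying on an edge count as inside.
#'
#' @param px,py Point coordinates.
#' @param xy Polygon vertex matrix (closing edge implicit).
#' @param tol Tolerance for the on-edge test.
#' @return Logical vector.
#' @export
points_in_polygon <- function(px, py, xy, tol = 1e-9) {
  n <- nrow(xy)
  x1 <- xy[, 1L]; y1 <- xy[, 2L]
  x2 <- c(x1[-1L], x1[1L]); y2 <- c(y1[-1L], y1[1L])
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  for (e in seq_len(n)) {
    crosses <- which((y1[e] > py) != (y2[e] > py))
    if (length(crosses)) {
      xint <- x1[e] + (py[crosses] - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e])
      idx <- crosses[px[crosses] < xint]
      inside[idx] <- !inside[idx]
    }
    # on-edge: zero cross product and within bounding box
    dx <- x2[e] - x1[e]; dy <- y2[e] - y1[e]
    cr <- dx * (py - y1[e]) - dy * (px - x1[e])
    onedge <- onedge | (abs(cr) <= tol * (abs(dx) + abs(dy) + 1) &
                          px >= min(x1[e], x2[e]) - tol & px <= max(x1[e], x2[e]) + tol &
                          py >= min(y1[e], y2[e]) - tol & py <= max(y1[e], y2[e]) + tol)
  }
  inside | onedge
}

#' Bilinear image sampling at subpixel coordinates
#'
#' @param image Numeric matrix.
#' @param x,y 0-based pixel-center coordinates (x = column, y = row).
#' @return Interpolated intensities.
#' @export
bilinear_sample <- function(image, x, y) {
  h <- nrow(image); w <- ncol(image)
  if (any(x < 0 | x > w - 1 | y < 0 | y > h - 1)) {
    stop_boundary("sample coordinates outside image bounds")
  }
  x0 <- pmin(floor(x), w - 2); y0 <- pmin(floor(y), h - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- image[cbind(y0 + 1, x0 + 1)]
  i01 <- image[cbind(y0 + 1, x0 + 2)]
  i10 <- image[cbind(y0 + 2, x0 + 1)]
  i11 <- image[cbind(y0 + 2, x0 + 2)]
  i00 * (1 - fx) * (1 - fy) + i01 * fx * (1 - fy) +
    i10 * (1 - fx) * fy + i11 * fx * fy
}

# -- geometry features ------------------------------------------------------

#' Per-row width and per-segment step-length profile of a mesh
#'
#' @param mesh A [cell_mesh()].
#' @param pixel_size Micrometers per pixel (default 1 leaves pixel units).
#' @return List with `widths` (per-row left-right distances), `step_lengths`
#'   (consecutive midpoint distances) and `midline` (midpoint matrix, in
#'   pixel coordinates).
#' @export
geometry_profile <- function(mesh, pixel_size = 1) {
  if (!is_cell_mesh(mesh)) mesh <- cell_mesh(mesh)
  if (pixel_size <= 0) stop_validation("pixel_size must be positive")
  widths <- sqrt((mesh[, 1L] - mesh[, 3L])^2 + (mesh[, 2L] - mesh[, 4L])^2) * pixel_size
  mid <- midline_from_mesh(mesh)
  dmid <- diff(mid)
  step_lengths <- sqrt(rowSums(dmid^2)) * pixel_size
  list(widths = widths, step_lengths = step_lengths, midline = mid)
}

#' Cell length: summed midline step lengths
#' @param profile A [geometry_profile()].
#' @return Scalar length.
#' @export
cell_length <- function(profile) sum(profile$step_lengths)

#' Cell width: mean of the top one-third of segment widths
#'
#' The widths are sorted descending and the largest `k = max(1,
#' round(n/3))` are averaged (half-away-from-zero rounding).
#'
#' @param profile A [geometry_profile()].
#' @return Scalar width.
#' @export
cell_width <- function(profile) {
  w <- sort(profile$widths, decreasing = TRUE)
  k <- max(1L, floor(length(w) / 3 + 0.5))
  mean(w[seq_len(k)])
}

#' Cell area from the contour (shoelace)
#' @param ctr A [contour()].
#' @param pixel_size Micrometers per pixel.
#' @return Scalar area (pixel_size^2 scaling).
#' @export
cell_area <- function(ctr, pixel_size = 1) {
  a <- abs(polygon_signed_area(ctr)) * pixel_size^2
  if (a <= 0) stop_validation("degenerate (zero-area) contour")
  a
}

#' Cell perimeter: closed-loop sum of consecutive vertex distances
#' @inheritParams cell_area
#' @return Scalar perimeter.
#' @export
cell_perimeter <- function(ctr, pixel_size = 1) {
  closed <- rbind(ctr, ctr[1L, ])
  sum(sqrt(rowSums(diff(closed)^2))) * pixel_size
}

#' Circularity, compactness and sphericity
#'
#' Circularity is `4*pi*area / perimeter^2` (1 for a circle), compactness
#' its reciprocal scaled to `perimeter^2 / area`, and sphericity
#' `2*sqrt(pi*area) / perimeter` (the square root of circularity; also 1
#' for a circle). Set `options(cellcurator.sphericity = function(area,
#' perimeter) ...)` to swap the sphericity formula.
#'
#' @param area,perimeter Positive scalars.
#' @return Named vector `(circularity, compactness, sphericity)`.
#' @export
shape_indices <- function(area, perimeter) {
  if (!is.finite(area) || !is.finite(perimeter) || area <= 0 || perimeter <= 0) {
    stop_validation("area and perimeter must be positive")
  }
  sph_fun <- getOption("cellcurator.sphericity",
                       function(area, perimeter) 2 * sqrt(pi * area) / perimeter)
  c(circularity = 4 * pi * area / perimeter^2,
    compactness = perimeter^2 / area,
    sphericity = sph_fun(area, perimeter))
}

#' Cell volume: per-segment cylinders, trapezoidal rule
#'
#' Each mesh segment contributes `pi * (r_i^2 + r_{i+1}^2)/2 * step`, with
#' `r = width/2`.
#'
#' @param profile A [geometry_profile()].
#' @return Scalar volume.
#' @export
cell_volume <- function(profile) {
  r <- profile$widths / 2
  n <- length(r)
  sum(pi * (r[-n]^2 + r[-1L]^2) / 2 * profile$step_lengths)
}

#' Cell surface area: per-segment lateral cylinder surfaces
#'
#' Each segment contributes `2*pi * (r_i + r_{i+1})/2 * step`; the pole
#' rows enter through their (possibly zero) widths and no separate
#' end-cap term is added.
#'
#' @param profile A [geometry_profile()].
#' @return Scalar surface area.
#' @export
cell_surface_area <- function(profile) {
  r <- profile$widths / 2
  n <- length(r)
  sum(2 * pi * (r[-n] + r[-1L]) / 2 * profile$step_lengths)
}

#' Signed curvature statistics along a contour
#'
#' Per-vertex signed plane-curve curvature
#' `k = (x'y'' - y'x'') / (x'^2 + y'^2)^(3/2)` with wrap-around central
#' differences; positive for counter-clockwise traversal of a convex
#' region.
#'
#' @param ctr A [contour()] with at least 5 vertices (consecutive
#'   duplicates are collapsed first).
#' @param pixel_size Micrometers per pixel; curvature scales as its
#'   reciprocal.
#' @return Named vector `(max, min, mean)` of the per-vertex curvatures.
#' @export
curvature_stats <- function(ctr, pixel_size = 1) {
  xy <- drop_consecutive_duplicates(as.matrix(unclass(ctr)))
  n <- nrow(xy)
  if (n < 5L) stop_validation("curvature needs a contour with at least 5 distinct vertices")
  ip <- c(2:n, 1L); im <- c(n, 1:(n - 1L))
  d1 <- (xy[ip, , drop = FALSE] - xy[im, , drop = FALSE]) / 2
  d2 <- xy[ip, , drop = FALSE] - 2 * xy + xy[im, , drop = FALSE]
  speed2 <- d1[, 1L]^2 + d1[, 2L]^2
  if (any(speed2 < 1e-18)) stop_validation("zero tangent in contour; cannot compute curvature")
  kappa <- (d1[, 1L] * d2[, 2L] - d1[, 2L] * d2[, 1L]) / speed2^1.5 / pixel_size
  c(max = max(kappa), min = min(kappa), mean = mean(kappa))
}

# -- intensity features -----------------------------------------------------

#' Intensity profile along a contour
#'
#' Bilinear interpolation of the preprocessed image at each vertex, in
#' traversal order.
#'
#' @param pimage A [preprocess_frame()] result (or bare numeric matrix).
#' @param ctr Vertex matrix.
#' @return Numeric vector of intensities.
#' @export
contour_profile <- function(pimage, ctr) {
  img <- if (inherits(pimage, "preprocessed_frame")) pimage$intensity else as.matrix(pimage)
  bilinear_sample(img, ctr[, 1L], ctr[, 2L])
}

#' Max, min and mean of an intensity profile
#' @param intensities Non-empty numeric vector.
#' @return Named vector `(max, min, mean)`.
#' @export
contour_stats <- function(intensities) {
  if (!length(intensities)) stop_validation("empty intensity profile")
  c(max = max(intensities), min = min(intensities), mean = mean(intensities))
}

#' Count local maxima of an intensity profile
#'
#' Strict local maxima in a linear (non-circular) traversal; a plateau is
#' counted once; the endpoints are never peaks.
#'
#' @param intensities Non-empty numeric vector.
#' @return Integer peak count.
#' @export
contour_peak_count <- function(intensities) {
  r <- rle(as.numeric(intensities))
  v <- r$values
  k <- length(v)
  if (k < 3L) return(0L)
  core <- 2:(k - 1L)
  sum(v[core] > v[core - 1L] & v[core] > v[core + 1L])
}

#' Rolling standard deviation of a contour intensity profile
#'
#' Sample (n-1) standard deviation over each full window of `window`
#' consecutive values; partial windows are not used.
#'
#' @param intensities Numeric vector of length at least `window`.
#' @param window Window size (default 10).
#' @return Named vector `(max, mean)` over the rolling values.
#' @export
contour_variability <- function(intensities, window = 10L) {
  if (length(intensities) < window) {
    stop_validation(sprintf("profile shorter than rolling window (%d < %d)",
                            length(intensities), window))
  }
  rs <- zoo::rollapply(as.numeric(intensities), width = window, FUN = sd)
  c(max = max(rs), mean = mean(rs))
}

#' Skewness and excess kurtosis of midline intensities
#'
#' Fisher definitions, bias-uncorrected: third and fourth standardized
#' moments of the intensities sampled (bilinearly) at the midline points;
#' kurtosis is reported as excess (normal = 0). Degenerate variance
#' (< 1e-12) returns (0, 0).
#'
#' @param pimage A [preprocess_frame()] result (or matrix).
#' @param midline Midpoint matrix from [midline_from_mesh()].
#' @return Named vector `(skewness, kurtosis)`.
#' @export
midline_moments <- function(pimage, midline) {
  v <- contour_profile(pimage, midline)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 < 1e-12) return(c(skewness = 0, kurtosis = 0))
  c(skewness = mean((v - m)^3) / m2^1.5,
    kurtosis = mean((v - m)^4) / m2^2 - 3)
}

#' Offset a contour along its outward normals
#'
#' Each vertex is displaced by `offset_px` along the outward normal
#' (wrap-around central-difference tangents), preserving vertex count and
#' correspondence. Positive offsets expand, negative erode.
#'
#' @param ctr A [contour()] (CCW).
#' @param offset_px Signed offset in pixels.
#' @return Offset contour (same vertex order and count).
#' @export
offset_contour <- function(ctr, offset_px) {
  xy <- as.matrix(unclass(ctr))
  n <- nrow(xy)
  ip <- c(2:n, 1L); im <- c(n, 1:(n - 1L))
  tx <- (xy[ip, 1L] - xy[im, 1L]) / 2
  ty <- (xy[ip, 2L] - xy[im, 2L]) / 2
  len <- sqrt(tx^2 + ty^2)
  if (any(len < 1e-12)) stop_validation("zero tangent in contour; cannot offset")
  # for CCW (positive shoelace) orientation the outward normal is (t_y, -t_x)
  out <- xy + offset_px * cbind(ty / len, -tx / len)
  if (!is_simple_polygon(out)) {
    stop_validation(sprintf("offsetting by %g px collapses the contour", offset_px))
  }
  structure(out, dimnames = list(NULL, c("x", "y")),
            class = c("cell_contour", "matrix", "array"))
}

#' Max and mean intensity along the 2-px-expanded contour
#' @inheritParams contour_profile
#' @return Named vector `(max, mean)`.
#' @export
expanded_contour_stats <- function(pimage, ctr) {
  s <- contour_stats(contour_profile(pimage, offset_contour(ctr, 2)))
  s[c("max", "mean")]
}

#' Mean intensity gradient across the cell edge
#'
#' Mean over corresponding vertices of (intensity on the 2-px-eroded
#' contour minus intensity on the 2-px-expanded contour); positive when
#' the (inverted) cell interior is brighter than its surroundings.
#'
#' @inheritParams contour_profile
#' @return Scalar mean gradient.
#' @export
edge_gradient <- function(pimage, ctr) {
  inner <- contour_profile(pimage, offset_contour(ctr, -2))
  outer <- contour_profile(pimage, offset_contour(ctr, 2))
  mean(inner - outer)
}

#' Total, max and mean intensity inside a contour
#'
#' Over pixels whose centers fall inside or on the polygon.
#'
#' @inheritParams contour_profile
#' @return Named vector `(total, max, mean)`.
#' @export
interior_intensity_stats <- function(pimage, ctr) {
  img <- if (inherits(pimage, "preprocessed_frame")) pimage$intensity else as.matrix(pimage)
  mask <- rasterize_polygon(as.matrix(unclass(ctr)), dim(img))
  if (!any(mask)) stop_validation("contour contains no pixel centers")
  v <- img[mask]
  c(total = sum(v), max = max(v), mean = mean(v))
}

# -- orchestration ----------------------------------------------------------

#' Extract the 26-feature vector for one cell
#'
#' @param mesh The cell's [cell_mesh()].
#' @param pimage The frame's [preprocess_frame()] result.
#' @param pixel_size Micrometers per pixel (default 1 = pixel units).
#' @return Named numeric vector with the 26 features in manifest order.
#' @export
extract_features <- function(mesh, pimage, pixel_size = 1) {
  if (!is_cell_mesh(mesh)) mesh <- cell_mesh(mesh)
  ctr <- contour_from_mesh(mesh)
  prof <- geometry_profile(mesh, pixel_size)
  len <- cell_length(prof)
  wid <- cell_width(prof)
  area <- cell_area(ctr, pixel_size)
  peri <- cell_perimeter(ctr, pixel_size)
  shp <- shape_indices(area, peri)
  curv <- curvature_stats(ctr, pixel_size)
  interior <- interior_intensity_stats(pimage, ctr)
  cprof <- contour_profile(pimage, ctr)
  cstat <- contour_stats(cprof)
  cvar <- contour_variability(cprof)
  mm <- midline_moments(pimage, prof$midline)
  exp2 <- expanded_contour_stats(pimage, ctr)
  grad <- edge_gradient(pimage, ctr)
  out <- c(
    cell_length = len, cell_width = wid, cell_area = area,
    cell_volume = cell_volume(prof), cell_surface_area = cell_surface_area(prof),
    max_contour_curvature = unname(curv["max"]),
    min_contour_curvature = unname(curv["min"]),
    mean_contour_curvature = unname(curv["mean"]),
    cell_perimeter = peri,
    circularity = unname(shp["circularity"]),
    compactness = unname(shp["compactness"]),
    sphericity = unname(shp["sphericity"]),
    total_phaco_intensity = unname(interior["total"]),
    max_phaco_intensity = unname(interior["max"]),
    mean_phaco_intensity = unname(interior["mean"]),
    phaco_contour_intensity_peaks = as.numeric(contour_peak_count(cprof)),
    max_contour_intensity = unname(cstat["max"]),
    min_contour_intensity = unname(cstat["min"]),
    mean_contour_intensity = unname(cstat["mean"]),
    max_contour_intensity_variability = unname(cvar["max"]),
    mean_contour_intensity_variability = unname(cvar["mean"]),
    midline_intensity_skewness = unname(mm["skewness"]),
    midline_intensity_kurtosis = unname(mm["kurtosis"]),
    max_expanded_contour_intensity = unname(exp2["max"]),
    mean_expanded_contour_intensity = unname(exp2["mean"]),
    mean_cell_edge_gradient = grad
  )
  stopifnot(identical(names(out), feature_names()))
  out
}

#' Extract features for a whole cell table
#'
#' Each frame is preprocessed once (inversion + background subtraction
#' using all meshes of that frame); every record is then featurized. A
#' record failing any sub-step (e.g. a mesh hanging off the image edge)
#' yields an all-missing feature row and is retained; failures are
#' reported in the `failures` attribute and summarized in a warning.
#'
#' @param records A [cell_table()] tibble. The `frame` column indexes into
#'   `images` (frame index as produced by [read_image_frames()]).
#' @param images Named list of frame images (names = frame indices).
#' @param pixel_size Micrometers per pixel.
#' @return Tibble with columns `frame`, `cell_id`, `contour` (list of
#'   vertex matrices) and the 26 feature columns; attribute `failures` is
#'   a tibble of (frame, cell_id, reason) for failed records.
#' @export
extract_feature_table <- function(records, images, pixel_size = 1) {
  frames <- unique(records$frame)
  pimgs <- list()
  for (f in frames) {
    key <- as.character(f)
    if (is.null(images[[key]])) {
      stop_validation(sprintf("no image for frame %d", f))
    }
    pimgs[[key]] <- preprocess_frame(images[[key]],
                                     records$mesh[records$frame == f])
  }
  n <- nrow(records)
  mat <- matrix(NA_real_, n, length(feature_names()),
                dimnames = list(NULL, feature_names()))
  contours <- vector("list", n)
  fail_frame <- integer(0); fail_cell <- integer(0); fail_reason <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch({
      contours[[i]] <- tryCatch(unclass(contour_from_mesh(records$mesh[[i]])),
                                error = function(e) NULL)
      extract_features(records$mesh[[i]], pimgs[[as.character(records$frame[i])]],
                       pixel_size)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fail_frame <- c(fail_frame, records$frame[i])
      fail_cell <- c(fail_cell, records$cell_id[i])
      fail_reason <- c(fail_reason, conditionMessage(res))
    } else {
      mat[i, ] <- res
    }
  }
  if (length(fail_frame)) {
    warn(sprintf("feature extraction failed for %d of %d record(s); rows kept with missing values",
                 length(fail_frame), n))
  }
  out <- tibble::tibble(frame = records$frame, cell_id = records$cell_id,
                        contour = contours)
  out <- cbind(out, tibble::as_tibble(mat))
  out <- tibble::as_tibble(out)
  attr(out, "failures") <- tibble::tibble(frame = fail_frame, cell_id = fail_cell,
                                          reason = fail_reason)
  out
}

#' Write / read a feature table (CSV dialect)
#'
#' Columns: `frame`, `cell_id`, `contour` (JSON array of vertices), the 26
#' features, and `label` if present. File names conventionally end in
#' `svm_features.csv`.
#'
#' @param features Feature tibble from [extract_feature_table()].
#' @param path CSV path.
#' @return Invisibly `path` (write); the tibble (read).
#' @export
write_feature_table <- function(features, path) {
  df <- as.data.frame(features)
  if (!is.null(features$contour)) {
    df$contour <- vapply(features$contour, function(ctr) {
      if (is.null(ctr)) return(NA_character_)
      as.character(jsonlite::toJSON(as.matrix(unclass(ctr)), digits = NA))
    }, character(1))
  }
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("feature table not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(c("frame", "cell_id", feature_names()), names(df))
  if (length(missing_cols)) {
    stop_format(sprintf("feature table %s lacks column(s): %s", path,
                        paste(missing_cols, collapse = ", ")))
  }
  if ("contour" %in% names(df)) {
    ctr <- lapply(df$contour, function(s) {
      if (is.na(s) || !nzchar(s)) return(NULL)
      m <- jsonlite::fromJSON(s)
      matrix(as.numeric(m), ncol = 2, dimnames = list(NULL, c("x", "y")))
    })
    df$contour <- NULL
    out <- tibble::as_tibble(df)
    out <- tibble::add_column(out, contour = ctr, .after = "cell_id")
  } else {
    out <- tibble::as_tibble(df)
  }
  out
}
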