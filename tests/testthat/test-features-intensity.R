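# Intensity features: preprocessing, sampling, profiles, moments,
# contour offsets, interior statistics.

# rectangle mesh whose contour is [2.5, 9.5] x [2.5, 7.5]
block_mesh <- function() {
  x <- seq(2.5, 9.5, by = 1)
  cell_mesh(cbind(x, 2.5, x, 7.5))
}

test_that("preprocessing inverts and subtracts the outside-cell background", {
  const <- matrix(7, 12, 12)
  p <- preprocess_frame(const, list(block_mesh()))
  expect_equal(p$background, 0)
  expect_true(all(p$intensity == 0))

  b <- 100; v <- 60
  img <- matrix(b, 12, 12)
  mask <- cellcurator:::rasterize_polygon(unclass(contour_from_mesh(block_mesh())),
                                          dim(img))
  img[mask] <- v
  p2 <- preprocess_frame(img, list(block_mesh()))
  expect_equal(unique(p2$intensity[mask]), b - v)
  expect_equal(unique(p2$intensity[!mask]), 0)
})

test_that("with no meshes the background is the whole-frame mean", {
  set.seed(2)
  img <- matrix(runif(100, 0, 10), 10)
  p <- preprocess_frame(img)
  expect_equal(mean(p$intensity), 0, tolerance = 1e-12)
})

test_that("exterior of a preprocessed noisy scene averages to zero", {
  set.seed(31)
  sc <- generate_scene(scene_config(seed = 31), frame = 0L)
  p <- preprocess_frame(sc$image, sc$records$mesh)
  mask <- Reduce(`|`, lapply(sc$records$mesh, function(m) {
    cellcurator:::rasterize_polygon(unclass(contour_from_mesh(m)), dim(sc$image))
  }))
  ext <- p$intensity[!mask]
  se <- sd(ext) / sqrt(length(ext))
  expect_lt(abs(mean(ext)), 3 * se)
})

test_that("bilinear sampling is exact at pixel centers and averages between", {
  img <- matrix(0, 4, 4)
  img[3, ] <- 4; img[4, ] <- 4  # rows y = 2, 3 hold value 4
  expect_equal(bilinear_sample(img, 1, 0), 0)
  expect_equal(bilinear_sample(img, 1, 2), 4)
  expect_equal(bilinear_sample(img, 0.5, 1.5), 2)  # midpoint of 0,0,4,4
  expect_error(bilinear_sample(img, -0.1, 0), class = "cellcurator_boundary_error")
  expect_error(bilinear_sample(img, 0, 3.2), class = "cellcurator_boundary_error")
})

test_that("contour profile statistics match brute-force scans", {
  expect_equal(unname(contour_stats(c(1, 2, 3))), c(3, 1, 2))
  expect_equal(unname(contour_stats(rep(4.2, 9))), c(4.2, 4.2, 4.2))
  set.seed(7)
  x <- rnorm(200)
  expect_equal(unname(contour_stats(x)), c(max(x), min(x), mean(x)))
  expect_error(contour_stats(numeric(0)), class = "cellcurator_validation_error")
})

test_that("peak counting finds strict maxima, plateaus once, no wrap-around", {
  expect_equal(contour_peak_count(rep(1, 50)), 0L)
  expect_equal(contour_peak_count(c(0, 1, 0, 1, 0)), 2L)
  expect_equal(contour_peak_count(c(0, 2, 2, 2, 0)), 1L)  # plateau counted once
  expect_equal(contour_peak_count(c(5, 1, 5)), 0L)        # endpoints excluded
  set.seed(13)
  x <- rnorm(200)
  brute <- sum(vapply(2:199, function(i) x[i] > x[i - 1] && x[i] > x[i + 1],
                      logical(1)))
  expect_equal(contour_peak_count(x), brute)
})

test_that("rolling variability uses full sample-sd windows", {
  expect_equal(unname(contour_variability(rep(3, 25))), c(0, 0))
  x <- c(rep(0, 20), 10, rep(0, 20))
  win_sds <- vapply(1:(length(x) - 9), function(i) sd(x[i:(i + 9)]), numeric(1))
  expect_equal(unname(contour_variability(x)), c(max(win_sds), mean(win_sds)))
  set.seed(19)
  r <- rnorm(60)
  v <- contour_variability(r)
  expect_gte(v[["max"]], v[["mean"]])
  expect_error(contour_variability(rnorm(9)), class = "cellcurator_validation_error")
})

test_that("midline moments follow the Fisher conventions", {
  img <- matrix(5, 6, 6)
  mid <- cbind(x = 0:4, y = 2)
  expect_equal(unname(midline_moments(img, mid)), c(0, 0))  # degenerate variance
  # values symmetric about their mean -> zero third moment
  img2 <- matrix(rep(c(1, 2, 3, 4, 5), each = 5), 5, 5)
  expect_equal(midline_moments(img2, cbind(0:4, 2))[["skewness"]], 0)
  set.seed(23)
  big <- matrix(rnorm(10000), 100)
  pts <- expand.grid(x = 0:99, y = 0:99)
  mm <- midline_moments(big, as.matrix(pts))
  expect_equal(mm[["skewness"]], 0, tolerance = 0.1)
  expect_equal(mm[["kurtosis"]], 0, tolerance = 0.1)
})

test_that("contour offsetting matches the circle oracle and round-trips", {
  gon <- regular_polygon(64, R = 5, center = c(20, 20))
  expect_equal(unclass(offset_contour(gon, 0)), unclass(gon), ignore_attr = TRUE)
  out <- offset_contour(gon, 2)
  radii <- sqrt(rowSums(sweep(unclass(out), 2, c(20, 20))^2))
  expect_equal(radii, rep(7, 64), tolerance = 0.01)
  back <- offset_contour(out, -2)
  expect_lt(max(abs(unclass(back) - unclass(gon))), 0.1)
  # degenerate tangent (coincident neighbors in a raw vertex matrix)
  spike <- matrix(c(0, 2, 0, -2, 0, 0, 0, 0), 4, 2)
  expect_error(offset_contour(spike, 1), class = "cellcurator_validation_error")
  # eroding past the half-width of a slotted shape self-intersects
  slot <- contour(cbind(c(0, 20, 20, 11, 11, 9, 9, 0),
                        c(0, 0, 10, 10, 2, 2, 10, 10)))
  expect_error(offset_contour(slot, -2), class = "cellcurator_validation_error")
})

test_that("expanded-contour statistics compose the primitive operations", {
  img <- matrix(3.5, 40, 40)
  gon <- regular_polygon(32, R = 6, center = c(20, 20))
  expect_equal(unname(expanded_contour_stats(img, gon)), c(3.5, 3.5))
  set.seed(3)
  img2 <- matrix(runif(1600), 40)
  direct <- contour_stats(contour_profile(img2, offset_contour(gon, 2)))
  expect_equal(expanded_contour_stats(img2, gon), direct[c("max", "mean")])
})

test_that("a halo ring outside the cell raises the expanded-contour mean", {
  set.seed(41)
  cfg <- scene_config(seed = 41, noise_sd = 0)
  cell <- generate_cell(cfg)
  p <- preprocess_frame(cell$stamp, list(cell$mesh))
  ctr <- contour_from_mesh(cell$mesh)
  on_ctr <- mean(contour_profile(p, ctr))
  expanded <- expanded_contour_stats(p, ctr)
  # the halo peaks ~1.5 px outside the boundary: stepping 2 px out must not
  # fall back to background level; in the inverted image the halo is a dark
  # ring, so the expanded mean drops below the boundary mean
  expect_lt(expanded[["mean"]], on_ctr)
  expect_gt(abs(expanded[["mean"]] - on_ctr), 1)
})

test_that("edge gradient is positive across a bright-interior edge and antisymmetric", {
  img <- matrix(0, 60, 60)
  gon <- regular_polygon(48, R = 10, center = c(30, 30))
  mask <- cellcurator:::rasterize_polygon(unclass(gon), dim(img))
  img[mask] <- 10
  g <- edge_gradient(img, gon)
  inner <- contour_profile(img, offset_contour(gon, -2))
  outer <- contour_profile(img, offset_contour(gon, 2))
  expect_equal(g, mean(inner - outer))
  expect_gt(g, 5)
  expect_equal(edge_gradient(-img, gon), -g)
  expect_equal(edge_gradient(matrix(2, 60, 60), gon), 0)
})

test_that("interior statistics count pixels inside or on the contour", {
  img <- matrix(2, 4, 4)
  full <- contour(cbind(c(-0.5, 3.5, 3.5, -0.5), c(-0.5, -0.5, 3.5, 3.5)))
  s <- interior_intensity_stats(img, full)
  expect_equal(unname(s), c(32, 2, 2))
  img2 <- matrix(0, 10, 10); img2[5, 5] <- 7
  box <- contour(cbind(c(1, 8, 8, 1), c(1, 1, 8, 8)))
  s2 <- interior_intensity_stats(img2, box)
  expect_equal(s2[["total"]], 7)
  expect_equal(s2[["max"]], 7)
})

test_that("rasterization agrees with a brute-force point-in-polygon scan", {
  rect <- contour(cbind(c(0.5, 9.5, 9.5, 0.5), c(0.5, 0.5, 2.5, 2.5)))
  mask <- cellcurator:::rasterize_polygon(unclass(rect), c(12, 12))
  # independent scan: winding test via angle summation at each pixel center
  brute <- 0L
  for (r in 1:12) for (cc in 1:12) {
    x <- cc - 1; y <- r - 1
    vx <- unclass(rect)[, 1] - x; vy <- unclass(rect)[, 2] - y
    ang <- atan2(vy, vx)
    dang <- diff(c(ang, ang[1]))
    dang <- ifelse(dang > pi, dang - 2 * pi, ifelse(dang < -pi, dang + 2 * pi, dang))
    if (abs(sum(dang)) > pi) brute <- brute + 1L
  }
  expect_equal(sum(mask), brute)
  expect_equal(sum(mask), 18L)  # 9 x 2 interior pixel centers
})

test_that("extract_features returns 26 finite values for a clean cell", {
  set.seed(43)
  cfg <- scene_config(seed = 43)
  cell <- generate_cell(cfg)
  p <- preprocess_frame(cell$stamp, list(cell$mesh))
  fv <- extract_features(cell$mesh, p)
  expect_length(fv, 26L)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
  expect_gt(fv[["cell_length"]], 0)
  expect_gt(fv[["total_phaco_intensity"]], 0)
})

test_that("a mesh hanging off the image edge yields an all-missing row", {
  dat <- small_scene_data()
  off_mesh <- cell_mesh(unclass(rect_mesh()) - 20)  # negative coordinates
  recs <- cell_table(0L, 99L, list(off_mesh))
  expect_warning(
    ft <- extract_feature_table(recs, list("0" = dat$images[["0"]])),
    "failed")
  expect_true(all(is.na(as.data.frame(ft)[1, feature_names()])))
  expect_equal(nrow(attr(ft, "failures")), 1L)
})

test_that("batch extraction keeps the shape contract", {
  dat <- small_scene_data()
  ft <- dat$features
  expect_equal(nrow(ft), nrow(dat$records))
  expect_true(all(feature_names() %in% names(ft)))
  expect_identical(names(ft)[1:3], c("frame", "cell_id", "contour"))
})

test_that("intensity features are invariant under integer scene translation", {
  set.seed(47)
  cfg <- scene_config(seed = 47, noise_sd = 10)
  cell <- generate_cell(cfg)
  img <- cell$stamp + matrix(rnorm(length(cell$stamp), 0, 10), nrow(cell$stamp))
  p <- preprocess_frame(img, list(cell$mesh))
  fv <- extract_features(cell$mesh, p)
  # shift image content and mesh by the same integer offset (dx right, dy up
  # in pixel coordinates, i.e. toward larger row index)
  dx <- 6L; dy <- -4L
  img2 <- matrix(median(img), nrow(img), ncol(img))
  rows <- seq_len(nrow(img) - abs(dy)); cols <- seq_len(ncol(img) - abs(dx))
  img2[rows + ifelse(dy > 0, dy, 0L), cols + ifelse(dx > 0, dx, 0L)] <-
    img[rows + ifelse(dy < 0, -dy, 0L), cols + ifelse(dx < 0, -dx, 0L)]
  mesh2 <- cell_mesh(sweep(unclass(cell$mesh), 2, c(dx, dy, dx, dy), "+"))
  p2 <- preprocess_frame(img2, list(mesh2))
  fv2 <- extract_features(mesh2, p2)
  geo <- c("cell_length", "cell_width", "cell_area", "cell_perimeter")
  expect_equal(fv2[geo], fv[geo], tolerance = 1e-9)
  inten <- c("max_contour_intensity", "mean_contour_intensity",
             "mean_cell_edge_gradient", "max_phaco_intensity")
  expect_equal(fv2[inten], fv[inten], tolerance = 0.05)
})
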