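# Fixtures built in code: simple meshes, polygons and miniature scenes.

# 11-row rectangle mesh: left side along y = 0, right side along y = 2
rect_mesh <- function() {
  x <- 0:10
  cell_mesh(cbind(x, 0, x, 2))
}

# regular n-gon contour (CCW), circumradius R
regular_polygon <- function(n, R = 5, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  contour(cbind(center[1] + R * cos(th), center[2] + R * sin(th)))
}

# analytic capsule mesh (spherocylinder), via the generator's primitive
capsule_fixture <- function(center = c(50, 50), angle = 0.4, len = 30,
                            width = 8, spacing = 1) {
  cellcurator:::capsule_mesh(center, angle, len, width, spacing)
}

rotate_mesh <- function(mesh, theta, pivot = c(0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  m <- unclass(mesh)
  left <- sweep(sweep(m[, 1:2], 2, pivot) %*% t(R), 2, pivot, "+")
  right <- sweep(sweep(m[, 3:4], 2, pivot) %*% t(R), 2, pivot, "+")
  cell_mesh(cbind(left, right))
}

# tiny labeled feature table (k rows) with valid schema for labeling tests
toy_feature_table <- function(k = 3) {
  mat <- matrix(seq_len(k * 26), k, dimnames = list(NULL, feature_names()))
  out <- tibble::tibble(frame = rep(0L, k), cell_id = seq_len(k) - 1L)
  cbind(out, tibble::as_tibble(mat))
}

# one small rendered scene with features extracted; cached per session
small_scene_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- scene_config(seed = 303)
      scenes <- generate_dataset(cfg, 3)
      imgs <- lapply(scenes, `[[`, "image")
      names(imgs) <- as.character(seq_along(imgs) - 1L)
      recs <- do.call(rbind, lapply(scenes, `[[`, "records"))
      truth <- do.call(rbind, lapply(scenes, `[[`, "truth"))
      feats <- suppressWarnings(extract_feature_table(recs, imgs))
      cache <<- list(scenes = scenes, images = imgs, records = recs,
                     truth = truth, features = feats)
    }
    cache
  }
})
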