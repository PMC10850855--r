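# Seeded generator of phase-contrast-like scenes: rod-shaped (capsule)
# cells with dark interiors and bright halos on a noisy background,
# ground-truth meshes, and controlled defective detections. The rendering
# is a stylized model (smooth interior depression + Gaussian halo ring +
# additive Gaussian noise), not an optics simulation; it is sufficient to
# exercise every geometry and intensity feature.

#' Configuration for synthetic scene generation
#'
#' @param image_size Frame size in pixels, `c(rows, cols)`.
#' @param cells_per_frame Cells detected per frame.
#' @param length_range,width_range Tip-to-tip cell length and width ranges
#'   in pixels (uniform sampling).
#' @param depression_depth Intensity drop of the cell interior below the
#'   background (raw units).
#' @param halo_amplitude,halo_width,halo_offset Gaussian halo ring:
#'   amplitude above background, standard deviation (px), and peak
#'   distance outside the cell boundary (px).
#' @param background_level Mean raw background intensity.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param defect_mix Named fractions for `truncated`, `shifted`, `merged`,
#'   `adjacent` defects; their sum is the bad-class fraction (must be
#'   <= 1).
#' @param margin Minimum distance of cell tips from the frame border (px);
#'   must leave room for shifts (up to 5 px) and contour expansion.
#' @param mesh_spacing Approximate mesh row spacing along the cell axis (px).
#' @param seed Seed consumed by [generate_dataset()].
#' @return A `scene_config` list.
#' @export
scene_config <- function(image_size = c(256L, 256L),
                         cells_per_frame = 20L,
                         length_range = c(22, 40),
                         width_range = c(7, 10),
                         depression_depth = 350,
                         halo_amplitude = 250,
                         halo_width = 1.5,
                         halo_offset = 1.5,
                         background_level = 2000,
                         noise_sd = 40,
                         defect_mix = c(truncated = 0.1, shifted = 0.1,
                                        merged = 0.1, adjacent = 0.1),
                         margin = 14,
                         mesh_spacing = 1,
                         seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 32L))
  if (any(length_range <= 0) || any(width_range <= 0) ||
      diff(range(length_range)) < 0 || diff(range(width_range)) < 0) {
    stop_validation("length_range and width_range must be positive and ordered")
  }
  req <- c("truncated", "shifted", "merged", "adjacent")
  if (!all(req %in% names(defect_mix))) {
    stop_validation("defect_mix needs fractions for truncated, shifted, merged, adjacent")
  }
  defect_mix <- defect_mix[req]
  if (any(defect_mix < 0) || sum(defect_mix) > 1) {
    stop_validation("defect fractions must lie in [0,1] and sum to at most 1")
  }
  structure(list(image_size = as.integer(image_size),
                 cells_per_frame = as.integer(cells_per_frame),
                 length_range = length_range, width_range = width_range,
                 depression_depth = depression_depth,
                 halo_amplitude = halo_amplitude, halo_width = halo_width,
                 halo_offset = halo_offset,
                 background_level = background_level, noise_sd = noise_sd,
                 defect_mix = defect_mix, margin = margin,
                 mesh_spacing = mesh_spacing, seed = as.integer(seed)),
            class = "scene_config")
}

# -- capsule primitives -----------------------------------------------------

# ground-truth mesh of a capsule: rows sampled tip-to-tip along the axis,
# coincident pole rows at both tips
capsule_mesh <- function(center, angle, length, width, spacing = 1) {
  r <- width / 2
  u <- c(cos(angle), sin(angle))
  nv <- c(-sin(angle), cos(angle))
  tip0 <- center - (length / 2) * u
  n_rows <- max(9L, round(length / spacing) + 1L)
  s <- seq(0, length, length.out = n_rows)
  h <- ifelse(s < r, sqrt(pmax(0, r^2 - (r - s)^2)),
              ifelse(s > length - r, sqrt(pmax(0, r^2 - (s - (length - r))^2)), r))
  mid <- cbind(tip0[1L] + s * u[1L], tip0[2L] + s * u[2L])
  cell_mesh(cbind(mid[, 1L] + h * nv[1L], mid[, 2L] + h * nv[2L],
                  mid[, 1L] - h * nv[1L], mid[, 2L] - h * nv[2L]))
}

# distance from points to the cylinder-axis segment of a capsule
dist_to_segment <- function(px, py, p0, p1) {
  vx <- p1[1L] - p0[1L]; vy <- p1[2L] - p0[2L]
  len2 <- vx^2 + vy^2
  if (len2 < 1e-12) return(sqrt((px - p0[1L])^2 + (py - p0[2L])^2))
  t <- pmin(1, pmax(0, ((px - p0[1L]) * vx + (py - p0[2L]) * vy) / len2))
  sqrt((px - p0[1L] - t * vx)^2 + (py - p0[2L] - t * vy)^2)
}

# add one rendered cell (interior depression + halo ring) to an image
render_cell_onto <- function(img, cell, config) {
  r <- cell$width / 2
  a <- (cell$length - cell$width) / 2
  u <- c(cos(cell$angle), sin(cell$angle))
  p0 <- cell$center - a * u; p1 <- cell$center + a * u
  reach <- r + config$halo_offset + 4 * config$halo_width
  cmin <- max(1L, floor(min(p0[1L], p1[1L]) - reach) + 1L)
  cmax <- min(ncol(img), ceiling(max(p0[1L], p1[1L]) + reach) + 1L)
  rmin <- max(1L, floor(min(p0[2L], p1[2L]) - reach) + 1L)
  rmax <- min(nrow(img), ceiling(max(p0[2L], p1[2L]) + reach) + 1L)
  if (cmin > cmax || rmin > rmax) return(img)
  cols <- cmin:cmax; rows <- rmin:rmax
  px <- rep(cols - 1, each = length(rows))
  py <- rep(rows - 1, times = length(cols))
  d <- dist_to_segment(px, py, p0, p1)
  interior <- pmin(1, pmax(0, r - d))          # 1 px soft edge
  halo <- exp(-(d - (r + config$halo_offset))^2 / (2 * config$halo_width^2))
  delta <- -config$depression_depth * interior + config$halo_amplitude * halo
  idx <- cbind(rep(rows, times = length(cols)), rep(cols, each = length(rows)))
  img[idx] <- img[idx] + delta
  img
}

# minimum distance between the axis segments of two capsules
capsule_gap <- function(a, b) {
  seg <- function(cell) {
    u <- c(cos(cell$angle), sin(cell$angle))
    half <- (cell$length - cell$width) / 2
    list(p0 = cell$center - half * u, p1 = cell$center + half * u)
  }
  sa <- seg(a); sb <- seg(b)
  ts <- seq(0, 1, length.out = 9L)
  ax <- sa$p0[1L] + ts * (sa$p1[1L] - sa$p0[1L])
  ay <- sa$p0[2L] + ts * (sa$p1[2L] - sa$p0[2L])
  d1 <- min(dist_to_segment(ax, ay, sb$p0, sb$p1))
  bx <- sb$p0[1L] + ts * (sb$p1[1L] - sb$p0[1L])
  by <- sb$p0[2L] + ts * (sb$p1[2L] - sb$p0[2L])
  d2 <- min(dist_to_segment(bx, by, sa$p0, sa$p1))
  min(d1, d2) - a$width / 2 - b$width / 2
}

# -- single-cell generation -------------------------------------------------

#' Generate one synthetic cell (truth mesh + rendered stamp)
#'
#' Samples a random capsule (length, width, orientation, position) that
#' fits the frame with the configured margin, renders it onto a
#' background-level image, and returns the ground-truth mesh. Uses the
#' global RNG; seed with [set.seed()] for reproducibility.
#'
#' @param config A [scene_config()].
#' @param existing Optional list of previously placed cell parameter lists
#'   (for overlap avoidance).
#' @return List with `mesh` ([cell_mesh()]), `params` (center, angle,
#'   length, width) and `stamp` (rendered frame containing only this cell,
#'   background level included, no noise).
#' @export
generate_cell <- function(config, existing = list()) {
  cell <- place_cell(config, existing)
  stamp <- matrix(config$background_level, config$image_size[1L], config$image_size[2L])
  stamp <- render_cell_onto(stamp, cell, config)
  list(mesh = capsule_mesh(cell$center, cell$angle, cell$length, cell$width,
                           config$mesh_spacing),
       params = cell, stamp = stamp)
}

place_cell <- function(config, existing, max_tries = 400L, min_gap = 3) {
  h <- config$image_size[1L]; w <- config$image_size[2L]
  for (try in seq_len(max_tries)) {
    len <- runif(1, config$length_range[1L], config$length_range[2L])
    wid <- runif(1, config$width_range[1L], config$width_range[2L])
    if (wid >= len) next
    ang <- runif(1, 0, pi)
    half <- len / 2
    cx <- runif(1, config$margin + half, w - 1 - config$margin - half)
    cy <- runif(1, config$margin + half, h - 1 - config$margin - half)
    cand <- list(center = c(cx, cy), angle = ang, length = len, width = wid)
    ok <- TRUE
    for (e in existing) {
      if (capsule_gap(cand, e) < min_gap) { ok <- FALSE; break }
    }
    if (ok) return(cand)
  }
  stop_validation("could not place a cell without overlap; frame too crowded")
}

# place a companion cell near `host`: collinear beyond a tip for "merged",
# side-by-side within `gap` px for "adjacent"
place_companion <- function(host, config, existing, kind, max_tries = 50L) {
  u <- c(cos(host$angle), sin(host$angle))
  nv <- c(-sin(host$angle), cos(host$angle))
  h <- config$image_size[1L]; w <- config$image_size[2L]
  for (try in seq_len(max_tries)) {
    len <- runif(1, config$length_range[1L], config$length_range[2L])
    wid <- runif(1, config$width_range[1L], config$width_range[2L])
    if (wid >= len) next
    if (kind == "merged") {
      side <- sample(c(-1, 1), 1L)
      gap <- runif(1, 1, 2)
      ang <- host$angle + runif(1, -0.08, 0.08)
      ctr <- host$center + side * (host$length / 2 + gap + len / 2) * u +
        runif(1, -0.5, 0.5) * nv
    } else {
      side <- sample(c(-1, 1), 1L)
      gap <- runif(1, 0.2, 1)          # within 1 px of the host outline
      ang <- host$angle + runif(1, -0.15, 0.15)
      ctr <- host$center + side * (host$width / 2 + wid / 2 + gap) * nv +
        runif(1, -3, 3) * u
    }
    cand <- list(center = ctr, angle = ang, length = len, width = wid)
    tip_reach <- len / 2 + wid / 2
    if (ctr[1L] - tip_reach < 4 || ctr[1L] + tip_reach > w - 5 ||
        ctr[2L] - tip_reach < 4 || ctr[2L] + tip_reach > h - 5) next
    ok <- TRUE
    for (e in existing) {
      if (identical(e, host)) next
      if (capsule_gap(cand, e) < 2) { ok <- FALSE; break }
    }
    if (ok) return(cand)
  }
  NULL
}

# -- detection perturbation -------------------------------------------------

#' Corrupt a detection mesh with a controlled defect
#'
#' `truncated` keeps a random contiguous 40--70% run of mesh rows;
#' `shifted` translates the mesh 2--5 px in a random direction; `merged`
#' splices rows from a neighboring cell's mesh onto this one (the two
#' inner pole regions are dropped so the spliced outline stays simple);
#' `adjacent` leaves the mesh unchanged (the defect lives in the image,
#' where a second cell is rendered against the first).
#'
#' @param mesh A [cell_mesh()].
#' @param defect_type One of `"truncated"`, `"shifted"`, `"merged"`,
#'   `"adjacent"`.
#' @param neighbor_mesh Required for `"merged"`: the neighbor's mesh,
#'   roughly collinear beyond one pole of `mesh`.
#' @param max_tries Resampling bound when a perturbation breaks mesh
#'   validity.
#' @return A valid [cell_mesh()].
#' @export
perturb_detection <- function(mesh, defect_type, neighbor_mesh = NULL,
                              max_tries = 20L) {
  if (!is_cell_mesh(mesh)) mesh <- cell_mesh(mesh)
  defect_type <- match.arg(defect_type, c("truncated", "shifted", "merged", "adjacent"))
  n <- nrow(mesh)
  if (defect_type == "adjacent") return(mesh)
  for (try in seq_len(max_tries)) {
    out <- tryCatch(switch(defect_type,
      truncated = {
        keep <- max(6L, round(runif(1, 0.4, 0.7) * n))
        if (keep >= n) keep <- n - 1L
        start <- sample.int(n - keep + 1L, 1L)
        cell_mesh(unclass(mesh)[start:(start + keep - 1L), , drop = FALSE])
      },
      shifted = {
        d <- runif(1, 2, 5); a <- runif(1, 0, 2 * pi)
        shift <- c(d * cos(a), d * sin(a))
        cell_mesh(sweep(unclass(mesh), 2, shift[c(1, 2, 1, 2)], "+"))
      },
      merged = {
        if (is.null(neighbor_mesh)) {
          stop_validation("merged defect requires a neighbor mesh")
        }
        splice_meshes(mesh, neighbor_mesh)
      }), cellcurator_validation_error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  stop_validation(sprintf("could not produce a valid '%s' perturbation", defect_type))
}

# splice: host rows up to its wide section nearest the neighbor, then the
# neighbor's rows from its wide section onward; requires rough collinearity
splice_meshes <- function(host, neighbor) {
  h <- unclass(host); nb <- unclass(neighbor)
  hmid <- midline_from_mesh(host); nmid <- midline_from_mesh(neighbor)
  # orient both meshes so the host's last row is the pole facing the neighbor
  d_head <- sum((hmid[1L, ] - colMeans(nmid))^2)
  d_tail <- sum((hmid[nrow(h), ] - colMeans(nmid))^2)
  if (d_head < d_tail) h <- flip_mesh(h)
  hmid <- (h[, 1:2] + h[, 3:4]) / 2
  d_nb_head <- sum((nmid[1L, ] - hmid[nrow(h), ])^2)
  d_nb_tail <- sum((nmid[nrow(nb), ] - hmid[nrow(h), ])^2)
  if (d_nb_tail < d_nb_head) nb <- flip_mesh(nb)
  wide <- function(m) sqrt((m[, 1L] - m[, 3L])^2 + (m[, 2L] - m[, 4L])^2)
  hw <- wide(h); nw <- wide(nb)
  hcut <- max(which(hw >= 0.9 * max(hw)))
  ncut <- min(which(nw >= 0.9 * max(nw)))
  # match side pairing across the junction: left sides must connect
  if (nrow(h) >= hcut && ncut <= nrow(nb)) {
    gap_ll <- sum((h[hcut, 1:2] - nb[ncut, 1:2])^2)
    gap_lr <- sum((h[hcut, 1:2] - nb[ncut, 3:4])^2)
    if (gap_lr < gap_ll) nb <- nb[, c(3, 4, 1, 2)]
  }
  cell_mesh(rbind(h[seq_len(hcut), , drop = FALSE],
                  nb[ncut:nrow(nb), , drop = FALSE]))
}

flip_mesh <- function(m) m[nrow(m):1L, c(3, 4, 1, 2), drop = FALSE]

# -- scene and dataset generation -------------------------------------------

#' Generate one synthetic scene
#'
#' Places `cells_per_frame` non-overlapping cells, assigns defect types in
#' the exact configured proportions (rounded counts, shuffled), renders
#' every cell (plus companion cells for merged/adjacent defects, which are
#' rendered but not recorded), applies the defect perturbations to the
#' recorded meshes, and adds Gaussian noise. Uses the global RNG.
#'
#' @param config A [scene_config()].
#' @param frame Frame index for the records.
#' @return List with `image` (integer-valued matrix), `records`
#'   ([cell_table()]), and `truth` (tibble: frame, cell_id, class,
#'   defect_type).
#' @export
generate_scene <- function(config, frame = 0L) {
  n <- config$cells_per_frame
  types <- defect_assignment(n, config$defect_mix)
  cells <- list()
  for (i in seq_len(n)) cells[[i]] <- place_cell(config, cells)
  render_list <- cells
  companions <- vector("list", n)
  for (i in seq_len(n)) {
    if (types[i] %in% c("merged", "adjacent")) {
      comp <- place_companion(cells[[i]], config, render_list, types[i])
      if (is.null(comp)) {
        types[i] <- "truncated"  # rare fallback: keep the record in the bad class
      } else {
        companions[[i]] <- comp
        render_list <- c(render_list, list(comp))
      }
    }
  }
  img <- matrix(config$background_level, config$image_size[1L], config$image_size[2L])
  for (cell in render_list) img <- render_cell_onto(img, cell, config)
  img <- img + matrix(rnorm(length(img), 0, config$noise_sd), nrow(img))
  img <- pmax(round(img), 0)

  meshes <- vector("list", n)
  for (i in seq_len(n)) {
    truth_mesh <- capsule_mesh(cells[[i]]$center, cells[[i]]$angle,
                               cells[[i]]$length, cells[[i]]$width,
                               config$mesh_spacing)
    meshes[[i]] <- if (types[i] == "none") truth_mesh else {
      nb <- if (types[i] == "merged") {
        comp <- companions[[i]]
        capsule_mesh(comp$center, comp$angle, comp$length, comp$width,
                     config$mesh_spacing)
      } else NULL
      perturb_detection(truth_mesh, types[i], neighbor_mesh = nb)
    }
  }
  records <- cell_table(rep(frame, n), seq_len(n) - 1L, meshes)
  truth <- tibble::tibble(frame = rep(as.integer(frame), n),
                          cell_id = seq_len(n) - 1L,
                          class = ifelse(types == "none", "good", "bad"),
                          defect_type = types,
                          true_length = vapply(cells, function(c) c$length, 0),
                          true_width = vapply(cells, function(c) c$width, 0))
  list(image = img, records = records, truth = truth)
}

defect_assignment <- function(n, mix) {
  counts <- round(mix * n)
  while (sum(counts) > n) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  types <- c(rep(names(counts), counts), rep("none", n - sum(counts)))
  sample(types)
}

#' Generate a multi-frame synthetic dataset
#'
#' Seeds the RNG from `config$seed`, so identical config + seed yields an
#' identical dataset. Overall class proportions match the configured
#' defect mix up to per-frame rounding (defect counts are allocated
#' exactly per frame, then shuffled).
#'
#' @param config A [scene_config()].
#' @param n_frames Number of frames.
#' @return List of scenes as returned by [generate_scene()].
#' @export
generate_dataset <- function(config, n_frames) {
  set.seed(config$seed)
  lapply(seq_len(n_frames) - 1L, function(f) generate_scene(config, frame = f))
}

#' Write a synthetic dataset to disk
#'
#' Writes one 16-bit TIFF per frame, the cell table (CSV dialect of
#' [write_cell_table()]) and the ground-truth table.
#'
#' @param scenes Output of [generate_dataset()].
#' @param directory Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_scene_dataset <- function(scenes, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  write_image_frames(lapply(scenes, `[[`, "image"),
                     file.path(directory, "images"))
  records <- do.call(rbind, lapply(scenes, `[[`, "records"))
  truth <- do.call(rbind, lapply(scenes, `[[`, "truth"))
  write_cell_table(records, file.path(directory, "cells.csv"))
  write.csv(as.data.frame(truth[, c("frame", "cell_id", "class", "defect_type")]),
            file.path(directory, "truth.csv"), row.names = FALSE)
  invisible(directory)
}
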