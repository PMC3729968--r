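# Synthetic measurement geometry: a helmet-like cap of magnetometers around a
# single homogeneous head sphere, and compact non-overlapping ROI voxel
# clusters inside it.

# Deterministic quasi-uniform points on a unit sphere (Fibonacci lattice),
# optionally restricted to an upper cap (z >= z_min).
fibonacci_sphere <- function(n, z_min = -1) {
  golden <- (1 + sqrt(5)) / 2
  i <- seq_len(n) - 0.5
  z <- z_min + (1 - z_min) * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- 2 * pi * i / golden
  cbind(x = r * cos(theta), y = r * sin(theta), z = z)
}

#' Generate synthetic sensor, head and atlas geometry
#'
#' Builds a magnetometer array on a helmet-like spherical cap outside a
#' homogeneous head sphere, and an ROI atlas of compact non-overlapping voxel
#' clusters strictly inside the sphere. With `n_rois = 78` the ROIs carry the
#' cortical AAL labels so the shipped resting-state-network definitions apply.
#'
#' @param n_channels number of magnetometers (default 151).
#' @param n_rois number of ROIs (default 78).
#' @param voxels_per_roi voxels per ROI cluster (default 5); the first voxel
#'   of each cluster is the ROI centroid.
#' @param seed integer seed; identical seeds give bit-identical geometry.
#' @param head_radius head sphere radius in meters (default 0.09).
#' @param helmet_radius sensor cap radius in meters (default 0.12).
#' @return list with `sensors` (class `sensor_array`: `channel_id`,
#'   `position`, `orientation`), `head` (class `head_model`), and `atlas`
#'   (class `roi_atlas`: `labels`, `voxels` (matrix), `roi_index`,
#'   `centroid_index`).
#' @export
generate_geometry <- function(n_channels = 151, n_rois = 78, voxels_per_roi = 5,
                              seed = 1, head_radius = 0.09, helmet_radius = 0.12) {
  stopifnot(n_channels >= 8, n_rois >= 2, voxels_per_roi >= 1,
            helmet_radius > head_radius)
  with_seed(seed, {
    pos <- fibonacci_sphere(n_channels, z_min = -0.2) * helmet_radius
    sensors <- structure(
      list(channel_id = sprintf("MEG%03d", seq_len(n_channels)),
           position = pos,
           orientation = pos / helmet_radius),
      class = "sensor_array")
    head <- structure(
      list(sphere_center = c(0, 0, 0), sphere_radius = head_radius),
      class = "head_model")

    shell <- 0.72 * head_radius
    cent <- fibonacci_sphere(n_rois, z_min = -0.85) * shell
    # nearest-neighbor spacing of the quasi-uniform lattice (hexagonal-packing
    # estimate; conservative against the exact minimum)
    dmin <- 2.6 * shell / sqrt(n_rois)
    cluster_r <- min(0.30 * dmin, 0.05 * head_radius)
    if (voxels_per_roi > 1 && cluster_r < 5e-4) {
      stop("geometry infeasible: ", n_rois, " ROIs of ", voxels_per_roi,
           " voxels cannot be placed without overlap inside the sphere")
    }
    labels <- if (n_rois == 78) cortical_labels() else sprintf("roi_%03d", seq_len(n_rois))
    vox <- matrix(0, n_rois * voxels_per_roi, 3)
    roi_index <- integer(n_rois * voxels_per_roi)
    centroid_index <- integer(n_rois)
    row <- 1L
    for (k in seq_len(n_rois)) {
      centroid_index[k] <- row
      vox[row, ] <- cent[k, ]
      roi_index[row] <- k
      row <- row + 1L
      if (voxels_per_roi > 1) {
        for (j in seq_len(voxels_per_roi - 1)) {
          repeat {
            off <- stats::rnorm(3)
            off <- off / vnorm(off) * stats::runif(1, 0.3, 1) * cluster_r
            p <- cent[k, ] + off
            if (vnorm(p) < 0.97 * head_radius) break
          }
          vox[row, ] <- p
          roi_index[row] <- k
          row <- row + 1L
        }
      }
    }
    if (max(sqrt(rowSums(vox^2))) >= head_radius) {
      stop("geometry infeasible: voxels fall outside the head sphere")
    }
    atlas <- structure(
      list(labels = labels, voxels = vox, roi_index = roi_index,
           centroid_index = centroid_index),
      class = "roi_atlas")
    list(sensors = sensors, head = head, atlas = atlas)
  })
}
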