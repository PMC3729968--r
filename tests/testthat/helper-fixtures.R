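# Shared small fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small helmet/atlas geometry: 24 channels, 4 ROIs x 2 voxels
small_geometry <- function() {
  cached("geom24", function() generate_geometry(24, 4, 2, seed = 11))
}

# noiseless single-dipole recording built directly from a lead field:
# narrowband source at ROI 1's centroid, tangential orientation
single_source_recording <- function(n_epochs = 3, epoch_samples = 4096,
                                    fs = 625) {
  cached("single_src", function() {
    g <- small_geometry()
    vx <- g$atlas$voxels[g$atlas$centroid_index[1], ]
    Tb <- megconn:::tangential_basis(vx, g$head)
    l <- leadfield_sphere(vx, Tb[, 1] * 1e-8, g$sensors, g$head)$gain
    s <- withr::with_seed(5, {
      matrix(rnorm(epoch_samples * n_epochs), epoch_samples)
    })
    s <- bandpass(s, "alpha2", fs)
    dat <- array(0, dim = c(length(l), epoch_samples, n_epochs))
    for (e in seq_len(n_epochs)) dat[, , e] <- l %o% s[, e]
    list(recording = structure(list(data = dat, fs = fs,
                                    channel_id = g$sensors$channel_id),
                               class = "epoched_recording"),
         source = s, geometry = g, leadfield = l, voxel_index = g$atlas$centroid_index[1])
  })
}

# random symmetric adjacency values with labels
random_adjacency <- function(n_roi, labels = sprintf("r%02d", seq_len(n_roi))) {
  v <- matrix(runif(n_roi^2), n_roi)
  v <- (v + t(v)) / 2
  diag(v) <- 0
  dimnames(v) <- list(labels, labels)
  v
}
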