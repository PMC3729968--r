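fs <- 625
n <- 4096
tt <- (0:(n - 1)) / fs

test_that("band-pass keeps in-band tones and strongly rejects out-of-band ones", {
  x11 <- sin(2 * pi * 11 * tt)
  y11 <- bandpass(x11, "alpha2", fs)
  expect_equal(sd(y11) / sd(x11), 1, tolerance = 0.05)
  x25 <- sin(2 * pi * 25 * tt)
  y25 <- bandpass(x25, "alpha2", fs)
  expect_lt(20 * log10(sd(y25) / sd(x25)), -40)
  expect_identical(bandpass(rep(0, n), "alpha2", fs), rep(0, n))
  expect_error(bandpass(x11, c(200, 400), fs), "Nyquist")
  expect_error(bandpass(x11[1:100], "alpha2", fs), "too short")
  # zero phase: an in-band bin-centered tone passes with no shift
  f0 <- 70 * fs / n  # ~10.68 Hz, alpha2
  x0 <- sin(2 * pi * f0 * tt)
  expect_equal(bandpass(x0, "alpha2", fs), x0, tolerance = 1e-10)
})

test_that("instantaneous phase of sinusoids behaves analytically", {
  f0 <- 64 * fs / n  # bin-centered tone: exact analytic signal
  s <- sin(2 * pi * f0 * tt)
  ph <- instantaneous_phase(s)
  expect_true(all(ph > -pi & ph <= pi))
  expect_equal(wrap_phase(diff(ph)), rep(2 * pi * f0 / fs, n - 1),
               tolerance = 1e-3)
  phc <- instantaneous_phase(cos(2 * pi * f0 * tt))
  expect_equal(wrap_phase(phc - ph), rep(pi / 2, n), tolerance = 1e-3)
  phn <- instantaneous_phase(-s)
  expect_equal(abs(wrap_phase(phn - ph)), rep(pi, n), tolerance = 1e-3)
  expect_error(instantaneous_phase(rep(0, 100)), "all-zero")
})

test_that("PLI reproduces its analytic values", {
  m <- 1000
  expect_identical(pli(rep(pi / 2, m), rep(0, m)), 1)     # constant +pi/2 lag
  expect_identical(pli(rep(0.3, m), rep(0.3, m)), 0)      # identical phases
  expect_equal(pli(c(pi / 4, pi / 4, pi / 4, -pi / 4), rep(0, 4)), 0.5)
  expect_error(pli(1:10, 1:9), "mismatch")
})

test_that("PLI is symmetric, bounded, and invariant to scaling and offsets", {
  withr::with_seed(8, {
    for (i in 1:20) {
      x <- runif(500, -pi, pi)
      y <- runif(500, -pi, pi)
      p <- pli(x, y)
      expect_gte(p, 0); expect_lte(p, 1)
      expect_equal(pli(y, x), p)
      expect_equal(pli(wrap_phase(x + 1.1), wrap_phase(y + 1.1)), p)
    }
    # amplitude rescaling of the underlying series leaves phases unchanged
    s <- bandpass(matrix(rnorm(2 * n), n), "alpha2", fs)
    p1 <- instantaneous_phase(s[, 1])
    expect_equal(instantaneous_phase(5 * s[, 1]), p1, tolerance = 1e-12)
  })
})

test_that("adjacency is symmetric, zero-diagonal, with the right pair count", {
  g <- small_geometry()
  # strong oscillation so the noiseless lag survives the 1/f background
  cs <- coupling_spec("alpha2", rbind(g$atlas$labels[1:2]),
                      jitter_kappa = Inf, amplitude_snr = 50)
  sim <- simulate_sources(g$atlas, cs, n_epochs = 5, epoch_samples = 4096,
                          seed = 2)
  A <- adjacency(sim$series, "alpha2", fs, n_epochs = 5)
  v <- A$values
  expect_equal(v, t(v))
  expect_true(all(diag(v) == 0))
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(sum(upper.tri(v)), 4 * 3 / 2)
  expect_equal(choose(78, 2), 3003)  # the full-atlas edge count
  expect_gt(v[1, 2], 0.95)  # implanted noiseless lag survives measurement
  expect_error(adjacency(sim$series, "alpha2", fs, n_epochs = 6), "epochs")
})

test_that("independent ROI series give a low adjacency null level", {
  withr::with_seed(13, {
    x <- array(rnorm(4096 * 5 * 4), c(4096, 5, 4))
    A <- adjacency(x, "alpha2", fs, n_epochs = 5)
    off <- A$values[upper.tri(A$values)]
    expect_lt(mean(off), 0.2)
  })
})

test_that("node strength and whole-brain mean reduce rows correctly", {
  v <- matrix(0.3, 4, 4); diag(v) <- 0
  dimnames(v) <- list(letters[1:4], letters[1:4])
  expect_equal(unname(node_strength(v)), rep(0.3, 4))
  expect_equal(whole_brain_mean(v), 0.3)

  v2 <- matrix(0, 3, 3)
  v2[1, 2] <- v2[2, 1] <- 0.2
  v2[1, 3] <- v2[3, 1] <- 0.4
  v2[2, 3] <- v2[3, 2] <- 0.6
  dimnames(v2) <- list(letters[1:3], letters[1:3])
  expect_equal(unname(node_strength(v2)[1]), 0.3)  # (0.2 + 0.4) / 2

  # permutation equivariance
  perm <- c(3, 1, 2)
  expect_equal(node_strength(v2[perm, perm]), node_strength(v2)[perm])
  expect_equal(whole_brain_mean(v2[perm, perm]), whole_brain_mean(v2))
  expect_error(node_strength(matrix(0, 1, 1)), "at least 2")
})

test_that("whole-brain and RSN means equal brute-force pair enumeration", {
  withr::with_seed(21, {
    for (i in 1:100) {
      n_roi <- sample(4:12, 1)
      v <- random_adjacency(n_roi)
      labels <- rownames(v)
      # brute-force oracle: explicit loop over unordered pairs
      brute <- function(members) {
        idx <- match(members, labels)
        tot <- 0; cnt <- 0
        for (a in seq_along(idx)) for (b in seq_along(idx)) {
          if (a < b) { tot <- tot + v[idx[a], idx[b]]; cnt <- cnt + 1 }
        }
        tot / cnt
      }
      expect_equal(whole_brain_mean(v), brute(labels))
      members <- sample(labels, sample(2:n_roi, 1))
      expect_equal(rsn_mean_pli(v, members), brute(members))
    }
    v <- random_adjacency(5)
    expect_equal(rsn_mean_pli(v, rownames(v)), whole_brain_mean(v))
    expect_error(rsn_mean_pli(v, c(rownames(v)[1], "zz")), "unknown")
    expect_error(rsn_mean_pli(v, rownames(v)[1]), "fewer than 2")
  })
})

test_that("hand-set RSN entries average as expected", {
  v <- random_adjacency(4, c("p", "q", "r", "s"))
  v["p", "q"] <- v["q", "p"] <- 0.2
  v["p", "r"] <- v["r", "p"] <- 0.4
  v["q", "r"] <- v["r", "q"] <- 0.6
  expect_equal(rsn_mean_pli(v, c("p", "q", "r")), 0.4)
})

test_that("phase scrambling preserves the amplitude spectrum", {
  withr::with_seed(4, {
    x <- bandpass(rnorm(n), "beta", fs)
    y <- phase_scramble(x)
    expect_equal(Mod(fft(y)), Mod(fft(x)), tolerance = 1e-8)
    expect_gt(max(abs(y - x)), 1e-3)  # actually scrambled
  })
})
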