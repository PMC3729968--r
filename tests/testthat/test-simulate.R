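test_that("von Mises sampler matches the analytic resultant length", {
  withr::with_seed(1, {
    for (kappa in c(0.5, 2, 8)) {
      x <- rvonmises(2e5, mu = 0.7, kappa = kappa)
      expect_true(all(x > -pi & x <= pi))
      r_hat <- sqrt(mean(cos(x))^2 + mean(sin(x))^2)
      r_true <- besselI(kappa, 1) / besselI(kappa, 0)
      expect_equal(r_hat, r_true, tolerance = 0.01)
      mu_hat <- atan2(mean(sin(x)), mean(cos(x)))
      expect_equal(mu_hat, 0.7, tolerance = 0.02)
    }
    expect_equal(rvonmises(5, 0.3, Inf), rep(0.3, 5))
    u <- rvonmises(2e5, 0, 0)
    expect_lt(abs(mean(u)), 0.02)  # circular uniform
  })
})

test_that("noiseless constant-lag coupling gives source-level PLI exactly 1", {
  g <- small_geometry()
  cs <- coupling_spec("alpha2", rbind(g$atlas$labels[1:2]),
                      lag_delta = pi / 2, jitter_kappa = Inf)
  sim <- simulate_sources(g$atlas, cs, n_epochs = 2, epoch_samples = 1024,
                          seed = 3)
  ph <- sim$phases[["alpha2"]]
  expect_identical(pli(ph[, , 1], ph[, , 2]), 1)
})

test_that("jittered coupling matches the brute-force von Mises oracle", {
  g <- small_geometry()
  kappa <- 2
  cs <- coupling_spec("alpha2", rbind(g$atlas$labels[1:2]),
                      lag_delta = pi / 2, jitter_kappa = kappa)
  # many epochs so the held-jitter draws give a tight Monte-Carlo estimate
  sim <- simulate_sources(g$atlas, cs, n_epochs = 60, epoch_samples = 4096,
                          seed = 4)
  ph <- sim$phases[["alpha2"]]
  emp <- pli(ph[, , 1], ph[, , 2])
  oracle <- withr::with_seed(99, pli_vonmises_oracle(pi / 2, kappa, 1e6))
  # effective sample size = number of independent held jitter draws
  hold <- round(625 / 3)
  n_eff <- ceiling(4096 / hold) * 60
  se <- sqrt((1 - oracle$pli^2) / n_eff)
  expect_lt(abs(emp - oracle$pli), 3 * se)
})

test_that("an uncoupled pair stays below the phase-scrambling null's 95th percentile", {
  g <- small_geometry()
  labs <- g$atlas$labels
  # ROIs 3-4 coupled; 1-2 carry independent alpha2 carriers
  cs <- coupling_spec("alpha2", rbind(labs[3:4]), jitter_kappa = 3)
  sim <- simulate_sources(g$atlas, cs, n_epochs = 5, epoch_samples = 4096,
                          seed = 6)
  fs <- sim$fs
  band <- as_band("alpha2")
  keep <- megconn:::edge_retain_idx(4096, band, fs)
  phase_of <- function(x) megconn:::band_phase(x, band, fs)[keep, , drop = FALSE]
  p1 <- phase_of(sim$series[, , 1])
  observed <- pli(p1, phase_of(sim$series[, , 2]))
  null_pli <- withr::with_seed(7, vapply(seq_len(100), function(i) {
    pli(p1, phase_of(phase_scramble(sim$series[, , 2])))
  }, numeric(1)))
  expect_lt(observed, quantile(null_pli, 0.95))
  # the coupled pair in the same simulation clears the same bar
  coupled <- pli(phase_of(sim$series[, , 3]), phase_of(sim$series[, , 4]))
  expect_gt(coupled, quantile(null_pli, 0.95))
})

test_that("expected PLI is non-decreasing in the jitter concentration", {
  g <- small_geometry()
  kappas <- c(0.5, 1, 2, 4, 8)
  plis <- ses <- numeric(length(kappas))
  for (i in seq_along(kappas)) {
    cs <- coupling_spec("alpha2", rbind(g$atlas$labels[1:2]),
                        jitter_kappa = kappas[i])
    sim <- simulate_sources(g$atlas, cs, n_epochs = 30, epoch_samples = 4096,
                            seed = 20 + i)
    ph <- sim$phases[["alpha2"]]
    plis[i] <- pli(ph[, , 1], ph[, , 2])
    n_eff <- ceiling(4096 / round(625 / 3)) * 30
    ses[i] <- sqrt((1 - plis[i]^2) / n_eff)
  }
  expect_true(all(diff(plis) > -3 * sqrt(ses[-1]^2 + ses[-length(ses)]^2)))
  expect_gt(plis[length(plis)], plis[1])
})

test_that("simulation is deterministic and validates its inputs", {
  g <- small_geometry()
  cs <- coupling_spec("theta", rbind(g$atlas$labels[1:2]))
  a <- simulate_sources(g$atlas, cs, n_epochs = 2, epoch_samples = 512, seed = 5)
  b <- simulate_sources(g$atlas, cs, n_epochs = 2, epoch_samples = 512, seed = 5)
  expect_identical(a, b)
  expect_error(simulate_sources(g$atlas, coupling_spec(c(200, 400), rbind(g$atlas$labels[1:2])),
                                epoch_samples = 512, seed = 1), "Nyquist")
  expect_error(simulate_sources(g$atlas, coupling_spec("alpha2", rbind(c("roi_001", "nope"))),
                                epoch_samples = 512, seed = 1), "unknown ROI")
  cyc <- coupling_spec("alpha2", rbind(g$atlas$labels[c(1, 2)],
                                       g$atlas$labels[c(2, 3)],
                                       g$atlas$labels[c(1, 3)]))
  expect_error(simulate_sources(g$atlas, cyc, epoch_samples = 512, seed = 1),
               "cycle")
})

test_that("forward projection is linear with rank-1 single-source data", {
  g <- small_geometry()
  sim <- simulate_sources(g$atlas, list(), n_epochs = 2, epoch_samples = 512,
                          seed = 9)
  rec <- project_to_sensors(sim, g$atlas, g$sensors, g$head, snr = Inf)
  expect_equal(dim(rec$data), c(24, 512, 2))

  sim2 <- sim
  sim2$series <- 2 * sim$series
  rec2 <- project_to_sensors(sim2, g$atlas, g$sensors, g$head, snr = Inf)
  expect_equal(rec2$data, 2 * rec$data, tolerance = 1e-10)

  # superposition: projecting the sum equals the sum of projections
  simA <- sim; simA$series[, , 2:4] <- 0
  simB <- sim; simB$series[, , 1] <- 0
  recA <- project_to_sensors(simA, g$atlas, g$sensors, g$head, snr = Inf)
  recB <- project_to_sensors(simB, g$atlas, g$sensors, g$head, snr = Inf)
  expect_equal(recA$data + recB$data, rec$data, tolerance = 1e-10)

  # single active dipole spans a rank-1 sensor space
  X <- matrix(recA$data, nrow = dim(recA$data)[1])
  sv <- svd(X)$d
  expect_lt(sv[2] / sv[1], 1e-10)

  # fixed seed holds the sensor noise fixed across amplitude scalings
  recn <- project_to_sensors(sim, g$atlas, g$sensors, g$head, snr = 4, seed = 2)
  recn2 <- project_to_sensors(sim2, g$atlas, g$sensors, g$head, snr = 4, seed = 2)
  noise1 <- recn$data - rec$data
  # noise scales with the (doubled) signal power: compare normalized noise
  expect_equal((recn2$data - rec2$data) / 2, noise1, tolerance = 1e-12)
  expect_error(project_to_sensors(sim, g$atlas, g$sensors, g$head, snr = 0),
               "snr")
})
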