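test_that("Mann-Whitney U matches enumeration and its identities", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$statistic_u, 0)  # no pairwise wins for x
  expect_equal(mw$n1, 3); expect_equal(mw$n2, 3)
  expect_equal(mw$direction, "lower_in_x")

  x <- c(2.2, 3.1, 4.5, 5.0)
  same <- mann_whitney(x, x)
  expect_equal(same$statistic_u, length(x)^2 / 2)  # symmetric multisets

  y <- c(1.9, 3.3, 6.1)
  a <- mann_whitney(x, y)
  b <- mann_whitney(y, x)
  expect_equal(b$statistic_u, length(x) * length(y) - a$statistic_u)
  expect_equal(a$p_value, b$p_value)
  expect_true(a$statistic_u >= 0 && a$statistic_u <= length(x) * length(y))

  tied <- mann_whitney(rep(1, 5), rep(1, 4))
  expect_equal(tied$p_value, 1)
})

test_that("exhaustive permutation test reaches its minimal two-sided p", {
  res <- permutation_roi_test(c(1, 2, 3, 10, 11, 12),
                              c("a", "a", "a", "b", "b", "b"),
                              n_perm = 5000)
  expect_true(res$exhaustive)
  expect_equal(res$n_permutations, choose(6, 3))
  # two-sided: the observed split and its label-swapped mirror share max |t|
  expect_equal(res$per_roi_p, 2 / choose(6, 3))
})

test_that("permutation p-values are label-swap invariant and bounded below", {
  withr::with_seed(31, {
    vals <- matrix(rnorm(16 * 3), 16)
    labs <- rep(c("g1", "g2"), each = 8)
    r1 <- permutation_roi_test(vals, labs, n_perm = 1000, seed = 5)
    swapped <- ifelse(labs == "g1", "g2", "g1")
    r2 <- permutation_roi_test(vals, swapped, n_perm = 1000, seed = 5)
    expect_equal(r1$per_roi_p, r2$per_roi_p)
    expect_true(all(r1$per_roi_p >= 1 / (r1$n_permutations + 1)))
    # determinism under the seed
    r3 <- permutation_roi_test(vals, labs, n_perm = 1000, seed = 5)
    expect_identical(r1, r3)
    # max-statistic correction is never more liberal
    r4 <- permutation_roi_test(vals, labs, n_perm = 1000, seed = 5,
                               correction = "maxstat")
    expect_true(all(r4$per_roi_p >= r1$per_roi_p))
  })
})

test_that("degenerate-variance ROIs are flagged with p = 1", {
  vals <- cbind(rep(1, 10), rnorm(10))
  labs <- rep(c("a", "b"), 5)
  res <- permutation_roi_test(vals, labs, n_perm = 1000, seed = 1)
  expect_true(res$degenerate[1])
  expect_equal(res$per_roi_p[1], 1)
  expect_false(res$degenerate[2])
  expect_error(permutation_roi_test(rnorm(6), rep("a", 6), n_perm = 1000),
               "non-empty")
})

test_that("Spearman correlation matches the hand formula and monotone limits", {
  expect_equal(spearman(1:6, (1:6)^3)$rho, 1)
  expect_equal(spearman(1:6, -(1:6)^3)$rho, -1)
  # 1 - 6 * sum(d^2) / (n (n^2 - 1)) with sum(d^2) = 4
  expect_equal(spearman(1:5, c(1, 3, 2, 5, 4))$rho, 0.8)
  expect_error(spearman(rep(2, 6), 1:6), "rank variance")
  expect_error(spearman(1:4, 1:4))
})

test_that("effect-modification regression recovers constructed slopes", {
  withr::with_seed(41, {
    n <- 40
    group <- rep(c("control", "patient"), each = n / 2)
    volume <- c(rnorm(n / 2, 10, 2), rnorm(n / 2, 9, 2))

    # exact linear outcome, same slope: interaction ~ 0, slopes exact
    # (suppress lm's perfect-fit warning: the zero-noise case is deliberate)
    y <- 1 + 0.5 * volume
    em <- suppressWarnings(effect_modification_regression(y, volume, group))
    expect_equal(em$per_group$B, c(0.5, 0.5), tolerance = 1e-10)
    expect_lt(abs(em$interaction$B), 1e-10)

    # same slope plus noise: interaction's standardized beta stays small
    y2 <- 1 + 0.5 * volume + rnorm(n, sd = 0.3)
    em2 <- effect_modification_regression(y2, volume, group)
    expect_lt(abs(em2$interaction$beta), 0.25)
    expect_equal(em2$per_group$B, c(0.5, 0.5), tolerance = 0.15)

    # opposite slopes by construction: recovered signs match
    y3 <- ifelse(group == "control", 2 + 0.8 * volume, 2 - 0.8 * volume) +
      rnorm(n, sd = 0.2)
    em3 <- effect_modification_regression(y3, volume, group)
    Bc <- em3$per_group$B[em3$per_group$group == "control"]
    Bp <- em3$per_group$B[em3$per_group$group == "patient"]
    expect_gt(Bc, 0); expect_lt(Bp, 0)
    expect_lt(em3$interaction$p_value, 0.01)

    vol_bad <- volume; vol_bad[group == "patient"] <- 7
    expect_error(effect_modification_regression(y, vol_bad, group), "collinear")
  })
})

test_that("normality test is calibrated on normal data and rejects skew", {
  withr::with_seed(51, {
    ks <- ks_normality(rnorm(200))
    expect_gte(ks$statistic, 0); expect_lte(ks$statistic, 1)

    p_norm <- vapply(1:200, function(i) ks_normality(rnorm(100))$p_value,
                     numeric(1))
    rate <- mean(p_norm < 0.05)
    expect_lt(abs(rate - 0.05), 0.05)  # roughly nominal under the null
    # uniformity of the null p-values (coarse Kolmogorov bound)
    expect_lt(max(abs(sort(p_norm) - (1:200) / 200)), 0.12)

    p_exp <- vapply(1:100, function(i) ks_normality(rexp(200))$p_value,
                    numeric(1))
    expect_gte(mean(p_exp < 0.05), 0.9)  # power against strong skew
    expect_error(ks_normality(rep(3, 10)), "constant")
  })
})
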