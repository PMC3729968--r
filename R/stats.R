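# Nonparametric statistical battery: Mann-Whitney group comparisons,
# permutation t-tests per ROI, Spearman correlations, effect-modification
# regression and a Lilliefors-type normality check. Standard tests are
# delegated to stats/nortest; the permutation machinery is implemented here.

#' Mann-Whitney U test between two groups
#'
#' @param x,y numeric samples for the two groups (each n >= 3).
#' @return list of class `group_comparison`: `statistic_u` (U for `x`, ties
#'   mid-ranked), `p_value` (two-sided; exact for small untied samples, normal
#'   approximation with tie correction otherwise), `n1`, `n2`, `direction`
#'   (`"higher_in_x"` / `"lower_in_x"` / `"none"` by mean rank).
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 3, n2 >= 3)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(c(x, y))) == 1L) {
    p <- 1
  } else {
    p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
  }
  direction <- if (u > n1 * n2 / 2) "higher_in_x" else if (u < n1 * n2 / 2) "lower_in_x" else "none"
  structure(list(statistic_u = u, p_value = p, n1 = n1, n2 = n2,
                 direction = direction),
            class = "group_comparison")
}

pooled_t <- function(x_mat, g1) {
  # two-sample pooled-variance t statistic per column; g1: logical group-1 rows
  n1 <- sum(g1); n2 <- sum(!g1)
  m1 <- colMeans(x_mat[g1, , drop = FALSE])
  m2 <- colMeans(x_mat[!g1, , drop = FALSE])
  v1 <- apply(x_mat[g1, , drop = FALSE], 2, stats::var)
  v2 <- apply(x_mat[!g1, , drop = FALSE], 2, stats::var)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  denom <- sp * sqrt(1 / n1 + 1 / n2)
  t <- (m1 - m2) / denom
  t[!is.finite(t)] <- 0  # degenerate variance: flagged as no effect
  t
}

#' Permutation t-test per ROI
#'
#' Derives a null distribution of two-sample (pooled) t statistics per ROI by
#' permuting group assignment. When the number of distinct group-1 subsets is
#' within `n_perm` the permutation distribution is enumerated exhaustively;
#' otherwise `n_perm` permutations are drawn (the identity assignment always
#' included, so p >= 1/n_permutations). Two-sided p-values are the proportion
#' of permuted |t| at or above the observed |t|; the optional max-statistic
#' correction compares against the permutation distribution of the maximum
#' |t| across ROIs.
#'
#' @param values numeric matrix, subjects x ROIs (a vector is treated as one
#'   ROI).
#' @param labels group label per subject (2 levels).
#' @param n_perm number of permutations (>= 1000 unless exhaustive
#'   enumeration is smaller; default 5000).
#' @param seed integer seed (ignored when exhaustive).
#' @param correction `"none"` (default) or `"maxstat"`.
#' @return list of class `permutation_result`: `per_roi_t`, `per_roi_p`,
#'   `n_permutations`, `corrected`, `exhaustive`, `degenerate` (logical per
#'   ROI: zero pooled variance).
#' @export
permutation_roi_test <- function(values, labels, n_perm = 5000, seed = 1,
                                 correction = c("none", "maxstat")) {
  correction <- match.arg(correction)
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  values <- as.matrix(values)
  labels <- as.factor(labels)
  stopifnot(nrow(values) == length(labels))
  if (nlevels(labels) != 2) stop("both groups must be non-empty (need exactly 2 group levels)")
  g1 <- labels == levels(labels)[1]
  n1 <- sum(g1); n <- length(labels)
  if (n1 == 0 || n1 == n) stop("both groups must be non-empty")
  n_exhaustive <- choose(n, n1)
  exhaustive <- n_exhaustive <= n_perm
  if (!exhaustive && n_perm < 1000) stop("n_perm must be >= 1000")

  t_obs <- pooled_t(values, g1)
  degenerate <- apply(values, 2, function(col) {
    stats::var(col[g1]) == 0 && stats::var(col[!g1]) == 0
  })

  perm_t <- if (exhaustive) {
    sets <- utils::combn(n, n1)
    vapply(seq_len(ncol(sets)), function(k) {
      gg <- logical(n); gg[sets[, k]] <- TRUE
      pooled_t(values, gg)
    }, numeric(ncol(values)))
  } else {
    with_seed(seed, {
      vapply(seq_len(n_perm), function(k) {
        gg <- if (k == 1) g1 else {
          idx <- sample.int(n, n1)
          out <- logical(n); out[idx] <- TRUE; out
        }
        pooled_t(values, gg)
      }, numeric(ncol(values)))
    })
  }
  perm_t <- matrix(perm_t, nrow = ncol(values))  # ROIs x permutations
  n_used <- ncol(perm_t)

  abs_obs <- abs(t_obs)
  p <- vapply(seq_len(ncol(values)), function(j) {
    mean(abs(perm_t[j, ]) >= abs_obs[j] - 1e-12)
  }, numeric(1))
  if (correction == "maxstat") {
    maxnull <- apply(abs(perm_t), 2, max)
    p <- vapply(abs_obs, function(a) mean(maxnull >= a - 1e-12), numeric(1))
  }
  p[degenerate] <- 1
  structure(list(per_roi_t = t_obs, per_roi_p = p, n_permutations = n_used,
                 corrected = correction, exhaustive = exhaustive,
                 degenerate = degenerate),
            class = "permutation_result")
}

#' Spearman rank correlation
#'
#' Rank correlation with mid-ranks for ties; two-sided p-value from the t
#' approximation.
#'
#' @param x,y numeric vectors (n >= 5 complete pairs).
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopifnot(n >= 5)
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    stop("zero rank variance: Spearman correlation undefined")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Effect-modification regression of connectivity on a volume
#'
#' Fits `y ~ group * volume` to test whether the volume-connectivity
#' association differs between groups (the volume acting as effect modifier),
#' and reports per-group unstandardized slopes (B), standardized slopes
#' (beta) and p-values from within-group fits.
#'
#' @param y outcome (e.g. PLI values), numeric.
#' @param volume effect modifier, numeric.
#' @param group two-level group labels.
#' @return list with `per_group` (data.frame: group, B, beta, p_value, n) and
#'   `interaction` (B, beta, p_value of the group x volume term).
#' @export
effect_modification_regression <- function(y, volume, group) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2)
  ok <- stats::complete.cases(y, volume, group)
  y <- y[ok]; volume <- volume[ok]; group <- droplevels(group[ok])
  if (length(y) < 10) stop("effect-modification regression needs n >= 10")
  for (g in levels(group)) {
    if (stats::sd(volume[group == g]) == 0) {
      stop("volume is constant within group '", g, "': collinear design")
    }
  }
  fit <- stats::lm(y ~ group * volume)
  sm <- summary(fit)$coefficients
  inter_row <- grep(":volume", rownames(sm))
  inter_B <- sm[inter_row, "Estimate"]
  inter_p <- sm[inter_row, "Pr(>|t|)"]
  inter_beta <- inter_B * stats::sd(volume) / stats::sd(y)

  per_group <- do.call(rbind, lapply(levels(group), function(g) {
    i <- group == g
    f <- stats::lm(y[i] ~ volume[i])
    cf <- summary(f)$coefficients
    B <- cf[2, "Estimate"]
    p <- cf[2, "Pr(>|t|)"]
    beta <- if (stats::sd(y[i]) > 0) B * stats::sd(volume[i]) / stats::sd(y[i]) else 0
    data.frame(group = g, B = B, beta = beta, p_value = p, n = sum(i),
               stringsAsFactors = FALSE)
  }))
  list(per_group = per_group,
       interaction = list(B = inter_B, beta = inter_beta, p_value = inter_p))
}

#' Lilliefors-type Kolmogorov-Smirnov normality test
#'
#' One-sample KS test against a normal distribution with mean and SD
#' estimated from the data (Lilliefors correction).
#'
#' @param x numeric vector (n >= 5).
#' @return list with `statistic` (in `[0, 1]`) and `p_value`.
#' @export
ks_normality <- function(x) {
  x <- x[!is.na(x)]
  stopifnot(length(x) >= 5)
  if (stats::sd(x) == 0) stop("constant input: normality test undefined")
  lt <- nortest::lillie.test(x)
  list(statistic = unname(lt$statistic), p_value = lt$p.value)
}
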