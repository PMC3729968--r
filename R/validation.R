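# Replicate-level validation studies: type-I-error calibration on null
# cohorts and detection power / correlation recovery on cohorts with the
# default implanted effects. Both run at the source level (generator ROI
# series -> connectivity -> statistics); the forward/inverse stage has its
# own round-trip contracts and is deliberately excluded from these loops so
# that hundreds of replicate cohorts stay computable.

#' Type-I-error calibration of the cohort-level Mann-Whitney test
#'
#' Generates replicate null cohorts (zero group effect) with a reduced
#' recording size, computes the whole-brain mean PLI per subject in `band`,
#' and counts how often the patient/control Mann-Whitney test rejects at
#' `alpha`.
#'
#' @param n_reps number of replicate cohorts (default 200).
#' @param n_patients,n_controls group sizes (defaults 21, 17).
#' @param band band analyzed (default `"alpha2"`).
#' @param n_rois number of simulated ROIs (default 4).
#' @param n_epochs,epoch_samples reduced recording size (defaults 2, 512).
#' @param alpha nominal level (default 0.05).
#' @param seed integer seed.
#' @return list with `rejections`, `n_reps`, `rate`.
#' @export
calibrate_mann_whitney <- function(n_reps = 200, n_patients = 21,
                                   n_controls = 17, band = "alpha2",
                                   n_rois = 4, n_epochs = 2,
                                   epoch_samples = 512, alpha = 0.05,
                                   seed = 1) {
  labels <- cortical_labels()[seq_len(n_rois)]
  rsns <- list(calibration = labels)
  spec <- null_effect_spec()
  spec$bands <- list()  # no implanted coupling at all: pure background
  rej <- 0L
  for (r in seq_len(n_reps)) {
    coh <- generate_cohort(
      n_patients = n_patients, n_controls = n_controls, effect_spec = spec,
      seed = derive_seed(seed, r), rsns = rsns, level = "source",
      n_epochs = n_epochs, epoch_samples = epoch_samples,
      roi_labels = labels)
    pli_tab <- cohort_rsn_pli(coh, bands = band, whole_brain = TRUE,
                              n_epochs = n_epochs)
    wb <- pli_tab[pli_tab$scope == "whole_brain", ]
    mw <- mann_whitney(wb$value[wb$group == "patient"],
                       wb$value[wb$group == "control"])
    if (mw$p_value < alpha) rej <- rej + 1L
  }
  list(rejections = rej, n_reps = n_reps, rate = rej / n_reps)
}

#' Type-I-error calibration of the per-ROI permutation test
#'
#' Draws replicate null datasets (exchangeable per-subject, per-ROI values),
#' runs [permutation_roi_test()] and records the rejection rate at `alpha`
#' for the first ROI of each replicate (one binomial draw per replicate).
#'
#' @param n_reps number of replicates (default 200).
#' @param n_subjects,n_rois dataset shape (defaults 38, 10).
#' @param n_perm permutations per test (default 1000).
#' @param alpha nominal level (default 0.05).
#' @param seed integer seed.
#' @return list with `rejections`, `n_reps`, `rate`.
#' @export
calibrate_permutation_test <- function(n_reps = 200, n_subjects = 38,
                                       n_rois = 10, n_perm = 1000,
                                       alpha = 0.05, seed = 1) {
  labels <- rep(c("patient", "control"), length.out = n_subjects)
  rej <- 0L
  for (r in seq_len(n_reps)) {
    vals <- with_seed(derive_seed(seed, 5000 + r),
                      matrix(stats::rnorm(n_subjects * n_rois), n_subjects))
    res <- permutation_roi_test(vals, labels, n_perm = n_perm,
                                seed = derive_seed(seed, 6000 + r))
    if (res$per_roi_p[1] < alpha) rej <- rej + 1L
  }
  list(rejections = rej, n_reps = n_reps, rate = rej / n_reps)
}

#' Detection power and covariate-link recovery on default cohorts
#'
#' Generates replicate cohorts with the default implanted effects (alpha2
#' decrease in the default-mode and visual networks, beta increase in the
#' default-mode and temporo-parietal networks), restricted to the RSN member
#' ROIs, and for every band x RSN combination runs the patient/control
#' Mann-Whitney test on the within-RSN mean PLI (uncorrected). Also records,
#' per replicate, the patient-group Spearman correlation between total
#' thalamic volume and the alpha2 visual-network PLI (the tuned rho = 0.58
#' link).
#'
#' @param n_reps number of replicate cohorts (default 50).
#' @param n_patients,n_controls group sizes (defaults 21, 17).
#' @param bands bands tested (default all six canonical).
#' @param alpha test level (default 0.05).
#' @param seed integer seed.
#' @param effect_spec effect specification (default [default_effect_spec()]).
#' @return list with `rates` (data.frame: band, rsn, implanted, rejection
#'   rate), `implanted_rate`, `false_positive_rate`, `spearman_rho` (vector
#'   over replicates), `n_reps`.
#' @export
power_study <- function(n_reps = 50, n_patients = 21, n_controls = 17,
                        bands = canonical_bands()$name, alpha = 0.05,
                        seed = 1, effect_spec = default_effect_spec()) {
  rsns <- default_rsns()
  members <- sort(unique(unlist(rsns)))
  implanted_keys <- unlist(lapply(names(effect_spec$bands), function(b)
    paste(b, effect_spec$bands[[b]]$rsns, sep = ".")))

  combos <- expand.grid(band = bands, rsn = names(rsns),
                        stringsAsFactors = FALSE)
  combos$implanted <- paste(combos$band, combos$rsn, sep = ".") %in% implanted_keys
  reject <- matrix(0L, nrow(combos), n_reps)
  rho <- numeric(n_reps)

  for (r in seq_len(n_reps)) {
    coh <- generate_cohort(
      n_patients = n_patients, n_controls = n_controls,
      effect_spec = effect_spec, seed = derive_seed(seed, 100 + r),
      rsns = rsns, level = "source", roi_labels = members)
    tab <- cohort_rsn_pli(coh, bands = bands, whole_brain = FALSE)
    pat <- coh$subjects$group == "patient"
    for (k in seq_len(nrow(combos))) {
      v <- tab[tab$band == combos$band[k] & tab$scope == combos$rsn[k], ]
      v <- v[match(coh$subjects$subject_id, v$subject_id), "value"]
      mw <- mann_whitney(v[pat], v[!pat])
      if (mw$p_value < alpha) reject[k, r] <- 1L
    }
    va <- tab[tab$band == "alpha2" & tab$scope == "visual", ]
    va <- va[match(coh$subjects$subject_id, va$subject_id), "value"]
    rho[r] <- spearman(coh$subjects$thalamic_volume[pat], va[pat])$rho
  }
  combos$rate <- rowMeans(reject)
  list(rates = combos,
       implanted_rate = mean(reject[combos$implanted, , drop = FALSE]),
       false_positive_rate = mean(reject[!combos$implanted, , drop = FALSE]),
       spearman_rho = rho, n_reps = n_reps)
}
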