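# Study orchestration: simulate -> (beamform) -> connectivity -> statistics,
# as one reproducible, configured, logged run that owns all file output.

#' Build a study configuration
#'
#' @param n_patients,n_controls group sizes (defaults 21, 17).
#' @param n_channels,n_rois,voxels_per_roi synthetic geometry (defaults 151,
#'   78, 5; see [generate_geometry()]).
#' @param bands band names analyzed (default the six canonical bands).
#' @param level `"sensor"` runs the full forward + beamformer pipeline;
#'   `"source"` computes connectivity on the simulated ROI series directly.
#' @param effect_spec an `effect_spec` (default [default_effect_spec()]).
#' @param n_epochs,epoch_samples,fs recording shape (defaults 5, 4096, 625).
#' @param reg_fraction beamformer diagonal loading (default 0.05).
#' @param snr sensor-level SNR (default 5).
#' @param edge_trim trim epoch edges before the PLI (default TRUE).
#' @param n_perm permutations for the per-ROI test (default 5000).
#' @param alpha gate level for the post-hoc hierarchy (default 0.05).
#' @param correction per-ROI correction: `"none"` or `"maxstat"`.
#' @param outlier_rule `"none"` or `"resid3"` (re-run correlations after
#'   dropping |studentized residual| > 3 points).
#' @param rsns named list of RSN memberships; `NULL` (default) uses
#'   [default_rsns()] (requires the 78-ROI atlas labels).
#' @param seed master seed.
#' @return list of class `study_config`.
#' @export
study_config <- function(n_patients = 21, n_controls = 17,
                         n_channels = 151, n_rois = 78, voxels_per_roi = 5,
                         bands = canonical_bands()$name,
                         level = c("sensor", "source"),
                         effect_spec = default_effect_spec(),
                         n_epochs = 5, epoch_samples = 4096, fs = 625,
                         reg_fraction = 0.05, snr = 5, edge_trim = TRUE,
                         n_perm = 5000, alpha = 0.05,
                         correction = c("none", "maxstat"),
                         outlier_rule = c("none", "resid3"),
                         rsns = NULL, seed = 42) {
  structure(list(
    n_patients = n_patients, n_controls = n_controls,
    n_channels = n_channels, n_rois = n_rois, voxels_per_roi = voxels_per_roi,
    bands = bands, level = match.arg(level), effect_spec = effect_spec,
    n_epochs = n_epochs, epoch_samples = epoch_samples, fs = fs,
    reg_fraction = reg_fraction, snr = snr, edge_trim = edge_trim,
    n_perm = n_perm, alpha = alpha, correction = match.arg(correction),
    outlier_rule = match.arg(outlier_rule), rsns = rsns, seed = seed
  ), class = "study_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

spearman_dropping_outliers <- function(x, y) {
  fit <- stats::lm(y ~ x)
  keep <- abs(stats::rstudent(fit)) <= 3
  if (sum(keep) < 5 || all(keep)) return(NULL)
  c(spearman(x[keep], y[keep]), list(n_dropped = sum(!keep)))
}

#' Run the full study pipeline
#'
#' Generates the synthetic cohort, reconstructs ROI time series (through the
#' beamformer when `level = "sensor"`), computes PLI adjacency matrices, node
#' strengths, whole-brain and within-RSN means per band, and applies the
#' statistical hierarchy: whole-brain Mann-Whitney per band; for significant
#' bands, per-ROI permutation tests and per-RSN Mann-Whitney tests; for
#' significant band x RSN combinations, Spearman correlations with the
#' clinical covariates (per group) and effect-modification regressions for
#' the volumetric covariates.
#'
#' @param config a `study_config`.
#' @param out_dir optional output directory; when given, writes the resolved
#'   config (YAML), covariates (TSV), per-subject adjacency matrices (CSV),
#'   an edge list (TSV), summary and test tables (TSV) and a run log.
#' @return list of class `study_result`: `summaries` (long data.frame of
#'   whole-brain/RSN values), `node_strength` (subjects x ROI per band),
#'   `adjacency` (per subject per band), `tests` (data.frame), `correlations`
#'   (data.frame), `effect_modification` (data.frame), `subjects`,
#'   `provenance` (seed, config hash, package version).
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), msg))
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  geometry <- NULL
  if (config$level == "sensor") {
    geometry <- stage("geometry", generate_geometry(
      n_channels = config$n_channels, n_rois = config$n_rois,
      voxels_per_roi = config$voxels_per_roi,
      seed = derive_seed(config$seed, 11)))
    say("geometry: %d channels, %d ROIs, %d voxels",
        config$n_channels, length(geometry$atlas$labels),
        nrow(geometry$atlas$voxels))
  }

  cohort <- stage("cohort", generate_cohort(
    n_patients = config$n_patients, n_controls = config$n_controls,
    effect_spec = config$effect_spec, seed = derive_seed(config$seed, 23),
    geometry = geometry, rsns = config$rsns %||% default_rsns(),
    level = config$level, n_epochs = config$n_epochs,
    epoch_samples = config$epoch_samples, fs = config$fs, snr = config$snr))
  subjects <- cohort$subjects
  n_sub <- nrow(subjects)
  labels <- cohort$labels
  say("cohort: %d patients + %d controls, %d epochs x %d samples at %g Hz",
      config$n_patients, config$n_controls, config$n_epochs,
      config$epoch_samples, config$fs)

  # --- ROI series and adjacency per subject per band ----------------------
  adjacencies <- list()
  summaries <- list()
  strength <- lapply(config$bands, function(b) matrix(
    NA_real_, n_sub, length(labels), dimnames = list(subjects$subject_id, labels)))
  names(strength) <- config$bands

  for (s in seq_len(n_sub)) {
    sid <- subjects$subject_id[s]
    rec <- cohort$recordings[[s]]
    roi_by_band <- stage(paste0("beamform:", sid), {
      if (config$level == "sensor") {
        C <- compute_covariance(rec)
        model <- compute_weights(geometry$atlas$voxels, geometry$sensors,
                                 geometry$head, C,
                                 reg_fraction = config$reg_fraction)
        vox <- reconstruct_voxels(rec, model)
        out <- lapply(config$bands, function(b) {
          select_roi_voxel(vox, geometry$atlas, b, config$fs)$series
        })
        names(out) <- config$bands
        out
      } else {
        out <- lapply(config$bands, function(b) rec$series)
        names(out) <- config$bands
        out
      }
    })
    for (b in config$bands) {
      A <- stage(paste0("connectivity:", sid), adjacency(
        roi_by_band[[b]], b, config$fs, n_epochs = config$n_epochs,
        edge_trim = config$edge_trim, labels = labels, subject_id = sid))
      adjacencies[[paste(sid, b, sep = ".")]] <- A
      ns <- node_strength(A)
      strength[[b]][s, ] <- ns
      wb <- mean(ns)
      rsn_vals <- vapply(names(cohort$rsns), function(rn)
        rsn_mean_pli(A, cohort$rsns[[rn]]), numeric(1))
      summaries[[length(summaries) + 1]] <- data.frame(
        subject_id = sid, group = subjects$group[s], band = b,
        scope = c("whole_brain", names(cohort$rsns)),
        value = c(wb, unname(rsn_vals)), stringsAsFactors = FALSE)
    }
  }
  summaries <- do.call(rbind, summaries)
  say("connectivity: %d adjacency matrices (%d bands)", length(adjacencies),
      length(config$bands))

  # --- statistical hierarchy ---------------------------------------------
  pat <- subjects$group == "patient"
  tests <- list()
  correlations <- list()
  effectmod <- list()
  covar_names <- c("edss", "cognition_z", "thalamic_volume", "nbv", "ngmv")
  volume_names <- c("thalamic_volume", "nbv", "ngmv")

  get_vals <- function(b, scope) {
    v <- summaries[summaries$band == b & summaries$scope == scope, ]
    v[match(subjects$subject_id, v$subject_id), "value"]
  }

  for (b in config$bands) {
    wb <- get_vals(b, "whole_brain")
    mw <- mann_whitney(wb[pat], wb[!pat])
    gate_open <- mw$p_value < config$alpha
    tests[[length(tests) + 1]] <- data.frame(
      test = "mann_whitney", band = b, scope = "whole_brain",
      statistic = mw$statistic_u, p = mw$p_value, n1 = mw$n1, n2 = mw$n2,
      direction = mw$direction, stringsAsFactors = FALSE)
    if (!gate_open) next
    say("band %s: whole-brain group difference (p = %.4g), running post-hoc tests",
        b, mw$p_value)

    perm <- permutation_roi_test(strength[[b]], subjects$group,
                                 n_perm = config$n_perm,
                                 seed = derive_seed(config$seed, 31),
                                 correction = config$correction)
    for (k in seq_along(labels)) {
      tests[[length(tests) + 1]] <- data.frame(
        test = "permutation_t", band = b, scope = labels[k],
        statistic = perm$per_roi_t[k], p = perm$per_roi_p[k],
        n1 = sum(pat), n2 = sum(!pat),
        direction = if (perm$per_roi_t[k] == 0) "none" else
          if (xor(perm$per_roi_t[k] > 0,
                  levels(as.factor(subjects$group))[1] == "patient"))
            "lower_in_patients" else "higher_in_patients",
        stringsAsFactors = FALSE)
    }

    for (rn in names(cohort$rsns)) {
      rv <- get_vals(b, rn)
      mw_r <- mann_whitney(rv[pat], rv[!pat])
      tests[[length(tests) + 1]] <- data.frame(
        test = "mann_whitney", band = b, scope = rn,
        statistic = mw_r$statistic_u, p = mw_r$p_value, n1 = mw_r$n1,
        n2 = mw_r$n2, direction = mw_r$direction, stringsAsFactors = FALSE)
      if (mw_r$p_value >= config$alpha) next
      for (cv in covar_names) {
        for (g in c("patient", "control")) {
          gi <- subjects$group == g
          x <- subjects[[cv]][gi]; yv <- rv[gi]
          if (stats::sd(rank(x)) == 0) next
          sp <- spearman(x, yv)
          correlations[[length(correlations) + 1]] <- data.frame(
            band = b, scope = rn, covariate = cv, group = g,
            rho = sp$rho, p = sp$p_value, n = sp$n, outliers_dropped = 0L,
            stringsAsFactors = FALSE)
          if (config$outlier_rule == "resid3") {
            sp2 <- spearman_dropping_outliers(x, yv)
            if (!is.null(sp2)) {
              say("outlier rule dropped %d point(s): %s %s %s (%s)",
                  sp2$n_dropped, b, rn, cv, g)
              correlations[[length(correlations) + 1]] <- data.frame(
                band = b, scope = rn, covariate = cv, group = g,
                rho = sp2$rho, p = sp2$p_value, n = sp2$n,
                outliers_dropped = sp2$n_dropped, stringsAsFactors = FALSE)
            }
          }
        }
      }
      for (cv in volume_names) {
        em <- tryCatch(
          effect_modification_regression(rv, subjects[[cv]], subjects$group),
          error = function(e) NULL)
        if (is.null(em)) next
        effectmod[[length(effectmod) + 1]] <- cbind(
          data.frame(band = b, scope = rn, covariate = cv,
                     interaction_B = em$interaction$B,
                     interaction_beta = em$interaction$beta,
                     interaction_p = em$interaction$p_value,
                     stringsAsFactors = FALSE),
          stats::setNames(
            as.data.frame(t(unlist(em$per_group[, c("B", "beta", "p_value")]))),
            paste(rep(c("B", "beta", "p"), times = nrow(em$per_group)),
                  rep(em$per_group$group, each = 3), sep = "_")))
      }
    }
  }

  result <- structure(list(
    summaries = summaries,
    node_strength = strength,
    adjacency = adjacencies,
    tests = if (length(tests)) do.call(rbind, tests) else NULL,
    correlations = if (length(correlations)) do.call(rbind, correlations) else NULL,
    effect_modification = if (length(effectmod)) do.call(rbind, effectmod) else NULL,
    subjects = subjects,
    provenance = list(seed = config$seed, config_hash = config_hash(config),
                      version = as.character(utils::packageVersion("megconn")))
  ), class = "study_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(unclass(config)[!vapply(unclass(config), is.list, logical(1))],
                     file.path(out_dir, "config.yaml"))
    write_covariates_tsv(subjects, file.path(out_dir, "covariates.tsv"))
    utils::write.table(summaries, file.path(out_dir, "pli_summaries.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(result$tests)) {
      utils::write.table(result$tests, file.path(out_dir, "tests.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    if (!is.null(result$correlations)) {
      utils::write.table(result$correlations, file.path(out_dir, "correlations.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    if (!is.null(result$effect_modification)) {
      utils::write.table(result$effect_modification,
                         file.path(out_dir, "effect_modification.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    adj_dir <- file.path(out_dir, "adjacency")
    dir.create(adj_dir, showWarnings = FALSE)
    edges <- list()
    for (nm in names(adjacencies)) {
      write_adjacency_csv(adjacencies[[nm]],
                          file.path(adj_dir, paste0(nm, ".csv")))
      edges[[nm]] <- adjacency_edges(adjacencies[[nm]])
    }
    utils::write.table(do.call(rbind, edges), file.path(out_dir, "edges.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(c(sprintf("seed: %d", config$seed),
                 sprintf("config_hash: %s", result$provenance$config_hash),
                 sprintf("version: %s", result$provenance$version),
                 log_lines),
               file.path(out_dir, "run.log"))
    say("outputs written to %s", out_dir)
  }
  result
}
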