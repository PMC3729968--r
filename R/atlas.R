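#' Cerebral parcellation labels
#'
#' Returns the 90-region automated-anatomical-labelling (AAL) cerebrum
#' parcellation as a data.frame with a `cortical` flag. The 12 subcortical
#' regions (bilateral hippocampus, amygdala, caudate, putamen, pallidum,
#' thalamus) are the ones conventionally dropped to obtain the 78 cortical
#' regions used for source-space connectivity.
#'
#' @return data.frame with columns `label` and `cortical` (logical), 90 rows.
#' @export
aal_labels <- function() {
  path <- system.file("extdata", "aal90_labels.tsv", package = "megconn")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$cortical <- as.logical(tab$cortical)
  tab
}

#' Cortical ROI labels
#'
#' @param labels parcellation table as returned by [aal_labels()].
#' @return character vector of the 78 cortical region labels.
#' @export
cortical_labels <- function(labels = aal_labels()) {
  labels$label[labels$cortical]
}

#' Default resting-state network definitions
#'
#' Named ROI subsets for seven resting-state networks (default mode, left and
#' right fronto-parietal, executive control, sensorimotor, temporo-parietal,
#' visual) expressed in cortical AAL labels. Memberships are a best-effort
#' reconstruction from the fMRI literature with two adjustments that keep
#' within-network connections unique: the fronto-parietal networks use the
#' superior parietal gyrus rather than the precuneus, and the inferior frontal
#' gyrus is split between the temporo-parietal network (pars opercularis) and
#' the fronto-parietal networks (pars triangularis). Treat these memberships
#' as configuration: [read_rsn_json()] loads alternatives.
#'
#' @return named list of character vectors of ROI labels.
#' @export
default_rsns <- function() {
  path <- system.file("extdata", "rsn_default.json", package = "megconn")
  read_rsn_json(path, roi_labels = cortical_labels())
}

#' Validate RSN definitions against an atlas
#'
#' @param rsns named list of character vectors of ROI labels.
#' @param roi_labels character vector of valid ROI labels.
#' @return `rsns`, invisibly, after validation.
#' @export
validate_rsns <- function(rsns, roi_labels) {
  stopifnot(is.list(rsns), !is.null(names(rsns)), all(nzchar(names(rsns))))
  for (nm in names(rsns)) {
    members <- rsns[[nm]]
    unknown <- setdiff(members, roi_labels)
    if (length(unknown) > 0) {
      stop("RSN '", nm, "' references unknown ROI label(s): ",
           paste(unknown, collapse = ", "))
    }
    if (length(members) < 2) {
      stop("RSN '", nm, "' has fewer than 2 member ROIs")
    }
    if (anyDuplicated(members)) {
      stop("RSN '", nm, "' has duplicated ROI labels")
    }
  }
  invisible(rsns)
}
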