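required_cohort_cols <- c("Tumour", "FinalGleason", "ISUP", "pctGP4",
                          "meanADC", "lactateSNR", "pyruvateSNR",
                          "totalCarbonSNR", "meanKPL")

#' Read a cohort CSV of per-tumour imaging and pathology metrics
#'
#' Expects one row per lesion with the columns `Tumour`, `FinalGleason`,
#' `ISUP`, `pctGP4`, `meanADC` (1e-6 mm2/s), `lactateSNR`, `pyruvateSNR`,
#' `totalCarbonSNR` and `meanKPL` (1/s); optional logical columns
#' `excluded_from_correlation` and `excluded_from_histology` are honoured by
#' the statistics layer. Censored `"<5"` percent-GP4 entries are parsed to a
#' numeric value (default midpoint 2.5) with a `pctGP4_censored` flag.
#'
#' @param path CSV file path.
#' @param gp4_midpoint Numeric value assigned to censored `"<5"` entries,
#'   strictly inside (0, 5).
#' @return Data frame of class `"cohort_table"`.
#' @export
read_cohort_csv <- function(path, gp4_midpoint = 2.5) {
  df <- utils::read.csv(path, check.names = TRUE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required_cohort_cols, names(df))
  if (length(missing_cols))
    stop("missing cohort columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$Tumour)) stop("duplicate lesion ids in cohort CSV")
  gp4 <- gp4_numeric(df$pctGP4, midpoint = gp4_midpoint)
  df$pctGP4 <- gp4$value
  df$pctGP4_censored <- gp4$censored
  if (any(df$meanKPL < 0 | df$meanKPL > 1, na.rm = TRUE))
    stop("meanKPL outside plausible 1/s range: wrong units?")
  if (any(df$meanADC < 10, na.rm = TRUE))
    stop("meanADC outside plausible 1e-6 mm2/s range: wrong units?")
  for (col in c("excluded_from_correlation", "excluded_from_histology"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' The packaged 13-tumour reference cohort
#'
#' Histopathological and imaging characteristics of the 13 prostate tumours
#' (final Gleason score, ISUP grade group, percent Gleason pattern 4, mean
#' ADC, lactate / pyruvate / total-carbon SNR, mean kPL) that the package's
#' correlation and grouping reproductions run on. Two lesions belonging to
#' the patient who received interval androgen deprivation therapy carry
#' exclusion flags: both are excluded from histology-linked analyses, and one
#' from the correlation analysis.
#'
#' @inheritParams read_cohort_csv
#' @return Data frame of class `"cohort_table"`, 13 rows.
#' @export
reference_cohort <- function(gp4_midpoint = 2.5) {
  read_cohort_csv(system.file("extdata", "reference_prostate_cohort.csv",
                              package = "hp13c", mustWork = TRUE),
                  gp4_midpoint = gp4_midpoint)
}

#' Write a dynamic series to NIfTI-1 with a JSON sidecar
#'
#' One 4-D NIfTI file per metabolite (frames along the 4th axis) plus a JSON
#' sidecar carrying the acquisition schedule, noise sigma, seed, and the
#' ground-truth phantom parameters when present - enough provenance to
#' reproduce the series.
#'
#' @param series A `"dynamic_series"`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_dynamic_series <- function(series, dir, prefix = "series") {
  stopifnot(inherits(series, "dynamic_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mets <- dimnames(series$signal)[[4]]
  paths <- character()
  for (m in mets) {
    vol <- series$signal[, , , m, drop = TRUE]
    dim(vol) <- c(dim(vol)[1:2], 1L, dim(vol)[3])  # x, y, z = 1, t
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, m))
    RNifti::writeNifti(RNifti::asNifti(vol), p)
    paths <- c(paths, p)
  }
  truth <- series$truth
  sidecar <- list(
    schedule = unclass(series$schedule),
    times = series$times,
    sigma = series$sigma,
    seed = series$seed,
    metabolites = mets,
    truth = if (is.null(truth)) NULL else list(
      bolus = unclass(truth$bolus),
      T1_pyruvate = truth$T1_pyruvate,
      T1_lactate = truth$T1_lactate,
      lesions = lapply(truth$phantom$lesions, function(l)
        list(kpl = l$kpl, amplitude = l$amplitude, label = l$label,
             n_voxels = sum(l$mask))),
      background_amplitude = truth$phantom$background_amplitude))
  jp <- file.path(dir, sprintf("%s.json", prefix))
  jsonlite::write_json(sidecar, jp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(paths, jp))
}

#' Read a dynamic series written by [write_dynamic_series()]
#'
#' @param dir Directory holding the NIfTI volumes and JSON sidecar.
#' @param prefix File-name prefix used at write time.
#' @return A `"dynamic_series"` (without the ground-truth phantom masks).
#' @export
read_dynamic_series <- function(dir, prefix = "series") {
  sidecar <- jsonlite::read_json(file.path(dir, sprintf("%s.json", prefix)),
                                 simplifyVector = TRUE)
  mets <- sidecar$metabolites
  vols <- lapply(mets, function(m) {
    v <- RNifti::readNifti(file.path(dir, sprintf("%s_%s.nii.gz", prefix, m)))
    a <- as.array(v)
    array(a, dim = dim(a)[c(1, 2, 4)])
  })
  d <- dim(vols[[1]])
  sig <- array(0, dim = c(d, length(mets)),
               dimnames = list(NULL, NULL, NULL, mets))
  for (i in seq_along(mets)) sig[, , , i] <- vols[[i]]
  sched <- sidecar$schedule
  schedule <- acquisition_schedule(
    n_frames = sched$n_frames, frame_interval = sched$frame_interval,
    matrix_size = sched$matrix_size, mode = sched$mode,
    flip_pyruvate = sched$flip_pyruvate, flip_lactate = sched$flip_lactate,
    excitations_per_frame = sched$excitations_per_frame)
  structure(list(signal = sig, times = sidecar$times, schedule = schedule,
                 sigma = sidecar$sigma,
                 seed = if (is.null(sidecar$seed)) NULL else sidecar$seed,
                 truth = NULL),
            class = "dynamic_series")
}

#' Write a 2-D map (e.g. a kPL map or ROI mask) as NIfTI-1
#'
#' @param map Numeric or logical matrix.
#' @param path Output `.nii.gz` path.
#' @return Invisibly, `path`.
#' @export
write_map_nifti <- function(map, path) {
  RNifti::writeNifti(RNifti::asNifti(map * 1), path)
  invisible(path)
}
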