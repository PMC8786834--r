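#' Acquisition schedule for a dynamic 13C series
#'
#' Describes the frame timing, matrix size and radiofrequency (RF) excitation
#' scheme of a dynamic hyperpolarised 13C acquisition. The default reproduces
#' a 32 x 32 matrix sampled every 4 s for 20 time points. Two excitation
#' schemes are supported: `"ideal"`, in which pyruvate and lactate share a
#' small nominal flip angle applied several times per frame (an
#' IDEAL-spiral-like multi-echo readout), and `"spsp"`, in which a
#' spectral-spatial pulse addresses the metabolites separately with different
#' flip angles.
#'
#' RF consumption of longitudinal magnetisation is modelled per frame as a
#' multiplicative `cos(flip)^excitations_per_frame` factor applied after each
#' frame is sampled (see [simulate_dynamic_series()]).
#'
#' @param n_frames Number of time frames (>= 2).
#' @param frame_interval Temporal resolution in seconds (> 0).
#' @param matrix_size Length-2 integer vector, image grid size.
#' @param mode `"ideal"` or `"spsp"`.
#' @param flip_pyruvate,flip_lactate Flip angles in degrees, in (0, 90].
#'   Defaults depend on `mode`: 15/15 for `"ideal"`, 15/40 for `"spsp"`.
#' @param excitations_per_frame Effective number of RF excitations consuming
#'   longitudinal magnetisation per frame. Defaults to 2 for both modes: for
#'   `"spsp"` this is the 2 s repetition time within a 4 s frame; for
#'   `"ideal"` the multi-echo cycle shares excited magnetisation across
#'   echoes, so the effective consumption per frame is far below the echo
#'   count and is left configurable.
#' @return An object of class `"acquisition_schedule"`.
#' @export
acquisition_schedule <- function(n_frames = 20,
                                 frame_interval = 4,
                                 matrix_size = c(32L, 32L),
                                 mode = c("ideal", "spsp"),
                                 flip_pyruvate = NULL,
                                 flip_lactate = NULL,
                                 excitations_per_frame = NULL) {
  mode <- match.arg(mode)
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (length(matrix_size) != 2 || any(matrix_size < 1))
    stop("matrix_size must be two positive integers")
  if (is.null(flip_pyruvate)) flip_pyruvate <- 15
  if (is.null(flip_lactate)) flip_lactate <- if (mode == "spsp") 40 else 15
  if (is.null(excitations_per_frame)) excitations_per_frame <- 2L
  for (fl in c(flip_pyruvate, flip_lactate))
    if (fl <= 0 || fl > 90) stop("flip angles must lie in (0, 90] degrees")
  structure(list(
    n_frames = as.integer(n_frames),
    frame_interval = frame_interval,
    matrix_size = as.integer(matrix_size),
    mode = mode,
    flip_pyruvate = flip_pyruvate,
    flip_lactate = flip_lactate,
    excitations_per_frame = as.integer(excitations_per_frame)
  ), class = "acquisition_schedule")
}

#' @export
print.acquisition_schedule <- function(x, ...) {
  cat(sprintf(
    "<acquisition_schedule> %d frames @ %g s, %d x %d, mode=%s, flips %g/%g deg, %d exc/frame\n",
    x$n_frames, x$frame_interval, x$matrix_size[1], x$matrix_size[2],
    x$mode, x$flip_pyruvate, x$flip_lactate, x$excitations_per_frame))
  invisible(x)
}

#' Frame time stamps of a schedule
#' @param schedule An [acquisition_schedule()].
#' @return Numeric vector of frame times in seconds, starting at 0.
#' @export
frame_times <- function(schedule) {
  seq(0, by = schedule$frame_interval, length.out = schedule$n_frames)
}
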