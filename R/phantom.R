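#' Digital phantom: lesions with known kinetics on an image grid
#'
#' A phantom stands in for the prostate and its tumour regions: each lesion
#' carries its own exchange kinetics ([kinetic_params()]) and bolus amplitude,
#' and an optional background region receives perfused pyruvate but performs
#' no pyruvate-to-lactate exchange. Voxels outside all regions are empty.
#'
#' @param dim Length-2 grid size (must match the schedule's matrix).
#' @param lesions List of [phantom_lesion()] objects.
#' @param background Logical matrix of perfused background voxels, or `NULL`.
#'   Defaults to a central disc of radius `dim[1]/4` (minus lesion voxels).
#' @param background_amplitude Bolus amplitude in the background region.
#' @return An object of class `"phantom"`.
#' @export
phantom <- function(dim = c(32L, 32L), lesions = list(),
                    background = NULL, background_amplitude = 0.5) {
  dim <- as.integer(dim)
  if (length(dim) != 2 || any(dim < 1)) stop("dim must be two positive integers")
  for (l in lesions) {
    if (!inherits(l, "phantom_lesion")) stop("lesions must be phantom_lesion objects")
    if (any(l$mask_dim != dim)) stop("lesion mask does not match phantom grid")
  }
  if (is.null(background)) {
    background <- disc_mask(dim, centre = (dim + 1) / 2, radius = dim[1] / 4)
  }
  if (!is.logical(background) || !all(dim(background) == dim))
    stop("background must be a logical matrix matching dim")
  for (l in lesions) background[l$mask] <- FALSE
  if (background_amplitude < 0) stop("amplitudes must be >= 0")
  structure(list(dim = dim, lesions = lesions, background = background,
                 background_amplitude = background_amplitude),
            class = "phantom")
}

#' A single phantom lesion
#'
#' @param mask Logical matrix marking the lesion voxels.
#' @param kpl Apparent pyruvate-to-lactate exchange rate constant in 1/s.
#' @param amplitude Bolus amplitude in this lesion (>= 0).
#' @param label Optional lesion label.
#' @return An object of class `"phantom_lesion"`.
#' @export
phantom_lesion <- function(mask, kpl, amplitude = 1, label = NULL) {
  if (!is.logical(mask) || !is.matrix(mask)) stop("mask must be a logical matrix")
  if (!any(mask)) stop("lesion mask is empty")
  if (kpl < 0) stop("kpl must be >= 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  structure(list(mask = mask, mask_dim = dim(mask), kpl = kpl,
                 amplitude = amplitude, label = label),
            class = "phantom_lesion")
}

#' Circular region-of-interest mask
#'
#' @param dim Length-2 grid size.
#' @param centre Length-2 centre (row, col), 1-based voxel coordinates.
#' @param radius Radius in voxels.
#' @return Logical matrix.
#' @export
disc_mask <- function(dim, centre, radius) {
  r <- row(matrix(0, dim[1], dim[2])) - centre[1]
  c <- col(matrix(0, dim[1], dim[2])) - centre[2]
  r * r + c * c <= radius * radius
}

#' Rectangular region-of-interest mask
#'
#' @param dim Length-2 grid size.
#' @param rows,cols Integer index ranges of the rectangle.
#' @return Logical matrix.
#' @export
rect_mask <- function(dim, rows, cols) {
  m <- matrix(FALSE, dim[1], dim[2])
  m[rows, cols] <- TRUE
  m
}

#' Default background-noise region
#'
#' A fixed rectangular strip along the first rows of the grid, away from the
#' central (prostate) region; used as the "background only" region entering
#' the noise mean/standard-deviation estimates and recorded in output
#' sidecars for reproducibility.
#'
#' @param dim Length-2 grid size.
#' @param n_rows Number of edge rows to use.
#' @return Logical matrix.
#' @export
default_noise_roi <- function(dim, n_rows = 4L) {
  rect_mask(dim, seq_len(min(n_rows, dim[1])), seq_len(dim[2]))
}
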