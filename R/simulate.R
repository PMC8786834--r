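#' Forward model for one voxel class: magnetisation curves at frame times
#'
#' Integrates the two-site exchange system on a fine internal time grid
#' (trapezoidal accumulation of the exact exponential-decay convolution,
#' vectorised with [stats::filter()]) and samples the longitudinal
#' magnetisation at the frame times. RF consumption is applied discretely:
#' after each frame is sampled, both pools are multiplied by
#' `cos(flip)^excitations_per_frame`.
#'
#' The model is
#' \deqn{dM_P/dt = b(t) - (1/T_{1P} + k_{PL}) M_P,\qquad
#'       dM_L/dt = k_{PL} M_P - (1/T_{1L}) M_L,}
#' with b(t) the bolus input. Measured signal per frame is
#' `sin(flip) * M` just before the RF consumption of that frame.
#'
#' @param kpl Exchange rate constant in 1/s.
#' @param schedule An [acquisition_schedule()].
#' @param bolus A [bolus_input()].
#' @param T1_pyruvate,T1_lactate Longitudinal relaxation times in seconds.
#' @param dt Internal integration step in seconds (default 0.01).
#' @return List with `times`, magnetisations `Mp`, `Ml` and measured signals
#'   `signal_pyruvate`, `signal_lactate` at the frame times.
#' @keywords internal
simulate_voxel_curves <- function(kpl, schedule, bolus,
                                  T1_pyruvate = 30, T1_lactate = 25,
                                  dt = 0.01) {
  nf <- schedule$n_frames
  dt_frame <- schedule$frame_interval
  m <- max(2L, round(dt_frame / dt))
  dt <- dt_frame / m
  rp <- 1 / T1_pyruvate + kpl
  rl <- 1 / T1_lactate
  cp <- cos(schedule$flip_pyruvate * pi / 180)^schedule$excitations_per_frame
  cl <- cos(schedule$flip_lactate * pi / 180)^schedule$excitations_per_frame
  Ep <- exp(-rp * dt)
  El <- exp(-rl * dt)

  Mp_s <- numeric(nf)
  Ml_s <- numeric(nf)
  Mp <- 0
  Ml <- 0
  for (f in seq_len(nf)) {
    Mp_s[f] <- Mp
    Ml_s[f] <- Ml
    if (f == nf) break
    Mp <- Mp * cp
    Ml <- Ml * cl
    t0 <- (f - 1) * dt_frame
    tt <- t0 + dt * (0:m)
    b <- bolus_signal(bolus, tt)
    # trapezoidal accumulation of the decay convolution, recursively:
    # Mp_j = Ep Mp_{j-1} + dt/2 (b_j + Ep b_{j-1})
    up <- dt / 2 * (b[-1] + Ep * b[-(m + 1)])
    Mp_path <- c(Mp, stats::filter(up, Ep, method = "recursive", init = Mp))
    ul <- kpl * dt / 2 * (Mp_path[-1] + El * Mp_path[-(m + 1)])
    Ml <- as.numeric(stats::filter(ul, El, method = "recursive", init = Ml))[m]
    Mp <- Mp_path[m + 1]
  }
  list(times = frame_times(schedule),
       Mp = Mp_s, Ml = Ml_s,
       signal_pyruvate = sin(schedule$flip_pyruvate * pi / 180) * Mp_s,
       signal_lactate = sin(schedule$flip_lactate * pi / 180) * Ml_s)
}

#' Simulate a noiseless dynamic metabolite image series
#'
#' Builds the per-metabolite 4-D signal stack (x, y, frame, metabolite) for a
#' phantom under an acquisition schedule and bolus input. Lesion voxels follow
#' the two-site exchange model with the lesion's kPL; background voxels
#' receive perfused pyruvate with no exchange; all other voxels are zero.
#' Voxels are spatially independent (no point-spread model).
#'
#' @param phantom A [phantom()]; its grid must match the schedule matrix.
#' @param schedule An [acquisition_schedule()].
#' @param bolus A [bolus_input()]; per-region amplitudes multiply its
#'   (unit-amplitude) shape.
#' @param T1_pyruvate,T1_lactate Relaxation times in seconds.
#' @param dt Internal integration step in seconds.
#' @return A `"dynamic_series"` object: `signal` array
#'   `[x, y, frame, metabolite]` with metabolites `pyruvate`, `lactate`;
#'   `times`; the `schedule`; `sigma = 0`; and the ground-truth provenance.
#' @export
simulate_dynamic_series <- function(phantom, schedule = acquisition_schedule(),
                                    bolus = bolus_input(),
                                    T1_pyruvate = 30, T1_lactate = 25,
                                    dt = 0.01) {
  if (!inherits(phantom, "phantom")) stop("phantom must be a phantom object")
  if (any(phantom$dim != schedule$matrix_size))
    stop("phantom grid does not match schedule matrix size")
  nf <- schedule$n_frames
  dims <- c(phantom$dim, nf, 2L)
  sig <- array(0, dim = dims,
               dimnames = list(NULL, NULL, NULL, c("pyruvate", "lactate")))
  unit_bolus <- bolus_input(arrival = bolus$arrival, shape = bolus$shape,
                            scale = bolus$scale, amplitude = 1)
  curve_cache <- list()
  curves_for <- function(kpl) {
    key <- sprintf("%.12g", kpl)
    if (is.null(curve_cache[[key]])) {
      curve_cache[[key]] <<- simulate_voxel_curves(
        kpl, schedule, unit_bolus, T1_pyruvate, T1_lactate, dt)
    }
    curve_cache[[key]]
  }
  fill_region <- function(mask, kpl, amplitude) {
    cv <- curves_for(kpl)
    idx <- which(mask)
    npx <- phantom$dim[1] * phantom$dim[2]
    for (f in seq_len(nf)) {
      sig[idx + (f - 1) * npx] <<-
        amplitude * bolus$amplitude * cv$signal_pyruvate[f]
      sig[idx + (f - 1) * npx + nf * npx] <<-
        amplitude * bolus$amplitude * cv$signal_lactate[f]
    }
  }
  if (any(phantom$background) && phantom$background_amplitude > 0)
    fill_region(phantom$background, 0, phantom$background_amplitude)
  for (l in phantom$lesions) fill_region(l$mask, l$kpl, l$amplitude)

  structure(list(
    signal = sig,
    times = frame_times(schedule),
    schedule = schedule,
    sigma = 0,
    seed = NULL,
    truth = list(phantom = phantom, bolus = bolus,
                 T1_pyruvate = T1_pyruvate, T1_lactate = T1_lactate)
  ), class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<dynamic_series> %d x %d grid, %d frames, metabolites: %s; sigma = %g\n",
              d[1], d[2], d[3], paste(dimnames(x$signal)[[4]], collapse = ", "),
              x$sigma))
  invisible(x)
}

#' Add Rician (magnitude-of-complex-Gaussian) noise to a dynamic series
#'
#' Each voxel value v is replaced by `|(v + g1) + i g2|` with g1, g2
#' independent zero-mean Gaussians of standard deviation `sigma`. This is the
#' magnitude-noise model under which the background follows a Rayleigh
#' distribution, making the sqrt(2) factor of the SNR definition
#' (see [compute_snr()]) self-consistent. Noise is never added as Gaussian on
#' magnitudes.
#'
#' @param series A `"dynamic_series"`.
#' @param sigma Noise standard deviation in signal units (>= 0). `sigma = 0`
#'   returns the input unchanged.
#' @param seed Integer seed for reproducibility, or `NULL`.
#' @return A `"dynamic_series"` with noisy non-negative magnitudes.
#' @export
add_noise <- function(series, sigma, seed = NULL) {
  if (!inherits(series, "dynamic_series")) stop("series must be a dynamic_series")
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(series)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    }, add = TRUE)
    set.seed(seed)
  }
  n <- length(series$signal)
  g1 <- stats::rnorm(n, 0, sigma)
  g2 <- stats::rnorm(n, 0, sigma)
  noisy <- sqrt((series$signal + g1)^2 + g2^2)
  out <- series
  out$signal <- array(noisy, dim = dim(series$signal),
                      dimnames = dimnames(series$signal))
  out$sigma <- sigma
  out$seed <- seed
  out
}
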