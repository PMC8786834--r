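# Independent oracles used across the suite. These deliberately avoid the
# package's own integration and testing code paths: fixed-step RK4 for the
# exchange ODE, exhaustive enumeration for the Mann-Whitney p-value, and the
# closed-form 1 - 6*sum(d^2)/(n(n^2-1)) Spearman formula for tie-free ranks.

# RK4 for dL/dt = kpl * P(t) - rho * L with P given by linear interpolation
rk4_lactate <- function(kpl, rho, P, times, dt = 0.01) {
  pfun <- stats::approxfun(times, P, rule = 2)
  out <- numeric(length(times))
  t <- times[1]
  L <- 0
  i <- 2
  f <- function(t, L) kpl * pfun(t) - rho * L
  while (i <= length(times)) {
    h <- min(dt, times[i] - t)
    k1 <- f(t, L)
    k2 <- f(t + h / 2, L + h / 2 * k1)
    k3 <- f(t + h / 2, L + h / 2 * k2)
    k4 <- f(t + h, L + h * k3)
    L <- L + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
    if (abs(t - times[i]) < 1e-9) {
      out[i] <- L
      i <- i + 1
    }
  }
  out
}

# RK4 for the full magnetisation system with discrete RF consumption at frame
# boundaries (independent re-implementation of the simulate forward model)
rk4_full_system <- function(kpl, schedule, bolus, T1p = 30, T1l = 25,
                            dt = 0.01) {
  nf <- schedule$n_frames
  dtf <- schedule$frame_interval
  rp <- 1 / T1p + kpl
  rl <- 1 / T1l
  cp <- cos(schedule$flip_pyruvate * pi / 180)^schedule$excitations_per_frame
  cl <- cos(schedule$flip_lactate * pi / 180)^schedule$excitations_per_frame
  b <- function(t) bolus_signal(bolus, t)
  f <- function(t, y) c(b(t) - rp * y[1], kpl * y[1] - rl * y[2])
  y <- c(0, 0)
  Mp <- numeric(nf)
  Ml <- numeric(nf)
  for (fr in seq_len(nf)) {
    Mp[fr] <- y[1]
    Ml[fr] <- y[2]
    if (fr == nf) break
    y <- y * c(cp, cl)
    t <- (fr - 1) * dtf
    n_steps <- round(dtf / dt)
    h <- dtf / n_steps
    for (s in seq_len(n_steps)) {
      k1 <- f(t, y)
      k2 <- f(t + h / 2, y + h / 2 * k1)
      k3 <- f(t + h / 2, y + h / 2 * k2)
      k4 <- f(t + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
  }
  list(Mp = Mp, Ml = Ml,
       signal_pyruvate = sin(schedule$flip_pyruvate * pi / 180) * Mp,
       signal_lactate = sin(schedule$flip_lactate * pi / 180) * Ml)
}

# two-sided Mann-Whitney p by enumerating all choose(n1+n2, n1) labelings
enum_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(idx) {
    x <- pooled[idx]
    y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  all_u <- apply(utils::combn(length(pooled), n1), 2, u_of)
  mu <- n1 * length(b) / 2
  mean(abs(all_u - mu) >= abs(u_obs - mu) - 1e-9)
}

# tie-free Spearman via the closed-form rank-difference formula
brute_spearman <- function(x, y) {
  n <- length(x)
  rx <- match(x, sort(x))
  ry <- match(y, sort(y))
  1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
}

default_test_schedule <- function(...) acquisition_schedule(...)

small_lesion_phantom <- function(kpl = 0.01, amplitude = 1, dim = c(32L, 32L),
                                 radius = 3) {
  mask <- disc_mask(dim, centre = (dim + 1) / 2, radius = radius)
  phantom(dim, lesions = list(phantom_lesion(mask, kpl, amplitude)))
}
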