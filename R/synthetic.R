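#' Additive Gaussian noise model
#'
#' @param sigma standard deviation as a fraction of the signal span (>= 0);
#'   0.005 is a realistic photomultiplier-trace noise level after averaging.
#' @param seed integer seed; seeded generation is bit-reproducible.
#' @return Object of class \code{noise_model}.
#' @export
noise_model <- function(sigma = 0.005, seed = 1L) {
  if (!is.numeric(sigma) || sigma < 0) stop("sigma must be >= 0")
  structure(list(sigma = sigma, seed = as.integer(seed)), class = "noise_model")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  expr
}

#' Generate a synthetic CO-rebinding trace
#'
#' Forward-simulates the cavity-migration scheme on a log-spaced 1 ns - 1 s
#' window (the span of a flash-photolysis experiment) and adds seeded
#' Gaussian noise.
#'
#' @param rates a [rate_constants()] object.
#' @param cond a [condition()].
#' @param n_points number of log-spaced samples (default 181, i.e. 20 per
#'   decade over 9 decades).
#' @param noise a [noise_model()].
#' @param t_min,t_max sampling window, s.
#' @param protein,wavelength_nm metadata stored on the trace.
#' @param method forward solver passed to [simulate_scheme()].
#' @return A [kinetic_trace()].
#' @export
#' @examples
#' tr <- gen_rebinding(ngb_rates("cace")$rates, condition(co_atm = 1),
#'                     noise = noise_model(0, 1))
gen_rebinding <- function(rates, cond, n_points = 181,
                          noise = noise_model(), t_min = 1e-9, t_max = 1,
                          protein = NA_character_, wavelength_nm = 436,
                          method = "ode") {
  if (!inherits(noise, "noise_model")) stop("noise must be a noise_model")
  times <- 10^seq(log10(t_min), log10(t_max), length.out = n_points)
  sim <- simulate_scheme(rates, cond, times, method = method)
  signal <- sim$signal
  if (noise$sigma > 0)
    signal <- signal + with_seed(noise$seed,
                                 stats::rnorm(n_points, 0, noise$sigma))
  kinetic_trace(times, signal, condition = cond, protein = protein,
                wavelength_nm = wavelength_nm)
}

#' Generate rebinding traces over a temperature series
#'
#' Rates at each temperature are generated from per-rate Eyring activation
#' parameters, then each temperature yields one trace via [gen_rebinding()];
#' fitting each temperature independently and regressing the rates
#' ln(k/T) ~ 1/T mirrors how activation free energies are obtained from
#' flash-photolysis series.
#'
#' @param delta_h named vector of activation enthalpies (kcal/mol), one per
#'   rate of [rate_names()].
#' @param delta_s named vector of activation entropies (kcal/(mol K));
#'   default 0 for rates not named.
#' @param temps temperatures in K (within 273-310 K).
#' @param cond a [condition()]; its temperature is replaced per trace.
#' @param noise a [noise_model()]; the seed is offset per temperature.
#' @param ... passed to [gen_rebinding()].
#' @return List with one element per temperature: \code{temperature_K},
#'   \code{rates} (the generating [rate_constants()]) and \code{trace}.
#' @export
gen_temperature_series <- function(delta_h, delta_s = NULL, temps,
                                   cond = condition(co_atm = 1),
                                   noise = noise_model(), ...) {
  if (!length(temps)) stop("empty temperature list")
  if (any(temps < 273) || any(temps > 310))
    stop("temperatures must lie within 273-310 K")
  nm <- rate_names()
  dh <- stats::setNames(rep(NA_real_, length(nm)), nm)
  dh[names(delta_h)] <- delta_h
  if (any(is.na(dh))) stop("need delta_h for every rate")
  ds <- stats::setNames(rep(0, length(nm)), nm)
  if (!is.null(delta_s)) ds[names(delta_s)] <- delta_s
  lapply(seq_along(temps), function(i) {
    Tk <- temps[i]
    k <- eyring_rate(Tk, dh, ds)
    rk <- rate_constants(stats::setNames(k, nm))
    cond_i <- condition(temperature_K = Tk, co_atm = cond$co_atm,
                        henry_M_per_atm = cond$henry_M_per_atm, phi = cond$phi)
    noise_i <- noise_model(noise$sigma, noise$seed + i - 1L)
    list(temperature_K = Tk, rates = rk,
         trace = gen_rebinding(rk, cond_i, noise = noise_i, ...))
  })
}

#' Generate a synthetic multi-exponential relaxation trace
#'
#' Signal \eqn{\sum_i a_i e^{-k_i t}} plus seeded Gaussian noise: the form
#' of an autoxidation decay (single component) or a stopped-flow
#' displacement with a minor secondary phase.
#'
#' @param components matrix or data frame with columns (amplitude, rate);
#'   amplitudes > 0, rates per unit of \code{time_unit}.
#' @param duration trace length in \code{time_unit}.
#' @param n_points number of evenly spaced samples.
#' @param sigma Gaussian noise standard deviation (absolute, the signal is
#'   normalized); alternatively pass a [noise_model()] as \code{noise}.
#' @param noise optional [noise_model()] overriding \code{sigma}/\code{seed}.
#' @param seed RNG seed used when \code{noise} is not given.
#' @param time_unit \code{"s"} or \code{"min"}.
#' @param ... metadata passed to [relaxation_trace()].
#' @return A [relaxation_trace()].
#' @export
#' @examples
#' gen_relaxation(cbind(0.96, 0.115), duration = 40, n_points = 200,
#'                sigma = 0.005)
gen_relaxation <- function(components, duration, n_points = 200, sigma = 0,
                           noise = NULL, seed = 1L, time_unit = "s", ...) {
  components <- as.matrix(components)
  if (ncol(components) != 2) stop("components must have columns (amplitude, rate)")
  if (any(components[, 1] <= 0)) stop("amplitudes must be > 0")
  if (any(components[, 2] <= 0)) stop("rates must be > 0")
  if (!is.null(noise)) { sigma <- noise$sigma; seed <- noise$seed }
  t <- seq(0, duration, length.out = n_points)
  y <- rowSums(vapply(seq_len(nrow(components)),
                      function(i) components[i, 1] * exp(-components[i, 2] * t),
                      numeric(length(t))))
  if (sigma > 0) y <- y + with_seed(seed, stats::rnorm(n_points, 0, sigma))
  relaxation_trace(t, y, time_unit = time_unit, ...)
}

#' Toy trajectory of a Lennard-Jones cavity system
#'
#' Builds a fixed template and perturbs it with per-frame Gaussian
#' coordinate jitter: a large spherical cage of LJ atoms with an exit
#' channel (an angular opening towards +z), connected by construction to
#' the outside vacuum, plus a second, smaller cage. The two pockets differ
#' in radius, so the larger one (walls near the probe's LJ minimum
#' distance) shows a deeper insertion free-energy minimum than the tight
#' one, and the channel shows a saddle between the big pocket and empty
#' space -- the qualitative features of a protein cavity system at desk
#' scale.
#'
#' @param n_frames number of frames (>= 1).
#' @param jitter per-atom Gaussian coordinate jitter (Angstrom).
#' @param seed RNG seed; generation is bit-reproducible per seed.
#' @param epsilon,rmin_half LJ parameters given to every template atom.
#' @return A [trajectory_frames()] object. The template (zero jitter) is
#'   returned when \code{jitter = 0}.
#' @export
gen_toy_trajectory <- function(n_frames = 50, jitter = 0.15, seed = 1L,
                               epsilon = 0.12, rmin_half = 1.9) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (jitter < 0) stop("jitter must be >= 0")
  tmpl <- toy_template()
  frames <- if (jitter == 0) {
    rep(list(tmpl), n_frames)
  } else {
    with_seed(seed, lapply(seq_len(n_frames), function(i)
      tmpl + matrix(stats::rnorm(length(tmpl), 0, jitter), nrow(tmpl), 3)))
  }
  trajectory_frames(frames, rep(epsilon, nrow(tmpl)), rep(rmin_half, nrow(tmpl)))
}

# fixed template: big cage (radius 4.6 A, centred at x = -4) with a channel
# opening towards +z, and a tight cage (radius 2.8 A, centred at x = +4)
toy_template <- function() {
  fib_shell <- function(n, radius, centre) {
    u <- probe_orientations(n)
    sweep(u * radius, 2, centre, "+")
  }
  big <- fib_shell(64, 4.6, c(-4, 0, 0))
  # channel: remove atoms within 35 degrees of +z
  keep <- acos(pmin(pmax((big[, 3]) / 4.6, -1), 1)) > 35 * pi / 180
  big <- big[keep, , drop = FALSE]
  small <- fib_shell(40, 2.8, c(4, 0, 0))
  rbind(big, small)
}

#' Coordinates of the toy-template cavity landmarks
#'
#' Waypoints for pathway extraction on grids computed from
#' [gen_toy_trajectory()] frames: the big-pocket centre, the channel mouth
#' and a solvent (vacuum) point beyond the channel.
#'
#' @return Named list of length-3 coordinate vectors.
#' @export
toy_waypoints <- function() {
  list(pocket_large = c(-4, 0, 0),
       channel = c(-4, 0, 4.6),
       solvent = c(-4, 0, 9),
       pocket_small = c(4, 0, 0))
}
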