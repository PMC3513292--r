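#' Relaxation trace container
#'
#' Holds a normalized single-wavelength relaxation time course, e.g. an
#' autoxidation decay (oxy -> met, conventionally monitored at 580 nm) or a
#' stopped-flow ligand displacement (CO replaced by excess NO, 415 nm).
#'
#' @param times monotone non-decreasing times in seconds (use
#'   \code{time_unit = "min"} to pass minutes, stored internally in the
#'   given unit).
#' @param signal normalized signal.
#' @param time_unit \code{"s"} or \code{"min"}; retained as metadata.
#' @param wavelength_nm,temperature_K optional metadata.
#' @return Object of class \code{relaxation_trace}.
#' @export
relaxation_trace <- function(times, signal, time_unit = "s",
                             wavelength_nm = NA_real_, temperature_K = NA_real_) {
  if (length(times) != length(signal)) stop("times and signal lengths differ")
  if (length(times) == 0) stop("empty trace")
  if (any(!is.finite(times)) || any(!is.finite(signal)))
    stop("trace contains non-finite values")
  if (is.unsorted(times)) stop("times must be monotone")
  time_unit <- match.arg(time_unit, c("s", "min"))
  structure(list(times = as.numeric(times), signal = as.numeric(signal),
                 time_unit = time_unit, wavelength_nm = wavelength_nm,
                 temperature_K = temperature_K),
            class = "relaxation_trace")
}

#' @export
print.relaxation_trace <- function(x, ...) {
  cat(sprintf("<relaxation_trace> %d points, t in [%.3g, %.3g] %s\n",
              length(x$times), min(x$times), max(x$times), x$time_unit))
  invisible(x)
}

#' Normalize a raw trace between two reference values
#'
#' Affine rescaling so that the reference value of the initial species (e.g.
#' the pure oxy spectrum) maps to 1 and the final species (e.g. the
#' ferricyanide-oxidised met form) maps to 0.
#'
#' @param times,raw time base and raw signal.
#' @param oxy_reference raw value corresponding to the pure initial form.
#' @param met_reference raw value corresponding to the pure final form.
#' @param ... passed to [relaxation_trace()].
#' @return A [relaxation_trace()] with signal
#'   \code{(raw - met) / (oxy - met)}.
#' @export
normalize_endpoints <- function(times, raw, oxy_reference, met_reference, ...) {
  if (!is.finite(oxy_reference) || !is.finite(met_reference))
    stop("references must be finite")
  if (oxy_reference == met_reference) stop("references must be distinct")
  relaxation_trace(times, (raw - met_reference) / (oxy_reference - met_reference),
                   ...)
}

#' Fit a 1- or 2-exponential relaxation
#'
#' Nonlinear least squares of \eqn{\sum_i a_i e^{-k_i t}} with positivity
#' constraints (amplitudes and rates are searched on the log scale).
#' Components are ordered by amplitude; the \code{heterogeneous} flag is set
#' when the minor component carries at least \code{minor_threshold} (default
#' 5 percent) of the total amplitude, so a below-threshold minor phase is
#' reported but not flagged.
#'
#' @param trace a [relaxation_trace()] (or a [kinetic_trace()]).
#' @param n_components 1 or 2.
#' @param minor_threshold amplitude fraction above which a second phase
#'   marks the kinetics as heterogeneous.
#' @return Object of class \code{exponential_fit}: list with
#'   \code{amplitudes}, \code{rates} (per unit of the trace time base),
#'   \code{tau} (1/rates), \code{se_rates}, \code{rms}, \code{n_components},
#'   \code{heterogeneous}, \code{minor_fraction}, \code{converged}.
#' @export
#' @examples
#' tr <- gen_relaxation(components = cbind(1, 1/39), duration = 200,
#'                      n_points = 100, sigma = 0, time_unit = "min")
#' fit_exponential(tr)$tau     # 39 min
fit_exponential <- function(trace, n_components = 1, minor_threshold = 0.05) {
  if (!inherits(trace, c("relaxation_trace", "kinetic_trace")))
    stop("trace must be a relaxation_trace or kinetic_trace")
  if (!n_components %in% 1:2) stop("n_components must be 1 or 2")
  t <- trace$times
  y <- trace$signal
  span <- diff(range(y))
  if (span == 0) stop("constant trace: zero signal span")
  npar <- 2 * n_components
  if (length(t) < 5 * npar)
    stop("need at least ", 5 * npar, " points for ", npar, " free parameters")

  # crude single-exponential scales for initialisation
  t_half <- stats::approx(y, t, xout = (max(y) + min(y)) / 2, ties = "ordered")$y
  if (!is.finite(t_half) || t_half <= 0) t_half <- stats::median(t[t > 0])
  k0 <- log(2) / t_half
  start <- if (n_components == 1) log(c(span, k0))
           else log(c(0.7 * span, 0.3 * span, k0, 5 * k0))
  model <- function(p) {
    a <- exp(p[seq_len(n_components)])
    k <- exp(p[n_components + seq_len(n_components)])
    rowSums(vapply(seq_len(n_components),
                   function(i) a[i] * exp(-k[i] * t), numeric(length(t))))
  }
  fit <- minpack.lm::nls.lm(par = start, fn = function(p) model(p) - y,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  conv <- fit$info %in% 1:4
  if (!conv && fit$deviance > 1e-2 * sum((y - mean(y))^2))
    stop("exponential fit did not converge")
  a <- exp(fit$par[seq_len(n_components)])
  k <- exp(fit$par[n_components + seq_len(n_components)])
  ord <- order(a, decreasing = TRUE)
  a <- a[ord]; k <- k[ord]
  se <- tryCatch({
    covm <- solve(fit$hessian) * fit$deviance / max(length(y) - npar, 1)
    # delta method back to the natural scale: d(exp(p)) = exp(p) dp
    (sqrt(pmax(diag(covm), 0)) * exp(fit$par))[n_components + seq_len(n_components)][ord]
  }, error = function(e) rep(NA_real_, n_components))
  minor <- if (n_components == 2) a[2] / sum(a) else 0
  structure(list(amplitudes = a, rates = k, tau = 1 / k, se_rates = se,
                 rms = sqrt(fit$deviance / length(y)),
                 n_components = n_components,
                 heterogeneous = n_components == 2 && minor >= minor_threshold,
                 minor_fraction = minor, minor_threshold = minor_threshold,
                 converged = conv, time_unit = trace$time_unit %||% "s"),
            class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("<exponential_fit> %d component(s), rms %.3g%s\n",
              x$n_components, x$rms,
              if (isTRUE(x$heterogeneous)) ", heterogeneous" else ""))
  for (i in seq_len(x$n_components))
    cat(sprintf("  a = %.4g, k = %.4g /%s (tau = %.4g %s)\n",
                x$amplitudes[i], x$rates[i], x$time_unit, x$tau[i], x$time_unit))
  invisible(x)
}

#' CO off-rate from a ligand-displacement trace
#'
#' For a stopped-flow displacement experiment with the replacing ligand in
#' excess, the observed decay rate is the dissociation rate of the original
#' ligand. The trace is fitted with up to two exponentials; the rate of the
#' dominant-amplitude component is returned as k_OFF, and heterogeneity
#' (minor component >= 5 percent of the amplitude) is reported through the
#' attached fit.
#'
#' @param trace a [relaxation_trace()] in seconds.
#' @param n_components maximum number of components to try (default 2; the
#'   fit falls back to 1 component when the 2-component fit fails).
#' @param minor_threshold see [fit_exponential()].
#' @return The main-component rate (s^-1) with the full
#'   \code{exponential_fit} in attribute \code{"fit"}.
#' @export
koff_from_displacement <- function(trace, n_components = 2,
                                   minor_threshold = 0.05) {
  fit <- tryCatch(fit_exponential(trace, n_components, minor_threshold),
                  error = function(e) NULL)
  if (is.null(fit) && n_components > 1)
    fit <- fit_exponential(trace, 1, minor_threshold)
  if (is.null(fit)) stop("displacement fit failed")
  structure(fit$rates[1], fit = fit)
}
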