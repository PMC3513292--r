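#' State labels of the cavity-migration scheme
#'
#' The explicit states are: \code{B0} (CO-bound protein, absorbing on the
#' observation window), \code{DS} (geminate pair, photodissociated ligand in
#' the primary docking site), \code{A}, \code{B}, \code{T1}, \code{T2}
#' (ligand in internal cavities; T1 is a dead-end trap, T2 has its own
#' solvent connection), \code{P5} (five-coordinate deoxy protein, ligand in
#' solvent) and \code{P6} (bis-His six-coordinate deoxy protein, ligand in
#' solvent). The solvent CO reservoir is implicit and held constant; it
#' enters only through the pseudo-first-order products k_m2[CO] and k_m3[CO].
#'
#' @return Character vector of the eight state labels, in canonical order.
#' @export
scheme_states <- function() c("B0", "DS", "A", "B", "T1", "T2", "P5", "P6")

#' Build the pseudo-first-order generator matrix of the scheme
#'
#' Constructs the generator \code{Q} of the linear kinetic system
#' \code{dp/dt = Q p} over the states of [scheme_states()], with the
#' convention \code{Q[i, j]} = rate of the transition j -> i (columns sum to
#' zero, so total probability is conserved by construction). Transitions:
#' DS -> B0 (k_m1), DS <-> P5 (k_2 / k_m2[CO]), DS <-> A (k_c / k_mc),
#' A <-> B (k_d / k_md), B <-> T1 (k_e / k_me), B <-> T2 (k_f / k_mf),
#' T2 <-> P5 (k_3 / k_m3[CO]), P5 <-> P6 (k_b / k_mb). His coordination
#' (P5 <-> P6) is only possible while the ligand is in solvent. B0 is
#' absorbing unless a thermal dissociation rate \code{k_off} is supplied.
#'
#' @param rates a [rate_constants()] object.
#' @param cond a [condition()] object (resolves the CO molarity).
#' @param k_off optional thermal CO dissociation rate from B0 (s^-1),
#'   default 0 (B0 absorbing, appropriate for observation windows of ~1 s
#'   when k_off is of order 0.1 s^-1). When positive it re-forms the
#'   geminate pair (B0 -> DS).
#' @return An 8 x 8 matrix with dimnames from [scheme_states()].
#' @export
#' @examples
#' Q <- build_generator(ngb_rates("cace")$rates, condition(co_atm = 1))
#' Q["B0", "DS"]   # k_m1
#' colSums(Q)      # all zero
build_generator <- function(rates, cond, k_off = 0) {
  if (!inherits(rates, "rate_constants")) rates <- rate_constants(rates)
  if (!inherits(cond, "ngb_condition")) stop("cond must be a condition object")
  if (!is.finite(k_off) || k_off < 0) stop("k_off must be a finite value >= 0")
  co <- cond$co_conc
  s <- scheme_states()
  Q <- matrix(0, 8, 8, dimnames = list(s, s))
  add <- function(from, to, k) Q[to, from] <<- Q[to, from] + k
  k <- as.list(unclass(rates))
  add("DS", "B0", k$k_m1)
  add("DS", "P5", k$k_2)
  add("P5", "DS", k$k_m2 * co)
  add("DS", "A",  k$k_c)
  add("A",  "DS", k$k_mc)
  add("A",  "B",  k$k_d)
  add("B",  "A",  k$k_md)
  add("B",  "T1", k$k_e)
  add("T1", "B",  k$k_me)
  add("B",  "T2", k$k_f)
  add("T2", "B",  k$k_mf)
  add("T2", "P5", k$k_3)
  add("P5", "T2", k$k_m3 * co)
  add("P5", "P6", k$k_b)
  add("P6", "P5", k$k_mb)
  if (k_off > 0) add("B0", "DS", k_off)
  diag(Q) <- diag(Q) - colSums(Q)
  Q
}

#' Observable weights for the monitored transient signal
#'
#' The default observable is the unbound fraction N(t) = 1 - B0(t): weight 0
#' on the bound state and 1 elsewhere. A different weighting (e.g. letting
#' the six-coordinate species P6 contribute with a different extinction at
#' the monitoring wavelength) can be supplied as a named vector.
#'
#' @param weights named numeric vector over (a subset of) [scheme_states()];
#'   unnamed states keep their defaults.
#' @return Named numeric vector of length 8.
#' @export
observable_weights <- function(weights = NULL) {
  w <- stats::setNames(c(0, rep(1, 7)), scheme_states())
  if (!is.null(weights)) {
    bad <- setdiff(names(weights), scheme_states())
    if (length(bad)) stop("unknown states in weights: ", paste(bad, collapse = ", "))
    if (any(!is.finite(weights))) stop("weights must be finite")
    w[names(weights)] <- weights
  }
  w
}

#' Simulate the cavity-migration scheme
#'
#' Integrates \code{dp/dt = Q p} from the post-photolysis initial condition
#' \code{DS = phi, B0 = 1 - phi} and returns per-state populations together
#' with the monitored signal. The default integrator is a stiff ODE solver
#' (\code{deSolve::lsoda} with the analytic Jacobian); \code{method =
#' "eigen"} uses the closed-form solution by eigendecomposition of the
#' generator, which is faster and is what the trace-fitting machinery uses
#' internally. If the ODE integrator fails, the closed form is used instead
#' and the result is flagged.
#'
#' @param rates a [rate_constants()] object.
#' @param cond a [condition()] object.
#' @param times strictly increasing positive output times (s). Rates span
#'   ~10 decades, so log-spaced grids (see [log_times()]) are the natural
#'   choice.
#' @param weights observable weights, see [observable_weights()].
#' @param method "ode" (stiff solver), "eigen" (closed form) or "expm"
#'   (scaling-and-squaring matrix exponential per time point).
#' @param rtol,atol relative/absolute integrator tolerances. The defaults
#'   hold the populations to well below 1e-8 absolute error over rate sets
#'   spanning 1e-2 to 1e10 s^-1.
#' @param k_off optional thermal dissociation rate, see [build_generator()].
#' @return A list of class \code{scheme_sim} with elements \code{times},
#'   \code{states} (length(times) x 8 population matrix), \code{signal},
#'   \code{trace} (a [kinetic_trace()]), \code{generator}, \code{condition},
#'   \code{method} and \code{fallback} (TRUE if the ODE route failed and the
#'   matrix exponential was used).
#' @export
#' @examples
#' sim <- simulate_scheme(ngb_rates("cace")$rates, condition(co_atm = 1),
#'                        log_times(1e-9, 1, 20))
#' head(sim$states)
simulate_scheme <- function(rates, cond, times, weights = NULL,
                            method = c("ode", "eigen", "expm"),
                            rtol = 1e-10, atol = 1e-12, k_off = 0) {
  method <- match.arg(method)
  if (!is.numeric(times) || length(times) == 0 || any(!is.finite(times)))
    stop("times must be finite and positive")
  if (any(times <= 0)) stop("times must be > 0")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  Q <- build_generator(rates, cond, k_off = k_off)
  p0 <- stats::setNames(numeric(8), scheme_states())
  p0["DS"] <- cond$phi
  p0["B0"] <- 1 - cond$phi
  fallback <- FALSE
  P <- switch(method,
    eigen = propagate_eigen(Q, p0, times),
    expm  = propagate_expm(Q, p0, times),
    ode = {
      out <- tryCatch(propagate_ode(Q, p0, times, rtol, atol),
                      error = function(e) NULL, warning = function(w) NULL)
      if (is.null(out) || any(!is.finite(out))) {
        fallback <- TRUE
        propagate_expm(Q, p0, times)
      } else out
    })
  P[P < 0 & P > -1e-12] <- 0   # clip integrator round-off only
  colnames(P) <- scheme_states()
  w <- observable_weights(weights)
  signal <- as.numeric(P %*% w)
  trace <- kinetic_trace(times, signal, condition = cond)
  structure(list(times = times, states = P, signal = signal, trace = trace,
                 generator = Q, condition = cond, method = method,
                 fallback = fallback),
            class = "scheme_sim")
}

#' @export
print.scheme_sim <- function(x, ...) {
  cat(sprintf("<scheme_sim> %d time points over [%.3g, %.3g] s, method = %s%s\n",
              length(x$times), min(x$times), max(x$times), x$method,
              if (x$fallback) " (expm fallback)" else ""))
  invisible(x)
}

propagate_ode <- function(Q, p0, times, rtol, atol) {
  deriv <- function(t, y, parms) list(parms %*% y)
  jac <- function(t, y, parms) parms
  out <- deSolve::ode(y = p0, times = c(0, times), func = deriv, parms = Q,
                      jacfunc = jac, jactype = "fullusr", method = "lsoda",
                      rtol = rtol, atol = atol, maxsteps = 100000)
  unname(out[-1, -1, drop = FALSE])
}

propagate_eigen <- function(Q, p0, times) {
  eg <- eigen(Q)
  V <- eg$vectors
  c0 <- tryCatch(solve(V, p0 + 0i), error = function(e) NULL)
  # near-defective eigenbasis: fall back to scaling-and-squaring
  if (is.null(c0) || max(Mod(c0)) > 1e12) return(propagate_expm(Q, p0, times))
  E <- exp(outer(times, eg$values))          # ntimes x 8
  Re(sweep(E, 2, c0, "*") %*% t(V))
}

# dense matrix exponential, Pade scaling-and-squaring (Higham 2005, degree 13)
expm_dense <- function(A) {
  b <- c(64764752532480000, 32382376266240000, 7771770303897600,
         1187353796428800, 129060195264000, 10559470521600, 670442572800,
         33522128640, 1323241920, 40840800, 960960, 16380, 182, 1)
  n <- nrow(A)
  nrmA <- max(colSums(abs(A)))
  s <- max(0, ceiling(log2(max(nrmA, .Machine$double.xmin) / 5.37)))
  A <- A / 2^s
  I <- diag(n)
  A2 <- A %*% A; A4 <- A2 %*% A2; A6 <- A2 %*% A4
  U <- A %*% (A6 %*% (b[14] * A6 + b[12] * A4 + b[10] * A2) +
              b[8] * A6 + b[6] * A4 + b[4] * A2 + b[2] * I)
  V <- A6 %*% (b[13] * A6 + b[11] * A4 + b[9] * A2) +
       b[7] * A6 + b[5] * A4 + b[3] * A2 + b[1] * I
  X <- solve(V - U, V + U)
  if (s > 0) for (i in seq_len(s)) X <- X %*% X
  X
}

propagate_expm <- function(Q, p0, times) {
  P <- matrix(NA_real_, length(times), length(p0))
  # step incrementally: expm(Q dt_i) applied to the running state
  p <- p0
  tprev <- 0
  for (i in seq_along(times)) {
    p <- expm_dense(Q * (times[i] - tprev)) %*% p
    tprev <- times[i]
    P[i, ] <- p
  }
  P
}

#' Log-spaced time grid
#'
#' @param from,to window limits in seconds (both > 0).
#' @param points_per_decade grid density.
#' @return Numeric vector \code{10^seq(log10(from), log10(to),
#'   by = 1/points_per_decade)}.
#' @export
log_times <- function(from = 1e-9, to = 1, points_per_decade = 10) {
  if (from <= 0 || to <= from) stop("need 0 < from < to")
  10^seq(log10(from), log10(to), by = 1 / points_per_decade)
}

#' Unbound fraction N(t)
#'
#' The fraction of hemes not carrying their ligand, N(t) = 1 - B0(t): the
#' default normalized observable of a rebinding experiment.
#'
#' @param sim a \code{scheme_sim} from [simulate_scheme()], or a population
#'   matrix with a \code{B0} column.
#' @return Numeric vector along the simulation time grid.
#' @export
unbound_fraction <- function(sim) {
  P <- if (inherits(sim, "scheme_sim")) sim$states else sim
  if (is.null(colnames(P)) || !"B0" %in% colnames(P))
    stop("need a population matrix with a B0 column")
  as.numeric(1 - P[, "B0"])
}

#' Fraction of photodissociated ligands inside the protein matrix
#'
#' Sum of the populations of the internal states DS + A + B + T1 + T2: the
#' time course of ligands migrating through the cavity system.
#'
#' @inheritParams unbound_fraction
#' @return Numeric vector along the simulation time grid.
#' @export
cavity_occupancy <- function(sim) {
  P <- if (inherits(sim, "scheme_sim")) sim$states else sim
  need <- c("DS", "A", "B", "T1", "T2")
  if (is.null(colnames(P)) || !all(need %in% colnames(P)))
    stop("need a population matrix with cavity state columns")
  as.numeric(rowSums(P[, need, drop = FALSE]))
}

#' Kinetic trace container
#'
#' @param times strictly increasing positive times (s).
#' @param signal normalized transient signal, same length as \code{times}.
#' @param condition optional [condition()] metadata.
#' @param protein,wavelength_nm optional metadata.
#' @return An object of class \code{kinetic_trace}.
#' @export
kinetic_trace <- function(times, signal, condition = NULL, protein = NA_character_,
                          wavelength_nm = NA_real_) {
  if (length(times) != length(signal)) stop("times and signal lengths differ")
  if (length(times) == 0) stop("empty trace")
  if (any(!is.finite(times)) || any(!is.finite(signal)))
    stop("trace contains non-finite values")
  if (any(times <= 0)) stop("times must be > 0")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  structure(list(times = as.numeric(times), signal = as.numeric(signal),
                 condition = condition, protein = protein,
                 wavelength_nm = wavelength_nm),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace> %d points, t in [%.3g, %.3g] s%s\n",
              length(x$times), min(x$times), max(x$times),
              if (!is.na(x$protein)) paste0(", ", x$protein) else ""))
  invisible(x)
}
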