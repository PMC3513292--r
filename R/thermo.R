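# Physical constants: gas constant in kcal/(mol K), and kB/h in s^-1 K^-1
# (CODATA kB = 1.380649e-23 J/K, h = 6.62607015e-34 J s).
.R_kcal <- 1.98720e-3
.kB_over_h <- 1.380649e-23 / 6.62607015e-34

#' Activation free energy from a rate constant (transition-state theory)
#'
#' Single-temperature TST with transmission coefficient 1:
#' \deqn{\Delta G^\ddagger = R T \ln\!\big(k_B T / (h\,k)\big).}
#' Bimolecular rate constants (M^-1 s^-1) must first be brought to
#' pseudo-first order at a 1 M standard state; [rates_delta_g()] does this
#' for whole rate tables and flags the conversion.
#'
#' @param k rate constant, s^-1 (vectorised; must be > 0).
#' @param temperature_K temperature in kelvin.
#' @return Activation free energy in kcal/mol.
#' @export
#' @examples
#' tst_delta_g(6.0, 293.15)     # ~16.1 kcal/mol
#' tst_delta_g(2.0e7, 293.15)   # ~7.4 kcal/mol
tst_delta_g <- function(k, temperature_K = 293.15) {
  if (any(!is.finite(k)) || any(k <= 0)) stop("rate constants must be > 0")
  if (temperature_K <= 0) stop("temperature_K must be > 0")
  .R_kcal * temperature_K * log(.kB_over_h * temperature_K / k)
}

#' Rate constant from an activation free energy (inverse TST)
#'
#' @param delta_g activation free energy, kcal/mol.
#' @param temperature_K temperature in kelvin.
#' @return Rate constant in s^-1; exact inverse of [tst_delta_g()].
#' @export
tst_rate <- function(delta_g, temperature_K = 293.15) {
  if (temperature_K <= 0) stop("temperature_K must be > 0")
  .kB_over_h * temperature_K * exp(-delta_g / (.R_kcal * temperature_K))
}

#' TST activation free energies for a whole rate table
#'
#' @param rates a [rate_constants()] object or list from [read_rates()].
#' @param temperature_K temperature in kelvin.
#' @return Data frame with columns \code{rate}, \code{k}, \code{unit},
#'   \code{pseudo_first_order} (TRUE where a bimolecular rate was taken at
#'   the 1 M standard state) and \code{delta_g_kcal}.
#' @export
rates_delta_g <- function(rates, temperature_K = 293.15) {
  if (!inherits(rates, "rate_constants")) rates <- rates$rates
  k <- as.numeric(rates)
  data.frame(rate = rate_names(), k = k, unit = unlist(rate_units()),
             pseudo_first_order = rate_names() %in% bimolecular_rates(),
             delta_g_kcal = tst_delta_g(k, temperature_K),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Eyring regression of rate constants against temperature
#'
#' Ordinary least squares of \eqn{\ln(k/T)} on \eqn{1/T}:
#' \deqn{\ln(k/T) = \ln(k_B/h) + \Delta S^\ddagger/R - \Delta H^\ddagger/(R T),}
#' so the slope gives the activation enthalpy and the intercept the
#' activation entropy. When the data lie exactly on an Eyring line the
#' regenerated \code{k(T)} reproduce the inputs.
#'
#' @param temperature_K temperatures (K), at least two distinct values.
#' @param k rate constants (s^-1), same length.
#' @param ref_temperature_K reference temperature for the reported
#'   \eqn{\Delta G^\ddagger}.
#' @return An object of class \code{eyring_fit}: list with
#'   \code{delta_h_kcal}, \code{delta_s_kcal_per_K}, \code{delta_g_kcal}
#'   (at the reference temperature; identically
#'   \code{delta_h - T delta_s}), standard errors \code{se_h}, \code{se_s},
#'   the reference temperature and the underlying \code{lm} fit.
#' @export
#' @examples
#' Tk <- c(278.15, 283.15, 288.15, 293.15)
#' k <- eyring_rate(Tk, delta_h_kcal = 10, delta_s_kcal_per_K = 0.01)
#' eyring_fit(Tk, k)$delta_h_kcal
eyring_fit <- function(temperature_K, k, ref_temperature_K = 293.15) {
  if (length(temperature_K) != length(k)) stop("lengths differ")
  if (any(temperature_K <= 0) || any(k <= 0)) stop("need positive T and k")
  if (length(unique(temperature_K)) < 2)
    stop("need at least two distinct temperatures")
  x <- 1 / temperature_K
  y <- log(k / temperature_K)
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  # an exact Eyring line has zero residuals; silence the perfect-fit note
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  dh <- -cf[["x"]] * .R_kcal
  ds <- (cf[["(Intercept)"]] - log(.kB_over_h)) * .R_kcal
  structure(list(delta_h_kcal = dh,
                 delta_s_kcal_per_K = ds,
                 delta_g_kcal = dh - ref_temperature_K * ds,
                 se_h = se[["x"]] * .R_kcal,
                 se_s = se[["(Intercept)"]] * .R_kcal,
                 ref_temperature_K = ref_temperature_K,
                 lm = fit),
            class = "eyring_fit")
}

#' @export
print.eyring_fit <- function(x, ...) {
  cat(sprintf(paste0("<eyring_fit> dH = %.4g kcal/mol, dS = %.4g kcal/(mol K), ",
                     "dG(%.2f K) = %.4g kcal/mol\n"),
              x$delta_h_kcal, x$delta_s_kcal_per_K, x$ref_temperature_K,
              x$delta_g_kcal))
  invisible(x)
}

#' Rate constant from Eyring activation parameters
#'
#' \deqn{k(T) = (k_B T / h)\exp(\Delta S^\ddagger / R)
#'   \exp(-\Delta H^\ddagger / (R T)).}
#'
#' @param temperature_K temperature(s) in kelvin.
#' @param delta_h_kcal activation enthalpy, kcal/mol.
#' @param delta_s_kcal_per_K activation entropy, kcal/(mol K).
#' @return Rate constant(s), s^-1.
#' @export
eyring_rate <- function(temperature_K, delta_h_kcal, delta_s_kcal_per_K = 0) {
  if (any(temperature_K <= 0)) stop("temperature_K must be > 0")
  .kB_over_h * temperature_K *
    exp(delta_s_kcal_per_K / .R_kcal) *
    exp(-delta_h_kcal / (.R_kcal * temperature_K))
}

#' Distal-His coordination equilibrium constant
#'
#' \eqn{K_H = k_b / k_{-b}}, the equilibrium constant between the
#' five-coordinate and bis-His six-coordinate deoxy ferrous protein.
#'
#' @param rates a [rate_constants()] object (or anything with named
#'   \code{k_b}, \code{k_mb} entries).
#' @return Dimensionless equilibrium constant.
#' @export
#' @examples
#' his_equilibrium(ngb_rates("cace")$rates)   # ~483
his_equilibrium <- function(rates) {
  kb <- rates[["k_b"]]; kmb <- rates[["k_mb"]]
  if (!is.finite(kmb) || kmb <= 0) stop("k_mb must be > 0")
  kb / kmb
}

#' Effective bimolecular on-rate to the five-coordinate protein
#'
#' A ligand entering from solvent through the His gate (rate k_m2[CO])
#' reaches the distal pocket, from which it either binds the heme (k_m1) or
#' escapes again (k_2). The effective on-rate is the entry rate times the
#' inner binding yield:
#' \deqn{k_{ON} = k_{-2}\, k_{-1} / (k_{-1} + k_2).}
#'
#' @param rates a [rate_constants()] object.
#' @return Effective on-rate, M^-1 s^-1.
#' @export
#' @examples
#' effective_kon(ngb_rates("cace")$rates)    # ~2.2e8
effective_kon <- function(rates) {
  km1 <- rates[["k_m1"]]; k2 <- rates[["k_2"]]; km2 <- rates[["k_m2"]]
  if (!is.finite(km1 + k2) || km1 + k2 <= 0) stop("k_m1 + k_2 must be > 0")
  km2 * km1 / (km1 + k2)
}

#' Observed on-rate to the six-coordinate protein
#'
#' In a resting hexacoordinate globin the exogenous ligand competes with the
#' endogenous distal His, so the observed pseudo-first-order binding rate at
#' ligand concentration [CO] is
#' \deqn{k_{ON,obs} = k_{-b}\, k_{ON} [CO] / (k_b + k_{ON} [CO]),}
#' bounded above by the His dissociation rate \eqn{k_{-b}} and monotonically
#' increasing in [CO].
#'
#' @param rates a [rate_constants()] object.
#' @param co_conc ligand concentration, mol/L (>= 0).
#' @return Observed binding rate, s^-1.
#' @export
#' @examples
#' observed_kon(ngb_rates("cace")$rates, 1e-3)   # ~5.9 -> 6 s^-1
observed_kon <- function(rates, co_conc) {
  if (!is.numeric(co_conc) || any(co_conc < 0)) stop("co_conc must be >= 0")
  kon <- effective_kon(rates)
  kb <- rates[["k_b"]]; kmb <- rates[["k_mb"]]
  kmb * kon * co_conc / (kb + kon * co_conc)
}

#' Equilibrium fraction of the six-coordinate species
#'
#' @param K_H His-coordination equilibrium constant (>= 0).
#' @return \eqn{K_H / (1 + K_H)}.
#' @export
hexacoordinate_fraction <- function(K_H) {
  if (any(!is.finite(K_H)) || any(K_H < 0)) stop("K_H must be >= 0")
  K_H / (1 + K_H)
}

#' Derived binding constants for a rate table
#'
#' Convenience wrapper computing the His equilibrium, effective and observed
#' on-rates and hexacoordinate fraction for one protein.
#'
#' @param rates a [rate_constants()] object or list from [read_rates()].
#' @param co_conc ligand concentration for the observed on-rate, mol/L.
#' @param signif_digits significant digits for the \code{rounded} element
#'   (reported values are conventionally quoted to 2 s.f.); full precision
#'   is kept in the main fields.
#' @return List of class \code{derived_constants} with \code{K_H},
#'   \code{k_on_M_s}, \code{k_on_obs_s} (at \code{co_conc}),
#'   \code{hexacoordinate_fraction}, \code{co_conc} and \code{rounded}.
#' @export
derived_constants <- function(rates, co_conc = 1e-3, signif_digits = 2) {
  protein <- NA_character_
  if (!inherits(rates, "rate_constants")) {
    protein <- rates$protein %||% NA_character_
    rates <- rates$rates
  }
  KH <- his_equilibrium(rates)
  kon <- effective_kon(rates)
  konobs <- observed_kon(rates, co_conc)
  out <- list(protein = protein, K_H = KH, k_on_M_s = kon,
              k_on_obs_s = konobs,
              hexacoordinate_fraction = hexacoordinate_fraction(KH),
              co_conc = co_conc)
  out$rounded <- list(K_H = round(KH),
                      k_on_M_s = signif(kon, signif_digits),
                      k_on_obs_s = round(konobs))
  structure(out, class = "derived_constants")
}

#' @export
print.derived_constants <- function(x, ...) {
  cat(sprintf("<derived_constants>%s\n",
              if (!is.na(x$protein)) paste0(" ", x$protein) else ""))
  cat(sprintf("  K_H                 = %.4g (fraction 6c: %.3f)\n",
              x$K_H, x$hexacoordinate_fraction))
  cat(sprintf("  k_ON                = %.3g M^-1 s^-1\n", x$k_on_M_s))
  cat(sprintf("  k_ON,obs at %.3g M  = %.3g s^-1\n", x$co_conc, x$k_on_obs_s))
  invisible(x)
}
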