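#' Microscopic rate constants of the branched cavity-migration scheme
#'
#' The minimal kinetic scheme for CO rebinding in hexacoordinate globins has
#' fifteen microscopic rate constants. Thirteen are first order (s^-1); two,
#' the solvent entry rates \code{k_m2} (solvent -> distal pocket) and
#' \code{k_m3} (solvent -> trap T2), are bimolecular (M^-1 s^-1) and only ever
#' enter the kinetics multiplied by the CO concentration.
#'
#' Rate names follow the conventional labels:
#' \describe{
#'   \item{k_m1}{heme rebinding from the primary docking site DS (s^-1)}
#'   \item{k_2, k_m2}{DS -> solvent escape (s^-1) and solvent -> DS entry
#'     (M^-1 s^-1) through the His gate}
#'   \item{k_3, k_m3}{trap T2 -> solvent exit (s^-1) and solvent -> T2 entry
#'     (M^-1 s^-1), the second solvent connection}
#'   \item{k_b, k_mb}{distal-His binding (5c -> 6c) and dissociation
#'     (6c -> 5c) of the deoxy protein (s^-1)}
#'   \item{k_c, k_mc}{DS <-> cavity A (s^-1)}
#'   \item{k_d, k_md}{cavity A <-> cavity B (s^-1)}
#'   \item{k_e, k_me}{cavity B <-> dead-end trap T1 (s^-1)}
#'   \item{k_f, k_mf}{cavity B <-> trap T2 (s^-1)}
#' }
#'
#' @param ... named rate values, or a single named list/vector. All fifteen
#'   names above must be present and non-negative.
#' @return An object of class \code{rate_constants}: a named numeric vector
#'   with a \code{units} attribute.
#' @seealso [ngb_rates()] for the packaged neuroglobin rate sets,
#'   [build_generator()], [simulate_scheme()].
#' @export
#' @examples
#' rk <- ngb_rates("cace")
#' rk[["k_m1"]]
rate_constants <- function(...) {
  x <- list(...)
  if (length(x) == 1L && is.null(names(x)) && (is.list(x[[1]]) || !is.null(names(x[[1]]))))
    x <- as.list(x[[1]])
  x <- unlist(x)
  miss <- setdiff(rate_names(), names(x))
  if (length(miss))
    stop("missing rate constants: ", paste(miss, collapse = ", "))
  extra <- setdiff(names(x), rate_names())
  if (length(extra))
    stop("unknown rate constants: ", paste(extra, collapse = ", "))
  x <- x[rate_names()]
  if (any(!is.finite(x))) stop("rate constants must be finite")
  if (any(x < 0)) stop("rate constants must be >= 0")
  structure(x, class = "rate_constants", units = rate_units())
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("<rate_constants>\n")
  u <- attr(x, "units")
  for (nm in names(x))
    cat(sprintf("  %-5s %12.4g  %s\n", nm, unname(x[nm]), u[[nm]]))
  invisible(x)
}

rate_names <- function() {
  c("k_m1", "k_2", "k_m2", "k_3", "k_m3", "k_b", "k_mb",
    "k_c", "k_mc", "k_d", "k_md", "k_e", "k_me", "k_f", "k_mf")
}

bimolecular_rates <- function() c("k_m2", "k_m3")

rate_units <- function() {
  u <- rep("s^-1", length(rate_names()))
  names(u) <- rate_names()
  u[bimolecular_rates()] <- "M^-1 s^-1"
  as.list(u)
}

#' Packaged neuroglobin rate sets
#'
#' Microscopic rate constants at 20 degrees C for the icefish
#' (\emph{C. aceratus}), \emph{D. mawsoni} and human neuroglobins, as
#' determined by global fits of flash-photolysis CO-rebinding data, together
#' with the activation free energies (and their uncertainties) obtained from
#' linear Eyring plots over 5-20 degrees C. These are the canonical test
#' points for every stage of the pipeline.
#'
#' @param protein one of \code{"cace"}, \code{"dmaw"}, \code{"human"}
#'   (prefix matching of the common labels is accepted, e.g. \code{"C. ace"}).
#' @return A list with elements \code{protein} (label),
#'   \code{temperature_K}, \code{rates} (a [rate_constants()] object),
#'   \code{delta_g_kcal} and \code{delta_g_err_kcal} (named numeric vectors,
#'   kcal/mol).
#' @export
#' @examples
#' ngb_rates("cace")$rates[["k_b"]]
ngb_rates <- function(protein = c("cace", "dmaw", "human")) {
  key <- tolower(gsub("[^a-z]", "", tolower(protein[1])))
  file <- if (grepl("^cace|^ace", key)) "cace_ngb.json"
          else if (grepl("^dmaw|^maw", key)) "dmaw_ngb.json"
          else if (grepl("^human|^hngb", key)) "human_ngb.json"
          else stop("unknown protein: ", protein[1])
  read_rates(system.file("extdata", "rates", file, package = "ngbkin",
                         mustWork = TRUE))
}

#' Read a rate table from JSON or CSV
#'
#' JSON files carry the full record (rates, units, printed activation free
#' energies where available). CSV files have columns
#' \code{rate,value,unit} and optional \code{delta_g_kcal,delta_g_err_kcal}.
#'
#' @param path file path; format inferred from the extension.
#' @return A list as described in [ngb_rates()].
#' @export
read_rates <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    out <- list(protein = doc$protein %||% NA_character_,
                temperature_K = doc$temperature_K %||% 293.15,
                rates = rate_constants(doc$rates))
    if (!is.null(doc$delta_g_kcal))
      out$delta_g_kcal <- unlist(doc$delta_g_kcal)[rate_names()]
    if (!is.null(doc$delta_g_err_kcal))
      out$delta_g_err_kcal <- unlist(doc$delta_g_err_kcal)[rate_names()]
    out
  } else {
    df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    if (!all(c("rate", "value") %in% names(df)))
      stop("rate CSV needs columns 'rate' and 'value'")
    k <- stats::setNames(df$value, df$rate)
    out <- list(protein = NA_character_, temperature_K = 293.15,
                rates = rate_constants(k))
    if ("delta_g_kcal" %in% names(df))
      out$delta_g_kcal <- stats::setNames(df$delta_g_kcal, df$rate)[rate_names()]
    if ("delta_g_err_kcal" %in% names(df))
      out$delta_g_err_kcal <- stats::setNames(df$delta_g_err_kcal, df$rate)[rate_names()]
    out
  }
}

#' Write a rate table to JSON or CSV
#'
#' @param rates a [rate_constants()] object or a list as returned by
#'   [read_rates()].
#' @param path output path; format inferred from the extension.
#' @return \code{path}, invisibly.
#' @export
write_rates <- function(rates, path) {
  if (inherits(rates, "rate_constants"))
    rates <- list(protein = NA_character_, temperature_K = 293.15, rates = rates)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- list(schema_version = 1L,
                protein = rates$protein,
                temperature_K = rates$temperature_K,
                units = rate_units(),
                rates = as.list(unclass(rates$rates)))
    if (!is.null(rates$delta_g_kcal))
      doc$delta_g_kcal <- as.list(rates$delta_g_kcal)
    if (!is.null(rates$delta_g_err_kcal))
      doc$delta_g_err_kcal <- as.list(rates$delta_g_err_kcal)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    df <- data.frame(rate = rate_names(),
                     value = as.numeric(rates$rates[rate_names()]),
                     unit = unlist(rate_units()),
                     stringsAsFactors = FALSE)
    if (!is.null(rates$delta_g_kcal)) df$delta_g_kcal <- rates$delta_g_kcal[rate_names()]
    if (!is.null(rates$delta_g_err_kcal)) df$delta_g_err_kcal <- rates$delta_g_err_kcal[rate_names()]
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Experimental condition for a rebinding measurement
#'
#' @param temperature_K temperature in kelvin (> 0).
#' @param co_conc CO concentration in mol/L. Give exactly one of
#'   \code{co_conc} or \code{co_atm}.
#' @param co_atm CO partial pressure in atm, converted to molarity with
#'   \code{henry_M_per_atm}.
#' @param henry_M_per_atm aqueous CO solubility; the default 1e-3 M/atm is the
#'   standard value near 20 degrees C, so 1 atm CO corresponds to 1.0 mM.
#' @param phi photolysis yield, the fraction of liganded hemes dissociated by
#'   the laser pulse at t = 0; in (0, 1], default 1 (normalized traces).
#' @return An object of class \code{condition}.
#' @export
#' @examples
#' condition(293.15, co_atm = 1)      # 1 mM CO
#' condition(293.15, co_conc = 1e-4)
condition <- function(temperature_K = 293.15, co_conc = NULL, co_atm = NULL,
                      henry_M_per_atm = 1e-3, phi = 1) {
  if (!is.numeric(temperature_K) || temperature_K <= 0)
    stop("temperature_K must be > 0")
  if (is.null(co_conc) == is.null(co_atm))
    stop("give exactly one of co_conc or co_atm")
  if (is.null(co_conc)) {
    if (co_atm < 0) stop("co_atm must be >= 0")
    co_conc <- co_atm * henry_M_per_atm
  } else {
    if (co_conc < 0) stop("co_conc must be >= 0")
    co_atm <- co_conc / henry_M_per_atm
  }
  if (phi <= 0 || phi > 1) stop("phi must be in (0, 1]")
  structure(list(temperature_K = temperature_K, co_conc = co_conc,
                 co_atm = co_atm, henry_M_per_atm = henry_M_per_atm,
                 phi = phi),
            class = "ngb_condition")
}

#' @export
print.ngb_condition <- function(x, ...) {
  cat(sprintf("<condition> T = %.2f K, [CO] = %.3g M (%.3g atm), phi = %g\n",
              x$temperature_K, x$co_conc, x$co_atm, x$phi))
  invisible(x)
}
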