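#' Read a trace CSV
#'
#' The trace dialect is a plain CSV with header \code{time_s,signal} (or
#' \code{time_min,signal}; minute time bases are converted to seconds) and
#' optional \code{#} comment lines carrying \code{key = value} metadata
#' (recognised keys: \code{protein}, \code{T_K}, \code{co_atm}, \code{co_M},
#' \code{henry_M_per_atm}, \code{phi}, \code{wavelength_nm}, \code{mode}).
#' Decimal points only, no locale-dependent parsing.
#'
#' @param path input file.
#' @param type \code{"auto"} (relaxation when the file declares
#'   \code{mode = relaxation} or uses a minute time base, kinetic
#'   otherwise), \code{"kinetic"} or \code{"relaxation"}.
#' @return A [kinetic_trace()] (with a [condition()] when the metadata
#'   determine one) or a [relaxation_trace()], times in seconds.
#' @export
read_trace_csv <- function(path, type = c("auto", "kinetic", "relaxation")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^\\s*#", lines)
  meta <- list()
  for (ln in lines[meta_lines]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z_0-9]+)\\s*=\\s*(.*\\S)\\s*$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  body <- lines[setdiff(seq_along(lines), meta_lines)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("no data rows in ", path)
  header <- strsplit(trimws(body[1]), ",")[[1]]
  tcol <- intersect(c("time_s", "time_min"), header)
  if (length(tcol) != 1 || !"signal" %in% header)
    stop("trace CSV needs columns time_s (or time_min) and signal")
  rows <- strsplit(body[-1], ",")
  nums <- suppressWarnings(lapply(rows, as.numeric))
  bad <- which(vapply(nums, function(x) length(x) != length(header) || any(is.na(x)), TRUE))
  if (length(bad)) {
    lineno <- setdiff(seq_along(lines), meta_lines)[bad + 1]
    stop("non-numeric or malformed data at line(s): ",
         paste(utils::head(lineno, 5), collapse = ", "))
  }
  df <- do.call(rbind, nums)
  colnames(df) <- header
  times <- df[, tcol]
  if (tcol == "time_min") times <- times * 60
  signal <- df[, "signal"]

  num <- function(key) if (!is.null(meta[[key]])) as.numeric(meta[[key]]) else NULL
  if (type == "auto")
    type <- if (identical(meta$mode, "relaxation") || tcol == "time_min")
      "relaxation" else "kinetic"
  if (type == "relaxation") {
    relaxation_trace(times, signal, time_unit = "s",
                     wavelength_nm = num("wavelength_nm") %||% NA_real_,
                     temperature_K = num("T_K") %||% NA_real_)
  } else {
    cond <- NULL
    if (!is.null(num("T_K")) && (!is.null(num("co_atm")) || !is.null(num("co_M"))))
      cond <- condition(temperature_K = num("T_K"), co_conc = num("co_M"),
                        co_atm = num("co_atm"),
                        henry_M_per_atm = num("henry_M_per_atm") %||% 1e-3,
                        phi = num("phi") %||% 1)
    kinetic_trace(times, signal, condition = cond,
                  protein = meta$protein %||% NA_character_,
                  wavelength_nm = num("wavelength_nm") %||% NA_real_)
  }
}

#' Write a trace CSV
#'
#' Inverse of [read_trace_csv()]: metadata as \code{# key = value} comment
#' lines, then \code{time_s,signal} rows.
#'
#' @param trace a [kinetic_trace()] or [relaxation_trace()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  meta <- character(0)
  add <- function(key, val) {
    if (!is.null(val) && !all(is.na(val)))
      meta <<- c(meta, sprintf("# %s = %s", key, format(val, digits = 15)))
  }
  times <- trace$times
  if (inherits(trace, "kinetic_trace")) {
    add("protein", trace$protein)
    add("wavelength_nm", trace$wavelength_nm)
    if (!is.null(trace$condition)) {
      add("T_K", trace$condition$temperature_K)
      add("co_atm", trace$condition$co_atm)
      add("henry_M_per_atm", trace$condition$henry_M_per_atm)
      add("phi", trace$condition$phi)
    }
  } else {
    meta <- c(meta, "# mode = relaxation")
    add("wavelength_nm", trace$wavelength_nm)
    add("T_K", trace$temperature_K)
    if (identical(trace$time_unit, "min")) times <- times * 60
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines("time_s,signal", con)
  writeLines(sprintf("%.12g,%.12g", times, trace$signal), con)
  invisible(path)
}

result_payload <- function(x) {
  if (inherits(x, "fit_result")) {
    list(type = "fit_result",
         rates = as.list(unclass(x$rates)),
         log10_estimates = as.list(x$log10_estimates),
         se_log10 = as.list(x$se_log10),
         ssr = x$ssr, per_trace_rms = x$per_trace_rms,
         converged = x$converged, jacobian_rank = x$jacobian_rank,
         n_free = x$n_free, seed = x$seed, n_starts = x$n_starts)
  } else if (inherits(x, "derived_constants")) {
    list(type = "derived_constants", protein = x$protein, K_H = x$K_H,
         k_on_M_s = x$k_on_M_s, k_on_obs_s = x$k_on_obs_s,
         hexacoordinate_fraction = x$hexacoordinate_fraction,
         co_conc = x$co_conc, rounded = x$rounded)
  } else if (inherits(x, "exponential_fit")) {
    list(type = "exponential_fit", amplitudes = x$amplitudes,
         rates = x$rates, tau = x$tau, se_rates = x$se_rates,
         rms = x$rms, n_components = x$n_components,
         heterogeneous = x$heterogeneous, minor_fraction = x$minor_fraction,
         time_unit = x$time_unit)
  } else if (inherits(x, "eyring_fit")) {
    list(type = "eyring_fit", delta_h_kcal = x$delta_h_kcal,
         delta_s_kcal_per_K = x$delta_s_kcal_per_K,
         delta_g_kcal = x$delta_g_kcal, se_h = x$se_h, se_s = x$se_s,
         ref_temperature_K = x$ref_temperature_K)
  } else if (is.list(x)) {
    x
  } else stop("cannot serialise object of class ", paste(class(x), collapse = "/"))
}

#' Write analysis results to a schema-versioned JSON document
#'
#' Serialises fit results, derived constants, exponential and Eyring fits
#' (single objects or named lists of them). Numeric values round-trip at
#' full precision.
#'
#' @param results a result object or named list of result objects.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(results, path) {
  known <- c("fit_result", "derived_constants", "exponential_fit", "eyring_fit")
  single <- inherits(results, known)
  payload <- if (single) result_payload(results) else lapply(results, result_payload)
  doc <- list(schema_version = 1L, results = payload, single = single)
  tryCatch(
    suppressWarnings(jsonlite::write_json(doc, path, auto_unbox = TRUE,
                                          digits = NA, pretty = TRUE)),
    error = function(e) stop("cannot write results to '", path, "': ",
                             conditionMessage(e)))
  invisible(path)
}

#' Read a results JSON document
#'
#' @param path file written by [write_results()].
#' @return The deserialised results (lists; classes are not restored).
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema_version)) stop("not a results document: ", path)
  doc$results
}

#' Read trajectory frames with an LJ sidecar table
#'
#' Frames come as a multi-model PDB (MODEL/ENDMDL records, fixed-column
#' coordinates in Angstrom) or an extended XYZ file (repeated blocks of
#' atom-count line, comment line, \code{element x y z} rows). Per-atom
#' Lennard-Jones parameters are supplied in a sidecar CSV with columns
#' \code{atom_index,epsilon_kcal,rmin_half_A}, one row per atom.
#'
#' @param path PDB (\code{.pdb}) or XYZ (\code{.xyz}) file.
#' @param sidecar path to the LJ parameter CSV.
#' @return A [trajectory_frames()] object.
#' @export
read_frames <- function(path, sidecar) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(sidecar)) stop("no such sidecar file: ", sidecar)
  coords <- if (grepl("\\.pdb$", path, ignore.case = TRUE))
    read_pdb_frames(path) else read_xyz_frames(path)
  lj <- utils::read.csv(sidecar, stringsAsFactors = FALSE)
  need <- c("atom_index", "epsilon_kcal", "rmin_half_A")
  if (!all(need %in% names(lj)))
    stop("sidecar needs columns ", paste(need, collapse = ", "))
  n <- nrow(coords[[1]])
  if (nrow(lj) != n)
    stop("sidecar has ", nrow(lj), " rows but frames have ", n, " atoms")
  lj <- lj[order(lj$atom_index), ]
  trajectory_frames(coords, lj$epsilon_kcal, lj$rmin_half_A)
}

read_pdb_frames <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
}

read_xyz_frames <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1) stop("malformed XYZ atom-count line at line ", i)
    if (i + 1 + n > length(lines)) stop("truncated XYZ frame starting at line ", i)
    rows <- strsplit(trimws(lines[(i + 2):(i + 1 + n)]), "\\s+")
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) stop("non-numeric coordinates in XYZ frame at line ", i)
    frames[[length(frames) + 1]] <- xyz
    i <- i + 2 + n
  }
  nat <- vapply(frames, nrow, 0L)
  if (length(unique(nat)) != 1) stop("atom count differs across XYZ frames")
  frames
}

#' Write trajectory frames to a multi-model PDB or an XYZ file
#'
#' @param frames a [trajectory_frames()].
#' @param path output file; format from the extension (.pdb or .xyz).
#' @param element element symbol written for every atom.
#' @return \code{path}, invisibly.
#' @export
write_frames <- function(frames, path, element = "C") {
  if (!inherits(frames, "trajectory_frames")) stop("frames must be trajectory_frames")
  con <- file(path, "w")
  on.exit(close(con))
  if (grepl("\\.pdb$", path, ignore.case = TRUE)) {
    for (m in seq_along(frames$frames)) {
      writeLines(sprintf("MODEL     %4d", m), con)
      f <- frames$frames[[m]]
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        seq_len(nrow(f)), element, "LIG", 1L, f[, 1], f[, 2], f[, 3],
        1, 0, element), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    for (f in frames$frames) {
      writeLines(as.character(nrow(f)), con)
      writeLines("toy LJ cavity frames", con)
      writeLines(sprintf("%s %12.6f %12.6f %12.6f", element,
                         f[, 1], f[, 2], f[, 3]), con)
    }
  }
  invisible(path)
}

#' Write the LJ sidecar table for a set of frames
#'
#' @param frames a [trajectory_frames()].
#' @param path output CSV.
#' @return \code{path}, invisibly.
#' @export
write_lj_sidecar <- function(frames, path) {
  utils::write.csv(data.frame(atom_index = seq_len(frames$n_atoms),
                              epsilon_kcal = frames$epsilon,
                              rmin_half_A = frames$rmin_half),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a free-energy grid in OpenDX scalar format
#'
#' The standard volumetric text format readable by molecular viewers
#' (values written with the last grid index varying fastest).
#'
#' @param grid an \code{fe_grid}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_dx <- function(grid, path) {
  if (!inherits(grid, "fe_grid")) stop("grid must be an fe_grid")
  d <- grid$dim
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# insertion free energy (kcal/mol)",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", grid$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", grid$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))  # z fastest
  pad <- (3 - length(vals) %% 3) %% 3
  m <- matrix(c(sprintf("%.6g", vals), rep("", pad)), ncol = 3, byrow = TRUE)
  writeLines(trimws(apply(m, 1, paste, collapse = " ")), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "free energy" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read a free-energy grid from an OpenDX file
#'
#' @param path a file written by [write_dx()] (or any regular-grid scalar
#'   DX file with axis-aligned deltas and identical spacing on all axes).
#' @param temperature_K,cap metadata to attach (not stored in DX).
#' @return An \code{fe_grid}.
#' @export
read_dx <- function(path, temperature_K = 300, cap = 100) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  gp <- grep("class gridpositions", lines, value = TRUE)[1]
  if (is.na(gp)) stop("not an OpenDX grid file: ", path)
  d <- as.integer(strsplit(sub(".*counts\\s+", "", gp), "\\s+")[[1]])
  org <- as.numeric(strsplit(sub("^\\s*origin\\s+", "",
                                 grep("^\\s*origin", lines, value = TRUE)[1]),
                             "\\s+")[[1]])
  deltas <- grep("^\\s*delta", lines, value = TRUE)[1:3]
  dm <- t(vapply(deltas, function(x)
    as.numeric(strsplit(sub("^\\s*delta\\s+", "", x), "\\s+")[[1]]), numeric(3)))
  sp <- unique(round(diag(dm), 9))
  if (length(sp) != 1 || any(abs(dm - diag(diag(dm))) > 1e-9))
    stop("only axis-aligned grids with uniform spacing are supported")
  istart <- grep("data follows", lines)[1]
  iend <- grep("^attribute|class field", lines)
  iend <- if (length(iend)) min(iend[iend > istart]) - 1 else length(lines)
  vals <- as.numeric(unlist(strsplit(trimws(lines[(istart + 1):iend]), "\\s+")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(d)) stop("value count does not match grid dimensions")
  arr <- aperm(array(vals, dim = rev(d)), c(3, 2, 1))
  fe_grid(arr, origin = org, spacing = sp, temperature_K = temperature_K,
          cap = cap)
}

#' Write a pathway profile as CSV
#'
#' @param profile a \code{pathway_profile} from [path_profile()].
#' @param path output CSV with columns \code{s_A,G_kcal,leg}.
#' @return \code{path}, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  if (!inherits(profile, "pathway_profile")) stop("profile must be a pathway_profile")
  utils::write.csv(profile$profile, path, row.names = FALSE)
  invisible(path)
}
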