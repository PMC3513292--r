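#' Lennard-Jones parameters of the diatomic probe
#'
#' Two-site apolar CO probe. Well depths are stored positive (the magnitude
#' of the LJ minimum; tables in the CHARMM convention print them negative).
#' Defaults are the standard CO set: eps_O 0.12, eps_C 0.11 kcal/mol,
#' R_min/2 of 1.70 and 2.10 Angstrom, bond length 1.13 Angstrom.
#'
#' @param eps_C,eps_O well depths, kcal/mol (> 0).
#' @param rmin_half_C,rmin_half_O half minimum-energy distances, Angstrom.
#' @param bond_A bond length, Angstrom (> 0).
#' @return Object of class \code{probe_params}.
#' @export
probe_params <- function(eps_C = 0.11, eps_O = 0.12,
                         rmin_half_C = 2.10, rmin_half_O = 1.70,
                         bond_A = 1.13) {
  vals <- c(eps_C, eps_O, rmin_half_C, rmin_half_O, bond_A)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("probe parameters must be positive and finite")
  structure(list(eps = c(C = eps_C, O = eps_O),
                 rmin_half = c(C = rmin_half_C, O = rmin_half_O),
                 bond_A = bond_A),
            class = "probe_params")
}

#' Trajectory frames with per-atom Lennard-Jones parameters
#'
#' @param frames list of coordinate matrices (rows = atoms, columns x/y/z in
#'   Angstrom); every frame must have the same atom count.
#' @param epsilon per-atom LJ well depths, kcal/mol (stored positive).
#' @param rmin_half per-atom R_min/2, Angstrom.
#' @return Object of class \code{trajectory_frames}.
#' @export
trajectory_frames <- function(frames, epsilon, rmin_half) {
  if (!is.list(frames) || !length(frames)) stop("need at least one frame")
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (ncol(f) != 3 || any(!is.finite(f))) stop("frames must be finite n x 3 matrices")
    unname(f)
  })
  n <- nrow(frames[[1]])
  if (any(vapply(frames, nrow, 0L) != n))
    stop("atom count differs across frames")
  epsilon <- abs(as.numeric(epsilon))
  rmin_half <- as.numeric(rmin_half)
  if (length(epsilon) != n || length(rmin_half) != n)
    stop("need one epsilon and rmin_half per atom")
  if (any(!is.finite(epsilon)) || any(!is.finite(rmin_half)) || any(rmin_half <= 0))
    stop("invalid LJ parameters")
  structure(list(frames = frames, epsilon = epsilon, rmin_half = rmin_half,
                 n_atoms = n),
            class = "trajectory_frames")
}

#' @export
print.trajectory_frames <- function(x, ...) {
  cat(sprintf("<trajectory_frames> %d frames x %d atoms\n",
              length(x$frames), x$n_atoms))
  invisible(x)
}

#' Quasi-uniform probe orientations (Fibonacci sphere)
#'
#' Deterministic quasi-uniform unit vectors from the Fibonacci (golden
#' angle) lattice on the sphere. If \code{seed} is given, a deterministic
#' rotation derived from it is applied to the whole set, so different seeds
#' give differently oriented but equally uniform lattices.
#'
#' @param n number of orientations (>= 1).
#' @param seed optional integer controlling the global rotation.
#' @return n x 3 matrix of unit vectors.
#' @export
probe_orientations <- function(n = 20, seed = NULL) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n) - 1)
  U <- cbind(r * cos(phi), r * sin(phi), z)
  if (!is.null(seed)) {
    a <- (seed %% 360) * pi / 180
    b <- ((seed * 7) %% 360) * pi / 180
    Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cos(b), sin(b), 0, -sin(b), cos(b)), 3, 3)
    U <- U %*% (Rz %*% Rx)
  }
  U
}

probe_site_params <- function(probe) {
  # site offsets from the insertion point (bond midpoint) along +/- u
  list(offset = c(C = -probe$bond_A / 2, O = probe$bond_A / 2),
       eps = probe$eps, rmin_half = probe$rmin_half)
}

#' Probe-frame interaction energy for one pose
#'
#' 12-6 Lennard-Jones energy of the two-site probe against all atoms of one
#' frame, with Lorentz-Berthelot combination (epsilon_ij = sqrt(eps_i
#' eps_j), R_min_ij = R_min_i/2 + R_min_j/2) and a radial cutoff. The probe
#' is placed with its bond midpoint at \code{position} and its axis along
#' \code{orientation}. Overlapping poses give large positive energies,
#' optionally capped.
#'
#' @param frames a [trajectory_frames()] object.
#' @param position length-3 insertion point (Angstrom).
#' @param orientation length-3 direction (normalised internally).
#' @param probe a [probe_params()].
#' @param frame frame index (default 1).
#' @param cutoff LJ cutoff in Angstrom (default 10, no switching).
#' @param cap energy cap in kcal/mol (default Inf: uncapped).
#' @return Interaction energy in kcal/mol.
#' @export
interaction_energy <- function(frames, position, orientation,
                               probe = probe_params(), frame = 1,
                               cutoff = 10, cap = Inf) {
  if (!inherits(frames, "trajectory_frames")) stop("frames must be trajectory_frames")
  if (length(position) != 3 || any(!is.finite(position))) stop("invalid position")
  nu <- sqrt(sum(orientation^2))
  if (!is.finite(nu) || nu == 0) stop("invalid orientation")
  u <- orientation / nu
  xyz <- frames$frames[[frame]]
  sp <- probe_site_params(probe)
  E <- 0
  for (s in c("C", "O")) {
    p <- position + sp$offset[[s]] * u
    d2 <- pmax(colSums((t(xyz) - p)^2), 1e-12)
    sel <- d2 <= cutoff^2
    if (any(sel)) {
      rmin <- sp$rmin_half[[s]] + frames$rmin_half[sel]
      epsij <- sqrt(sp$eps[[s]] * frames$epsilon[sel])
      t6 <- (rmin^2 / d2[sel])^3
      E <- E + sum(epsij * (t6^2 - 2 * t6))
    }
  }
  min(E, cap)
}

#' Regular grid specification
#'
#' @param origin length-3 coordinates of the first grid point (Angstrom).
#' @param spacing grid spacing in Angstrom (default 0.5).
#' @param dim integer vector of grid counts (nx, ny, nz).
#' @return Object of class \code{grid_spec}.
#' @export
grid_spec <- function(origin, dim, spacing = 0.5) {
  if (length(origin) != 3 || any(!is.finite(origin))) stop("invalid origin")
  if (length(dim) != 3 || any(dim < 1)) stop("invalid dim")
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be > 0")
  structure(list(origin = as.numeric(origin), dim = as.integer(dim),
                 spacing = spacing),
            class = "grid_spec")
}

grid_points <- function(gs) {
  ax <- lapply(1:3, function(i) gs$origin[i] + gs$spacing * (seq_len(gs$dim[i]) - 1))
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                        KEEP.OUT.ATTRS = FALSE))
}

#' Insertion free-energy grid by implicit ligand sampling
#'
#' Boltzmann-averages the probe-protein interaction energy over trajectory
#' frames and probe orientations at every node of a regular grid:
#' \deqn{G(r) = -k_B T \ln\Big[\frac{1}{N_f N_r}\sum_{f}\sum_{\Omega}
#'   e^{-E(r,\Omega)/k_B T}\Big],}
#' the free energy of inserting the ligand at r relative to the
#' non-interacting (bulk ideal gas) reference, so empty space is exactly 0.
#' Interaction energies are capped before exponentiation, which bounds G
#' from above by the cap in overlap regions.
#'
#' @param frames a [trajectory_frames()].
#' @param gs a [grid_spec()].
#' @param probe a [probe_params()].
#' @param temperature_K temperature, default 300 K.
#' @param n_orientations probe rotamers per grid point (default 20,
#'   Fibonacci set from [probe_orientations()]).
#' @param orientation_seed optional seed passed to [probe_orientations()].
#' @param cutoff,cap LJ cutoff and energy cap (Angstrom, kcal/mol).
#' @return Object of class \code{fe_grid}: list with \code{origin},
#'   \code{spacing}, \code{dim}, \code{values} (3-D array, kcal/mol),
#'   \code{temperature_K}, \code{n_frames}, \code{n_orientations},
#'   \code{cap}.
#' @export
compute_grid <- function(frames, gs, probe = probe_params(),
                         temperature_K = 300, n_orientations = 20,
                         orientation_seed = NULL, cutoff = 10, cap = 100) {
  if (!inherits(frames, "trajectory_frames")) stop("frames must be trajectory_frames")
  if (!inherits(gs, "grid_spec")) stop("gs must be a grid_spec")
  if (temperature_K <= 0) stop("temperature_K must be > 0")
  P <- grid_points(gs)
  np <- nrow(P)
  U <- probe_orientations(n_orientations, seed = orientation_seed)
  kT <- .R_kcal * temperature_K
  sp <- probe_site_params(probe)
  cutoff2 <- cutoff^2
  W <- numeric(np)
  nf <- length(frames$frames)
  for (f in seq_len(nf)) {
    xyz <- frames$frames[[f]]
    c2 <- rowSums(xyz^2)
    for (r in seq_len(nrow(U))) {
      u <- U[r, ]
      E <- numeric(np)
      for (s in c("C", "O")) {
        S <- P + matrix(sp$offset[[s]] * u, np, 3, byrow = TRUE)
        d2 <- outer(rowSums(S^2), c2, "+") - 2 * (S %*% t(xyz))
        d2[d2 < 1e-12] <- 1e-12
        rmin2 <- (sp$rmin_half[[s]] + frames$rmin_half)^2
        epsij <- sqrt(sp$eps[[s]] * frames$epsilon)
        t6 <- sweep(1 / d2, 2, rmin2, "*")^3
        lj <- sweep(t6^2 - 2 * t6, 2, epsij, "*")
        lj[d2 > cutoff2] <- 0
        E <- E + rowSums(lj)
      }
      W <- W + exp(-pmin(E, cap) / kT)
    }
  }
  G <- -kT * log(W / (nf * nrow(U)))
  structure(list(origin = gs$origin, spacing = gs$spacing, dim = gs$dim,
                 values = array(G, dim = gs$dim),
                 temperature_K = temperature_K, n_frames = nf,
                 n_orientations = nrow(U), cap = cap),
            class = "fe_grid")
}

#' @export
print.fe_grid <- function(x, ...) {
  cat(sprintf("<fe_grid> %d x %d x %d, spacing %.2f A, G in [%.3g, %.3g] kcal/mol\n",
              x$dim[1], x$dim[2], x$dim[3], x$spacing,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Construct an fe_grid from an array of values
#'
#' Useful for synthetic test grids and for data read from OpenDX files.
#'
#' @param values 3-D numeric array (kcal/mol).
#' @param origin,spacing grid geometry.
#' @param temperature_K,cap metadata.
#' @return An \code{fe_grid}.
#' @export
fe_grid <- function(values, origin = c(0, 0, 0), spacing = 0.5,
                    temperature_K = 300, cap = 100) {
  if (length(dim(values)) != 3) stop("values must be a 3-D array")
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dim = dim(values), values = values,
                 temperature_K = temperature_K, n_frames = NA_integer_,
                 n_orientations = NA_integer_, cap = cap),
            class = "fe_grid")
}

grid_index <- function(grid, xyz) {
  ijk <- round((xyz - matrix(grid$origin, nrow(xyz), 3, byrow = TRUE)) /
                 grid$spacing) + 1
  if (any(ijk < 1) || any(sweep(ijk, 2, grid$dim, ">")))
    stop("waypoint outside the grid")
  ijk
}

#' Minimum-barrier pathway profile between waypoints
#'
#' Finds, for each consecutive pair of waypoints, the path through the
#' 26-connected grid lattice that minimises the highest free energy
#' encountered (the minimax / widest-path objective, the natural cost for
#' barrier extraction: with edge cost max(G_i, G_j) and max-composition the
#' path cost is the saddle height, and it is well defined even where G is
#' negative). Returns the free-energy profile along the concatenated path
#' and the barrier of each leg.
#'
#' @param grid an \code{fe_grid}.
#' @param waypoints matrix of waypoint coordinates (rows, Angstrom) or list
#'   of length-3 vectors; optionally row-named with site labels.
#' @return Object of class \code{pathway_profile}: data frame
#'   \code{profile} with columns \code{s_A} (arc length), \code{G_kcal},
#'   \code{leg}; \code{barriers} (per-leg, max(G on leg) - G(leg start));
#'   \code{waypoint_G}; \code{labels}.
#' @export
path_profile <- function(grid, waypoints) {
  if (!inherits(grid, "fe_grid")) stop("grid must be an fe_grid")
  if (is.list(waypoints)) waypoints <- do.call(rbind, waypoints)
  waypoints <- as.matrix(waypoints)
  if (ncol(waypoints) != 3 || nrow(waypoints) < 2)
    stop("need at least two 3-D waypoints")
  labels <- rownames(waypoints)
  if (is.null(labels)) labels <- paste0("W", seq_len(nrow(waypoints)))
  ijk <- grid_index(grid, waypoints)
  G <- grid$values
  wp_G <- G[ijk]
  if (any(wp_G >= grid$cap))
    stop("waypoint lies in a capped (overlap) region")
  dims <- grid$dim
  nodes <- apply(ijk, 1, function(v)
    (v[3] - 1L) * dims[1] * dims[2] + (v[2] - 1L) * dims[1] + v[1])

  prof_s <- numeric(0); prof_g <- numeric(0); prof_leg <- integer(0)
  barriers <- numeric(nrow(waypoints) - 1)
  s0 <- 0
  for (leg in seq_len(nrow(waypoints) - 1)) {
    path <- minimax_path(G, dims, nodes[leg], nodes[leg + 1])
    coords <- node_coords(path, dims, grid$origin, grid$spacing)
    gvals <- G[path]
    step <- c(0, sqrt(rowSums(diff(coords)^2)))
    s <- s0 + cumsum(step)
    keep <- if (leg > 1) -1 else TRUE   # drop duplicated waypoint node
    prof_s <- c(prof_s, s[keep])
    prof_g <- c(prof_g, gvals[keep])
    prof_leg <- c(prof_leg, rep(leg, length(s[keep])))
    barriers[leg] <- max(gvals) - gvals[1]
    s0 <- s[length(s)]
  }
  structure(list(profile = data.frame(s_A = prof_s, G_kcal = prof_g,
                                      leg = prof_leg),
                 barriers = barriers, waypoint_G = wp_G, labels = labels),
            class = "pathway_profile")
}

#' @export
print.pathway_profile <- function(x, ...) {
  cat(sprintf("<pathway_profile> %s; barriers (kcal/mol): %s\n",
              paste(x$labels, collapse = " -> "),
              paste(sprintf("%.3g", x$barriers), collapse = ", ")))
  invisible(x)
}

node_coords <- function(nodes, dims, origin, spacing) {
  k <- (nodes - 1L) %/% (dims[1] * dims[2])
  rem <- (nodes - 1L) %% (dims[1] * dims[2])
  j <- rem %/% dims[1]
  i <- rem %% dims[1]
  cbind(origin[1] + i * spacing, origin[2] + j * spacing,
        origin[3] + k * spacing)
}

# minimax Dijkstra on the 26-connected lattice: path cost is the maximum
# node value along the path (ties broken towards fewer/cheaper hops by the
# scan order); returns the node sequence from src to dst.
minimax_path <- function(G, dims, src, dst) {
  n <- prod(dims)
  g <- as.numeric(G)
  dist <- rep(Inf, n)
  parent <- integer(n)
  visited <- rep(FALSE, n)
  dist[src] <- g[src]
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  repeat {
    u <- which.min(replace(dist, visited, Inf))
    if (!length(u) || !is.finite(dist[u])) stop("waypoints not connected")
    if (u == dst) break
    visited[u] <- TRUE
    k <- (u - 1L) %/% (dims[1] * dims[2])
    rem <- (u - 1L) %% (dims[1] * dims[2])
    j <- rem %/% dims[1]
    i <- rem %% dims[1]
    ni <- i + offs[, 1]; nj <- j + offs[, 2]; nk <- k + offs[, 3]
    ok <- ni >= 0 & ni < dims[1] & nj >= 0 & nj < dims[2] & nk >= 0 & nk < dims[3]
    v <- nk[ok] * dims[1] * dims[2] + nj[ok] * dims[1] + ni[ok] + 1L
    v <- v[!visited[v]]
    if (length(v)) {
      nd <- pmax(dist[u], g[v])
      upd <- nd < dist[v]
      dist[v[upd]] <- nd[upd]
      parent[v[upd]] <- u
    }
  }
  path <- dst
  while (path[1] != src) path <- c(parent[path[1]], path)
  path
}

#' Rigid-body least-squares alignment of trajectory frames
#'
#' Kabsch superposition of every frame onto a reference frame (optionally
#' using a subset of atoms). Frame alignment before gridding is the
#' caller's responsibility; this utility covers the common case.
#'
#' @param frames a [trajectory_frames()].
#' @param reference index of the reference frame.
#' @param atoms optional atom indices used to compute the superposition.
#' @return A new [trajectory_frames()] with aligned coordinates.
#' @export
align_frames <- function(frames, reference = 1, atoms = NULL) {
  if (!inherits(frames, "trajectory_frames")) stop("frames must be trajectory_frames")
  if (is.null(atoms)) atoms <- seq_len(frames$n_atoms)
  ref <- frames$frames[[reference]][atoms, , drop = FALSE]
  mu_ref <- colMeans(ref)
  refc <- sweep(ref, 2, mu_ref)
  out <- lapply(frames$frames, function(f) {
    sub <- f[atoms, , drop = FALSE]
    mu <- colMeans(sub)
    H <- crossprod(sweep(sub, 2, mu), refc)
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    sweep(sweep(f, 2, mu) %*% t(R), 2, mu_ref, "+")
  })
  trajectory_frames(out, frames$epsilon, frames$rmin_half)
}
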