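# Independent oracles used across the suite.

# closed-form propagation of dp/dt = Q p: eigendecomposition of the
# generator (direct scaling-and-squaring via Matrix::expm loses ~1e-6
# absolute accuracy once ||Q t|| reaches 1e10, so it only serves as the
# fallback for near-defective generators). The default route under test
# is the package's stiff ODE integrator, which is independent of this.
expm_oracle <- function(Q, p0, times) {
  eg <- eigen(Q)
  c0 <- tryCatch(solve(eg$vectors, p0 + 0i), error = function(e) NULL)
  if (!is.null(c0) && max(Mod(c0)) < 1e10) {
    return(t(vapply(times, function(t)
      as.numeric(Re(eg$vectors %*% (exp(eg$values * t) * c0))),
      numeric(length(p0)))))
  }
  P <- matrix(NA_real_, length(times), length(p0))
  p <- p0
  tprev <- 0
  for (i in seq_along(times)) {
    p <- as.numeric(Matrix::expm(Q * (times[i] - tprev)) %*% p)
    tprev <- times[i]
    P[i, ] <- p
  }
  P
}

oracle_states <- function(rates, cond, times, k_off = 0) {
  Q <- build_generator(rates, cond, k_off = k_off)
  p0 <- stats::setNames(numeric(8), scheme_states())
  p0["DS"] <- cond$phi
  p0["B0"] <- 1 - cond$phi
  P <- expm_oracle(Q, p0, times)
  colnames(P) <- scheme_states()
  P
}

# extended-precision matrix-exponential oracle via python/mpmath: in double
# precision any expm-style algorithm carries an absolute error of order
# eps * ||Q|| * t (the conditioning of Q -> exp(Qt)), which reaches 1e-6
# for generators with rates of 1e10 s^-1 at t = 1 s; 30 decimal digits
# remove that wall, making the oracle sharp enough for a 1e-8 comparison.
# Qs: list of 8x8 generators; returns list of length(times) x 8 matrices
# for the initial condition p0 = (0, 1, 0, ..., 0).
mpmath_oracle <- function(Qs, times, dps = 30) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(list(dps = dps, times = times,
                            Q = lapply(Qs, as.vector)),
                       infile, digits = NA, auto_unbox = TRUE)
  py <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "import mpmath as mp",
    "doc = json.load(open(sys.argv[1]))",
    "mp.mp.dps = doc['dps']",
    "times = doc['times']",
    "out = []",
    "for qflat in doc['Q']:",
    "    Q = mp.matrix(8, 8)",
    "    for j in range(8):",
    "        for i in range(8):",
    "            Q[i, j] = mp.mpf(repr(qflat[j * 8 + i]))",
    "    p0 = mp.matrix([0, 1, 0, 0, 0, 0, 0, 0])",
    "    rows = []",
    "    for t in times:",
    "        p = mp.expm(Q * mp.mpf(repr(t))) * p0",
    "        rows.append([float(p[i]) for i in range(8)])",
    "    out.append(rows)",
    "json.dump(out, open(sys.argv[2], 'w'))"), py)
  status <- system2("python", c(py, infile, outfile))
  stopifnot(status == 0)
  res <- jsonlite::read_json(outfile, simplifyVector = TRUE)
  lapply(seq_len(dim(res)[1]), function(i) matrix(res[i, , ], dim(res)[2], 8))
}

# brute-force double-loop Lennard-Jones sum for one probe pose
lj_brute <- function(frames, frame, position, orientation, probe = probe_params(),
                     cutoff = 10) {
  u <- orientation / sqrt(sum(orientation^2))
  xyz <- frames$frames[[frame]]
  sites <- list(C = list(pos = position - probe$bond_A / 2 * u,
                         eps = probe$eps[["C"]], rh = probe$rmin_half[["C"]]),
                O = list(pos = position + probe$bond_A / 2 * u,
                         eps = probe$eps[["O"]], rh = probe$rmin_half[["O"]]))
  E <- 0
  for (s in sites) {
    for (a in seq_len(nrow(xyz))) {
      d <- sqrt(sum((xyz[a, ] - s$pos)^2))
      if (d <= cutoff) {
        rmin <- s$rh + frames$rmin_half[a]
        eps <- sqrt(s$eps * frames$epsilon[a])
        E <- E + eps * ((rmin / d)^12 - 2 * (rmin / d)^6)
      }
    }
  }
  E
}

# Widom-insertion Monte-Carlo estimate of the insertion free energy at a
# set of points: random orientations, same LJ model, fixed seed
widom_oracle <- function(frames, points, probe = probe_params(),
                         temperature_K = 300, n_orient = 1e4, seed = 42,
                         cutoff = 10, cap = 100) {
  set.seed(seed)
  kT <- 1.98720e-3 * temperature_K
  u <- matrix(stats::rnorm(n_orient * 3), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  offC <- -probe$bond_A / 2 * u
  offO <- probe$bond_A / 2 * u
  nf <- length(frames$frames)
  chunks <- split(seq_len(nf), ceiling(seq_len(nf) / 5))
  vapply(seq_len(nrow(points)), function(ip) {
    p <- points[ip, ]
    acc <- 0
    for (ch in chunks) {
      xyz <- do.call(rbind, frames$frames[ch])      # stacked frame block
      rmh <- rep(frames$rmin_half, length(ch))
      eps <- rep(frames$epsilon, length(ch))
      na <- frames$n_atoms
      E <- matrix(0, n_orient, length(ch))
      for (s in 1:2) {
        S <- sweep(if (s == 1) offC else offO, 2, p, "+")
        rh <- if (s == 1) probe$rmin_half[["C"]] else probe$rmin_half[["O"]]
        ep <- if (s == 1) probe$eps[["C"]] else probe$eps[["O"]]
        d2 <- outer(rowSums(S^2), rowSums(xyz^2), "+") - 2 * (S %*% t(xyz))
        d2 <- pmax(d2, 1e-12)
        t6 <- sweep(1 / d2, 2, (rh + rmh)^2, "*")^3
        lj <- sweep(t6^2 - 2 * t6, 2, sqrt(ep * eps), "*")
        lj[d2 > cutoff^2] <- 0
        # per-frame sums within the stacked block
        for (k in seq_along(ch))
          E[, k] <- E[, k] + rowSums(lj[, (k - 1) * na + seq_len(na), drop = FALSE])
      }
      acc <- acc + sum(exp(-pmin(E, cap) / kT))
    }
    -kT * log(acc / (nf * n_orient))
  }, numeric(1))
}

# Wald-Wolfowitz runs test Z statistic on residual signs
runs_test_z <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0) return(0)
  r <- 1 + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / (n1 + n2) + 1
  v <- (mu - 1) * (mu - 2) / (n1 + n2 - 1)
  (r - mu) / sqrt(v)
}
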