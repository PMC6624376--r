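test_that("distance-dependent-dielectric Coulomb potential follows C q / r^2", {
  rec <- one_atom(charge = 1)
  expect_equal(coulomb_phi(rec, cbind(2, 0, 0)), 332.0637 / 4,
               tolerance = 1e-12)
  # +1/-1 pair is antisymmetric about the midplane
  at <- data.frame(name = c("P", "M"), type = c("N.3", "O.2"),
                   x = c(-1, 1), y = 0, z = 0, charge = c(1, -1),
                   stringsAsFactors = FALSE)
  dip <- assign_vdw_parameters(molecule("dip", at))
  expect_equal(coulomb_phi(dip, cbind(0, 3.3, -1.2)), 0, tolerance = 1e-12)
  # brute-force per-atom oracle on a 5-atom fixture
  rec5 <- make_ligand(fixture_spec(seed = 11, ligand_atoms = 5))
  set.seed(2); pts <- matrix(runif(30, -6, 6), ncol = 3)
  oracle <- sapply(seq_len(nrow(pts)), function(i) {
    d <- sqrt(rowSums(sweep(coords(rec5), 2, pts[i, ])^2))
    332.0637 * sum(rec5$atoms$charge / d^2)
  })
  expect_equal(coulomb_phi(rec5, pts), oracle, tolerance = 1e-10)
  expect_error(coulomb_phi(rec5, coords(rec5)[1, , drop = FALSE]),
               "coincides")
})

test_that("per-atom LJ coefficients place the like-pair minimum at 2 r0 with depth eps", {
  r0 <- 1.908; eps <- 0.1094
  lj <- lj_coefficients(r0, eps)
  e_of <- function(r) lj$A / r^12 - lj$B / r^6
  expect_equal(e_of(2 * r0), -eps, tolerance = 1e-12)
  # stationary point at 2 r0
  h <- 1e-6
  expect_lt(abs(e_of(2 * r0 + h) - e_of(2 * r0 - h)) / (2 * h), 1e-6)
  expect_gt(e_of(2 * r0 * 0.9), e_of(2 * r0))
})

test_that("separable geometric-mean grid decomposition is algebraically exact", {
  set.seed(4)
  for (k in 1:50) {
    r0 <- runif(2, 1.0, 2.4); eps <- runif(2, 0.02, 0.5)
    d <- runif(1, 1, 8); dv <- sample(c(0, 0.5, 2.0), 1)
    li <- lj_coefficients(r0[1], eps[1]); lj <- lj_coefficients(r0[2], eps[2])
    den <- d^6 + dv^6
    pair <- sqrt(li$A * lj$A) / den^2 - sqrt(li$B * lj$B) / den
    sep <- sqrt(lj$A) * (sqrt(li$A) / den^2) - sqrt(lj$B) * (sqrt(li$B) / den)
    expect_equal(sep, pair, tolerance = 1e-12)
  }
})

test_that("soft-core potential is finite at contact, reduces to 6-12 at delta = 0, and its wall never grows with delta", {
  rec <- one_atom(charge = 0)
  lig <- one_atom(c(1e-4, 0, 0))
  lj <- lj_coefficients(1.908, 0.1094)
  for (dv in c(0.5, 1.0, 2.5)) {
    e <- direct_energy(rec, lig, model = "coulomb", delta_vdw = dv)
    expect_true(is.finite(e[["E_vdw"]]))
    expect_equal(e[["E_vdw"]], lj$A / dv^12 - lj$B / dv^6, tolerance = 1e-3)
  }
  # delta = 0 equals the plain 6-12 potential at the pair minimum
  lig2 <- one_atom(c(2 * 1.908, 0, 0))
  e0 <- direct_energy(rec, lig2, model = "coulomb", delta_vdw = 0)
  expect_equal(e0[["E_vdw"]], -0.1094, tolerance = 1e-12)
  # monotone: larger delta never raises the repulsive wall at r < 2 r0
  for (r in c(1.0, 2.0, 3.0)) {
    ligr <- one_atom(c(r, 0, 0))
    walls <- sapply(c(0, 0.5, 1, 1.5, 2, 2.5), function(dv) {
      direct_energy(rec, ligr, model = "coulomb", delta_vdw = dv)[["E_vdw"]]
    })
    expect_true(all(diff(walls) <= 1e-12))
  }
})

test_that("the worked receptor-ligand pair reproduces the closed-form energies", {
  rec <- one_atom(charge = 1)
  lig <- one_atom(c(2 * 1.908, 0, 0), charge = -1)
  e <- direct_energy(rec, lig, model = "coulomb", delta_vdw = 0)
  expect_equal(e[["E_vdw"]], -0.1094, tolerance = 1e-12)
  expect_equal(e[["E_elec"]], -332.0637 / (2 * 1.908)^2, tolerance = 1e-12)
  expect_equal(e[["E_total"]], e[["E_elec"]] + e[["E_vdw"]])
  # the -83.0159 textbook value at 2 A separation
  lig2 <- one_atom(c(2, 0, 0), charge = -1)
  expect_equal(direct_energy(rec, lig2, model = "coulomb")[["E_elec"]],
               -83.015925, tolerance = 1e-6)
})

test_that("grid geometry follows the 30 A / 0.4 A / 75-node convention", {
  g <- grid_geometry(c(0, 0, 0), 30, 0.4)
  expect_identical(g$dims, rep(75L, 3))
  gs <- std_pocket()$grids
  expect_identical(gs$geom$dims, rep(75L, 3))
})

test_that("grid nodes hold the direct per-atom sums and interpolation is exact at nodes", {
  env <- std_pocket()
  gs <- env$grids
  g <- gs$geom
  set.seed(8)
  idx <- cbind(sample(10:65, 5), sample(10:65, 5), sample(10:65, 5))
  node_xyz <- sweep((idx - 1) * g$spacing, 2, g$origin, FUN = "+")
  # phi nodes = clamped Coulomb sum
  expect_equal(gs$phi[idx], coulomb_phi(env$pocket, node_xyz, clamp = 0.5),
               tolerance = 1e-10)
  # A/B sums against a brute-force per-atom oracle
  lj <- lj_coefficients(env$pocket$atoms$r0, env$pocket$atoms$eps)
  for (row in 1:5) {
    d6 <- rowSums(sweep(coords(env$pocket), 2, node_xyz[row, ])^2)^3
    expect_equal(gs$vdw_a[idx[row, , drop = FALSE]],
                 sum(sqrt(lj$A) / d6^2), tolerance = 1e-10)
    expect_equal(gs$vdw_b[idx[row, , drop = FALSE]],
                 sum(sqrt(lj$B) / d6), tolerance = 1e-10)
  }
  # interpolation: exact at nodes, mean of corners at a cell center
  v <- interpolate_grids(gs, node_xyz)
  expect_equal(v[, "phi"], gs$phi[idx], tolerance = 1e-12)
  cc <- node_xyz[1, ] + g$spacing / 2
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  corner_idx <- corners + rep(idx[1, ], each = 8)
  expect_equal(unname(interpolate_grids(gs, rbind(cc))[, "phi"]),
               mean(gs$phi[corner_idx]), tolerance = 1e-12)
  # out-of-bounds points are flagged with NA
  expect_true(is.na(interpolate_grids(gs, rbind(g$origin - 5))[, "phi"]))
})

test_that("grid-interpolated energies track the direct sums within 2%", {
  env <- std_pocket()
  lig <- env$ligand
  for (jit in perturbed_poses(env$pocket, lig, n = 10, seed = 21)) {
    eg <- grid_energy(env$grids, lig, jit)
    ed <- direct_energy(env$pocket, lig, jit, model = "coulomb",
                        delta_vdw = 0)
    expect_equal(eg[["E_total"]], ed[["E_total"]], tolerance = 0.02)
  }
  # zero-charge ligand scores zero electrostatics
  lig0 <- lig
  lig0$atoms$charge[] <- 0
  expect_equal(grid_energy(env$grids, lig0)[["E_elec"]], 0)
  expect_equal(direct_energy(env$pocket, lig0, model = "coulomb")[["E_elec"]],
               0)
})

test_that("coulomb E_elec for a unit charge pair decays as 1/r^2", {
  rec <- one_atom(charge = 1)
  rs <- seq(2, 10, length.out = 10)
  es <- sapply(rs, function(r) {
    direct_energy(rec, one_atom(c(r, 0, 0), charge = -1),
                  model = "coulomb")[["E_elec"]]
  })
  expect_equal(es, -332.0637 / rs^2, tolerance = 1e-12)
})

test_that("grid sets serialize to DX plus sidecar and read back", {
  env <- std_pocket()
  prefix <- file.path(tempdir(), "gridset_roundtrip")
  write_grids(env$grids, prefix)
  back <- read_grids(prefix)
  expect_equal(back$model, "coulomb")
  expect_equal(back$delta_vdw, env$grids$delta_vdw)
  expect_equal(back$phi, env$grids$phi, tolerance = 1e-5)
  e1 <- grid_energy(env$grids, env$ligand)
  e2 <- grid_energy(back, env$ligand)
  expect_equal(e2[["E_total"]], e1[["E_total"]], tolerance = 1e-4)
})
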