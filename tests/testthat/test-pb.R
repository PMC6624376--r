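test_that("Debye screening matches the closed-form Debye-Hueckel length", {
  # 145 mM monovalent salt in water at 298.15 K: lambda_D ~ 8.0 A
  expect_equal(1 / sqrt(debye_kappa2(0.145, 298.15, 78.5)), 8.0,
               tolerance = 0.01)
  expect_equal(debye_kappa2(0, 298.15, 78.5), 0)
})

test_that("dielectric map marks atom interiors and the Stern layer", {
  geom <- grid_geometry(c(0, 0, 0), 10, 0.4)
  # no atoms: uniform solvent dielectric and uniform screening
  empty <- pb_problem(matrix(numeric(0), 0, 3), numeric(0), numeric(0),
                      salt = 0.145)
  d0 <- build_dielectric_map(empty, geom)
  expect_true(all(d0$eps_x == 78.5) && all(d0$eps_y == 78.5) &&
                all(d0$eps_z == 78.5))
  expect_equal(length(unique(as.numeric(d0$kappa2))), 1L)
  # single sphere: interior edge volume ~ sphere volume within 10%
  prob <- pb_problem(matrix(0, 1, 3), 1, 2.0, salt = 0)
  d1 <- build_dielectric_map(prob, geom)
  vol_sphere <- 4 / 3 * pi * 2^3
  est <- sum(d1$eps_x == prob$eps_in) * geom$spacing^3
  expect_equal(est, vol_sphere, tolerance = 0.1)
  # screening is zeroed inside radius + Stern layer
  probs <- pb_problem(matrix(0, 1, 3), 1, 2.0, salt = 0.145, stern = 2.0)
  ds <- build_dielectric_map(probs, geom)
  ax <- pbdock:::grid_axes(geom)
  node_r <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+"))
  expect_true(all(ds$kappa2[node_r < 4.0] == 0))
  expect_true(all(ds$kappa2[node_r > 4.5] > 0))
  # atoms outside the box are rejected by default
  off <- pb_problem(matrix(c(20, 0, 0), 1, 3), 1, 2.0)
  expect_error(build_dielectric_map(off, geom), "outside")
})

test_that("uniform-dielectric solve reproduces the Coulomb potential", {
  prob <- pb_problem(matrix(0, 1, 3), 1, 0.01, eps_in = 4, eps_out = 4,
                     salt = 0)
  geom <- grid_geometry(c(0, 0, 0), 12.25, 0.25)
  map <- solve_lpbe(prob, geom)
  C <- 332.0637 / kT_kcal()
  for (r in c(0.75, 1.5, 3, 5)) {
    u <- r / sqrt(3)
    expect_equal(map_interpolate(map, cbind(r, 0, 0))[1], C / (4 * r),
                 tolerance = 0.03, info = paste("axis r =", r))
    expect_equal(map_interpolate(map, cbind(u, u, u))[1], C / (4 * r),
                 tolerance = 0.03, info = paste("diag r =", r))
  }
  # convergence diagnostic (discrete Dirichlet energy) is monotone
  en <- attr(map, "energy_trace")
  expect_true(all(diff(en) <= abs(en[1]) * 1e-12))
})

test_that("zero charges give an identically zero potential", {
  prob <- pb_problem(matrix(c(0, 0, 0, 1, 1, 1), 2, 3, byrow = TRUE),
                     c(0, 0), c(1.5, 1.5), salt = 0.145)
  map <- solve_lpbe(prob, grid_geometry(c(0, 0, 0), 8, 0.5))
  expect_true(all(map$values == 0))
})

test_that("the linear PB solution superposes and scales with charge", {
  xyz <- rbind(c(1, 0, 0), c(-1.5, 0.5, 0))
  radii <- c(1.5, 1.8)
  geom <- grid_geometry(c(0, 0, 0), 12, 0.5)
  mk <- function(q) pb_problem(xyz, q, radii, salt = 0.145)
  diel <- build_dielectric_map(mk(c(1, -0.5)), geom)
  m1 <- solve_lpbe(mk(c(1, 0)), geom, dielectric = diel, tol = 1e-6)
  m2 <- solve_lpbe(mk(c(0, -0.5)), geom, dielectric = diel, tol = 1e-6)
  m12 <- solve_lpbe(mk(c(1, -0.5)), geom, dielectric = diel, tol = 1e-6)
  expect_lt(max(abs(m12$values - m1$values - m2$values)) /
              max(abs(m12$values)), 1e-6)
  m2x <- solve_lpbe(mk(c(2, 0)), geom, dielectric = diel, tol = 1e-6)
  expect_lt(max(abs(m2x$values - 2 * m1$values)) / max(abs(m2x$values)), 1e-6)
})

test_that("degenerate focusing (fine box = coarse box) equals the plain solve", {
  prob <- pb_problem(matrix(0, 1, 3), 1, 1.8, salt = 0.145)
  geom <- grid_geometry(c(0, 0, 0), 12, 0.5)
  plain <- solve_lpbe(prob, geom)
  focused <- focus_solve(prob, center = c(0, 0, 0), size = 12, spacing = 0.5,
                         coarse_size = 12, coarse_nodes = 24,
                         coarse_center = c(0, 0, 0))
  expect_identical(focused$values, plain$values)
})

test_that("OpenDX round trip preserves geometry and values", {
  vals <- array(rnorm(4 * 3 * 5), dim = c(4, 3, 5))
  map <- potential_map(c(-1.5, 0, 2), 0.5, vals)
  f <- tempfile(fileext = ".dx")
  write_dx(map, f, digits = 9)
  back <- read_dx(f)
  expect_equal(back$origin, map$origin, tolerance = 1e-6)
  expect_equal(back$spacing, map$spacing, tolerance = 1e-9)
  expect_identical(back$dims, map$dims)
  expect_equal(back$values, map$values, tolerance = 1e-6)
})

test_that("a hand-written DX file reads in documented (z-fastest) order", {
  txt <- c("# toy grid",
           "object 1 class gridpositions counts 2 2 2",
           "origin 0.0 0.0 0.0",
           "delta 1.0 0.0 0.0", "delta 0.0 1.0 0.0", "delta 0.0 0.0 1.0",
           "object 2 class gridconnections counts 2 2 2",
           "object 3 class array type double rank 0 items 8 data follows",
           "1 2 3", "4 5 6", "7 8")
  f <- tempfile(fileext = ".dx")
  writeLines(txt, f)
  m <- read_dx(f)
  # z varies fastest: value at (i,j,k) = 4(i-1) + 2(j-1) + (k-1) + 1
  expect_equal(m$values[1, 1, 1], 1)
  expect_equal(m$values[1, 1, 2], 2)
  expect_equal(m$values[1, 2, 1], 3)
  expect_equal(m$values[2, 1, 1], 5)
  expect_equal(m$values[2, 2, 2], 8)
  bad <- tempfile(fileext = ".dx")
  writeLines(c("object 1 class gridpositions counts 2 2 2", "no origin here"),
             bad)
  expect_error(read_dx(bad), "malformed")
})

test_that("imported maps drive the grid builder exactly like internal ones", {
  env <- std_pocket()
  prob <- pb_problem_from_molecule(env$pocket)
  ctr <- colMeans(coords(env$ligand))
  map <- focus_solve(prob, center = ctr, size = 16, spacing = 0.8)
  f <- tempfile(fileext = ".dx")
  write_dx(map, f, digits = 10)
  ext <- read_dx(f)
  g1 <- build_grids(env$pocket, "pb", center = ctr, size = 12, spacing = 0.8,
                    pb_map = map)
  g2 <- build_grids(env$pocket, "pb", center = ctr, size = 12, spacing = 0.8,
                    pb_map = ext)
  expect_lt(max(abs(g2$phi - g1$phi)), 1e-5)
})
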