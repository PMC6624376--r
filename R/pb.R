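## Finite-difference linearized Poisson-Boltzmann electrostatics.
##
## The receptor is a set of point charges at atom centers inside a
## two-valued dielectric: eps_in inside the atomic vdW spheres, eps_out
## outside, with monovalent-salt Debye screening outside the molecule and
## its Stern ion-exclusion layer.  The linearized PB equation
##   div(eps grad phi) - kbar^2 phi = -4 pi (e^2/kT) rho
## is discretized on a uniform grid with face-centered dielectrics and
## solved by successive over-relaxation; charges are spread to the eight
## surrounding nodes (cloud-in-cell) and box faces carry analytic
## Debye-Hueckel boundary values.  Potentials are in kT/e.

#' Define a linearized PB problem
#'
#' @param xyz n x 3 matrix of charge positions (atom centers), Angstrom.
#' @param charges atomic partial charges, e.
#' @param radii atomic vdW radii, Angstrom (dielectric boundary).
#' @param eps_in interior (solute) dielectric.
#' @param eps_out exterior (solvent) dielectric.
#' @param salt monovalent ionic strength, mol/L.
#' @param temperature Kelvin.
#' @param stern Stern ion-exclusion layer thickness, Angstrom.
#' @return an object of class `pb_problem`.
#' @export
pb_problem <- function(xyz, charges, radii, eps_in = 2.06, eps_out = 78.5,
                       salt = 0.145, temperature = 298.15, stern = 2.0) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, length(charges) == nrow(xyz),
            length(radii) == nrow(xyz),
            eps_in > 0, eps_out > 0, salt >= 0, all(radii > 0))
  structure(list(xyz = xyz, charges = as.numeric(charges),
                 radii = as.numeric(radii), eps_in = eps_in,
                 eps_out = eps_out, salt = salt,
                 temperature = temperature, stern = stern),
            class = "pb_problem")
}

#' PB problem for a parameterized molecule
#' @param mol a `molecule` with vdW parameters assigned.
#' @param ... further arguments to [pb_problem()].
#' @return a `pb_problem` using atom positions, charges and r0 radii.
#' @export
pb_problem_from_molecule <- function(mol, ...) {
  require_parameters(mol)
  pb_problem(coords(mol), mol$atoms$charge, mol$atoms$r0, ...)
}

## Bjerrum-like length e^2/(kT) in Angstrom (560.5 A at 298.15 K).
charge_constant <- function(temperature) COULOMB_KCAL / kT_kcal(temperature)

#' Debye screening parameter
#'
#' `kappa^2 = 8 pi l_B n_ion` with `l_B = e^2/(eps_out kT)` and the ion
#' number density of a 1:1 salt at ionic strength `salt` mol/L.
#'
#' @param salt monovalent ionic strength, mol/L.
#' @param temperature Kelvin.
#' @param eps_out solvent dielectric.
#' @return kappa^2 in 1/Angstrom^2; `1/sqrt(kappa^2)` is the Debye length
#'   (about 8 Angstrom at 145 mM, 298.15 K in water).
#' @export
debye_kappa2 <- function(salt, temperature = 298.15, eps_out = 78.5) {
  n_ion <- salt * AVOGADRO / 1e27      # ions per Angstrom^3 (per species pair)
  lb <- charge_constant(temperature) / eps_out
  8 * pi * lb * n_ion
}

#' Regular grid geometry
#'
#' `round(size / spacing)` nodes per axis (75 for the default 30 Angstrom
#' box at 0.4 Angstrom), spanning `(n - 1) * spacing` centered on `center`.
#'
#' @param center box center, Angstrom.
#' @param size box edge length, Angstrom.
#' @param spacing node spacing, Angstrom.
#' @return list with `origin`, `spacing`, `dims`.
#' @export
grid_geometry <- function(center, size, spacing) {
  stopifnot(length(center) == 3, size > 0, spacing > 0)
  n <- max(2L, as.integer(round(size / spacing)))
  dims <- rep(n, 3L)
  origin <- as.numeric(center) - (n - 1) * spacing / 2
  list(origin = origin, spacing = spacing, dims = dims)
}

grid_axes <- function(geom) {
  lapply(1:3, function(d) geom$origin[d] + (seq_len(geom$dims[d]) - 1) * geom$spacing)
}

## Mark nodes of an axis-aligned grid that fall inside any sphere.
mark_inside <- function(xs, ys, zs, centers, radii) {
  inside <- array(FALSE, dim = c(length(xs), length(ys), length(zs)))
  for (a in seq_len(nrow(centers))) {
    r <- radii[a]; ctr <- centers[a, ]
    ix <- which(abs(xs - ctr[1]) <= r)
    iy <- which(abs(ys - ctr[2]) <= r)
    iz <- which(abs(zs - ctr[3]) <= r)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (xs[ix] - ctr[1])^2
    dy2 <- (ys[iy] - ctr[2])^2
    dz2 <- (zs[iz] - ctr[3])^2
    m <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
    inside[ix, iy, iz] <- inside[ix, iy, iz] | m
  }
  inside
}

#' Build the dielectric and screening maps for a PB problem
#'
#' Grid edges whose midpoint falls inside any atomic vdW sphere take
#' `eps_in`, all others `eps_out`.  The modified screening coefficient
#' `kbar^2 = eps_out * kappa^2` is applied at nodes outside every atom's
#' radius plus the Stern layer, and is zero inside.
#'
#' @param problem a `pb_problem`.
#' @param geom grid geometry from [grid_geometry()].
#' @param allow_outside tolerate atom centers outside the box (used by
#'   focused solves, where out-of-box charges act through the boundary
#'   values and only their sphere intersections shape the dielectric);
#'   by default such atoms raise an error.
#' @return list with face dielectric arrays `eps_x`, `eps_y`, `eps_z`
#'   (dims reduced by one along their axis), nodal `kappa2` (modified,
#'   1/Angstrom^2) and the geometry.
#' @export
build_dielectric_map <- function(problem, geom, allow_outside = FALSE) {
  ax <- grid_axes(geom)
  h <- geom$spacing
  lo <- geom$origin
  hi <- geom$origin + (geom$dims - 1) * h
  out_of_box <- problem$xyz[, 1] < lo[1] | problem$xyz[, 1] > hi[1] |
    problem$xyz[, 2] < lo[2] | problem$xyz[, 2] > hi[2] |
    problem$xyz[, 3] < lo[3] | problem$xyz[, 3] > hi[3]
  if (any(out_of_box) && !allow_outside) {
    stop(sum(out_of_box), " atom(s) fall outside the PB grid box")
  }
  eps_of <- function(inside) ifelse(inside, problem$eps_in, problem$eps_out)
  n <- nrow(problem$xyz)
  if (n > 0) {
    midx <- ax[[1]][-geom$dims[1]] + h / 2
    midy <- ax[[2]][-geom$dims[2]] + h / 2
    midz <- ax[[3]][-geom$dims[3]] + h / 2
    eps_x <- eps_of(mark_inside(midx, ax[[2]], ax[[3]], problem$xyz, problem$radii))
    eps_y <- eps_of(mark_inside(ax[[1]], midy, ax[[3]], problem$xyz, problem$radii))
    eps_z <- eps_of(mark_inside(ax[[1]], ax[[2]], midz, problem$xyz, problem$radii))
    excl <- mark_inside(ax[[1]], ax[[2]], ax[[3]], problem$xyz,
                        problem$radii + problem$stern)
  } else {
    eps_x <- array(problem$eps_out, dim = c(geom$dims[1] - 1, geom$dims[2], geom$dims[3]))
    eps_y <- array(problem$eps_out, dim = c(geom$dims[1], geom$dims[2] - 1, geom$dims[3]))
    eps_z <- array(problem$eps_out, dim = c(geom$dims[1], geom$dims[2], geom$dims[3] - 1))
    excl <- array(FALSE, dim = geom$dims)
  }
  kbar2 <- problem$eps_out * debye_kappa2(problem$salt, problem$temperature,
                                          problem$eps_out)
  kappa2 <- array(kbar2, dim = geom$dims)
  kappa2[excl] <- 0
  list(eps_x = eps_x, eps_y = eps_y, eps_z = eps_z, kappa2 = kappa2,
       geom = geom)
}

## Spread point charges onto grid nodes.  "gaussian" (default) deposits a
## normalized spherical cloud of width sigma = spread_sigma * h over its
## 3.5-sigma support, which suppresses the near-field anisotropy of the
## 7-point lattice; "cic" is classic trilinear cloud-in-cell.  Total charge
## is conserved per atom in both schemes.
spread_charges <- function(xyz, charges, geom,
                           method = c("gaussian", "cic"),
                           spread_sigma = 1.0) {
  method <- match.arg(method)
  q <- array(0, dim = geom$dims)
  h <- geom$spacing
  for (a in seq_len(nrow(xyz))) {
    u <- (xyz[a, ] - geom$origin) / h
    if (method == "cic") {
      i0 <- pmin(pmax(floor(u), 0), geom$dims - 2)
      f <- u - i0
      for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        wgt <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
        id <- i0 + c(dx, dy, dz) + 1L
        q[id[1], id[2], id[3]] <- q[id[1], id[2], id[3]] + charges[a] * wgt
      }
    } else {
      rad <- ceiling(3.5 * spread_sigma)
      ii <- max(1L, floor(u[1]) + 1L - rad):min(geom$dims[1], floor(u[1]) + 1L + rad + 1L)
      jj <- max(1L, floor(u[2]) + 1L - rad):min(geom$dims[2], floor(u[2]) + 1L + rad + 1L)
      kk <- max(1L, floor(u[3]) + 1L - rad):min(geom$dims[3], floor(u[3]) + 1L + rad + 1L)
      d2 <- outer(outer((ii - 1 - u[1])^2, (jj - 1 - u[2])^2, "+"),
                  (kk - 1 - u[3])^2, "+")
      w <- exp(-d2 / (2 * spread_sigma^2))
      w <- w / sum(w)
      q[ii, jj, kk] <- q[ii, jj, kk] + charges[a] * w
    }
  }
  q
}

## Analytic Debye-Hueckel potential (kT/e) of the problem's charges at
## arbitrary points, used for box-face boundary values.
dh_potential <- function(problem, pts) {
  C <- charge_constant(problem$temperature)
  kap <- sqrt(debye_kappa2(problem$salt, problem$temperature, problem$eps_out))
  phi <- numeric(nrow(pts))
  for (a in seq_len(nrow(problem$xyz))) {
    d <- sqrt(rowSums(sweep(pts, 2, problem$xyz[a, ])^2))
    d <- pmax(d, 1e-6)
    phi <- phi + C * problem$charges[a] * exp(-kap * d) / (problem$eps_out * d)
  }
  phi
}

face_nodes <- function(geom) {
  ax <- grid_axes(geom)
  n <- geom$dims
  idx <- as.matrix(expand.grid(i = seq_len(n[1]), j = seq_len(n[2]),
                               k = seq_len(n[3])))
  on_face <- idx[, 1] == 1 | idx[, 1] == n[1] |
    idx[, 2] == 1 | idx[, 2] == n[2] |
    idx[, 3] == 1 | idx[, 3] == n[3]
  idx <- idx[on_face, , drop = FALSE]
  pts <- cbind(ax[[1]][idx[, 1]], ax[[2]][idx[, 2]], ax[[3]][idx[, 3]])
  list(idx = idx, pts = pts)
}

#' Construct a potential map
#' @param origin grid origin (first node), Angstrom.
#' @param spacing node spacing, Angstrom.
#' @param values 3-d array of potential values.
#' @param units unit label, `"kT/e"` or `"kcal/(mol e)"`.
#' @return an object of class `potential_map`.
#' @export
potential_map <- function(origin, spacing, values, units = "kT/e") {
  dims <- dim(values)
  stopifnot(length(dims) == 3, all(dims >= 2), spacing > 0,
            all(is.finite(values)))
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = dims, values = values, units = units),
            class = "potential_map")
}

#' @export
print.potential_map <- function(x, ...) {
  cat(sprintf("<potential map %dx%dx%d, spacing %.3f A, origin (%.2f, %.2f, %.2f), %s>\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3], x$units))
  invisible(x)
}

#' Trilinear interpolation of a potential map
#' @param map a `potential_map`.
#' @param pts n x 3 matrix of query points, Angstrom.
#' @return interpolated values; `NA` for points outside the grid.
#' @export
map_interpolate <- function(map, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  trilinear_array(map$values, map$origin, map$spacing, map$dims, pts)
}

trilinear_array <- function(values, origin, spacing, dims, pts) {
  u <- sweep(pts, 2, origin) / spacing
  out <- rep(NA_real_, nrow(pts))
  eps <- 1e-9
  ok <- u[, 1] >= -eps & u[, 1] <= dims[1] - 1 + eps &
    u[, 2] >= -eps & u[, 2] <= dims[2] - 1 + eps &
    u[, 3] >= -eps & u[, 3] <= dims[3] - 1 + eps
  if (!any(ok)) return(out)
  uu <- pmin(pmax(u[ok, , drop = FALSE], 0), rep(dims - 1, each = sum(ok)))
  i0 <- pmin(floor(uu), rep(dims - 2, each = nrow(uu)))
  f <- uu - i0
  acc <- numeric(nrow(uu))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx == 1) f[, 1] else 1 - f[, 1]) *
      (if (dy == 1) f[, 2] else 1 - f[, 2]) *
      (if (dz == 1) f[, 3] else 1 - f[, 3])
    id <- cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1, i0[, 3] + dz + 1)
    acc <- acc + w * values[id]
  }
  out[ok] <- acc
  out
}

#' Solve the linearized PB equation on a grid
#'
#' @param problem a `pb_problem`.
#' @param geom grid geometry from [grid_geometry()].
#' @param dielectric optional pre-built result of [build_dielectric_map()].
#' @param boundary optional `potential_map` supplying Dirichlet boundary
#'   values (used by focusing); by default box faces carry the analytic
#'   Debye-Hueckel potential of the problem charges.
#' @param tol convergence threshold on the max node update per sweep, kT/e.
#' @param maxit sweep cap; exceeding it raises an error reporting the final
#'   residual.
#' @param omega over-relaxation factor; `NULL` (default) uses red-black
#'   relaxation with the Chebyshev omega schedule.
#' @param spread charge-to-node assignment: `"gaussian"` cloud (default)
#'   or trilinear `"cic"`.
#' @param allow_outside tolerate (and drop the charges of) atoms outside
#'   the box; see [build_dielectric_map()].
#' @return a `potential_map` in kT/e with attributes `iterations` and
#'   `residual_trace`.
#' @export
solve_lpbe <- function(problem, geom, dielectric = NULL, boundary = NULL,
                       tol = 1e-4, maxit = 10000, omega = NULL,
                       spread = c("gaussian", "cic"), allow_outside = FALSE) {
  spread <- match.arg(spread)
  if (is.null(dielectric)) {
    dielectric <- build_dielectric_map(problem, geom, allow_outside)
  }
  n <- geom$dims
  C <- charge_constant(problem$temperature)
  h <- geom$spacing
  lo <- geom$origin
  hi <- geom$origin + (n - 1) * h
  inside <- problem$xyz[, 1] >= lo[1] & problem$xyz[, 1] <= hi[1] &
    problem$xyz[, 2] >= lo[2] & problem$xyz[, 2] <= hi[2] &
    problem$xyz[, 3] >= lo[3] & problem$xyz[, 3] <= hi[3]
  qn <- spread_charges(problem$xyz[inside, , drop = FALSE],
                       problem$charges[inside], geom, method = spread)
  src <- 4 * pi * C * qn / h

  phi <- array(0, dim = n)
  fn <- face_nodes(geom)
  bvals <- if (is.null(boundary)) {
    dh_potential(problem, fn$pts)
  } else {
    v <- map_interpolate(boundary, fn$pts)
    if (anyNA(v)) stop("boundary map does not cover the solve box")
    v
  }
  phi[fn$idx] <- bvals

  rho_j <- mean(cos(pi / n))
  res <- sor_lpbe(as.numeric(phi), as.numeric(dielectric$eps_x),
                  as.numeric(dielectric$eps_y), as.numeric(dielectric$eps_z),
                  as.numeric(dielectric$kappa2) * h^2, as.numeric(src),
                  n[1], n[2], n[3],
                  if (is.null(omega)) 0 else omega, tol,
                  as.integer(maxit), rho_j)
  if (res$residual >= tol) {
    stop(sprintf("PB solver did not converge in %d sweeps (residual %.3g kT/e)",
                 maxit, res$residual))
  }
  out <- potential_map(geom$origin, h, array(res$phi, dim = n), "kT/e")
  attr(out, "iterations") <- res$iterations
  attr(out, "residual_trace") <- res$trace
  attr(out, "energy_trace") <- res$energy
  out
}

#' Two-step focused PB solve
#'
#' A coarse solve on a large box (the molecule spanning half the box edge)
#' supplies interpolated Dirichlet boundary values for a fine solve on the
#' target box, mirroring the standard focusing protocol.
#'
#' @param problem a `pb_problem`.
#' @param center fine-box center, Angstrom (e.g. the reference-ligand
#'   center of mass).
#' @param size fine-box edge, Angstrom.
#' @param spacing fine-grid spacing, Angstrom.
#' @param coarse_nodes node count per axis of the coarse grid.
#' @param coarse_size optional coarse-box edge, Angstrom; by default twice
#'   the molecular span (grown if needed to contain the fine box).
#' @param coarse_center optional coarse-box center; defaults to the
#'   molecular centroid.
#' @param ... passed to [solve_lpbe()] (tolerance, sweep cap).
#' @return the fine `potential_map` (kT/e); the coarse map is attached as
#'   attribute `coarse`.
#' @export
focus_solve <- function(problem, center, size = 30, spacing = 0.4,
                        coarse_nodes = 75, coarse_size = NULL,
                        coarse_center = NULL, ...) {
  stopifnot(nrow(problem$xyz) > 0)
  span <- max(apply(problem$xyz, 2, function(v) diff(range(v))) +
                2 * max(problem$radii))
  mol_center <- if (is.null(coarse_center)) colMeans(problem$xyz) else coarse_center
  fine_geom <- grid_geometry(center, size, spacing)
  fine_lo <- fine_geom$origin
  fine_hi <- fine_geom$origin + (fine_geom$dims - 1) * spacing
  if (is.null(coarse_size)) {
    ## protein occupies 50% of the coarse box; grow the box if needed so
    ## the fine box is strictly contained
    coarse_size <- 2 * span
    need <- 2 * max(abs(c(fine_lo - mol_center, fine_hi - mol_center)))
    coarse_size <- max(coarse_size, need + 4 * spacing)
  }
  coarse_geom <- grid_geometry(mol_center, coarse_size,
                               coarse_size / coarse_nodes)
  ## degenerate focusing: identical geometry needs no coarse pass
  if (isTRUE(all.equal(coarse_geom$origin, fine_geom$origin)) &&
      coarse_geom$spacing == fine_geom$spacing &&
      all(coarse_geom$dims == fine_geom$dims)) {
    return(solve_lpbe(problem, fine_geom, allow_outside = TRUE, ...))
  }
  coarse <- solve_lpbe(problem, coarse_geom, allow_outside = TRUE, ...)
  co_lo <- coarse_geom$origin
  co_hi <- coarse_geom$origin + (coarse_geom$dims - 1) * coarse_geom$spacing
  if (any(fine_lo < co_lo) || any(fine_hi > co_hi)) {
    stop("fine box is not contained in the coarse box")
  }
  fine <- solve_lpbe(problem, fine_geom, boundary = coarse,
                     allow_outside = TRUE, ...)
  attr(fine, "coarse") <- coarse
  fine
}
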