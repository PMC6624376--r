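## Receptor interaction grids and grid-interpolated binding energies.
##
## The binding energy scored during docking is
##   E_bind = sum_j q_j phi(r_j)
##          + sum_i sum_j [ A_ij/(r_ij^6 + d^6)^2 - B_ij/(r_ij^6 + d^6) ]
## with d = delta_vdw the soft-core smoothing length (d = 0 recovers the
## plain 6-12 potential) and geometric-mean combining A_ij = sqrt(A_i A_j),
## B_ij = sqrt(B_i B_j), where A_i = eps_i (2 r0_i)^12 and
## B_i = 2 eps_i (2 r0_i)^6.  Geometric combining makes the double sum
## separable, so the receptor side is pre-computed once per node:
##   Asum(r) = sum_i sqrt(A_i)/(r_i^6 + d^6)^2,
##   Bsum(r) = sum_i sqrt(B_i)/(r_i^6 + d^6),
## and a ligand atom j contributes sqrt(A_j) Asum - sqrt(B_j) Bsum.
## The electrostatic grid holds either the distance-dependent-dielectric
## Coulomb potential (eps = r, so phi = C sum q_i/r_i^2) or an imported /
## solved PB map converted to kcal/(mol e).

#' Per-atom Lennard-Jones coefficients
#'
#' `A_i = eps_i (2 r0_i)^12`, `B_i = 2 eps_i (2 r0_i)^6`; under
#' geometric-mean combining the like pair has its minimum at `2 r0_i` with
#' depth `eps_i`.
#'
#' @param r0 vdW radius (Rmin/2), Angstrom.
#' @param eps well depth, kcal/mol.
#' @return list with vectors `A` (kcal A^12/mol) and `B` (kcal A^6/mol).
#' @export
lj_coefficients <- function(r0, eps) {
  list(A = eps * (2 * r0)^12, B = 2 * eps * (2 * r0)^6)
}

#' Distance-dependent-dielectric Coulomb potential of a receptor
#'
#' With the dielectric set to the interatomic distance (eps = r) the
#' potential of charge `q_i` at distance `r_i` is `C q_i / r_i^2`,
#' `C = 332.0637` kcal A/(mol e^2).
#'
#' @param receptor a `molecule` (charges used; parameters not required).
#' @param pts n x 3 matrix of query points, Angstrom.
#' @param clamp distances below this value (Angstrom) are clamped before
#'   the division, which regularizes grid nodes that fall inside receptor
#'   atoms; use 0 to forbid near-coincident points instead.
#' @return potential in kcal/(mol e) at each point.
#' @export
coulomb_phi <- function(receptor, pts, clamp = 0) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  xyz <- coords(receptor)
  q <- receptor$atoms$charge
  phi <- numeric(nrow(pts))
  for (a in seq_len(nrow(xyz))) {
    d2 <- rowSums(sweep(pts, 2, xyz[a, ])^2)
    if (clamp > 0) {
      d2 <- pmax(d2, clamp^2)
    } else if (any(d2 < 1e-12)) {
      stop("query point coincides with a receptor atom")
    }
    phi <- phi + q[a] / d2
  }
  COULOMB_KCAL * phi
}

#' Pre-compute receptor interaction grids
#'
#' @param receptor parameterized `molecule`.
#' @param model `"coulomb"` (distance-dependent dielectric) or `"pb"`
#'   (potential taken from `pb_map`).
#' @param center box center, Angstrom.
#' @param size box edge, Angstrom (30 by default; with `spacing` 0.4 this
#'   gives 75 nodes per axis).
#' @param spacing node spacing, Angstrom.
#' @param delta_vdw soft-core smoothing length, Angstrom (>= 0).
#' @param pb_map `potential_map` in kT/e covering the box (required for
#'   `model = "pb"`), e.g. from [focus_solve()] or [read_dx()].
#' @param coulomb_clamp node-to-atom distance clamp for the Coulomb grid,
#'   Angstrom.
#' @param vdw_cap cap applied to the delta = 0 A/B node sums (nodes inside
#'   receptor atoms are never visited by accepted poses).
#' @return an object of class `interaction_grids` holding the phi grid
#'   (kcal/(mol e)) and the vdW A/B component grids on a common geometry.
#' @export
build_grids <- function(receptor, model = c("coulomb", "pb"), center,
                        size = 30, spacing = 0.4, delta_vdw = 0,
                        pb_map = NULL, coulomb_clamp = 0.5, vdw_cap = 1e12) {
  model <- match.arg(model)
  require_parameters(receptor, "receptor")
  stopifnot(delta_vdw >= 0)
  geom <- grid_geometry(center, size, spacing)
  ax <- grid_axes(geom)
  nodes <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))

  if (model == "pb") {
    if (is.null(pb_map)) stop("model = 'pb' requires a pb_map")
    kT <- kT_kcal()
    phiv <- map_interpolate(pb_map, nodes)
    if (anyNA(phiv)) stop("pb_map does not cover the grid box")
    phiv <- phiv * kT
  } else {
    phiv <- coulomb_phi(receptor, nodes, clamp = coulomb_clamp)
  }

  lj <- lj_coefficients(receptor$atoms$r0, receptor$atoms$eps)
  sqa <- sqrt(lj$A); sqb <- sqrt(lj$B)
  d6 <- delta_vdw^6
  xyz <- coords(receptor)
  asum <- numeric(nrow(nodes)); bsum <- numeric(nrow(nodes))
  for (a in seq_len(nrow(xyz))) {
    r6 <- rowSums(sweep(nodes, 2, xyz[a, ])^2)^3
    den <- r6 + d6
    asum <- asum + sqa[a] / den^2
    bsum <- bsum + sqb[a] / den
  }
  asum <- pmin(asum, vdw_cap)
  bsum <- pmin(bsum, sqrt(vdw_cap))

  new_interaction_grids(model, geom, delta_vdw,
                        array(phiv, dim = geom$dims),
                        array(asum, dim = geom$dims),
                        array(bsum, dim = geom$dims),
                        as.numeric(center))
}

## The A/B component fields vary as r^-24 and r^-12 near atoms, far too
## steep for accurate trilinear interpolation; their 8th and 2nd roots vary
## as ~r^-3, so interpolation is carried out on the root-transformed fields
## and the result is raised back.  Node values are exact either way.
new_interaction_grids <- function(model, geom, delta_vdw, phi, vdw_a, vdw_b,
                                  center) {
  structure(list(
    model = model, geom = geom, delta_vdw = delta_vdw,
    phi = phi, vdw_a = vdw_a, vdw_b = vdw_b,
    vdw_a_rt = vdw_a^(1 / 8), vdw_b_rt = sqrt(vdw_b),
    center = center
  ), class = "interaction_grids")
}

#' @export
print.interaction_grids <- function(x, ...) {
  cat(sprintf("<interaction grids (%s): %dx%dx%d @ %.2f A, delta_vdw = %.2f A>\n",
              x$model, x$geom$dims[1], x$geom$dims[2], x$geom$dims[3],
              x$geom$spacing, x$delta_vdw))
  invisible(x)
}

#' Interpolate the interaction grids at arbitrary points
#'
#' The electrostatic grid is interpolated trilinearly; the vdW component
#' sums are interpolated on their 8th-/2nd-root transforms (which vary as
#' ~1/r^3 instead of 1/r^24 and 1/r^12 near atoms) and raised back, which
#' keeps node values exact and sharpens off-node accuracy near the
#' repulsive wall.
#'
#' @param gridset an `interaction_grids` object.
#' @param pts n x 3 matrix, Angstrom.
#' @return matrix with columns `phi`, `asum`, `bsum`; rows of `NA` flag
#'   out-of-grid points (the caller applies the out-of-box penalty).
#' @export
interpolate_grids <- function(gridset, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  g <- gridset$geom
  cbind(
    phi = trilinear_array(gridset$phi, g$origin, g$spacing, g$dims, pts),
    asum = trilinear_array(gridset$vdw_a_rt, g$origin, g$spacing,
                           g$dims, pts)^8,
    bsum = trilinear_array(gridset$vdw_b_rt, g$origin, g$spacing,
                           g$dims, pts)^2
  )
}

#' Grid-interpolated binding energy of a ligand pose
#'
#' @param gridset an `interaction_grids` object.
#' @param ligand parameterized `molecule`.
#' @param xyz optional pose coordinates (defaults to the ligand's own).
#' @param out_penalty energy added per out-of-grid atom, kcal/mol.
#' @return named vector `E_elec`, `E_vdw`, `E_total` in kcal/mol
#'   (`E_total = E_elec + E_vdw` exactly; the out-of-box penalty is booked
#'   under `E_vdw`).
#' @export
grid_energy <- function(gridset, ligand, xyz = NULL, out_penalty = 1e6) {
  require_parameters(ligand, "ligand")
  if (is.null(xyz)) xyz <- coords(ligand)
  vals <- interpolate_grids(gridset, xyz)
  out <- is.na(vals[, 1])
  q <- ligand$atoms$charge
  lj <- lj_coefficients(ligand$atoms$r0, ligand$atoms$eps)
  sqa <- sqrt(lj$A); sqb <- sqrt(lj$B)
  e_elec <- sum(q[!out] * vals[!out, "phi"])
  e_vdw <- sum(sqa[!out] * vals[!out, "asum"] - sqb[!out] * vals[!out, "bsum"]) +
    out_penalty * sum(out)
  c(E_elec = e_elec, E_vdw = e_vdw, E_total = e_elec + e_vdw)
}

#' Serialize interaction grids to OpenDX files plus a metadata sidecar
#'
#' Writes `<prefix>.phi.dx`, `<prefix>.vdwa.dx`, `<prefix>.vdwb.dx` and a
#' JSON sidecar `<prefix>.json` recording the model, soft-core length and
#' geometry.
#'
#' @param gridset an `interaction_grids` object.
#' @param prefix output path prefix.
#' @return the sidecar path, invisibly.
#' @export
write_grids <- function(gridset, prefix) {
  g <- gridset$geom
  as_map <- function(v) potential_map(g$origin, g$spacing, v, "kcal/(mol e)")
  write_dx(as_map(gridset$phi), paste0(prefix, ".phi.dx"))
  write_dx(as_map(gridset$vdw_a), paste0(prefix, ".vdwa.dx"))
  write_dx(as_map(gridset$vdw_b), paste0(prefix, ".vdwb.dx"))
  meta <- list(model = gridset$model, delta_vdw = gridset$delta_vdw,
               coulomb_constant = COULOMB_KCAL, origin = g$origin,
               spacing = g$spacing, dims = g$dims, center = gridset$center)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(prefix, ".json"))
}

#' Load interaction grids written by [write_grids()]
#' @param prefix path prefix used when writing.
#' @return an `interaction_grids` object.
#' @export
read_grids <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  phi <- read_dx(paste0(prefix, ".phi.dx"), units = "kcal/(mol e)")
  va <- read_dx(paste0(prefix, ".vdwa.dx"))
  vb <- read_dx(paste0(prefix, ".vdwb.dx"))
  geom <- list(origin = phi$origin, spacing = phi$spacing, dims = phi$dims)
  new_interaction_grids(meta$model, geom, meta$delta_vdw, phi$values,
                        va$values, vb$values, as.numeric(meta$center))
}
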