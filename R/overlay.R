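## Gaussian shape-and-charge overlay.
##
## Each atom i is described by an isotropic Gaussian density
##   rho_i(r) = p_i exp(-alpha_i |r - r_i|^2),
## with amplitude p_i = 2*sqrt(2) and exponent
##   alpha_i = pi * (3 p_i / (4 pi sigma_i^3))^(2/3),
## where sigma_i is the atom's vdW radius.  With this amplitude the Gaussian
## carries the volume of the vdW hard sphere.  The overlap volume between two
## molecules is the double sum of closed-form Gaussian pair integrals over a
## shape channel (all atoms) plus positive- and negative-charge channels
## (atoms partitioned by the sign of their partial charge), each channel
## weighted by w (1.0 by default).  The Hodgkin similarity index normalizes
## the overlap by the self-overlaps: SI = 2 V_AB / (V_AA + V_BB).

GAUSSIAN_AMPLITUDE <- 2 * sqrt(2)

#' Gaussian exponent for an atomic density
#'
#' @param sigma vdW radius, Angstrom.
#' @param p Gaussian amplitude (dimensionless).
#' @return exponent alpha in 1/Angstrom^2 such that the Gaussian
#'   `p exp(-alpha r^2)` integrates to the volume of the radius-`sigma`
#'   sphere.
#' @export
gaussian_exponent <- function(sigma, p = GAUSSIAN_AMPLITUDE) {
  stopifnot(all(sigma > 0))
  pi * (3 * p / (4 * pi * sigma^3))^(2 / 3)
}

#' Closed-form overlap volume of two atomic Gaussians
#'
#' @param p_i,p_j amplitudes.
#' @param alpha_i,alpha_j exponents, 1/Angstrom^2.
#' @param d center-center distance, Angstrom (vectorized).
#' @return overlap volume(s), Angstrom^3:
#'   `p_i p_j (pi/(alpha_i+alpha_j))^(3/2) exp(-alpha_i alpha_j d^2/(alpha_i+alpha_j))`.
#' @export
atom_pair_overlap <- function(p_i, alpha_i, p_j, alpha_j, d) {
  if (any(alpha_i <= 0) || any(alpha_j <= 0)) stop("Gaussian exponents must be positive")
  if (any(d < 0)) stop("negative distance")
  s <- alpha_i + alpha_j
  p_i * p_j * (pi / s)^1.5 * exp(-alpha_i * alpha_j * d^2 / s)
}

## Per-molecule Gaussian description: amplitudes, exponents and channel
## membership.  Channel "shape" holds every atom; charge channels partition
## atoms by sign of q (zero-charge atoms belong to neither).
gaussian_shape <- function(mol) {
  require_parameters(mol)
  list(
    xyz = coords(mol),
    p = rep(GAUSSIAN_AMPLITUDE, n_atoms(mol)),
    alpha = gaussian_exponent(mol$atoms$r0),
    pos = which(mol$atoms$charge > 0),
    neg = which(mol$atoms$charge < 0)
  )
}

channel_overlap <- function(sa, xyz_a, sb, xyz_b, ia, ib) {
  if (length(ia) == 0 || length(ib) == 0) return(0)
  d2 <- outer(rowSums(xyz_a[ia, , drop = FALSE]^2),
              rowSums(xyz_b[ib, , drop = FALSE]^2), "+") -
    2 * xyz_a[ia, , drop = FALSE] %*% t(xyz_b[ib, , drop = FALSE])
  d2[d2 < 0] <- 0
  s <- outer(sa$alpha[ia], sb$alpha[ib], "+")
  pp <- outer(sa$p[ia], sb$p[ib])
  sum(pp * (pi / s)^1.5 * exp(-outer(sa$alpha[ia], sb$alpha[ib]) * d2 / s))
}

#' Gaussian overlap volume between two molecules
#'
#' @param a,b parameterized `molecule` objects.
#' @param transform optional `rigid_transform` applied to `b` before the
#'   overlap is computed.
#' @param w channel weights, named `shape`, `pos`, `neg` (dimensionless,
#'   all 1 by default).
#' @return overlap volume V_AB in Angstrom^3 (shape channel plus weighted
#'   sign-matched charge channels).
#' @export
overlap_volume <- function(a, b, transform = NULL,
                           w = c(shape = 1, pos = 1, neg = 1)) {
  sa <- gaussian_shape(a)
  sb <- gaussian_shape(b)
  xyz_b <- if (is.null(transform)) sb$xyz else apply_transform(transform, sb$xyz)
  all_a <- seq_len(nrow(sa$xyz)); all_b <- seq_len(nrow(sb$xyz))
  w[["shape"]] * channel_overlap(sa, sa$xyz, sb, xyz_b, all_a, all_b) +
    w[["pos"]] * channel_overlap(sa, sa$xyz, sb, xyz_b, sa$pos, sb$pos) +
    w[["neg"]] * channel_overlap(sa, sa$xyz, sb, xyz_b, sa$neg, sb$neg)
}

#' Hodgkin similarity index
#'
#' `SI = 2 V_AB / (V_AA + V_BB)` with the self-overlaps taken at identity;
#' 1 for identical shapes in identical poses, near 0 for disjoint shapes.
#'
#' @inheritParams overlap_volume
#' @return similarity in `[0, 1]`.
#' @export
hodgkin_similarity <- function(a, b, transform = NULL,
                               w = c(shape = 1, pos = 1, neg = 1)) {
  if (n_atoms(a) == 0 && n_atoms(b) == 0) stop("both molecules are empty")
  vaa <- overlap_volume(a, a, NULL, w)
  vbb <- overlap_volume(b, b, NULL, w)
  if (vaa + vbb <= 0) stop("degenerate self-overlap")
  2 * overlap_volume(a, b, transform, w) / (vaa + vbb)
}

## Deterministic principal-axes starts: align mobile centroid+axes onto the
## target's, over the four proper sign flips of the eigenvector frame.
axis_starts <- function(xyz_mobile, xyz_target) {
  frame <- function(xyz) {
    c0 <- colMeans(xyz)
    xc <- sweep(xyz, 2, c0)
    ev <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)$vectors
    if (det(ev) < 0) ev[, 3] <- -ev[, 3]
    list(center = c0, axes = ev)
  }
  fm <- frame(xyz_mobile); ft <- frame(xyz_target)
  flips <- list(diag(3), diag(c(1, -1, -1)), diag(c(-1, 1, -1)), diag(c(-1, -1, 1)))
  lapply(flips, function(S) {
    R <- ft$axes %*% S %*% t(fm$axes)
    rigid_transform(matrix_to_quaternion(R), ft$center - fm$center, fm$center)
  })
}

#' Optimize the Gaussian overlay of one molecule onto another
#'
#' Maximizes the overlap volume V_AB over the six rigid degrees of freedom of
#' the mobile molecule with a seeded multi-start strategy: principal-axes /
#' centroid alignments plus randomized rotations, each refined by a
#' quasi-Newton ascent. Deterministic for a fixed seed.
#'
#' @param mobile parameterized `molecule` to be moved (the search ligand).
#' @param target parameterized `molecule` held fixed (the reference ligand).
#' @param seed integer seed for the randomized starts.
#' @param n_random number of random-rotation starts added to the
#'   deterministic principal-axes starts.
#' @param w channel weights as in [overlap_volume()].
#' @return list of class `overlay_result`: `transform` (best
#'   `rigid_transform` for `mobile`), `V_AB` (Angstrom^3), `SI` (Hodgkin
#'   similarity at the returned transform).
#' @export
optimize_overlay <- function(mobile, target, seed = 1, n_random = 8,
                             w = c(shape = 1, pos = 1, neg = 1)) {
  require_parameters(mobile, "mobile molecule")
  require_parameters(target, "target molecule")
  sm <- gaussian_shape(mobile)
  st <- gaussian_shape(target)
  cm <- colMeans(sm$xyz)

  objective <- function(par) {
    tr <- rigid_transform(par[1:4], par[5:7], cm)
    xyz_b <- apply_transform(tr, sm$xyz)
    all_t <- seq_len(nrow(st$xyz)); all_m <- seq_len(nrow(sm$xyz))
    v <- w[["shape"]] * channel_overlap(st, st$xyz, sm, xyz_b, all_t, all_m) +
      w[["pos"]] * channel_overlap(st, st$xyz, sm, xyz_b, st$pos, sm$pos) +
      w[["neg"]] * channel_overlap(st, st$xyz, sm, xyz_b, st$neg, sm$neg)
    if (!is.finite(v)) stop("overlay objective evaluated to a non-finite value")
    -v
  }

  starts <- axis_starts(sm$xyz, st$xyz)
  starts <- c(starts, list(rigid_transform(c(1, 0, 0, 0),
                                           colMeans(st$xyz) - cm, cm)))
  with_seed(seed, {
    if (n_random > 0) {
      qs <- random_unit_quaternion(n_random)
      for (k in seq_len(n_random)) {
        starts[[length(starts) + 1]] <-
          rigid_transform(qs[k, ], colMeans(st$xyz) - cm, cm)
      }
    }
    best <- NULL
    for (s in starts) {
      fit <- optim(c(s$q, s$t), objective, method = "BFGS",
                   control = list(maxit = 200, reltol = 1e-10))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    tr <- rigid_transform(best$par[1:4], best$par[5:7], cm)
    structure(list(transform = tr, V_AB = -best$value,
                   SI = hodgkin_similarity(target, mobile, tr, w)),
              class = "overlay_result")
  })
}

#' @export
print.overlay_result <- function(x, ...) {
  cat(sprintf("<overlay: V_AB = %.3f A^3, SI = %.4f>\n", x$V_AB, x$SI))
  print(x$transform)
  invisible(x)
}
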