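## Seeded synthetic fixtures: toy ligands, concave receptor "pockets",
## redocking pairs, and active/decoy screening sets.
##
## Pseudo-atoms carry real force-field parameters (carbon-, nitrogen- and
## oxygen-like SYBYL types) so that energies are physically scaled, but no
## chemical realism is attempted: bonds are decorative.  A pocket is a
## hemispherical shell of atoms built around a native ligand, each shell
## atom placed along a ray from the ligand centroid at exactly the
## Lennard-Jones pair-minimum distance (2 sqrt(r0_i r0_j) under
## geometric-mean combining) from its nearest ligand atom, so the native
## pose sits near the energy minimum by construction.  The shell leaves a
## conical opening (the "mouth" of the site); optionally a cluster of
## charged decoy atoms is planted outside the mouth to emulate the
## non-specific electrostatic traps that an unscreened Coulomb model
## overweights.

#' Fixture specification
#'
#' @param seed master integer seed; all generators are pure functions of
#'   the spec.
#' @param pocket_atoms shell atom count.
#' @param ligand_atoms native-ligand atom count (>= 4).
#' @param pocket_charge magnitude (e) of the complementary charge pairs
#'   planted in the shell (two positive and two negative shell atoms).
#' @param decoy_site number of charged decoy atoms outside the pocket
#'   mouth (0 for the standard family).
#' @param decoy_site_charge per-atom charge (e) of the decoy site.
#' @param n_active active count for screening sets.
#' @param decoy_ratio decoys per active (33 mirrors a typical benchmark
#'   decoy-to-ligand ratio).
#' @param decoy_charge_fractions named fractions over decoy net charges;
#'   the default (66% at 0 e, 30% at -1 e, 4% at -2 e) mirrors the net
#'   charges typical of actual binders.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, pocket_atoms = 40, ligand_atoms = 8,
                         pocket_charge = 0.5, decoy_site = 0,
                         decoy_site_charge = -0.8, n_active = 3,
                         decoy_ratio = 33,
                         decoy_charge_fractions = c("0" = 0.66, "-1" = 0.30,
                                                    "-2" = 0.04, "-3" = 0)) {
  stopifnot(pocket_atoms > 0, ligand_atoms >= 4, n_active > 0,
            decoy_ratio > 0,
            abs(sum(decoy_charge_fractions) - 1) < 1e-9)
  structure(list(seed = as.integer(seed), pocket_atoms = pocket_atoms,
                 ligand_atoms = ligand_atoms, pocket_charge = pocket_charge,
                 decoy_site = decoy_site,
                 decoy_site_charge = decoy_site_charge,
                 n_active = n_active, decoy_ratio = decoy_ratio,
                 decoy_charge_fractions = decoy_charge_fractions),
            class = "fixture_spec")
}

## Compact random atom cluster grown by sequential attachment at ~1.5 A
## with a 1.35 A clash floor.  Assumes an active RNG stream.
random_cluster_xyz <- function(n) {
  xyz <- matrix(0, nrow = n, ncol = 3)
  for (i in seq_len(n)[-1]) {
    repeat {
      anchor <- xyz[sample(i - 1, 1), ]
      dir <- rnorm(3)
      cand <- anchor + 1.5 * dir / sqrt(sum(dir^2))
      d <- sqrt(rowSums(sweep(xyz[seq_len(i - 1), , drop = FALSE], 2, cand)^2))
      if (all(d > 1.35)) break
    }
    xyz[i, ] <- cand
  }
  sweep(xyz, 2, colMeans(xyz))
}

#' Generate a synthetic ligand
#'
#' A compact cluster of parameterized pseudo-atoms: carbon scaffold with
#' one oxygen-like (negative) and one nitrogen-like (positive) site of
#' magnitude `charge_magnitude`, yielding a neutral molecule by default;
#' `net_charge` overrides the charge layout (spread in 0.5 e increments
#' over nitrogen- or oxygen-like atoms).
#'
#' @param spec a `fixture_spec` (atom count, seed policy).
#' @param seed overriding seed (defaults to the spec's).
#' @param net_charge target net charge, e.
#' @param charge_magnitude site charge magnitude for the neutral layout, e.
#' @return a parameterized `molecule`.
#' @export
make_ligand <- function(spec = fixture_spec(), seed = spec$seed,
                        net_charge = 0, charge_magnitude = 0.5) {
  n <- spec$ligand_atoms
  with_seed(seed, {
    xyz <- random_cluster_xyz(n)
    types <- rep("C.3", n)
    charges <- rep(0, n)
    if (net_charge == 0) {
      types[n - 1] <- "O.2"; charges[n - 1] <- -charge_magnitude
      types[n] <- "N.3"; charges[n] <- charge_magnitude
    } else {
      k <- max(1L, ceiling(abs(net_charge) / 0.5))
      k <- min(k, n)
      per <- net_charge / k
      idx <- seq(n, by = -1L, length.out = k)
      types[idx] <- if (net_charge > 0) "N.4" else "O.co2"
      charges[idx] <- per
    }
    atoms <- data.frame(name = paste0(sub("\\..*", "", types), seq_len(n)),
                        type = types, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        charge = charges, stringsAsFactors = FALSE)
    bonds <- cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
    assign_vdw_parameters(molecule(sprintf("ligand_s%d", seed), atoms, bonds))
  })
}

#' Generate a synthetic receptor pocket
#'
#' @param spec a `fixture_spec`.
#' @param ligand native ligand to wrap (generated from the spec when
#'   `NULL`).
#' @param max_attempts rejection-sampling budget; exhausted attempts at the
#'   requested density raise an error.
#' @return a parameterized pocket `molecule`; the native ligand is attached
#'   as attribute `native_ligand` and decoy-site atom indices (if any) as
#'   attribute `decoy_site`.
#' @export
make_pocket <- function(spec = fixture_spec(), ligand = NULL,
                        max_attempts = 20000) {
  if (is.null(ligand)) ligand <- make_ligand(spec)
  require_parameters(ligand)
  lig_center <- colMeans(coords(ligand))
  lig_xyz <- sweep(coords(ligand), 2, lig_center)  # rays leave the centroid
  lig_r0 <- ligand$atoms$r0
  rec_r0 <- 1.9080  # C.3 shell
  with_seed(spec$seed + 1000L, {
    placed <- matrix(numeric(0), ncol = 3)
    attempts <- 0
    while (nrow(placed) < spec$pocket_atoms) {
      attempts <- attempts + 1
      if (attempts > max_attempts) {
        stop("infeasible pocket geometry: could not place ",
             spec$pocket_atoms, " atoms without overlap")
      }
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      if (u[3] > 0.45) next  # leave the mouth open
      contact <- 2 * sqrt(lig_r0 * rec_r0)
      b <- lig_xyz %*% u
      a <- rowSums(lig_xyz^2)
      disc <- b^2 - (a - contact^2)
      ok <- disc >= 0
      if (!any(ok)) next
      t_exit <- max(b[ok] + sqrt(disc[ok]))
      cand <- t_exit * u
      if (nrow(placed) > 0) {
        d <- sqrt(rowSums(sweep(placed, 2, cand)^2))
        if (any(d < 1.5)) next
      }
      placed <- rbind(placed, as.numeric(cand))
    }
    n <- nrow(placed)
    types <- rep("C.3", n)
    charges <- rep(0, n)
    ## complementary polar pairs: shell atoms nearest the ligand's charged
    ## sites take the opposite charge
    qlig <- ligand$atoms$charge
    take <- function(target_xyz, q, k = 2) {
      d <- sqrt(rowSums(sweep(placed, 2, target_xyz)^2))
      free <- which(charges == 0)
      sel <- free[order(d[free])][seq_len(min(k, length(free)))]
      charges[sel] <<- q
      types[sel] <<- if (q > 0) "N.3" else "O.2"
    }
    if (any(qlig < 0)) {
      take(lig_xyz[which.min(qlig), ], spec$pocket_charge)
    }
    if (any(qlig > 0)) {
      take(lig_xyz[which.max(qlig), ], -spec$pocket_charge)
    }
    build_mol <- function(xyz, types, charges) {
      xyz <- sweep(xyz, 2, lig_center, FUN = "+")
      atoms <- data.frame(name = paste0("P", seq_len(nrow(xyz))),
                          type = types, x = xyz[, 1], y = xyz[, 2],
                          z = xyz[, 3], charge = charges,
                          stringsAsFactors = FALSE)
      assign_vdw_parameters(molecule(sprintf("pocket_s%d", spec$seed), atoms))
    }
    ## the native pose is the nearby local minimum of the grid-free
    ## reference force field against the native site alone (the synthetic
    ## analogue of a crystal pose sitting at a minimum of the physics);
    ## the decoy trap is appended afterwards so it cannot displace it
    native <- relax_native_pose(build_mol(placed, types, charges), ligand)
    decoy_idx <- integer(0)
    if (spec$decoy_site > 0) {
      ## charged cluster outside the pocket mouth, reachable by a ligand
      ## that abandons the site
      top <- max(lig_xyz[, 3])
      ctr <- c(0, 0, top + 6)
      for (k in seq_len(spec$decoy_site)) {
        ang <- 2 * pi * (k - 1) / spec$decoy_site
        placed <- rbind(placed, ctr + 1.8 * c(cos(ang), sin(ang), 0))
        types <- c(types, "O.co2")
        charges <- c(charges, spec$decoy_site_charge)
        decoy_idx <- c(decoy_idx, nrow(placed))
      }
    }
    pocket <- build_mol(placed, types, charges)
    attr(pocket, "native_ligand") <- native
    attr(pocket, "decoy_site") <- decoy_idx
    pocket
  })
}

## Rigid-body local minimization of the ligand in the pocket's grid-free
## Coulomb (eps = r) / 6-12 reference energy; deterministic.
relax_native_pose <- function(pocket, ligand) {
  xyz0 <- coords(ligand)
  c0 <- colMeans(xyz0)
  obj <- function(par) {
    xyz <- pose_coords(par, xyz0, c0)
    unname(direct_energy(pocket, ligand, xyz, model = "coulomb",
                         delta_vdw = 0)[["E_total"]])
  }
  fit <- optim(c(1, 0, 0, 0, c0), obj, method = "Nelder-Mead",
               control = list(maxit = 600, reltol = 1e-12))
  set_coords(ligand, pose_coords(fit$par, xyz0, c0))
}

#' Displaced copy of a ligand for redocking tests
#'
#' @param ligand a `molecule`.
#' @param seed integer seed.
#' @param min_translation,max_translation displacement magnitude bounds,
#'   Angstrom.
#' @return list with `reference` (the input), `displaced` (randomly
#'   rotated about its centroid and translated), and the ground-truth
#'   `transform`.
#' @export
make_redock_pair <- function(ligand, seed = 1, min_translation = 2,
                             max_translation = 5) {
  stopifnot(n_atoms(ligand) > 0)
  with_seed(seed, {
    q <- as.numeric(random_unit_quaternion(1))
    dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    mag <- runif(1, min_translation, max_translation)
    tr <- rigid_transform(q, mag * dir, colMeans(coords(ligand)))
    list(reference = ligand, displaced = apply_transform(tr, ligand),
         transform = tr)
  })
}

#' Generate an active/decoy screening set
#'
#' Actives are jittered copies of the pocket's native ligand (shape- and
#' charge-complementary by construction); decoys are independent random
#' clusters of matched size with net charges drawn from the spec's
#' distribution.
#'
#' @param spec a `fixture_spec`.
#' @param pocket pocket generated from the spec (built on demand when
#'   `NULL`); supplies the native ligand.
#' @return list with `actives` and `decoys` (lists of parameterized
#'   molecules), `labels`, and the decoy net charges drawn.
#' @export
make_screen_set <- function(spec = fixture_spec(), pocket = NULL) {
  if (is.null(pocket)) pocket <- make_pocket(spec)
  native <- attr(pocket, "native_ligand")
  n_dec <- spec$n_active * spec$decoy_ratio
  with_seed(spec$seed + 2000L, {
    actives <- lapply(seq_len(spec$n_active), function(i) {
      m <- set_coords(native, coords(native) + matrix(rnorm(3 * n_atoms(native),
                                                            sd = 0.15),
                                                      ncol = 3))
      m$name <- sprintf("active_%02d", i)
      m
    })
    qlevels <- as.numeric(names(spec$decoy_charge_fractions))
    qdraw <- sample(qlevels, n_dec, replace = TRUE,
                    prob = spec$decoy_charge_fractions)
    decoy_seeds <- sample.int(.Machine$integer.max %/% 2, n_dec)
    decoys <- lapply(seq_len(n_dec), function(i) {
      m <- make_ligand(spec, seed = decoy_seeds[i], net_charge = qdraw[i])
      m$name <- sprintf("decoy_%03d", i)
      m
    })
    list(actives = actives, decoys = decoys,
         labels = c(rep("active", length(actives)),
                    rep("decoy", length(decoys))),
         decoy_net_charges = qdraw)
  })
}
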