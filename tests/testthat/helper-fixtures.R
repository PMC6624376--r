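# Shared in-code fixtures for the suite.

water_mol2_text <- function() {
  at <- data.frame(name = c("O1", "H1", "H2"), type = c("O.3", "H", "H"),
                   x = c(0, 0.9572, -0.2400), y = c(0, 0, 0.9266),
                   z = c(0, 0, 0),
                   charge = c(-0.8340, 0.4170, 0.4170),
                   stringsAsFactors = FALSE)
  write_mol2(molecule("water", at, cbind(c(1, 1), c(2, 3))))
}

# small parameterized molecule with mixed charges
toy_molecule <- function(name = "toy", shift = c(0, 0, 0)) {
  at <- data.frame(
    name = c("C1", "C2", "O1", "N1"),
    type = c("C.3", "C.3", "O.2", "N.3"),
    x = c(0, 1.5, 2.2, -0.9) + shift[1],
    y = c(0, 0.2, 1.2, 1.1) + shift[2],
    z = c(0, 0.1, -0.4, 0.5) + shift[3],
    charge = c(0, 0.1, -0.5, 0.4),
    stringsAsFactors = FALSE
  )
  assign_vdw_parameters(molecule(name, at))
}

# single-atom parameterized molecule
one_atom <- function(xyz = c(0, 0, 0), type = "C.3", charge = 0) {
  at <- data.frame(name = "X1", type = type, x = xyz[1], y = xyz[2],
                   z = xyz[3], charge = charge, stringsAsFactors = FALSE)
  assign_vdw_parameters(molecule("one", at))
}

# clash-free rigid perturbations of the native pose: random small rotation +
# translation, kept only when no receptor-ligand pair compresses below 92%
# of its LJ contact distance (poses docking would accept)
perturbed_poses <- function(pocket, lig, n = 8, seed = 17,
                            rot_sd = 0.03, trans_sd = 0.1) {
  rx <- coords(pocket)
  contact <- outer(pocket$atoms$r0, lig$atoms$r0,
                   function(a, b) 2 * sqrt(a * b))
  x0 <- coords(lig)
  c0 <- colMeans(x0)
  poses <- list()
  set.seed(seed)
  while (length(poses) < n) {
    q <- c(1, rnorm(3, sd = rot_sd)); q <- q / sqrt(sum(q^2))
    jit <- sweep(sweep(x0, 2, c0) %*% t(quaternion_to_matrix(q)), 2,
                 c0 + rnorm(3, sd = trans_sd), FUN = "+")
    d <- sqrt(outer(rowSums(rx^2), rowSums(jit^2), "+") - 2 * rx %*% t(jit))
    if (min(d / contact) >= 0.92) poses[[length(poses) + 1]] <- jit
  }
  poses
}

# cached standard pocket + coulomb grids (built once per test run)
std_pocket_env <- new.env(parent = emptyenv())
std_pocket <- function(seed = 3) {
  key <- paste0("p", seed)
  if (is.null(std_pocket_env[[key]])) {
    spec <- fixture_spec(seed = seed, pocket_atoms = 35)
    pocket <- make_pocket(spec)
    lig <- attr(pocket, "native_ligand")
    gs <- build_grids(pocket, "coulomb", center = colMeans(coords(lig)),
                      delta_vdw = 0)
    std_pocket_env[[key]] <- list(pocket = pocket, ligand = lig, grids = gs)
  }
  std_pocket_env[[key]]
}
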