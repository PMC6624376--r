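## Docking pipeline: Gaussian-overlay initialization followed by seeded
## global minimization of the grid-interpolated binding energy over the six
## rigid-body degrees of freedom (unit quaternion + centroid translation).
## The search is differential evolution with the overlay pose injected into
## the initial population, followed by a local simplex polish of both the
## overlay pose and the best evolved member; the lower-energy result is
## returned, so the final energy never exceeds the initial one.

#' Docking configuration
#'
#' @param model electrostatic model, `"coulomb"` or `"pb"` (recorded for
#'   bookkeeping; the model actually scored is the one baked into the grid
#'   set).
#' @param delta_vdw soft-core smoothing length, Angstrom.
#' @param box_size,spacing grid geometry, Angstrom.
#' @param seed integer seed controlling overlay starts and the evolutionary
#'   search.
#' @param pop_size differential-evolution population size.
#' @param generations differential-evolution generation count.
#' @param trans_bound half-width of the translation search box around the
#'   reference centroid, Angstrom; default `box_size/2 - 2`.
#' @param f,cr differential-evolution mutation weight and crossover rate.
#' @return an object of class `docking_config`.
#' @export
docking_config <- function(model = c("coulomb", "pb"), delta_vdw = 0,
                           box_size = 30, spacing = 0.4, seed = 1,
                           pop_size = 30, generations = 120,
                           trans_bound = NULL, f = 0.7, cr = 0.9) {
  model <- match.arg(model)
  stopifnot(delta_vdw >= 0, pop_size >= 5, generations >= 1)
  if (is.null(trans_bound)) trans_bound <- box_size / 2 - 2
  structure(list(model = model, delta_vdw = delta_vdw, box_size = box_size,
                 spacing = spacing, seed = as.integer(seed),
                 pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 trans_bound = trans_bound, f = f, cr = cr),
            class = "docking_config")
}

## Pose parameterization: par = (q1..q4, cx, cy, cz); ligand is rotated
## about its input centroid and the centroid is moved to c.
pose_coords <- function(par, xyz0, centroid0) {
  R <- quaternion_to_matrix(par[1:4])
  sweep(sweep(xyz0, 2, centroid0) %*% t(R), 2, par[5:7], FUN = "+")
}

de_minimize <- function(objective, init_par, lower_c, upper_c, config) {
  np <- config$pop_size
  pop <- matrix(0, nrow = np, ncol = 7)
  pop[1, ] <- init_par
  if (np > 1) {
    qs <- random_unit_quaternion(np - 1)
    pop[-1, 1:4] <- qs
    for (d in 1:3) {
      pop[-1, 4 + d] <- runif(np - 1, lower_c[d], upper_c[d])
    }
  }
  cost <- apply(pop, 1, objective)
  for (gen in seq_len(config$generations)) {
    for (i in seq_len(np)) {
      idx <- sample(setdiff(seq_len(np), i), 3)
      trial <- pop[idx[1], ] + config$f * (pop[idx[2], ] - pop[idx[3], ])
      keep <- runif(7) > config$cr
      keep[sample(7, 1)] <- FALSE
      trial[keep] <- pop[i, keep]
      nq <- sqrt(sum(trial[1:4]^2))
      if (nq < 1e-8) trial[1:4] <- c(1, 0, 0, 0) else trial[1:4] <- trial[1:4] / nq
      trial[5:7] <- pmin(pmax(trial[5:7], lower_c), upper_c)
      tc <- objective(trial)
      if (tc <= cost[i]) {
        pop[i, ] <- trial
        cost[i] <- tc
      }
    }
  }
  best <- which.min(cost)
  list(par = pop[best, ], value = cost[best])
}

polish <- function(objective, par) {
  fit <- optim(par, objective, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-10))
  fit
}

#' Dock a ligand into pre-computed receptor grids
#'
#' The search ligand is first overlaid onto the reference ligand by Gaussian
#' shape-and-charge similarity, then the grid-interpolated binding energy is
#' minimized globally over rigid-body poses. Deterministic for a fixed seed.
#'
#' @param receptor parameterized receptor `molecule` (recorded in the
#'   result; the energetics come from `gridset`).
#' @param search_ligand parameterized `molecule` to dock.
#' @param reference_ligand parameterized `molecule` marking the binding
#'   mode (must sit inside the grid box).
#' @param gridset `interaction_grids` built for the receptor with the
#'   config's model and `delta_vdw`.
#' @param config a `docking_config`.
#' @return an object of class `docking_result` with the initial
#'   (overlay) and final poses, their energies, and the overlay similarity.
#' @export
dock <- function(receptor, search_ligand, reference_ligand, gridset, config) {
  require_parameters(search_ligand, "search ligand")
  require_parameters(reference_ligand, "reference ligand")
  ref_xyz <- coords(reference_ligand)
  if (anyNA(interpolate_grids(gridset, ref_xyz)[, 1])) {
    stop("reference ligand lies (partly) outside the grid box")
  }
  overlay <- optimize_overlay(search_ligand, reference_ligand,
                              seed = config$seed)
  xyz0 <- coords(search_ligand)
  centroid0 <- colMeans(xyz0)
  init_xyz <- apply_transform(overlay$transform, xyz0)
  if (all(is.na(interpolate_grids(gridset, init_xyz)[, 1]))) {
    stop("overlay-initialized pose is entirely outside the grid box")
  }
  e_init <- grid_energy(gridset, search_ligand, init_xyz)

  ref_c <- colMeans(ref_xyz)
  lower_c <- ref_c - config$trans_bound
  upper_c <- ref_c + config$trans_bound
  objective <- function(par) {
    unname(grid_energy(gridset, search_ligand,
                       pose_coords(par, xyz0, centroid0))["E_total"])
  }
  init_par <- c(overlay$transform$q, colMeans(init_xyz))

  fit <- with_seed(config$seed, {
    de <- de_minimize(objective, init_par, lower_c, upper_c, config)
    cand <- list(polish(objective, de$par), polish(objective, init_par),
                 list(par = init_par, value = e_init[["E_total"]]))
    cand[[which.min(vapply(cand, `[[`, numeric(1), "value"))]]
  })

  final_xyz <- pose_coords(fit$par, xyz0, centroid0)
  e_final <- grid_energy(gridset, search_ligand, final_xyz)
  structure(list(
    initial = list(par = init_par, xyz = init_xyz, energy = e_init),
    final = list(par = fit$par, xyz = final_xyz, energy = e_final),
    SI = overlay$SI, overlay = overlay, config = config,
    ligand_name = search_ligand$name
  ), class = "docking_result")
}

#' @export
print.docking_result <- function(x, ...) {
  cat(sprintf("<dock '%s': E_total %.3f -> %.3f kcal/mol (SI %.3f)>\n",
              x$ligand_name, x$initial$energy[["E_total"]],
              x$final$energy[["E_total"]], x$SI))
  invisible(x)
}

#' Screen a compound list against a receptor
#'
#' Each compound is docked independently with the same configuration and
#' seed policy, then ranked by ascending final energy (ties broken by input
#' order). Individual failures are recorded, not fatal.
#'
#' @inheritParams dock
#' @param compounds list of parameterized `molecule` objects.
#' @param labels optional character vector (e.g. `"active"`/`"decoy"`)
#'   carried into the ranking table.
#' @return an object of class `ranked_screen`: a data.frame with columns
#'   `compound`, `label`, `net_charge`, `E_elec`, `E_vdw`, `E_total`,
#'   `rank`, plus a `results` attribute holding the docking results.
#' @export
screen <- function(receptor, reference_ligand, compounds, gridset, config,
                   labels = NULL) {
  if (length(compounds) == 0) stop("empty compound list")
  if (is.null(labels)) labels <- rep(NA_character_, length(compounds))
  stopifnot(length(labels) == length(compounds))
  rows <- vector("list", length(compounds))
  results <- vector("list", length(compounds))
  for (i in seq_along(compounds)) {
    cmp <- compounds[[i]]
    nm <- if (nzchar(cmp$name)) cmp$name else paste0("compound_", i)
    res <- tryCatch(dock(receptor, cmp, reference_ligand, gridset, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(compound = nm, label = labels[i],
                              net_charge = net_charge(cmp),
                              E_elec = NA_real_, E_vdw = NA_real_,
                              E_total = NA_real_,
                              error = conditionMessage(res),
                              stringsAsFactors = FALSE)
    } else {
      e <- res$final$energy
      rows[[i]] <- data.frame(compound = nm, label = labels[i],
                              net_charge = net_charge(cmp),
                              E_elec = e[["E_elec"]], E_vdw = e[["E_vdw"]],
                              E_total = e[["E_total"]], error = NA_character_,
                              stringsAsFactors = FALSE)
      results[[i]] <- res
    }
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$E_total, seq_len(nrow(tab)), na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(tab, results = results[ord], class = c("ranked_screen", "data.frame"))
}

#' Grid-free reference binding energy
#'
#' Exact pairwise evaluation used as the oracle for [grid_energy()]:
#' Coulomb with distance-dependent dielectric
#' (`E_elec = C sum_ij q_i q_j / r_ij^2`) or, for the PB model, the ligand
#' charges read the supplied potential map; the vdW term is the pairwise
#' soft-core 6-12 sum under geometric-mean combining in both cases.
#'
#' @param receptor,ligand parameterized `molecule` objects.
#' @param xyz optional ligand pose coordinates.
#' @param model `"coulomb"` or `"pb"`.
#' @param pb_map `potential_map` in kT/e (required for `"pb"`).
#' @param delta_vdw soft-core smoothing length, Angstrom.
#' @return named vector `E_elec`, `E_vdw`, `E_total` in kcal/mol.
#' @export
direct_energy <- function(receptor, ligand, xyz = NULL,
                          model = c("coulomb", "pb"), pb_map = NULL,
                          delta_vdw = 0) {
  model <- match.arg(model)
  require_parameters(receptor, "receptor")
  require_parameters(ligand, "ligand")
  if (is.null(xyz)) xyz <- coords(ligand)
  rxyz <- coords(receptor)
  d2 <- outer(rowSums(rxyz^2), rowSums(xyz^2), "+") - 2 * rxyz %*% t(xyz)
  d2[d2 < 0] <- 0
  if (any(d2 < 1e-12)) stop("receptor and ligand atoms coincide")

  if (model == "coulomb") {
    e_elec <- COULOMB_KCAL *
      sum(outer(receptor$atoms$charge, ligand$atoms$charge) / d2)
  } else {
    if (is.null(pb_map)) stop("model = 'pb' requires pb_map")
    phiv <- map_interpolate(pb_map, xyz)
    if (anyNA(phiv)) stop("ligand pose outside the pb_map")
    e_elec <- sum(ligand$atoms$charge * phiv) * kT_kcal()
  }

  ljr <- lj_coefficients(receptor$atoms$r0, receptor$atoms$eps)
  ljl <- lj_coefficients(ligand$atoms$r0, ligand$atoms$eps)
  aij <- outer(sqrt(ljr$A), sqrt(ljl$A))
  bij <- outer(sqrt(ljr$B), sqrt(ljl$B))
  den <- d2^3 + delta_vdw^6
  e_vdw <- sum(aij / den^2 - bij / den)
  c(E_elec = e_elec, E_vdw = e_vdw, E_total = e_elec + e_vdw)
}
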