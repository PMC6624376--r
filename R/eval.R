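## Pose-accuracy and screening-enrichment metrics.
##
## RMSD comes in three flavors: all_atom (fixed correspondence including
## hydrogens, the primary pose metric), heavy_atom (hydrogens dropped), and
## heavy_symmetry (heavy atoms with the optimal within-element assignment,
## which forgives chemically equivalent atom relabelings without refitting
## the pose).  Enrichment is quantified by the ROC of an energy-ranked
## active/decoy screen and by the adjusted LogAUC: the area under TPR vs
## log10(FPR) over three decades, minus the analytic random-ranking area
## 100 (1 - 1e-3) / (3 ln 10) = 14.46 (the "14.5%" random correction).

#' Root-mean-square deviation between a reference and a pose
#'
#' @param reference a `molecule` (the reference conformation).
#' @param pose a `molecule` or an n x 3 coordinate matrix in the same atom
#'   order.
#' @param mode `"all_atom"`, `"heavy_atom"`, or `"heavy_symmetry"`
#'   (optimal within-element assignment over heavy atoms; exact search,
#'   element classes capped at 8 atoms).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(reference, pose, mode = c("all_atom", "heavy_atom",
                                           "heavy_symmetry")) {
  mode <- match.arg(mode)
  ref_xyz <- coords(reference)
  pose_xyz <- if (inherits(pose, "molecule")) coords(pose) else
    matrix(as.numeric(pose), ncol = 3)
  if (nrow(pose_xyz) != nrow(ref_xyz)) {
    stop("atom count mismatch: ", nrow(ref_xyz), " vs ", nrow(pose_xyz))
  }
  elem <- elements(reference)
  if (mode == "all_atom") {
    return(sqrt(mean(rowSums((ref_xyz - pose_xyz)^2))))
  }
  heavy <- elem != "H"
  if (!any(heavy)) stop("no heavy atoms")
  ref_h <- ref_xyz[heavy, , drop = FALSE]
  pose_h <- pose_xyz[heavy, , drop = FALSE]
  if (mode == "heavy_atom") {
    return(sqrt(mean(rowSums((ref_h - pose_h)^2))))
  }
  ## heavy_symmetry: within each element class, pick the assignment of pose
  ## atoms to reference atoms minimizing the total squared deviation.
  el_h <- elem[heavy]
  total <- 0
  for (e in unique(el_h)) {
    sel <- which(el_h == e)
    k <- length(sel)
    if (k == 1) {
      total <- total + sum((ref_h[sel, ] - pose_h[sel, ])^2)
      next
    }
    if (k > 8) stop("element class '", e, "' has ", k,
                    " atoms; exact symmetry assignment is capped at 8")
    cost <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j) {
      sum((ref_h[sel[i], ] - pose_h[sel[j], ])^2)
    }))
    perms <- permutations_of(k)
    best <- min(vapply(seq_len(nrow(perms)), function(p) {
      sum(cost[cbind(seq_len(k), perms[p, ])])
    }, numeric(1)))
    total <- total + best
  }
  sqrt(total / nrow(ref_h))
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1L))
  sub <- permutations_of(k - 1)
  do.call(rbind, lapply(seq_len(k), function(first) {
    cbind(first, matrix(setdiff(seq_len(k), first)[sub], nrow = nrow(sub)))
  }))
}

## Coerce a ranked screen (or a data.frame with label/E_total columns) to
## the ordered label vector used by the ROC machinery.
screen_labels <- function(screen) {
  df <- as.data.frame(screen)
  if (!all(c("label", "E_total") %in% names(df))) {
    stop("screen needs 'label' and 'E_total' columns")
  }
  df <- df[!is.na(df$E_total), , drop = FALSE]
  df <- df[order(df$E_total, seq_len(nrow(df))), , drop = FALSE]
  lab <- df$label
  if (!all(lab %in% c("active", "decoy"))) {
    stop("labels must be 'active' or 'decoy'")
  }
  if (!any(lab == "active") || !any(lab == "decoy")) {
    stop("need at least one active and one decoy")
  }
  list(labels = lab, energies = df$E_total)
}

#' ROC curve of an energy-ranked screen
#'
#' Compounds are ranked by ascending energy (best first); tied energies are
#' collapsed into a single diagonal ROC segment (average-step
#' interpolation).
#'
#' @param screen a `ranked_screen` or data.frame with columns `label`
#'   (`"active"`/`"decoy"`) and `E_total`.
#' @return data.frame of ROC points with columns `fpr`, `tpr`, starting at
#'   (0, 0) and ending at (1, 1), both monotone non-decreasing.
#' @export
roc_curve <- function(screen) {
  s <- screen_labels(screen)
  n_act <- sum(s$labels == "active")
  n_dec <- sum(s$labels == "decoy")
  grp <- cumsum(!duplicated(s$energies))
  tp <- unname(tapply(s$labels == "active", grp, sum))
  fp <- unname(tapply(s$labels == "decoy", grp, sum))
  data.frame(fpr = c(0, cumsum(fp) / n_dec), tpr = c(0, cumsum(tp) / n_act))
}

#' Area under the ROC curve
#' @inheritParams roc_curve
#' @return AUC in percent (50 for random ranking).
#' @export
roc_auc <- function(screen) {
  r <- roc_curve(screen)
  100 * sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2)
}

#' Random-ranking area of the log-scaled ROC
#'
#' Closed form `100 (1 - lower_limit) / (3 ln 10)`; 14.46% for the default
#' three-decade axis, the constant subtracted by the adjusted LogAUC.
#'
#' @param lower_limit lower FPR limit of the log axis.
#' @return area in percent.
#' @export
logauc_random_area <- function(lower_limit = 1e-3) {
  100 * (1 - lower_limit) / (-log10(lower_limit) * log(10))
}

#' Adjusted LogAUC of an energy-ranked screen
#'
#' Trapezoidal area of TPR against log10(FPR) over FPR in
#' `[lower_limit, 1]`, normalized by the number of decades and expressed in
#' percent, minus the analytic random area ([logauc_random_area()], 14.46%
#' for three decades). Early ROC points with FPR below the limit are
#' clipped to it, not dropped. Positive values indicate better-than-random
#' early enrichment; a perfect ranking approaches 100 - 14.46 = 85.5.
#'
#' @inheritParams roc_curve
#' @param lower_limit lower FPR limit (1e-3 spans three decades).
#' @return adjusted LogAUC in percent.
#' @export
adjusted_logauc <- function(screen, lower_limit = 1e-3) {
  r <- roc_curve(screen)
  decades <- -log10(lower_limit)
  fpr <- pmax(r$fpr, lower_limit)
  ## linear interpolation of the raw ROC at the clip point keeps the curve
  ## well-defined on [lower_limit, 1]
  x <- log10(fpr)
  keep <- c(TRUE, diff(x) > 0 | diff(r$tpr) > 0)
  x <- x[keep]; y <- r$tpr[keep]
  raw <- 100 * sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2) / decades
  raw - logauc_random_area(lower_limit)
}

#' Net-charge histogram of top-scored compounds
#'
#' @inheritParams roc_curve
#' @param top_fraction fraction (0, 1] of the ranked list to inspect.
#' @return table of integer-rounded net charges among the selected
#'   compounds.
#' @export
charge_distribution <- function(screen, top_fraction = 0.1) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  df <- as.data.frame(screen)
  if (!all(c("net_charge", "E_total") %in% names(df))) {
    stop("screen needs 'net_charge' and 'E_total' columns")
  }
  df <- df[!is.na(df$E_total), , drop = FALSE]
  df <- df[order(df$E_total, seq_len(nrow(df))), , drop = FALSE]
  n <- max(1L, floor(top_fraction * nrow(df)))
  if (n == 0 || nrow(df) == 0) stop("empty selection")
  table(round(df$net_charge[seq_len(n)]))
}
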