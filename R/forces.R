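#' Force and integration parameters
#'
#' Bundles the mechanical parameters of the model: the force amplitude `F0`
#' reached at deep cell--cell overlap, the eggshell response scale
#' `shell_gain`, the per-pair stable repulsion ratios `alpha`, the
#' per-component displacement noise variance and the integration time step.
#' With mobility set to 1 in the overdamped equation of motion, forces are
#' expressed directly as velocities (um/s).
#'
#' The stable repulsion ratio `alpha` is the centre-to-centre distance of two
#' attached cells at force balance divided by the sum of their radii:
#' `alpha = 1` means pure repulsion (contact at force zero), `alpha < 1` net
#' adhesion. Pairs not listed in `alpha_pairs` use `alpha_default`.
#'
#' @param F0 Force amplitude (um/s) at overlaps deeper than `min(Ri, Rj)`.
#' @param shell_gain Scale of the eggshell repulsion response (um/s).
#' @param noise_variance Per-component displacement variance per step (um^2).
#' @param dt Integration time step (s).
#' @param alpha_default Fallback stable repulsion ratio in (0, 1].
#' @param alpha_pairs Named list mapping unordered label pairs (key
#'   `"A:B"` with labels sorted alphabetically) to alpha values.
#' @return An object of class `force_params`.
#' @examples
#' aa_params()   # asymmetric attraction: EMS-P2 0.90, others 0.75
#' ro_params()   # repulsion-only: all alpha = 1
#' @export
force_params <- function(F0 = 0.1, shell_gain = 1.0, noise_variance = 0.027,
                         dt = 5, alpha_default = 0.75,
                         alpha_pairs = list("EMS:P2" = 0.90)) {
  stopifnot(F0 > 0, shell_gain > 0, noise_variance >= 0, dt > 0,
            alpha_default > 0, alpha_default <= 1)
  if (length(alpha_pairs)) {
    av <- unlist(alpha_pairs)
    if (any(av <= 0 | av > 1)) stop("alpha values must lie in (0, 1]")
  }
  structure(list(F0 = F0, shell_gain = shell_gain,
                 noise_variance = noise_variance, dt = dt,
                 alpha_default = alpha_default,
                 alpha_pairs = alpha_pairs),
            class = "force_params")
}

#' @rdname force_params
#' @param ... Overrides passed on to [force_params()].
#' @export
aa_params <- function(...) force_params(...)

#' @rdname force_params
#' @export
ro_params <- function(...) {
  force_params(..., alpha_default = 1, alpha_pairs = list())
}

#' Stable repulsion ratio for a labelled pair
#'
#' Symmetric lookup in the `alpha_pairs` table of a [force_params()] object;
#' unlisted pairs fall back to `alpha_default`.
#'
#' @param params A `force_params` object.
#' @param label_i,label_j Lineage labels of the two cells.
#' @return A single alpha value in (0, 1].
#' @export
alpha_for_pair <- function(params, label_i, label_j) {
  key <- paste(sort(c(label_i, label_j)), collapse = ":")
  a <- params$alpha_pairs[[key]]
  if (is.null(a)) params$alpha_default else a
}

#' Signed magnitude of the pairwise intercellular force
#'
#' Piecewise force--distance law for two soft spheres: constant `F0`
#' (repulsive) for deep overlap `0 < d <= min(Ri, Rj)` (cytokinetic
#' elongation at roughly constant velocity); then decreasing linearly
#' through zero at `d = alpha (Ri + Rj)` up to `d = 0.5 (1 + alpha)
#' (Ri + Rj)`; then linearly back to zero at contact loss `d = Ri + Rj`;
#' zero beyond. Positive values repel, negative values attract. With
#' `alpha = 1` the attraction interval is empty and the law reduces to the
#' repulsion-only model.
#'
#' @param d Centre-to-centre distance (um), > 0.
#' @param R_i,R_j Cell radii (um).
#' @param alpha Stable repulsion ratio in (0, 1].
#' @param F0 Force amplitude (um/s).
#' @return Signed scalar magnitude (um/s); positive = repulsion.
#' @export
pairwise_force_magnitude <- function(d, R_i, R_j, alpha, F0) {
  stopifnot(d > 0, R_i > 0, R_j > 0, alpha > 0, alpha <= 1, F0 > 0)
  rsum <- R_i + R_j
  rmin <- min(R_i, R_j)
  dzero <- alpha * rsum
  if (dzero <= rmin)
    stop("alpha too small for this radius asymmetry: alpha*(Ri+Rj) <= min(Ri,Rj)")
  mid <- 0.5 * (1 + alpha) * rsum
  if (d <= rmin) return(F0)
  if (d <= mid) return(F0 * (dzero - d) / (dzero - rmin))
  if (d <= rsum) {
    fmid <- F0 * (dzero - mid) / (dzero - rmin)   # attractive (< 0) for alpha < 1
    return(fmid * (rsum - d) / (rsum - mid))
  }
  0
}

#' Pairwise force vector on a cell
#'
#' Force exerted on cell i by cell j, acting along the line of centres:
#' repulsion pushes i away from j, attraction pulls i toward j.
#'
#' @param pos_i,pos_j Numeric 3-vectors, cell centres (um).
#' @param R_i,R_j Cell radii (um).
#' @inheritParams pairwise_force_magnitude
#' @return Numeric 3-vector, force on cell i (um/s).
#' @export
pairwise_force <- function(pos_i, R_i, pos_j, R_j, alpha, F0) {
  dvec <- pos_j - pos_i
  d <- sqrt(sum(dvec^2))
  if (d == 0) stop("coincident cell centres")
  mag <- pairwise_force_magnitude(d, R_i, R_j, alpha, F0)
  -mag * dvec / d
}

#' Repulsive force from the eggshell on a cell
#'
#' Zero while the centre-to-shell distance `a` exceeds the cell radius `R`;
#' once the cell touches the shell (`a <= R`) the force acts along the
#' inward surface normal with magnitude `shell_gain * (R - a) / R`,
#' vanishing continuously at contact onset and growing with overlap.
#'
#' @param shell An [eggshell()].
#' @param pos Cell centre, strictly inside the shell (um).
#' @param R Cell radius (um).
#' @param params A [force_params()] object (uses `shell_gain`).
#' @return Numeric 3-vector (um/s).
#' @export
shell_force <- function(shell, pos, R, params) {
  ft <- .shell_foot(shell, pos)
  if (ft$a > R) return(c(0, 0, 0))
  params$shell_gain * (R - ft$a) / R * ft$normal
}

#' Net forces on every cell of an embryo state
#'
#' Sum of all pairwise cell--cell forces and the eggshell repulsion, cell by
#' cell. Pairwise contributions obey Newton's third law by construction.
#'
#' @param state An [embryo_state()].
#' @param params A [force_params()] object.
#' @return Numeric matrix (n_cells x 3), rows named by cell label.
#' @export
net_forces <- function(state, params) {
  cells <- state$cells
  n <- nrow(cells)
  pos <- as.matrix(cells[, c("x", "y", "z")])
  forces <- matrix(0, n, 3, dimnames = list(cells$label, c("x", "y", "z")))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        al <- alpha_for_pair(params, cells$label[i], cells$label[j])
        f <- pairwise_force(pos[i, ], cells$radius[i], pos[j, ],
                            cells$radius[j], al, params$F0)
        forces[i, ] <- forces[i, ] + f
        forces[j, ] <- forces[j, ] - f
      }
    }
  }
  for (i in seq_len(n))
    forces[i, ] <- forces[i, ] + shell_force(state$shell, pos[i, ],
                                             cells$radius[i], params)
  forces
}
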