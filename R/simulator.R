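#' Initial two-cell configuration
#'
#' AB and P1 are placed at the centre of the eggshell, 2.0 um apart on the
#' x-axis, AB anterior (negative x), as the first cleavage is parallel to
#' the long axis of the egg.
#'
#' @param shell An [eggshell()].
#' @param total_volume Total blastomere volume (um^3).
#' @param ab_fraction AB share of the total volume, in (0, 1).
#' @param separation Centre-to-centre distance (um; default 2.0).
#' @return An [embryo_state()] at time 0 with cells AB and P1.
#' @export
initial_two_cell_state <- function(shell, total_volume, ab_fraction = 0.55,
                                   separation = 2.0) {
  stopifnot(total_volume > 0, ab_fraction > 0, ab_fraction < 1, separation > 0)
  h <- separation / 2
  if (!shell_contains(shell, c(h, 0, 0)) || !shell_contains(shell, c(-h, 0, 0)))
    stop("eggshell too small for the initial two-cell configuration")
  cells <- data.frame(
    label = c("AB", "P1"),
    x = c(-h, h), y = c(0, 0), z = c(0, 0),
    radius = radius_from_volume(total_volume * c(ab_fraction, 1 - ab_fraction)),
    stringsAsFactors = FALSE)
  embryo_state(0, cells, shell)
}

## Keep a centre strictly inside the shell: if its ellipsoidal radius
## reaches 0.99, rescale radially back to 0.99 (the rigid shell cannot be
## crossed; shell repulsion normally keeps centres far from the surface).
clamp_inside <- function(shell, pos) {
  rho <- sqrt(pos[1]^2 / shell$lx^2 + (pos[2]^2 + pos[3]^2) / shell$ly^2)
  if (rho >= 0.99) pos * (0.99 / rho) else pos
}

#' Advance an embryo state by one time step
#'
#' Explicit Euler--Maruyama step of the overdamped Langevin dynamics with
#' mobility 1: each centre moves by `net_force * dt` plus an isotropic
#' Gaussian displacement with the configured per-component variance, then
#' is clamped to remain strictly inside the eggshell. Consumes `3 * n_cells`
#' standard normal draws from the R RNG stream when `noise_variance > 0`.
#'
#' @param state An [embryo_state()].
#' @param params A [force_params()].
#' @return The advanced [embryo_state()] (time increased by `dt`).
#' @export
sim_step <- function(state, params) {
  cells <- state$cells
  n <- nrow(cells)
  pos <- as.matrix(cells[, c("x", "y", "z")])
  pos <- pos + net_forces(state, params) * params$dt
  if (params$noise_variance > 0) {
    pos <- pos + matrix(stats::rnorm(3 * n, 0, sqrt(params$noise_variance)),
                        ncol = 3, byrow = TRUE)
  }
  for (i in seq_len(n)) pos[i, ] <- clamp_inside(state$shell, pos[i, ])
  cells$x <- pos[, 1]; cells$y <- pos[, 2]; cells$z <- pos[, 3]
  embryo_state(state$time + params$dt, cells, state$shell)
}

state_snapshot <- function(state) {
  data.frame(time_s = state$time, label = state$cells$label,
             x_um = state$cells$x, y_um = state$cells$y, z_um = state$cells$z,
             radius_um = state$cells$radius, stringsAsFactors = FALSE)
}

## One contiguous block of integration steps (no divisions inside), using
## either the compiled core or the pure-R reference stepper. Both engines
## consume the RNG stream identically, so results agree to rounding.
integrate_block <- function(state, params, n_steps, engine) {
  if (n_steps <= 0) return(state)
  if (engine == "cpp") {
    pos <- as.matrix(state$cells[, c("x", "y", "z")])
    amat <- alpha_matrix(params, state$cells$label)
    out <- integrate_segment_cpp(pos, state$cells$radius, amat,
                                 state$shell$lx, state$shell$ly,
                                 params$F0, params$shell_gain,
                                 sqrt(params$noise_variance), params$dt,
                                 as.integer(n_steps))
    cells <- state$cells
    cells$x <- out[, 1]; cells$y <- out[, 2]; cells$z <- out[, 3]
    embryo_state(state$time + n_steps * params$dt, cells, state$shell)
  } else {
    for (k in seq_len(n_steps)) state <- sim_step(state, params)
    state
  }
}

alpha_matrix <- function(params, labels) {
  n <- length(labels)
  m <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    m[i, j] <- alpha_for_pair(params, labels[i], labels[j])
  m
}

#' Run a full simulation from the two-cell stage
#'
#' Integrates the overdamped dynamics with the given division program:
#' starting from the standard two-cell configuration, division events are
#' applied at their scheduled times between integration steps, and the run
#' continues for the program's settling interval after the last division.
#' Fully deterministic given `seed` and the configuration.
#'
#' @param shell An [eggshell()].
#' @param program A [division_program][build_program()].
#' @param params A [force_params()].
#' @param total_volume Total blastomere volume (um^3).
#' @param seed Integer RNG seed for this replicate.
#' @param duration Total simulated time (s); defaults to `program$duration`.
#' @param record_stride Record a trajectory snapshot every `record_stride`
#'   steps (0 = initial and final states only).
#' @param engine `"cpp"` (compiled core, default) or `"r"` (reference
#'   implementation); both produce the same trajectories.
#' @return A list with `state` (final [embryo_state()]) and `trajectory`
#'   (data frame `time_s, label, x_um, y_um, z_um, radius_um`).
#' @examples
#' sh <- axes_from_ar(1.6, 23561.94)
#' res <- sim_run(sh, build_program("T-div"), aa_params(),
#'                total_volume = 17671.46, seed = 1)
#' res$state
#' @export
sim_run <- function(shell, program, params, total_volume, seed,
                    duration = NULL, record_stride = 0,
                    engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(program, "division_program"),
            inherits(params, "force_params"))
  if (is.null(duration)) duration <- program$duration
  ev_times <- vapply(program$events, `[[`, numeric(1), "time")
  if (duration < max(ev_times))
    stop("duration must cover all scheduled division times")
  n_total <- as.integer(round(duration / params$dt))
  ev_steps <- as.integer(round(ev_times / params$dt))
  set.seed(as.integer(seed))
  state <- initial_two_cell_state(shell, total_volume, program$ab_fraction)
  traj <- list(state_snapshot(state))
  step_now <- 0L
  pending <- seq_along(program$events)
  advance <- function(state, k) {         # k steps, honouring record_stride
    if (record_stride > 0) {
      while (k > 0L) {
        kk <- min(k, as.integer(record_stride))
        state <- integrate_block(state, params, kk, engine)
        traj[[length(traj) + 1L]] <<- state_snapshot(state)
        k <- k - kk
      }
      state
    } else {
      integrate_block(state, params, k, engine)
    }
  }
  record <- function(state) {           # keep per-label times strictly increasing
    snap <- state_snapshot(state)
    last <- traj[[length(traj)]]
    if (last$time_s[1] == state$time) traj[[length(traj)]] <<- snap
    else traj[[length(traj) + 1L]] <<- snap
  }
  for (idx in pending) {
    state <- advance(state, ev_steps[idx] - step_now)
    step_now <- ev_steps[idx]
    state <- apply_division(state, program$events[[idx]])
    if (record_stride > 0) record(state)
  }
  state <- advance(state, n_total - step_now)
  record(state)
  list(state = state, trajectory = do.call(rbind, traj))
}

#' Write a trajectory to CSV
#'
#' @param trajectory Trajectory data frame from [sim_run()].
#' @param path Output file path.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(trajectory, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
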