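#' Default frozen simulation configuration
#'
#' The complete parameter set used for all shipped experiments, as a flat
#' named list. The eggshell volume corresponds to semi-axes 25 x 15 x 15 um
#' (a typical wild-type egg); blastomeres occupy 92% of it. Force and
#' timing constants were calibrated once -- a free two-cell system must
#' relax to its equilibrium separation well within one inter-division
#' interval, and the repulsion-only model must reproduce its reference
#' arrangement-vs-AR phase behaviour -- and then frozen (see the methods
#' vignette).
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    shell_volume = (4 / 3) * pi * 25 * 15^2,  # um^3, constant across AR sweeps
    ar = 1.6,                                 # wild-type mean aspect ratio
    cell_volume_fraction = 0.92,              # blastomere volume / shell volume
    F0 = 0.45,                                # um/s
    shell_gain = 0.8,                         # um/s
    noise_variance = 0.027,                   # um^2 per component per step
    dt = 5,                                   # s
    alpha_default = 0.75,
    alpha_pairs = list("EMS:P2" = 0.90),
    orientation_class = "T-div",
    timing_mode = "asynchronous",
    volume_mode = "asymmetric",
    t_first = 300,                            # s, AB division
    interval = 120,                           # s, P1 lags AB
    settle = 600,                             # s, before classification
    offset = 2.0,                             # um, daughter placement
    ab_fraction = 0.60,
    aba_fraction = 0.55,
    ems_fraction = 0.60,
    ar_min = 1.0, ar_max = 4.0, ar_step = 0.1,
    n_reps = 30
  )
}

#' Read and validate a configuration file
#'
#' JSON file holding exactly the keys of [default_config()]. Unknown and
#' missing keys are reported by name.
#'
#' @param path Path to a JSON configuration file.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$alpha_pairs)) cfg$alpha_pairs <- as.list(cfg$alpha_pairs)
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg Configuration list to validate.
#' @export
validate_config <- function(cfg) {
  ref <- default_config()
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(names(ref), names(cfg))
  if (length(missing))
    stop("missing required config key(s): ", paste(missing, collapse = ", "))
  num_pos <- c("shell_volume", "cell_volume_fraction", "F0", "shell_gain",
               "dt", "alpha_default", "offset", "ar_step")
  for (k in num_pos)
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || cfg[[k]] <= 0)
      stop("config key '", k, "' must be a positive number")
  if (cfg$noise_variance < 0) stop("config key 'noise_variance' must be >= 0")
  if (cfg$ar < 1 || cfg$ar_min < 1 || cfg$ar_max < cfg$ar_min)
    stop("aspect ratios must be >= 1 with ar_max >= ar_min")
  cfg[names(ref)]
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(validate_config(cfg), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Force parameters and division program from a configuration
#'
#' `params_from_config` builds the [force_params()]; with `model = "RO"`
#' every alpha is overridden to 1 (repulsion only). `program_from_config`
#' builds the [division_program][build_program()].
#'
#' @param cfg Configuration list (see [default_config()]).
#' @param model `"AA"` (asymmetric attraction) or `"RO"` (repulsion only).
#' @return A `force_params` / `division_program` object.
#' @export
params_from_config <- function(cfg, model = c("AA", "RO")) {
  model <- match.arg(model)
  if (model == "RO")
    force_params(F0 = cfg$F0, shell_gain = cfg$shell_gain,
                 noise_variance = cfg$noise_variance, dt = cfg$dt,
                 alpha_default = 1, alpha_pairs = list())
  else
    force_params(F0 = cfg$F0, shell_gain = cfg$shell_gain,
                 noise_variance = cfg$noise_variance, dt = cfg$dt,
                 alpha_default = cfg$alpha_default,
                 alpha_pairs = cfg$alpha_pairs)
}

#' @rdname params_from_config
#' @export
program_from_config <- function(cfg) {
  build_program(cfg$orientation_class, cfg$timing_mode, cfg$volume_mode,
                t_first = cfg$t_first, interval = cfg$interval,
                settle = cfg$settle, offset = cfg$offset,
                ab_fraction = cfg$ab_fraction,
                aba_fraction = cfg$aba_fraction,
                ems_fraction = cfg$ems_fraction)
}

## Deterministic, platform-stable replicate seed from
## (master seed, orientation class, AR grid key, replicate index).
## Multiplicative congruential mixing mod 2^31 - 1; all intermediate
## products stay below 2^53, so double arithmetic is exact. The model
## (RO vs AA) deliberately does not enter: an RO sweep must be able to
## share noise streams with an all-alpha-1 AA sweep.
derive_replicate_seed <- function(master_seed, class_id, ar_key, rep) {
  m <- 2147483647
  s <- master_seed %% m
  for (b in c(class_id, ar_key, rep))
    s <- (s * 48271 + b * 12345 + 1) %% m
  as.integer(s)
}

class_id <- function(orientation_class) {
  match(orientation_class, c("T-div", "I-div", "H-div", "C-div"))
}

#' Run one classified replicate
#'
#' Convenience wrapper: build the shell at the requested AR (constant
#' volume), run the program, classify the final four-cell state.
#'
#' @param ar Eggshell aspect ratio.
#' @param model `"AA"` or `"RO"`.
#' @param cfg Configuration list.
#' @param seed Replicate seed.
#' @param engine Integration engine, `"cpp"` or `"r"`.
#' @return List with `pattern` (character) and `state`.
#' @export
run_replicate <- function(ar, model = "AA", cfg = default_config(), seed = 1,
                          engine = "cpp") {
  shell <- axes_from_ar(ar, cfg$shell_volume)
  prog <- program_from_config(cfg)
  params <- params_from_config(cfg, model)
  res <- sim_run(shell, prog, params,
                 total_volume = cfg$cell_volume_fraction * cfg$shell_volume,
                 seed = seed, engine = engine)
  list(pattern = classify_pattern(contact_graph(res$state)),
       state = res$state)
}

#' Replicated aspect-ratio sweep
#'
#' For every AR on the grid, reshapes the eggshell at constant volume, runs
#' `n_reps` independently seeded replicates of the division program, and
#' tabulates the classified arrangement patterns. The repulsion-only model
#' is the same machinery with every alpha overridden to 1, and shares
#' replicate seeds with the AA model.
#'
#' @param model `"AA"` or `"RO"`.
#' @param cfg Configuration list (see [default_config()]).
#' @param ar_values Numeric vector of aspect ratios; defaults to the
#'   config's `ar_min`--`ar_max` grid in steps of `ar_step`.
#' @param n_reps Replicates per AR (default from config).
#' @param master_seed Master seed; replicate seeds are derived from it, the
#'   orientation class, the AR and the replicate index.
#' @param engine `"cpp"` or `"r"`.
#' @return A `sweep_result` data frame with columns `model`,
#'   `orientation_class`, `ar`, `pattern`, `count`, `fraction`, `n_reps`,
#'   `master_seed` (one row per AR x pattern label; fractions per AR sum
#'   to 1).
#' @examples
#' \donttest{
#' sw <- ar_sweep("AA", ar_values = c(1.6), n_reps = 5, master_seed = 1)
#' subset(sw, count > 0)
#' }
#' @export
ar_sweep <- function(model = c("AA", "RO"), cfg = default_config(),
                     ar_values = NULL, n_reps = cfg$n_reps, master_seed = 1,
                     engine = "cpp") {
  model <- match.arg(model)
  if (is.null(ar_values))
    ar_values <- seq(cfg$ar_min, cfg$ar_max, by = cfg$ar_step)
  stopifnot(n_reps >= 1)
  cid <- class_id(cfg$orientation_class)
  rows <- vector("list", length(ar_values))
  for (ai in seq_along(ar_values)) {
    ar <- ar_values[ai]
    ar_key <- as.integer(round(ar * 100))
    pats <- character(n_reps)
    for (rep in seq_len(n_reps)) {
      seed <- derive_replicate_seed(master_seed, cid, ar_key, rep)
      pats[rep] <- run_replicate(ar, model, cfg, seed, engine)$pattern
    }
    tab <- table(factor(pats, levels = pattern_levels()))
    rows[[ai]] <- data.frame(
      model = model, orientation_class = cfg$orientation_class, ar = ar,
      pattern = names(tab), count = as.integer(tab),
      fraction = as.integer(tab) / n_reps, n_reps = n_reps,
      master_seed = master_seed, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' First / last grid AR at which a pattern occurs
#'
#' Smallest (or largest) aspect ratio on the sweep grid whose fraction of
#' the given pattern is greater than zero; `NA` if the pattern never
#' occurs.
#'
#' @param result A `sweep_result` from [ar_sweep()].
#' @param pattern Pattern label (see [pattern_levels()]).
#' @return Single numeric AR, or `NA_real_`.
#' @export
first_ar_with_pattern <- function(result, pattern) {
  ars <- result$ar[result$pattern == pattern & result$fraction > 0]
  if (!length(ars)) NA_real_ else min(ars)
}

#' @rdname first_ar_with_pattern
#' @export
last_ar_with_pattern <- function(result, pattern) {
  ars <- result$ar[result$pattern == pattern & result$fraction > 0]
  if (!length(ars)) NA_real_ else max(ars)
}

#' Sweep-result CSV round trip
#'
#' Counts and replicate numbers are written as integers and fractions are
#' recomputed on read, so the round trip is lossless.
#'
#' @param result A `sweep_result`.
#' @param path CSV file path.
#' @export
write_sweep_csv <- function(result, path) {
  utils::write.csv(result, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("model", "orientation_class", "ar", "pattern", "count",
            "fraction", "n_reps", "master_seed")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sweep CSV is missing column(s): ", paste(miss, collapse = ", "))
  df$fraction <- df$count / df$n_reps
  class(df) <- c("sweep_result", "data.frame")
  df
}

#' Two-cell relaxation diagnostics
#'
#' Calibration aid: two equal free cells (huge shell, no noise) started at
#' a given separation must relax to the equilibrium separation
#' `alpha * (R1 + R2)` well within one inter-division interval. Reports the
#' final separation and the first time the separation is within `tol` of
#' equilibrium.
#'
#' @param params A [force_params()] (noise is switched off internally).
#' @param R1,R2 Cell radii (um).
#' @param d0 Initial separation (um).
#' @param alpha Stable repulsion ratio to probe.
#' @param duration Simulated time (s).
#' @param tol Convergence tolerance on the separation (um).
#' @return List with `separation`, `equilibrium`, `t_converged` (s, `NA` if
#'   never within `tol`).
#' @export
two_cell_relaxation <- function(params, R1 = 13, R2 = 12, d0 = 2,
                                alpha = 0.75, duration = 600, tol = 1e-3) {
  quiet <- force_params(F0 = params$F0, shell_gain = params$shell_gain,
                        noise_variance = 0, dt = params$dt,
                        alpha_default = alpha, alpha_pairs = list())
  shell <- eggshell(1e4, 1e4)           # effectively unconfined
  cells <- data.frame(label = c("AB", "P1"), x = c(-d0 / 2, d0 / 2),
                      y = 0, z = 0, radius = c(R1, R2),
                      stringsAsFactors = FALSE)
  state <- embryo_state(0, cells, shell)
  eq <- alpha * (R1 + R2)
  t_conv <- NA_real_
  n <- ceiling(duration / quiet$dt)
  for (k in seq_len(n)) {
    state <- sim_step(state, quiet)
    sep <- abs(state$cells$x[2] - state$cells$x[1])
    if (is.na(t_conv) && abs(sep - eq) < tol) t_conv <- state$time
  }
  list(separation = abs(state$cells$x[2] - state$cells$x[1]),
       equilibrium = eq, t_converged = t_conv)
}
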