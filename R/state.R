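#' Embryo state: cells inside an eggshell at a time point
#'
#' Cells are stored as a data frame with one row per blastomere: `label`
#' (lineage identity), centre coordinates `x`, `y`, `z` (um), `radius` (um)
#' and `volume` (um^3, always `(4/3) pi radius^3`).
#'
#' @param time Simulation time (s).
#' @param cells Data frame with columns `label`, `x`, `y`, `z`, `radius`
#'   (volume is recomputed from radius).
#' @param shell An [eggshell()].
#' @return An object of class `embryo_state`.
#' @export
embryo_state <- function(time, cells, shell) {
  stopifnot(inherits(shell, "eggshell"), is.data.frame(cells))
  need <- c("label", "x", "y", "z", "radius")
  if (!all(need %in% names(cells)))
    stop("cells must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(cells$label)) stop("cell labels must be unique")
  if (any(cells$radius <= 0)) stop("cell radii must be positive")
  cells$label <- as.character(cells$label)
  cells$volume <- (4 / 3) * pi * cells$radius^3
  inside <- vapply(seq_len(nrow(cells)), function(i)
    shell_contains(shell, c(cells$x[i], cells$y[i], cells$z[i])), logical(1))
  if (!all(inside)) stop("all cell centres must lie strictly inside the shell")
  structure(list(time = as.numeric(time), cells = cells, shell = shell),
            class = "embryo_state")
}

#' @export
print.embryo_state <- function(x, ...) {
  cat(sprintf("embryo_state at t = %g s, %d cell(s) in ", x$time, nrow(x$cells)))
  print(x$shell)
  print(x$cells, digits = 4)
  invisible(x)
}

#' Total cell volume of a state
#' @param state An [embryo_state()].
#' @return Total blastomere volume (um^3).
#' @export
total_cell_volume <- function(state) sum(state$cells$volume)

radius_from_volume <- function(v) (3 * v / (4 * pi))^(1 / 3)
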