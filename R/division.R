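#' A programmed cell-division event
#'
#' Replaces a mother cell by two daughters placed symmetrically about the
#' mother centre along a division axis. The first daughter is placed at
#' `centre + (offset/2) * axis` and receives `fraction` of the mother
#' volume; the second at `centre - (offset/2) * axis` with the remainder.
#'
#' @param mother Lineage label of the dividing cell.
#' @param time Scheduled division time (s).
#' @param axis Division axis; normalised internally.
#' @param fraction Volume fraction of the first daughter, in (0, 1).
#' @param daughters Character vector of two daughter labels (first label =
#'   daughter on the `+axis` side).
#' @param offset Initial centre-to-centre distance of the daughters (um).
#' @return An object of class `division_event`.
#' @export
division_event <- function(mother, time, axis, fraction, daughters,
                           offset = 2.0) {
  stopifnot(length(axis) == 3L, is.numeric(axis),
            fraction > 0, fraction < 1, offset > 0,
            length(daughters) == 2L, daughters[1] != daughters[2])
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("division axis must be non-zero")
  structure(list(mother = as.character(mother), time = as.numeric(time),
                 axis = axis / nrm, fraction = fraction,
                 daughters = as.character(daughters), offset = offset),
            class = "division_event")
}

#' Build a two-to-four-cell division program
#'
#' Encodes the second and third embryonic divisions (AB and P1 each dividing
#' once). Division-axis orientation classes, relative to the long (x) axis
#' of the egg:
#' \describe{
#'   \item{T-div}{wild type: AB divides along z (perpendicular), P1 along x.}
#'   \item{I-div}{both divide along x.}
#'   \item{H-div}{both divide along z.}
#'   \item{C-div}{AB divides along z, P1 along y (perpendicular to each
#'     other and to the long axis).}
#' }
#' `timing_mode = "asynchronous"` has AB divide `interval` seconds before
#' P1 (wild type); `"simultaneous"` schedules both at `t_first`, as in
#' par-depleted embryos. `volume_mode = "asymmetric"` uses the configured
#' AB/EMS volume fractions; `"equal"` makes all four daughters equal (and
#' implies an equal AB:P1 split at the two-cell stage).
#'
#' @param orientation_class One of `"T-div"`, `"I-div"`, `"H-div"`, `"C-div"`.
#' @param timing_mode `"asynchronous"` or `"simultaneous"`.
#' @param volume_mode `"asymmetric"` or `"equal"`.
#' @param t_first Time of the first (AB) division (s).
#' @param interval Delay of the P1 division after AB (s; asynchronous mode).
#' @param settle Post-division settling interval before classification (s).
#' @param offset Daughter placement offset (um).
#' @param ab_fraction AB share of total embryo volume at the two-cell stage.
#' @param aba_fraction ABa share of the AB volume.
#' @param ems_fraction EMS share of the P1 volume.
#' @return An object of class `division_program`: fields `events` (list of
#'   [division_event()]s sorted by time), `ab_fraction`, `settle`,
#'   `duration`, and the three mode strings.
#' @examples
#' build_program("T-div")  # wild type
#' build_program("I-div", "simultaneous", "equal")
#' @export
build_program <- function(orientation_class = c("T-div", "I-div", "H-div", "C-div"),
                          timing_mode = c("asynchronous", "simultaneous"),
                          volume_mode = c("asymmetric", "equal"),
                          t_first = 600, interval = 120, settle = 600,
                          offset = 2.0, ab_fraction = 0.55,
                          aba_fraction = 0.5, ems_fraction = 0.55) {
  orientation_class <- match.arg(orientation_class)
  timing_mode <- match.arg(timing_mode)
  volume_mode <- match.arg(volume_mode)
  stopifnot(t_first >= 0, interval >= 0, settle >= 0)
  axes <- switch(orientation_class,
    "T-div" = list(ab = c(0, 0, 1), p1 = c(-1, 0, 0)),
    "I-div" = list(ab = c(-1, 0, 0), p1 = c(-1, 0, 0)),
    "H-div" = list(ab = c(0, 0, 1), p1 = c(0, 0, 1)),
    "C-div" = list(ab = c(0, 0, 1), p1 = c(0, 1, 0)))
  t_ab <- t_first
  t_p1 <- if (timing_mode == "simultaneous") t_first else t_first + interval
  if (volume_mode == "equal") {
    ab_fraction <- 0.5; aba_fraction <- 0.5; ems_fraction <- 0.5
  }
  ev <- list(
    division_event("AB", t_ab, axes$ab, aba_fraction, c("ABa", "ABp"), offset),
    division_event("P1", t_p1, axes$p1, ems_fraction, c("EMS", "P2"), offset))
  ev <- ev[order(vapply(ev, `[[`, numeric(1), "time"))]
  structure(list(events = ev, orientation_class = orientation_class,
                 timing_mode = timing_mode, volume_mode = volume_mode,
                 ab_fraction = ab_fraction, settle = settle,
                 duration = max(t_ab, t_p1) + settle),
            class = "division_program")
}

#' Apply a division event to an embryo state
#'
#' Removes the mother and inserts the two daughters with volumes
#' `fraction * V` and `(1 - fraction) * V` and radii from
#' `R = (3V / 4 pi)^(1/3)`; total cell volume is conserved exactly. If a
#' daughter centre would fall on or outside the eggshell, the placement
#' offset is halved until both centres are interior (never below 0.1 um).
#'
#' @param state An [embryo_state()].
#' @param event A [division_event()].
#' @return The post-division [embryo_state()] (same time stamp).
#' @export
apply_division <- function(state, event) {
  cells <- state$cells
  i <- match(event$mother, cells$label)
  if (is.na(i)) stop("mother cell '", event$mother, "' not present")
  centre <- c(cells$x[i], cells$y[i], cells$z[i])
  vm <- cells$volume[i]
  v1 <- event$fraction * vm
  v2 <- vm - v1
  off <- event$offset
  repeat {
    p1 <- centre + (off / 2) * event$axis
    p2 <- centre - (off / 2) * event$axis
    if (shell_contains(state$shell, p1) && shell_contains(state$shell, p2))
      break
    if (off <= 0.1)
      stop("cannot place daughters of '", event$mother, "' inside the shell")
    off <- max(off / 2, 0.1)
  }
  daughters <- data.frame(
    label = event$daughters,
    x = c(p1[1], p2[1]), y = c(p1[2], p2[2]), z = c(p1[3], p2[3]),
    radius = radius_from_volume(c(v1, v2)),
    stringsAsFactors = FALSE)
  cells <- rbind(cells[-i, names(daughters)], daughters)
  rownames(cells) <- NULL
  embryo_state(state$time, cells, state$shell)
}
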