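#' Rigid ellipsoidal eggshell
#'
#' The eggshell is modelled as a rigid ellipsoid of revolution about the
#' anterior--posterior (x) axis, centred at the origin: semi-axis `lx` along
#' x and `ly = lz` transversally. The aspect ratio (AR) is `lx/ly`.
#'
#' @param lx Semi-axis along the long (x) axis, in micrometres.
#' @param ly Semi-axis along the short (y = z) axes, in micrometres.
#' @return An object of class `eggshell` with fields `lx`, `ly`, `lz`.
#' @examples
#' sh <- eggshell(20, 10)
#' aspect_ratio(sh)
#' shell_volume(sh)
#' @export
eggshell <- function(lx, ly) {
  stopifnot(is.numeric(lx), is.numeric(ly), length(lx) == 1L, length(ly) == 1L)
  if (!is.finite(lx) || !is.finite(ly) || ly <= 0 || lx < ly)
    stop("invalid eggshell semi-axes: need lx >= ly > 0")
  structure(list(lx = as.numeric(lx), ly = as.numeric(ly), lz = as.numeric(ly)),
            class = "eggshell")
}

#' @export
print.eggshell <- function(x, ...) {
  cat(sprintf("eggshell: lx = %.4g um, ly = lz = %.4g um (AR = %.3g, V = %.5g um^3)\n",
              x$lx, x$ly, aspect_ratio(x), shell_volume(x)))
  invisible(x)
}

#' @rdname eggshell
#' @param shell An `eggshell` object.
#' @export
aspect_ratio <- function(shell) shell$lx / shell$ly

#' @rdname eggshell
#' @export
shell_volume <- function(shell) (4 / 3) * pi * shell$lx * shell$ly * shell$lz

#' Eggshell from aspect ratio at constant volume
#'
#' Reshapes the eggshell to a given aspect ratio while keeping its volume
#' fixed, as in constant-volume AR sweeps: `ly = (3 V / (4 pi ar))^(1/3)`,
#' `lx = ar * ly`.
#'
#' @param ar Aspect ratio `lx/ly`, dimensionless, must be >= 1.
#' @param volume Eggshell volume in cubic micrometres, must be > 0.
#' @return An `eggshell`.
#' @examples
#' axes_from_ar(2, (4 / 3) * pi * 1000)
#' @export
axes_from_ar <- function(ar, volume) {
  if (!is.numeric(ar) || length(ar) != 1L || !is.finite(ar) || ar < 1)
    stop("invalid parameter: ar must be a finite number >= 1")
  if (!is.numeric(volume) || length(volume) != 1L || !is.finite(volume) || volume <= 0)
    stop("invalid parameter: volume must be > 0")
  ly <- (3 * volume / (4 * pi * ar))^(1 / 3)
  eggshell(ar * ly, ly)
}

#' Is a point strictly inside the eggshell?
#'
#' @param shell An `eggshell`.
#' @param point Numeric 3-vector (x, y, z) in micrometres.
#' @return Logical; `TRUE` iff `x^2/lx^2 + (y^2+z^2)/ly^2 < 1`. Points on the
#'   surface are outside.
#' @export
shell_contains <- function(shell, point) {
  stopifnot(inherits(shell, "eggshell"), is.numeric(point), length(point) == 3L)
  point[1]^2 / shell$lx^2 + (point[2]^2 + point[3]^2) / shell$ly^2 < 1
}

## Perpendicular-foot solve for the nearest surface point of an interior
## point. Axial symmetry reduces the 3-D problem to the 2-D ellipse
## (lx, ly) and the point (x, t) with t = sqrt(y^2 + z^2). The foot point
## satisfies xf = lx^2 x / (lx^2 + mu), tf = ly^2 t / (ly^2 + mu) on the
## ellipse; for interior points the relevant root has mu in (-ly^2, 0].
## F(mu) is convex and decreasing there, so Newton from mu = 0 converges
## monotonically; a bisection guard covers pathological rounding.
.ellipse_foot_mu <- function(lx, ly, x, t, tol = 1e-12) {
  px2 <- (lx * x)^2
  pt2 <- (ly * t)^2
  f <- function(mu) px2 / (lx^2 + mu)^2 + pt2 / (ly^2 + mu)^2 - 1
  mu <- 0
  lo <- -ly^2
  for (k in 1:200) {
    fmu <- f(mu)
    if (abs(fmu) < tol) break
    df <- -2 * (px2 / (lx^2 + mu)^3 + pt2 / (ly^2 + mu)^3)
    step <- fmu / df
    mu_new <- mu - step
    if (mu_new <= lo) mu_new <- (mu + lo) / 2  # guard: stay in bracket
    if (abs(mu_new - mu) < tol * ly^2) { mu <- mu_new; break }
    mu <- mu_new
  }
  mu
}

## Nearest surface point ("foot"), distance and inward normal for an
## interior point; shared backend of min_shell_distance / shell_inward_normal.
.shell_foot <- function(shell, point) {
  lx <- shell$lx; ly <- shell$ly
  x <- point[1]; t2 <- point[2]^2 + point[3]^2; t <- sqrt(t2)
  if (!shell_contains(shell, point))
    stop("point is on or outside the eggshell")
  if (lx == ly) {                      # sphere: radial
    r <- sqrt(x^2 + t2)
    if (r == 0)                        # degenerate centre: fixed +x normal
      return(list(a = lx, foot = c(-lx, 0, 0), normal = c(1, 0, 0)))
    foot <- point * (lx / r)
    return(list(a = lx - r, foot = foot, normal = -point / r))
  }
  if (t < 1e-12 * ly) {                # on the major axis, prolate shell
    xc <- (lx^2 - ly^2) / lx           # evolute cusp: beyond it the pole is nearest
    if (abs(x) >= xc) {
      s <- if (x >= 0) 1 else -1
      return(list(a = lx - abs(x), foot = c(s * lx, 0, 0),
                  normal = c(-s, 0, 0)))
    }
    xf <- lx^2 * x / (lx^2 - ly^2)     # nearest points form a ring; pick +y azimuth
    tf <- ly * sqrt(1 - xf^2 / lx^2)
    a <- sqrt((x - xf)^2 + tf^2)
    return(list(a = a, foot = c(xf, tf, 0),
                normal = c(x - xf, -tf, 0) / a))
  }
  mu <- .ellipse_foot_mu(lx, ly, x, t)
  xf <- lx^2 * x / (lx^2 + mu)
  tf <- ly^2 * t / (ly^2 + mu)
  foot <- c(xf, tf * point[2] / t, tf * point[3] / t)
  d <- point - foot
  a <- sqrt(sum(d^2))
  list(a = a, foot = foot, normal = d / a)
}

#' Minimum distance from an interior point to the eggshell surface
#'
#' Solves the perpendicular-foot condition (a 1-D root problem in the
#' foot-point parameter, by bracketed Newton iteration) and returns the
#' Euclidean distance to the nearest surface point.
#'
#' @inheritParams shell_contains
#' @return Distance in micrometres (> 0).
#' @examples
#' min_shell_distance(eggshell(10, 10), c(5, 0, 0))  # 5
#' @export
min_shell_distance <- function(shell, point) .shell_foot(shell, point)$a

#' Inward surface normal at the nearest surface point
#'
#' Unit vector perpendicular to the eggshell at the foot point of `point`,
#' pointing from the surface toward the interior (toward the cell centre).
#' For a point at the exact centre of a spherical shell the direction is
#' undefined; a fixed `(+1, 0, 0)` convention is used (foot at `(-lx, 0, 0)`),
#' relying on thermal noise to break the symmetry in practice.
#'
#' @inheritParams shell_contains
#' @return Unit numeric 3-vector.
#' @export
shell_inward_normal <- function(shell, point) .shell_foot(shell, point)$normal
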