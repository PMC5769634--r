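# Shared test helpers: independent oracles and small state factories.

# Brute-force minimum distance from an interior point to the surface of an
# axisymmetric ellipsoid: dense sampling of the generating ellipse followed
# by golden-section refinement. Independent of the package's foot-point
# root solve.
brute_force_shell_distance <- function(lx, ly, point) {
  x <- point[1]
  t <- sqrt(point[2]^2 + point[3]^2)
  f <- function(th) sqrt((x - lx * cos(th))^2 + (t - ly * sin(th))^2)
  th <- seq(0, pi, length.out = 20001)   # t >= 0: upper half-ellipse suffices
  i <- which.min(f(th))
  lo <- th[max(1L, i - 2L)]; hi <- th[min(length(th), i + 2L)]
  stats::optimize(f, c(lo, hi), tol = 1e-13)$objective
}

brute_force_foot <- function(lx, ly, point) {
  x <- point[1]
  t <- sqrt(point[2]^2 + point[3]^2)
  f <- function(th) sqrt((x - lx * cos(th))^2 + (t - ly * sin(th))^2)
  th <- seq(0, pi, length.out = 20001)
  i <- which.min(f(th))
  lo <- th[max(1L, i - 2L)]; hi <- th[min(length(th), i + 2L)]
  best <- stats::optimize(f, c(lo, hi), tol = 1e-13)$minimum
  xf <- lx * cos(best); tf <- ly * sin(best)
  if (t > 0) c(xf, tf * point[2] / t, tf * point[3] / t) else c(xf, tf, 0)
}

# Random interior point of an ellipsoid, at ellipsoidal radius <= rho_max.
random_interior_point <- function(lx, ly, rho_max = 0.95) {
  repeat {
    p <- c(stats::runif(1, -lx, lx), stats::runif(1, -ly, ly),
           stats::runif(1, -ly, ly))
    rho2 <- p[1]^2 / lx^2 + (p[2]^2 + p[3]^2) / ly^2
    if (rho2 < rho_max^2) return(p)
  }
}

# Random valid four-cell state inside a shell (no containment guarantees
# beyond centres interior; used for force-law property tests).
random_four_cell_state <- function(shell = eggshell(25, 15)) {
  labs <- c("ABa", "ABp", "EMS", "P2")
  pts <- t(vapply(labs, function(l)
    random_interior_point(shell$lx, shell$ly, rho_max = 0.9), numeric(3)))
  cells <- data.frame(
    label = labs, x = pts[, 1], y = pts[, 2], z = pts[, 3],
    radius = stats::runif(4, 8, 12),
    stringsAsFactors = FALSE)
  embryo_state(0, cells, shell)
}

# Adjacency matrix over the four-cell labels from a plain edge list, e.g.
# graph_from_edges(c("ABa", "ABp"), c("ABp", "EMS")).
graph_from_edges <- function(...) {
  labs <- c("ABa", "ABp", "EMS", "P2")
  g <- matrix(FALSE, 4, 4, dimnames = list(labs, labs))
  for (e in list(...)) g[e[1], e[2]] <- g[e[2], e[1]] <- TRUE
  g
}

# Independent brute-force pattern matcher used as the oracle for the
# classifier's ABd-swap invariance: tests a graph against explicitly
# enumerated edge sets for both daughter assignments.
oracle_classify <- function(g) {
  swap <- function(m) {
    p <- c("ABp", "ABa", "EMS", "P2")
    m2 <- m[p, p]
    dimnames(m2) <- dimnames(m)
    m2
  }
  key <- function(m) {
    labs <- rownames(m)
    es <- character(0)
    for (i in 1:3) for (j in (i + 1):4) if (m[i, j])
      es <- c(es, paste(sort(c(labs[i], labs[j])), collapse = "-"))
    paste(sort(es), collapse = ";")
  }
  named <- list(
    pyramid = graph_from_edges(c("ABa","ABp"), c("ABa","EMS"), c("ABa","P2"),
                               c("ABp","EMS"), c("ABp","P2"), c("EMS","P2")),
    diamond = graph_from_edges(c("ABa","ABp"), c("ABa","EMS"), c("ABp","EMS"),
                               c("ABp","P2"), c("EMS","P2")),
    T_shaped = graph_from_edges(c("ABa","ABp"), c("ABa","EMS"),
                                c("ABp","EMS"), c("EMS","P2")),
    linear = graph_from_edges(c("ABa","ABp"), c("ABp","EMS"), c("EMS","P2")),
    T_reverse = graph_from_edges(c("ABa","ABp"), c("ABp","EMS"),
                                 c("ABp","P2"), c("EMS","P2")))
  for (nm in names(named)) {
    if (key(g) == key(named[[nm]]) || key(swap(g)) == key(named[[nm]]))
      return(nm)
  }
  deg <- rowSums(g)
  reach <- function(m) {                 # connectivity by matrix powers
    r <- diag(4) + m
    for (k in 1:3) r <- r %*% (diag(4) + m)
    all(r > 0)
  }
  if (all(deg == 2) && reach(g * 1)) return("H_shaped")
  "other"
}

# Enumerate all 64 labelled graphs on the four blastomeres.
all_four_cell_graphs <- function() {
  labs <- c("ABa", "ABp", "EMS", "P2")
  pairs <- utils::combn(labs, 2)
  lapply(0:63, function(bits) {
    g <- matrix(FALSE, 4, 4, dimnames = list(labs, labs))
    for (k in 1:6) if (bitwAnd(bits, bitwShiftL(1L, k - 1L)) != 0) {
      g[pairs[1, k], pairs[2, k]] <- g[pairs[2, k], pairs[1, k]] <- TRUE
    }
    g
  })
}

# Fast small config for simulator-level tests (not the frozen defaults).
quick_config <- function() {
  cfg <- default_config()
  cfg$settle <- 300
  cfg
}
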