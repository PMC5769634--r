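#' Contact graph of a four-cell state
#'
#' Two blastomeres are in contact iff their centre-to-centre distance is
#' strictly smaller than the sum of their radii (`d_ij < R_i + R_j`; exact
#' equality counts as non-contact).
#'
#' @param state An [embryo_state()] with exactly four cells, or a data
#'   frame with columns `label`, `x`, `y`, `z`, `radius`.
#' @return Symmetric logical adjacency matrix with the cell labels as
#'   dimnames and a `FALSE` diagonal.
#' @export
contact_graph <- function(state) {
  cells <- if (inherits(state, "embryo_state")) state$cells else state
  if (nrow(cells) != 4L) stop("contact graph requires exactly four cells")
  pos <- as.matrix(cells[, c("x", "y", "z")])
  n <- 4L
  adj <- matrix(FALSE, n, n, dimnames = list(cells$label, cells$label))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    adj[i, j] <- adj[j, i] <- d < cells$radius[i] + cells$radius[j]
  }
  adj
}

## Canonical edge sets of the named four-cell patterns, written over the
## placeholder AB daughters D1/D2 (interchangeable), EMS and P2. Each edge
## is a sorted label pair.
.pattern_templates <- function() {
  e <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    apply(m, 1, function(r) paste(sort(r), collapse = "|"))
  }
  list(
    pyramid   = e("D1", "D2", "D1", "EMS", "D2", "EMS",
                  "D1", "P2", "D2", "P2", "EMS", "P2"),
    diamond   = e("D1", "D2", "D1", "EMS", "D2", "EMS",
                  "D2", "P2", "EMS", "P2"),
    T_shaped  = e("D1", "D2", "D1", "EMS", "D2", "EMS", "EMS", "P2"),
    linear    = e("D1", "D2", "D2", "EMS", "EMS", "P2"),
    T_reverse = e("D1", "D2", "D2", "EMS", "D2", "P2", "EMS", "P2")
  )
}

.edge_set <- function(graph, map) {
  labs <- rownames(graph)
  out <- character(0)
  for (i in 1:3) for (j in (i + 1):4) if (graph[i, j])
    out <- c(out, paste(sort(c(map[labs[i]], map[labs[j]])), collapse = "|"))
  sort(out)
}

#' Classify a four-cell contact graph into an arrangement pattern
#'
#' Named patterns (matched up to swapping the two AB daughters, which are
#' not distinguishable by the mechanics):
#' \describe{
#'   \item{pyramid}{all four cells mutually in contact (6 edges).}
#'   \item{diamond}{all contacts except one AB-daughter--P2 pair (5 edges).}
#'   \item{T_shaped}{diamond additionally missing the other AB-daughter--P2
#'     contact (4 edges).}
#'   \item{linear}{chain ABd--ABd--EMS--P2 (3 edges).}
#'   \item{T_reverse}{one AB daughter contacts EMS and P2 while its sister
#'     contacts only it (4 edges).}
#'   \item{H_shaped}{a 4-cycle: every cell contacts exactly its two
#'     neighbours.}
#'   \item{other}{anything else.}
#' }
#'
#' @param graph Logical adjacency matrix from [contact_graph()], with
#'   dimnames drawn from ABa, ABp, EMS, P2.
#' @return Single character pattern label.
#' @examples
#' st <- data.frame(label = c("ABa", "ABp", "EMS", "P2"),
#'                  x = c(0, 0, 10, 20), y = 0, z = c(0, 10, 5, 5),
#'                  radius = 7)
#' classify_pattern(contact_graph(st))
#' @export
classify_pattern <- function(graph) {
  labs <- sort(rownames(graph))
  if (!identical(labs, c("ABa", "ABp", "EMS", "P2")))
    stop("graph must be over labels ABa, ABp, EMS, P2")
  if (!isTRUE(all.equal(graph, t(graph))) || any(diag(graph)))
    stop("graph must be symmetric with no self-contacts")
  maps <- list(c(ABa = "D1", ABp = "D2", EMS = "EMS", P2 = "P2"),
               c(ABa = "D2", ABp = "D1", EMS = "EMS", P2 = "P2"))
  templates <- .pattern_templates()
  for (map in maps) {
    es <- .edge_set(graph, map)
    for (nm in names(templates))
      if (identical(es, sort(templates[[nm]]))) return(nm)
  }
  deg <- rowSums(graph)
  if (all(deg == 2) && .is_connected(graph)) return("H_shaped")
  "other"
}

.is_connected <- function(graph) {
  n <- nrow(graph)
  seen <- logical(n); seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(apply(graph[frontier, , drop = FALSE], 2, any) & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' All recognised pattern labels
#' @return Character vector of the seven labels in a fixed order.
#' @export
pattern_levels <- function() {
  c("pyramid", "diamond", "T_shaped", "linear", "T_reverse", "H_shaped",
    "other")
}

#' Stable repulsion ratio of an attached cell pair
#'
#' The centre-to-centre distance divided by the sum of radii,
#' `alpha = d_ij / (R_i + R_j)`. For two cells at mechanical equilibrium
#' this is the pair's stable repulsion ratio: 1.0 under pure repulsion,
#' below 1 when net adhesion pulls the centres closer than contact.
#'
#' @param d_ij Centre-to-centre distance (um), > 0.
#' @param R_i,R_j Cell radii (um), > 0.
#' @return Dimensionless ratio.
#' @examples
#' stable_repulsion_ratio(1.5, 1, 1)  # 0.75
#' @export
stable_repulsion_ratio <- function(d_ij, R_i, R_j) {
  if (any(c(d_ij, R_i, R_j) <= 0)) stop("all inputs must be positive")
  d_ij / (R_i + R_j)
}

#' Read a cell-configuration fixture from CSV
#'
#' Expects columns `label`, `x`, `y`, `z`, `radius` (micrometres), one row
#' per cell, as written by hand for classifier tests.
#'
#' @param path CSV file path.
#' @return Data frame suitable for [contact_graph()].
#' @export
read_cells_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z", "radius")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("fixture is missing column(s): ", paste(miss, collapse = ", "))
  df[need]
}
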