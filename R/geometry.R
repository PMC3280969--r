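#' Icosahedron face-adjacency graph
#'
#' Builds the 20-face adjacency matrix of a regular icosahedron from its
#' vertex coordinates (cyclic permutations of (0, +/-1, +/-phi)). Faces are
#' the 20 vertex triples at mutual unit edge distance; two faces are
#' adjacent when they share an edge. Every face has exactly 3 neighbours
#' and the graph has 30 edges.
#'
#' @return a 20 x 20 logical adjacency matrix.
#' @keywords internal
icosahedron_adjacency <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    cbind(0, c(1, 1, -1, -1), c(phi, -phi, phi, -phi)),
    cbind(c(1, 1, -1, -1), c(phi, -phi, phi, -phi), 0),
    cbind(c(phi, -phi, phi, -phi), 0, c(1, 1, -1, -1))
  )
  d <- as.matrix(dist(v))
  edge <- abs(d - 2) < 1e-9
  faces <- list()
  for (i in 1:10) for (j in (i + 1):11) for (k in (j + 1):12) {
    if (edge[i, j] && edge[j, k] && edge[i, k]) {
      faces[[length(faces) + 1L]] <- c(i, j, k)
    }
  }
  stopifnot(length(faces) == 20L)
  adj <- matrix(FALSE, 20, 20)
  for (a in 1:19) for (b in (a + 1):20) {
    if (length(intersect(faces[[a]], faces[[b]])) == 2L) {
      adj[a, b] <- adj[b, a] <- TRUE
    }
  }
  stopifnot(sum(adj) == 60L)  # 30 undirected edges
  adj
}

#' Per-addition contact schedule for one icosahedral layer
#'
#' Reconstructs the number of new inter-subunit contacts gained at each of
#' the 20 subunit additions of a layer by greedy growth on the icosahedron
#' face-adjacency graph: each new face is the one sharing the most edges
#' with the already-placed cluster (lowest face index on ties), i.e. the
#' next most stable arrangement. For a free-standing layer the first entry
#' is 0 and the entries sum to 30 (the icosahedron edge count). For a
#' template-docked layer every addition gains one additional contact with
#' the underlying completed layer, so the first entry is 1 and the entries
#' sum to 50.
#'
#' @param docked logical; does the layer assemble on a completed template?
#' @param n_subunits number of structural subunits; only 20 is supported.
#' @return integer vector of length 20; element m is the number of
#'   contacts gained when the m-th subunit is added.
#' @examples
#' sum(contact_schedule(docked = FALSE))  # 30
#' sum(contact_schedule(docked = TRUE))   # 50
#' @export
contact_schedule <- function(docked = FALSE, n_subunits = 20L) {
  if (n_subunits != 20L) {
    stop("only 20-subunit icosahedral layers are implemented", call. = FALSE)
  }
  adj <- icosahedron_adjacency()
  placed <- 1L
  sched <- integer(20)
  sched[1] <- 0L
  remaining <- 2:20
  for (m in 2:20) {
    gains <- vapply(remaining, function(f) sum(adj[f, placed]), integer(1))
    pick <- remaining[which.max(gains)]
    sched[m] <- max(gains)
    placed <- c(placed, pick)
    remaining <- setdiff(remaining, pick)
  }
  stopifnot(sum(sched) == 30L)
  if (docked) sched <- sched + 1L
  sched
}
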