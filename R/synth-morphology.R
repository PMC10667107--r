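#' Construct a skeletonized glial cell morphology
#'
#' A `cell_morphology` is a skeleton graph rooted at the soma — nodes are
#' 3D positions in micrometers, edges are straight process segments with a
#' thickness — plus a set of CD68-like (lysosomal label) connected
#' components given by their volumes.
#'
#' @param nodes numeric matrix (n x 3) of node coordinates in um; row 1 is
#'   the soma center.
#' @param edges data.frame with integer columns `from`, `to` (node row
#'   indices) and `thickness_um`.
#' @param cd68_volumes_um3 numeric vector of CD68 component volumes (um^3).
#' @param cell_id label.
#' @return An object of class `cell_morphology` with edge lengths derived
#'   from node coordinates.
#' @export
cell_morphology <- function(nodes, edges = NULL, cd68_volumes_um3 = numeric(0),
                            cell_id = "cell1") {
  nodes <- as.matrix(nodes)
  if (ncol(nodes) != 3L || nrow(nodes) < 1L)
    stop("'nodes' must be an n x 3 matrix with the soma in row 1", call. = FALSE)
  if (is.null(edges))
    edges <- data.frame(from = integer(0), to = integer(0),
                        thickness_um = numeric(0))
  if (nrow(edges)) {
    if (any(edges$from < 1L | edges$from > nrow(nodes) |
            edges$to < 1L | edges$to > nrow(nodes)))
      stop("edge endpoints outside node table", call. = FALSE)
    len <- sqrt(rowSums((nodes[edges$from, , drop = FALSE] -
                           nodes[edges$to, , drop = FALSE])^2))
    if (any(len <= 0)) stop("zero-length process edge", call. = FALSE)
    edges$length_um <- len
    # skeleton must be connected to the soma
    g <- igraph::graph_from_edgelist(cbind(edges$from, edges$to),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nrow(nodes) - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
    used <- unique(c(edges$from, edges$to))
    if (any(memb[used] != memb[1L]))
      stop("skeleton graph is not connected to the soma", call. = FALSE)
  } else {
    edges$length_um <- numeric(0)
  }
  if (any(cd68_volumes_um3 < 0))
    stop("CD68 component volumes must be >= 0", call. = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 soma_um = nodes[1L, ],
                 cd68_volumes_um3 = as.numeric(cd68_volumes_um3),
                 cell_id = cell_id),
            class = "cell_morphology")
}

#' Simulate a microglial morphology of a given phagocytic-state intent
#'
#' Builds a skeleton graph and CD68 component set whose quantitative
#' features fall inside the default scoring bands for the intended
#' phagocytic state (0 = ramified surveillant, 5 = fully amoeboid with
#' aggregated lysosomal label). Intent `s` is realized as the canonical
#' decomposition morphology + CD68 = `(0,0), (1,0), (2,0), (2,1), (3,1),
#' (3,2)` for `s = 0..5`.
#'
#' @param class_label intended phagocytic state, integer 0–5.
#' @param seed integer seed.
#' @param cell_id label.
#' @return A `cell_morphology`.
#' @seealso [score_morphology()], [score_cd68()], [phagocytic_state()]
#' @export
gen_microglia_morphology <- function(class_label, seed = 1L,
                                     cell_id = "cell1") {
  if (!is.numeric(class_label) || length(class_label) != 1L ||
      is.na(class_label) || class_label %% 1 != 0 ||
      class_label < 0 || class_label > 5)
    stop("'class_label' must be an integer in 0..5", call. = FALSE)
  s <- as.integer(class_label)
  morph <- c(0L, 1L, 2L, 2L, 3L, 3L)[s + 1L]
  cd68 <- s - morph
  with_stream(seed, paste0("microglia_morphology_", s), {
    soma <- c(0, 0, 0)
    nodes <- matrix(soma, 1L, 3L)
    edges <- data.frame(from = integer(0), to = integer(0),
                        thickness_um = numeric(0))
    add_node <- function(p) {
      nodes <<- rbind(nodes, p)
      nrow(nodes)
    }
    add_edge <- function(a, b, th) {
      edges <<- rbind(edges, data.frame(from = a, to = b, thickness_um = th))
    }
    unit <- function() {
      v <- rnorm(3L)
      v / sqrt(sum(v^2))
    }
    if (morph <= 1L) {
      # ramified: 4 long primaries, each bifurcating twice
      th <- if (morph == 0L) runif(1, 0.3, 0.5) else runif(1, 0.7, 0.9)
      for (p in 1:4) {
        d <- unit()
        mid <- add_node(soma + d * runif(1, 8, 10))
        add_edge(1L, mid, th)
        for (b in 1:2) {
          d2 <- d + rnorm(3L, 0, 0.4)
          d2 <- d2 / sqrt(sum(d2^2))
          tip <- add_node(nodes[mid, ] + d2 * runif(1, 7, 9))
          add_edge(mid, tip, th)
        }
      }
    } else if (morph == 2L) {
      # retracted: 3 thick stubby unbranched processes
      th <- runif(1, 1.3, 1.7)
      for (p in 1:3) {
        tip <- add_node(soma + unit() * runif(1, 3, 5))
        add_edge(1L, tip, th)
      }
    } # morph == 3: amoeboid, no process edges
    cd68_vols <- switch(as.character(cd68),
                        "0" = numeric(0),
                        "1" = runif(4L, 0.2, 0.4),
                        "2" = c(runif(1, 6, 10), runif(2L, 0.2, 0.4)))
    cell_morphology(nodes, if (nrow(edges)) edges else NULL, cd68_vols,
                    cell_id = cell_id)
  })
}
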