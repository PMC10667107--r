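#' Default band thresholds for the morphology sub-score
#'
#' The published rubric is qualitative; these bands operationalize it on
#' skeleton features so the 0–3 scale is reproducible: 0 = thin long
#' processes with multiple branches, 1 = thicker processes with similar
#' branching, 2 = thick retracted processes with few branches, 3 = no
#' clear processes.
#'
#' @param min_total_length_um below this total process length a cell
#'   counts as having no clear processes (score 3).
#' @param few_branch_max maximal branch-point count for score 2.
#' @param thick_um mean thickness at or above which retracted cells score 2.
#' @param thicker_um mean thickness separating score 0 from score 1.
#' @return Named list of thresholds.
#' @export
morphology_bands <- function(min_total_length_um = 5, few_branch_max = 3,
                             thick_um = 1.0, thicker_um = 0.6) {
  list(min_total_length_um = min_total_length_um,
       few_branch_max = few_branch_max,
       thick_um = thick_um, thicker_um = thicker_um)
}

#' Default band thresholds for the CD68 sub-score
#'
#' 0 = no/scarce expression, 1 = punctate expression, 2 = aggregated
#' expression or punctate expression all over the cell.
#'
#' @param scarce_total_um3 total CD68 volume below which expression is
#'   scored scarce (0).
#' @param aggregate_um3 single-component volume at or above which
#'   expression is scored aggregated (2).
#' @param widespread_count component count at or above which punctate
#'   expression covers the whole cell (2).
#' @return Named list of thresholds.
#' @export
cd68_bands <- function(scarce_total_um3 = 0.5, aggregate_um3 = 5,
                       widespread_count = 12) {
  list(scarce_total_um3 = scarce_total_um3, aggregate_um3 = aggregate_um3,
       widespread_count = widespread_count)
}

#' Score process morphology on the 0–3 scale
#'
#' @param cell a [cell_morphology()].
#' @param bands thresholds from [morphology_bands()].
#' @return Integer 0–3.
#' @export
score_morphology <- function(cell, bands = morphology_bands()) {
  stopifnot(inherits(cell, "cell_morphology"))
  e <- cell$edges
  if (nrow(e) == 0L || sum(e$length_um) < bands$min_total_length_um)
    return(3L)
  n_branch <- branch_count(cell)
  mean_thick <- mean(e$thickness_um)
  if (n_branch <= bands$few_branch_max && mean_thick >= bands$thick_um)
    return(2L)
  if (mean_thick >= bands$thicker_um) return(1L)
  0L
}

#' Score CD68 (lysosomal label) expression on the 0–2 scale
#'
#' @param cell a [cell_morphology()].
#' @param bands thresholds from [cd68_bands()].
#' @return Integer 0–2.
#' @export
score_cd68 <- function(cell, bands = cd68_bands()) {
  stopifnot(inherits(cell, "cell_morphology"))
  v <- cell$cd68_volumes_um3
  if (!length(v) || sum(v) < bands$scarce_total_um3) return(0L)
  if (max(v) >= bands$aggregate_um3 || length(v) >= bands$widespread_count)
    return(2L)
  1L
}

#' Phagocytic state of a microglial population
#'
#' Per cell, the state is the sum of the morphology (0–3) and CD68 (0–2)
#' sub-scores, giving 0 (least phagocytic) to 5 (most). The population
#' distribution is the percentage of cells at each score, summing to 100.
#'
#' @param cells list of [cell_morphology()] objects.
#' @param morph_bands,cd_bands band thresholds.
#' @param expected_n warn when the population is outside this range
#'   (cells per animal in the standard design); `NULL` disables.
#' @return A list with `scores` (data.frame cell_id, morphology_score,
#'   cd68_score, state) and `distribution` (named percentages for states
#'   0–5).
#' @examples
#' cells <- lapply(0:5, gen_microglia_morphology, seed = 4)
#' phagocytic_state(cells, expected_n = NULL)$scores$state
#' @export
phagocytic_state <- function(cells, morph_bands = morphology_bands(),
                             cd_bands = cd68_bands(),
                             expected_n = c(30L, 50L)) {
  if (!length(cells)) stop("empty cell population", call. = FALSE)
  if (!is.null(expected_n) &&
      (length(cells) < expected_n[1L] || length(cells) > expected_n[2L]))
    warning(sprintf("population of %d cells outside the expected %d-%d range",
                    length(cells), expected_n[1L], expected_n[2L]))
  m <- vapply(cells, score_morphology, 0L, bands = morph_bands)
  cd <- vapply(cells, score_cd68, 0L, bands = cd_bands)
  ids <- vapply(cells, function(c) c$cell_id, "")
  state <- m + cd
  dist <- 100 * tabulate(state + 1L, nbins = 6L) / length(state)
  names(dist) <- 0:5
  list(scores = data.frame(cell_id = ids, morphology_score = m,
                           cd68_score = cd, state = state),
       distribution = dist)
}

#' Sholl profile of a skeletonized cell
#'
#' For concentric spheres around the soma at a fixed radius step, counts
#' process intersections (edges crossing the sphere), branch points and
#' terminal points within each shell `(r - step, r]`.
#'
#' @param cell a [cell_morphology()].
#' @param radius_step_um shell width (um).
#' @return A data.frame (class `sholl_profile`) with columns `radius_um`,
#'   `intersections`, `branch_points`, `terminals`.
#' @export
sholl_profile <- function(cell, radius_step_um = 5) {
  stopifnot(inherits(cell, "cell_morphology"))
  stopifnot_scalar(radius_step_um, "radius_step_um", lower = 0,
                   strict_lower = TRUE)
  nd <- node_distances(cell)
  if (nrow(cell$edges) == 0L) {
    return(structure(data.frame(radius_um = radius_step_um,
                                intersections = 0L, branch_points = 0L,
                                terminals = 0L),
                     class = c("sholl_profile", "data.frame")))
  }
  rmax <- max(nd)
  radii <- seq(radius_step_um, ceiling(rmax / radius_step_um) * radius_step_um,
               by = radius_step_um)
  d1 <- nd[cell$edges$from]
  d2 <- nd[cell$edges$to]
  dn <- pmin(d1, d2); df <- pmax(d1, d2)
  deg <- node_degrees(cell)
  is_branch <- deg >= 3L & seq_along(deg) != 1L
  is_term <- deg == 1L & seq_along(deg) != 1L
  out <- data.frame(radius_um = radii,
                    intersections = vapply(radii, function(r)
                      sum(dn < r & df >= r), 0L),
                    branch_points = vapply(radii, function(r)
                      sum(is_branch & nd > r - radius_step_um & nd <= r), 0L),
                    terminals = vapply(radii, function(r)
                      sum(is_term & nd > r - radius_step_um & nd <= r), 0L))
  structure(out, class = c("sholl_profile", "data.frame"))
}

node_distances <- function(cell) {
  sqrt(rowSums(sweep(cell$nodes, 2L, cell$soma_um)^2))
}

node_degrees <- function(cell) {
  deg <- integer(nrow(cell$nodes))
  if (nrow(cell$edges)) {
    t1 <- tabulate(cell$edges$from, nbins = nrow(cell$nodes))
    t2 <- tabulate(cell$edges$to, nbins = nrow(cell$nodes))
    deg <- t1 + t2
  }
  deg
}

branch_count <- function(cell) {
  deg <- node_degrees(cell)
  sum(deg >= 3L & seq_along(deg) != 1L)
}
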