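# Phagocytic-state scoring and Sholl profiles.

make_cell <- function(nodes, edges, cd68 = numeric(0)) {
  cell_morphology(nodes, edges, cd68)
}

test_that("morphology scoring follows the 0-3 rubric bands", {
  # no processes at all -> 3
  bare <- cell_morphology(matrix(0, 1, 3))
  expect_equal(score_morphology(bare), 3L)
  # thick short unbranched stubs -> 2
  stubs <- make_cell(rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(-4, 0, 0)),
                     data.frame(from = 1, to = 2:4, thickness_um = 1.5))
  expect_equal(score_morphology(stubs), 2L)
  # long branched, thicker processes -> 1
  nodes <- rbind(c(0, 0, 0), c(10, 0, 0), c(18, 4, 0), c(18, -4, 0),
                 c(0, 10, 0), c(4, 18, 0), c(-4, 18, 0))
  edges <- data.frame(from = c(1, 2, 2, 1, 5, 5), to = c(2, 3, 4, 5, 6, 7),
                      thickness_um = 0.8)
  expect_equal(score_morphology(make_cell(nodes, edges)), 1L)
  # same geometry, thin processes -> 0
  edges$thickness_um <- 0.4
  expect_equal(score_morphology(make_cell(nodes, edges)), 0L)
})

test_that("CD68 scoring distinguishes scarce, punctate and aggregated", {
  base <- matrix(0, 1, 3)
  expect_equal(score_cd68(cell_morphology(base)), 0L)
  expect_equal(score_cd68(cell_morphology(base, cd68_volumes_um3 = c(0.1))), 0L)
  expect_equal(score_cd68(cell_morphology(base,
                                          cd68_volumes_um3 = rep(0.3, 4))), 1L)
  expect_equal(score_cd68(cell_morphology(base, cd68_volumes_um3 = c(8))), 2L)
  expect_equal(score_cd68(cell_morphology(base,
                                          cd68_volumes_um3 = rep(0.3, 15))), 2L)
})

test_that("state sums the sub-scores and the distribution sums to 100", {
  cells <- c(lapply(1:2, function(i) gen_microglia_morphology(5, seed = i)),
             lapply(3:4, function(i) gen_microglia_morphology(0, seed = i)))
  res <- phagocytic_state(cells, expected_n = NULL)
  expect_equal(res$scores$state,
               res$scores$morphology_score + res$scores$cd68_score)
  expect_equal(sort(unique(res$scores$state)), c(0L, 5L))
  expect_equal(unname(res$distribution[c("0", "5")]), c(50, 50))
  expect_equal(sum(res$distribution), 100, tolerance = 1e-9)
  expect_error(phagocytic_state(list()), "empty")
  expect_warning(phagocytic_state(cells, expected_n = c(30L, 50L)),
                 "expected 30-50")
})

test_that("state increases with either sub-score", {
  states <- vapply(0:5, function(s) {
    cell <- gen_microglia_morphology(s, seed = 3)
    score_morphology(cell) + score_cd68(cell)
  }, 0L)
  expect_identical(states, 0:5)
})

test_that("Sholl profile counts crossings for simple geometries", {
  # single straight 20-um process
  straight <- make_cell(rbind(c(0, 0, 0), c(20, 0, 0)),
                        data.frame(from = 1, to = 2, thickness_um = 0.5))
  sp <- sholl_profile(straight, radius_step_um = 5)
  expect_equal(sp$intersections[sp$radius_um %in% c(5, 10, 15)], c(1L, 1L, 1L))
  # bifurcation at 7 um: one crossing at 5, two at 10
  bif <- make_cell(rbind(c(0, 0, 0), c(7, 0, 0), c(12, 3, 0), c(12, -3, 0)),
                   data.frame(from = c(1, 2, 2), to = c(2, 3, 4),
                              thickness_um = 0.5))
  sb <- sholl_profile(bif, radius_step_um = 5)
  expect_equal(sb$intersections[sb$radius_um == 5], 1L)
  expect_equal(sb$intersections[sb$radius_um == 10], 2L)
  # no processes: all-zero profile
  sn <- sholl_profile(cell_morphology(matrix(0, 1, 3)))
  expect_true(all(sn$intersections == 0 & sn$branch_points == 0 &
                    sn$terminals == 0))
})

test_that("Sholl crossings equal terminals of the radius-truncated subtree", {
  # oracle: for a tree with radially monotone edges, the number of edges
  # crossing radius r equals the number of leaves of the tree truncated at r
  set.seed(19)
  for (rep in 1:20) {
    nodes <- matrix(0, 1, 3)
    edges <- data.frame(from = integer(0), to = integer(0),
                        thickness_um = numeric(0))
    n_edge <- sample(2:10, 1)
    for (e in seq_len(n_edge)) {
      parent <- sample(nrow(nodes), 1)
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      pr <- sqrt(sum(nodes[parent, ]^2))
      # child strictly farther from the soma than its parent
      child <- nodes[parent, ] + dir * runif(1, 1, 6)
      if (sqrt(sum(child^2)) <= pr) next
      nodes <- rbind(nodes, child)
      edges <- rbind(edges, data.frame(from = parent, to = nrow(nodes),
                                       thickness_um = 0.5))
    }
    if (!nrow(edges)) next
    cell <- cell_morphology(nodes, edges)
    prof <- sholl_profile(cell, radius_step_um = 2)
    nd <- sqrt(rowSums(nodes^2))
    for (k in seq_len(nrow(prof))) {
      r <- prof$radius_um[k]
      crossing <- sum(pmin(nd[edges$from], nd[edges$to]) < r &
                        pmax(nd[edges$from], nd[edges$to]) >= r)
      expect_equal(prof$intersections[k], crossing)
      # truncated-subtree leaves = edges cut by the sphere (tree topology)
      expect_equal(prof$intersections[k],
                   sum(nd[edges$from] < r & nd[edges$to] >= r))
    }
  }
})
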