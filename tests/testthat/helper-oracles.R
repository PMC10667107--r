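# Independent oracles and small fixture builders shared across tests.

# Brute-force maximum bipartite matching size by recursion over the first
# point set; exponential, only for small instances.
bf_match_count <- function(a, b, maxd) {
  n1 <- nrow(a); n2 <- nrow(b)
  if (n1 == 0L || n2 == 0L) return(0L)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  ok <- sqrt(pmax(d2, 0)) < maxd
  rec <- function(i, used) {
    if (i > n1) return(0L)
    best <- rec(i + 1L, used)           # leave i unmatched
    for (j in seq_len(n2)) {
      if (ok[i, j] && !used[j]) {
        used[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1L, logical(n2))
}

# igraph-based maximum matching size (independent of the package's own
# greedy + augmenting implementation).
igraph_match_count <- function(a, b, maxd) {
  n1 <- nrow(a); n2 <- nrow(b)
  if (n1 == 0L || n2 == 0L) return(0L)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  ok <- which(sqrt(pmax(d2, 0)) < maxd, arr.ind = TRUE)
  if (!nrow(ok)) return(0L)
  g <- igraph::make_empty_graph(n = n1 + n2, directed = FALSE)
  g <- igraph::add_edges(g, rbind(ok[, 1L], n1 + ok[, 2L]))
  igraph::V(g)$type <- c(rep(FALSE, n1), rep(TRUE, n2))
  igraph::max_bipartite_match(g)$matching_size
}

# Synthetic raw field from explicit centers (no noise) for detector tests.
field_from_centers <- function(centers, field_size = c(8, 8, 3),
                               voxel = c(0.1, 0.1, 0.25),
                               sigma = c(0.08, 0.08, 0.2),
                               snr = 30, bg = 20, seed = 1) {
  spec <- field_spec(field_size_um = field_size, voxel_size_um = voxel,
                     pre_density = 1e-9, coloc_fraction = 0,
                     complement_background_density = 0,
                     psf_sigma_um = sigma, snr = snr,
                     background_photons = bg, seed = seed)
  sim <- gen_synapse_field(spec)
  dimv <- dim(sim$field$intensities$pre)
  set.seed(seed)
  a <- array(rpois(prod(dimv), bg), dimv)
  for (r in seq_len(nrow(centers))) {
    ci <- centers[r, ] / voxel + 0.5
    lo <- pmax(1, floor(ci - 4)); hi <- pmin(dimv, ceiling(ci + 4))
    gx <- exp(-((lo[1]:hi[1] - ci[1]) * voxel[1])^2 / (2 * sigma[1]^2))
    gy <- exp(-((lo[2]:hi[2] - ci[2]) * voxel[2])^2 / (2 * sigma[2]^2))
    gz <- exp(-((lo[3]:hi[3] - ci[3]) * voxel[3])^2 / (2 * sigma[3]^2))
    blob <- bg * (snr - 1) * outer(outer(gx, gy), gz)
    a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + blob
  }
  sim$field$intensities$pre <- a
  sim$field
}

# Deterministic event train with given times/amps.
fixed_train <- function(times, amps = NULL, cell_id = "c1", group = "A",
                        duration = max(times, 1)) {
  if (is.null(amps)) amps <- rep(10, length(times))
  event_train(cell_id, group, times, amps, duration)
}
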