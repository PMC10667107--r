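# Internal utilities: seeded streams, validation, 3D Gaussian blur,
# connected-component labelling, bipartite matching.

# Derive a reproducible substream seed from a root seed and a stage name so
# that each generator draws from an isolated stream.
derive_seed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  as.integer((seed %% 2147483647L) * 48271 %% 2147483647 + h) %% 2147483647L
}

# Evaluate `expr` under a deterministic stream, restoring .Random.seed after.
with_stream <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, stage))
  expr
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  if (x > upper)
    stop(sprintf("'%s' must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}

stopifnot_vec3 <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 3L || anyNA(x))
    stop(sprintf("'%s' must be a numeric 3-vector", name), call. = FALSE)
  if (positive && any(x <= 0))
    stop(sprintf("all elements of '%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

# Separable Gaussian blur of a 3D array; sigma in voxel units per axis.
gauss_blur3d <- function(a, sigma_vox) {
  for (axis in 1:3) a <- blur_axis(a, axis, sigma_vox[axis])
  a
}

blur_axis <- function(a, axis, sigma) {
  if (sigma <= 0) return(a)
  k <- max(1L, ceiling(3 * sigma))
  w <- dnorm(seq(-k, k), sd = sigma)
  w <- w / sum(w)
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(a, perm), nrow = d[axis])
  mp <- rbind(m[rep(1L, k), , drop = FALSE], m,
              m[rep(nrow(m), k), , drop = FALSE])
  f <- stats::filter(mp, w, sides = 2)
  f <- f[(k + 1L):(k + nrow(m)), , drop = FALSE]
  aperm(array(as.numeric(f), d[perm]), order(perm))
}

# 6/4-connected component labelling of a logical 3D array via igraph.
# Returns integer labels (0 = background). connect_z = FALSE restricts
# connectivity to the imaging plane (per-plane 2D components).
label_components <- function(mask, connect_z = TRUE) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- integer(prod(d))
  if (!length(idx)) return(array(lab, d))
  key <- integer(prod(d))
  key[idx] <- seq_along(idx)
  pos <- arrayInd(idx, d)
  strides <- c(1L, d[1L], d[1L] * d[2L])
  axes <- if (connect_z) 1:3 else 1:2
  ef <- integer(0); et <- integer(0)
  for (ax in axes) {
    ok <- pos[, ax] < d[ax]
    nb <- idx[ok] + strides[ax]
    sel <- key[nb] > 0L
    ef <- c(ef, key[idx[ok]][sel])
    et <- c(et, key[nb][sel])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(ef))
    g <- igraph::add_edges(g, rbind(ef, et))
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  array(lab, d)
}

# Maximum-cardinality one-to-one matching between two point sets given a
# strict distance cutoff. Greedy by ascending distance, then Kuhn
# augmenting paths to guarantee maximum cardinality. Returns a data.frame
# (i, j, distance_um) with i indexing `a` rows, j indexing `b` rows.
match_points <- function(a, b, max_distance) {
  n1 <- nrow(a); n2 <- nrow(b)
  empty <- data.frame(i = integer(0), j = integer(0), distance_um = numeric(0))
  if (n1 == 0L || n2 == 0L) return(empty)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  D <- sqrt(d2)
  cand <- which(D < max_distance, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  ord <- order(D[cand])
  cand <- cand[ord, , drop = FALSE]
  match_a <- integer(n1); match_b <- integer(n2)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1L]; j <- cand[r, 2L]
    if (match_a[i] == 0L && match_b[j] == 0L) {
      match_a[i] <- j; match_b[j] <- i
    }
  }
  adj <- split(cand[, 2L], factor(cand[, 1L], levels = seq_len(n1)))
  # DFS augmenting path; seen_env / match vectors live in this frame
  kuhn_env <- function(i) {
    for (j in adj[[i]]) {
      if (!seen_env[j]) {
        seen_env[j] <<- TRUE
        if (match_b[j] == 0L || kuhn_env(match_b[j])) {
          match_a[i] <<- j; match_b[j] <<- i
          return(TRUE)
        }
      }
    }
    FALSE
  }
  for (i in seq_len(n1)) {
    if (match_a[i] == 0L && length(adj[[i]])) {
      seen_env <- logical(n2)
      kuhn_env(i)
    }
  }
  keep <- which(match_a > 0L)
  data.frame(i = keep, j = match_a[keep],
             distance_um = D[cbind(keep, match_a[keep])])
}

# Empirical quantile, type 7 (linear interpolation of the ECDF).
quantile7 <- function(x, q) {
  n <- length(x)
  if (n == 1L) return(x)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  fr <- h - lo
  hi <- min(lo + 1, n)
  xs <- sort(x, partial = unique(c(lo, hi)))
  xs[lo] + fr * (xs[hi] - xs[lo])
}
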