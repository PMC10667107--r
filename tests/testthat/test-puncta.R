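# Puncta detection, synapse pairing, co-localization and the rotation null.

test_that("degenerate channels give empty spot sets", {
  f <- list(intensities = list(pre = array(0, c(10, 10, 4))),
            voxel_size_um = c(0.1, 0.1, 0.25), field_id = "f")
  expect_warning(s <- detect_puncta(f, "pre"), "constant")
  expect_equal(nrow(s), 0L)
  expect_error(detect_puncta(f, "nope"), "not present")
})

test_that("well-separated spots are recovered near their true centers", {
  set.seed(11)
  grid <- expand.grid(x = seq(1, 7, by = 1.5), y = seq(1, 7, by = 1.5))
  centers <- cbind(grid$x, grid$y, 1.5)[1:25, ]
  centers <- centers + matrix(runif(75, -0.2, 0.2), ncol = 3)
  f <- field_from_centers(centers)
  spots <- detect_puncta(f, "pre", detection_params())
  expect_equal(nrow(spots), 25, tolerance = 0)
  m <- pair_synapses(spot_set(centers, field_id = "f"),
                     structure(spots, field_id = "f"), max_distance_um = 0.3)
  expect_equal(nrow(m), 25)
  expect_lt(max(m$distance_um), 0.1)
})

test_that("dimension criteria exclude components outside the volume bounds", {
  a <- array(0, c(20, 20, 6))
  a[10, 10, 3] <- 100                        # single-voxel blob, 0.0025 um3
  a[3:5, 3:5, 2:4] <- 100                    # 27 voxels = 0.0675 um3
  f <- list(intensities = list(pre = a), voxel_size_um = c(0.1, 0.1, 0.25),
            field_id = "f")
  p <- detection_params(smoothing_sigma_um = c(0, 0, 0),
                        threshold_method = "fixed", threshold = 50,
                        min_volume_um3 = 0.02, min_peak_snr = 0,
                        split_touching = FALSE)
  spots <- detect_puncta(f, "pre", p)
  expect_equal(nrow(spots), 1L)
  expect_equal(spots$volume_um3, 27 * 0.0025)
})

test_that("synapse calling applies a strict distance threshold", {
  pre <- spot_set(rbind(c(1, 1, 1)), "pre")
  post_near <- spot_set(rbind(c(1.25, 1, 1)), "post")
  expect_equal(nrow(pair_synapses(pre, post_near)), 1L)
  post_at <- spot_set(rbind(c(1.30, 1, 1)), "post")
  expect_equal(nrow(pair_synapses(pre, post_at)), 0L)  # exactly 0.3 excluded
})

test_that("pairing maximizes pair count, not greedy shortsightedness", {
  # pre1 near two posts; pre2 only reaches post2: maximum matching pairs both
  pre <- spot_set(rbind(c(0, 0, 0), c(0.45, 0, 0)), "pre")
  post <- spot_set(rbind(c(0.10, 0, 0), c(0.20, 0, 0)), "post")
  m <- pair_synapses(pre, post, max_distance_um = 0.3)
  expect_equal(nrow(m), 2L)
  expect_equal(bf_match_count(rbind(c(0, 0, 0), c(0.45, 0, 0)),
                              rbind(c(0.10, 0, 0), c(0.20, 0, 0)), 0.3), 2L)
  expect_error(pair_synapses(spot_set(rbind(c(0, 0, 0)), field_id = "a"),
                             spot_set(rbind(c(0, 0, 0)), field_id = "b")),
               "different fields")
})

test_that("pairing matches brute force and igraph on random small instances", {
  set.seed(42)
  for (rep in 1:60) {
    n1 <- sample(0:6, 1); n2 <- sample(0:6, 1)
    a <- matrix(runif(3 * n1, 0, 1.2), ncol = 3)
    b <- matrix(runif(3 * n2, 0, 1.2), ncol = 3)
    got <- nrow(pair_synapses(spot_set(a), spot_set(b), 0.3))
    expect_equal(got, bf_match_count(a, b, 0.3))
    expect_equal(got, igraph_match_count(a, b, 0.3))
  }
})

test_that("pair count is symmetric and monotone in the distance threshold", {
  set.seed(7)
  for (rep in 1:20) {
    a <- matrix(runif(30, 0, 1.5), ncol = 3)
    b <- matrix(runif(36, 0, 1.5), ncol = 3)
    sa <- spot_set(a); sb <- spot_set(b)
    expect_equal(nrow(pair_synapses(sa, sb, 0.3)),
                 nrow(pair_synapses(sb, sa, 0.3)))
    counts <- vapply(c(0.1, 0.2, 0.3, 0.5), function(d)
      nrow(pair_synapses(sa, sb, d)), 0L)
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("co-localized fraction handles empty inputs as specified", {
  ref <- spot_set(rbind(c(1, 1, 1)), "pre")
  expect_equal(coloc_fraction(ref, spot_set(matrix(numeric(0), 0, 3))), 0)
  expect_warning(v <- coloc_fraction(spot_set(matrix(numeric(0), 0, 3)), ref),
                 "undefined")
  expect_true(is.na(v))
})

test_that("four 90-degree rotations restore the channel bit-exactly", {
  sim <- gen_synapse_field(field_spec(field_size_um = c(6, 6, 3), seed = 5))
  f <- sim$field
  r <- f
  for (k in 1:4) r <- rotate_channel_90(r, "complement")
  expect_identical(r$intensities$complement, f$intensities$complement)
  expect_identical(r$intensities$pre, f$intensities$pre)
})

test_that("rotation nulls true co-localization but preserves chance", {
  # tagged fields: rotation must reduce the measured fraction
  hits <- 0; n <- 12
  for (s in 1:n) {
    sim <- gen_synapse_field(field_spec(field_size_um = c(10, 10, 3),
                                        pre_density = 0.3,
                                        complement_tag_fraction = 0.6,
                                        seed = 300 + s))
    p <- detection_params()
    pairs <- pair_synapses(detect_puncta(sim$field, "pre", p),
                           detect_puncta(sim$field, "post", p))
    cf <- coloc_fraction(pairs, detect_puncta(sim$field, "complement", p))
    rot <- rotate_channel_90(sim$field, "complement")
    cfr <- coloc_fraction(pairs, detect_puncta(rot, "complement", p))
    hits <- hits + (cfr < cf)
  }
  expect_gte(hits, n - 1)
})

test_that("counts are invariant to uniform intensity rescaling (quantile mode)", {
  sim <- gen_synapse_field(field_spec(field_size_um = c(8, 8, 3), seed = 21))
  p <- detection_params()
  n1 <- nrow(detect_puncta(sim$field, "pre", p))
  f2 <- sim$field
  f2$intensities <- lapply(f2$intensities, function(a) a * 7.3)
  expect_equal(nrow(detect_puncta(f2, "pre", p)), n1)
})

test_that("per-animal summaries follow the nine-image design", {
  d <- expand.grid(field = 1:3, plane = 1:3)
  d$value <- rep(4, 9)
  expect_equal(summarize_animal(d)$animal_mean, 4)
  d$value <- 1:9
  expect_equal(summarize_animal(d)$animal_mean, 5)
  expect_error(summarize_animal(d[-1, ]), "missing field/plane")
  expect_equal(summarize_animal(d[-1, ], allow_missing = TRUE)$n_values, 8L)
})

test_that("percent of reference is the scaled ratio to the reference mean", {
  expect_equal(percent_of_reference(10, c(8, 12)), 100)
  expect_equal(percent_of_reference(5, c(10, 10)), 50)
  expect_error(percent_of_reference(5, numeric(0)), "empty")
  expect_error(percent_of_reference(5, c(-1, 1)), "zero")
})
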