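# Synthetic-data generators: determinism, distributional ground truth,
# degenerate settings.

test_that("field generation is deterministic and validates its spec", {
  fs <- field_spec(field_size_um = c(6, 6, 3), pre_density = 0.3,
                   complement_tag_fraction = 0.4, seed = 9)
  a <- gen_synapse_field(fs)
  b <- gen_synapse_field(fs)
  expect_identical(a$field$intensities, b$field$intensities)
  expect_identical(a$truth$puncta, b$truth$puncta)

  expect_error(field_spec(coloc_fraction = 1.2), "coloc_fraction")
  expect_error(field_spec(pre_density = -1), "pre_density")
  expect_error(field_spec(pair_distance_max_um = 0.35), "0.3")
  expect_error(field_spec(voxel_size_um = c(0.1, 0, 0.1)), "voxel_size_um")
})

test_that("presynaptic counts follow the Poisson expectation", {
  d <- 0.5; fsz <- c(8, 8, 3)
  V <- prod(fsz)
  counts <- vapply(1:200, function(s)
    gen_synapse_field(field_spec(field_size_um = fsz, pre_density = d,
                                 seed = s), render = FALSE)$truth$n_pre, 0)
  se <- sqrt(d * V / 200)
  expect_lt(abs(mean(counts) - d * V), 3 * se)
})

test_that("zero coloc fraction yields no true pairs; realized fraction is binomial", {
  sim <- gen_synapse_field(field_spec(coloc_fraction = 0, seed = 3),
                           render = FALSE)
  expect_equal(nrow(sim$truth$true_pair_index), 0L)

  p <- 0.6
  fr <- vapply(1:100, function(s) {
    t <- gen_synapse_field(field_spec(field_size_um = c(8, 8, 3),
                                      pre_density = 0.5, coloc_fraction = p,
                                      seed = 100 + s), render = FALSE)$truth
    t$true_coloc_fraction
  }, 0)
  n_mean <- 0.5 * prod(c(8, 8, 3))
  ci_half <- 2.58 * sqrt(p * (1 - p) / (100 * n_mean))
  expect_lt(abs(mean(fr) - p), ci_half)
})

test_that("engulfment scenes realize the requested cargo fraction", {
  sim <- gen_engulfment_scene(cell_volume_um3 = 1000,
                              cargo_inside_fraction = 0.05, seed = 2)
  voxvol <- sim$truth$voxel_volume_um3
  expect_lt(abs(sim$truth$engulfed_volume_um3 - 0.05 * 1000),
            0.05 * 1000 * 0.1 + voxvol)
  expect_equal(sim$truth$engulfed_volume_um3 / sim$truth$cell_volume_um3,
               0.05, tolerance = voxvol / (0.05 * 1000))

  none <- gen_engulfment_scene(cargo_inside_fraction = 0, seed = 2)
  mask <- segment_cell(none$scene)
  expect_equal(sum(none$scene$cargo[mask]), 0)

  a <- gen_engulfment_scene(seed = 5); b <- gen_engulfment_scene(seed = 5)
  expect_identical(a$scene$cargo, b$scene$cargo)
  expect_identical(a$scene$cell, b$scene$cell)

  expect_error(gen_engulfment_scene(cell_volume_um3 = 1000,
                                    cargo_inside_fraction = 1e-5, seed = 1),
               "quantum")
})

test_that("morphology generator hits the intended scoring class", {
  for (s in 0:5) {
    cell <- gen_microglia_morphology(s, seed = 20 + s)
    expect_equal(score_morphology(cell) + score_cd68(cell), s,
                 info = paste("intent", s))
  }
  ramified <- gen_microglia_morphology(0, seed = 1)
  expect_gt(nrow(ramified$edges), 4)
  expect_length(ramified$cd68_volumes_um3, 0)
  amoeboid <- gen_microglia_morphology(5, seed = 1)
  expect_equal(nrow(amoeboid$edges), 0L)
  expect_gte(max(amoeboid$cd68_volumes_um3), cd68_bands()$aggregate_um3)

  a <- gen_microglia_morphology(2, seed = 7)
  b <- gen_microglia_morphology(2, seed = 7)
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$edges, b$edges)
  expect_error(gen_microglia_morphology(6), "0..5")
})

test_that("event trains have exponential ISIs and respect group effects", {
  tr <- gen_event_trains(train_spec(n_cells = 5, events_per_cell_mean = 2000,
                                    isi_rate_hz = 2, seed = 4))
  grp <- vapply(tr, function(t) t$group, "")
  isis_a <- unlist(lapply(tr[grp == "A"], function(t) diff(t$times)))
  expect_gt(length(isis_a), 5000)
  expect_lt(abs(mean(isis_a) - 0.5), 3 * 0.5 / sqrt(length(isis_a)))

  tr2 <- gen_event_trains(train_spec(n_cells = 5, events_per_cell_mean = 2000,
                                     isi_rate_hz = 2,
                                     group_effect = list(freq = 0.5, amp = 1),
                                     seed = 4))
  grp2 <- vapply(tr2, function(t) t$group, "")
  mean_b <- mean(unlist(lapply(tr2[grp2 == "B"], function(t) diff(t$times))))
  expect_equal(mean_b / mean(isis_a), 2, tolerance = 0.1)

  empty <- gen_event_trains(train_spec(n_cells = 1, events_per_cell_mean = 0,
                                       seed = 1))
  expect_length(empty[[1]]$times, 0)

  a <- gen_event_trains(train_spec(seed = 6))
  b <- gen_event_trains(train_spec(seed = 6))
  expect_identical(lapply(a, `[[`, "times"), lapply(b, `[[`, "times"))
})

test_that("cohorts respect group criteria and encode a recoverable age slope", {
  coh <- gen_cohort(cohort_spec(seed = 13))
  ep <- coh[coh$group == "early_premanifest", ]
  expect_true(all(ep$cag >= 40))
  expect_true(all(burden_score(ep$age, ep$cag) < 250))
  lp <- coh[coh$group == "late_premanifest", ]
  expect_true(all(burden_score(lp$age, lp$cag) >= 250))
  em <- coh[coh$group == "early_manifest", ]
  expect_true(all(em$cag >= 36 & em$dcl == 4 & em$tfc >= 7 & em$tfc <= 13))

  flat <- gen_cohort(cohort_spec(b_true = 0, cap_slope = 0, noise_sd = 0,
                                 intercept = 42, seed = 2))
  expect_true(all(abs(flat$C3 - 42) < 1e-9))

  big <- gen_cohort(cohort_spec(
    n_per_group = c(control = 500L, early_premanifest = 2L,
                    late_premanifest = 2L, early_manifest = 2L),
    b_true = 0.3, noise_sd = 5, seed = 8))
  ctl <- big[big$group == "control", ]
  fit <- lm(C3 ~ age, data = ctl)
  expect_lt(abs(coef(fit)[2] - 0.3), 3 * summary(fit)$coefficients[2, 2])
})
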