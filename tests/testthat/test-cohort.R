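# CAP/burden scoring, stratification, age adjustment and the statistics
# battery.

test_that("CAP score evaluates the printed formula", {
  expect_equal(cap_score(50, 30), 0)
  expect_equal(cap_score(50, 42), 100 * 50 * 12 / 627, tolerance = 1e-12)
  expect_equal(cap_score(31.35, 50), 100, tolerance = 1e-12)
  expect_warning(v <- cap_score(40, 25), "negative")
  expect_lt(v, 0)
  expect_error(cap_score(0, 42), "age")
})

test_that("CAP is strictly increasing in age (cag > 30) and in cag", {
  ages <- seq(20, 80, by = 5)
  expect_true(all(diff(cap_score(ages, 42)) > 0))
  expect_true(all(diff(cap_score(50, 36:50)) > 0))
})

test_that("burden score is (CAG - 35.5) x age", {
  expect_equal(burden_score(60, 35.5), 0)
  expect_equal(burden_score(40, 42), 260)
  expect_equal(burden_score(50, 40.5), 250)
})

test_that("stratification applies the subject-placement criteria", {
  s <- data.frame(age = c(35, 50, 40, 30, 50),
                  cag = c(41, 43, 38, 20, 42),
                  dcl = c(2, 4, 2, 0, 1),
                  tfc = c(13, 10, 13, 13, 12))
  got <- as.character(stratify(s))
  expect_equal(got, c("early_premanifest",  # burden 192.5
                      "early_manifest",
                      "unclassified",       # cag 38 premanifest-like
                      "healthy",
                      "late_premanifest"))  # burden 325
  expect_error(stratify(data.frame(age = 40, cag = 42)), "dcl")
})

test_that("premanifest carriers partition at burden 250 with no gaps", {
  # boundary value exactly 250 goes to late premanifest
  b250 <- data.frame(age = 250 / (42 - 35.5), cag = 42, dcl = 2, tfc = 13)
  expect_equal(as.character(stratify(b250)), "late_premanifest")
  set.seed(31)
  sub <- data.frame(age = runif(200, 20, 70), cag = sample(40:50, 200, TRUE),
                    dcl = sample(0:3, 200, TRUE), tfc = 13)
  lab <- stratify(sub)
  expect_true(all(lab %in% c("early_premanifest", "late_premanifest")))
})

test_that("generated cohorts re-stratify with full agreement", {
  coh <- gen_cohort(cohort_spec(seed = 17))
  lab <- as.character(stratify(coh))
  lab[lab == "healthy"] <- "control"
  expect_equal(lab, coh$group)
})

test_that("the control age model is recovered and removes the trend it fits", {
  set.seed(5)
  controls <- data.frame(age = runif(200, 25, 65))
  controls$C3 <- 100 + 0.3 * controls$age + rnorm(200, 0, 0.5)
  m <- fit_age_model(controls, "C3")
  expect_lt(abs(m$b - 0.3), 3 * 0.5 / sqrt(200) / sd(controls$age))
  adj <- age_adjust(controls$C3, controls$age, m)
  refit <- lm(adj ~ controls$age)
  expect_lt(abs(coef(refit)[2]), 1e-8)

  flat <- data.frame(age = c(30, 40, 50), C3 = c(7, 7, 7))
  expect_equal(fit_age_model(flat, "C3")$b, 0)
  expect_error(fit_age_model(flat[1:2, ], "C3"), "at least 3")
})

test_that("age adjustment arithmetic matches the closed form", {
  m <- structure(list(b = 0.2, mean_age = 50, analyte = "C3", n = 10),
                 class = "age_model")
  expect_equal(age_adjust(10, 60, m), 8)
  expect_equal(age_adjust(10, 50, m), 10)
  m0 <- structure(list(b = 0, mean_age = 50, analyte = "C3", n = 10),
                  class = "age_model")
  expect_equal(age_adjust(c(3, 9), c(20, 80), m0), c(3, 9))
})

test_that("group comparison runs Kruskal-Wallis with Dunn pairwise tests", {
  coh <- gen_cohort(cohort_spec(cap_slope = 3, noise_sd = 5, seed = 23))
  gc <- group_compare(coh, "C3")
  expect_true(gc$kw_p < 0.01)         # strong CAP effect separates groups
  expect_equal(nrow(gc$pairwise), choose(4, 2))
  expect_true(all(gc$pairwise$p_adjusted >= gc$pairwise$p - 1e-12))
  expect_error(group_compare(coh[coh$group == "control", ], "C3"), ">= 2")

  # k = 2 identity: the Kruskal-Wallis statistic equals the Dunn z squared
  two <- coh[coh$group %in% c("control", "early_manifest"), ]
  g2 <- group_compare(two, "C3")
  expect_equal(g2$kw_statistic, g2$pairwise$z[1]^2, tolerance = 1e-9)
})

test_that("null group comparison rejects near the nominal rate", {
  reps <- 200
  pvals <- vapply(seq_len(reps), function(s) {
    coh <- gen_cohort(cohort_spec(cap_slope = 0, b_true = 0, noise_sd = 10,
                                  seed = 5000 + s))
    group_compare(coh, "C3")$kw_p
  }, 0)
  rate <- mean(pvals <= 0.05)
  expect_gt(rate, 0.02); expect_lt(rate, 0.09)
})

test_that("CAP correlation is monotone-consistent and flags constants", {
  coh <- gen_cohort(cohort_spec(noise_sd = 0, b_true = 0, cap_slope = 2,
                                seed = 3))
  cc <- cap_correlation(coh, "C3", subset = "carriers")
  expect_equal(cc$rho, 1, tolerance = 1e-9)
  const <- coh
  const$C3 <- 5
  expect_warning(u <- cap_correlation(const, "C3"), "constant")
  expect_true(u$undefined)

  hits <- mean(vapply(1:50, function(s) {
    c2 <- gen_cohort(cohort_spec(cap_slope = 1.5, noise_sd = 20,
                                 seed = 900 + s))
    cap_correlation(c2, "C3", subset = "carriers")$rho > 0
  }, TRUE))
  expect_gte(hits, 0.95)
})
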