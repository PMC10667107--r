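#' Specification of a synthetic patient cohort
#'
#' Emulates a CSF-biomarker cohort with four groups — healthy controls,
#' early premanifest, late premanifest and early manifest gene-expansion
#' carriers — whose CAG repeat lengths, ages and clinical scores respect
#' the stratification criteria used downstream (premanifest requires CAG
#' >= 40 with the burden-of-pathology split at 250; manifest requires CAG
#' >= 36, dcl = 4 and TFC 7–13). The analyte concentration is linear in
#' age for everyone (slope `b_true`), with an additional CAP-score term
#' for carriers, plus Gaussian noise.
#'
#' Default group sizes (20/13/18/32) follow the CSF cohort sizes typical
#' of this design.
#'
#' @param n_per_group named counts for `control`, `early_premanifest`,
#'   `late_premanifest`, `early_manifest`.
#' @param age_range named list of 2-vectors (years) per group.
#' @param cag_range named list of integer 2-vectors per group.
#' @param intercept analyte level at age 0 in controls (assay units).
#' @param b_true analyte change per year of age (all subjects).
#' @param cap_slope analyte change per CAP unit (carriers only).
#' @param noise_sd Gaussian noise standard deviation (assay units).
#' @param analyte analyte name used for the concentration column.
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(control = 20L, early_premanifest = 13L,
                                        late_premanifest = 18L,
                                        early_manifest = 32L),
                        age_range = list(control = c(25, 65),
                                         early_premanifest = c(20, 45),
                                         late_premanifest = c(30, 60),
                                         early_manifest = c(35, 70)),
                        cag_range = list(control = c(17, 26),
                                         early_premanifest = c(40, 45),
                                         late_premanifest = c(40, 48),
                                         early_manifest = c(40, 50)),
                        intercept = 300, b_true = 2, cap_slope = 1.5,
                        noise_sd = 20, analyte = "C3", seed = 1L) {
  groups <- c("control", "early_premanifest", "late_premanifest",
              "early_manifest")
  if (!all(groups %in% names(n_per_group)) ||
      !all(groups %in% names(age_range)) ||
      !all(groups %in% names(cag_range)))
    stop("n_per_group, age_range and cag_range must name all four groups",
         call. = FALSE)
  for (g in groups) {
    if (any(age_range[[g]] <= 0)) stop("ages must be positive", call. = FALSE)
    if (diff(age_range[[g]]) < 0 || diff(cag_range[[g]]) < 0)
      stop("ranges must be non-decreasing", call. = FALSE)
  }
  if (cag_range$early_premanifest[1] < 40 || cag_range$late_premanifest[1] < 40)
    stop("premanifest carriers require CAG >= 40", call. = FALSE)
  if (cag_range$early_manifest[1] < 36)
    stop("manifest carriers require CAG >= 36", call. = FALSE)
  # feasibility of the burden criteria inside the stated ranges
  if ((cag_range$early_premanifest[1] - 35.5) * age_range$early_premanifest[1]
      >= 250)
    stop("early premanifest ranges cannot satisfy burden < 250", call. = FALSE)
  if ((cag_range$late_premanifest[2] - 35.5) * age_range$late_premanifest[2]
      < 250)
    stop("late premanifest ranges cannot satisfy burden >= 250", call. = FALSE)
  stopifnot_scalar(noise_sd, "noise_sd", lower = 0)
  structure(list(n_per_group = n_per_group, age_range = age_range,
                 cag_range = cag_range, intercept = intercept,
                 b_true = b_true, cap_slope = cap_slope, noise_sd = noise_sd,
                 analyte = analyte, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a patient cohort table
#'
#' Subjects are sampled per group with age and CAG uniform inside the
#' group's legal ranges, rejection-sampled so premanifest subjects respect
#' the burden-of-pathology split at 250. Clinical scores follow the group
#' definition (controls dcl 0; premanifest dcl 0–3, TFC 13; manifest dcl
#' 4, TFC 7–13). Analyte concentration is
#' `intercept + b_true * age (+ cap_slope * CAP for carriers) + noise`.
#'
#' @param spec a [cohort_spec()].
#' @return A data.frame (class `cohort_table`) with columns `subject_id`,
#'   `group`, `sex`, `age`, `cag`, `dcl`, `tfc`, `fluid` and one analyte
#'   concentration column named after `spec$analyte`. The generating
#'   coefficients are attached as attribute `truth`.
#' @examples
#' coh <- gen_cohort(cohort_spec(seed = 11))
#' table(coh$group)
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c("control", "early_premanifest", "late_premanifest",
              "early_manifest")
  with_stream(spec$seed, "cohort", {
    rows <- list()
    for (g in groups) {
      n <- spec$n_per_group[[g]]
      ar <- spec$age_range[[g]]; cr <- spec$cag_range[[g]]
      for (i in seq_len(n)) {
        for (attempt in 1:10000) {
          age <- runif(1, ar[1], ar[2])
          cag <- sample(seq(cr[1], cr[2]), 1L)
          b <- burden_score(age, cag)
          ok <- switch(g,
                       control = TRUE,
                       early_premanifest = b < 250,
                       late_premanifest = b >= 250,
                       early_manifest = TRUE)
          if (ok) break
          if (attempt == 10000)
            stop("could not satisfy burden criteria inside the given ranges",
                 call. = FALSE)
        }
        dcl <- switch(g, control = 0L, early_manifest = 4L,
                      sample(0:3, 1L))
        tfc <- switch(g, early_manifest = sample(7:13, 1L), 13L)
        carrier <- g != "control"
        y <- spec$intercept + spec$b_true * age +
          (if (carrier) spec$cap_slope * cap_score(age, cag) else 0) +
          rnorm(1, 0, spec$noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("%s_%03d", g, i), group = g,
          sex = sample(c("F", "M"), 1L), age = age, cag = cag,
          dcl = dcl, tfc = tfc, fluid = "CSF", analyte = y)
      }
    }
    coh <- do.call(rbind, rows)
    names(coh)[names(coh) == "analyte"] <- spec$analyte
    attr(coh, "truth") <- list(intercept = spec$intercept,
                               b_true = spec$b_true,
                               cap_slope = spec$cap_slope,
                               noise_sd = spec$noise_sd,
                               analyte = spec$analyte)
    class(coh) <- c("cohort_table", "data.frame")
    coh
  })
}
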