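#' CAG-age-product (CAP) disease-burden score
#'
#' `CAP = scale x age x (cag - L) / S` with the standard constants
#' `L = 30` (lower anchor of pathologically relevant CAG lengths) and
#' `S = 627` (normalizing constant placing CAP near 100 at the expected
#' age of clinical onset).
#'
#' @param age age in years (> 0); vectorized.
#' @param cag CAG repeat length; vectorized.
#' @param L,S,scale model constants.
#' @return CAP score (dimensionless). Repeat lengths below `L` give a
#'   negative score with a warning.
#' @examples
#' cap_score(50, 42)           # 95.6938...
#' cap_score(31.35, 50)        # 100 by construction
#' @export
cap_score <- function(age, cag, L = 30, S = 627, scale = 100) {
  if (any(age <= 0)) stop("age must be > 0", call. = FALSE)
  if (S <= 0) stop("'S' must be > 0", call. = FALSE)
  if (any(cag < L))
    warning("CAG below the anchor L gives a negative CAP score")
  scale * age * (cag - L) / S
}

#' Burden-of-pathology score
#'
#' `(cag - 35.5) x age`, used to split premanifest carriers into early
#' (< 250) and late (>= 250) groups.
#'
#' @param age age in years (> 0); vectorized.
#' @param cag CAG repeat length; vectorized.
#' @return Burden score (dimensionless).
#' @export
burden_score <- function(age, cag) {
  if (any(age <= 0)) stop("age must be > 0", call. = FALSE)
  (cag - 35.5) * age
}

#' Stratify subjects into study groups
#'
#' Applies the subject-placement criteria: `healthy` (no expansion risk,
#' CAG < 36); `early_premanifest` (dcl < 4, CAG >= 40, burden < 250);
#' `late_premanifest` (dcl < 4, CAG >= 40, burden >= 250 — the boundary
#' value 250 is assigned late); `early_manifest` (dcl = 4, CAG >= 36, TFC
#' 7–13 inclusive); anything else `unclassified` (notably premanifest-like
#' subjects with CAG 36–39).
#'
#' @param subjects data.frame with columns `age`, `cag`, `dcl` (diagnostic
#'   motor confidence, 0–4) and `tfc` (total functional capacity, 0–13).
#' @return Factor of group labels, one per row.
#' @examples
#' stratify(data.frame(age = 35, cag = 41, dcl = 2, tfc = 13))
#' @export
stratify <- function(subjects) {
  req <- c("age", "cag", "dcl", "tfc")
  missing <- setdiff(req, names(subjects))
  if (length(missing))
    stop("missing required fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- !complete.cases(subjects[req])
  if (any(bad))
    stop("missing values in required fields for rows: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  if (any(subjects$dcl < 0 | subjects$dcl > 4))
    stop("dcl must be in [0, 4]", call. = FALSE)
  if (any(subjects$tfc < 0 | subjects$tfc > 13))
    stop("tfc must be in [0, 13]", call. = FALSE)
  b <- burden_score(subjects$age, subjects$cag)
  lab <- rep("unclassified", nrow(subjects))
  lab[subjects$cag < 36] <- "healthy"
  pre <- subjects$dcl < 4 & subjects$cag >= 40
  lab[pre & b < 250] <- "early_premanifest"
  lab[pre & b >= 250] <- "late_premanifest"
  man <- subjects$dcl == 4 & subjects$cag >= 36 &
    subjects$tfc >= 7 & subjects$tfc <= 13
  lab[man] <- "early_manifest"
  factor(lab, levels = c("healthy", "early_premanifest", "late_premanifest",
                         "early_manifest", "unclassified"))
}

#' Fit the control-group age model for an analyte
#'
#' Ordinary least-squares regression of the analyte concentration on age
#' in control (clinically normal) subjects; the slope `b` and the control
#' mean age parameterize the age adjustment.
#'
#' @param controls data.frame of control subjects with an `age` column.
#' @param analyte name of the concentration column.
#' @return A list (class `age_model`) with `b`, `mean_age`, `analyte`,
#'   `n`.
#' @export
fit_age_model <- function(controls, analyte) {
  if (!analyte %in% names(controls))
    stop(sprintf("analyte column '%s' not found", analyte), call. = FALSE)
  d <- controls[complete.cases(controls[c("age", analyte)]), ]
  if (nrow(d) < 3L)
    stop("need at least 3 controls with the analyte measured", call. = FALSE)
  fit <- lm(d[[analyte]] ~ d$age)
  structure(list(b = unname(coef(fit)[2L]), mean_age = mean(d$age),
                 analyte = analyte, n = nrow(d)),
            class = "age_model")
}

#' Age-adjust an analyte concentration
#'
#' `adjusted = y - b * (age - mean_age)` with `b` and `mean_age` from the
#' control-group fit, removing the normal-aging trend from carrier
#' measurements.
#'
#' @param y observed concentration(s).
#' @param age corresponding age(s) in years.
#' @param model an `age_model` from [fit_age_model()].
#' @return Adjusted concentration(s).
#' @export
age_adjust <- function(y, age, model) {
  stopifnot(inherits(model, "age_model"))
  y - model$b * (age - model$mean_age)
}

#' Omnibus and pairwise group comparison of an analyte
#'
#' Kruskal–Wallis test across groups followed by Dunn's pairwise
#' comparisons on the joint ranks (z statistics with tie correction),
#' adjusted for the family of comparisons.
#'
#' @param cohort data.frame with a group column and the analyte column.
#' @param analyte name of the concentration column.
#' @param group_col name of the group column.
#' @param p_adjust multiplicity adjustment passed to [stats::p.adjust()]
#'   (default `"bonferroni"`, the family-wise control Dunn's test is
#'   usually reported with).
#' @return A list (class `group_comparison`) with `kw_statistic`, `kw_df`,
#'   `kw_p` and `pairwise` (data.frame group1, group2, z, p, p_adjusted).
#' @export
group_compare <- function(cohort, analyte, group_col = "group",
                          p_adjust = "bonferroni") {
  if (!analyte %in% names(cohort) || !group_col %in% names(cohort))
    stop("analyte or group column not found", call. = FALSE)
  d <- cohort[complete.cases(cohort[c(group_col, analyte)]), ]
  g <- factor(d[[group_col]])
  g <- droplevels(g)
  counts <- table(g)
  if (length(counts) < 2L || any(counts < 2L))
    stop("need >= 2 groups with >= 2 subjects each", call. = FALSE)
  y <- d[[analyte]]
  kw <- kruskal.test(y, g)
  r <- rank(y)
  N <- length(y)
  ties <- table(y)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  levs <- levels(g)
  pairs <- utils::combn(levs, 2L)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / counts[[i]] + 1 / counts[[j]]))
    z[k] <- (rbar[[i]] - rbar[[j]]) / se
    p[k] <- 2 * pnorm(-abs(z[k]))
  }
  structure(list(kw_statistic = unname(kw$statistic),
                 kw_df = unname(kw$parameter), kw_p = kw$p.value,
                 pairwise = data.frame(group1 = pairs[1L, ],
                                       group2 = pairs[2L, ], z = z, p = p,
                                       p_adjusted = p.adjust(p, p_adjust))),
            class = "group_comparison")
}

#' Spearman correlation of an analyte with CAP score
#'
#' Two-tailed Spearman rank correlation between CAP score and the analyte
#' concentration, computed for all gene-expansion carriers and for the
#' premanifest subset.
#'
#' @param cohort data.frame with `age`, `cag`, a group column and the
#'   analyte column.
#' @param analyte name of the concentration column.
#' @param subset `"carriers"` (every non-control group) or
#'   `"premanifest"` (early + late premanifest only).
#' @param group_col name of the group column.
#' @return A list (class `cap_correlation`) with `rho`, `p`, `n` and
#'   `undefined` (`TRUE` when the analyte is constant so the rank
#'   correlation is undefined).
#' @export
cap_correlation <- function(cohort, analyte,
                            subset = c("carriers", "premanifest"),
                            group_col = "group") {
  subset <- match.arg(subset)
  keep <- if (subset == "carriers") cohort[[group_col]] != "control" &
    cohort[[group_col]] != "healthy"
  else cohort[[group_col]] %in% c("early_premanifest", "late_premanifest")
  d <- cohort[keep & complete.cases(cohort[c("age", "cag", analyte)]), ]
  if (nrow(d) < 3L)
    stop("need at least 3 subjects with CAP computable", call. = FALSE)
  cap <- cap_score(d$age, d$cag)
  y <- d[[analyte]]
  if (diff(range(y)) == 0) {
    warning("constant analyte: Spearman correlation undefined")
    return(structure(list(rho = NA_real_, p = NA_real_, n = nrow(d),
                          undefined = TRUE), class = "cap_correlation"))
  }
  ct <- suppressWarnings(cor.test(cap, y, method = "spearman",
                                  alternative = "two.sided", exact = FALSE))
  structure(list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(d),
                 undefined = FALSE), class = "cap_correlation")
}
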