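#' Specification of a synthetic synaptic-puncta field
#'
#' Collects the parameters of the homogeneous-Poisson puncta simulator:
#' field extents, voxel size, presynaptic density, the fraction of
#' presynaptic puncta carrying a true postsynaptic partner, the maximal
#' center offset of a true pair, the fraction of true pairs tagged by a
#' complement punctum, an independent complement background, Gaussian PSF
#' widths, and the peak-signal-to-background ratio used for rendering.
#'
#' Defaults describe a striatal confocal field at high magnification:
#' 14 x 14 x 4 um imaged at 0.1 x 0.1 x 0.25 um voxels, 0.4 presynaptic
#' puncta per um^3, and a 0.15 um pairing offset (safely below the 0.3 um
#' synapse-calling threshold).
#'
#' @param field_size_um x, y, z extents in micrometers.
#' @param voxel_size_um voxel pitch in micrometers per voxel.
#' @param pre_density presynaptic puncta per cubic micrometer.
#' @param coloc_fraction fraction of presynaptic puncta with a true
#'   postsynaptic partner, in `[0, 1]`.
#' @param pair_distance_max_um maximal center offset of a true pair (um);
#'   must stay below the downstream synapse-calling threshold.
#' @param complement_tag_fraction fraction of true pairs carrying a
#'   complement punctum, in `[0, 1]`.
#' @param complement_background_density independently placed complement
#'   puncta per cubic micrometer.
#' @param psf_sigma_um Gaussian PSF sigma per axis (um).
#' @param snr peak signal over background ratio of a rendered spot.
#' @param background_photons mean background photon count per voxel.
#' @param seed integer seed; together with the spec it fully determines
#'   the simulated field.
#' @return An object of class `field_spec`.
#' @seealso [gen_synapse_field()]
#' @export
field_spec <- function(field_size_um = c(14, 14, 4),
                       voxel_size_um = c(0.1, 0.1, 0.25),
                       pre_density = 0.4,
                       coloc_fraction = 0.6,
                       pair_distance_max_um = 0.15,
                       complement_tag_fraction = 0,
                       complement_background_density = 0.05,
                       psf_sigma_um = c(0.08, 0.08, 0.2),
                       snr = 10,
                       background_photons = 20,
                       seed = 1L) {
  stopifnot_vec3(field_size_um, "field_size_um", positive = TRUE)
  stopifnot_vec3(voxel_size_um, "voxel_size_um", positive = TRUE)
  stopifnot_vec3(psf_sigma_um, "psf_sigma_um")
  stopifnot_scalar(pre_density, "pre_density", lower = 0)
  stopifnot_scalar(coloc_fraction, "coloc_fraction", lower = 0, upper = 1)
  stopifnot_scalar(pair_distance_max_um, "pair_distance_max_um", lower = 0,
                   strict_lower = TRUE)
  stopifnot_scalar(complement_tag_fraction, "complement_tag_fraction",
                   lower = 0, upper = 1)
  stopifnot_scalar(complement_background_density,
                   "complement_background_density", lower = 0)
  stopifnot_scalar(snr, "snr", lower = 1)
  stopifnot_scalar(background_photons, "background_photons", lower = 0,
                   strict_lower = TRUE)
  if (pair_distance_max_um >= 0.3)
    stop("'pair_distance_max_um' must stay below the 0.3 um synapse-calling threshold",
         call. = FALSE)
  structure(list(field_size_um = as.numeric(field_size_um),
                 voxel_size_um = as.numeric(voxel_size_um),
                 pre_density = pre_density,
                 coloc_fraction = coloc_fraction,
                 pair_distance_max_um = pair_distance_max_um,
                 complement_tag_fraction = complement_tag_fraction,
                 complement_background_density = complement_background_density,
                 psf_sigma_um = as.numeric(psf_sigma_um),
                 snr = snr,
                 background_photons = background_photons,
                 seed = as.integer(seed)),
            class = "field_spec")
}

#' Scale a field spec into a disease-like scenario
#'
#' Returns a copy of `spec` with presynaptic density and complement tag
#' fraction scaled by effect sizes, emulating a genotype with reduced
#' synapse density and altered complement tagging. The default density
#' effect of 0.5 mirrors the approximately 50% corticostriatal synapse
#' loss context these analyses are used in.
#'
#' @param spec a [field_spec()].
#' @param density_effect multiplier on `pre_density`.
#' @param coloc_effect multiplier on `complement_tag_fraction` (clamped to 1).
#' @param seed optional new seed for the scenario field.
#' @return A `field_spec`.
#' @export
field_scenario <- function(spec, density_effect = 0.5, coloc_effect = 1,
                           seed = NULL) {
  stopifnot(inherits(spec, "field_spec"))
  spec$pre_density <- spec$pre_density * density_effect
  spec$complement_tag_fraction <-
    min(1, spec$complement_tag_fraction * coloc_effect)
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  spec
}

#' Simulate a multi-channel synaptic puncta field with ground truth
#'
#' Presynaptic puncta are placed by a homogeneous Poisson process at
#' `pre_density`; a `coloc_fraction` subset receives a postsynaptic partner
#' at a uniform-random offset inside the ball of radius
#' `pair_distance_max_um`; the remaining postsynaptic puncta are placed
#' independently so that the expected postsynaptic density matches the
#' presynaptic one. Complement puncta sit on a `complement_tag_fraction`
#' subset of true pairs (offset like a partner) plus an independent
#' Poisson background. Channels are rendered as Gaussian spots over a
#' constant background with Poisson shot noise; peak amplitude is
#' `snr x background`.
#'
#' @param spec a [field_spec()].
#' @param render if `FALSE`, skip rendering and return ground truth with
#'   empty intensity arrays (useful for count-level simulation studies).
#' @param field_id,animal_id metadata labels carried into the result.
#' @return A list with components `field` (a `puncta_field`: named list of
#'   3D intensity arrays `pre`/`post`/`complement`, voxel size, metadata)
#'   and `truth` (a `field_truth`: per-punctum table with coordinates,
#'   channel and pair id, the realized co-localized fraction, and counts).
#' @examples
#' fs <- field_spec(field_size_um = c(6, 6, 3), pre_density = 0.2, seed = 7)
#' sim <- gen_synapse_field(fs)
#' names(sim$field$intensities)
#' sim$truth$true_coloc_fraction
#' @export
gen_synapse_field <- function(spec, render = TRUE,
                              field_id = "field1", animal_id = "animal1") {
  stopifnot(inherits(spec, "field_spec"))
  fs <- spec$field_size_um
  V <- prod(fs)
  with_stream(spec$seed, "synapse_field", {
    n_pre <- rpois(1L, spec$pre_density * V)
    pre <- cbind(runif(n_pre, 0, fs[1]), runif(n_pre, 0, fs[2]),
                 runif(n_pre, 0, fs[3]))
    paired <- if (n_pre > 0)
      which(rbinom(n_pre, 1L, spec$coloc_fraction) == 1L) else integer(0)
    post_paired <- offset_in_ball(pre[paired, , drop = FALSE],
                                  spec$pair_distance_max_um, fs)
    n_post_bg <- rpois(1L, spec$pre_density * V * (1 - spec$coloc_fraction))
    post_bg <- cbind(runif(n_post_bg, 0, fs[1]), runif(n_post_bg, 0, fs[2]),
                     runif(n_post_bg, 0, fs[3]))
    post <- rbind(post_paired, post_bg)
    tagged <- if (length(paired))
      paired[rbinom(length(paired), 1L, spec$complement_tag_fraction) == 1L]
    else integer(0)
    comp_tag <- offset_in_ball(pre[tagged, , drop = FALSE],
                               spec$pair_distance_max_um, fs)
    n_comp_bg <- rpois(1L, spec$complement_background_density * V)
    comp_bg <- cbind(runif(n_comp_bg, 0, fs[1]), runif(n_comp_bg, 0, fs[2]),
                     runif(n_comp_bg, 0, fs[3]))
    comp <- rbind(comp_tag, comp_bg)

    pair_id_pre <- rep(NA_integer_, n_pre)
    pair_id_pre[paired] <- seq_along(paired)
    truth_tab <- rbind(
      punctum_rows(pre, "pre", pair_id_pre),
      punctum_rows(post, "post",
                   c(seq_along(paired), rep(NA_integer_, n_post_bg))),
      punctum_rows(comp, "complement",
                   c(match(tagged, paired), rep(NA_integer_, n_comp_bg))))
    truth <- structure(list(
      puncta = truth_tab,
      true_pair_index = data.frame(pre = paired,
                                   post = seq_along(paired)),
      tagged_pairs = match(tagged, paired),
      true_coloc_fraction = if (n_pre > 0) length(paired) / n_pre else NA_real_,
      true_tag_fraction = if (length(paired))
        length(tagged) / length(paired) else NA_real_,
      n_pre = n_pre, n_post = nrow(post), n_complement = nrow(comp),
      scenario = NULL), class = "field_truth")

    intens <- list()
    if (render) {
      dimv <- pmax(1L, as.integer(round(fs / spec$voxel_size_um)))
      intens <- list(
        pre = render_spots(pre, dimv, spec$voxel_size_um, spec$psf_sigma_um,
                           spec$snr, spec$background_photons),
        post = render_spots(post, dimv, spec$voxel_size_um, spec$psf_sigma_um,
                            spec$snr, spec$background_photons),
        complement = render_spots(comp, dimv, spec$voxel_size_um,
                                  spec$psf_sigma_um, spec$snr,
                                  spec$background_photons))
    }
    field <- structure(list(intensities = intens,
                            voxel_size_um = spec$voxel_size_um,
                            field_size_um = fs,
                            channel_names = c("pre", "post", "complement"),
                            field_id = field_id, animal_id = animal_id),
                       class = "puncta_field")
    list(field = field, truth = truth)
  })
}

# uniform offsets inside the ball of given radius, resampled to stay in field
offset_in_ball <- function(centers, radius, fs) {
  n <- nrow(centers)
  if (n == 0L) return(matrix(numeric(0), 0L, 3L))
  out <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    repeat {
      o <- runif(3L, -radius, radius)
      if (sum(o^2) > radius^2) next
      p <- centers[i, ] + o
      if (all(p >= 0) && all(p <= fs)) { out[i, ] <- p; break }
    }
  }
  out
}

punctum_rows <- function(xyz, channel, pair_id) {
  if (!nrow(xyz))
    return(data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      channel = character(0), pair_id = integer(0)))
  data.frame(x_um = xyz[, 1L], y_um = xyz[, 2L], z_um = xyz[, 3L],
             channel = channel, pair_id = pair_id)
}

# Render point emitters as Gaussian spots + constant background, then apply
# Poisson shot noise. Coordinates use the center-of-voxel convention:
# physical x of voxel i is (i - 0.5) * voxel.
render_spots <- function(centers, dimv, voxel, psf_sigma, snr, bg) {
  g <- array(0, dimv)
  sig <- pmax(psf_sigma, 1e-6)
  hw <- pmax(1L, ceiling(3 * sig / voxel))
  for (r in seq_len(nrow(centers))) {
    ci <- centers[r, ] / voxel + 0.5
    lo <- pmax(1L, floor(ci - hw))
    hi <- pmin(dimv, ceiling(ci + hw))
    if (any(lo > hi)) next
    gx <- exp(-((lo[1]:hi[1] - ci[1]) * voxel[1])^2 / (2 * sig[1]^2))
    gy <- exp(-((lo[2]:hi[2] - ci[2]) * voxel[2])^2 / (2 * sig[2]^2))
    gz <- exp(-((lo[3]:hi[3] - ci[3]) * voxel[3])^2 / (2 * sig[3]^2))
    g[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      g[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + outer(outer(gx, gy), gz)
  }
  lam <- bg * (1 + (snr - 1) * g)
  array(rpois(length(lam), lam), dimv)
}
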