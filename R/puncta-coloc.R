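#' Call synapses by one-to-one center-distance matching
#'
#' Pairs presynaptic and postsynaptic spots whose centers are strictly
#' less than `max_distance_um` apart, one-to-one, maximizing the number of
#' pairs (greedy by ascending distance followed by augmenting paths, which
#' guarantees maximum cardinality). The pair count is the synapse count of
#' the field.
#'
#' @param pre,post `spot_set` objects from the same field.
#' @param max_distance_um strict center-distance threshold (um); centers
#'   exactly at the threshold are not paired.
#' @return A `pair_set`: data.frame with columns `pre_idx`, `post_idx`,
#'   `distance_um` and the paired centers (`pre_x_um` ... `post_z_um`),
#'   with attributes `max_distance_um` and `field_id`.
#' @examples
#' a <- spot_set(rbind(c(1, 1, 1)), "pre")
#' b <- spot_set(rbind(c(1.25, 1, 1)), "post")
#' nrow(pair_synapses(a, b))     # 0.25 um apart -> one synapse
#' @export
pair_synapses <- function(pre, post, max_distance_um = 0.3) {
  stopifnot(inherits(pre, "spot_set"), inherits(post, "spot_set"))
  stopifnot_scalar(max_distance_um, "max_distance_um", lower = 0,
                   strict_lower = TRUE)
  f1 <- attr(pre, "field_id"); f2 <- attr(post, "field_id")
  if (!is.na(f1) && !is.na(f2) && !identical(f1, f2))
    stop(sprintf("spot sets come from different fields ('%s' vs '%s')",
                 f1, f2), call. = FALSE)
  a <- as.matrix(pre[, c("x_um", "y_um", "z_um")])
  b <- as.matrix(post[, c("x_um", "y_um", "z_um")])
  m <- match_points(a, b, max_distance_um)
  out <- data.frame(pre_idx = m$i, post_idx = m$j, distance_um = m$distance_um,
                    pre_x_um = a[m$i, 1L], pre_y_um = a[m$i, 2L],
                    pre_z_um = a[m$i, 3L],
                    post_x_um = b[m$j, 1L], post_y_um = b[m$j, 2L],
                    post_z_um = b[m$j, 3L])
  structure(out, max_distance_um = max_distance_um,
            field_id = if (!is.na(f1)) f1 else f2,
            class = c("pair_set", "data.frame"))
}

#' Percentage of reference items co-localized with a probe channel
#'
#' Reports the percentage of reference items (spots, or called synapses —
#' their presynaptic centers) that have a probe center within
#' `max_distance_um`, matched one-to-one as in [pair_synapses()] so a
#' single probe punctum cannot co-localize with many references.
#'
#' @param reference a `spot_set`, or a `pair_set` whose presynaptic
#'   centers are used.
#' @param probe a `spot_set`.
#' @param max_distance_um strict distance threshold (um).
#' @return Percentage in `[0, 100]`; `NA` (with a warning) when the
#'   reference is empty, since the ratio is undefined.
#' @export
coloc_fraction <- function(reference, probe, max_distance_um = 0.3) {
  stopifnot(inherits(probe, "spot_set"))
  ref <- if (inherits(reference, "pair_set"))
    as.matrix(reference[, c("pre_x_um", "pre_y_um", "pre_z_um")])
  else if (inherits(reference, "spot_set"))
    as.matrix(reference[, c("x_um", "y_um", "z_um")])
  else stop("'reference' must be a spot_set or pair_set", call. = FALSE)
  if (!nrow(ref)) {
    warning("empty reference: co-localized fraction is undefined")
    return(NA_real_)
  }
  if (!nrow(probe)) return(0)
  prb <- as.matrix(probe[, c("x_um", "y_um", "z_um")])
  m <- match_points(ref, prb, max_distance_um)
  100 * nrow(m) / nrow(ref)
}

#' Rotate one channel 90 degrees in the imaging plane
#'
#' The chance-level control for co-localization: rotating the probe
#' (complement) channel about the field center destroys true spatial
#' relationships while preserving the channel's intensity statistics and
#' spot density. All other channels are untouched. Non-square in-plane
#' fields are center-cropped to a square (all channels, with a message).
#' Four successive rotations restore the original channel bit-exactly.
#'
#' @param field a `puncta_field`.
#' @param channel channel to rotate.
#' @return The field with the stated channel rotated.
#' @export
rotate_channel_90 <- function(field, channel) {
  if (!channel %in% names(field$intensities))
    stop(sprintf("channel '%s' not present in field", channel), call. = FALSE)
  d <- dim(field$intensities[[channel]])
  if (d[1L] != d[2L]) {
    n <- min(d[1L], d[2L])
    o1 <- (d[1L] - n) %/% 2L
    o2 <- (d[2L] - n) %/% 2L
    message(sprintf("center-cropping %d x %d field to %d x %d for rotation",
                    d[1L], d[2L], n, n))
    field$intensities <- lapply(field$intensities, function(a)
      a[o1 + seq_len(n), o2 + seq_len(n), , drop = FALSE])
    if (!is.null(field$field_size_um))
      field$field_size_um[1:2] <- n * field$voxel_size_um[1:2]
  }
  a <- field$intensities[[channel]]
  b <- aperm(a, c(2L, 1L, 3L))
  field$intensities[[channel]] <- b[, dim(b)[2L]:1L, , drop = FALSE]
  field
}
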