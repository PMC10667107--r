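#' Puncta detection parameters
#'
#' Controls the threshold-and-label detector: Gaussian pre-smoothing,
#' global intensity threshold (data quantile or fixed value), the
#' dimension criteria (minimal and maximal component volume), and a
#' minimal peak-to-background ratio that rejects noise blobs.
#'
#' With `threshold_method = "quantile"`, detected counts are invariant to
#' uniform intensity rescaling of the channel.
#'
#' @param smoothing_sigma_um Gaussian smoothing sigma per axis (um).
#' @param threshold_method `"quantile"` (default) or `"fixed"`.
#' @param threshold quantile in `(0, 1)` or absolute intensity, per
#'   `threshold_method`.
#' @param min_volume_um3,max_volume_um3 component volume bounds (um^3);
#'   defaults bracket typical punctum sizes at high magnification.
#' @param min_peak_snr minimal ratio of the component's peak smoothed
#'   intensity to the channel's median smoothed intensity.
#' @param split_touching if `TRUE` (default), components containing more
#'   than one intensity local maximum are split by assigning voxels to
#'   the nearest peak, so touching puncta are counted separately.
#' @param peak_min_separation_um local maxima closer than this are
#'   treated as one peak (suppresses noise-split of a single punctum).
#' @param mode `"3d"` (volumetric components) or `"2d"` (per-plane
#'   components, the confocal per-z-plane counting variant).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(smoothing_sigma_um = c(0.06, 0.06, 0.15),
                             threshold_method = c("quantile", "fixed"),
                             threshold = 0.97,
                             min_volume_um3 = 0.02, max_volume_um3 = 1.0,
                             min_peak_snr = 3,
                             split_touching = TRUE,
                             peak_min_separation_um = 0.25,
                             mode = c("3d", "2d")) {
  threshold_method <- match.arg(threshold_method)
  mode <- match.arg(mode)
  stopifnot_vec3(smoothing_sigma_um, "smoothing_sigma_um")
  if (any(smoothing_sigma_um < 0))
    stop("'smoothing_sigma_um' must be >= 0", call. = FALSE)
  stopifnot_scalar(min_volume_um3, "min_volume_um3", lower = 0)
  stopifnot_scalar(max_volume_um3, "max_volume_um3", lower = 0)
  if (min_volume_um3 >= max_volume_um3)
    stop("'min_volume_um3' must be below 'max_volume_um3'", call. = FALSE)
  if (threshold_method == "quantile")
    stopifnot_scalar(threshold, "threshold", lower = 0, upper = 1)
  stopifnot_scalar(min_peak_snr, "min_peak_snr", lower = 0)
  structure(list(smoothing_sigma_um = as.numeric(smoothing_sigma_um),
                 threshold_method = threshold_method, threshold = threshold,
                 min_volume_um3 = min_volume_um3,
                 max_volume_um3 = max_volume_um3,
                 min_peak_snr = min_peak_snr,
                 split_touching = isTRUE(split_touching),
                 peak_min_separation_um = peak_min_separation_um,
                 mode = mode),
            class = "detection_params")
}

#' Detect fluorescent puncta in one channel of a 3D field
#'
#' Smooths the channel, thresholds it into a binary state, labels
#' connected components (6-connected in 3D, or per-plane in `"2d"` mode),
#' filters them to the dimension criteria and the minimal peak SNR, and
#' reports intensity-weighted centroids in physical micrometers together
#' with equivalent-sphere radii.
#'
#' @param field a `puncta_field` (see [gen_synapse_field()]) or a plain
#'   named list of 3D arrays with a `voxel_size_um` element.
#' @param channel channel name.
#' @param params a [detection_params()].
#' @return A `spot_set`: data.frame with columns `x_um`, `y_um`, `z_um`,
#'   `radius_um`, `volume_um3`, `intensity` (summed smoothed intensity)
#'   and attributes `channel`, `field_id`, `voxel_size_um`,
#'   `field_size_um`.
#' @examples
#' sim <- gen_synapse_field(field_spec(field_size_um = c(6, 6, 3),
#'                                     pre_density = 0.15, seed = 5))
#' spots <- detect_puncta(sim$field, "pre", detection_params())
#' nrow(spots)
#' @export
detect_puncta <- function(field, channel, params = detection_params()) {
  stopifnot(inherits(params, "detection_params"))
  if (!channel %in% names(field$intensities))
    stop(sprintf("channel '%s' not present in field", channel), call. = FALSE)
  raw <- field$intensities[[channel]]
  voxel <- field$voxel_size_um
  d <- dim(raw)
  shapes <- vapply(field$intensities, function(a) identical(dim(a), d), TRUE)
  if (!all(shapes)) stop("channels do not share a common shape", call. = FALSE)
  empty <- spot_set_frame(NULL, channel, field, voxel)
  if (all(raw == raw[1L])) {
    warning("channel is constant (empty or saturated); returning no spots")
    return(empty)
  }
  sm <- gauss_blur3d(raw, params$smoothing_sigma_um / voxel)
  thr <- if (params$threshold_method == "quantile")
    quantile(sm, params$threshold, names = FALSE) else params$threshold
  mask <- sm > thr
  if (!any(mask)) {
    warning("no voxels above threshold; returning no spots")
    return(empty)
  }
  lab <- label_components(mask, connect_z = params$mode == "3d")
  if (params$split_touching)
    lab <- split_by_peaks(lab, sm, voxel, params$peak_min_separation_um,
                          in_plane = params$mode == "2d")
  idx <- which(lab > 0L)
  comp <- lab[idx]
  w <- sm[idx]
  pos <- arrayInd(idx, d)
  voxvol <- prod(voxel)
  nvox <- tabulate(comp)
  sums <- rowsum(cbind(w, w * pos[, 1L], w * pos[, 2L], w * pos[, 3L]), comp)
  peak <- vapply(split(w, comp), max, 0)
  bg <- median(sm)
  vol <- nvox * voxvol
  keep <- vol >= params$min_volume_um3 & vol <= params$max_volume_um3 &
    (bg <= 0 | peak / bg >= params$min_peak_snr)
  if (!any(keep)) return(empty)
  cen_idx <- sums[keep, 2:4, drop = FALSE] / sums[keep, 1L]
  centers <- sweep(cen_idx - 0.5, 2L, voxel, "*")
  spot_set_frame(data.frame(x_um = centers[, 1L], y_um = centers[, 2L],
                            z_um = centers[, 3L],
                            radius_um = (3 * vol[keep] / (4 * pi))^(1 / 3),
                            volume_um3 = vol[keep],
                            intensity = sums[keep, 1L]),
                 channel, field, voxel)
}

# Split labelled components that contain several intensity local maxima:
# voxels of a multi-peak component are reassigned to the nearest peak
# (physical distance). Peaks closer than `min_sep` are merged, keeping the
# brightest, so a noisy single punctum is not over-split.
split_by_peaks <- function(lab, sm, voxel, min_sep, in_plane = FALSE) {
  d <- dim(lab)
  fg <- lab > 0L
  if (!any(fg)) return(lab)
  is_peak <- fg
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = if (in_plane) 0L else -1:1)
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  for (r in seq_len(nrow(offs))) {
    sh <- shift_array(sm, unlist(offs[r, ]), fill = -Inf)
    is_peak <- is_peak & (sm >= sh)
  }
  pk <- which(is_peak)
  if (!length(pk)) return(lab)
  pk_comp <- lab[pk]
  pk_val <- sm[pk]
  pk_pos <- sweep(arrayInd(pk, d) - 0.5, 2L, voxel, "*")
  out <- lab
  next_label <- max(lab)
  for (cid in unique(pk_comp[duplicated(pk_comp)])) {
    sel <- which(pk_comp == cid)
    # merge peaks closer than min_sep, brightest first
    ord <- sel[order(-pk_val[sel])]
    kept <- integer(0)
    for (p in ord) {
      if (!length(kept) ||
          min(sqrt(colSums((t(pk_pos[kept, , drop = FALSE]) - pk_pos[p, ])^2)))
          >= min_sep)
        kept <- c(kept, p)
    }
    if (length(kept) < 2L) next
    vox <- which(lab == cid)
    vpos <- sweep(arrayInd(vox, d) - 0.5, 2L, voxel, "*")
    dd <- outer(rowSums(vpos^2), rowSums(pk_pos[kept, , drop = FALSE]^2), "+") -
      2 * tcrossprod(vpos, pk_pos[kept, , drop = FALSE])
    assign_k <- max.col(-dd, ties.method = "first")
    newlab <- c(cid, next_label + seq_len(length(kept) - 1L))
    next_label <- next_label + length(kept) - 1L
    out[vox] <- newlab[assign_k]
  }
  out
}

# Shift a 3D array by an integer offset, filling exposed borders.
shift_array <- function(a, off, fill = 0) {
  d <- dim(a)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= 0) {
      src[[ax]] <- seq_len(d[ax] - o)
      dst[[ax]] <- src[[ax]] + o
    } else {
      src[[ax]] <- seq_len(d[ax] + o) - o
      dst[[ax]] <- seq_len(d[ax] + o)
    }
  }
  out <- array(fill, d)
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
  out
}

spot_set_frame <- function(df, channel, field, voxel) {
  if (is.null(df))
    df <- data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                     radius_um = numeric(0), volume_um3 = numeric(0),
                     intensity = numeric(0))
  structure(df, channel = channel,
            field_id = field$field_id %||% NA_character_,
            voxel_size_um = voxel,
            field_size_um = field$field_size_um %||% NULL,
            class = c("spot_set", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a spot set directly from known centers
#'
#' Convenience constructor used when centers come from an external source
#' (or ground truth) rather than from image detection.
#'
#' @param centers_um n x 3 matrix or data.frame of centers (um).
#' @param channel channel label.
#' @param radius_um spot radii (recycled).
#' @param field_id source field id.
#' @return A `spot_set`.
#' @export
spot_set <- function(centers_um, channel = "spots", radius_um = 0.1,
                     field_id = "field1") {
  m <- as.matrix(centers_um)
  if (length(m) && ncol(m) != 3L)
    stop("'centers_um' must have three columns", call. = FALSE)
  df <- if (nrow(m))
    data.frame(x_um = m[, 1L], y_um = m[, 2L], z_um = m[, 3L],
               radius_um = rep_len(radius_um, nrow(m)),
               volume_um3 = 4 / 3 * pi * rep_len(radius_um, nrow(m))^3,
               intensity = NA_real_)
  else NULL
  spot_set_frame(df, channel, list(field_id = field_id), c(NA, NA, NA))
}
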