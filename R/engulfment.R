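#' Segment a glial cell from its marker channel
#'
#' Thresholds the cell-marker channel (Iba1-like for microglia,
#' S100beta-like for astrocytes) and returns the connected component
#' containing the seed point. The cell volume is the voxel count times
#' the voxel volume.
#'
#' @param scene an `engulfment_scene` (see [gen_engulfment_scene()]).
#' @param threshold absolute intensity threshold on the cell channel, or
#'   a quantile when `threshold_method = "quantile"`.
#' @param threshold_method `"fixed"` (default) or `"quantile"`.
#' @param seed_um optional seed point (um); defaults to the scene's.
#' @return A logical 3D mask with attributes `volume_um3` and
#'   `voxel_size_um`.
#' @export
segment_cell <- function(scene, threshold = 0.5,
                         threshold_method = c("fixed", "quantile"),
                         seed_um = NULL) {
  threshold_method <- match.arg(threshold_method)
  a <- scene$cell
  voxel <- scene$voxel_size_um
  thr <- if (threshold_method == "quantile")
    quantile(a, threshold, names = FALSE) else threshold
  mask <- a >= thr
  seed <- seed_um %||% scene$seed_point_um
  si <- pmin(dim(a), pmax(1L, as.integer(ceiling(seed / voxel))))
  seed_lin <- si[1L] + (si[2L] - 1L) * dim(a)[1L] +
    (si[3L] - 1L) * dim(a)[1L] * dim(a)[2L]
  if (!mask[seed_lin])
    stop("seed point lies below the cell threshold (background)",
         call. = FALSE)
  lab <- label_components(mask)
  cell <- lab == lab[seed_lin]
  structure(cell, volume_um3 = sum(cell) * prod(voxel),
            voxel_size_um = voxel)
}

#' Percent engulfment: engulfed cargo volume over cell volume
#'
#' `100 x (cargo-positive voxel volume inside the cell mask) / (cell
#' volume)`. Invariant to any cargo intensity rescaling that preserves
#' the thresholded voxel set.
#'
#' @param cell_mask logical mask from [segment_cell()].
#' @param cargo cargo channel 3D array (same shape).
#' @param cargo_threshold absolute threshold on the cargo channel.
#' @return Percentage in `[0, 100]`.
#' @export
percent_engulfment <- function(cell_mask, cargo, cargo_threshold = 0.5) {
  if (!any(cell_mask)) stop("empty cell mask", call. = FALSE)
  if (!identical(dim(cell_mask), dim(cargo)))
    stop("cell mask and cargo channel shapes differ", call. = FALSE)
  engulfed <- sum(cargo >= cargo_threshold & cell_mask)
  stopifnot(engulfed <= sum(cell_mask))  # engulfed volume <= cell volume
  100 * engulfed / sum(cell_mask)
}

#' Input density: total cargo volume over field volume
#'
#' Dimensionless volume fraction of cargo-positive voxels in the whole
#' field of view, used to normalize engulfment for local input abundance.
#'
#' @param scene an `engulfment_scene`.
#' @param cargo_threshold absolute threshold on the cargo channel.
#' @return Fraction in `[0, 1]`.
#' @export
input_density <- function(scene, cargo_threshold = 0.5) {
  if (is.null(scene$cargo)) stop("scene has no cargo channel", call. = FALSE)
  mean(scene$cargo >= cargo_threshold)
}

#' Engulfment normalized to input density
#'
#' Divides percent engulfment by the field's input density, so a cell in
#' a denser field scores lower for the same engulfed fraction.
#'
#' @param percent percent engulfment (see [percent_engulfment()]).
#' @param density input density (see [input_density()]); must be > 0.
#' @return Normalized engulfment value.
#' @export
normalized_engulfment <- function(percent, density) {
  if (any(density <= 0))
    stop("input density must be > 0 for normalization", call. = FALSE)
  percent / density
}

#' Group engulfment values relative to a reference group
#'
#' Expresses per-cell (or per-animal) engulfment values as a percentage
#' of the reference-group mean ("relative % engulfment").
#'
#' @param group_values numeric values.
#' @param reference_group_values numeric reference values.
#' @return Percentages.
#' @export
relative_percent <- function(group_values, reference_group_values) {
  percent_of_reference(group_values, reference_group_values)
}

#' Run the full engulfment measurement on one scene
#'
#' @param scene an `engulfment_scene`.
#' @param cell_threshold,cargo_threshold channel thresholds.
#' @return A one-row data.frame (class `engulfment_result`) with cell
#'   volume, engulfed volume, percent engulfment, input density and
#'   normalized engulfment.
#' @export
measure_engulfment <- function(scene, cell_threshold = 0.5,
                               cargo_threshold = 0.5) {
  mask <- segment_cell(scene, threshold = cell_threshold)
  voxvol <- prod(scene$voxel_size_um)
  pct <- percent_engulfment(mask, scene$cargo, cargo_threshold)
  dens <- input_density(scene, cargo_threshold)
  structure(data.frame(
    cell_type = scene$cell_type,
    cell_volume_um3 = attr(mask, "volume_um3"),
    engulfed_volume_um3 = pct / 100 * attr(mask, "volume_um3"),
    percent_engulfment = pct,
    input_density = dens,
    normalized_engulfment = if (dens > 0) pct / dens else NA_real_),
    class = c("engulfment_result", "data.frame"))
}
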