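#' Simulate a glial engulfment scene with known engulfed-cargo fraction
#'
#' Builds a blob-shaped (randomly oriented ellipsoidal) cell mask of
#' approximately `cell_volume_um3` centered in the field, then places
#' cargo-positive voxels so that the engulfed-cargo volume divided by the
#' cell volume equals `cargo_inside_fraction` up to voxel quantization.
#' Extracellular cargo occupies a `cargo_field_density` volume fraction of
#' the space outside the cell. The cell channel is the mask at unit
#' intensity plus weak Gaussian readout noise; the cargo channel is binary.
#'
#' @param cell_volume_um3 target cell volume (um^3).
#' @param cargo_inside_fraction engulfed-cargo volume as a fraction of the
#'   cell volume, in `[0, 1]`.
#' @param cargo_field_density extracellular cargo volume fraction in `[0, 1]`.
#' @param voxel_size_um voxel pitch (um).
#' @param field_size_um field extents (um).
#' @param cell_type `"microglia"` or `"astrocyte"`; label only, the
#'   procedure is identical for both.
#' @param seed integer seed.
#' @return A list with `scene` (class `engulfment_scene`: `cell` and
#'   `cargo` 3D arrays, voxel size, cell seed point in um, cell type) and
#'   `truth` (realized cell volume, engulfed volume, inside fraction and
#'   field-wide input density).
#' @examples
#' sim <- gen_engulfment_scene(cell_volume_um3 = 500,
#'                             cargo_inside_fraction = 0.05, seed = 3)
#' sim$truth$engulfed_volume_um3 / sim$truth$cell_volume_um3
#' @export
gen_engulfment_scene <- function(cell_volume_um3 = 1000,
                                 cargo_inside_fraction = 0.05,
                                 cargo_field_density = 0.01,
                                 voxel_size_um = c(0.5, 0.5, 0.5),
                                 field_size_um = c(30, 30, 30),
                                 cell_type = c("microglia", "astrocyte"),
                                 seed = 1L) {
  cell_type <- match.arg(cell_type)
  stopifnot_scalar(cell_volume_um3, "cell_volume_um3", lower = 0,
                   strict_lower = TRUE)
  stopifnot_scalar(cargo_inside_fraction, "cargo_inside_fraction",
                   lower = 0, upper = 1)
  stopifnot_scalar(cargo_field_density, "cargo_field_density",
                   lower = 0, upper = 1)
  stopifnot_vec3(voxel_size_um, "voxel_size_um", positive = TRUE)
  stopifnot_vec3(field_size_um, "field_size_um", positive = TRUE)
  voxvol <- prod(voxel_size_um)
  dimv <- pmax(2L, as.integer(round(field_size_um / voxel_size_um)))
  with_stream(seed, "engulfment_scene", {
    # randomly oriented ellipsoid with axes scaled to the target volume
    ratio <- runif(2L, 0.6, 1.4)
    abc0 <- c(1, ratio)
    scale <- (cell_volume_um3 / (4 / 3 * pi * prod(abc0)))^(1 / 3)
    abc <- abc0 * scale
    ctr <- field_size_um / 2
    if (any(abc * 2 > field_size_um))
      stop("cell does not fit in the field at the requested volume",
           call. = FALSE)
    ax <- (seq_len(dimv[1]) - 0.5) * voxel_size_um[1]
    ay <- (seq_len(dimv[2]) - 0.5) * voxel_size_um[2]
    az <- (seq_len(dimv[3]) - 0.5) * voxel_size_um[3]
    q <- outer(outer((ax - ctr[1])^2 / abc[1]^2,
                     (ay - ctr[2])^2 / abc[2]^2, "+"),
               (az - ctr[3])^2 / abc[3]^2, "+")
    mask <- q <= 1
    n_cell <- sum(mask)
    n_in <- round(cargo_inside_fraction * n_cell)
    if (cargo_inside_fraction > 0 && n_in == 0L)
      stop(sprintf(paste0("requested cargo_inside_fraction %.3g is below the ",
                          "achievable quantum of one voxel (%.3g)"),
                   cargo_inside_fraction, 1 / n_cell), call. = FALSE)
    inside_idx <- which(mask)
    outside_idx <- which(!mask)
    cargo <- array(0, dimv)
    if (n_in > 0)
      cargo[sample(inside_idx, n_in)] <- 1
    n_out <- round(cargo_field_density * length(outside_idx))
    if (n_out > 0)
      cargo[sample(outside_idx, n_out)] <- 1
    cell <- array(0, dimv)
    cell[mask] <- 1
    cell <- cell + array(abs(rnorm(length(cell), 0, 0.02)), dimv) * (cell == 0) +
      array(rnorm(length(cell), 0, 0.02), dimv) * (cell > 0)
    scene <- structure(list(cell = cell, cargo = cargo,
                            voxel_size_um = as.numeric(voxel_size_um),
                            field_size_um = as.numeric(field_size_um),
                            seed_point_um = ctr, cell_type = cell_type),
                       class = "engulfment_scene")
    truth <- list(cell_volume_um3 = n_cell * voxvol,
                  engulfed_volume_um3 = n_in * voxvol,
                  inside_fraction = if (n_cell > 0) n_in / n_cell else NA_real_,
                  input_density = (n_in + n_out) * voxvol /
                    (length(cargo) * voxvol),
                  voxel_volume_um3 = voxvol)
    list(scene = scene, truth = truth)
  })
}
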