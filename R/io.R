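# File IO: multi-channel TIFF stacks with OME-style companion metadata,
# and CSV tables for spots, events and cohorts.

#' Write a multi-channel field as TIFF plus OME companion metadata
#'
#' Pixel data go into a multi-page 16-bit TIFF (pages ordered z within
#' channel); voxel size and channel names go into a companion OME-XML
#' file (`<path>.companion.ome`) so physical calibration survives the
#' round trip.
#'
#' @param field a `puncta_field` or any list with `intensities` (named
#'   3D arrays) and `voxel_size_um`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(length(field$intensities) > 0)
  mx <- max(1, vapply(field$intensities, max, 0))
  pages <- list()
  for (ch in names(field$intensities)) {
    a <- field$intensities[[ch]]
    for (z in seq_len(dim(a)[3L]))
      pages[[length(pages) + 1L]] <- t(a[, , z]) / mx
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  d <- dim(field$intensities[[1L]])
  doc <- xml2::xml_new_root("OME")
  img <- xml2::xml_add_child(doc, "Image", Name = field$field_id %||% "field")
  xml2::xml_add_child(img, "Pixels",
                      SizeX = d[1L], SizeY = d[2L], SizeZ = d[3L],
                      SizeC = length(field$intensities), SizeT = 1L,
                      PhysicalSizeX = field$voxel_size_um[1L],
                      PhysicalSizeY = field$voxel_size_um[2L],
                      PhysicalSizeZ = field$voxel_size_um[3L],
                      PhysicalSizeXUnit = "um", PhysicalSizeYUnit = "um",
                      PhysicalSizeZUnit = "um",
                      DimensionOrder = "XYZCT", IntensityScale = mx)
  for (ch in names(field$intensities))
    xml2::xml_add_child(img, "Channel", Name = ch)
  xml2::write_xml(doc, paste0(path, ".companion.ome"))
  invisible(path)
}

#' Read a field written by [write_field_tiff()]
#'
#' @param path TIFF path (the companion OME-XML must sit next to it).
#' @return A `puncta_field`.
#' @export
read_field_tiff <- function(path) {
  meta_path <- paste0(path, ".companion.ome")
  if (!file.exists(meta_path))
    stop("companion OME metadata file not found: ", meta_path, call. = FALSE)
  doc <- xml2::read_xml(meta_path)
  px <- xml2::xml_find_first(doc, ".//Pixels")
  d <- as.integer(c(xml2::xml_attr(px, "SizeX"), xml2::xml_attr(px, "SizeY"),
                    xml2::xml_attr(px, "SizeZ")))
  nc <- as.integer(xml2::xml_attr(px, "SizeC"))
  voxel <- as.numeric(c(xml2::xml_attr(px, "PhysicalSizeX"),
                        xml2::xml_attr(px, "PhysicalSizeY"),
                        xml2::xml_attr(px, "PhysicalSizeZ")))
  scale <- as.numeric(xml2::xml_attr(px, "IntensityScale"))
  chans <- xml2::xml_attr(xml2::xml_find_all(doc, ".//Channel"), "Name")
  pages <- tiff::readTIFF(path, all = TRUE)
  intens <- list()
  k <- 0L
  for (ci in seq_len(nc)) {
    a <- array(0, d)
    for (z in seq_len(d[3L])) {
      k <- k + 1L
      a[, , z] <- t(pages[[k]]) * scale
    }
    intens[[chans[ci]]] <- a
  }
  structure(list(intensities = intens, voxel_size_um = voxel,
                 field_size_um = d * voxel, channel_names = chans,
                 field_id = xml2::xml_attr(xml2::xml_find_first(doc, ".//Image"),
                                           "Name"),
                 animal_id = NA_character_),
            class = "puncta_field")
}

#' Write a spot set to CSV
#'
#' @param spots a `spot_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spots_csv <- function(spots, path) {
  df <- as.data.frame(spots)
  df$channel <- attr(spots, "channel")
  df$field_id <- attr(spots, "field_id")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write event trains to a tidy CSV
#'
#' One row per event: `cell_id`, `group`, `event_time_s`, `amplitude_pa`,
#' `duration_s`.
#'
#' @param trains list of [event_train()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(trains, path) {
  rows <- lapply(trains, function(tr) {
    if (!length(tr$times))
      return(data.frame(cell_id = character(0), group = character(0),
                        event_time_s = numeric(0), amplitude_pa = numeric(0),
                        duration_s = numeric(0)))
    data.frame(cell_id = tr$cell_id, group = tr$group,
               event_time_s = tr$times, amplitude_pa = tr$amplitudes,
               duration_s = tr$duration_s)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read event trains from a tidy CSV
#'
#' @param path CSV with columns `cell_id`, `group`, `event_time_s`,
#'   `amplitude_pa`, `duration_s`.
#' @return List of [event_train()] objects.
#' @export
read_events_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("cell_id", "group", "event_time_s", "amplitude_pa", "duration_s")
  missing <- setdiff(req, names(d))
  if (length(missing))
    stop("events CSV missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  lapply(split(d, d$cell_id), function(dd) {
    o <- order(dd$event_time_s)
    event_train(dd$cell_id[1L], dd$group[1L], dd$event_time_s[o],
                dd$amplitude_pa[o], dd$duration_s[1L])
  })
}

#' Write / read a cohort table
#'
#' @param cohort a data.frame as returned by [gen_cohort()].
#' @param path CSV path.
#' @return `path` invisibly (write); a data.frame (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
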