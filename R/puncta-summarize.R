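#' Per-animal summary of per-plane synapse counts
#'
#' Each animal contributes a fixed design of fields and z-planes (default
#' three fields of view with three planes each, nine values per animal);
#' the per-animal value is the mean of those plane values. Missing planes
#' are an error unless explicitly allowed.
#'
#' @param counts data.frame with columns `field`, `plane`, `value`.
#' @param n_fields,n_planes expected design (fields per animal, planes
#'   per field).
#' @param allow_missing if `TRUE`, average whatever planes are present.
#' @return A list with `per_field` (named per-field means), `animal_mean`
#'   and `n_values`.
#' @examples
#' d <- expand.grid(field = 1:3, plane = 1:3)
#' d$value <- 1:9
#' summarize_animal(d)$animal_mean   # 5
#' @export
summarize_animal <- function(counts, n_fields = 3L, n_planes = 3L,
                             allow_missing = FALSE) {
  req <- c("field", "plane", "value")
  if (!is.data.frame(counts) || !all(req %in% names(counts)))
    stop("'counts' must be a data.frame with columns field, plane, value",
         call. = FALSE)
  expected <- expand.grid(field = sort(unique(counts$field)),
                          plane = seq_len(n_planes))
  if (!allow_missing) {
    if (length(unique(counts$field)) != n_fields)
      stop(sprintf("expected %d fields, found %d", n_fields,
                   length(unique(counts$field))), call. = FALSE)
    have <- paste(counts$field, counts$plane)
    want <- paste(expected$field, expected$plane)
    missing <- setdiff(want, have)
    if (length(missing))
      stop("missing field/plane combinations: ",
           paste(missing, collapse = ", "),
           " (set allow_missing = TRUE to override)", call. = FALSE)
  }
  per_field <- tapply(counts$value, counts$field, mean)
  list(per_field = per_field,
       animal_mean = mean(counts$value),
       n_values = nrow(counts))
}

#' Express values as a percentage of a reference-group mean
#'
#' The normalization used throughout the imaging analyses: each group
#' value is divided by the mean of the reference (wild-type) group at the
#' same age and multiplied by 100.
#'
#' @param group_values numeric values to normalize.
#' @param reference_group_values numeric reference values; must be
#'   nonempty with nonzero mean.
#' @return Percentages.
#' @export
percent_of_reference <- function(group_values, reference_group_values) {
  if (!length(reference_group_values))
    stop("reference group is empty", call. = FALSE)
  m <- mean(reference_group_values)
  if (!is.finite(m) || m == 0)
    stop("reference group mean is zero or non-finite", call. = FALSE)
  100 * group_values / m
}
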