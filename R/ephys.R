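#' Inter-event intervals of an event train
#'
#' @param train an [event_train()].
#' @return Successive differences of the event times (s); length is the
#'   event count minus one. Fewer than two events give an empty vector
#'   with a warning.
#' @export
isis <- function(train) {
  stopifnot(inherits(train, "event_train"))
  if (length(train$times) < 2L) {
    warning("fewer than two events: no inter-event intervals")
    return(numeric(0))
  }
  diff(train$times)
}

#' Per-cell mean frequency and amplitude
#'
#' @param train an [event_train()].
#' @return A one-row data.frame with `cell_id`, `group`,
#'   `frequency_hz` (event count / duration) and `mean_amplitude_pa`
#'   (`NA` when the train has no events).
#' @export
cell_summary <- function(train) {
  stopifnot(inherits(train, "event_train"))
  if (train$duration_s <= 0)
    stop("recording duration must be > 0", call. = FALSE)
  data.frame(cell_id = train$cell_id, group = train$group,
             frequency_hz = length(train$times) / train$duration_s,
             mean_amplitude_pa = if (length(train$amplitudes))
               mean(train$amplitudes) else NA_real_)
}

metric_values <- function(train, metric) {
  switch(metric,
         isi = if (length(train$times) >= 2L) diff(train$times) else numeric(0),
         amplitude = train$amplitudes)
}

# One bootstrap resampling matrix per group: n_iterations rows, each row a
# pooled draw of n_events values with replacement from every cell.
resample_pool <- function(values_by_cell, n_events, n_iterations) {
  mats <- lapply(values_by_cell, function(v)
    matrix(v[sample.int(length(v), n_events * n_iterations, replace = TRUE)],
           nrow = n_iterations))
  do.call(cbind, mats)
}

#' Equal-cell-weight bootstrap of a pooled cumulative distribution
#'
#' To weight every recorded cell equally regardless of how many events it
#' contributed, each iteration draws `n_events` values with replacement
#' from every cell, pools them (`n_cells x n_events` values per
#' iteration), and evaluates the empirical CDF on a fixed grid. The band
#' is the pointwise variance of the CDF across iterations.
#'
#' @param trains list of [event_train()] objects from one group.
#' @param metric `"isi"` or `"amplitude"`.
#' @param n_events events resampled per cell per iteration.
#' @param n_iterations bootstrap iterations for the band.
#' @param grid optional fixed evaluation grid; defaults to 201 points
#'   spanning the pooled observed range.
#' @param seed integer seed.
#' @return A list (class `bootstrap_cdf`) with `grid`, `mean_cdf`,
#'   `var_band`, `pooled_n` (values pooled per iteration), `n_events`,
#'   `n_iterations`, `metric`.
#' @export
bootstrap_cdf <- function(trains, metric = c("isi", "amplitude"),
                          n_events = 100L, n_iterations = 1000L,
                          grid = NULL, seed = 1L) {
  metric <- match.arg(metric)
  if (!length(trains)) stop("empty group", call. = FALSE)
  vals <- lapply(trains, metric_values, metric = metric)
  if (any(lengths(vals) == 0L))
    stop("every cell must have at least one value of the metric",
         call. = FALSE)
  if (is.null(grid)) {
    pooled <- unlist(vals)
    grid <- if (diff(range(pooled)) == 0) range(pooled)[1L]
    else seq(min(pooled), max(pooled), length.out = 201L)
  }
  with_stream(seed, "bootstrap_cdf", {
    m <- resample_pool(vals, n_events, n_iterations)
    np <- ncol(m)
    s1 <- numeric(length(grid)); s2 <- numeric(length(grid))
    for (i in seq_len(n_iterations)) {
      cdf <- findInterval(grid, sort(m[i, ])) / np
      s1 <- s1 + cdf; s2 <- s2 + cdf^2
    }
    mean_cdf <- s1 / n_iterations
    var_band <- pmax(0, s2 / n_iterations - mean_cdf^2)
    structure(list(grid = grid, mean_cdf = mean_cdf, var_band = var_band,
                   pooled_n = np, n_events = n_events,
                   n_iterations = n_iterations, metric = metric),
              class = "bootstrap_cdf")
  })
}

#' Bootstrap comparison of two groups at a distribution percentile
#'
#' Each iteration resamples both groups with equal cell weighting (as in
#' [bootstrap_cdf()]) and computes each group's pooled quantile at `q`
#' (default the 75th percentile, linear interpolation). The fraction `f`
#' of iterations in which group A's quantile exceeds group B's (ties
#' counted half to each side) gives the two-sided p-value
#' `2 * min(f, 1 - f)`, floored at `1 / n_iterations` — the test's
#' resolution limit (0.0002 at 5,000 iterations).
#'
#' @param a_trains,b_trains lists of [event_train()] objects.
#' @param metric `"isi"` or `"amplitude"`.
#' @param q percentile compared, in `(0, 1)`.
#' @param n_events events resampled per cell per iteration.
#' @param n_iterations bootstrap iterations.
#' @param alternative `"two.sided"` (default) or one-sided
#'   `"greater"`/`"less"` (A's quantile vs B's).
#' @param seed integer seed.
#' @return A list (class `percentile_test`) with `p_value`, `f_a_greater`,
#'   `p_floor`, `q`, `metric`, `n_iterations`.
#' @examples
#' tr <- gen_event_trains(train_spec(n_cells = 4, events_per_cell_mean = 200,
#'                                   group_effect = list(freq = 0.5, amp = 1),
#'                                   seed = 8))
#' grp <- vapply(tr, function(t) t$group, "")
#' percentile_test(tr[grp == "A"], tr[grp == "B"], "isi",
#'                 n_iterations = 200, seed = 1)$p_value
#' @export
percentile_test <- function(a_trains, b_trains, metric = c("isi", "amplitude"),
                            q = 0.75, n_events = 100L, n_iterations = 5000L,
                            alternative = c("two.sided", "greater", "less"),
                            seed = 1L) {
  metric <- match.arg(metric)
  alternative <- match.arg(alternative)
  stopifnot_scalar(q, "q", lower = 0, upper = 1)
  if (!length(a_trains) || !length(b_trains))
    stop("both groups must be nonempty", call. = FALSE)
  va <- lapply(a_trains, metric_values, metric = metric)
  vb <- lapply(b_trains, metric_values, metric = metric)
  if (any(lengths(va) == 0L) || any(lengths(vb) == 0L))
    stop("every cell must have at least one value of the metric",
         call. = FALSE)
  # per-group streams keyed by the group's cell ids: swapping the two
  # arguments leaves each group's resamples unchanged, so the two-sided
  # p-value is exactly symmetric
  stream_of <- function(trains)
    paste0("percentile_test:",
           paste(vapply(trains, `[[`, "", "cell_id"), collapse = ","))
  ma <- with_stream(seed, stream_of(a_trains),
                    resample_pool(va, n_events, n_iterations))
  mb <- with_stream(seed, stream_of(b_trains),
                    resample_pool(vb, n_events, n_iterations))
  {
    qa <- row_quantile(ma, q)
    qb <- row_quantile(mb, q)
    f <- (sum(qa > qb) + 0.5 * sum(qa == qb)) / n_iterations
    floor_p <- 1 / n_iterations
    p <- switch(alternative,
                two.sided = min(1, 2 * min(f, 1 - f)),
                greater = 1 - f,
                less = f)
    p <- max(p, floor_p)
    structure(list(p_value = p, f_a_greater = f, p_floor = floor_p,
                   q = q, metric = metric, n_events = n_events,
                   n_iterations = n_iterations, alternative = alternative),
              class = "percentile_test")
  }
}

# type-7 quantile of every row via partial sorting
row_quantile <- function(m, q) {
  n <- ncol(m)
  h <- (n - 1) * q + 1
  lo <- floor(h); fr <- h - lo; hi <- min(lo + 1, n)
  parts <- unique(c(lo, hi))
  vapply(seq_len(nrow(m)), function(i) {
    xs <- sort.int(m[i, ], partial = parts)
    xs[lo] + fr * (xs[hi] - xs[lo])
  }, 0)
}
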