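#' Specification of synthetic sEPSC event trains
#'
#' Inter-event intervals are exponential at `isi_rate_hz`; amplitudes are
#' log-normal in pA. The recording duration per cell is
#' `events_per_cell_mean / isi_rate_hz`, so the realized event count per
#' cell is Poisson with mean `events_per_cell_mean`. A second group is
#' generated with its rate multiplied by `group_effect$freq` and its
#' amplitudes by `group_effect$amp` over the same duration.
#'
#' @param n_cells cells per group.
#' @param events_per_cell_mean expected events per cell in group 1.
#' @param isi_rate_hz exponential rate of inter-event intervals (Hz).
#' @param amp_lognorm_mu,amp_lognorm_sigma log-normal amplitude
#'   parameters (log-pA scale).
#' @param group_effect list with multiplicative shifts `freq` and `amp`
#'   applied to the second group.
#' @param seed integer seed.
#' @return An object of class `train_spec`.
#' @export
train_spec <- function(n_cells = 10L, events_per_cell_mean = 600,
                       isi_rate_hz = 2, amp_lognorm_mu = log(15),
                       amp_lognorm_sigma = 0.4,
                       group_effect = list(freq = 1, amp = 1),
                       seed = 1L) {
  stopifnot_scalar(n_cells, "n_cells", lower = 1)
  stopifnot_scalar(events_per_cell_mean, "events_per_cell_mean", lower = 0)
  stopifnot_scalar(isi_rate_hz, "isi_rate_hz", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(amp_lognorm_sigma, "amp_lognorm_sigma", lower = 0)
  stopifnot_scalar(group_effect$freq, "group_effect$freq", lower = 0,
                   strict_lower = TRUE)
  stopifnot_scalar(group_effect$amp, "group_effect$amp", lower = 0,
                   strict_lower = TRUE)
  structure(list(n_cells = as.integer(n_cells),
                 events_per_cell_mean = events_per_cell_mean,
                 isi_rate_hz = isi_rate_hz,
                 amp_lognorm_mu = amp_lognorm_mu,
                 amp_lognorm_sigma = amp_lognorm_sigma,
                 group_effect = group_effect,
                 seed = as.integer(seed)),
            class = "train_spec")
}

#' Per-cell sEPSC event train
#'
#' @param cell_id cell label.
#' @param group group label.
#' @param times event times in seconds, strictly increasing within
#'   `[0, duration_s]`.
#' @param amplitudes event amplitude magnitudes in pA, all positive.
#' @param duration_s recording duration in seconds.
#' @return An object of class `event_train`.
#' @export
event_train <- function(cell_id, group, times, amplitudes, duration_s) {
  times <- as.numeric(times); amplitudes <- as.numeric(amplitudes)
  if (length(times) != length(amplitudes))
    stop("'times' and 'amplitudes' must have equal length", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("event times must be strictly increasing", call. = FALSE)
  if (length(times) && (min(times) < 0 || max(times) > duration_s))
    stop("event times must lie within [0, duration_s]", call. = FALSE)
  if (any(amplitudes <= 0))
    stop("amplitudes must be positive magnitudes (pA)", call. = FALSE)
  structure(list(cell_id = cell_id, group = group, times = times,
                 amplitudes = amplitudes, duration_s = duration_s),
            class = "event_train")
}

#' Simulate sEPSC event trains for two groups
#'
#' @param spec a [train_spec()].
#' @return A list of [event_train()] objects, `n_cells` per group, with
#'   group labels `"A"` (reference) and `"B"` (effect group).
#' @examples
#' trains <- gen_event_trains(train_spec(n_cells = 2,
#'                                       events_per_cell_mean = 50, seed = 2))
#' length(trains)
#' @export
gen_event_trains <- function(spec) {
  stopifnot(inherits(spec, "train_spec"))
  duration <- spec$events_per_cell_mean / spec$isi_rate_hz
  with_stream(spec$seed, "event_trains", {
    out <- list()
    for (grp in c("A", "B")) {
      rate <- spec$isi_rate_hz *
        if (grp == "B") spec$group_effect$freq else 1
      amp_mu <- spec$amp_lognorm_mu +
        if (grp == "B") log(spec$group_effect$amp) else 0
      for (i in seq_len(spec$n_cells)) {
        times <- numeric(0)
        if (duration > 0) {
          t <- cumsum(rexp(max(20L, ceiling(rate * duration * 2)), rate))
          while (length(t) && t[length(t)] <= duration)
            t <- c(t, t[length(t)] +
                     cumsum(rexp(ceiling(rate * duration * 0.5) + 10L, rate)))
          times <- t[t <= duration]
        }
        amps <- rlnorm(length(times), amp_mu, spec$amp_lognorm_sigma)
        out[[length(out) + 1L]] <-
          event_train(sprintf("%s_cell%02d", grp, i), grp, times, amps,
                      duration_s = duration)
      }
    }
    out
  })
}
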