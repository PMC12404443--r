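# Single-channel trace operations: segment concatenation, baseline
# subtraction, half-amplitude idealization, temperature-current relations.

infer_sampling_rate <- function(time_s) {
  dt <- median(diff(time_s))
  if (!is.finite(dt) || dt <= 0) {
    stop_ardscan("bad_trace", "cannot infer a positive sampling interval from `time_s`")
  }
  1 / dt
}

#' Concatenate tagged sweep segments of a recording
#'
#' Voltage-clamp sweeps alternate holding levels; single-channel analysis is
#' done on one level only (e.g. the +80 mV segment of each sweep), so the
#' tagged segment of every sweep is extracted and appended in sweep order.
#' Each sweep listed in `segments` must contain the tag.
#'
#' @param trace Tibble with columns `time_s`, `current_pA` (uniform sampling).
#' @param segments Sidecar segment table with columns `sweep_id`, `segment`,
#'   `start_s`, `end_s` and optional condition labels (`voltage_mV`,
#'   `ligand_uM`, `pH`), carried into the output.
#' @param segment Tag selecting the segments to concatenate (default
#'   `"+80mV"`).
#' @return A tibble with a fresh uniform `time_s` axis, `current_pA`, the
#'   originating `sweep_id` and any condition-label columns.
#' @export
concatenate_segments <- function(trace, segments, segment = "+80mV") {
  assert_columns(trace, c("time_s", "current_pA"), "`trace`")
  assert_columns(segments, c("sweep_id", "segment", "start_s", "end_s"), "`segments`")
  if (nrow(segments) == 0) stop_ardscan("empty_input", "no sweeps in `segments`")

  sweeps <- unique(segments$sweep_id)
  tagged <- segments %>% filter(.data$segment == !!segment)
  missing <- setdiff(sweeps, tagged$sweep_id)
  if (length(missing) > 0) {
    stop_ardscan("missing_segment",
                 sprintf("sweep(s) without a '%s' segment: %s",
                         segment, paste(missing, collapse = ", ")))
  }
  fs <- infer_sampling_rate(trace$time_s)
  labels <- intersect(c("voltage_mV", "ligand_uM", "pH"), names(tagged))

  pieces <- purrr::map(seq_len(nrow(tagged)), function(r) {
    seg <- tagged[r, ]
    piece <- trace %>%
      filter(.data$time_s >= seg$start_s, .data$time_s < seg$end_s) %>%
      mutate(sweep_id = seg$sweep_id)
    for (lb in labels) piece[[lb]] <- seg[[lb]]
    piece
  })
  out <- bind_rows(pieces)
  if (nrow(out) == 0) stop_ardscan("empty_selection", "tagged segments contain no samples")
  out %>% mutate(time_s = (row_number() - 1) / fs)
}

#' Subtract a slowly varying current baseline
#'
#' Estimates the baseline as a rolling 10th percentile of the current over
#' windows of `window_s` seconds (evaluated on a stride and linearly
#' interpolated between evaluation points), which tracks slow drift while
#' ignoring channel openings. Because a low percentile of a noisy closed
#' level sits below its mean, the subtracted trace is then recentred by the
#' mode of its amplitude density — the closed state, assumed to be the
#' dominant state — so the closed level lands at ~0.
#'
#' @param trace Tibble with columns `time_s`, `current_pA`.
#' @param window_s Baseline window length in seconds (default 1); must be
#'   shorter than the trace.
#' @return The trace with `current_pA` baseline-subtracted and an added
#'   `baseline_pA` column holding the subtracted baseline.
#' @export
subtract_baseline <- function(trace, window_s = 1) {
  assert_columns(trace, c("time_s", "current_pA"), "`trace`")
  n <- nrow(trace)
  fs <- infer_sampling_rate(trace$time_s)
  w <- round(window_s * fs)
  if (w >= n) {
    stop_ardscan("window_too_long", "baseline window must be shorter than the trace")
  }
  w <- max(w, 2L)
  x <- trace$current_pA
  half <- w %/% 2L
  stride <- max(1L, half %/% 2L)
  centers <- unique(c(seq(1L, n, by = stride), n))
  base_at <- vapply(centers, function(c0) {
    lo <- max(1L, c0 - half); hi <- min(n, c0 + half)
    unname(quantile(x[lo:hi], 0.10, names = FALSE))
  }, numeric(1))
  baseline <- approx(centers, base_at, xout = seq_len(n), rule = 2)$y
  y <- x - baseline

  # recentre on the dominant (closed) amplitude mode
  if (sd(y) > 0) {
    d <- density(y, n = 512)
    mode_y <- d$x[which.max(d$y)]
  } else {
    mode_y <- mean(y)
  }
  trace %>% mutate(baseline_pA = baseline + mode_y,
                   current_pA = y - mode_y)
}

#' Idealize a single-channel trace by half-amplitude thresholds
#'
#' Assigns each sample to an occupancy level 0..k using thresholds halfway
#' between unitary levels, i.e. a sample is at level m when its current lies
#' within `(m - 1/2) * i` to `(m + 1/2) * i`. Open probability is the mean
#' occupancy divided by the channel count; for one channel this is the
#' fraction of samples in the open state. The trace must be
#' baseline-subtracted; openings are treated as positive deflections (set
#' `polarity = "negative"` for -80 mV segments).
#'
#' @param trace Tibble with columns `time_s`, `current_pA`.
#' @param unitary_current Single-channel current `i` in pA (> 0).
#' @param n_channels Number of channels `k` in the patch (default 1).
#' @param polarity `"positive"` (default) or `"negative"` opening direction.
#' @return An object of class `idealized_trace`: the trace tibble with an
#'   added integer `state` column, plus fields `unitary_current`,
#'   `n_channels` and `po`. Supports [glance()] and [autoplot()].
#' @export
idealize_half_amplitude <- function(trace, unitary_current, n_channels = 1L,
                                    polarity = c("positive", "negative")) {
  assert_columns(trace, c("time_s", "current_pA"), "`trace`")
  polarity <- match.arg(polarity)
  if (!is.finite(unitary_current) || unitary_current <= 0) {
    stop_ardscan("bad_unitary_current", "`unitary_current` must be > 0")
  }
  k <- as.integer(n_channels)
  if (k < 1) stop_ardscan("bad_channels", "`n_channels` must be >= 1")
  cur <- trace$current_pA
  if (polarity == "negative") cur <- -cur
  # thresholds at (m - 1/2) * i <=> floor(x/i + 1/2), clipped to [0, k]
  state <- pmin(pmax(floor(cur / unitary_current + 0.5), 0), k)
  out <- trace %>% mutate(state = as.integer(state))
  structure(
    list(
      trace = out,
      unitary_current = unitary_current,
      n_channels = k,
      po = mean(state) / k
    ),
    class = "idealized_trace"
  )
}

#' @export
print.idealized_trace <- function(x, ...) {
  cat(sprintf("<idealized_trace> %d samples, i = %.3g pA, k = %d, Po = %.4f\n",
              nrow(x$trace), x$unitary_current, x$n_channels, x$po))
  invisible(x)
}

#' @rdname idealize_half_amplitude
#' @param x An `idealized_trace` object.
#' @param ... Unused.
#' @export
glance.idealized_trace <- function(x, ...) {
  tibble(
    n_samples = nrow(x$trace),
    unitary_current = x$unitary_current,
    n_channels = x$n_channels,
    po = x$po
  )
}

#' Normalized current-temperature relations
#'
#' Normalizes each cell's steady-state currents (at +100 mV) by that cell's
#' mean current inside the room-temperature window, pools cells, and
#' summarizes per 2 degC temperature bin (half-open intervals around even
#' centers) with the median and the standard error across cells.
#'
#' @param sweeps Tibble with columns `cell_id`, `temp_C`, `current_pA`, one
#'   row per sweep.
#' @param room Room-temperature reference window `c(lo, hi)` in degC
#'   (default 20-25); every cell must have at least one sweep inside it.
#' @param bin_width Bin width in degC (default 2).
#' @return A tibble with columns `temp_bin` (bin center, degC), `median_norm`
#'   (median across cells of the per-cell bin mean), `sem` and `n_cells`.
#' @export
temperature_relation <- function(sweeps, room = c(20, 25), bin_width = 2) {
  assert_columns(sweeps, c("cell_id", "temp_C", "current_pA"), "`sweeps`")
  refs <- sweeps %>%
    group_by(.data$cell_id) %>%
    summarise(
      ref = mean(.data$current_pA[.data$temp_C >= room[[1]] & .data$temp_C <= room[[2]]]),
      .groups = "drop"
    )
  if (any(is.nan(refs$ref))) {
    stop_ardscan("no_reference",
                 sprintf("cell(s) with no sweep in the room window [%g, %g] degC: %s",
                         room[[1]], room[[2]],
                         paste(refs$cell_id[is.nan(refs$ref)], collapse = ", ")))
  }
  if (any(refs$ref == 0)) {
    stop_ardscan("zero_reference", "room-window mean current is zero for some cell")
  }
  sweeps %>%
    left_join(refs, by = "cell_id") %>%
    mutate(
      norm = .data$current_pA / .data$ref,
      temp_bin = floor(.data$temp_C / bin_width) * bin_width + bin_width / 2
    ) %>%
    group_by(.data$cell_id, .data$temp_bin) %>%
    summarise(cell_mean = mean(.data$norm), .groups = "drop") %>%
    group_by(.data$temp_bin) %>%
    summarise(
      median_norm = median(.data$cell_mean),
      sem = sd(.data$cell_mean) / sqrt(n()),
      n_cells = n(),
      .groups = "drop"
    ) %>%
    arrange(.data$temp_bin)
}
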