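# Calcium-imaging responder classification and response fractions.

# wide (frame_time_s, cell_001, ...) -> long (cell_id, frame_time_s, f)
cell_traces_long <- function(traces) {
  if ("frame_time_s" %in% names(traces) && !"cell_id" %in% names(traces)) {
    traces <- traces %>%
      tidyr::pivot_longer(-"frame_time_s", names_to = "cell_id", values_to = "f")
  }
  assert_columns(traces, c("cell_id", "frame_time_s", "f"), "`traces`")
  traces
}

#' Classify calcium-imaging cell traces by stimulus response
#'
#' Labels each cell from its fluorescence time series: the baseline `F0` is
#' the mean over the pre-capsaicin frames; a cell is a `capsaicin_responder`
#' if its peak dF/F0 between the capsaicin and ionomycin additions reaches
#' the rise threshold `theta`, otherwise `ionomycin_only` if its peak dF/F0
#' after ionomycin does, and otherwise `excluded` (dead cells and cells that
#' start bright and stay flat never increase, so both fall here; so do cells
#' with a non-positive baseline, with the cause recorded).
#'
#' @param traces Per-cell fluorescence series, either long format (columns
#'   `cell_id`, `frame_time_s`, `f`) or wide format (`frame_time_s` plus one
#'   column per cell). Duplicate cell ids are rejected.
#' @param cap_time Capsaicin addition time, s (default 30).
#' @param iono_time Ionomycin addition time, s (default 120).
#' @param theta Rise threshold on peak dF/F0 (> 0; default 0.5).
#' @return A tibble with one row per cell: `cell_id`, `label`, `f0`,
#'   `peak_cap_dff`, `peak_iono_dff`, `exclusion_cause`.
#' @export
classify_cells <- function(traces, cap_time = 30, iono_time = 120, theta = 0.5) {
  if (theta <= 0) stop_ardscan("bad_threshold", "`theta` must be > 0")
  long <- cell_traces_long(traces)
  if (max(long$frame_time_s) <= iono_time || cap_time >= iono_time) {
    stop_ardscan("bad_event_times",
                 "need cap_time < iono_time < end of trace")
  }
  dup <- long %>%
    distinct(.data$cell_id, .data$frame_time_s) %>%
    count(.data$cell_id) %>%
    left_join(count(long, .data$cell_id, name = "n_rows"), by = "cell_id") %>%
    filter(.data$n_rows > .data$n)
  if (nrow(dup) > 0) {
    stop_ardscan("duplicate_cell_id",
                 sprintf("duplicate rows for cell id(s): %s",
                         paste(dup$cell_id, collapse = ", ")))
  }
  long %>%
    group_by(.data$cell_id) %>%
    summarise(
      f0 = mean(.data$f[.data$frame_time_s < cap_time]),
      peak_cap = max(c(-Inf, .data$f[.data$frame_time_s > cap_time &
                                       .data$frame_time_s < iono_time])),
      peak_iono = max(c(-Inf, .data$f[.data$frame_time_s > iono_time])),
      .groups = "drop"
    ) %>%
    mutate(
      peak_cap_dff = (.data$peak_cap - .data$f0) / .data$f0,
      peak_iono_dff = (.data$peak_iono - .data$f0) / .data$f0,
      exclusion_cause = dplyr::case_when(
        !is.finite(.data$f0) | .data$f0 <= 0 ~ "nonpositive_baseline",
        .data$peak_cap_dff < theta & .data$peak_iono_dff < theta ~ "no_rise",
        TRUE ~ NA_character_
      ),
      label = dplyr::case_when(
        !is.na(.data$exclusion_cause) ~ "excluded",
        .data$peak_cap_dff >= theta ~ "capsaicin_responder",
        TRUE ~ "ionomycin_only"
      )
    ) %>%
    select("cell_id", "label", "f0", "peak_cap_dff", "peak_iono_dff",
           "exclusion_cause")
}

#' Capsaicin response fraction over healthy cells
#'
#' The response fraction is the number of capsaicin responders divided by
#' the number of healthy cells (capsaicin responders plus ionomycin-only
#' cells); excluded cells never enter the denominator.
#'
#' @param labels Character vector of labels, or the classification tibble
#'   from [classify_cells()] (its `label` column is used).
#' @return A one-row tibble: `n_capsaicin_responders`, `n_ionomycin_only`,
#'   `n_excluded`, `fraction`.
#' @export
response_fraction <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  ok <- c("capsaicin_responder", "ionomycin_only", "excluded")
  if (!all(labels %in% ok)) {
    stop_ardscan("bad_label",
                 sprintf("labels must be one of: %s", paste(ok, collapse = ", ")))
  }
  n_resp <- sum(labels == "capsaicin_responder")
  n_iono <- sum(labels == "ionomycin_only")
  n_excl <- sum(labels == "excluded")
  if (n_resp + n_iono == 0) {
    stop_ardscan("no_healthy_cells", "no healthy (responding) cells in the field")
  }
  tibble(
    n_capsaicin_responders = n_resp,
    n_ionomycin_only = n_iono,
    n_excluded = n_excl,
    fraction = n_resp / (n_resp + n_iono)
  )
}

#' Normalize a response fraction to a same-day control
#'
#' Ratios the experimental response fraction against the same-day control
#' fraction, so the control normalized against itself is exactly 1.0 and
#' ratios above 1 are permitted.
#'
#' @param fraction Experimental response fraction(s).
#' @param control_fraction Same-day control response fraction (> 0).
#' @return Numeric normalized fraction(s).
#' @export
normalize_to_control <- function(fraction, control_fraction) {
  if (length(control_fraction) != 1 || !is.finite(control_fraction) ||
      control_fraction <= 0) {
    stop_ardscan("zero_control", "`control_fraction` must be a single positive value")
  }
  fraction / control_fraction
}
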