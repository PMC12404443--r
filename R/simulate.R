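# Synthetic-data generators. Every generator takes an explicit seed, leaves
# the global random state untouched (withr::with_seed), and emits the same
# tabular/file formats the analysis functions consume, so the whole pipeline
# runs and is testable with no downloads. Identical seed + configuration
# gives bit-identical output.

#' Simulate a missense-variant table with SASA-coupled variant rates
#'
#' Emulates the statistical structure the burial analysis assumes: the
#' number of distinct variant types at a residue is Poisson with log-rate
#' `intercept + slope * frac_sasa` (truncated at 19), so more exposed
#' residues accumulate more variant types; allele counts per type are
#' `1 + Geometric`. Planted outliers add extra variant types at chosen
#' (typically buried) positions, emulating an M308-like discordant residue.
#'
#' @param residues Tibble with columns `position`, `restype` (one-letter
#'   reference amino acid) and `frac_sasa`.
#' @param intercept,slope Log-linear coefficients of the type-count rate
#'   (slope >= 0; slope 0 decouples variant counts from burial).
#' @param outliers Optional tibble with columns `position`, `extra_types`:
#'   additional distinct variant types planted at those positions.
#' @param geom_prob Success probability of the allele-count Geometric
#'   (default 0.3; mean count 1 + (1-p)/p).
#' @param seed Integer seed.
#' @return A missense-variant tibble (`ref_aa`, `position`, `alt_aa`,
#'   `allele_count`, `source_release = "synthetic"`), one row per variant
#'   type, ready for [build_spectra()].
#' @export
simulate_variant_table <- function(residues, intercept = -1, slope = 2,
                                   outliers = NULL, geom_prob = 0.3, seed = 1L) {
  assert_columns(residues, c("position", "restype", "frac_sasa"), "`residues`")
  if (slope < 0) stop_ardscan("bad_slope", "`slope` must be >= 0")
  withr::with_seed(as.integer(seed), {
    rows <- purrr::pmap(
      list(residues$position, residues$restype, residues$frac_sasa),
      function(pos, ref, fs) {
        n_types <- min(rpois(1, exp(intercept + slope * fs)), 19L)
        if (!is.null(outliers) && pos %in% outliers$position) {
          extra <- outliers$extra_types[match(pos, outliers$position)]
          n_types <- min(n_types + extra, 19L)
        }
        if (n_types == 0) return(NULL)
        alts <- sample(setdiff(names(AA_THREE), ref), n_types)
        tibble(
          ref_aa = ref, position = pos, alt_aa = alts,
          allele_count = 1L + rgeom(n_types, geom_prob)
        )
      }
    )
    out <- bind_rows(rows)
    if (nrow(out) == 0) {
      out <- tibble(ref_aa = character(), position = integer(),
                    alt_aa = character(), allele_count = integer())
    }
    out %>% mutate(source_release = "synthetic")
  })
}

#' Simulate a two-state Markov single-channel recording
#'
#' Each of `n_channels` independent channels follows a continuous-time
#' two-state (closed/open) Markov process with opening rate `open_rate` and
#' closing rate `close_rate` (stationary open probability
#' `open_rate / (open_rate + close_rate)`), started from its stationary
#' distribution. The sampled current is `unitary_current * (open channels)`
#' plus Gaussian noise and a linear baseline drift.
#'
#' @param open_rate,close_rate Transition rates in 1/s (> 0).
#' @param unitary_current Single-channel current, pA.
#' @param sampling_rate Samples per second (default 20000).
#' @param duration Trace length, s (default 60).
#' @param noise_sd Gaussian current noise SD, pA.
#' @param drift Linear baseline drift, pA/s (default 0).
#' @param n_channels Number of independent channels (default 1).
#' @param seed Integer seed.
#' @return A list: `trace` (tibble `time_s`, `current_pA`), `occupancy`
#'   (true open-channel count per sample), `po_true` (time-averaged true
#'   open probability), `po_stationary` (`open_rate/(open_rate+close_rate)`).
#' @export
simulate_two_state_channel <- function(open_rate, close_rate, unitary_current = 1,
                                       sampling_rate = 20000, duration = 60,
                                       noise_sd = 0.1, drift = 0,
                                       n_channels = 1L, seed = 1L) {
  if (open_rate <= 0 || close_rate <= 0) {
    stop_ardscan("bad_rates", "transition rates must be > 0")
  }
  n <- round(sampling_rate * duration)
  t <- (seq_len(n) - 1) / sampling_rate
  po_stat <- open_rate / (open_rate + close_rate)
  withr::with_seed(as.integer(seed), {
    occupancy <- integer(n)
    for (ch in seq_len(n_channels)) {
      state0 <- runif(1) < po_stat  # TRUE = open
      # alternating exponential dwells out to the trace end
      rate_mean <- 2 * open_rate * close_rate / (open_rate + close_rate)
      n_guess <- max(16L, ceiling(duration * rate_mean * 1.5) + 20L)
      repeat {
        k <- seq_len(n_guess)
        open_dwell <- (k %% 2L == 1L) == state0
        dwells <- rexp(n_guess, ifelse(open_dwell, close_rate, open_rate))
        if (sum(dwells) > duration) break
        n_guess <- n_guess * 2L
      }
      ends <- cumsum(dwells)
      seg <- findInterval(t, ends, left.open = TRUE) + 1L
      open_now <- if (state0) (seg %% 2L == 1L) else (seg %% 2L == 0L)
      occupancy <- occupancy + as.integer(open_now)
    }
    current <- unitary_current * occupancy + rnorm(n, 0, noise_sd) + drift * t
    list(
      trace = tibble(time_s = t, current_pA = current),
      occupancy = occupancy,
      po_true = mean(occupancy) / n_channels,
      po_stationary = po_stat
    )
  })
}

#' Simulate normalized Hill dose-response tables
#'
#' Draws normalized responses from the Hill curve
#' `Imax * [L]^n / (EC50^n + [L]^n)` at the given concentrations with
#' additive Gaussian noise, one table per replicate.
#'
#' @param Imax,EC50,n Hill parameters (EC50 in uM); all positive.
#' @param concentrations Concentrations in uM (default the capsaicin series
#'   0.03, 0.1, 0.3, 1, 5, 10).
#' @param noise_sd Additive Gaussian noise SD (normalized units).
#' @param replicates Number of replicate tables.
#' @param seed Integer seed.
#' @return A tibble with columns `replicate`, `conc_uM`, `norm_current`.
#' @export
simulate_dose_response <- function(Imax = 1, EC50 = 0.3, n = 2,
                                   concentrations = c(0.03, 0.1, 0.3, 1, 5, 10),
                                   noise_sd = 0.05, replicates = 1L, seed = 1L) {
  if (Imax <= 0 || EC50 <= 0 || n <= 0) {
    stop_ardscan("bad_parameters", "Hill parameters must be positive")
  }
  mu <- hill_curve(concentrations, Imax, EC50, n)
  withr::with_seed(as.integer(seed), {
    purrr::map(seq_len(replicates), function(r) {
      tibble(
        replicate = r,
        conc_uM = concentrations,
        norm_current = mu + rnorm(length(mu), 0, noise_sd)
      )
    }) %>% bind_rows()
  })
}

#' Simulate temperature-activation current tables
#'
#' Per cell, currents on a 10-60 degC heating ramp follow a two-state
#' van 't Hoff occupancy `1 / (1 + exp((dH/R) (1/T - 1/T_half)))` (T in
#' kelvin) times a cell-specific maximal current, plus a leak floor and
#' Gaussian noise — the shape of heat-activated channel currents at
#' +100 mV. Occupancy is exactly 0.5 at `T_half`.
#'
#' @param delta_H Activation enthalpy, kcal/mol (> 0; default 100, the steep
#'   temperature dependence characteristic of TRPV1).
#' @param T_half Half-activation temperature, degC (default 45).
#' @param leak Leak current as a fraction of the maximal current (default
#'   0.02).
#' @param n_cells Number of cells (default 10).
#' @param noise_sd Noise SD as a fraction of the maximal current.
#' @param temps Ramp temperatures, degC.
#' @param seed Integer seed.
#' @return A tibble with columns `cell_id`, `temp_C`, `current_pA` suitable
#'   for [temperature_relation()].
#' @export
simulate_temperature_currents <- function(delta_H = 100, T_half = 45, leak = 0.02,
                                          n_cells = 10L, noise_sd = 0.02,
                                          temps = seq(10, 60, by = 0.5), seed = 1L) {
  if (delta_H <= 0) stop_ardscan("bad_parameters", "`delta_H` must be > 0")
  R_gas <- 1.98720425e-3  # kcal / (mol K)
  occ <- 1 / (1 + exp((delta_H / R_gas) * (1 / (temps + 273.15) - 1 / (T_half + 273.15))))
  withr::with_seed(as.integer(seed), {
    purrr::map(seq_len(n_cells), function(cell) {
      imax <- stats::rlnorm(1, log(1000), 0.3)
      tibble(
        cell_id = sprintf("cell_%03d", cell),
        temp_C = temps,
        current_pA = imax * (occ + leak) + imax * noise_sd * rnorm(length(temps))
      )
    }) %>% bind_rows()
  })
}

#' Simulate a calcium-imaging cell field
#'
#' Generates per-cell fluorescence time series with capsaicin and ionomycin
#' step responses at the configured event times: responders step up at both
#' additions, ionomycin-only cells step up only at the ionophore, and
#' excluded cells stay flat; all traces carry multiplicative Gaussian noise.
#' Labels are drawn independently per cell with the given probabilities and
#' returned as ground truth.
#'
#' @param n_cells Number of cells.
#' @param f_responder,f_iono_only,f_excluded Label probabilities; must sum
#'   to 1.
#' @param amplitude Step response amplitude as dF/F0 (default 2).
#' @param noise_sd Multiplicative noise SD relative to baseline (default
#'   0.05).
#' @param baseline Baseline fluorescence, arbitrary units (default 100).
#' @param cap_time,iono_time,frame_interval,duration Acquisition timing in
#'   seconds (defaults 30, 120, 0.5, 180: capsaicin at 30 s, ionomycin at
#'   the 2 min mark of a 3 min movie sampled every 0.5 s).
#' @param seed Integer seed.
#' @return A list: `traces` (wide tibble `frame_time_s`, one column per
#'   cell) and `labels` (tibble `cell_id`, `true_label`).
#' @export
simulate_cell_field <- function(n_cells = 100L, f_responder = 0.6,
                                f_iono_only = 0.3, f_excluded = 0.1,
                                amplitude = 2, noise_sd = 0.05, baseline = 100,
                                cap_time = 30, iono_time = 120,
                                frame_interval = 0.5, duration = 180, seed = 1L) {
  fractions <- c(f_responder, f_iono_only, f_excluded)
  if (abs(sum(fractions) - 1) > 1e-8 || any(fractions < 0)) {
    stop_ardscan("bad_fractions", "label fractions must be non-negative and sum to 1")
  }
  t <- seq(0, duration, by = frame_interval)
  withr::with_seed(as.integer(seed), {
    labs <- sample(c("capsaicin_responder", "ionomycin_only", "excluded"),
                   n_cells, replace = TRUE, prob = fractions)
    ids <- sprintf("cell_%03d", seq_len(n_cells))
    traces <- purrr::map2(labs, ids, function(lab, id) {
      f <- rep(baseline, length(t))
      if (lab == "capsaicin_responder") {
        f[t > cap_time] <- baseline * (1 + amplitude)
        f[t > iono_time] <- baseline * (1 + amplitude * 1.5)
      } else if (lab == "ionomycin_only") {
        f[t > iono_time] <- baseline * (1 + amplitude * 1.5)
      }
      f * (1 + rnorm(length(t), 0, noise_sd))
    })
    wide <- tibble(frame_time_s = t)
    for (j in seq_along(ids)) wide[[ids[j]]] <- traces[[j]]
    list(
      traces = wide,
      labels = tibble(cell_id = ids, true_label = labs)
    )
  })
}
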