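#' The Hill dose-response curve
#'
#' Forward model `I = Imax * [L]^n / (EC50^n + [L]^n)`; by construction the
#' curve passes through `Imax / 2` at `[L] = EC50`.
#'
#' @param conc Ligand concentration(s), uM.
#' @param Imax Maximal response (normalized units).
#' @param EC50 Half-maximal concentration, uM.
#' @param n Hill coefficient.
#' @return Numeric vector of responses.
#' @export
hill_curve <- function(conc, Imax, EC50, n) {
  Imax * conc^n / (EC50^n + conc^n)
}

#' Normalize dose-response currents to a reference concentration
#'
#' Divides every current by the current measured at the reference
#' concentration (the maximal response at 5 uM capsaicin in TRPV1
#' recordings), so the reference point maps to 1 by construction. If several
#' rows share the reference concentration their mean current is used.
#'
#' @param points Tibble with columns `conc_uM` and `current_pA`.
#' @param reference_conc Reference concentration in uM (default 5).
#' @return The input with an added `norm_current` column.
#' @export
normalize_dose_response <- function(points, reference_conc = 5) {
  assert_columns(points, c("conc_uM", "current_pA"), "`points`")
  at_ref <- abs(points$conc_uM - reference_conc) < 1e-9
  if (!any(at_ref)) {
    stop_ardscan("missing_reference",
                 sprintf("no point at the reference concentration %g uM", reference_conc))
  }
  ref <- mean(points$current_pA[at_ref])
  if (ref == 0) {
    stop_ardscan("zero_reference", "reference current is zero; cannot normalize")
  }
  points %>% mutate(norm_current = .data$current_pA / ref)
}

#' Fit the Hill equation to a normalized dose-response
#'
#' Least-squares fit of `I = Imax * [L]^n / (EC50^n + [L]^n)` with `Imax`,
#' `EC50` and `n` all free, under bounds `EC50 in (0, 100]` uM and
#' `n in (0, 10]`. The Levenberg-Marquardt optimizer is started from a grid
#' of `EC50 in {0.03, 0.3, 3}` uM crossed with `n in {1, 2, 4}` (with
#' `Imax` started at the largest response) and the lowest-residual fit is
#' kept; non-convergence is flagged on the returned object, never raised.
#'
#' @param points Tibble of normalized dose-response points; by default
#'   columns `conc_uM` and `norm_current` (see [normalize_dose_response()]).
#' @param conc,response Column names of concentration and response.
#' @return An object of class `hill_fit` with elements `Imax`, `EC50`, `n`,
#'   `rss`, `converged`, `n_points` and `data`. Supports `coef()`,
#'   `predict()`, [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' pts <- tibble::tibble(
#'   conc_uM = c(0.03, 0.1, 0.3, 1, 5, 10),
#'   norm_current = hill_curve(c(0.03, 0.1, 0.3, 1, 5, 10), 1, 0.3, 2)
#' )
#' hill_fit(pts)
hill_fit <- function(points, conc = "conc_uM", response = "norm_current") {
  assert_columns(points, c(conc, response), "`points`")
  x <- points[[conc]]
  y <- points[[response]]
  keep <- is.finite(x) & is.finite(y) & x > 0
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 3) {
    stop_ardscan("too_few_concentrations",
                 "need at least 3 distinct concentrations to fit the Hill equation")
  }

  df <- data.frame(x = x, y = y)
  lower <- c(Imax = 1e-9, EC50 = 1e-9, n = 1e-3)
  upper <- c(Imax = Inf, EC50 = 100, n = 10)
  starts <- expand.grid(EC50 = c(0.03, 0.3, 3), n = c(1, 2, 4))
  imax0 <- max(y)

  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ Imax * x^n / (EC50^n + x^n),
        data = df,
        start = list(Imax = max(imax0, 1e-6), EC50 = starts$EC50[s], n = starts$n[s]),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    out <- list(Imax = NA_real_, EC50 = NA_real_, n = NA_real_,
                rss = NA_real_, converged = FALSE, n_points = length(x),
                data = tibble(conc_uM = x, norm_current = y))
    class(out) <- "hill_fit"
    return(out)
  }
  cf <- stats::coef(best$fit)
  conv <- isTRUE(best$fit$convInfo$isConv)
  out <- list(
    Imax = unname(cf[["Imax"]]), EC50 = unname(cf[["EC50"]]), n = unname(cf[["n"]]),
    rss = best$rss, converged = conv, n_points = length(x),
    data = tibble(conc_uM = x, norm_current = y)
  )
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("<hill_fit>\n")
  cat(sprintf("  Imax = %.4g, EC50 = %.4g uM, n = %.4g\n", x$Imax, x$EC50, x$n))
  cat(sprintf("  RSS = %.3g over %d points; converged: %s\n",
              x$rss, x$n_points, x$converged))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(Imax = object$Imax, EC50 = object$EC50, n = object$n)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc_uM else newdata$conc_uM
  hill_curve(conc, object$Imax, object$EC50, object$n)
}

#' @rdname hill_fit
#' @param x A `hill_fit` object.
#' @param ... Unused.
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble(
    term = c("Imax", "EC50", "n"),
    estimate = c(x$Imax, x$EC50, x$n)
  )
}

#' @rdname hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(
    Imax = x$Imax, EC50 = x$EC50, n = x$n,
    rss = x$rss, n_points = x$n_points, converged = x$converged
  )
}

#' Approximate open probability from macroscopic currents
#'
#' Normalizes the steady current under a condition by the maximal reference
#' response (5 uM capsaicin in the TRPV1 experiments), which approximates
#' open probability under the assumption that the reference drives Po near
#' 1. Ratios above 1 are reported as-is with `over_unity = TRUE`.
#'
#' @param i_condition Current(s) under the condition of interest, pA.
#' @param i_max_reference Maximal reference current, pA (> 0).
#' @return A tibble with columns `po` and `over_unity`.
#' @export
macro_open_probability <- function(i_condition, i_max_reference) {
  if (length(i_max_reference) != 1 || !is.finite(i_max_reference) || i_max_reference <= 0) {
    stop_ardscan("bad_reference", "`i_max_reference` must be a single positive value")
  }
  po <- i_condition / i_max_reference
  tibble(po = po, over_unity = po > 1)
}
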