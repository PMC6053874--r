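#' A single pKa estimate
#'
#' @param pka Estimated pKa (pH units).
#' @param method One of `"isosbestic_intersection"`, `"derivative_isosbestic"`,
#'   `"zero_crossing"`, `"baseline_to_peak"`, `"seok"`.
#' @param wavelengths_nm Wavelengths used by the method.
#' @param derivative_order 0 (raw spectra), 1 or 2.
#' @param diagnostics Named list of method diagnostics (fit residuals,
#'   crossing gaps, ambiguity notes).
#' @return Object of class `pka_estimate`.
#' @export
pka_estimate <- function(pka, method, wavelengths_nm = numeric(),
                         derivative_order = 0L, diagnostics = list()) {
  methods <- c("isosbestic_intersection", "derivative_isosbestic",
               "zero_crossing", "baseline_to_peak", "seok")
  if (!is.finite(pka)) stop("pka must be finite")
  if (!method %in% methods)
    stop("unknown method: ", method)
  if (!derivative_order %in% 0:2) stop("derivative_order must be 0, 1 or 2")
  structure(list(pka = pka, method = method,
                 wavelengths_nm = as.numeric(wavelengths_nm),
                 derivative_order = as.integer(derivative_order),
                 diagnostics = diagnostics),
            class = "pka_estimate")
}

#' @export
print.pka_estimate <- function(x, ...) {
  wl <- if (length(x$wavelengths_nm))
    paste0(" @ ", paste(format(x$wavelengths_nm), collapse = ", "), " nm")
  else ""
  cat(sprintf("pKa = %.2f  (%s%s%s)\n", round(x$pka, 2), x$method,
              if (x$derivative_order > 0)
                paste0(", derivative order ", x$derivative_order) else "",
              wl))
  invisible(x)
}

#' Savitzky-Golay derivative of a titration series
#'
#' Differentiates every pH column with respect to wavelength using a
#' Savitzky-Golay polynomial filter; the standard preprocessing when raw
#' spectra show no usable isosbestic point.  Defaults (window 7, cubic) suit
#' broad UV bands sampled at 1 nm.
#'
#' @param series A [titration_series()].
#' @param order Derivative order, 1 or 2.
#' @param window Odd filter length (> polyorder).
#' @param polyorder Fitting polynomial degree (>= order).
#' @return A [titration_series()] holding dA/d(lambda) (AU/nm) or the second
#'   derivative (AU/nm^2); grids unchanged.
#' @export
derivative_spectra <- function(series, order = 1L, window = 7L,
                               polyorder = 3L) {
  stopifnot(inherits(series, "titration_series"))
  if (!order %in% 1:2) stop("order must be 1 or 2")
  if (window %% 2L != 1L) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (order > polyorder) stop("order must not exceed polyorder")
  if (window > length(series$wavelengths_nm))
    stop("window larger than the wavelength grid")
  step <- mean(diff(series$wavelengths_nm))
  d <- apply(series$absorbance, 2L, signal::sgolayfilt,
             p = polyorder, n = window, m = order, ts = step)
  titration_series(series$wavelengths_nm, series$ph_values, d)
}

# Photometric noise estimate: median absolute first difference along pH in
# the long-wavelength tail, where catechol chromophores no longer absorb.
estimate_noise_sd <- function(series) {
  wl <- series$wavelengths_nm
  tail_rows <- which(wl >= stats::quantile(wl, 0.9))
  d <- apply(series$absorbance[tail_rows, , drop = FALSE], 1L,
             function(x) stats::mad(diff(x)) / sqrt(2))
  stats::median(d)
}

#' Locate isosbestic points
#'
#' An isosbestic point is a wavelength at which all spectra of a two-species
#' equilibrium intersect, so the across-pH standard deviation of the
#' absorbance dips to the noise floor there.  Candidates are local minima of
#' that spread below a threshold (default five times the estimated
#' photometric noise).
#'
#' In a multi-step system analysed window by window, a residual tail of the
#' neighbouring dissociation leaks a little pH dependence into the window,
#' so the spread at a genuine isosbestic point does not reach zero even
#' without noise.  A candidate therefore qualifies if its spread is below
#' the noise threshold *or* below a small fraction of the window's maximum
#' spread, and the dip must be flanked by genuine signal (wavelengths
#' nearby whose spread is a substantial part of the maximum) so that flat
#' baseline regions do not qualify.
#'
#' @param series A [titration_series()] (raw or derivative).
#' @param ph_window Optional `c(lo, hi)` pH interval (needs >= 3 columns).
#' @param threshold Spread threshold in AU; `NULL` for the automatic
#'   noise-based default.
#' @param rel_frac Relative threshold: fraction of the maximum spread a
#'   candidate dip must stay below (default 0.02).
#' @return data.frame with columns `wavelength_nm` and `spread`, sorted by
#'   spread ascending; empty when no wavelength qualifies (the caller should
#'   fall through to the next estimation method).  Attribute `degenerate` is
#'   `TRUE` when the series shows no pH dependence at all.
#' @export
find_isosbestic_points <- function(series, ph_window = NULL,
                                   threshold = NULL, rel_frac = 0.02) {
  stopifnot(inherits(series, "titration_series"))
  cols <- ph_columns(series, ph_window)
  if (length(cols) < 3L) stop("ph_window must contain at least 3 pH columns")
  a <- series$absorbance[, cols, drop = FALSE]
  spread <- apply(a, 1L, stats::sd)
  if (is.null(threshold))
    threshold <- max(5 * estimate_noise_sd(series), 1e-9)
  out <- data.frame(wavelength_nm = numeric(), spread = numeric())
  smax <- max(spread)
  degenerate <- smax <= threshold
  if (!degenerate) {
    n <- length(spread)
    wl <- series$wavelengths_nm
    cut <- max(threshold, rel_frac * smax)
    is_min <- spread <= c(spread[-1L], Inf) & spread <= c(Inf, spread[-n])
    # a genuine isosbestic point is a sign change of the base-minus-acid
    # difference spectrum; a crossing falling between grid points leaves a
    # local spread minimum above the cut, so a sign change in the immediate
    # neighbourhood also qualifies a dip
    delta <- a[, ncol(a)] - a[, 1L]
    flips <- sign(delta[pmax(1L, seq_len(n) - 1L)]) *
      sign(delta[pmin(n, seq_len(n) + 1L)]) <= 0
    keep <- which(is_min & (spread < cut | (flips & spread < 0.1 * smax)))
    # the dip must sit inside real signal, not in a flat baseline region
    keep <- keep[vapply(keep, function(i) {
      nb <- abs(wl - wl[i]) <= 20
      max(spread[nb]) >= 0.2 * smax
    }, TRUE)]
    if (length(keep)) {
      out <- data.frame(wavelength_nm = wl[keep], spread = spread[keep])
      out <- out[order(out$spread), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  attr(out, "degenerate") <- degenerate
  attr(out, "threshold") <- threshold
  out
}

# indices of pH columns inside a c(lo, hi) window (NULL = all)
ph_columns <- function(series, ph_window = NULL) {
  if (is.null(ph_window)) return(seq_along(series$ph_values))
  which(series$ph_values >= ph_window[1L] & series$ph_values <= ph_window[2L])
}

#' pKa from the intersection of two absorbance-versus-pH traces
#'
#' With two wavelengths flanking an isosbestic point, one trace rises and the
#' other falls across the dissociation; their crossing marks the pH where the
#' acid and base forms contribute equally, i.e. the pKa.  The crossing is
#' located by linear interpolation between the bracketing pH grid points.
#'
#' @param series A [titration_series()] (raw or derivative).
#' @param lambda_low,lambda_high Two distinct wavelengths on the grid (nm).
#' @param ph_window Optional `c(lo, hi)` restricting the search to one
#'   dissociation transition; with several crossings the one inside this
#'   window is returned and the ambiguity is recorded in the diagnostics.
#' @return A [pka_estimate()] with method `"isosbestic_intersection"`.
#' @export
intersection_pka <- function(series, lambda_low, lambda_high,
                             ph_window = NULL) {
  stopifnot(inherits(series, "titration_series"))
  i1 <- match(lambda_low, series$wavelengths_nm)
  i2 <- match(lambda_high, series$wavelengths_nm)
  if (is.na(i1) || is.na(i2)) stop("both wavelengths must be on the grid")
  if (i1 == i2) stop("the two wavelengths must differ (identical traces never cross)")
  d <- series$absorbance[i1, ] - series$absorbance[i2, ]
  if (all(abs(d) < .Machine$double.eps * 10))
    stop("traces are identical; no crossing")
  sgn <- sign(d)
  cross <- which(sgn[-length(sgn)] * sgn[-1L] < 0 |
                   (sgn[-length(sgn)] != 0 & sgn[-1L] == 0))
  exact <- which(sgn == 0)
  ph <- series$ph_values
  cand <- c(
    vapply(cross, function(j)
      ph[j] + (ph[j + 1L] - ph[j]) * d[j] / (d[j] - d[j + 1L]), 0),
    ph[exact]
  )
  cand <- sort(unique(cand))
  if (!length(cand)) stop("no crossing of the two traces in the pH range")
  ambiguous <- length(cand) > 1L
  pick <- cand
  if (!is.null(ph_window))
    pick <- cand[cand >= ph_window[1L] & cand <= ph_window[2L]]
  if (!length(pick)) stop("no crossing inside the transition window")
  if (length(pick) > 1L) {
    # several crossings even inside the window: take the one nearest the
    # steepest pH-change of the trace difference
    mid <- ph[which.max(abs(diff(d)))] + 0.5 * mean(diff(ph))
    pick <- pick[which.min(abs(pick - mid))]
  }
  pka_estimate(pick, "isosbestic_intersection",
               wavelengths_nm = c(lambda_low, lambda_high),
               diagnostics = list(n_crossings = length(cand),
                                  ambiguous = ambiguous,
                                  crossings = cand))
}

#' pKa by the zero-crossing method on derivative spectra
#'
#' Searches the derivative series for a wavelength where the acid-side
#' spectrum is (numerically) zero while the base-side signal is large, and a
#' second wavelength with the roles swapped; each trace then reports a single
#' species selectively and their intersection gives the pKa.
#'
#' @param series_derivative A derivative [titration_series()] from
#'   [derivative_spectra()].
#' @param ph_acid,ph_base pH of the acid-side and base-side reference
#'   columns (must exist on the grid, nearest column is used).
#' @param ph_window Optional transition window passed to the intersection.
#' @param zero_tol_frac A derivative counts as zero when its magnitude is
#'   below this fraction of the column's maximum amplitude (default 0.02).
#' @return A [pka_estimate()] with method `"zero_crossing"`.
#' @export
zero_crossing_pka <- function(series_derivative, ph_acid, ph_base,
                              ph_window = NULL, zero_tol_frac = 0.02) {
  stopifnot(inherits(series_derivative, "titration_series"))
  ph <- series_derivative$ph_values
  ja <- which.min(abs(ph - ph_acid))
  jb <- which.min(abs(ph - ph_base))
  ca <- series_derivative$absorbance[, ja]
  cb <- series_derivative$absorbance[, jb]
  amp_a <- max(abs(ca)); amp_b <- max(abs(cb))
  if (amp_a == 0 && amp_b == 0)
    stop("derivative series is identically zero in the reference columns")
  zero_a <- which(abs(ca) < zero_tol_frac * amp_a)
  zero_b <- which(abs(cb) < zero_tol_frac * amp_b)
  # drop wavelengths where both are zero (no selectivity there)
  sel1 <- setdiff(zero_a, zero_b)
  sel2 <- setdiff(zero_b, zero_a)
  if (!length(sel1) || !length(sel2))
    stop("no wavelength pair satisfies the zero-crossing condition")
  i1 <- sel1[which.max(abs(cb[sel1]))]   # acid-derivative zero, base large
  i2 <- sel2[which.max(abs(ca[sel2]))]   # base-derivative zero, acid large
  # each selected trace follows a single species; derivative signs are
  # arbitrary, so the crossing is located on the trace magnitudes
  abs_series <- titration_series(series_derivative$wavelengths_nm,
                                 series_derivative$ph_values,
                                 abs(series_derivative$absorbance))
  est <- intersection_pka(abs_series,
                          series_derivative$wavelengths_nm[min(i1, i2)],
                          series_derivative$wavelengths_nm[max(i1, i2)],
                          ph_window = ph_window)
  pka_estimate(est$pka, "zero_crossing", est$wavelengths_nm,
               derivative_order = 1L,
               diagnostics = c(est$diagnostics,
                               list(ph_acid = ph[ja], ph_base = ph[jb])))
}

#' pKa by the baseline-to-peak log-ratio fit
#'
#' At a wavelength where absorbance grows with pH across one dissociation,
#' M(pH) = A(pH) - A_acid and N(pH) = A_base - A(pH) are proportional to the
#' base and acid amounts, so log10(M/N) is linear in pH with unit slope and
#' crosses zero at the pKa.  The line is fit by ordinary least squares over
#' the points where both M and N are resolvable; the pKa is the fitted zero
#' (-intercept/slope) and the slope is kept as a diagnostic rather than
#' constrained to one.
#'
#' @param series A [titration_series()].
#' @param wavelength Analysis wavelength (nm, on the grid).
#' @param ph_fit_range Optional `c(lo, hi)` pH interval containing the single
#'   transition; its end columns supply the acid/base limiting absorbances.
#' @param floor_frac Points with M or N below this fraction of the total
#'   amplitude are excluded from the fit (default 0.02).
#' @return A [pka_estimate()] with method `"baseline_to_peak"`; diagnostics
#'   hold the fitted slope, residual standard deviation and the number of
#'   points used.
#' @export
baseline_to_peak_pka <- function(series, wavelength, ph_fit_range = NULL,
                                 floor_frac = 0.02) {
  stopifnot(inherits(series, "titration_series"))
  i <- match(wavelength, series$wavelengths_nm)
  if (is.na(i)) stop("wavelength must be on the grid")
  cols <- ph_columns(series, ph_fit_range)
  if (length(cols) < 3L) stop("need at least 3 pH points in the fit range")
  tr <- series$absorbance[i, cols]
  ph <- series$ph_values[cols]
  a_acid <- tr[1L]
  a_base <- tr[length(tr)]
  amp <- a_base - a_acid
  if (abs(amp) < .Machine$double.eps * 100)
    stop("no transition amplitude at this wavelength")
  non_monotone <- abs(amp) < 0.5 * (max(tr) - min(tr))
  m <- tr - a_acid
  n <- a_base - tr
  floor <- floor_frac * abs(amp)
  use <- which(m * sign(amp) > floor & n * sign(amp) > floor)
  if (length(use) < 3L)
    stop("fewer than 3 usable points between the acid and base limits")
  y <- log10((m / n)[use])
  fit <- stats::lm.fit(cbind(1, ph[use]), y)
  b <- fit$coefficients
  if (!is.finite(b[2L]) || b[2L] == 0) stop("degenerate log-ratio fit")
  diag <- list(slope = unname(b[2L]),
               residual_sd = stats::sd(fit$residuals),
               n_points = length(use))
  if (non_monotone) diag$warning <- "trace not monotone across the fit range"
  pka_estimate(unname(-b[1L] / b[2L]), "baseline_to_peak",
               wavelengths_nm = wavelength, diagnostics = diag)
}

#' Three-point inputs for the Seok closed form
#'
#' @param ph Three increasing pH values on one dissociation transition.
#' @param A The absorbances at those pH at one wavelength (AU).
#' @return Object of class `seok_inputs` with fields `ph1..ph3`, the pH
#'   offsets `a = ph2 - ph1` and `b = ph3 - ph1`, and `A1..A3`.
#' @export
seok_inputs <- function(ph, A) {
  ph <- as.numeric(ph); A <- as.numeric(A)
  if (length(ph) != 3L || length(A) != 3L) stop("need exactly three (pH, A) points")
  if (any(diff(ph) <= 0)) stop("pH values must be strictly increasing")
  structure(list(ph1 = ph[1L], ph2 = ph[2L], ph3 = ph[3L],
                 a = ph[2L] - ph[1L], b = ph[3L] - ph[1L],
                 A1 = A[1L], A2 = A[2L], A3 = A[3L]),
            class = "seok_inputs")
}

#' pKa from three (pH, absorbance) points: the Seok closed form
#'
#' For a single dissociation the trace at one wavelength follows
#' A(pH) = (A_acid + A_base * r) / (1 + r) with r = 10^(pH - pKa).  Writing
#' this at three pH values and eliminating the two unknown limiting
#' absorbances leaves one equation in the pKa with the closed-form solution
#' pKa = pH1 - log10(N / D),
#' N = (10^b - 10^a) A1 + (1 - 10^b) A2 + (10^a - 1) A3,
#' D = (10^a - 10^b) A1 + (10^(a+b) - 10^a) A2 + (10^b - 10^(a+b)) A3,
#' where a = pH2 - pH1 and b = pH3 - pH1.  Exact (not a fit) when the three
#' points lie on one transition.
#'
#' @param inputs A [seok_inputs()].
#' @param wavelength Optional wavelength the points were read at (nm).
#' @return A [pka_estimate()] with method `"seok"`.
#' @export
seok_pka <- function(inputs, wavelength = numeric()) {
  stopifnot(inherits(inputs, "seok_inputs"))
  A1 <- inputs$A1; A2 <- inputs$A2; A3 <- inputs$A3
  if (isTRUE(all.equal(c(A1, A2), c(A2, A3), tolerance = 1e-12)))
    stop("A1 = A2 = A3: no transition in the three points")
  al <- 10^inputs$a
  be <- 10^inputs$b
  num <- (be - al) * A1 + (1 - be) * A2 + (al - 1) * A3
  den <- (al - be) * A1 + (al * be - al) * A2 + (be - al * be) * A3
  scale <- max(abs(c(A1, A2, A3))) * max(al, be)
  if (abs(den) < 1e-12 * scale) stop("ill-conditioned: denominator vanishes")
  ratio <- num / den
  if (ratio <= 0)
    stop("points are inconsistent with a single dissociation (negative 10^x)")
  pka_estimate(inputs$ph1 - log10(ratio), "seok",
               wavelengths_nm = wavelength,
               diagnostics = list(a = inputs$a, b = inputs$b))
}
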