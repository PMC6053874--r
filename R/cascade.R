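#' Configuration for the estimation cascade
#'
#' @param sg_window,sg_polyorder Savitzky-Golay filter length and polynomial
#'   degree for derivative preprocessing.
#' @param isosbestic_threshold Spread threshold in AU for
#'   [find_isosbestic_points()]; `NULL` = automatic (5 x estimated noise).
#' @param zero_tol_frac Zero tolerance for [zero_crossing_pka()], as a
#'   fraction of the column's maximum derivative amplitude.
#' @param floor_frac Exclusion floor for [baseline_to_peak_pka()].
#' @param seok_quantiles pH-column quantiles of the transition window used as
#'   the three Seok points.
#' @param min_separation Minimum pH separation imposed between detected
#'   transition centres.
#' @return List of class `pka_config`.
#' @export
pka_config <- function(sg_window = 7L, sg_polyorder = 3L,
                       isosbestic_threshold = NULL, zero_tol_frac = 0.02,
                       floor_frac = 0.02,
                       seok_quantiles = c(0.25, 0.5, 0.75),
                       min_separation = 1) {
  structure(list(sg_window = sg_window, sg_polyorder = sg_polyorder,
                 isosbestic_threshold = isosbestic_threshold,
                 zero_tol_frac = zero_tol_frac, floor_frac = floor_frac,
                 seok_quantiles = seok_quantiles,
                 min_separation = min_separation),
            class = "pka_config")
}

#' Locate dissociation-transition windows on the pH axis
#'
#' The aggregate spectral change between adjacent pH columns (summed absolute
#' absorbance difference per pH unit) peaks at each pKa.  The `n` strongest
#' well-separated peaks are taken as transition centres; window boundaries
#' are the midpoints between consecutive centres, extended to the grid ends.
#'
#' @param series A [titration_series()].
#' @param n Number of dissociation steps expected (1-4).
#' @param min_separation Minimum pH distance between accepted centres.
#' @return List of `c(lo, hi)` pH windows, ordered by centre pH; attribute
#'   `centers` carries the detected centres.
#' @export
transition_windows <- function(series, n, min_separation = 1) {
  stopifnot(inherits(series, "titration_series"))
  if (!n %in% 1:4) stop("n must be between 1 and 4")
  ph <- series$ph_values
  a <- series$absorbance
  rate <- colSums(abs(a[, -1L, drop = FALSE] - a[, -ncol(a), drop = FALSE])) /
    diff(ph)
  mid <- (ph[-1L] + ph[-length(ph)]) / 2
  ord <- order(rate, decreasing = TRUE)
  centers <- numeric(0)
  for (j in ord) {
    if (all(abs(mid[j] - centers) >= min_separation)) {
      centers <- c(centers, mid[j])
      if (length(centers) == n) break
    }
  }
  if (length(centers) < n)
    stop(sprintf("found only %d of %d transitions", length(centers), n))
  centers <- sort(centers)
  bounds <- c(ph[1L], (centers[-1L] + centers[-n]) / 2, ph[length(ph)])
  wins <- lapply(seq_len(n), function(i) c(bounds[i], bounds[i + 1L]))
  attr(wins, "centers") <- centers
  wins
}

# Choose two wavelengths flanking an isosbestic point such that one trace
# rises and the other falls across the window, with matched acid+base
# absorbance sums (the condition for the traces to cross at the pKa).
choose_flanking <- function(series, lambda_iso, ph_window) {
  cols <- ph_columns(series, ph_window)
  lo <- cols[1L]; hi <- cols[length(cols)]
  a <- series$absorbance[, lo]
  b <- series$absorbance[, hi]
  delta <- b - a
  i0 <- which.min(abs(series$wavelengths_nm - lambda_iso))
  left <- seq_len(i0 - 1L)
  right <- seq.int(i0 + 1L, length(delta))
  if (!length(left) || i0 >= length(delta))
    stop("isosbestic point lies at the grid edge")
  pick_side <- function(idx) idx[abs(delta[idx]) >= 0.5 * max(abs(delta[idx]))]
  cl <- pick_side(left); cr <- pick_side(right)
  pairs <- expand.grid(l = cl, r = cr)
  # the traces cross only if one wavelength reads higher in acid and lower
  # in base than the other
  u <- a[pairs$l] - a[pairs$r]
  v <- b[pairs$l] - b[pairs$r]
  ok <- u * v < 0
  pairs <- pairs[ok, , drop = FALSE]
  if (!nrow(pairs))
    stop("no opposite-trend wavelength pair flanks the isosbestic point")
  score <- abs((a + b)[pairs$l] - (a + b)[pairs$r])
  best <- pairs[which.min(score), ]
  series$wavelengths_nm[c(best$l, best$r)]
}

# wavelength with the largest increasing amplitude across the window
pick_rising_wavelength <- function(series, ph_window) {
  cols <- ph_columns(series, ph_window)
  delta <- series$absorbance[, cols[length(cols)]] - series$absorbance[, cols[1L]]
  if (max(delta) <= 0) stop("no wavelength with rising absorbance in window")
  series$wavelengths_nm[which.max(delta)]
}

# Refine a crossing-based estimate against transition truncation.  The two
# traces cross exactly at the pKa only when the pure acid+base absorbance
# sums match at the two wavelengths; when the transition is cut off by the
# end of the pH grid the window-edge columns are still partly mixed and the
# naive choice is biased.  Given a provisional pKa, the pure species spectra
# are unmixed from the edge columns, the wavelength pair is re-chosen on
# them, and the crossing is corrected by the residual trace-amplitude ratio;
# a few fixed-point iterations converge to well under 0.01 pH units.
refine_crossing <- function(series, ph_window, pka0, n_iter = 4L) {
  cols <- ph_columns(series, ph_window)
  ph_lo <- series$ph_values[cols[1L]]
  ph_hi <- series$ph_values[cols[length(cols)]]
  a_lo <- series$absorbance[, cols[1L]]
  a_hi <- series$absorbance[, cols[length(cols)]]
  wl <- series$wavelengths_nm
  est <- NULL
  for (it in seq_len(n_iter)) {
    fl <- 1 / (1 + 10^(pka0 - ph_lo))
    fh <- 1 / (1 + 10^(pka0 - ph_hi))
    if (abs(fh - fl) < 0.5) break   # window barely spans the transition
    pure_a <- (fh * a_lo - fl * a_hi) / (fh - fl)
    pure_b <- ((1 - fl) * a_hi - (1 - fh) * a_lo) / (fh - fl)
    delta <- pure_b - pure_a
    pos <- which(delta >= 0.5 * max(delta, 0))
    neg <- which(-delta >= 0.5 * max(-delta, 0))
    if (!length(pos) || !length(neg) || max(delta) <= 0 || min(delta) >= 0)
      break
    pairs <- expand.grid(p = pos, q = neg)
    uu <- pure_a[pairs$p] - pure_a[pairs$q]
    vv <- pure_b[pairs$p] - pure_b[pairs$q]
    pairs <- pairs[uu * vv < 0, , drop = FALSE]
    if (!nrow(pairs)) break
    s <- pure_a + pure_b
    best <- pairs[which.min(abs(s[pairs$p] - s[pairs$q])), ]
    i1 <- min(best$p, best$q); i2 <- max(best$p, best$q)
    cross <- tryCatch(
      intersection_pka(series, wl[i1], wl[i2], ph_window = ph_window),
      error = function(e) NULL)
    if (is.null(cross)) break
    rho <- (pure_a[i1] - pure_a[i2]) / (pure_b[i2] - pure_b[i1])
    if (!is.finite(rho) || rho <= 0) break
    pka_new <- cross$pka - log10(rho)
    cross$pka <- pka_new
    cross$diagnostics$refined <- TRUE
    cross$diagnostics$iterations <- it
    est <- cross
    if (abs(pka_new - pka0) < 1e-4) { pka0 <- pka_new; break }
    pka0 <- pka_new
  }
  est
}

# One isosbestic + intersection attempt on a (possibly derivative) series.
iso_intersect_attempt <- function(series, ph_window, config, order) {
  cand <- find_isosbestic_points(series, ph_window,
                                 threshold = config$isosbestic_threshold)
  if (isTRUE(attr(cand, "degenerate")))
    stop("series shows no pH dependence (degenerate)")
  if (!nrow(cand)) stop("no isosbestic point below the spread threshold")
  err <- NULL
  for (k in seq_len(min(nrow(cand), 3L))) {
    est <- tryCatch({
      wl <- choose_flanking(series, cand$wavelength_nm[k], ph_window)
      intersection_pka(series, wl[1L], wl[2L], ph_window = ph_window)
    }, error = function(e) e)
    if (!inherits(est, "error")) {
      refined <- refine_crossing(series, ph_window, est$pka)
      if (!is.null(refined)) est <- refined
      est$derivative_order <- as.integer(order)
      if (order > 0) est$method <- "derivative_isosbestic"
      est$diagnostics$isosbestic_nm <- cand$wavelength_nm[k]
      est$diagnostics$isosbestic_spread <- cand$spread[k]
      return(est)
    }
    err <- est
  }
  stop("isosbestic candidates found but no usable intersection: ",
       conditionMessage(err))
}

#' Fit dissociation constants to a titration series
#'
#' The estimator for UV-Vis pH-titration data.  For each expected
#' dissociation it tries, in order: isosbestic-point intersection on the raw
#' spectra; the same on first- then second-derivative spectra; the
#' zero-crossing method on first-derivative spectra; the baseline-to-peak
#' log-ratio fit; and finally the three-point Seok closed form.  The first
#' method that succeeds supplies the estimate; every skipped method is
#' recorded with the reason.
#'
#' @param series A [titration_series()].
#' @param n_dissociations Number of dissociation steps to resolve (1-4).
#' @param config A [pka_config()].
#' @return An object of class `pka_fit`: list with `estimates` (one
#'   [pka_estimate()] per dissociation, ascending pH), `windows`, `skipped`
#'   (per-dissociation list of method/reason pairs), `config` and `series`.
#' @seealso [coef.pka_fit()], [summary.pka_fit()], [predict.pka_fit()],
#'   [plot.pka_fit()]
#' @export
pka_fit <- function(series, n_dissociations = 2L, config = pka_config()) {
  stopifnot(inherits(series, "titration_series"),
            inherits(config, "pka_config"))
  wins <- tryCatch(
    transition_windows(series, n_dissociations, config$min_separation),
    error = function(e) e)
  if (inherits(wins, "error"))
    stop_unresolved(list(list(step = NA_integer_, method = "windowing",
                              reason = conditionMessage(wins))))
  d1 <- tryCatch(derivative_spectra(series, 1L, config$sg_window,
                                    config$sg_polyorder),
                 error = function(e) NULL)
  d2 <- tryCatch(derivative_spectra(series, 2L, config$sg_window,
                                    config$sg_polyorder),
                 error = function(e) NULL)
  estimates <- vector("list", n_dissociations)
  skipped <- vector("list", n_dissociations)
  for (i in seq_len(n_dissociations)) {
    w <- wins[[i]]
    skip <- list()
    try_method <- function(label, expr) {
      res <- tryCatch(expr, error = function(e) e)
      if (inherits(res, "error")) {
        skip[[length(skip) + 1L]] <<- list(method = label,
                                           reason = conditionMessage(res))
        NULL
      } else res
    }
    est <- try_method("isosbestic_intersection",
                      iso_intersect_attempt(series, w, config, 0L))
    if (is.null(est))
      est <- try_method("derivative_isosbestic(1)", {
        if (is.null(d1)) stop("first-derivative spectra unavailable")
        iso_intersect_attempt(d1, w, config, 1L)
      })
    if (is.null(est))
      est <- try_method("derivative_isosbestic(2)", {
        if (is.null(d2)) stop("second-derivative spectra unavailable")
        iso_intersect_attempt(d2, w, config, 2L)
      })
    if (is.null(est))
      est <- try_method("zero_crossing", {
        if (is.null(d1)) stop("first-derivative spectra unavailable")
        zero_crossing_pka(d1, w[1L], w[2L], ph_window = w,
                          zero_tol_frac = config$zero_tol_frac)
      })
    if (is.null(est))
      est <- try_method("baseline_to_peak", {
        wl <- pick_rising_wavelength(series, w)
        baseline_to_peak_pka(series, wl, ph_fit_range = w,
                             floor_frac = config$floor_frac)
      })
    if (is.null(est))
      est <- try_method("seok", {
        wl <- pick_rising_wavelength(series, w)
        i_wl <- match(wl, series$wavelengths_nm)
        cols <- ph_columns(series, w)
        q <- cols[pmax(1L, round(config$seok_quantiles * (length(cols) - 1L)) + 1L)]
        q <- unique(q)
        if (length(q) < 3L) stop("window too narrow for three Seok points")
        seok_pka(seok_inputs(series$ph_values[q], series$absorbance[i_wl, q]),
                 wavelength = wl)
      })
    skipped[[i]] <- skip
    if (is.null(est)) {
      stop_unresolved(c(list(list(step = i, method = "all", reason =
        "every estimation method failed for this transition")), skip))
    }
    estimates[[i]] <- est
  }
  structure(list(estimates = estimates, windows = wins, skipped = skipped,
                 config = config, series = series,
                 n_dissociations = as.integer(n_dissociations)),
            class = "pka_fit")
}

stop_unresolved <- function(details) {
  msg <- paste0(
    "unresolved dissociation: ",
    paste(vapply(details, function(d)
      sprintf("[%s] %s", d$method, d$reason), ""), collapse = "; "))
  stop(structure(class = c("dhbpka_unresolved", "error", "condition"),
                 list(message = msg, call = sys.call(-1), details = details)))
}

#' @export
print.pka_fit <- function(x, ...) {
  cat(sprintf("Spectrophotometric pKa fit: %d dissociation step%s\n",
              x$n_dissociations, if (x$n_dissociations > 1L) "s" else ""))
  for (i in seq_len(x$n_dissociations)) {
    e <- x$estimates[[i]]
    cat(sprintf("  pKa%d = %5.2f  via %s%s\n", i, round(e$pka, 2), e$method,
                if (length(e$wavelengths_nm))
                  paste0(" (", paste(format(e$wavelengths_nm), collapse = ", "),
                         " nm)") else ""))
  }
  invisible(x)
}

#' Extract fitted pKa values
#' @param object A `pka_fit`.
#' @param ... Unused.
#' @return Named numeric vector `pKa1`, `pKa2`, ...
#' @export
coef.pka_fit <- function(object, ...) {
  p <- vapply(object$estimates, `[[`, 0, "pka")
  names(p) <- paste0("pKa", seq_along(p))
  p
}

#' Summarise a pKa fit, including the method audit trail
#' @param object A `pka_fit`.
#' @param ... Unused.
#' @return Object of class `summary.pka_fit`; printed as a per-dissociation
#'   table of estimates plus the skipped-method reasons.
#' @export
summary.pka_fit <- function(object, ...) {
  tab <- data.frame(
    dissociation = seq_len(object$n_dissociations),
    pka = round(vapply(object$estimates, `[[`, 0, "pka"), 2),
    method = vapply(object$estimates, `[[`, "", "method"),
    derivative_order = vapply(object$estimates, `[[`, 0L, "derivative_order"),
    wavelengths_nm = vapply(object$estimates, function(e)
      paste(format(e$wavelengths_nm), collapse = ", "), ""),
    window = vapply(object$windows, function(w)
      sprintf("%.2f-%.2f", w[1L], w[2L]), "")
  )
  structure(list(table = tab, skipped = object$skipped),
            class = "summary.pka_fit")
}

#' @export
print.summary.pka_fit <- function(x, ...) {
  print(x$table, row.names = FALSE)
  for (i in seq_along(x$skipped)) {
    for (s in x$skipped[[i]])
      cat(sprintf("  step %d skipped %s: %s\n", i, s$method, s$reason))
  }
  invisible(x)
}

#' Predicted species fractions from a fitted system
#'
#' @param object A `pka_fit`.
#' @param ph pH values at which to evaluate the speciation (default: the
#'   fitted series' grid).
#' @param ... Unused.
#' @return The `speciation_profile` implied by the fitted pKa values.
#' @export
predict.pka_fit <- function(object, ph = object$series$ph_values, ...) {
  species_fractions(acid_system(sort(coef(object))), ph)
}

#' Plot a fitted titration series
#'
#' Draws the absorbance-versus-pH traces at the analysis wavelengths of each
#' estimate and marks the fitted pKa values.
#'
#' @param x A `pka_fit`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.pka_fit <- function(x, ...) {
  wl <- unique(unlist(lapply(x$estimates, `[[`, "wavelengths_nm")))
  if (!length(wl)) wl <- x$series$wavelengths_nm[
    round(length(x$series$wavelengths_nm) / 2)]
  idx <- match(wl, x$series$wavelengths_nm)
  graphics::matplot(x$series$ph_values, t(x$series$absorbance[idx, ,
                    drop = FALSE]), type = "l", lty = 1,
                    xlab = "pH", ylab = "Absorbance (AU)", ...)
  graphics::abline(v = coef(x), lty = 3, col = "grey40")
  graphics::legend("topleft", legend = paste0(format(wl), " nm"),
                   lty = 1, col = seq_along(wl), bty = "n")
  invisible(x)
}
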