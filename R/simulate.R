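#' Gaussian-band absorption spectrum of one protonation state
#'
#' Real catechol chromophores show a small number of broad UV bands that
#' shift and grow as hydroxyls deprotonate; a sum of Gaussian bands in
#' wavelength is the standard idealisation.
#'
#' @param bands Matrix or data.frame with columns `center_nm`, `width_nm`
#'   (Gaussian sigma, > 0) and `peak_au` (band height in absorbance units,
#'   >= 0); one row per band.
#' @param label Species index (0 = fully protonated).
#' @return Object of class `species_spectrum`.
#' @export
species_spectrum <- function(bands, label = 0L) {
  bands <- as.data.frame(bands)
  need <- c("center_nm", "width_nm", "peak_au")
  if (!all(need %in% names(bands)))
    stop("bands needs columns center_nm, width_nm, peak_au")
  if (any(bands$width_nm <= 0)) stop("band widths must be positive")
  if (any(bands$peak_au < 0)) stop("band heights must be non-negative")
  structure(list(bands = bands, label = as.integer(label)),
            class = "species_spectrum")
}

#' Evaluate a species spectrum on a wavelength grid
#' @param spectrum A [species_spectrum()].
#' @param wavelengths_nm Numeric wavelength grid.
#' @return Numeric vector of absorbances (AU).
#' @export
eval_spectrum <- function(spectrum, wavelengths_nm) {
  stopifnot(inherits(spectrum, "species_spectrum"))
  b <- spectrum$bands
  a <- numeric(length(wavelengths_nm))
  for (k in seq_len(nrow(b)))
    a <- a + b$peak_au[k] *
      exp(-0.5 * ((wavelengths_nm - b$center_nm[k]) / b$width_nm[k])^2)
  a
}

#' Construct a titration series
#'
#' Container for an absorbance matrix over a wavelength grid (rows) and a pH
#' grid (columns), as produced by a diode-array spectrophotometer reading
#' one buffered solution per pH.
#'
#' @param wavelengths_nm Strictly increasing wavelength grid (nm).
#' @param ph_values Increasing pH grid.
#' @param absorbance Matrix, length(wavelengths_nm) x length(ph_values), AU.
#' @param blank Optional blank spectrum (one value per wavelength).
#' @return Object of class `titration_series`.
#' @export
titration_series <- function(wavelengths_nm, ph_values, absorbance,
                             blank = NULL) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  ph_values <- as.numeric(ph_values)
  absorbance <- as.matrix(absorbance)
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  if (length(ph_values) > 1L && any(diff(ph_values) <= 0))
    stop("pH values must be strictly increasing")
  if (!all(dim(absorbance) == c(length(wavelengths_nm), length(ph_values))))
    stop("absorbance must be n_wavelength x n_pH")
  if (any(!is.finite(absorbance))) stop("absorbance must be finite")
  if (!is.null(blank) && length(blank) != length(wavelengths_nm))
    stop("blank must have one value per wavelength")
  structure(list(wavelengths_nm = wavelengths_nm, ph_values = ph_values,
                 absorbance = absorbance, blank = blank),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "Titration series: %d wavelengths (%.0f-%.0f nm) x %d pH (%.2f-%.2f)\n",
    length(x$wavelengths_nm), min(x$wavelengths_nm), max(x$wavelengths_nm),
    length(x$ph_values), min(x$ph_values), max(x$ph_values)))
  invisible(x)
}

#' Default pH grid for a wide-range titration
#'
#' Britton-Robinson buffers cover pH 2 to 14, the span used for catechol
#' titrations so that both hydroxyl dissociations are bracketed.
#'
#' @param from,to,step Grid limits and spacing in pH units.
#' @return Numeric pH grid.
#' @export
default_ph_grid <- function(from = 2, to = 14, step = 0.25) {
  seq(from, to, by = step)
}

#' Default wavelength grid
#' @param from,to,step Grid limits and spacing in nm.
#' @return Numeric wavelength grid (nm), 190-500 nm by default, covering the
#'   analysis wavelengths (194-450 nm) reported for substituted catechols.
#' @export
default_wavelength_grid <- function(from = 190, to = 500, step = 1) {
  seq(from, to, by = step)
}

#' Simulate a UV-Vis pH titration
#'
#' Beer-Lambert mixing: at each pH the observed spectrum is the
#' speciation-weighted sum of the pure species spectra, plus optional i.i.d.
#' Gaussian instrument noise per (wavelength, pH) cell.  The default noise
#' level, 0.002 AU, is typical diode-array photometric noise.
#'
#' @param system An [acid_system()].
#' @param species_spectra List of [species_spectrum()], one per protonation
#'   state (n_protons + 1, ordered from fully protonated).
#' @param wavelengths Wavelength grid (nm); default [default_wavelength_grid()].
#' @param ph_values pH grid; default [default_ph_grid()].
#' @param noise_sd Gaussian noise standard deviation in AU (>= 0).
#' @param seed Integer seed; a fixed seed gives bit-identical output and the
#'   caller's RNG state is left untouched.
#' @return A [titration_series()].
#' @export
simulate_titration <- function(system, species_spectra,
                               wavelengths = default_wavelength_grid(),
                               ph_values = default_ph_grid(),
                               noise_sd = 0.002, seed = 1L) {
  stopifnot(inherits(system, "acid_system"))
  if (length(species_spectra) != system$n_protons + 1L)
    stop(sprintf("need %d species spectra (one per protonation state), got %d",
                 system$n_protons + 1L, length(species_spectra)))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  pure <- vapply(species_spectra, eval_spectrum, numeric(length(wavelengths)),
                 wavelengths_nm = wavelengths)     # n_wl x n_species
  frac <- species_fractions(system, ph_values)$fractions  # n_species x n_pH
  a <- pure %*% frac
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv()))
              rm(".Random.seed", envir = globalenv()))
    set.seed(as.integer(seed))
    a <- a + matrix(stats::rnorm(length(a), 0, noise_sd), nrow = nrow(a))
  }
  titration_series(wavelengths, ph_values, a)
}

#' Write / read a titration series as CSV
#'
#' Layout: first column `wavelength_nm`, remaining column headers are the pH
#' values formatted with two decimals.  `write` then `read` then `write`
#' reproduces the file byte for byte.
#'
#' @param series A [titration_series()].
#' @param path File path.
#' @return `write_titration_csv` returns `path` invisibly;
#'   `read_titration_csv` returns a [titration_series()].
#' @export
write_titration_csv <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  df <- data.frame(wavelength_nm = series$wavelengths_nm,
                   series$absorbance, check.names = FALSE)
  names(df)[-1L] <- sprintf("%.2f", series$ph_values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_titration_csv
#' @export
read_titration_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "wavelength_nm")
    stop("first column must be wavelength_nm")
  titration_series(df[[1L]], as.numeric(names(df)[-1L]),
                   as.matrix(df[, -1L, drop = FALSE]))
}

#' Reference pKa tables for the 24 studied catechols
#'
#' Returns the packaged reference data: spectrophotometric pKa values with
#' their standard deviations, computed site-resolved pKa values (hydroxyl
#' meta / para to the 4-substituent, and substituent protons), the Hammett
#' sigma-para constant of each 4-substituent, and the three-compound
#' solvation-model comparison (PCM / IPCM / CPCM first pKa).
#'
#' @return A list with data.frames `experimental`, `computed` and
#'   `solvation_models`.  `computed` carries two substituent-proton columns
#'   because Dopa dissociates twice in its side chain.
#' @export
dhb_compounds <- function() {
  p <- function(f) system.file("extdata", f, package = "dhbpka", mustWork = TRUE)
  list(
    experimental = utils::read.csv(p("dhb_experimental_pka.csv")),
    computed = utils::read.csv(p("dhb_computed_pka.csv")),
    solvation_models = utils::read.csv(p("dhb_solvation_models.csv"))
  )
}
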