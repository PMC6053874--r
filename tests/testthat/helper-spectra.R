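# Shared fixtures: band constructions and independent numeric oracles.

# Generic species spectra for an n-step system: each successive species gets
# red-shifted, slightly taller bands, the usual pattern when catecholate
# anions form.
generic_spectra <- function(n_species) {
  lapply(seq_len(n_species) - 1L, function(j)
    species_spectrum(data.frame(
      center_nm = c(215 + 12 * j, 275 + 15 * j),
      width_nm = c(9 + j, 11 + j),
      peak_au = c(1.1 - 0.05 * j, 0.75 + 0.1 * j)
    ), label = j))
}

# Catechol-like diprotic simulation used across tests.
catechol_series <- function(noise_sd = 0, seed = 1L) {
  simulate_titration(acid_system(c(8.83, 13.07), c("OH_m", "OH_p")),
                     generic_spectra(3L), noise_sd = noise_sd, seed = seed)
}

# Monoprotic pair of mirror-image Gaussian bands: equal amplitude sums at
# symmetric wavelengths, so crossing-based estimators are exact.
mirror_monoprotic <- function(pka = 9, center_acid = 250, center_base = 280,
                              width = 10, peak = 0.8,
                              ph_values = default_ph_grid(), noise_sd = 0,
                              seed = 1L) {
  simulate_titration(
    acid_system(pka),
    list(species_spectrum(data.frame(center_nm = center_acid,
                                     width_nm = width, peak_au = peak), 0L),
         species_spectrum(data.frame(center_nm = center_base,
                                     width_nm = width, peak_au = peak), 1L)),
    ph_values = ph_values, noise_sd = noise_sd, seed = seed)
}

# Ideal monoprotic trace at one wavelength (two-state Beer-Lambert model).
hh_trace <- function(ph, pka, a_acid, a_base) {
  r <- 10^(ph - pka)
  (a_acid + a_base * r) / (1 + r)
}

# Independent numeric oracle for the three-point closed form: for a trial
# pKa the two limiting absorbances follow linearly from the first two
# points; the root of the residual on the third point is the answer.
seok_oracle <- function(ph, A, interval = range(ph) + c(-2, 2)) {
  resid <- function(pka) {
    r <- 10^(ph - pka)
    m <- cbind(1 / (1 + r[1:2]), r[1:2] / (1 + r[1:2]))
    lim <- solve(m, A[1:2])
    (lim[1] + lim[2] * r[3]) / (1 + r[3]) - A[3]
  }
  stats::uniroot(resid, interval, tol = 1e-12)$root
}
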