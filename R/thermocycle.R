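#' Free-energy terms of the proton-exchange thermodynamic cycle
#'
#' One deprotonation HA + H2O -> A- + H3O+ is characterised by the gas-phase
#' reaction free energy and the solvation free energies of the four species,
#' all in kcal/mol, computed with one continuum solvation model.
#'
#' @param dG_gas Gas-phase deprotonation reaction free energy (kcal/mol).
#' @param dGsolv_anion,dGsolv_hydronium,dGsolv_acid,dGsolv_water Solvation
#'   free energies of A-, H3O+, HA and H2O (kcal/mol).
#' @param model Continuum solvation model: `"PCM"`, `"IPCM"` or `"CPCM"`.
#' @param temperature_K Temperature (K), default 298.15.
#' @return Object of class `free_energy_set`.
#' @export
free_energy_set <- function(dG_gas, dGsolv_anion, dGsolv_hydronium,
                            dGsolv_acid, dGsolv_water,
                            model = c("CPCM", "PCM", "IPCM"),
                            temperature_K = 298.15) {
  model <- match.arg(model)
  vals <- c(dG_gas, dGsolv_anion, dGsolv_hydronium, dGsolv_acid, dGsolv_water)
  if (any(!is.finite(vals))) stop("all free-energy terms must be finite")
  structure(list(dG_gas = dG_gas, dGsolv_anion = dGsolv_anion,
                 dGsolv_hydronium = dGsolv_hydronium,
                 dGsolv_acid = dGsolv_acid, dGsolv_water = dGsolv_water,
                 model = model, temperature_K = temperature_K),
            class = "free_energy_set")
}

#' Thermodynamic-cycle configuration
#'
#' @param water_molarity Molar concentration of pure water (mol/L); 55.34 at
#'   25 degrees C.
#' @param kcal_per_pka_unit The RT ln(10) conversion (kcal/mol per pKa unit)
#'   as conventionally printed, 1.364 at 298.15 K; kept as the printed
#'   constant for reproducibility and validated by [rt_ln10_kcal()].
#' @param pliego_correction Empirical correction (pH units, default 4.54)
#'   subtracted from the cycle pKa to offset the systematic error of the
#'   proton-exchange scheme.
#' @return List of class `thermo_config`.
#' @export
thermo_config <- function(water_molarity = 55.34, kcal_per_pka_unit = 1.364,
                          pliego_correction = 4.54) {
  if (any(c(water_molarity, kcal_per_pka_unit, pliego_correction) <= 0))
    stop("all configuration constants must be positive")
  structure(list(water_molarity = water_molarity,
                 kcal_per_pka_unit = kcal_per_pka_unit,
                 pliego_correction = pliego_correction),
            class = "thermo_config")
}

#' Solution-phase deprotonation free energy
#'
#' Closes the thermodynamic cycle:
#' dGsol = dGg + dGsolv(A-) + dGsolv(H3O+) - dGsolv(HA) - dGsolv(H2O).
#'
#' @param fes A [free_energy_set()].
#' @return dGsol in kcal/mol.
#' @export
delta_g_solution <- function(fes) {
  stopifnot(inherits(fes, "free_energy_set"))
  fes$dG_gas + fes$dGsolv_anion + fes$dGsolv_hydronium -
    fes$dGsolv_acid - fes$dGsolv_water
}

#' pKa from the thermodynamic cycle
#'
#' pKa = dGsol / (RT ln 10) - log10(\[H2O\]), optionally minus the empirical
#' proton-exchange correction of 4.54 pH units.
#'
#' @param fes A [free_energy_set()].
#' @param cfg A [thermo_config()].
#' @param apply_correction Subtract the empirical correction? Default `TRUE`.
#' @return pKa in pH units.
#' @export
pka_from_cycle <- function(fes, cfg = thermo_config(),
                           apply_correction = TRUE) {
  stopifnot(inherits(cfg, "thermo_config"))
  pka <- delta_g_solution(fes) / cfg$kcal_per_pka_unit -
    log10(cfg$water_molarity)
  if (apply_correction) pka <- pka - cfg$pliego_correction
  pka
}

#' RT ln(10) in kcal/mol
#'
#' Validates the conventional 1.364 kcal/mol-per-pKa-unit constant:
#' R = 1.98720425e-3 kcal/(mol K) gives 1.3642 at 298.15 K.
#'
#' @param temperature_K Temperature in kelvin (> 0, or 0 for the limit).
#' @return RT ln(10) in kcal/mol.
#' @export
rt_ln10_kcal <- function(temperature_K = 298.15) {
  if (any(temperature_K < 0)) stop("temperature must be non-negative")
  1.98720425e-3 * temperature_K * log(10)
}

#' Relative error of a calculated pKa, in percent
#'
#' @param experimental Reference experimental pKa (non-zero).
#' @param calculated Computed pKa.
#' @return 100 * |experimental - calculated| / experimental.
#' @examples
#' relative_error_pct(8.83, 8.58)  # 2.83
#' @export
relative_error_pct <- function(experimental, calculated) {
  if (any(experimental == 0)) stop("experimental pKa must be non-zero")
  100 * abs(experimental - calculated) / experimental
}

#' Rank continuum solvation models by their pKa relative error
#'
#' @param model_pka data.frame with column `compound` and one numeric column
#'   per solvation model holding the calculated first pKa; alternatively a
#'   list of [free_energy_set()] per compound/model, converted via
#'   [pka_from_cycle()].
#' @param experimental data.frame with columns `compound` and `experimental`
#'   (pKa); compound sets must match.
#' @param cfg,apply_correction Passed to [pka_from_cycle()] when free-energy
#'   sets are supplied.
#' @return data.frame with one row per model: `model`, `max_error_pct`,
#'   `mean_error_pct`, ranked by max error ascending; attribute `per_compound`
#'   holds the full error matrix.
#' @export
compare_solvation_models <- function(model_pka, experimental,
                                     cfg = thermo_config(),
                                     apply_correction = TRUE) {
  if (is.list(model_pka) && !is.data.frame(model_pka)) {
    rows <- lapply(names(model_pka), function(cmp) {
      sets <- model_pka[[cmp]]
      vals <- vapply(sets, pka_from_cycle, 0, cfg = cfg,
                     apply_correction = apply_correction)
      names(vals) <- vapply(sets, `[[`, "", "model")
      c(list(compound = cmp), as.list(vals))
    })
    model_pka <- do.call(rbind, lapply(rows, as.data.frame))
  }
  if (!"compound" %in% names(model_pka) ||
      !all(c("compound", "experimental") %in% names(experimental)))
    stop("inputs need 'compound' columns and an 'experimental' column")
  if (!setequal(model_pka$compound, experimental$compound))
    stop("compound sets do not match between calculated and experimental tables")
  m <- merge(experimental[, c("compound", "experimental")], model_pka,
             by = "compound")
  models <- setdiff(names(model_pka), "compound")
  err <- sapply(models, function(md)
    relative_error_pct(m$experimental, m[[md]]))
  err <- matrix(err, nrow = nrow(m),
                dimnames = list(m$compound, models))
  out <- data.frame(model = models,
                    max_error_pct = apply(err, 2L, max),
                    mean_error_pct = colMeans(err))
  out <- out[order(out$max_error_pct), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "per_compound") <- err
  out
}

#' Read per-compound free-energy tables
#'
#' Tab-separated columns: `compound`, `model`, `site`, `dG_gas`,
#' `dGsolv_anion`, `dGsolv_hydronium`, `dGsolv_acid`, `dGsolv_water`
#' (kcal/mol).  Each row becomes a [free_energy_set()].
#'
#' @param path TSV file path.
#' @return data.frame of the raw table with an extra list-column `fes`
#'   holding the corresponding [free_energy_set()] objects.
#' @export
read_free_energies <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("compound", "model", "dG_gas", "dGsolv_anion",
            "dGsolv_hydronium", "dGsolv_acid", "dGsolv_water")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  df$fes <- lapply(seq_len(nrow(df)), function(i)
    free_energy_set(df$dG_gas[i], df$dGsolv_anion[i], df$dGsolv_hydronium[i],
                    df$dGsolv_acid[i], df$dGsolv_water[i],
                    model = df$model[i]))
  df
}
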