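#' Define a polyprotic acid system
#'
#' An `acid_system` holds the ordered dissociation constants of a mono- to
#' tetraprotic acid, optionally tagged with the deprotonation site each step
#' corresponds to.  For substituted catechols the sites are the hydroxyl meta
#' to the 4-substituent (`"OH_m"`), the hydroxyl para to it (`"OH_p"`), or a
#' dissociable proton on the substituent itself (`"RH"`).
#'
#' @param pkas Numeric vector of pKa values (pH units), strictly increasing,
#'   length 1 to 4.
#' @param site_labels Optional character vector, one of `"OH_m"`, `"OH_p"`,
#'   `"RH"` per dissociation step.
#' @return An object of class `acid_system` with elements `n_protons`,
#'   `pkas` and `site_labels`.
#' @examples
#' catechol <- acid_system(c(8.83, 13.07), c("OH_m", "OH_p"))
#' species_fractions(catechol, c(2, 8.83, 14))
#' @export
acid_system <- function(pkas, site_labels = NULL) {
  pkas <- as.numeric(pkas)
  if (length(pkas) < 1L || length(pkas) > 4L)
    stop("between 1 and 4 dissociation steps are supported")
  if (any(!is.finite(pkas)))
    stop("all pKa values must be finite")
  if (length(pkas) > 1L && any(diff(pkas) <= 0))
    stop("pKa values must be strictly increasing")
  if (!is.null(site_labels)) {
    site_labels <- as.character(site_labels)
    if (length(site_labels) != length(pkas))
      stop("site_labels must have one entry per dissociation step")
    if (!all(site_labels %in% c("OH_m", "OH_p", "RH")))
      stop("site labels must be 'OH_m', 'OH_p' or 'RH'")
  }
  structure(
    list(n_protons = length(pkas), pkas = pkas, site_labels = site_labels),
    class = "acid_system"
  )
}

#' @export
print.acid_system <- function(x, ...) {
  cat(sprintf("Polyprotic acid system (%d dissociation step%s)\n",
              x$n_protons, if (x$n_protons > 1L) "s" else ""))
  lab <- if (is.null(x$site_labels)) rep("", x$n_protons) else
    paste0(" [", x$site_labels, "]")
  for (i in seq_len(x$n_protons))
    cat(sprintf("  pKa%d = %.2f%s\n", i, x$pkas[i], lab[i]))
  invisible(x)
}

#' Equilibrium mole fractions of every protonation state
#'
#' Computes the mole fraction of each species HnL, H(n-1)L-, ..., L(n-) on a
#' pH grid from the stepwise Henderson-Hasselbalch relation
#' pH = pKa_i + log10(\[base_i\]/\[acid_i\]).  The fraction of the species
#' that has lost j protons is proportional to 10^(j*pH - sum(pKa_1..j)); the
#' largest log-weight is factored out before exponentiation so the
#' computation is stable even at pH 14 against a pKa of 2.
#'
#' @param system An [acid_system()].
#' @param ph_grid Numeric vector of pH values (finite, non-empty).
#' @return An object of class `speciation_profile`: a list with `ph_grid`
#'   and `fractions`, a matrix of dimension (n_protons + 1) x length(ph_grid)
#'   whose columns sum to one.  Row `i` is the species that has lost `i - 1`
#'   protons (row 1 = fully protonated).
#' @export
species_fractions <- function(system, ph_grid) {
  stopifnot(inherits(system, "acid_system"))
  ph_grid <- as.numeric(ph_grid)
  if (length(ph_grid) == 0L || any(!is.finite(ph_grid)))
    stop("ph_grid must be non-empty and finite")
  n <- system$n_protons
  cum_pka <- c(0, cumsum(system$pkas))          # sum of first j pKas, j = 0..n
  # log10 weight of species j (j protons lost) at each pH
  lw <- outer(0:n, ph_grid) - cum_pka           # (n+1) x n_pH
  lw <- sweep(lw, 2L, apply(lw, 2L, max))
  w <- 10^lw
  frac <- sweep(w, 2L, colSums(w), "/")
  dimnames(frac) <- list(species = paste0("lost", 0:n), NULL)
  structure(list(ph_grid = ph_grid, fractions = frac),
            class = "speciation_profile")
}

#' Henderson-Hasselbalch pKa from a base/acid ratio
#'
#' Inverts pH = pKa + log10(ratio) for a single dissociation step.
#'
#' @param ph pH at which the ratio was observed.
#' @param ratio_base_over_acid Concentration ratio \[base\]/\[acid\], > 0.
#' @return The pKa in pH units.
#' @examples
#' hh_pka_from_ratio(8.0, 10.0)  # 7.0
#' @export
hh_pka_from_ratio <- function(ph, ratio_base_over_acid) {
  if (any(ratio_base_over_acid <= 0))
    stop("base/acid ratio must be strictly positive")
  ph - log10(ratio_base_over_acid)
}
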