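#' One compound's experimental and computed pKa record
#'
#' @param name Compound name.
#' @param experimental_pkas Numeric vector of experimental pKa values.
#' @param computed_site_pkas Named numeric vector; names from `OH_m`, `OH_p`,
#'   `RH` (`RH` may occur twice for side chains that deprotonate twice).
#' @param sigma_p Hammett sigma-para constant of the 4-substituent, or `NA`.
#' @param substituent Optional short formula of the 4-substituent (used to
#'   recognise halogen/hydroxyl weak deactivators).
#' @return Object of class `compound_record`.
#' @export
compound_record <- function(name, experimental_pkas = numeric(),
                            computed_site_pkas = numeric(),
                            sigma_p = NA_real_, substituent = NA_character_) {
  experimental_pkas <- experimental_pkas[!is.na(experimental_pkas)]
  computed_site_pkas <- computed_site_pkas[!is.na(computed_site_pkas)]
  if (!length(experimental_pkas) && !length(computed_site_pkas))
    stop("record needs at least one experimental or computed value")
  if (length(computed_site_pkas) &&
      !all(names(computed_site_pkas) %in% c("OH_m", "OH_p", "RH")))
    stop("computed site names must be OH_m, OH_p or RH")
  structure(list(name = name, experimental_pkas = experimental_pkas,
                 computed_site_pkas = computed_site_pkas,
                 sigma_p = sigma_p, substituent = substituent),
            class = "compound_record")
}

#' Build compound records from the packaged reference tables
#'
#' @return Named list of [compound_record()], one per studied catechol.
#' @export
compound_records <- function() {
  tabs <- dhb_compounds()
  ex <- tabs$experimental
  cp <- tabs$computed
  out <- lapply(seq_len(nrow(ex)), function(i) {
    j <- match(ex$id[i], cp$id)
    comp <- c(OH_m = cp$pka_OH_m[j], OH_p = cp$pka_OH_p[j],
              RH = cp$pka_RH[j], RH = cp$pka_RH2[j])
    compound_record(ex$compound[i],
                    experimental_pkas = unlist(ex[i, c("pka1", "pka2", "pka3")]),
                    computed_site_pkas = comp,
                    sigma_p = cp$sigma_p[j],
                    substituent = cp$substituent[j])
  })
  names(out) <- ex$compound
  out
}

#' Pair experimental with computed pKa values by acidity rank
#'
#' Computed site pKa values are flattened, sorted ascending, truncated to the
#' number of experimental values (and vice versa), then paired index-wise
#' with the ascending experimental values: the i-th most acidic computed
#' proton is matched to the i-th experimental dissociation.
#'
#' @param record A [compound_record()] with both sides present.
#' @return data.frame with columns `index`, `experimental`, `computed`.
#' @export
pair_sorted <- function(record) {
  stopifnot(inherits(record, "compound_record"))
  e <- sort(record$experimental_pkas)
  k <- sort(unname(record$computed_site_pkas))
  if (!length(e) || !length(k))
    stop("pairing needs both experimental and computed values")
  n <- min(length(e), length(k))
  data.frame(index = seq_len(n), experimental = e[seq_len(n)],
             computed = k[seq_len(n)])
}

#' Coefficient of determination of computed versus experimental pKa
#'
#' Ordinary least-squares r-squared of computed on experimental values,
#' computed separately for each dissociation index (all first dissociations
#' together, all second, ...).
#'
#' @param pairs data.frame as stacked [pair_sorted()] output (columns
#'   `index`, `experimental`, `computed`), e.g. over all compounds.
#' @return Named numeric vector of r-squared per dissociation index.
#' @export
correlation_r2 <- function(pairs) {
  stopifnot(all(c("index", "experimental", "computed") %in% names(pairs)))
  idx <- sort(unique(pairs$index))
  r2 <- vapply(idx, function(i) {
    p <- pairs[pairs$index == i, ]
    if (nrow(p) < 3L)
      stop(sprintf("need >= 3 pairs for dissociation index %d", i))
    if (stats::sd(p$experimental) == 0)
      stop("experimental values are constant; r-squared undefined")
    if (stats::sd(p$computed) == 0) return(0)  # flat fit explains nothing
    stats::cor(p$experimental, p$computed)^2
  }, 0)
  names(r2) <- paste0("pKa", idx)
  r2
}

#' Classify a 4-substituent by its Hammett sigma-para constant
#'
#' @param sigma_p Hammett constant; negative marks an electron-donating
#'   group (EDG), positive an electron-withdrawing group (EWG), zero the
#'   unsubstituted reference.
#' @return `"EDG"`, `"EWG"` or `"neutral"`.
#' @export
classify_substituent <- function(sigma_p) {
  if (is.na(sigma_p)) stop("sigma_p missing: substituent not classifiable")
  if (sigma_p < 0) "EDG" else if (sigma_p > 0) "EWG" else "neutral"
}

# Halogens and hydroxyl withdraw electron density inductively but donate by
# resonance; their sigma sign misstates the ring effect on acidity, so the
# EDG/EWG site rule is not expected to hold for them.
is_weak_deactivator <- function(substituent) {
  !is.na(substituent) && substituent %in% c("F", "Cl", "Br", "I", "OH")
}

#' First deprotonation site and consistency with the Hammett rule
#'
#' The rule: electron-donating 4-substituents (sigma < 0) make the hydroxyl
#' meta to the substituent the most acidic (`OH_m`); electron-withdrawing
#' ones (sigma > 0) shift the first deprotonation to the para hydroxyl
#' (`OH_p`), whose anion they stabilise by resonance.  The assigned site is
#' the hydroxyl with the lowest computed pKa; a substituent proton (`RH`)
#' that is globally most acidic is reported alongside.  The record is
#' flagged as an exception when the site contradicts the sigma rule, or when
#' the substituent is a halogen/hydroxyl weak deactivator for which the
#' sigma sign is not a reliable guide.
#'
#' @param record A [compound_record()] with computed site pKa values.
#' @return List with `site` (`"OH_m"` or `"OH_p"`), `site_pka`,
#'   `global_site` (may be `"RH"`), `classification` (`"EDG"`, `"EWG"`,
#'   `"neutral"` or `"not_classifiable"`) and logical `exception`.
#' @export
first_deprotonation_site <- function(record) {
  stopifnot(inherits(record, "compound_record"))
  k <- record$computed_site_pkas
  if (!length(k)) stop("record has no computed site pKa values")
  oh <- k[names(k) %in% c("OH_m", "OH_p")]
  if (!length(oh)) stop("record has no hydroxyl site pKa values")
  site <- names(oh)[which.min(oh)]
  cls <- tryCatch(classify_substituent(record$sigma_p),
                  error = function(e) "not_classifiable")
  exception <- FALSE
  if (cls == "EDG" && site != "OH_m") exception <- TRUE
  if (cls == "EWG" && site != "OH_p") exception <- TRUE
  if (is_weak_deactivator(record$substituent)) exception <- TRUE
  list(site = site, site_pka = unname(min(oh)),
       global_site = names(k)[which.min(k)],
       classification = cls, exception = exception)
}

#' Combined validation report over the packaged reference compounds
#'
#' Recomputes the three validation analyses from the packaged tables: the
#' solvation-model relative-error ranking, the per-dissociation
#' experimental-versus-computed r-squared, and the first-deprotonation-site
#' table with Hammett-rule exceptions.
#'
#' @return List of class `dhb_report` with elements `solvation`, `r2`,
#'   `sites` and `schema_version`.
#' @export
dhb_report <- function() {
  tabs <- dhb_compounds()
  recs <- compound_records()
  pairs <- do.call(rbind, lapply(recs, pair_sorted))
  rownames(pairs) <- NULL
  sites <- do.call(rbind, lapply(recs, function(r) {
    s <- first_deprotonation_site(r)
    data.frame(compound = r$name, sigma_p = r$sigma_p,
               classification = s$classification, first_site = s$site,
               first_site_pka = s$site_pka, global_site = s$global_site,
               exception = s$exception)
  }))
  rownames(sites) <- NULL
  structure(list(
    schema_version = "1.0",
    solvation = compare_solvation_models(
      tabs$solvation_models[, c("compound", "PCM", "IPCM", "CPCM")],
      tabs$solvation_models[, c("compound", "experimental")]),
    r2 = correlation_r2(pairs),
    sites = sites
  ), class = "dhb_report")
}

#' @export
print.dhb_report <- function(x, ...) {
  cat("Solvation-model ranking (max % relative error):\n")
  print(x$solvation, row.names = FALSE)
  cat("\nComputed-vs-experimental r-squared per dissociation:\n")
  print(round(x$r2, 3))
  cat("\nHammett-rule exceptions:\n")
  print(x$sites[x$sites$exception, c("compound", "sigma_p", "first_site")],
        row.names = FALSE)
  invisible(x)
}

#' Write estimates or a report as JSON
#'
#' @param x A [pka_estimate()], `pka_fit` or `dhb_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  payload <- if (inherits(x, "pka_fit")) {
    list(schema_version = "1.0",
         estimates = lapply(x$estimates, unclass))
  } else if (inherits(x, "pka_estimate")) {
    list(schema_version = "1.0", estimates = list(unclass(x)))
  } else if (inherits(x, "dhb_report")) {
    c(list(schema_version = x$schema_version),
      lapply(unclass(x)[-1L], function(el) el))
  } else stop("unsupported object")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
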