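test_that("acidity-rank pairing matches experiment to computed sites", {
  cat6 <- compound_record("Catechol", c(8.83, 13.07),
                          c(OH_m = 8.82, OH_p = 13.07), sigma_p = 0)
  p <- pair_sorted(cat6)
  expect_equal(p$experimental, c(8.83, 13.07))
  expect_equal(p$computed, c(8.82, 13.07))

  # a fourth computed proton is dropped when only three dissociations were
  # measured (Dopa deprotonates twice in its side chain)
  dopa <- compound_record("Dopa", c(2.06, 8.55, 9.93),
                          c(OH_m = 13.6, OH_p = 8.86, RH = 2.31, RH = 10.2))
  pd <- pair_sorted(dopa)
  expect_equal(nrow(pd), 3)
  expect_equal(pd$computed, c(2.31, 8.86, 10.2))

  only <- compound_record("x", computed_site_pkas = c(OH_m = 9))
  expect_error(pair_sorted(only), "both")
  # permutation invariance of the computed input ordering
  perm <- compound_record("Dopa", c(2.06, 8.55, 9.93),
                          c(RH = 10.2, OH_p = 8.86, OH_m = 13.6, RH = 2.31))
  expect_equal(pair_sorted(perm)$computed, pd$computed)
})

test_that("per-dissociation r-squared matches a closed-form check", {
  p3 <- data.frame(index = 1, experimental = c(1, 2, 4),
                   computed = c(3.9, 2.2, 1.1))
  r2 <- correlation_r2(p3)
  x <- p3$experimental; y <- p3$computed
  hand <- cov(x, y)^2 / (var(x) * var(y))
  expect_equal(unname(r2), hand, tolerance = 1e-12)

  same <- data.frame(index = 1, experimental = c(3, 5, 9),
                     computed = c(3, 5, 9))
  expect_equal(unname(correlation_r2(same)), 1)
  const <- data.frame(index = 1, experimental = c(4, 4, 4),
                      computed = c(1, 2, 3))
  expect_error(correlation_r2(const), "constant")
  expect_error(correlation_r2(p3[1:2, ]), "3 pairs")
  # invariant to exchanging pair order and to joint affine rescaling
  p3r <- p3[c(3, 1, 2), ]
  expect_equal(correlation_r2(p3r), r2)
  p3s <- transform(p3, experimental = 2 * experimental + 1,
                   computed = 2 * computed + 1)
  expect_equal(correlation_r2(p3s), r2)
})

test_that("reference compounds correlate above 0.87 in every series", {
  pairs <- do.call(rbind, lapply(compound_records(), pair_sorted))
  r2 <- correlation_r2(pairs)
  expect_length(r2, 3)
  expect_true(all(r2 >= 0.87))
})

test_that("Hammett sign classifies donors and acceptors", {
  expect_identical(classify_substituent(-0.17), "EDG")
  expect_identical(classify_substituent(0.78), "EWG")
  expect_identical(classify_substituent(0), "neutral")
  expect_error(classify_substituent(NA), "not classifiable")
})

test_that("first deprotonation site follows the substituent's sigma", {
  nitro <- compound_record("4-Nitrocatechol", c(5.93, 11.05),
                           c(OH_m = 11.15, OH_p = 6.10), sigma_p = 0.78,
                           substituent = "NO2")
  s <- first_deprotonation_site(nitro)
  expect_identical(s$site, "OH_p")
  expect_false(s$exception)

  methyl <- compound_record("4-Methylcatechol", c(9.36, 13.49),
                            c(OH_m = 9.23, OH_p = 13.33), sigma_p = -0.17,
                            substituent = "Me")
  s <- first_deprotonation_site(methyl)
  expect_identical(s$site, "OH_m")
  expect_false(s$exception)

  chloro <- compound_record("4-Chlorocatechol", c(7.90, 10.35),
                            c(OH_m = 8.13, OH_p = 10.41), sigma_p = 0.23,
                            substituent = "Cl")
  s <- first_deprotonation_site(chloro)
  expect_identical(s$site, "OH_m")   # contradicts the sigma > 0 rule
  expect_true(s$exception)

  # a carboxylic acid proton can be globally most acidic without changing
  # the hydroxyl-site assignment
  caffeic <- compound_record("Caffeic acid", c(3.95, 8.47, 12.56),
                             c(OH_m = 12.50, OH_p = 8.50, RH = 3.92),
                             sigma_p = 0.09, substituent = "CH=CHCOOH")
  s <- first_deprotonation_site(caffeic)
  expect_identical(s$site, "OH_p")
  expect_identical(s$global_site, "RH")
})

test_that("site assignment over all reference compounds matches the rule", {
  recs <- compound_records()
  sites <- lapply(recs, first_deprotonation_site)
  sigma <- vapply(recs, `[[`, 0, "sigma_p")
  # every electron-donating substituent deprotonates the meta hydroxyl first
  edg <- !is.na(sigma) & sigma < 0
  expect_true(all(vapply(sites[edg], `[[`, "", "site") == "OH_m"))
  # the two weak deactivators are the only flagged exceptions
  flagged <- names(which(vapply(sites, `[[`, TRUE, "exception")))
  expect_setequal(flagged, c("4-Chlorocatechol", "1,2,4-Benzenetriol"))
})

test_that("the combined report reproduces all three validation analyses", {
  rep <- dhb_report()
  expect_identical(rep$solvation$model[1], "CPCM")
  expect_true(all(rep$r2 >= 0.87))
  expect_equal(sum(rep$sites$exception), 2)
  expect_output(print(rep), "CPCM")
  f <- tempfile(fileext = ".json")
  write_report_json(rep, f)
  parsed <- jsonlite::read_json(f)
  expect_identical(parsed$schema_version, "1.0")
  expect_length(parsed$sites, 24)
  unlink(f)
})
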