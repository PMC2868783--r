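test_that("species fractions reproduce the low-pKa reference table", {
  fr <- species_fractions(5.0, ks_low)
  expect_equal(round(c(fr$fH2B, fr$fHB, fr$fB), 4),
               c(0.0656, 0.4137, 0.5208))
  fr <- species_fractions(4.0, ks_low)
  expect_equal(round(c(fr$fH2B, fr$fHB, fr$fB), 4),
               c(0.5847, 0.3689, 0.0464))

  tab <- fraction_table(seq(4, 10, by = 0.5), ks_low)
  expect_equal(nrow(tab), 13L)
  expect_lt(max(abs(as.matrix(tab[, c("fH2B", "fHB", "fB")]) -
                      table1_reference)), 1e-4)
})

test_that("species fractions obey defining identities and limits", {
  # at pH = pKa1 (second ionization far away) diacid and monoanion tie
  ks <- ionization_constants(4.0, 12.0)
  fr <- species_fractions(4.0, ks)
  expect_equal(fr$fH2B, fr$fHB, tolerance = 1e-12)

  # strongly acid limit: all diacid
  fr <- species_fractions(0, ks_high)
  expect_gt(fr$fH2B, 0.9999)
  expect_lt(fr$fB, 1e-10)

  # under the high pKa pair the diacid still dominates at pH 6
  expect_gt(species_fractions(6.0, ks_high)$fH2B, 0.99)

  # a single-point table equals the direct call
  expect_equal(as.data.frame(fraction_table(7.0, ks_high)),
               species_fractions(7.0, ks_high), ignore_attr = TRUE)
})

test_that("fractions sum to one and are monotone in pH", {
  set.seed(401)
  for (i in 1:50) {
    ks <- ionization_constants(runif(1, 2, 12), runif(1, 2, 12))
    pH <- sort(runif(25, 0, 14))
    fr <- species_fractions(pH, ks)
    expect_lt(max(abs(fr$fH2B + fr$fHB + fr$fB - 1)), 1e-12)
    expect_true(all(diff(fr$fB) > 0))
    expect_true(all(diff(fr$fH2B) < 0))
  }
})

test_that("grid and pH validation is enforced", {
  expect_error(fraction_table(numeric(0)), class = "bilispec_validation_error")
  expect_error(fraction_table(c(5, 4)), class = "bilispec_validation_error")
  expect_error(species_fractions(NaN), class = "bilispec_domain_error")
  expect_error(species_fractions(Inf), class = "bilispec_domain_error")
})

test_that("monomer composition splits totals and honors the dimer", {
  # KD = 0 reduces exactly to the fraction split
  fr <- species_fractions(7.5, ks_high)
  comp <- monomer_composition(8, 7.5, ks_high, dim_off)
  expect_equal(comp$cH2B, 8 * fr$fH2B)
  expect_equal(comp$cHB, 8 * fr$fHB)
  expect_equal(comp$cB, 8 * fr$fB)
  expect_identical(comp$cDimer, 0)

  # diacid-dominated regime: dimer negligible
  comp <- monomer_composition(5.1, 6.54, ks_high, dim_ucb)
  expect_equal(comp$cH2B, 4.968, tolerance = 1e-3)
  expect_lt(comp$cDimer, 1e-6)

  expect_error(monomer_composition(-1, 7), class = "bilispec_domain_error")
})

test_that("monomer composition inverts its own mass balance", {
  # forward-construct a composition with cB = 1 uM, then invert
  pH <- 9.0
  s <- species_fractions(pH, ks_high)
  cH2B <- 1 / (s$fB / s$fH2B)   # cH2B giving cB = 1
  total <- cH2B * (1 + s$fHB / s$fH2B + s$fB / s$fH2B) + 2 * 0.26 * 1^2
  comp <- monomer_composition(total, pH, ks_high, dim_ucb)
  expect_equal(comp$cB, 1, tolerance = 1e-9)
  expect_equal(comp$cDimer, 0.26, tolerance = 1e-9)

  # property: compose -> total -> decompose round-trips across regimes
  set.seed(402)
  for (i in 1:30) {
    pH <- runif(1, 4, 11)
    total <- runif(1, 0, 50)
    KD <- sample(c(0, 0.26, 2), 1)
    comp <- monomer_composition(total, pH, ks_high, dimerization_model(KD))
    expect_equal(composition_total(comp), total, tolerance = 1e-9)
    comp2 <- monomer_composition(composition_total(comp), pH, ks_high,
                                 dimerization_model(KD))
    expect_equal(comp2$cB, comp$cB, tolerance = 1e-9)
  }
})

test_that("total solubility matches the reference profile", {
  expect_lt(abs(total_solubility(7.40) - 0.062), 0.001)
  expect_lt(abs(total_solubility(8.2) - 0.148), 0.001)
  # un-ionized limit
  expect_lt(abs(total_solubility(4.0) - 0.051), 1e-4)
  # never below the diacid solubility
  expect_true(all(total_solubility(seq(-2, 12, by = 0.5)) > 0.051))
})

test_that("dianion saturation follows the power law", {
  expect_equal(dianion_saturation(8.28), 0.051)   # exponent exactly 0
  expect_equal(dianion_saturation(9.3), 0.051 * 10^2.04, tolerance = 1e-9)
  expect_equal(dianion_saturation(7.0), 0.051 * 10^-2.56, tolerance = 1e-9)
})

test_that("saturation ratio flags supersaturation", {
  expect_equal(saturation_ratio(total_solubility(7.8), 7.8), 1)
  expect_equal(saturation_ratio(20.3, 7.0), 369, tolerance = 0.001)
  expect_identical(saturation_ratio(0, 9.0), 0)
})
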