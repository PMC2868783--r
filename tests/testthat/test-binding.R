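test_that("midpoint pH reproduces the reference series", {
  expect_equal(midpoint_pH(host_binding_model("H2B", 100), ks_high)$midpoint_pH,
               9.251, tolerance = 0.01 / 9.251)
  expect_equal(midpoint_pH(host_binding_model("H2B", 1000), ks_high)$midpoint_pH,
               9.778, tolerance = 0.01 / 9.778)
  kp <- c(1, 10, 100, 1000, 10000)
  mids <- vapply(kp, function(k) {
    midpoint_pH(host_binding_model("B", k), ks_high)$midpoint_pH
  }, numeric(1))
  expect_equal(mids, c(8.348, 7.863, 7.315, 6.794, 6.287), tolerance = 0.0015)
  expect_equal(limiting_midpoint("B", ks_high), 8.574, tolerance = 0.01 / 8.574)
  expect_equal(limiting_midpoint("H2B", ks_high), 7.994,
               tolerance = 0.01 / 7.994)
})

test_that("closed form and bisection agree across the K range", {
  set.seed(411)
  for (sp in c("H2B", "B", "HB")) {
    for (K in 10^runif(12, -3, 6)) {
      m <- host_binding_model(sp, K)
      a <- midpoint_pH(m, ks_high, method = "closed_form")$midpoint_pH
      b <- midpoint_pH(m, ks_high, method = "bisection")$midpoint_pH
      expect_lt(abs(a - b), 1e-8)
    }
  }
})

test_that("the midpoint satisfies its defining equation", {
  for (spec in list(list("H2B", 100), list("B", 10), list("HB", 50))) {
    m <- host_binding_model(spec[[1]], spec[[2]])
    res <- midpoint_pH(m, ks_high)
    expect_equal(bound_fraction(res$midpoint_pH, m, ks_high), res$F_max / 2,
                 tolerance = 1e-9)
  }
  # explicit value: at the H2B K=100 midpoint, F is half of 100/101
  m <- host_binding_model("H2B", 100)
  expect_equal(bound_fraction(midpoint_pH(m, ks_high)$midpoint_pH, m, ks_high),
               0.5 * 100 / 101, tolerance = 1e-9)
})

test_that("midpoints shift monotonically with affinity and approach limits", {
  kgrid <- 10^seq(-2, 4, by = 0.5)
  mid_h2b <- vapply(kgrid, function(k) {
    midpoint_pH(host_binding_model("H2B", k), ks_high)$midpoint_pH
  }, numeric(1))
  mid_b <- vapply(kgrid, function(k) {
    midpoint_pH(host_binding_model("B", k), ks_high)$midpoint_pH
  }, numeric(1))
  expect_true(all(diff(mid_h2b) > 0))   # H2B binding: midpoint rises with K
  expect_true(all(diff(mid_b) < 0))     # B= binding: midpoint falls with K

  expect_lt(abs(midpoint_pH(host_binding_model("H2B", 1e-6), ks_high)$midpoint_pH -
                  limiting_midpoint("H2B", ks_high)), 1e-3)
  expect_lt(abs(midpoint_pH(host_binding_model("B", 1e-6), ks_high)$midpoint_pH -
                  limiting_midpoint("B", ks_high)), 1e-3)
})

test_that("low pKa values force dianion-binding midpoints below 5.1", {
  for (k in 10^seq(-2, 4)) {
    expect_lt(midpoint_pH(host_binding_model("B", k), ks_low)$midpoint_pH, 5.1)
  }
  expect_lt(limiting_midpoint("B", ks_low), 5.1)
})

test_that("limiting midpoint agrees with a brute-force grid search", {
  # equal pKa values: locate where fB crosses half its maximum on a fine grid
  ks <- ionization_constants(7, 7)
  grid <- seq(0, 14, by = 1e-5)
  fB <- species_fractions(grid, ks)$fB
  expect_lt(abs(limiting_midpoint("B", ks) - grid[which.min(abs(fB - 0.5))]),
            1e-4)
  # and for the monoanion, against half its own peak (ascending branch)
  fHB <- species_fractions(grid, ks)$fHB
  half <- max(fHB) / 2
  asc <- grid <= grid[which.max(fHB)]
  expect_lt(abs(limiting_midpoint("HB", ks) -
                  grid[asc][which.min(abs(fHB[asc] - half))]), 1e-4)
})

test_that("bound fraction and binding curves behave", {
  expect_identical(bound_fraction(c(5, 7, 9), host_binding_model("B", 0),
                                  ks_high), c(0, 0, 0))
  expect_equal(bound_fraction(8.13, host_binding_model("B", 730), ks_high),
               0.9932, tolerance = 1e-4)

  cv <- binding_curve(host_binding_model("H2B", 1e4), ks_high, seq(4, 10))
  expect_equal(cv$F[1], 1e4 / (1e4 + 1), tolerance = 1e-4)
  cv <- binding_curve(host_binding_model("B", 0.2), ks_high, seq(4, 10, 0.5))
  expect_true(all(cv$F < 0.2 / 1.2))

  # the curve crosses half its asymptote exactly at the midpoint
  m <- host_binding_model("B", 10)
  res <- midpoint_pH(m, ks_high)
  expect_equal(bound_fraction(res$midpoint_pH, m, ks_high), res$F_max / 2,
               tolerance = 1e-9)

  expect_error(binding_curve(m, ks_high, c(8, 6)),
               class = "bilispec_validation_error")
  expect_error(midpoint_pH(host_binding_model("B", 0)),
               class = "bilispec_domain_error")
})
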