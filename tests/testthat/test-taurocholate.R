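test_that("bound species fractions match the distribution-ratio formula", {
  fr <- tc_bound_species_fractions(7.23)
  expect_lt(abs(fr$fs_HB - 0.1661), 1e-4)
  expect_equal(fr$fs_B, 0.5794420, tolerance = 1e-6)  # frozen from the formula
  fr <- tc_bound_species_fractions(9.35)
  expect_lt(abs(fr$fs_HB - 0.00217), 1e-5)
  expect_equal(fr$fs_B, 0.996277, tolerance = 1e-6)

  # the tabulated monoanion column is reproduced throughout; the tabulated
  # dianion column carries last-digit slop of up to ~4.4e-4 in its source
  t2 <- tc_table2()
  fr <- tc_bound_species_fractions(t2$pH)
  expect_lt(max(abs(fr$fs_HB - t2$fs_HB)), 1e-4)
  expect_lt(max(abs(fr$fs_B - t2$fs_B)), 5e-4)

  none <- tc_bound_species_fractions(7.5, micelle_distribution(0, 0, 0))
  expect_equal(none$fs_H2B + none$fs_HB + none$fs_B, 0)
})

test_that("bound and free fractions partition all UCB", {
  fr <- tc_bound_species_fractions(seq(5, 12, by = 0.5))
  total <- fr$fs_H2B + fr$fs_HB + fr$fs_B + fr$ff_H2B + fr$ff_HB + fr$ff_B
  expect_lt(max(abs(total - 1)), 1e-14)
  expect_true(all(diff(fr$fs_B) > 0))
  # monoanion pool peaks and then declines as the dianion takes over
  late <- fr$fs_HB[fr$pH >= 7.5]
  expect_true(all(diff(late) < 0))
})

test_that("apparent pKa values shift by the log ratio of uptake", {
  expect_equal(apparent_pKa(8.12, 1.41, 12.9), 7.16, tolerance = 0.005 / 7.16)
  expect_equal(apparent_pKa(8.44, 12.9, 730), 6.69, tolerance = 0.005 / 6.69)
  expect_equal(apparent_pKa(16.56, 1.41, 730), 13.85,
               tolerance = 0.005 / 13.85)
  # equal uptake leaves the pKa untouched
  expect_equal(apparent_pKa(8.12, 5, 5), 8.12)
  # exact sum rule
  expect_equal(apparent_pKa(8.12, 1.41, 12.9) + apparent_pKa(8.44, 12.9, 730),
               apparent_pKa(16.56, 1.41, 730), tolerance = 1e-12)
  expect_error(apparent_pKa(8.12, 0, 5), class = "bilispec_domain_error")
})

test_that("apparent pKa equals the pH of equal bound adjacent species", {
  dist <- micelle_distribution()
  cross <- function(f1, f2) {
    stats::uniroot(function(p) {
      fr <- tc_bound_species_fractions(p, dist)
      fr[[f1]] - fr[[f2]]
    }, c(2, 12), tol = 1e-10)$root
  }
  expect_equal(cross("fs_H2B", "fs_HB"), apparent_pKa(8.12, 1.41, 12.9),
               tolerance = 1e-6)
  expect_equal(cross("fs_HB", "fs_B"), apparent_pKa(8.44, 12.9, 730),
               tolerance = 1e-6)
})

test_that("the log partition profile has the right limits", {
  p <- tc_partition_params(logPo = 2, A = 5, B = 20)
  expect_equal(tc_log_partition(1, p), 2, tolerance = 1e-4)       # acid limit
  expect_equal(tc_log_partition(5, p), 2 - log10(2), tolerance = 1e-6)
  # default constants at pH = A: bracket is 2 + 10^0.64
  expect_equal(tc_log_partition(7.36), -log10(2 + 10^0.64), tolerance = 1e-9)
  # partition falls monotonically as ionization rises
  expect_true(all(diff(tc_log_partition(seq(4, 11, 0.5))) < 0))
})

test_that("two-component ellipticity model predicts and fits", {
  expect_identical(tc_predict_ellipticity(0, 0), 0)
  expect_identical(tc_predict_ellipticity(0, 1, B_star = 5.24), 5.24)
  expect_equal(tc_predict_ellipticity(0.1661, 0.5790, -98.73, 5.237),
               -13.36, tolerance = 1e-3)

  fit <- fit_tc_ellipticity(tc_table2())
  expect_equal(fit$A_star, -98.7, tolerance = 0.1 / 98.7)
  expect_equal(fit$B_star, 5.24, tolerance = 0.01 / 5.24)
  expect_equal(fit$A_se, 5.6, tolerance = 0.02)
  expect_equal(fit$B_se, 0.54, tolerance = 0.02)
  expect_equal(fit$r, 0.992, tolerance = 5e-4)
  expect_equal(fit$sd, 1.1, tolerance = 0.01)
  expect_identical(fit$n, 7L)
})

test_that("noise-free synthetic ellipticity data are fit exactly", {
  d <- gen_tc_dataset(A_star = -98.7, B_star = 5.24, sd = 0)
  fit <- fit_tc_ellipticity(d)
  expect_equal(fit$A_star, -98.7, tolerance = 1e-10)
  expect_equal(fit$B_star, 5.24, tolerance = 1e-10)

  # collinear design (duplicated composition) is rejected
  bad <- data.frame(fs_HB = c(0.1, 0.1), fs_B = c(0.5, 0.5),
                    theta = c(-5, -4))
  expect_error(fit_tc_ellipticity(bad), class = "bilispec_validation_error")
  expect_error(fit_tc_ellipticity(d[1, ]), class = "bilispec_validation_error")
})

test_that("ellipticity rescaling is linear and invertible", {
  expect_equal(scale_ellipticity(-12.60, 4.6, 34), -12.60 * 34 / 4.6)
  expect_equal(scale_ellipticity(5.5, 34, 34), 5.5)
  expect_equal(scale_ellipticity(scale_ellipticity(3.2, 4.6, 34), 34, 4.6),
               3.2, tolerance = 1e-12)
  expect_error(scale_ellipticity(1, 0, 34), class = "bilispec_domain_error")
})
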