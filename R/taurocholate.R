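#' Micelle/water distribution ratios
#'
#' Per-species bound/free distribution ratios of UCB in a micellar bile
#' salt solution. Defaults are the 50 mM taurocholate values: 1.41 (H2B),
#' 12.9 (HB-), 730 (B=) -- the dianion binds ~500x more avidly than the
#' diacid, which is what shifts the apparent pKa values downward.
#'
#' @param K_H2B,K_HB,K_B distribution ratios, dimensionless, >= 0.
#' @return An object of class `"micelle_distribution"`.
#' @export
micelle_distribution <- function(K_H2B = 1.41, K_HB = 12.9, K_B = 730) {
  check_scalar(K_H2B, "K_H2B", min = 0)
  check_scalar(K_HB, "K_HB", min = 0)
  check_scalar(K_B, "K_B", min = 0)
  structure(list(K_H2B = K_H2B, K_HB = K_HB, K_B = K_B),
            class = "micelle_distribution")
}

#' Fractions of total UCB bound to micelles, per species
#'
#' With `x = 10^(pH - pKa1)` and `y = 10^(2 pH - pKa1 - pKa2)`, the total
#' pool (free + bound, in units of free \[H2B\]) is
#' `T = (1 + K_H2B) + (1 + K_HB) x + (1 + K_B) y`, and the fraction of
#' *total* UCB present bound as each species is `K_H2B/T`, `K_HB x/T`,
#' `K_B y/T`. The free fractions (`1/T`, `x/T`, `y/T`) are returned too;
#' all six sum to 1 exactly.
#'
#' @param pH numeric vector of pH values.
#' @param dist a [micelle_distribution()].
#' @param ks an [ionization_constants()] object (aqueous pKa values).
#' @return Data frame with columns `pH`, `fs_H2B`, `fs_HB`, `fs_B` (bound)
#'   and `ff_H2B`, `ff_HB`, `ff_B` (free).
#' @examples
#' tc_bound_species_fractions(7.23)  # fs_HB 0.1661, fs_B 0.5794
#' @export
tc_bound_species_fractions <- function(pH, dist = micelle_distribution(),
                                       ks = ionization_constants()) {
  check_ph(pH)
  stopifnot(inherits(dist, "micelle_distribution"))
  s <- speciation_xy(pH, ks)
  T <- (1 + dist$K_H2B) + (1 + dist$K_HB) * s$x + (1 + dist$K_B) * s$y
  data.frame(
    pH = pH,
    fs_H2B = dist$K_H2B / T,
    fs_HB = dist$K_HB * s$x / T,
    fs_B = dist$K_B * s$y / T,
    ff_H2B = 1 / T,
    ff_HB = s$x / T,
    ff_B = s$y / T
  )
}

#' Apparent pKa shift from preferential micellar uptake
#'
#' A micelle that takes up the more-ionized species preferentially makes
#' the acid look stronger: the apparent pKa of the bound pool is
#' \deqn{pKa_{app} = pKa_{aq} + \log_{10}(K_{up}/K_{down})}
#' where `K_up`/`K_down` are the distribution ratios of the less/more
#' ionized species of the step. Equivalently, the apparent pKa is the pH at
#' which equal amounts of the two adjacent species are micelle-bound.
#' With the taurocholate defaults: 7.16 for pKa1 (from 8.12), 6.69 for
#' pKa2 (from 8.44), 13.85 for the sum (from 16.56, using K_H2B/K_B).
#'
#' @param pKa_aq aqueous pKa of the ionization step (or sum of steps).
#' @param K_upstream distribution ratio of the less ionized species (> 0).
#' @param K_downstream distribution ratio of the more ionized species (> 0).
#' @return Single apparent pKa value.
#' @examples
#' apparent_pKa(8.12, 1.41, 12.9)   # 7.16
#' apparent_pKa(8.44, 12.9, 730)    # 6.69
#' apparent_pKa(16.56, 1.41, 730)   # 13.85 (sum)
#' @export
apparent_pKa <- function(pKa_aq, K_upstream, K_downstream) {
  check_scalar(pKa_aq, "pKa_aq")
  check_scalar(K_upstream, "K_upstream")
  check_scalar(K_downstream, "K_downstream")
  if (K_upstream <= 0 || K_downstream <= 0) {
    stop_domain("distribution ratios must be > 0")
  }
  pKa_aq + log10(K_upstream / K_downstream)
}

#' Micelle partition-equation parameters
#'
#' Parameters of the pH profile of the micelle/water (or solvent/water)
#' partition coefficient of UCB,
#' `log10 P(pH) = logPo - log10(1 + 10^(pH - A) + 10^(2 pH - B))`,
#' where `Po` is the partition ratio of the diacid and `A`, `B` play the
#' role of the first apparent pKa and the apparent pKa sum of the
#' partitioning system. Defaults: A = 7.36, B = 14.08 (50 mM taurocholate).
#' `logPo` is a free offset (never pinned by the titration shape alone).
#'
#' Note the bracket enters through its base-10 logarithm; the partition
#' coefficient decreases monotonically with pH as the ionized species grow.
#'
#' @param logPo log10 partition ratio of H2B (offset).
#' @param A,B profile constants, dimensionless.
#' @return An object of class `"tc_partition_params"`.
#' @export
tc_partition_params <- function(logPo = 0, A = 7.36, B = 14.08) {
  check_scalar(logPo, "logPo")
  check_scalar(A, "A")
  check_scalar(B, "B")
  structure(list(logPo = logPo, A = A, B = B), class = "tc_partition_params")
}

#' Log partition coefficient vs pH
#'
#' @param pH numeric vector of pH values.
#' @param params a [tc_partition_params()] object.
#' @return Numeric vector of log10 P values.
#' @export
tc_log_partition <- function(pH, params = tc_partition_params()) {
  check_ph(pH)
  stopifnot(inherits(params, "tc_partition_params"))
  params$logPo - log10(1 + 10^(pH - params$A) + 10^(2 * pH - params$B))
}

#' Two-component ellipticity model
#'
#' Predicted circular-dichroism signal of micelle-bound UCB,
#' `10^3 theta = A* fs_HB + B* fs_B`: the micelle-bound monoanion
#' contributes a (large, negative) molar signal `A*` and the bound dianion
#' a (small, positive) `B*`. Defaults are the fitted 50 mM taurocholate
#' coefficients.
#'
#' @param fs_HB,fs_B fractions of total UCB bound as monoanion / dianion.
#' @param A_star,B_star species signal coefficients, 10^3 theta units.
#' @return Numeric vector of predicted 10^3 theta.
#' @export
tc_predict_ellipticity <- function(fs_HB, fs_B, A_star = -98.7,
                                   B_star = 5.24) {
  A_star * fs_HB + B_star * fs_B
}

#' Fit the two-component ellipticity model
#'
#' No-intercept least squares of observed `10^3 theta` on the two
#' bound-fraction columns (see [lstsq_no_intercept()]); `r` is the Pearson
#' correlation of observed vs fitted values and `sd` the residual SD with
#' an n - 2 denominator.
#'
#' @param data data frame with numeric columns `fs_HB`, `fs_B`, `theta`
#'   (at least 2 rows, fractions not collinear).
#' @return An object of class `"tc_ellipticity_fit"`: list with `A_star`,
#'   `B_star`, their standard errors `A_se`, `B_se`, `r`, `sd`, `n`, and
#'   the underlying `fit`.
#' @examples
#' fit_tc_ellipticity(tc_table2())  # A* = -98.7, B* = 5.24
#' @export
fit_tc_ellipticity <- function(data) {
  if (!is.data.frame(data) ||
      !all(c("fs_HB", "fs_B", "theta") %in% names(data))) {
    stop_validation("`data` must have columns `fs_HB`, `fs_B`, `theta`")
  }
  if (nrow(data) < 2L) stop_validation("need at least 2 points to fit")
  fit <- lstsq_no_intercept(
    cbind(fs_HB = data$fs_HB, fs_B = data$fs_B), data$theta
  )
  structure(
    list(
      A_star = unname(fit$coefficients["fs_HB"]),
      B_star = unname(fit$coefficients["fs_B"]),
      A_se = unname(fit$se["fs_HB"]),
      B_se = unname(fit$se["fs_B"]),
      r = fit$r, sd = fit$sd, n = fit$n, fit = fit
    ),
    class = "tc_ellipticity_fit"
  )
}

#' @export
print.tc_ellipticity_fit <- function(x, ...) {
  cat(sprintf(
    "Micellar UCB ellipticity fit (n = %d): A* = %.1f +/- %.1f, B* = %.2f +/- %.2f, r = %.3f, SD = %.2f\n",
    x$n, x$A_star, x$A_se, x$B_star, x$B_se, x$r, x$sd))
  invisible(x)
}

#' Rescale an ellipticity to a different UCB concentration
#'
#' CD signals measured at different total UCB concentrations are made
#' comparable by linear scaling, `theta * to_conc / from_conc` (signal
#' proportional to chromophore concentration).
#'
#' @param theta observed signal(s).
#' @param from_conc concentration at which `theta` was measured, uM (> 0).
#' @param to_conc target concentration, uM.
#' @return Rescaled signal(s).
#' @export
scale_ellipticity <- function(theta, from_conc, to_conc) {
  check_scalar(from_conc, "from_conc")
  if (from_conc <= 0) stop_domain("`from_conc` must be > 0")
  check_scalar(to_conc, "to_conc")
  theta * to_conc / from_conc
}

#' Reference taurocholate ellipticity table
#'
#' The packaged seven-point 50 mM taurocholate CD dataset: pH, total UCB
#' (uM), experimental `10^3 theta` at 458 nm (values measured at 4.6 uM
#' already scaled by 34/4.6 to the 34 uM basis), the bound-species
#' fractions `fs_HB`/`fs_B` as tabulated, and the tabulated model signal.
#'
#' @return Data frame with columns `pH`, `ucb_uM`, `theta`, `fs_HB`,
#'   `fs_B`, `theta_calc`.
#' @export
tc_table2 <- function() {
  path <- system.file("extdata", "tc_table2.csv", package = "bilispec",
                      mustWork = TRUE)
  utils::read.csv(path)
}
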