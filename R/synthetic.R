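# Synthetic titration-data generators. Each is a pure function of its
# parameters and seed (the caller's RNG state is left untouched), and with
# sd = 0 returns the exact model curve of the corresponding analysis stage.

#' Synthetic vesicle titration dataset
#'
#' Draws `nbar_i = predict_nbar(pH_i) + eps_i`, `eps ~ N(0, sd)`. By
#' default the Gaussian noise is left unclipped: truncating at the
#' physical bounds would bias the per-point ratio estimator of
#' [fit_vesicle_K()] wherever the model curve is close to zero (pH >~ 9
#' under the default parameters), which defeats the purpose of
#' parameter-recovery simulations. Set `clip = TRUE` to enforce
#' `0 <= nbar <= total_UCB/total_PC` when physically plausible draws are
#' required instead.
#'
#' @param K_dblprime generating distribution constant, uM^-1.
#' @param pH_grid strictly increasing grid within \[4, 12\]; the default
#'   9-point 6.5--9.5 grid mirrors the classical vesicle titration design.
#' @param sys a [vesicle_system()].
#' @param ks an [ionization_constants()] object.
#' @param dim a [dimerization_model()] object.
#' @param sd Gaussian noise SD on nbar (default 0.002, the residual scale
#'   of the reference dataset).
#' @param seed integer seed, or NULL to use the current RNG state.
#' @param clip clip draws to the physical range? Default FALSE (see above).
#' @return Data frame of class `"titration_dataset"` with columns `pH`,
#'   `nbar`; generator parameters attached as attributes.
#' @export
gen_vesicle_dataset <- function(K_dblprime = 0.00932,
                                pH_grid = seq(6.5, 9.5, length.out = 9),
                                sys = vesicle_system(),
                                ks = ionization_constants(),
                                dim = dimerization_model(),
                                sd = 0.002, seed = NULL, clip = FALSE) {
  check_sorted_grid(pH_grid)
  if (any(pH_grid < 4 | pH_grid > 12)) {
    stop_validation("`pH_grid` must lie within [4, 12]")
  }
  check_scalar(sd, "sd", min = 0)
  mu <- predict_nbar(pH_grid, K_dblprime, sys, ks, dim)
  nbar <- with_seed(seed, mu + stats::rnorm(length(mu), 0, sd))
  if (clip) {
    nbar <- pmin(pmax(nbar, 0), sys$total_UCB / sys$total_PC)
  }
  out <- data.frame(pH = pH_grid, nbar = nbar)
  class(out) <- c("titration_dataset", "data.frame")
  attr(out, "observable") <- "nbar"
  attr(out, "params") <- list(K_dblprime = K_dblprime, sd = sd, seed = seed,
                              clip = clip)
  out
}

#' Synthetic taurocholate ellipticity dataset
#'
#' `theta_i = A* fs_HB(pH_i) + B* fs_B(pH_i) + eps_i`, with the bound
#' fractions from [tc_bound_species_fractions()]. The default grid is the
#' seven reference pH values; the default noise SD (1.1) is the residual
#' scale of the reference fit.
#'
#' @param A_star,B_star generating coefficients.
#' @param dist a [micelle_distribution()].
#' @param ks an [ionization_constants()] object.
#' @param pH_grid strictly increasing grid within \[4, 12\].
#' @param sd Gaussian noise SD on theta.
#' @param seed integer seed, or NULL.
#' @return Data frame of class `"titration_dataset"` with columns `pH`,
#'   `fs_HB`, `fs_B`, `theta`.
#' @export
gen_tc_dataset <- function(A_star = -98.7, B_star = 5.24,
                           dist = micelle_distribution(),
                           ks = ionization_constants(),
                           pH_grid = c(7.23, 7.35, 8.13, 8.15, 9.12, 9.35,
                                       11.60),
                           sd = 1.1, seed = NULL) {
  check_sorted_grid(pH_grid)
  check_scalar(sd, "sd", min = 0)
  fr <- tc_bound_species_fractions(pH_grid, dist, ks)
  mu <- tc_predict_ellipticity(fr$fs_HB, fr$fs_B, A_star, B_star)
  theta <- with_seed(seed, mu + stats::rnorm(length(mu), 0, sd))
  out <- data.frame(pH = pH_grid, fs_HB = fr$fs_HB, fs_B = fr$fs_B,
                    theta = theta)
  class(out) <- c("titration_dataset", "data.frame")
  attr(out, "observable") <- "theta"
  attr(out, "params") <- list(A_star = A_star, B_star = B_star, sd = sd,
                              seed = seed)
  out
}

#' Synthetic cyclodextrin ellipticity dataset
#'
#' `delta_eps_i = cdx_predict_ellipticity(pH_i) + eps_i` over a sigmoidal
#' titration grid (default pH 5.5--10.8).
#'
#' @param Q generating signal coefficient (per uM free dianion); the
#'   system's Q is overridden by this value.
#' @param sys a [cdx_system()].
#' @param ks an [ionization_constants()] object.
#' @param dim a [dimerization_model()] object.
#' @param pH_grid strictly increasing grid within \[4, 12\].
#' @param sd Gaussian noise SD on delta-epsilon.
#' @param seed integer seed, or NULL.
#' @return Data frame of class `"titration_dataset"` with columns `pH`,
#'   `delta_eps`.
#' @export
gen_cdx_dataset <- function(Q = 1.099, sys = cdx_system(),
                            ks = ionization_constants(),
                            dim = dimerization_model(),
                            pH_grid = seq(5.5, 10.8, length.out = 22),
                            sd = 0, seed = NULL) {
  check_sorted_grid(pH_grid)
  check_scalar(sd, "sd", min = 0)
  sys$Q <- Q
  mu <- cdx_predict_ellipticity(pH_grid, sys, ks, dim)
  de <- with_seed(seed, mu + stats::rnorm(length(mu), 0, sd))
  out <- data.frame(pH = pH_grid, delta_eps = de)
  class(out) <- c("titration_dataset", "data.frame")
  attr(out, "observable") <- "delta_eps"
  attr(out, "params") <- list(Q = Q, sd = sd, seed = seed)
  out
}
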