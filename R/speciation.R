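#' Ionization constants of a diprotic acid
#'
#' Bundles the two successive acid dissociation constants that govern the
#' speciation of unconjugated bilirubin (UCB) between its diacid (H2B),
#' monoanion (HB-) and dianion (B=) forms. The package default is the
#' solvent-partition pair pKa1 = 8.12, pKa2 = 8.44; the widely quoted low
#' pair 4.2/4.9 is accepted as well (the two are compared throughout the
#' package). Note pKa1 <= pKa2 is *not* required.
#'
#' @param pKa1 first ionization constant (H2B -> HB-), dimensionless.
#' @param pKa2 second ionization constant (HB- -> B=), dimensionless.
#' @return An object of class `"ionization_constants"` with fields `pKa1`,
#'   `pKa2` and the derived `K1 = 10^-pKa1`, `K2 = 10^-pKa2`.
#' @examples
#' ionization_constants()            # high (partition-derived) pair
#' ionization_constants(4.2, 4.9)    # low literature pair
#' @export
ionization_constants <- function(pKa1 = 8.12, pKa2 = 8.44) {
  check_scalar(pKa1, "pKa1")
  check_scalar(pKa2, "pKa2")
  structure(
    list(pKa1 = pKa1, pKa2 = pKa2, K1 = 10^(-pKa1), K2 = 10^(-pKa2)),
    class = "ionization_constants"
  )
}

#' @export
print.ionization_constants <- function(x, ...) {
  cat(sprintf("Diprotic ionization constants: pKa1 = %g, pKa2 = %g (sum %g)\n",
              x$pKa1, x$pKa2, x$pKa1 + x$pKa2))
  invisible(x)
}

#' Dianion dimerization model
#'
#' Self-association of two B= dianions into a dimer, with equilibrium
#' constant `KD` in 1/uM so that `[dimer] = KD * [B=]^2`. The default 0.26
#' is the partition-derived value for UCB.
#'
#' @param KD dimerization constant, 1/uM; `KD = 0` disables dimerization.
#' @return An object of class `"dimerization_model"`.
#' @export
dimerization_model <- function(KD = 0.26) {
  check_scalar(KD, "KD", min = 0)
  structure(list(KD = KD), class = "dimerization_model")
}

#' Diacid solubility model
#'
#' pH-independent solubility of the fully protonated diacid H2B (`S_H2B`,
#' uM) together with the pKa sum entering the dianion saturation relation
#' `[B=]sat = S_H2B * 10^(2 pH - pKa_sum)`. Defaults: 0.051 uM and 16.56.
#'
#' @param S_H2B solubility of H2B, uM.
#' @param pKa_sum pKa1 + pKa2, dimensionless.
#' @return An object of class `"solubility_model"`.
#' @export
solubility_model <- function(S_H2B = 0.051, pKa_sum = 16.56) {
  check_scalar(S_H2B, "S_H2B")
  if (S_H2B <= 0) stop_domain("`S_H2B` must be > 0")
  check_scalar(pKa_sum, "pKa_sum")
  structure(list(S_H2B = S_H2B, pKa_sum = pKa_sum), class = "solubility_model")
}

# shared speciation kernel: x = [HB-]/[H2B], y = [B=]/[H2B]
speciation_xy <- function(pH, ks) {
  list(
    x = 10^(pH - ks$pKa1),
    y = 10^(2 * pH - ks$pKa1 - ks$pKa2)
  )
}

#' Fractions of the unbound monomeric UCB species
#'
#' At a given pH, the unbound monomeric pool splits into the diacid,
#' monoanion and dianion according to
#' \deqn{f_{H2B} = 1/D, \quad f_{HB^-} = (K_1/[H^+])/D, \quad
#'       f_{B^=} = (K_1 K_2/[H^+]^2)/D}
#' with \eqn{D = 1 + K_1/[H^+] + K_1 K_2/[H^+]^2}. The three fractions sum
#' to 1 at every pH.
#'
#' @param pH numeric vector of pH values (finite).
#' @param ks an [ionization_constants()] object.
#' @return A data frame with columns `pH`, `fH2B`, `fHB`, `fB`.
#' @examples
#' species_fractions(5.0, ionization_constants(4.2, 4.9))
#' @export
species_fractions <- function(pH, ks = ionization_constants()) {
  check_ph(pH)
  stopifnot(inherits(ks, "ionization_constants"))
  s <- speciation_xy(pH, ks)
  D <- 1 + s$x + s$y
  data.frame(pH = pH, fH2B = 1 / D, fHB = s$x / D, fB = s$y / D)
}

#' Species-fraction table over a pH grid
#'
#' Convenience wrapper around [species_fractions()] that validates the grid
#' (non-empty, strictly increasing) and returns a printable table. All
#' values are kept at full precision; rounding to 4 decimals happens only
#' in the print method.
#'
#' @param pH_grid strictly increasing numeric vector of pH values.
#' @inheritParams species_fractions
#' @return A data frame of class `"fraction_table"`.
#' @examples
#' fraction_table(seq(4, 10, by = 0.5), ionization_constants(4.2, 4.9))
#' @export
fraction_table <- function(pH_grid, ks = ionization_constants()) {
  if (length(pH_grid) == 0L) stop_validation("`pH_grid` must be non-empty")
  check_sorted_grid(pH_grid)
  out <- species_fractions(pH_grid, ks)
  class(out) <- c("fraction_table", "data.frame")
  attr(out, "ks") <- ks
  out
}

#' @export
print.fraction_table <- function(x, digits = 4, ...) {
  ks <- attr(x, "ks")
  cat(sprintf("Unbound monomeric UCB species fractions (pKa %g/%g)\n",
              ks$pKa1, ks$pKa2))
  fmt <- as.data.frame(lapply(x[c("fH2B", "fHB", "fB")], function(col) {
    ifelse(col >= 10^(-digits) / 2,
           formatC(col, format = "f", digits = digits),
           formatC(col, format = "e", digits = 2))
  }))
  print(cbind(pH = format(x$pH), fmt), row.names = FALSE)
  invisible(x)
}

#' Free monomer composition from total unbound UCB
#'
#' Splits a total unbound UCB concentration into the free monomeric species
#' and the dianion dimer. Mass balance (each dimer counts as 2 monomer
#' units):
#' \deqn{B_f = [H_2B] D + 2 K_D [B^=]^2, \qquad [B^=] = [H_2B]\,K_1K_2/[H^+]^2}
#' which is a quadratic in \eqn{[H_2B]}; the unique non-negative root is
#' taken with the numerically stable form
#' `cH2B = 2 total / (D + sqrt(D^2 + 8 KD y^2 total))` (no cancellation when
#' the dimer term vanishes). With `KD = 0` this reduces exactly to
#' `total * species_fractions()`.
#'
#' @param total_free total unbound UCB, uM (monomer units; >= 0). Recycled
#'   against `pH`.
#' @param pH numeric vector of pH values.
#' @param ks an [ionization_constants()] object.
#' @param dim a [dimerization_model()] object.
#' @return A data frame of class `"monomer_composition"` with columns
#'   `pH`, `cH2B`, `cHB`, `cB`, `cDimer`, `total_free` (all uM).
#' @seealso [composition_total()] for the inverse mass balance.
#' @examples
#' monomer_composition(5.1, 6.54)  # diacid-dominated at this pH
#' @export
monomer_composition <- function(total_free, pH,
                                ks = ionization_constants(),
                                dim = dimerization_model()) {
  if (!is.numeric(total_free) || any(!is.finite(total_free))) {
    stop_domain("`total_free` must be numeric and finite")
  }
  if (any(total_free < 0)) stop_domain("`total_free` must be >= 0")
  check_ph(pH)
  s <- speciation_xy(pH, ks)
  D <- 1 + s$x + s$y
  disc <- D^2 + 8 * dim$KD * s$y^2 * total_free
  cH2B <- 2 * total_free / (D + sqrt(disc))
  cB <- cH2B * s$y
  out <- data.frame(
    pH = pH,
    cH2B = cH2B,
    cHB = cH2B * s$x,
    cB = cB,
    cDimer = dim$KD * cB^2,
    total_free = total_free + numeric(length(cH2B))
  )
  class(out) <- c("monomer_composition", "data.frame")
  out
}

#' Total unbound UCB implied by a monomer composition
#'
#' Inverse of [monomer_composition()]: sums the free species plus twice the
#' dimer (each dimer holds two monomer units).
#'
#' @param comp a `"monomer_composition"` data frame.
#' @return Numeric vector of totals, uM.
#' @export
composition_total <- function(comp) {
  stopifnot(inherits(comp, "monomer_composition"))
  comp$cH2B + comp$cHB + comp$cB + 2 * comp$cDimer
}

#' Total solubility of monomeric UCB vs pH
#'
#' When the solution is saturated, the diacid concentration is pinned at
#' `S_H2B` and the total monomeric solubility follows
#' \deqn{S_t(pH) = S_{H2B}\,(1 + 10^{pH - pKa_1} + 10^{2pH - (pKa_1+pKa_2)})}
#' Defaults give 0.062 uM at pH 7.40 rising to 0.148 uM at pH 8.2.
#'
#' @param pH numeric vector of pH values.
#' @param sol a [solubility_model()] object.
#' @param ks an [ionization_constants()] object (supplies pKa1; the pKa sum
#'   comes from `sol`).
#' @return Numeric vector, uM.
#' @export
total_solubility <- function(pH, sol = solubility_model(),
                             ks = ionization_constants()) {
  check_ph(pH)
  sol$S_H2B * (1 + 10^(pH - ks$pKa1) + 10^(2 * pH - sol$pKa_sum))
}

#' Saturation concentration of the free dianion
#'
#' At saturation the free dianion obeys
#' `[B=]sat = S_H2B * 10^(2 pH - pKa_sum)`; with the defaults,
#' `0.051 * 10^(2 pH - 16.56)` uM.
#'
#' @inheritParams total_solubility
#' @return Numeric vector, uM.
#' @export
dianion_saturation <- function(pH, sol = solubility_model()) {
  check_ph(pH)
  sol$S_H2B * 10^(2 * pH - sol$pKa_sum)
}

#' Supersaturation ratio
#'
#' `R = Bf / St(pH)`, the free UCB concentration over the equilibrium
#' total solubility at that pH. `R > 1` flags a (possibly metastable)
#' supersaturated solution.
#'
#' @param free_total free (unbound) UCB concentration, uM; >= 0.
#' @inheritParams total_solubility
#' @return Numeric vector, dimensionless.
#' @examples
#' saturation_ratio(20.3, 7.0)  # ~369: strongly supersaturated
#' @export
saturation_ratio <- function(free_total, pH, sol = solubility_model(),
                             ks = ionization_constants()) {
  if (!is.numeric(free_total) || any(!is.finite(free_total)) ||
      any(free_total < 0)) {
    stop_domain("`free_total` must be numeric, finite and >= 0")
  }
  free_total / total_solubility(pH, sol, ks)
}
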