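#' Single-species host binding model
#'
#' Binding of UCB to a pH-insensitive host under the assumption that a
#' single ionization species is bound, described by a distribution ratio
#' `K = mols bound / mols free` of that species. The fraction of *total*
#' UCB bound is then `F = K f / (K f + 1)` where `f` is the unbound
#' fraction of the bound species at that pH.
#'
#' @param species which species the host binds: `"H2B"` (diacid, e.g.
#'   phosphatidylcholine vesicles), `"HB"` (monoanion) or `"B"` (dianion,
#'   e.g. dodecylmaltoside micelles or cyclodextrins).
#' @param K distribution ratio, dimensionless, >= 0.
#' @return An object of class `"host_binding_model"`.
#' @export
host_binding_model <- function(species = c("H2B", "HB", "B"), K) {
  species <- match.arg(species)
  check_scalar(K, "K", min = 0)
  structure(list(species = species, K = K), class = "host_binding_model")
}

species_fraction_of <- function(pH, species, ks) {
  fr <- species_fractions(pH, ks)
  switch(species, H2B = fr$fH2B, HB = fr$fHB, B = fr$fB)
}

#' Fraction of total UCB bound to a host
#'
#' `F(pH) = K f(pH) / (K f(pH) + 1)`, bounded above by the asymptotic
#' maximum `F_max = K/(K+1)` reached where the bound species' fraction
#' approaches 1.
#'
#' @param pH numeric vector of pH values.
#' @param model a [host_binding_model()].
#' @param ks an [ionization_constants()] object.
#' @return Numeric vector of bound fractions in \[0, 1\].
#' @export
bound_fraction <- function(pH, model, ks = ionization_constants()) {
  stopifnot(inherits(model, "host_binding_model"))
  f <- species_fraction_of(pH, model$species, ks)
  model$K * f / (model$K * f + 1)
}

# Asymptotic maximum of F over pH. For H2B and B the bound species'
# fraction tends to 1; for HB it peaks at x = 10^((pKa2-pKa1)/2).
f_species_max <- function(species, ks) {
  if (species == "HB") {
    xs <- 10^((ks$pKa2 - ks$pKa1) / 2)
    xs / (2 + xs)
  } else {
    1
  }
}

f_asymptote <- function(model, ks) {
  fm <- f_species_max(model$species, ks)
  model$K * fm / (model$K * fm + 1)
}

# Closed-form pH at which the species fraction equals fstar, via the
# quadratic in x = 10^(pH - pKa1) with c = 10^(pKa1 - pKa2). Roots are
# computed in the cancellation-free (q-method) form so that extreme K
# values (fstar near 0) and widely split pKa pairs (c near 0) stay
# accurate. For HB (non-monotone) the ascending-branch root is returned.
ph_at_fraction <- function(species, fstar, ks) {
  cc <- 10^(ks$pKa1 - ks$pKa2)
  x <- switch(
    species,
    H2B = {
      # c x^2 + x - A = 0,  A = 1/fstar - 1 > 0
      A <- 1 / fstar - 1
      2 * A / (1 + sqrt(1 + 4 * cc * A))
    },
    B = {
      # c (1 - fstar) x^2 - fstar x - fstar = 0
      (fstar + sqrt(fstar^2 + 4 * cc * (1 - fstar) * fstar)) /
        (2 * cc * (1 - fstar))
    },
    HB = {
      # fstar c x^2 - (1 - fstar) x + fstar = 0; smaller root
      disc <- (1 - fstar)^2 - 4 * cc * fstar^2
      if (disc < 0) stop_numerical("no crossing: fstar above the HB- maximum")
      2 * fstar / ((1 - fstar) + sqrt(disc))
    }
  )
  ks$pKa1 + log10(x)
}

#' Midpoint pH of a host binding curve
#'
#' Solves `F(pH) = F_max / 2`, where `F_max = K f_max/(K f_max + 1)` is the
#' asymptotic maximum of the bound fraction (with `f_max = 1` for H2B- and
#' B=-binding hosts). Stronger H2B binding pushes the midpoint *above* the
#' pKa values; stronger B= binding pushes it *below* -- the basis for
#' reading distribution ratios off titration midpoints.
#'
#' The closed form reduces to a quadratic in `x = 10^(pH - pKa1)`; the
#' bisection route solves the same equation with [stats::uniroot()] to
#' 1e-10 and serves as an internal cross-check. For the non-monotone HB-
#' curve the ascending-branch (lower-pH) crossing is reported.
#'
#' @param model a [host_binding_model()] with `K > 0`.
#' @param ks an [ionization_constants()] object.
#' @param method `"closed_form"` (default) or `"bisection"`.
#' @return An object of class `"midpoint_result"`: a list with
#'   `midpoint_pH`, `F_max`, `method`.
#' @examples
#' midpoint_pH(host_binding_model("H2B", 100))   # 9.251
#' midpoint_pH(host_binding_model("B", 1000))    # 6.790
#' @export
midpoint_pH <- function(model, ks = ionization_constants(),
                        method = c("closed_form", "bisection")) {
  stopifnot(inherits(model, "host_binding_model"))
  method <- match.arg(method)
  if (model$K <= 0) stop_domain("`K` must be > 0 for a midpoint")
  Fmax <- f_asymptote(model, ks)
  # F = Fmax/2  <=>  f = fmax / (K fmax + 2)
  fm <- f_species_max(model$species, ks)
  fstar <- fm / (model$K * fm + 2)
  if (method == "closed_form") {
    mid <- ph_at_fraction(model$species, fstar, ks)
  } else {
    g <- function(p) species_fraction_of(p, model$species, ks) - fstar
    lo <- 0; hi <- 14
    if (model$species != "HB") {
      while (g(lo) * g(hi) > 0 && hi < 30) { lo <- lo - 2; hi <- hi + 2 }
    } else {
      hi <- (ks$pKa1 + ks$pKa2) / 2  # ascending branch ends at the peak
      while (g(lo) > 0 && lo > -10) lo <- lo - 2
    }
    if (g(lo) * g(hi) > 0) {
      stop_numerical("bisection bracket does not enclose the midpoint")
    }
    mid <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  }
  structure(
    list(midpoint_pH = mid, F_max = Fmax, method = method),
    class = "midpoint_result"
  )
}

#' @export
print.midpoint_result <- function(x, ...) {
  cat(sprintf("Midpoint pH %.4f (F_max = %.4f, %s)\n",
              x$midpoint_pH, x$F_max, x$method))
  invisible(x)
}

#' Limiting midpoint pH in the weak-binding limit
#'
#' As `K -> 0` the binding curve shadows the species fraction itself and
#' the midpoint converges to the pH at which the species' unbound fraction
#' equals half of its own maximum over pH (the maximum is 1 for H2B and B;
#' for HB it is the peak value of the monoanion fraction).
#'
#' @param species `"H2B"`, `"HB"` or `"B"`.
#' @param ks an [ionization_constants()] object.
#' @return Single pH value.
#' @examples
#' limiting_midpoint("B")    # 8.572 under the high pKa pair
#' limiting_midpoint("H2B")  # 7.989
#' @export
limiting_midpoint <- function(species = c("H2B", "HB", "B"),
                              ks = ionization_constants()) {
  species <- match.arg(species)
  ph_at_fraction(species, f_species_max(species, ks) / 2, ks)
}

#' Binding curve over a pH grid
#'
#' Element-wise [bound_fraction()] over a sorted grid, with the
#' monotonicity expected of single-species binding (decreasing for an
#' H2B-binding host, increasing for a B=-binding host) verified.
#'
#' @param model a [host_binding_model()].
#' @param ks an [ionization_constants()] object.
#' @param pH_grid strictly increasing numeric vector.
#' @return A data frame of class `"binding_curve"` with columns `pH`, `F`.
#' @export
binding_curve <- function(model, ks = ionization_constants(), pH_grid) {
  check_sorted_grid(pH_grid)
  F <- bound_fraction(pH_grid, model, ks)
  if (model$species == "H2B" && is.unsorted(rev(F))) {
    stop_numerical("H2B binding curve must be non-increasing in pH")
  }
  if (model$species == "B" && is.unsorted(F)) {
    stop_numerical("B= binding curve must be non-decreasing in pH")
  }
  out <- data.frame(pH = pH_grid, F = F)
  class(out) <- c("binding_curve", "data.frame")
  attr(out, "model") <- model
  out
}
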