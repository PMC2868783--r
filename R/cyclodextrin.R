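#' Beta-cyclodextrin system
#'
#' Parameters of a UCB / beta-cyclodextrin (CDx) ellipticity titration.
#' The host cavity binds the UCB dianion; the circular-dichroism signal is
#' proportional to the free monomeric dianion, `delta_eps = Q * [B=]f`.
#' Defaults: affinity 23 L/mol, 10 mM CDx, 25 uM total UCB, Q = 1.099 per
#' uM (Q is a shipped configuration constant, not refit here).
#'
#' @param affinity binding affinity constant, L/mol.
#' @param cdx_conc cyclodextrin concentration, mol/L.
#' @param total_UCB total UCB, uM.
#' @param Q signal coefficient, ellipticity units per uM of free dianion.
#' @return An object of class `"cdx_system"`.
#' @export
cdx_system <- function(affinity = 23, cdx_conc = 0.010, total_UCB = 25,
                       Q = 1.099) {
  for (nm in c("affinity", "cdx_conc", "total_UCB", "Q")) {
    check_scalar(get(nm), nm, min = 0)
  }
  structure(list(affinity = affinity, cdx_conc = cdx_conc,
                 total_UCB = total_UCB, Q = Q),
            class = "cdx_system")
}

#' Bound UCB from the affinity constant
#'
#' With the host in vast excess (10 mM host vs <= 25 uM guest, so host
#' depletion is negligible), the bound fraction is the simple isotherm
#' `Ka C / (1 + Ka C)`. Defaults give 4.67 uM bound, 18.7% of total.
#'
#' @param sys a [cdx_system()].
#' @return List with `bound` (uM), `percent` (%), `fraction`.
#' @export
cdx_bound_from_affinity <- function(sys = cdx_system()) {
  stopifnot(inherits(sys, "cdx_system"))
  frac <- sys$affinity * sys$cdx_conc / (1 + sys$affinity * sys$cdx_conc)
  list(bound = frac * sys$total_UCB, percent = 100 * frac, fraction = frac)
}

# Self-consistent bound amount at one pH. Binding is proportional to the
# free monomeric dianion; the proportionality constant is normalized at
# the anchor pH where the affinity-constant bound fraction applies
# (default pH 10.8, 18.7% bound with the default system).
cdx_bound_at <- function(pH, sys, ks, dim, anchor_pH = 10.8) {
  anchor <- cdx_bound_from_affinity(sys)
  cB_anchor <- monomer_composition(sys$total_UCB - anchor$bound, anchor_pH,
                                   ks, dim)$cB
  kb <- anchor$bound / cB_anchor
  vapply(pH, function(p) {
    g <- function(b) {
      b - kb * monomer_composition(sys$total_UCB - b, p, ks, dim)$cB
    }
    stats::uniroot(g, c(0, sys$total_UCB), tol = 1e-12)$root
  }, numeric(1))
}

#' Predicted cyclodextrin ellipticity vs pH
#'
#' `delta_eps = Q * [B=]f`, where the free monomeric dianion `[B=]f` is
#' obtained from the unbound pool `Bf = total_UCB - bound` via
#' [monomer_composition()]. The bound amount is itself proportional to
#' `[B=]f` and is solved self-consistently, normalized so that at
#' `anchor_pH` the bound fraction equals the affinity-constant value of
#' [cdx_bound_from_affinity()]. Supersaturation of the unbound pool is
#' assumed stable (no precipitation); see [cdx_saturated_ellipticity()]
#' for the saturation-capped counterfactual.
#'
#' @param pH numeric vector of pH values.
#' @param sys a [cdx_system()].
#' @param ks an [ionization_constants()] object.
#' @param dim a [dimerization_model()] object.
#' @param anchor_pH pH at which the affinity-constant bound fraction is
#'   imposed (default 10.8).
#' @return Numeric vector of delta-epsilon values.
#' @export
cdx_predict_ellipticity <- function(pH, sys = cdx_system(),
                                    ks = ionization_constants(),
                                    dim = dimerization_model(),
                                    anchor_pH = 10.8) {
  check_ph(pH)
  bound <- cdx_bound_at(pH, sys, ks, dim, anchor_pH)
  cB <- monomer_composition(sys$total_UCB - bound, pH, ks, dim)$cB
  sys$Q * cB
}

#' Saturation-limited cyclodextrin ellipticity
#'
#' The no-supersaturation counterfactual: the free dianion cannot exceed
#' its saturation value `S_H2B * 10^(2 pH - pKa_sum)`, so
#' `delta_eps = Q * [B=]sat`, capped from above by the undersaturated
#' prediction of [cdx_predict_ellipticity()] (the cap is active at high pH
#' where the solution is genuinely undersaturated).
#'
#' @inheritParams cdx_predict_ellipticity
#' @param sol a [solubility_model()] object.
#' @return Numeric vector of delta-epsilon values.
#' @export
cdx_saturated_ellipticity <- function(pH, sys = cdx_system(),
                                      sol = solubility_model(),
                                      ks = ionization_constants(),
                                      dim = dimerization_model()) {
  check_ph(pH)
  pmin(sys$Q * dianion_saturation(pH, sol),
       cdx_predict_ellipticity(pH, sys, ks, dim))
}

#' Fit the ellipticity coefficient Q
#'
#' Proportional (through-origin) least squares of observed delta-epsilon
#' on the free-dianion concentrations implied by the binding model, for
#' synthetic-data parameter recovery. The dianion concentrations depend
#' only on the system/speciation parameters, not on Q itself.
#'
#' @param data data frame with columns `pH` and `delta_eps`.
#' @inheritParams cdx_predict_ellipticity
#' @return An object of class `"lstsq_fit"` (see [lstsq_no_intercept()]);
#'   the fitted Q is `coefficients[1]`.
#' @export
fit_cdx_Q <- function(data, sys = cdx_system(),
                      ks = ionization_constants(),
                      dim = dimerization_model()) {
  if (!is.data.frame(data) || !all(c("pH", "delta_eps") %in% names(data))) {
    stop_validation("`data` must have columns `pH` and `delta_eps`")
  }
  bound <- cdx_bound_at(data$pH, sys, ks, dim)
  cB <- monomer_composition(sys$total_UCB - bound, data$pH, ks, dim)$cB
  lstsq_no_intercept(matrix(cB, ncol = 1, dimnames = list(NULL, "cB")),
                     data$delta_eps)
}
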