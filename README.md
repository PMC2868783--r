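# bilispec

pH-dependent speciation, solubility and host binding of unconjugated
bilirubin (UCB), in R.

## The problem

UCB is a sparingly soluble diprotic acid. At any pH its unbound pool is a
mixture of diacid (H2B), monoanions (HB-) and dianion (B=), with fractions
fixed by its two pKa values:

```
fH2B = 1/D,   fHB = (K1/[H+])/D,   fB = (K1K2/[H+]^2)/D,
D = 1 + K1/[H+] + K1K2/[H+]^2
```

Whether a host (phospholipid vesicle, cyclodextrin, micelle) takes up more
UCB as pH rises or falls depends on *which* species it binds and on the
distribution ratio K = mols bound / mols free of that species: the bound
fraction of total UCB is `F = K f/(K f + 1)`. For hosts that are
themselves indifferent to pH, the shape and midpoint of `F(pH)` therefore
discriminate between the two pKa pairs proposed for UCB — 8.12/8.44 (from
solvent partition) versus 4.2/4.9 (often assumed). The package implements
the full equilibrium machinery: speciation with dianion dimerization
(`[dimer] = KD [B=]^2`), pH-dependent solubility and supersaturation,
binding-curve midpoint analysis, and the specific models for four host
systems, plus synthetic-data generators for parameter-recovery testing.

The models it fits:

* **Vesicles (diacid uptake):** `nbar = K'' [H2B]f`, with `nbar` mols UCB
  bound per mol phospholipid.
* **Beta-cyclodextrin (dianion uptake):** ellipticity
  `delta_eps = Q [B=]f`, anchored to an affinity-constant bound fraction
  at pH 10.8.
* **Taurocholate micelles (all three species):** bound fractions from
  per-species distribution ratios (1.41 / 12.9 / 730 at 50 mM), apparent
  pKa shifts `pKa_app = pKa_aq + log10(K_up/K_down)`, and a two-component
  CD model `10^3 theta = A* fs_HB + B* fs_B` fit by no-intercept least
  squares.

## Worked example

```r
library(bilispec)

# Species fractions under the high pKa pair: all three species matter
# between pH 6.5 and 10
fraction_table(c(6.0, 7.0, 8.0, 9.0))
#> Unbound monomeric UCB species fractions (pKa 8.12/8.44)
#>  pH   fH2B    fHB       fB
#>   6 0.9924 0.0075 2.73e-05
#>   7 0.9271 0.0703   0.0026
#>   8 0.4916 0.3729   0.1354
#>   9 0.0277 0.2100   0.7624

# A dianion-binding host with K' = 730 titrates with a midpoint well
# below the pKa values
midpoint_pH(host_binding_model("B", 730))
#> Midpoint pH 6.8596 (F_max = 0.9986, closed_form)

# Solubility of monomeric UCB barely rises from pH 7.4 to 8.2 (uM):
round(total_solubility(c(7.40, 7.83, 8.05, 8.2)), 3)
#> [1] 0.062 0.084 0.112 0.148

# Vesicle anchor point (pH 6.54, nbar 0.049, free UCB 5.1 uM) under the
# low pKa pair: an absurdly large K'' would be required
fit_vesicle_K(data.frame(pH = 6.54, nbar = 0.049),
              ks = ionization_constants(4.2, 4.9),
              dim = dimerization_model(0))
#> Vesicle diacid partition fit: K'' = 93.866 +/- NA uM^-1 (n = 1)

# Taurocholate: apparent pKa shifts and the two-component CD fit
apparent_pKa(8.12, 1.41, 12.9)   # 7.16
apparent_pKa(8.44, 12.9, 730)    # 6.69
fit_tc_ellipticity(tc_table2())
#> Micellar UCB ellipticity fit (n = 7): A* = -98.7 +/- 5.6,
#>   B* = 5.24 +/- 0.54, r = 0.992, SD = 1.11
```

Reading the output: at the vesicle anchor, the high pKa pair implies
`K'' ~ 0.0099` per uM (the diacid is ~97% of the free pool at pH 6.54),
while the low pair leaves only 0.01% of the pool as diacid and demands
`K'' ~ 94` — and then predicts binding collapsing roughly forty-fold
within one pH unit, unlike any observed vesicle titration. The taurocholate fit
says micelle-bound monoanion contributes a large negative CD signal
(A\* = -98.7) and bound dianion a small positive one (B\* = 5.24), which
reproduces the sign flip of the observed ellipticity near pH 8.

`reproduce_reference()` reruns the package's whole reference-value suite
(26 checks) and returns a pass/fail table.

## Layout

* `R/` — speciation core, binding/midpoint analysis, the three host
  stages, shared no-intercept least squares, synthetic-data generators,
  CSV/JSON I/O.
* `inst/extdata/tc_table2.csv` — the packaged seven-point taurocholate
  CD table (the only tabulated dataset the models consume).
* `vignettes/bilirubin-speciation.Rmd` — the methods vignette: model
  derivations, normalization choices, noise-model rationale, known
  limitations of the reference tables.
* `tests/testthat/` — unit, property and acceptance tests.
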