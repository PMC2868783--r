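# Shared model objects and frozen reference values used across test files.

ks_high <- ionization_constants(8.12, 8.44)
ks_low <- ionization_constants(4.2, 4.9)
dim_ucb <- dimerization_model(0.26)
dim_off <- dimerization_model(0)

# Low-pKa species-fraction reference table (pKa 4.2/4.9), pH 4 to 10 in
# steps of 0.5, as tabulated in the reference source. Two cells are known
# to deviate from the defining formula in their last printed digit (fH2B
# at pH 6.0: formula gives 1.1649e-3; fH2B at pH 10.0: formula gives
# 1.26e-11, an exponent slip in the source); both deviations are far
# below the 1e-4 absolute tolerance used wherever this matrix is compared.
table1_reference <- matrix(c(
  0.5847, 0.3689, 0.0464,
  0.2639, 0.5265, 0.2096,
  0.0656, 0.4137, 0.5208,
  9.96e-03, 0.1988, 0.7913,
  1.17e-03, 0.0735, 0.9253,
  1.23e-04, 0.0245, 0.9753,
  1.25e-05, 7.88e-03, 0.9921,
  1.26e-06, 2.51e-03, 0.9975,
  1.26e-07, 7.94e-04, 0.9992,
  1.26e-08, 2.51e-04, 0.9997,
  1.26e-09, 7.94e-05, 0.9999,
  1.26e-10, 2.51e-05, 0.99997,
  1.26e-10, 7.94e-06, 0.99999
), ncol = 3, byrow = TRUE,
dimnames = list(NULL, c("fH2B", "fHB", "fB")))

# Brute-force RSS minimizer over a rectangular coefficient grid for the
# 2-predictor no-intercept model: independent oracle for the closed-form
# least-squares solution. Vectorized via the quadratic form
# RSS(b) = b' X'X b - 2 b' X'y + y'y.
grid_lstsq_oracle <- function(X, y, b1, b2) {
  M <- crossprod(X)
  v <- crossprod(X, y)
  g <- expand.grid(b1 = b1, b2 = b2)
  rss <- M[1, 1] * g$b1^2 + 2 * M[1, 2] * g$b1 * g$b2 + M[2, 2] * g$b2^2 -
    2 * (g$b1 * v[1] + g$b2 * v[2]) + sum(y^2)
  i <- which.min(rss)
  list(b = c(g$b1[i], g$b2[i]), rss = rss[i])
}
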