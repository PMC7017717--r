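# Published reference values for the built-in worked example (a three-item
# QOL + ERS battery on a 3x3 demonstration grid).  The source tables print
# item parameters to 2 dp but were computed from unrounded estimates, so
# recomputation from the printed parameters reproduces 2-dp cells to within
# 0.0075 and 3-dp cells to within 0.003 (rounding propagation, measured once
# against every cell).
TOL2 <- 0.0075
TOL3 <- 0.003

# absolute-error expectation (expect_equal's tolerance is relative, which
# is meaningless for table cells that print as 0.000)
expect_close <- function(actual, expected, tol) {
  expect_lt(max(abs(unname(actual) - unname(expected))), tol)
}

# category response surface of the example item at six latent points,
# rows (x_QOL, x_ERS) = (-3,-3),(0,-3),(3,-3),(-3,3),(0,3),(3,3)
ref_surface_points <- rbind(
  c(-3, -3), c(0, -3), c(3, -3), c(-3, 3), c(0, 3), c(3, 3))
ref_surface <- rbind(
  c(0.03, 0.60, 0.15, 0.15, 0.05, 0.01, 0.00),
  c(0.00, 0.06, 0.06, 0.22, 0.31, 0.34, 0.01),
  c(0.00, 0.00, 0.00, 0.03, 0.16, 0.70, 0.10),
  c(0.94, 0.03, 0.01, 0.01, 0.00, 0.00, 0.00),
  c(0.05, 0.01, 0.01, 0.03, 0.04, 0.05, 0.81),
  c(0.00, 0.00, 0.00, 0.00, 0.00, 0.01, 0.98))

# normalized 3x3 grid weights (ERS nodes -2,0,2 major; QOL -1,0,1 minor)
ref_weights <- c(0.019, 0.046, 0.040, 0.215, 0.361, 0.215,
                 0.040, 0.046, 0.019)

# collapsed ERS response functions T_j^ERS(m | eta, xi), same node order
ref_collapsed0 <- rbind(
  c(0.997, 0.997, 0.987, 0.910, 0.916, 0.722, 0.259, 0.274, 0.082),
  c(0.978, 0.965, 0.924, 0.853, 0.779, 0.606, 0.426, 0.310, 0.164),
  c(0.994, 0.994, 0.987, 0.901, 0.901, 0.792, 0.318, 0.317, 0.163))
ref_collapsed1 <- rbind(
  c(0.003, 0.003, 0.013, 0.090, 0.084, 0.278, 0.741, 0.726, 0.918),
  c(0.022, 0.035, 0.076, 0.147, 0.221, 0.394, 0.574, 0.690, 0.836),
  c(0.006, 0.006, 0.013, 0.099, 0.099, 0.208, 0.682, 0.683, 0.837))

# final-step summed-score likelihoods L_3(v | eta, xi), v = 0..3
ref_final_L <- rbind(
  c(0.970, 0.957, 0.899, 0.700, 0.643, 0.347, 0.035, 0.027, 0.002),
  c(0.030, 0.043, 0.099, 0.266, 0.312, 0.450, 0.223, 0.189, 0.047),
  c(0.000, 0.000, 0.002, 0.033, 0.043, 0.181, 0.452, 0.442, 0.309),
  c(0.000, 0.000, 0.000, 0.001, 0.002, 0.023, 0.290, 0.342, 0.642))

# nuisance-marginalized kernel sum_xi L(v | eta, xi) W(x), eta = -2, 0, 2
ref_kernel <- rbind(
  c(0.098, 0.457, 0.003),
  c(0.006, 0.267, 0.018),
  c(0.000, 0.062, 0.044),
  c(0.000, 0.006, 0.039))

# translation table: p(v), E(eta | v), V(eta | v) for v = 0..3
ref_table <- data.frame(
  v = 0:3,
  p = c(0.558, 0.292, 0.106, 0.045),
  eap = c(-0.340, 0.082, 0.829, 1.740),
  var = c(0.603, 0.333, 0.979, 0.452))

# published fit summaries (deviance and parameter counts per model)
ref_fits <- data.frame(
  model = c("QOL", "QOL+MRS", "QOL+ERS", "QOL+ERS+MRS"),
  minus2LL = c(67424, 66325, 65008, 63958),
  np = c(245, 281, 281, 318),
  AIC = c(67914, 66887, 65570, 64594),
  BIC = c(68985, 68116, 66799, 65984))

# an example respondent: original 0..6 responses to 35 seven-category items
ref_pattern <- as.integer(strsplit("11111131116361131163661661161363466",
                                   "")[[1]])

# a random item generator for property tests (independent of the simulator)
rand_item <- function(K = 7L, D = 2L) {
  a <- runif(D, 0.3, 1.5)
  cc <- c(0, rnorm(K - 1L, 1, 1))
  list(item = mnrm_item(a, cc),
       s = cbind(matrix(runif(K * (D - 1L), -1, 2), K, D - 1L),
                 seq_len(K) - 1))
}
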