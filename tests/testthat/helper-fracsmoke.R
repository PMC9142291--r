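# shared test helpers: random states/parameters and an independent
# finite-difference Jacobian

random_positive_state <- function() {
  stats::runif(5, 0.01, 1)
}

random_params <- function() {
  r <- stats::runif(6, 0.01, 1)
  smoking_params(a = r[1], b = r[2], c = r[3], d = r[4],
                 e = stats::runif(1), f = r[6])
}

# central-difference Jacobian of the PS-incidence vector field
fd_jacobian <- function(state, params, eps = 1e-6) {
  J <- matrix(NA_real_, 5, 5)
  for (k in 1:5) {
    up <- state; up[k] <- up[k] + eps
    dn <- state; dn[k] <- dn[k] - eps
    J[, k] <- (smoking_rhs(up, params, "PS") -
                 smoking_rhs(dn, params, "PS")) / (2 * eps)
  }
  J
}
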