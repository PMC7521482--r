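# Independent oracles used across tests: generic matrix exponential,
# high-resolution ODE integration of the Kolmogorov forward equations, and
# constant-rate closed forms for expectancies.

gen_Q <- function(q12, q13, q23) {
  matrix(c(-(q12 + q13), q12, q13,
           0, -q23, q23,
           0, 0, 0), 3, 3, byrow = TRUE)
}

oracle_expm <- function(q12, q13, q23, dt) {
  as.matrix(Matrix::expm(gen_Q(q12, q13, q23) * dt))
}

oracle_ode <- function(q12, q13, q23, dt) {
  Q <- gen_Q(q12, q13, q23)
  deriv <- function(t, y, parms) list(as.vector(matrix(y, 3, 3) %*% Q))
  out <- deSolve::ode(y = as.vector(diag(3)), times = c(0, dt), func = deriv,
                      rtol = 1e-12, atol = 1e-14)
  matrix(out[2, -1], 3, 3)
}

# Exact remaining-life integrals for age-constant intensities from state 1
# (no truncation): CIFLE = 1/(q12+q13), TLE = CIFLE + q12/((q12+q13) q23).
oracle_const_expectancy <- function(q12, q13, q23) {
  s <- q12 + q13
  list(cifle = 1 / s, tle = 1 / s + q12 / (s * q23))
}

rand_rate_triple <- function() exp(stats::runif(3, log(0.05), log(0.4)))

# Small panel builder for hand-constructed likelihood cases.
panel_row <- function(id, age, state, kind = "wave") {
  data.frame(subject_id = id, age = age, state = state, record_kind = kind)
}
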