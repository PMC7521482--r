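test_that("intensity matrix has generator structure and unit-rate baseline", {
  p <- intensity_params(1, 1, 1, ref_age = 65)
  Q <- intensity_matrix(p, 65)
  expect_equal(unname(Q[1, ]), c(-2, 1, 1))
  expect_equal(unname(Q[2, ]), c(0, -1, 1))
  expect_equal(unname(Q[3, ]), c(0, 0, 0))
  expect_equal(unname(rowSums(Q)), c(0, 0, 0))
})

test_that("positive age slope makes the onset intensity increase with age", {
  p <- intensity_params(0.1, 0.05, 0.2, age_slope = c(log(2) / 10, 0, 0),
                        ref_age = 65)
  ages <- seq(65, 100, by = 5)
  q12 <- vapply(ages, function(a) intensity_matrix(p, a)[1, 2], numeric(1))
  expect_true(all(diff(q12) > 0))
  expect_equal(q12[2] / q12[1], sqrt(2), tolerance = 1e-10)
})

test_that("non-finite intensities are rejected", {
  p <- intensity_params(0.1, 0.05, 0.2, age_slope = c(1000, 0, 0),
                        ref_age = 65)
  expect_error(intensity_matrix(p, 110), "non-finite")
  expect_error(transition_probability(p, 100, 110), "non-finite")
})

test_that("zero-length interval gives the identity matrix", {
  p <- intensity_params(0.1, 0.05, 0.2)
  expect_equal(transition_probability(p, 80, 80), diag(3),
               ignore_attr = TRUE)
})

test_that("constant-rate probabilities match closed forms and the oracles", {
  p <- intensity_params(0.1, 0.05, 0.2)
  P <- transition_probability(p, 65, 66)
  expect_equal(P[1, 1], 0.860708, tolerance = 1e-6)
  expect_equal(P[1, 2], 0.083954, tolerance = 1e-5)
  expect_equal(P[2, 2], 0.818731, tolerance = 1e-6)
  expect_equal(unname(rowSums(P)), c(1, 1, 1), tolerance = 1e-12)
  expect_equal(P[2, 1], 0)
  expect_equal(unname(P), oracle_expm(0.1, 0.05, 0.2, 1), tolerance = 1e-10)

  # degenerate case q23 = q12 + q13 uses the limit formula
  pd <- intensity_params(0.1, 0.05, 0.15)
  Pd <- transition_probability(pd, 65, 66)
  expect_equal(Pd[1, 2], 0.1 * exp(-0.15), tolerance = 1e-10)
  expect_equal(unname(Pd), oracle_expm(0.1, 0.05, 0.15, 1), tolerance = 1e-9)
})

test_that("piecewise solution agrees with expm and ODE on random draws", {
  skip_if_not_installed("Matrix")
  skip_if_not_installed("deSolve")
  set.seed(42)
  for (i in 1:40) {
    q <- rand_rate_triple()
    dt <- stats::runif(1, 0.25, 5)
    p <- intensity_params(q[1], q[2], q[3])
    P <- transition_probability(p, 70, 70 + dt)
    expect_equal(unname(P), oracle_expm(q[1], q[2], q[3], dt),
                 tolerance = 1e-8)
    expect_equal(unname(P), oracle_ode(q[1], q[2], q[3], dt),
                 tolerance = 1e-8)
  }
})

test_that("Chapman-Kolmogorov composition holds with aligned boundaries", {
  p <- intensity_params(0.05, 0.03, 0.1, age_slope = c(0.08, 0.09, 0.07),
                        ref_age = 80)
  for (b in c(70.5, 71, 72.25)) {
    full <- transition_probability(p, 70, 73)
    split <- transition_probability(p, 70, b) %*%
      transition_probability(p, b, 73)
    expect_equal(unname(full), unname(split), tolerance = 1e-8)
  }
})

test_that("absorption probabilities are monotone in interval length", {
  p <- intensity_params(0.06, 0.04, 0.12, age_slope = c(0.05, 0.08, 0.06),
                        ref_age = 75)
  lens <- seq(0.5, 10, by = 0.5)
  Ps <- lapply(lens, function(d) transition_probability(p, 75, 75 + d))
  p13 <- vapply(Ps, function(P) P[1, 3], numeric(1))
  p23 <- vapply(Ps, function(P) P[2, 3], numeric(1))
  p11 <- vapply(Ps, function(P) P[1, 1], numeric(1))
  p22 <- vapply(Ps, function(P) P[2, 2], numeric(1))
  expect_true(all(diff(p13) > 0) && all(diff(p23) > 0))
  expect_true(all(diff(p11) < 0) && all(diff(p22) < 0))
})

test_that("halving the piece step barely moves age-varying probabilities", {
  p <- intensity_params(0.05, 0.03, 0.1, age_slope = c(0.08, 0.09, 0.07),
                        ref_age = 80)
  P1 <- transition_probability(p, 70, 85, piece_step = 0.25)
  P2 <- transition_probability(p, 70, 85, piece_step = 0.125)
  expect_lt(max(abs(P1 - P2)), 1e-4)
})

test_that("subject log-likelihood matches hand-computable contributions", {
  p <- intensity_params(0.1, 0.05, 0.2)
  # survival in state 1 over two years
  ll <- subject_loglik(p, data.frame(age = c(70, 72), state = c(1, 1)))
  expect_equal(ll, -0.3, tolerance = 1e-10)
  # exact death one year after a CI-free observation: P11 q13 + P12 q23
  P <- transition_probability(p, 70, 71)
  ll_d <- subject_loglik(p, data.frame(age = c(70, 71), state = c(1, 3)))
  expect_equal(ll_d, log(P[1, 1] * 0.05 + P[1, 2] * 0.2), tolerance = 1e-10)
  # right censoring from state 1: alive, state unknown
  obs_rc <- data.frame(age = c(70, 73), state = c(1, NA),
                       record_kind = c("wave", "right_censor"))
  P3 <- transition_probability(p, 70, 73)
  expect_equal(subject_loglik(p, obs_rc), log(P3[1, 1] + P3[1, 2]),
               tolerance = 1e-10)
  # weight enters linearly
  expect_equal(subject_loglik(p, data.frame(age = c(70, 72), state = c(1, 1)),
                              weight = 2), -0.6, tolerance = 1e-10)
})

test_that("missing living states between known states change nothing", {
  p <- intensity_params(0.05, 0.03, 0.1, age_slope = c(0.08, 0.09, 0.07),
                        ref_age = 80)
  a <- data.frame(age = c(70, 76), state = c(1, 2))
  b <- data.frame(age = c(70, 73, 76), state = c(1, NA, 2))
  expect_identical(subject_loglik(p, a), subject_loglik(p, b))
})

test_that("an impossible path returns -Inf with a warning, not an error", {
  p <- intensity_params(0, 0.05, 0.2)   # onset impossible
  expect_warning(
    ll <- subject_loglik(p, data.frame(age = c(70, 73), state = c(1, 2))),
    "zero probability")
  expect_identical(ll, -Inf)
})

test_that("fitting recovers generating values and maximizes the likelihood", {
  tp <- intensity_params(0.1, 0.05, 0.2)
  cfg <- simulation_config(1500, tp, seed = 21)
  coh <- generate_cohort(cfg)
  spec <- illness_death_spec(age_effect = "constant")
  fit <- fit_illness_death(coh$panel, spec)
  expect_equal(fit$convergence$code, 0)
  # estimates near truth (log scale, ~4 SD slack at this n)
  expect_equal(unname(fit$theta), log(c(0.1, 0.05, 0.2)), tolerance = 0.15)
  # log-likelihood at the optimum beats the truth
  pre_ll <- function(params) {
    sum(vapply(split(coh$panel, coh$panel$subject_id), function(d) {
      suppressWarnings(subject_loglik(params, d))
    }, numeric(1)))
  }
  expect_gte(fit$loglik + 1e-6, pre_ll(tp))
  # covariance symmetric positive definite
  expect_equal(fit$vcov, t(fit$vcov))
  expect_true(all(eigen(fit$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  # deterministic given data
  fit2 <- fit_illness_death(coh$panel, spec)
  expect_identical(fit$theta, fit2$theta)
})

test_that("a transition with no events hits the boundary and is flagged", {
  tp <- intensity_params(0, 0.05, 0.2)
  cfg <- simulation_config(500, tp, seed = 8)
  coh <- generate_cohort(cfg)
  fit <- fit_illness_death(coh$panel, illness_death_spec(age_effect = "constant"))
  expect_lt(exp(fit$theta[["log_q12"]]), 1e-4)
  expect_true("12" %in% fit$non_identified)
  expect_true(is.na(fit$se[["log_q12"]]))
})

test_that("frequency weights scale the likelihood as duplication would", {
  tp <- intensity_params(0.1, 0.05, 0.2)
  cfg <- simulation_config(120, tp, seed = 31)
  panel <- generate_cohort(cfg)$panel
  spec <- illness_death_spec(age_effect = "constant")
  dup <- panel
  dup$subject_id <- dup$subject_id + 1000L
  both <- rbind(panel, dup)
  f_dup <- fit_illness_death(both, spec)
  w <- stats::setNames(rep(2, 120), unique(panel$subject_id))
  f_w <- fit_illness_death(panel, spec, weights = w)
  expect_equal(f_w$theta, f_dup$theta, tolerance = 1e-5)
  expect_equal(f_w$loglik, f_dup$loglik, tolerance = 1e-5)
})

test_that("observed recovery pairs are refused until recoded", {
  panel <- panel_row(1, c(70, 73, 76), c(1, 2, 1))
  spec <- illness_death_spec(age_effect = "constant")
  expect_error(fit_illness_death(panel, spec), "assemble_panel")
})
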