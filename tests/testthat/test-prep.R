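test_that("cognitive classification applies education-specific cutoffs", {
  cases <- data.frame(
    score = c(17, 18, 20, 21, 24, 25, 0, 30),
    edu = c("none", "none", "primary", "primary", "middle_plus",
            "middle_plus", "none", "none"),
    want = c(2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L)
  )
  expect_equal(classify_cognition(cases$score, cases$edu), cases$want)
  expect_true(is.na(classify_cognition(NA, "none")))
  expect_error(classify_cognition(31, "none"), "0-30")
  expect_error(classify_cognition(-1, "primary"), "0-30")
  expect_error(classify_cognition(25, "college"), "education")
})

test_that("classification is monotone in score within each education band", {
  for (edu in c("none", "primary", "middle_plus")) {
    states <- classify_cognition(0:30, edu)
    # once CI-free, higher scores never flip back to CI
    expect_true(all(diff(states) <= 0))
  }
})

test_that("dietary pattern requires three foods at least weekly", {
  expect_equal(classify_diet("daily", "weekly", "weekly", "rarely"),
               "healthy")
  expect_equal(classify_diet("weekly", "weekly", "monthly", "monthly"),
               "unhealthy")
  expect_equal(classify_diet("rarely", "rarely", "rarely", "rarely"),
               "unhealthy")
  expect_equal(classify_diet(c("daily", "rarely"), c("daily", "daily"),
                             c("weekly", "weekly"), c("rarely", "weekly")),
               c("healthy", "healthy"))
  expect_error(classify_diet("sometimes", "daily", "daily", "daily"),
               "frequency")
})

test_that("risk profiles count protective components deterministically", {
  rp <- build_risk_profile("never", "healthy", "in_marriage",
                           "no", "no", "yes", "no")
  expect_equal(rp$n_components, 3L)
  expect_equal(as.character(rp$label), "low")

  rp2 <- build_risk_profile("current", "healthy", "in_marriage",
                            "no", "yes", "no", "no")
  expect_equal(rp2$n_components, 2L)
  expect_equal(as.character(rp2$label), "medium_low")

  rp0 <- build_risk_profile("former", "unhealthy", "not_in_marriage",
                            "no", "no", "no", "no")
  expect_equal(rp0$n_components, 0L)
  expect_equal(as.character(rp0$label), "high")

  # label is the deterministic image of the component count
  smo <- c("never", "current"); mar <- c("in_marriage", "not_in_marriage")
  grid <- expand.grid(s = smo, d = c("healthy", "unhealthy"), m = mar,
                      l = c("yes", "no"), stringsAsFactors = FALSE)
  rp_all <- build_risk_profile(grid$s, grid$d, grid$m,
                               grid$l, "no", "no", "no")
  map <- c("high", "medium_high", "medium_low", "low")
  expect_equal(as.character(rp_all$label), map[rp_all$n_components + 1L])
  expect_error(build_risk_profile("never", NA, "in_marriage",
                                  "no", "no", "no", "no"), "diet")
})

test_that("post-stratification weights hit the target distribution exactly", {
  s <- data.frame(band = c("65-79", "80-89", "90+"),
                  sex = "f", count = c(100, 150, 250))
  t <- data.frame(band = c("65-79", "80-89", "90+"),
                  sex = "f", proportion = c(0.7, 0.2, 0.1))
  w <- post_stratification_weights(s, t)
  # weighted stratum proportions equal the target to machine precision
  wp <- w$weight * w$count / sum(w$weight * w$count)
  expect_equal(wp, t$proportion, tolerance = 1e-12)
  # subject-level mean weight is one
  expect_equal(sum(w$weight * w$count) / sum(w$count), 1, tolerance = 1e-12)

  # identical sample and target -> unit weights
  t2 <- data.frame(band = s$band, sex = "f", proportion = s$count / 500)
  expect_equal(post_stratification_weights(s, t2)$weight, rep(1, 3))

  # a stratum at 10% of sample but 20% of target doubles, pre-normalization
  s3 <- data.frame(g = c("a", "b"), count = c(10, 90))
  t3 <- data.frame(g = c("a", "b"), proportion = c(0.2, 0.8))
  w3 <- post_stratification_weights(s3, t3)
  expect_equal(w3$weight[1] / w3$weight[2], 2 / (8 / 9), tolerance = 1e-12)

  expect_error(post_stratification_weights(
    data.frame(g = "a", count = 5), data.frame(g = c("a", "b"),
                                               proportion = c(0.5, 0.5))),
    "no sample support")
})

test_that("weights can be attached to subjects by stratum", {
  s <- data.frame(band = c("y", "o"), count = c(3, 1))
  t <- data.frame(band = c("y", "o"), proportion = c(0.5, 0.5))
  w <- post_stratification_weights(s, t)
  subj <- data.frame(subject_id = 1:4, band = c("y", "y", "y", "o"))
  out <- attach_weights(subj, w)
  expect_equal(mean(out$weight), 1, tolerance = 1e-12)
  expect_true(out$weight[4] > out$weight[1])
})

test_that("panel assembly censors recoveries and handles trailing missingness", {
  # recovery at the last observation becomes a right censor
  raw <- data.frame(subject_id = 1, age = c(80, 83, 86), state = c(1, 2, 1))
  pan <- assemble_panel(raw)
  expect_equal(pan$state, c(1L, 2L, NA))
  expect_equal(pan$record_kind, c("wave", "wave", "right_censor"))
  expect_equal(pan$age[3], 86)

  # interior missing state dropped (interval bridges it)
  raw2 <- data.frame(subject_id = 1, age = c(70, 73, 76), state = c(1, NA, 2))
  pan2 <- assemble_panel(raw2)
  expect_equal(pan2$age, c(70, 76))
  expect_equal(pan2$state, c(1L, 2L))

  # trailing missing living state -> right censor at that age
  raw3 <- data.frame(subject_id = 1, age = c(70, 73, 76),
                     state = c(1, 1, NA))
  pan3 <- assemble_panel(raw3)
  expect_equal(pan3$record_kind, c("wave", "wave", "right_censor"))

  # death records keep their exact age and covariates carry through
  raw4 <- data.frame(subject_id = 2, age = c(70, 74.2), state = c(2, 3),
                     sex = "m")
  pan4 <- assemble_panel(raw4)
  expect_equal(pan4$record_kind, c("wave", "death"))
  expect_equal(pan4$sex, c("m", "m"))

  # missing baseline state excludes the subject with a logged reason
  raw5 <- rbind(data.frame(subject_id = 1, age = c(70, 73), state = c(NA, 1)),
                data.frame(subject_id = 2, age = c(70, 73), state = c(1, 1)))
  expect_message(pan5 <- assemble_panel(raw5), "excluded")
  expect_equal(unique(pan5$subject_id), 2)
  excl <- attr(pan5, "exclusions")
  expect_equal(excl$subject_id, 1)
  expect_match(excl$reason, "baseline")
})

test_that("assembled panels never contain an observed CI -> CI-free pair", {
  set.seed(123)
  for (rep in 1:20) {
    n_obs <- sample(3:6, 1)
    raw <- data.frame(subject_id = 1,
                      age = 70 + sort(sample(1:20, n_obs)),
                      state = sample(c(1L, 2L, NA), n_obs, replace = TRUE))
    pan <- suppressMessages(assemble_panel(raw))
    st <- pan$state[!is.na(pan$state) & pan$state %in% c(1, 2)]
    if (length(st) > 1) {
      expect_false(any(st[-length(st)] == 2 & st[-1] == 1))
    }
  }
})

test_that("sensitivity filters drop the intended subjects and only those", {
  pan <- rbind(
    data.frame(subject_id = 1, age = c(70, 73), state = c(1, 2)),   # onset at first follow-up
    data.frame(subject_id = 2, age = c(70, 70.9), state = c(1, 3)), # death in first year
    data.frame(subject_id = 3, age = c(70, 71.5), state = c(1, 3)), # later death
    data.frame(subject_id = 4, age = c(70, 73), state = c(1, 1))
  )
  # no active rule: identity
  same <- sensitivity_filter(pan)
  expect_equal(same$subject_id, pan$subject_id)

  f1 <- sensitivity_filter(pan, drop_first_interval_onsets = TRUE)
  expect_false(1 %in% f1$subject_id)
  expect_true(all(c(2, 3, 4) %in% f1$subject_id))

  f2 <- sensitivity_filter(pan, drop_first_year_deaths = TRUE)
  expect_false(2 %in% f2$subject_id)
  expect_true(all(c(1, 3, 4) %in% f2$subject_id))
  expect_equal(unname(attr(f2, "removed")["first_year_deaths"]), 1L)
})

test_that("flow accounting and baseline composition do the books", {
  fl <- flow_accounting(c(100, 50), c(drop = 30))
  expect_equal(fl$analytical_n, 120)
  expect_error(flow_accounting(10, c(a = 20)), "more exclusions")

  pan <- data.frame(subject_id = 1:10, age = 70,
                    state = c(rep(1L, 7), rep(2L, 3)))
  bc <- baseline_composition(pan)
  expect_equal(bc$pct_ci, 30)
  expect_equal(bc$pct_ci_free, 70)
})
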