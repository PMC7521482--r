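#' Configuration for a synthetic longitudinal cohort
#'
#' Describes a cohort with the observational structure the estimation
#' machinery assumes: entry ages 65-105 with designed oversampling of the
#' oldest-old, observation waves at fixed offsets after entry (about three
#' years apart, as in multi-wave longevity surveys), interval-censored CI
#' onset (living states seen only at waves), exactly dated deaths,
#' intermittent missing cognitive states, and no recovery from CI. The
#' latent truth is generated from known transition intensities, so
#' estimation and life-table stages can be validated by parameter and
#' expectancy recovery.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param true_params [intensity_params()] generating the latent
#'   trajectories.
#' @param entry_bands Data frame `lower`, `upper`, `weight`: entry-age bands
#'   with sampling weights (entry age uniform within the sampled band). The
#'   default oversamples ages 80+ relative to a real population, mirroring a
#'   targeted design with roughly equal numbers of young-old,
#'   octogenarians, nonagenarians and centenarians.
#' @param wave_offsets Years after entry of each observation wave; must
#'   start at 0 and be strictly increasing. Default five waves three years
#'   apart.
#' @param covariates Named list of baseline covariate generators: each
#'   element a probability in `[0, 1]` (Bernoulli 0/1 covariate) or a list
#'   `list(values =, probs =)` for a categorical draw.
#' @param missing_state_prob Probability that a living post-baseline wave
#'   records a missing cognitive state (the baseline state is always
#'   known). Default 0.05, a realistic non-completion rate for a
#'   cognitive screen in very old respondents.
#' @param horizon_age Administrative censoring age (years); subjects alive
#'   at the horizon have no death record.
#' @param seed Integer seed making [generate_cohort()] deterministic.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects,
                              true_params,
                              entry_bands = default_entry_bands(),
                              wave_offsets = c(0, 3, 6, 9, 12),
                              covariates = list(),
                              missing_state_prob = 0.05,
                              horizon_age = 110,
                              seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    stop("'n_subjects' must be at least 1", call. = FALSE)
  }
  stopifnot(inherits(true_params, "intensity_params"))
  if (wave_offsets[1] != 0 || is.unsorted(wave_offsets, strictly = TRUE)) {
    stop("'wave_offsets' must start at 0 and increase strictly",
         call. = FALSE)
  }
  if (missing_state_prob < 0 || missing_state_prob > 1) {
    stop("'missing_state_prob' must be in [0, 1]", call. = FALSE)
  }
  stopifnot(all(c("lower", "upper", "weight") %in% names(entry_bands)),
            all(entry_bands$weight >= 0), sum(entry_bands$weight) > 0)
  for (cv in covariates) {
    if (is.numeric(cv) && length(cv) == 1L) {
      if (cv < 0 || cv > 1) stop("covariate probability outside [0, 1]",
                                 call. = FALSE)
    } else if (!(is.list(cv) && all(c("values", "probs") %in% names(cv)))) {
      stop("each covariate generator is a probability or list(values, probs)",
           call. = FALSE)
    }
  }
  structure(list(
    n_subjects = as.integer(n_subjects), true_params = true_params,
    entry_bands = entry_bands, wave_offsets = wave_offsets,
    covariates = covariates, missing_state_prob = missing_state_prob,
    horizon_age = horizon_age, seed = as.integer(seed)
  ), class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_entry_bands <- function() {
  data.frame(lower = c(65, 80, 90, 100), upper = c(80, 90, 100, 105),
             weight = c(0.30, 0.30, 0.25, 0.15))
}

#' Simulate one latent illness-death trajectory
#'
#' Draws the latent CI-onset and death ages for one subject from the
#' age-inhomogeneous intensities. Simulation proceeds in fixed age steps:
#' within each step the intensities are frozen at the step midpoint and
#' competing exponential event times are drawn, which is exact for
#' age-constant intensities (memorylessness) and accurate to O(step) for
#' age-varying ones. Recovery (CI to CI-free) can never occur.
#'
#' @inheritParams intensity_matrix
#' @param entry_age Age at cohort entry (years).
#' @param horizon_age Administrative censoring age; events beyond it are
#'   discarded (the subject is recorded alive at the horizon).
#' @param step Age step (years) for the piecewise simulation.
#' @return List (class `true_trajectory`): `entry_age`, `onset_age` (CI
#'   onset, `NA` if none before death/horizon), `death_age` (`NA` if alive
#'   at the horizon).
#' @examples
#' set.seed(1)
#' simulate_trajectory(intensity_params(0.1, 0.05, 0.2), entry_age = 70)
#' @export
simulate_trajectory <- function(params, entry_age, profile = NULL,
                                horizon_age = 110, step = 0.25) {
  stopifnot(inherits(params, "intensity_params"))
  if (horizon_age <= entry_age) {
    stop("'horizon_age' must exceed 'entry_age'", call. = FALSE)
  }
  age <- entry_age
  state <- 1L
  onset <- NA_real_; death <- NA_real_
  while (age < horizon_age) {
    seg <- min(step, horizon_age - age)
    mid <- age + seg / 2
    if (state == 1L) {
      q12 <- transition_intensity(params, "12", mid, profile)
      q13 <- transition_intensity(params, "13", mid, profile)
      if (!is.finite(q12) || !is.finite(q13)) {
        stop("non-finite intensity at age ", mid, call. = FALSE)
      }
      tot <- q12 + q13
      t_ev <- if (tot > 0) stats::rexp(1, tot) else Inf
      if (t_ev < seg) {
        if (stats::runif(1) < q12 / tot) {
          state <- 2L
          onset <- age + t_ev
          age <- age + t_ev
          next
        }
        death <- age + t_ev
        break
      }
    } else {
      q23 <- transition_intensity(params, "23", mid, profile)
      if (!is.finite(q23)) stop("non-finite intensity at age ", mid,
                                call. = FALSE)
      t_ev <- if (q23 > 0) stats::rexp(1, q23) else Inf
      if (t_ev < seg) {
        death <- age + t_ev
        break
      }
    }
    age <- age + seg
  }
  structure(list(entry_age = entry_age, onset_age = onset, death_age = death),
            class = "true_trajectory")
}

#' Observe a latent trajectory at scheduled waves
#'
#' Converts a latent trajectory into panel records. Follow-up ends at
#' `F = min(entry age + last wave offset, horizon age)`: at each scheduled
#' wave age before death (and at or below `F`) the current living state is
#' recorded, replaced by missing with probability
#' `config$missing_state_prob` except at baseline; a death at or before `F`
#' is recorded once with its exact age; deaths after `F` are never
#' ascertained, so subjects alive at `F` are right-censored -- at their
#' final wave when it falls on `F`, otherwise by an explicit right-censor
#' record at `F` (vital status at the administrative horizon is known,
#' the cognitive state is not). Nothing is recorded after death. Recording
#' deaths through `F` and crediting survival through `F` keeps the
#' observation plan non-informative.
#'
#' @param traj A `true_trajectory` from [simulate_trajectory()].
#' @param config A [simulation_config()].
#' @return Data frame with columns `age`, `state` (1, 2, 3 or `NA`),
#'   `record_kind`.
#' @export
observe_panel <- function(traj, config) {
  fup_end <- min(traj$entry_age + max(config$wave_offsets),
                 config$horizon_age)
  dead <- !is.na(traj$death_age) && traj$death_age <= fup_end
  waves <- traj$entry_age + config$wave_offsets
  waves <- waves[waves <= fup_end]
  if (dead) waves <- waves[waves < traj$death_age]
  state <- ifelse(!is.na(traj$onset_age) & waves >= traj$onset_age, 2L, 1L)
  if (length(waves) > 1L && config$missing_state_prob > 0) {
    miss <- c(FALSE, stats::runif(length(waves) - 1L) <
                config$missing_state_prob)
    state[miss] <- NA_integer_
  }
  out <- data.frame(age = waves, state = state,
                    record_kind = rep("wave", length(waves)))
  if (dead) {
    out <- rbind(out, data.frame(age = traj$death_age, state = 3L,
                                 record_kind = "death"))
  } else if (length(waves) && max(waves) < fup_end - 1e-9) {
    # scheduled waves cut off by the horizon: subject known alive at the
    # horizon, cognitive state unknown there
    out <- rbind(out, data.frame(age = fup_end, state = NA_integer_,
                                 record_kind = "right_censor"))
  }
  out
}

#' Generate a synthetic cohort (observable panel plus latent truth)
#'
#' Draws entry ages from the configured bands, baseline covariates from
#' their generators, latent trajectories from the true intensities, and the
#' wave-structured observation records. Deterministic given
#' `config$seed`. When the true intensities are age-constant the latent
#' event times are drawn directly from the competing exponentials
#' (vectorized exact simulation); otherwise each trajectory is simulated
#' stepwise via [simulate_trajectory()].
#'
#' @param config A [simulation_config()].
#' @return List with `panel` (data frame: `subject_id`, `age`, `state`,
#'   `record_kind`, one column per covariate) and `truth` (data frame:
#'   `subject_id`, `entry_age`, `onset_age`, `death_age`, covariates).
#'   The truth table is for validation only; estimation sees the panel.
#' @examples
#' cfg <- simulation_config(50, intensity_params(0.1, 0.05, 0.2), seed = 7)
#' coh <- generate_cohort(cfg)
#' head(coh$panel)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  p <- config$true_params

  bands <- config$entry_bands
  bi <- sample.int(nrow(bands), n, replace = TRUE,
                   prob = bands$weight / sum(bands$weight))
  entry <- stats::runif(n, bands$lower[bi], bands$upper[bi])

  covm <- matrix(numeric(0), nrow = n, ncol = 0)
  for (nm in names(config$covariates)) {
    g <- config$covariates[[nm]]
    x <- if (is.numeric(g) && length(g) == 1L) {
      stats::rbinom(n, 1L, g)
    } else {
      sample(g$values, n, replace = TRUE, prob = g$probs)
    }
    covm <- cbind(covm, as.numeric(x))
    colnames(covm)[ncol(covm)] <- nm
  }

  constant_rates <- all(p$age_slope == 0)
  onset <- death <- rep(NA_real_, n)
  if (constant_rates) {
    q12 <- q13 <- q23 <- numeric(n)
    for (i in seq_len(n)) {
      prof <- if (ncol(covm)) covm[i, ] else NULL
      q12[i] <- transition_intensity(p, "12", entry[i], prof)
      q13[i] <- transition_intensity(p, "13", entry[i], prof)
      q23[i] <- transition_intensity(p, "23", entry[i], prof)
    }
    if (!all(is.finite(c(q12, q13, q23)))) {
      stop("non-finite true intensity", call. = FALSE)
    }
    tot <- q12 + q13
    t1 <- ifelse(tot > 0, stats::rexp(n, pmax(tot, 1e-300)), Inf)
    u <- stats::runif(n)
    t2 <- ifelse(q23 > 0, stats::rexp(n, pmax(q23, 1e-300)), Inf)
    first <- entry + t1
    to_ci <- u < ifelse(tot > 0, q12 / tot, 0)
    onset <- ifelse(to_ci & first <= config$horizon_age, first, NA_real_)
    death <- ifelse(to_ci, first + t2, first)
    death <- ifelse(death <= config$horizon_age, death, NA_real_)
  } else {
    for (i in seq_len(n)) {
      prof <- if (ncol(covm)) covm[i, ] else NULL
      tr <- simulate_trajectory(p, entry[i], prof,
                                horizon_age = config$horizon_age)
      onset[i] <- tr$onset_age
      death[i] <- tr$death_age
    }
  }

  # wave observations, vectorized across subjects; follow-up per subject
  # ends at min(last scheduled wave, horizon) and deaths are ascertained
  # only through that age, so censoring stays non-informative
  fup_end <- pmin(entry + max(config$wave_offsets), config$horizon_age)
  observed_death <- !is.na(death) & death <= fup_end
  nw <- length(config$wave_offsets)
  wage <- rep(entry, each = nw) + rep(config$wave_offsets, n)
  wsub <- rep(seq_len(n), each = nw)
  alive <- wage <= fup_end[wsub] &
    (!observed_death[wsub] | wage < death[wsub])
  wage <- wage[alive]; wsub <- wsub[alive]
  wstate <- ifelse(!is.na(onset[wsub]) & wage >= onset[wsub], 2L, 1L)
  baseline <- !duplicated(wsub)
  if (config$missing_state_prob > 0) {
    miss <- !baseline &
      stats::runif(length(wage)) < config$missing_state_prob
    wstate[miss] <- NA_integer_
  }
  panel <- data.frame(subject_id = wsub, age = wage, state = wstate,
                      record_kind = "wave")
  dsub <- which(observed_death)
  if (length(dsub)) {
    panel <- rbind(panel,
                   data.frame(subject_id = dsub, age = death[dsub],
                              state = 3L, record_kind = "death"))
  }
  # survivors whose scheduled waves were cut off by the horizon are known
  # alive at the horizon with unknown cognitive state
  last_wage <- tapply(wage, wsub, max)
  csub <- which(!observed_death)
  csub <- csub[fup_end[csub] - as.numeric(last_wage[as.character(csub)]) >
                 1e-9]
  if (length(csub)) {
    panel <- rbind(panel,
                   data.frame(subject_id = csub, age = fup_end[csub],
                              state = NA_integer_,
                              record_kind = "right_censor"))
  }
  panel <- panel[order(panel$subject_id, panel$age), , drop = FALSE]
  rownames(panel) <- NULL
  if (ncol(covm)) {
    for (nm in colnames(covm)) panel[[nm]] <- covm[panel$subject_id, nm]
  }

  truth <- data.frame(subject_id = seq_len(n), entry_age = entry,
                      onset_age = onset, death_age = death)
  if (ncol(covm)) for (nm in colnames(covm)) truth[[nm]] <- covm[, nm]

  list(panel = panel, truth = truth)
}
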