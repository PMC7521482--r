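#' Generator (intensity) matrix at a given age
#'
#' Evaluates the 3x3 transition intensity matrix Q of the progressive
#' illness-death model at one age for one covariate profile. Row 3 (dead) is
#' absorbing; the 2->1 entry is structurally zero; diagonals are the negated
#' row sums so every row of Q sums to zero.
#'
#' @param params An [intensity_params()] object.
#' @param age Age in years.
#' @param profile Optional named covariate vector; covariates named in the
#'   parameters but absent here are taken at 0 (reference).
#' @return 3x3 numeric matrix with rows/columns `c("healthy", "ci", "dead")`.
#' @examples
#' p <- intensity_params(0.1, 0.05, 0.2)
#' intensity_matrix(p, age = 70)
#' @export
intensity_matrix <- function(params, age, profile = NULL) {
  stopifnot(inherits(params, "intensity_params"), length(age) == 1L)
  q12 <- transition_intensity(params, "12", age, profile)
  q13 <- transition_intensity(params, "13", age, profile)
  q23 <- transition_intensity(params, "23", age, profile)
  if (!all(is.finite(c(q12, q13, q23)))) {
    stop("non-finite transition intensity at age ", age, call. = FALSE)
  }
  Q <- matrix(0, 3, 3, dimnames = list(STATES, STATES))
  Q[1, 2] <- q12; Q[1, 3] <- q13; Q[2, 3] <- q23
  Q[1, 1] <- -(q12 + q13); Q[2, 2] <- -q23
  Q
}

STATES <- c("healthy", "ci", "dead")

# Closed-form constant-rate transition probabilities over elapsed time dt for
# the progressive model, vectorized over pieces. Returns list(p11, p12, p22)
# (log_p11 and log_p22 exact in log scale; p13/p23 follow by complement).
piece_probs <- function(q12, q13, q23, dt) {
  s <- q12 + q13
  l11 <- -s * dt
  l22 <- -q23 * dt
  p11 <- exp(l11)
  p22 <- exp(l22)
  denom <- q23 - s
  # P12 = q12 (e^{-s dt} - e^{-q23 dt}) / (q23 - s), with the removable
  # singularity at q23 = s handled by its limit q12 dt e^{-q23 dt}.
  degen <- abs(denom) < 1e-8
  p12 <- ifelse(degen,
                q12 * dt * p22,
                q12 * (p11 - p22) / ifelse(degen, 1, denom))
  list(p11 = p11, p12 = p12, p22 = p22, l11 = l11, l22 = l22)
}

# Piecewise age grid over [a, b] with pieces of length <= step.
piece_grid <- function(a, b, step) {
  len <- b - a
  n <- max(1L, as.integer(ceiling(len / step - 1e-9)))
  dt <- len / n
  list(n = n, dt = dt, mid = a + (seq_len(n) - 0.5) * dt)
}

#' Transition probability matrix over an age interval
#'
#' Computes the 3x3 matrix of state-to-state transition probabilities
#' P(age_from, age_to) for a fixed covariate profile, by splitting the
#' interval into pieces of length at most `piece_step`, freezing the
#' intensities at each piece midpoint, applying the closed-form
#' constant-rate solution within each piece, and composing the pieces by
#' matrix multiplication (Chapman-Kolmogorov). For age-constant intensities
#' the result is exact for any `piece_step`.
#'
#' @inheritParams intensity_matrix
#' @param age_from,age_to Interval endpoints in years (`age_to >= age_from`).
#' @param piece_step Maximum piece length in years.
#' @return 3x3 probability matrix; rows sum to 1, row 3 is (0, 0, 1) and the
#'   2->1 entry is 0.
#' @examples
#' p <- intensity_params(0.1, 0.05, 0.2)
#' transition_probability(p, 65, 66)
#' @export
transition_probability <- function(params, age_from, age_to, profile = NULL,
                                   piece_step = 0.25) {
  stopifnot(inherits(params, "intensity_params"))
  if (age_to < age_from) {
    stop("'age_to' must not precede 'age_from'", call. = FALSE)
  }
  P11 <- 1; P12 <- 0; P22 <- 1
  if (age_to > age_from) {
    g <- piece_grid(age_from, age_to, piece_step)
    q12 <- transition_intensity(params, "12", g$mid, profile)
    q13 <- transition_intensity(params, "13", g$mid, profile)
    q23 <- transition_intensity(params, "23", g$mid, profile)
    if (!all(is.finite(c(q12, q13, q23)))) {
      stop("non-finite transition intensity inside the interval",
           call. = FALSE)
    }
    pp <- piece_probs(q12, q13, q23, g$dt)
    for (k in seq_len(g$n)) {
      P12 <- P11 * pp$p12[k] + P12 * pp$p22[k]
      P11 <- P11 * pp$p11[k]
      P22 <- P22 * pp$p22[k]
    }
  }
  P <- matrix(0, 3, 3, dimnames = list(STATES, STATES))
  P[1, ] <- c(P11, P12, 1 - P11 - P12)
  P[2, ] <- c(0, P22, 1 - P22)
  P[3, ] <- c(0, 0, 1)
  # numeric guard: clip roundoff-level violations, refuse anything larger
  lo <- P < 0; hi <- P > 1
  if (any(P[lo] < -1e-12) || any(P[hi] > 1 + 1e-12)) {
    stop("transition probabilities outside [0,1] beyond numeric tolerance",
         call. = FALSE)
  }
  P[lo] <- 0; P[hi] <- 1
  P
}

# ---------------------------------------------------------------------------
# Interval construction: turn a panel into likelihood contributions.
#
# A panel is a data.frame with one row per subject-record:
#   subject_id, age (years), state (1, 2, 3 or NA),
#   record_kind ("wave", "death", "right_censor"; inferred when absent),
# plus subject-level covariate columns and optionally a 'weight' column.
# Living waves with missing state between two known states are bridged by
# the spanning interval; a trailing run of missing living waves becomes a
# right censoring at its last age (the subject was known alive there).
# ---------------------------------------------------------------------------

infer_record_kind <- function(panel) {
  if (!is.null(panel$record_kind)) return(as.character(panel$record_kind))
  ifelse(!is.na(panel$state) & panel$state == 3, "death", "wave")
}

# Interval types: 1 = to living state 1, 2 = to living state 2,
# 3 = exactly observed death, 4 = right censoring (alive, state unknown).
build_intervals <- function(panel, spec, piece_step = 0.25) {
  req <- c("subject_id", "age", "state")
  if (!all(req %in% names(panel))) {
    stop("panel must have columns subject_id, age, state", call. = FALSE)
  }
  kind <- infer_record_kind(panel)
  ord <- order(panel$subject_id, panel$age)
  p <- panel[ord, , drop = FALSE]
  kind <- kind[ord]
  sid <- p$subject_id

  subj_ids <- unique(sid)
  n_subj <- length(subj_ids)
  subj_of <- match(sid, subj_ids)

  base_row <- which(!duplicated(subj_of))
  covs <- unique(unlist(spec$covariates))
  if (length(covs) && !all(covs %in% names(p))) {
    stop("panel lacks covariate column(s): ",
         paste(setdiff(covs, names(p)), collapse = ", "), call. = FALSE)
  }
  X <- if (length(covs)) {
    as.matrix(as.data.frame(lapply(p[base_row, covs, drop = FALSE],
                                   as.numeric)))
  } else {
    matrix(0, n_subj, 0)
  }
  w_subj <- if ("weight" %in% names(p)) as.numeric(p$weight[base_row]) else
    rep(1, n_subj)

  is_known <- !is.na(p$state) & p$state %in% c(1, 2) & kind == "wave"
  is_death <- kind == "death" | (!is.na(p$state) & p$state == 3)
  is_cens  <- kind == "right_censor"
  is_nawave <- is.na(p$state) & kind == "wave"

  a0 <- a1 <- numeric(0); fr <- ty <- isub <- integer(0)

  k <- which(is_known)
  if (length(k) > 1L) {
    same <- subj_of[k[-1]] == subj_of[k[-length(k)]]
    i0 <- k[-length(k)][same]; i1 <- k[-1][same]
    if (any(p$state[i0] == 2 & p$state[i1] == 1)) {
      stop("observed CI -> CI-free pair; run assemble_panel() to recode ",
           "recoveries before fitting", call. = FALSE)
    }
    a0 <- c(a0, p$age[i0]); a1 <- c(a1, p$age[i1])
    fr <- c(fr, p$state[i0]); ty <- c(ty, p$state[i1])
    isub <- c(isub, subj_of[i0])
  }

  # last known living record per subject
  last_known_age <- rep(NA_real_, n_subj)
  last_known_state <- rep(NA_integer_, n_subj)
  if (length(k)) {
    lk <- k[!duplicated(subj_of[k], fromLast = TRUE)]
    last_known_age[subj_of[lk]] <- p$age[lk]
    last_known_state[subj_of[lk]] <- p$state[lk]
  }
  if (anyNA(last_known_age[unique(subj_of)])) {
    bad <- subj_ids[unique(subj_of)[is.na(last_known_age[unique(subj_of)])]]
    stop("subject(s) without any known living state (baseline unknown): ",
         paste(utils::head(bad, 5), collapse = ", "),
         "; run assemble_panel() first", call. = FALSE)
  }

  d <- which(is_death)
  if (any(duplicated(subj_of[d]))) {
    stop("multiple death records for a subject", call. = FALSE)
  }
  if (length(d)) {
    s <- subj_of[d]
    if (any(p$age[d] < last_known_age[s] - 1e-9)) {
      stop("death record earlier than a living observation", call. = FALSE)
    }
    a0 <- c(a0, last_known_age[s]); a1 <- c(a1, p$age[d])
    fr <- c(fr, last_known_state[s]); ty <- c(ty, rep(3L, length(d)))
    isub <- c(isub, s)
  }

  has_death <- logical(n_subj); has_death[subj_of[d]] <- TRUE

  # explicit right-censor records, then trailing missing living waves
  cn <- which(is_cens)
  cens_age <- rep(NA_real_, n_subj)
  if (length(cn)) cens_age[subj_of[cn]] <- p$age[cn]
  nw <- which(is_nawave)
  if (length(nw)) {
    s <- subj_of[nw]
    trail <- !has_death[s] & is.na(cens_age[s]) &
      p$age[nw] > last_known_age[s] + 1e-9
    if (any(trail)) {
      mx <- tapply(p$age[nw][trail], s[trail], max)
      cens_age[as.integer(names(mx))] <- as.numeric(mx)
    }
  }
  cs <- which(!is.na(cens_age) & !has_death)
  if (length(cs)) {
    a0 <- c(a0, last_known_age[cs]); a1 <- c(a1, cens_age[cs])
    fr <- c(fr, last_known_state[cs]); ty <- c(ty, rep(4L, length(cs)))
    isub <- c(isub, cs)
  }

  if (any(a1 < a0 - 1e-9)) stop("negative observation interval", call. = FALSE)

  # piece structure (fixed given the data; independent of parameters)
  if (spec$age_effect == "constant" || length(a0) == 0L) {
    npc <- rep(1L, length(a0))
  } else {
    npc <- pmax(1L, as.integer(ceiling((a1 - a0) / piece_step - 1e-9)))
  }
  pc_ivl <- rep(seq_along(a0), npc)
  within <- sequence(npc)
  pc_dt <- (a1 - a0)[pc_ivl] / npc[pc_ivl]
  pc_mid <- a0[pc_ivl] + (within - 0.5) * pc_dt
  end_idx <- cumsum(npc)
  start_idx <- end_idx - npc + 1L

  list(
    n_subjects = n_subj, subj_ids = subj_ids,
    a0 = a0, a1 = a1, from = fr, type = ty, ivl_subject = isub,
    X = X, base_weight = w_subj,
    pc_ivl = pc_ivl, pc_dt = pc_dt, pc_mid = pc_mid,
    start_idx = start_idx, end_idx = end_idx,
    n_trans = c(
      "12" = sum(ty == 2L & fr == 1L),
      "13" = sum(ty == 3L & fr == 1L),
      "23" = sum(ty == 3L & fr == 2L)
    )
  )
}

# Weighted panel log-likelihood for packed parameters theta given the
# precomputed interval structure. `weights` is per subject (frequency /
# post-stratification); returns -Inf (no error) for impossible paths.
panel_loglik_theta <- function(theta, pre, spec, weights = NULL) {
  if (length(pre$a0) == 0L) return(0)
  if (is.null(weights)) weights <- pre$base_weight
  lb <- theta[1:3]
  slope <- if (spec$age_effect == "gompertz") theta[4:6] else c(0, 0, 0)
  i <- if (spec$age_effect == "gompertz") 6L else 3L
  beta <- list()
  for (tr in TRANSITIONS) {
    cv <- spec$covariates[[tr]]
    beta[[tr]] <- if (length(cv)) theta[i + seq_along(cv)] else numeric(0)
    i <- i + length(cv)
  }
  trix <- c("12" = 1L, "13" = 2L, "23" = 3L)

  # per-subject covariate contribution, indexed down to pieces
  subj_eta <- function(tr) {
    cv <- spec$covariates[[tr]]
    if (!length(cv)) return(0)
    as.numeric(pre$X[, cv, drop = FALSE] %*% beta[[tr]])
  }
  e12 <- subj_eta("12"); e13 <- subj_eta("13"); e23 <- subj_eta("23")
  ps <- pre$ivl_subject[pre$pc_ivl]
  agec <- pre$pc_mid - spec$ref_age
  q12 <- exp(lb[1] + slope[1] * agec + if (length(e12) > 1) e12[ps] else e12)
  q13 <- exp(lb[2] + slope[2] * agec + if (length(e13) > 1) e13[ps] else e13)
  q23 <- exp(lb[3] + slope[3] * agec + if (length(e23) > 1) e23[ps] else e23)
  if (any(!is.finite(q12)) || any(!is.finite(q13)) || any(!is.finite(q23))) {
    return(-Inf)
  }
  pp <- piece_probs(q12, q13, q23, pre$pc_dt)

  C11 <- c(0, cumsum(pp$l11))
  C22 <- c(0, cumsum(pp$l22))
  st <- pre$start_idx; en <- pre$end_idx
  LP11 <- C11[en + 1L] - C11[st]      # log P11 per interval, exact
  LP22 <- C22[en + 1L] - C22[st]

  st_pc <- st[pre$pc_ivl]; en_pc <- en[pre$pc_ivl]
  pcs <- seq_along(pre$pc_ivl)
  term <- pp$p12 * exp((C11[pcs] - C11[st_pc]) +
                         (C22[en_pc + 1L] - C22[pcs + 1L]))
  Tm <- c(0, cumsum(term))
  P12 <- Tm[en + 1L] - Tm[st]

  contrib <- numeric(length(pre$a0))
  fr <- pre$from; ty <- pre$type

  i1 <- ty == 1L
  contrib[i1] <- LP11[i1]                     # necessarily from state 1
  i2 <- ty == 2L
  contrib[i2] <- ifelse(fr[i2] == 1L, log(P12[i2]), LP22[i2])
  i3 <- which(ty == 3L)
  if (length(i3)) {
    s <- pre$ivl_subject[i3]
    ac <- pre$a1[i3] - spec$ref_age          # intensity at death age (left limit)
    qd13 <- exp(lb[2] + slope[2] * ac +
                  (if (length(e13) > 1) e13[s] else e13))
    qd23 <- exp(lb[3] + slope[3] * ac +
                  (if (length(e23) > 1) e23[s] else e23))
    from1 <- fr[i3] == 1L
    dens <- ifelse(from1,
                   exp(LP11[i3]) * qd13 + P12[i3] * qd23,
                   exp(LP22[i3]) * qd23)
    contrib[i3] <- log(dens)
  }
  i4 <- ty == 4L
  contrib[i4] <- ifelse(fr[i4] == 1L,
                        log(exp(LP11[i4]) + P12[i4]), LP22[i4])

  ll <- sum(weights[pre$ivl_subject] * contrib)
  if (is.nan(ll)) -Inf else ll
}

#' Log-likelihood contribution of one subject
#'
#' Evaluates the interval-censored illness-death log-likelihood for a single
#' subject's observation sequence. Consecutive known living states
#' contribute the log transition probability of the observed state pair; an
#' exactly observed death after last living state s at age t0 contributes
#' `log(sum_r P_sr(t0, t) q_r3(t))`; a terminal alive-but-state-unknown
#' record contributes `log(sum_r P_sr)` (right censoring). Living waves with
#' missing state are bridged, so they change nothing. The total is
#' multiplied by the subject weight. A path of probability zero yields
#' `-Inf` with a warning rather than an error so optimizers can recover.
#'
#' @inheritParams intensity_matrix
#' @param observations Data frame with columns `age`, `state` (1, 2, 3 or
#'   `NA`) and optionally `record_kind`.
#' @param weight Positive subject weight multiplying the contribution.
#' @param piece_step Maximum piece length (years) for the piecewise
#'   constant-intensity approximation when intensities vary with age.
#' @return The weighted log-likelihood (scalar, possibly `-Inf`).
#' @examples
#' p <- intensity_params(0.1, 0.05, 0.2)
#' obs <- data.frame(age = c(70, 72), state = c(1, 1))
#' subject_loglik(p, obs)  # log exp(-0.15 * 2) = -0.3
#' @export
subject_loglik <- function(params, observations, profile = NULL, weight = 1,
                           piece_step = 0.25) {
  stopifnot(inherits(params, "intensity_params"), weight > 0)
  panel <- data.frame(subject_id = 1L, age = observations$age,
                      state = observations$state)
  if (!is.null(observations$record_kind)) {
    panel$record_kind <- observations$record_kind
  }
  covs <- names(profile)
  for (nm in covs) panel[[nm]] <- as.numeric(profile[[nm]])
  spec <- illness_death_spec(
    covariates = if (length(covs)) {
      stats::setNames(rep(list(covs), 3), TRANSITIONS)
    } else {
      list()
    },
    age_effect = if (all(params$age_slope == 0)) "constant" else "gompertz",
    ref_age = params$ref_age
  )
  # align packed coefficient order with the spec (zeros where absent)
  pre <- build_intervals(panel, spec, piece_step = piece_step)
  theta <- params_to_theta(params, spec)
  ll <- panel_loglik_theta(theta, pre, spec, weights = weight)
  if (!is.finite(ll)) {
    warning("observed path has zero probability under these parameters",
            call. = FALSE)
  }
  ll
}

#' Fit the progressive illness-death model by maximum likelihood
#'
#' Maximizes the weighted interval-censored panel log-likelihood over the
#' packed parameter vector (baseline log-intensities, optional age slopes,
#' covariate log hazard ratios) by quasi-Newton (BFGS) search with
#' finite-difference gradients. Starting values are crude occurrence /
#' exposure rates with zero covariate and age effects unless supplied. The
#' covariance matrix is the inverse of the numerically differentiated
#' observed information at the optimum.
#'
#' @param panel Panel data frame (see [assemble_panel()] /
#'   [generate_cohort()]): columns `subject_id`, `age`, `state`, optional
#'   `record_kind` and `weight`, plus any covariate columns named in `spec`.
#' @param spec An [illness_death_spec()].
#' @param weights Optional per-subject weight vector named by subject id;
#'   overrides a `weight` column. Treated as frequency weights in the
#'   likelihood (no sandwich correction of the covariance).
#' @param piece_step Piece length (years) for age-varying intensities.
#' @param start Optional starting parameter vector (packed order of
#'   `spec_par_names`-style: baselines, age slopes, covariate effects).
#' @param control Passed to [stats::optim()] (defaults: `maxit = 500`,
#'   `reltol = 1e-10`, `ndeps = 1e-6`).
#' @return An object of class `illness_death_fit`: list with elements
#'   `params` ([intensity_params()] at the optimum), `theta`, `se`, `vcov`,
#'   `loglik`, `convergence` (code, gradient norm, function evaluations),
#'   `n_subjects`, `n_transitions`, `non_identified` (names of transitions
#'   with no observed events; their standard errors are `NA`).
#' @examples
#' \donttest{
#' cfg <- simulation_config(n_subjects = 400,
#'   true_params = intensity_params(0.1, 0.05, 0.2), seed = 1)
#' coh <- generate_cohort(cfg)
#' fit <- fit_illness_death(coh$panel,
#'   illness_death_spec(age_effect = "constant"))
#' coef(fit)
#' }
#' @export
fit_illness_death <- function(panel, spec, weights = NULL, piece_step = 0.25,
                              start = NULL, control = list()) {
  stopifnot(inherits(spec, "illness_death_spec"))
  pre <- build_intervals(panel, spec, piece_step = piece_step)
  if (!is.null(weights)) {
    w <- weights[match(pre$subj_ids, names(weights))]
    if (anyNA(w)) stop("'weights' must cover every subject id", call. = FALSE)
    pre$base_weight <- as.numeric(w)
  }
  fit_from_intervals(pre, spec, start = start, control = control)
}

# Core fitter over a precomputed interval structure (reused by the
# bootstrap, which only reweights subjects).
fit_from_intervals <- function(pre, spec, weights = NULL, start = NULL,
                               control = list(), hessian = TRUE) {
  if (is.null(weights)) weights <- pre$base_weight
  nm <- spec_par_names(spec)
  npar <- length(nm)

  non_id <- TRANSITIONS[pre$n_trans == 0]
  if (is.null(start)) {
    # crude occurrence/exposure rates: observed events over person-years at
    # risk in the origin state (0.5 continuity shift guards empty cells)
    py1 <- sum((pre$a1 - pre$a0)[pre$from == 1L]) + 1
    py2 <- sum((pre$a1 - pre$a0)[pre$from == 2L]) + 1
    crude <- log((pre$n_trans + 0.5) / c(py1, py1, py2))
    start <- stats::setNames(numeric(npar), nm)
    start[1:3] <- crude
  }
  ctrl <- utils::modifyList(
    list(maxit = 500L, reltol = 1e-10, ndeps = rep(1e-6, npar)), control)

  negll <- function(th) {
    v <- -panel_loglik_theta(th, pre, spec, weights = weights)
    if (!is.finite(v)) 1e10 else v
  }
  opt <- stats::optim(start, negll, method = "BFGS", control = ctrl)

  grad <- num_grad(negll, opt$par)
  se <- rep(NA_real_, npar)
  V <- matrix(NA_real_, npar, npar, dimnames = list(nm, nm))
  if (hessian) {
    H <- stats::optimHess(opt$par, negll,
                          control = list(ndeps = rep(1e-4, npar)))
    H <- (H + t(H)) / 2
    Vi <- try(solve(H), silent = TRUE)
    if (!inherits(Vi, "try-error") && all(is.finite(diag(Vi))) &&
        all(diag(Vi) > 0)) {
      V <- Vi
      dimnames(V) <- list(nm, nm)
      se <- sqrt(diag(V))
    }
  }
  if (length(non_id)) {
    se[match(paste0("log_q", non_id), nm)] <- NA_real_
  }

  structure(list(
    params = theta_to_params(stats::setNames(opt$par, nm), spec),
    spec = spec,
    theta = stats::setNames(opt$par, nm),
    se = stats::setNames(se, nm),
    vcov = V,
    loglik = -opt$value,
    convergence = list(code = opt$convergence,
                       gradient_norm = sqrt(sum(grad^2)),
                       counts = opt$counts),
    n_subjects = pre$n_subjects,
    n_transitions = pre$n_trans,
    non_identified = non_id
  ), class = "illness_death_fit")
}

num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h * max(1, abs(x[i]))
    (f(x + e) - f(x - e)) / (2 * e[i])
  }, numeric(1))
}

#' @export
print.illness_death_fit <- function(x, ...) {
  cat("Progressive illness-death model fit\n")
  cat(sprintf("  subjects: %d; observed transitions 1->2: %d, 1->3: %d, 2->3: %d\n",
              x$n_subjects, x$n_transitions[["12"]], x$n_transitions[["13"]],
              x$n_transitions[["23"]]))
  cat(sprintf("  log-likelihood: %.4f (convergence code %d, |grad| %.2e)\n",
              x$loglik, x$convergence$code, x$convergence$gradient_norm))
  est <- cbind(estimate = x$theta, se = x$se)
  print(round(est, 4))
  if (length(x$non_identified)) {
    cat("  non-identified transition(s):",
        paste(x$non_identified, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.illness_death_fit <- function(object, ...) object$theta

#' @export
vcov.illness_death_fit <- function(object, ...) object$vcov

#' @export
logLik.illness_death_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$theta), class = "logLik")
}
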