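#' Transition intensity parameters for the progressive illness-death model
#'
#' Bundles the parameters of the three allowed transitions of the progressive
#' illness-death model: 1 (CI-free) -> 2 (CI), 1 -> 3 (dead), 2 -> 3 (dead).
#' Each transition intensity is log-linear in age and covariates,
#' \deqn{q_{rs}(a, x) = \exp\{\beta_{0,rs} + \beta_{a,rs}(a - a_0) +
#'   \beta_{x,rs}' x\},}
#' where `a_0` is a reference age used to centre the age effect for numeric
#' conditioning. With `age_slope = 0` the intensities are constant in age
#' (exponential sojourn times); a positive slope gives a Gompertz-type hazard.
#'
#' @param q12,q13,q23 Baseline intensities (per year, at the reference age and
#'   reference covariate values). Must be positive and finite.
#' @param age_slope Numeric length 3 (order 1->2, 1->3, 2->3): log-intensity
#'   increase per year of age.
#' @param coefs Named list of per-transition covariate coefficient vectors.
#'   Names must be among `"12"`, `"13"`, `"23"`; each element is a named
#'   numeric vector (log-hazard-ratio scale). Covariates absent from a
#'   profile are treated as 0 (reference level).
#' @param ref_age Reference (centering) age in years.
#'
#' @return An object of class `intensity_params`.
#' @examples
#' intensity_params(q12 = 0.1, q13 = 0.05, q23 = 0.2)
#' intensity_params(0.08, 0.04, 0.15, age_slope = c(0.08, 0.09, 0.09),
#'                  coefs = list("12" = c(diet = -log(1.5))), ref_age = 65)
#' @export
intensity_params <- function(q12, q13, q23, age_slope = c(0, 0, 0),
                             coefs = list(), ref_age = 65) {
  rates <- c(q12, q13, q23)
  if (!is.numeric(rates) || length(rates) != 3L || any(!is.finite(rates)) ||
      any(rates < 0)) {
    stop("baseline intensities must be finite and non-negative", call. = FALSE)
  }
  if (length(age_slope) != 3L || any(!is.finite(age_slope))) {
    stop("'age_slope' must be three finite values", call. = FALSE)
  }
  if (length(coefs)) {
    if (is.null(names(coefs)) || !all(names(coefs) %in% TRANSITIONS)) {
      stop("names of 'coefs' must be among \"12\", \"13\", \"23\"",
           call. = FALSE)
    }
    for (b in coefs) {
      if (length(b) && (is.null(names(b)) || any(!is.finite(b)))) {
        stop("covariate coefficients must be named and finite", call. = FALSE)
      }
    }
  }
  # log(0) = -Inf encodes a structurally absent transition; allowed in
  # simulation truth, rejected at likelihood evaluation if it makes an
  # observed path impossible.
  lb <- log(rates)
  names(lb) <- TRANSITIONS
  age_slope <- stats::setNames(as.numeric(age_slope), TRANSITIONS)
  structure(
    list(log_baseline = lb, age_slope = age_slope, coefs = coefs,
         ref_age = ref_age),
    class = "intensity_params"
  )
}

TRANSITIONS <- c("12", "13", "23")

#' @export
print.intensity_params <- function(x, ...) {
  cat("Progressive illness-death intensity parameters\n")
  cat(sprintf("  reference age: %g years\n", x$ref_age))
  for (tr in TRANSITIONS) {
    cat(sprintf("  %s->%s: baseline %.5g /yr, age slope %.4g /yr",
                substr(tr, 1, 1), substr(tr, 2, 2),
                exp(x$log_baseline[[tr]]), x$age_slope[[tr]]))
    b <- x$coefs[[tr]]
    if (length(b)) {
      cat(", log-HR: ",
          paste(sprintf("%s=%.3g", names(b), b), collapse = ", "), sep = "")
    }
    cat("\n")
  }
  invisible(x)
}

#' Model specification for fitting the illness-death model
#'
#' Declares which covariates enter each transition and whether the
#' intensities carry a log-linear (Gompertz-type) age effect. The allowed
#' transitions are fixed at 1->2, 1->3 and 2->3; recovery (2->1) is
#' structurally impossible.
#'
#' @param covariates Named list with elements `"12"`, `"13"`, `"23"` (missing
#'   elements default to none), each a character vector of covariate column
#'   names entering that transition's intensity.
#' @param age_effect `"gompertz"` for log-linear age dependence of all three
#'   intensities, `"constant"` for age-homogeneous intensities.
#' @param ref_age Reference age (years) at which baseline intensities are
#'   anchored; usually the starting age of the expectancy calculation.
#'
#' @return An object of class `illness_death_spec`.
#' @examples
#' illness_death_spec(covariates = list("12" = "diet", "13" = "diet",
#'                                      "23" = "diet"))
#' @export
illness_death_spec <- function(covariates = list(),
                               age_effect = c("gompertz", "constant"),
                               ref_age = 65) {
  age_effect <- match.arg(age_effect)
  covs <- list("12" = character(), "13" = character(), "23" = character())
  if (length(covariates)) {
    if (is.null(names(covariates)) ||
        !all(names(covariates) %in% TRANSITIONS)) {
      stop("names of 'covariates' must be among \"12\", \"13\", \"23\"",
           call. = FALSE)
    }
    for (tr in names(covariates)) covs[[tr]] <- as.character(covariates[[tr]])
  }
  structure(
    list(covariates = covs, age_effect = age_effect, ref_age = ref_age),
    class = "illness_death_spec"
  )
}

#' @export
print.illness_death_spec <- function(x, ...) {
  cat("Illness-death model specification\n")
  cat(sprintf("  age effect: %s (reference age %g)\n", x$age_effect, x$ref_age))
  for (tr in TRANSITIONS) {
    cv <- x$covariates[[tr]]
    cat(sprintf("  %s->%s ~ %s\n", substr(tr, 1, 1), substr(tr, 2, 2),
                if (length(cv)) paste(cv, collapse = " + ") else "1"))
  }
  invisible(x)
}

# Names and layout of the packed parameter vector for a model spec.
spec_par_names <- function(spec) {
  nm <- paste0("log_q", TRANSITIONS)
  if (spec$age_effect == "gompertz") nm <- c(nm, paste0("age_q", TRANSITIONS))
  for (tr in TRANSITIONS) {
    cv <- spec$covariates[[tr]]
    if (length(cv)) nm <- c(nm, paste0("q", tr, ":", cv))
  }
  nm
}

# Unpack an optimizer vector into an intensity_params object.
theta_to_params <- function(theta, spec) {
  lb <- theta[1:3]
  i <- 3L
  if (spec$age_effect == "gompertz") {
    slope <- theta[4:6]
    i <- 6L
  } else {
    slope <- c(0, 0, 0)
  }
  coefs <- list()
  for (tr in TRANSITIONS) {
    cv <- spec$covariates[[tr]]
    if (length(cv)) {
      coefs[[tr]] <- stats::setNames(theta[i + seq_along(cv)], cv)
      i <- i + length(cv)
    }
  }
  p <- intensity_params(1, 1, 1, age_slope = slope, coefs = coefs,
                        ref_age = spec$ref_age)
  p$log_baseline <- stats::setNames(as.numeric(lb), TRANSITIONS)
  p
}

params_to_theta <- function(params, spec) {
  th <- as.numeric(params$log_baseline)
  if (spec$age_effect == "gompertz") th <- c(th, as.numeric(params$age_slope))
  for (tr in TRANSITIONS) {
    cv <- spec$covariates[[tr]]
    if (length(cv)) {
      b <- params$coefs[[tr]]
      th <- c(th, ifelse(cv %in% names(b), b[cv], 0))
    }
  }
  stats::setNames(th, spec_par_names(spec))
}

# Linear predictor components for one transition at given ages and a single
# covariate profile (named vector or NULL); vectorized over age.
transition_intensity <- function(params, tr, age, profile = NULL) {
  eta <- params$log_baseline[[tr]] + params$age_slope[[tr]] *
    (age - params$ref_age)
  b <- params$coefs[[tr]]
  if (length(b)) {
    x <- numeric(length(b))
    if (!is.null(profile)) {
      hit <- names(b) %in% names(profile)
      x[hit] <- as.numeric(profile[names(b)[hit]])
    }
    eta <- eta + sum(b * x)
  }
  exp(eta)
}
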