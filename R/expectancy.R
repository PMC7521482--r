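#' Age grid for multistate life-table integration
#'
#' @param start_age Starting age of the expectancy calculation (years).
#' @param max_age Upper truncation age (years); survivorship beyond it is
#'   reported as truncation mass.
#' @param step Grid step in years; `(max_age - start_age) / step` must be a
#'   whole number.
#' @return An object of class `age_grid` with fields `start_age`, `max_age`,
#'   `step`, `ages` (grid points including both ends).
#' @examples
#' age_grid(65)
#' @export
age_grid <- function(start_age, max_age = 110, step = 1 / 12) {
  stopifnot(step > 0)
  if (start_age >= max_age) {
    stop("'start_age' must be below 'max_age'", call. = FALSE)
  }
  n <- (max_age - start_age) / step
  if (abs(n - round(n)) > 1e-6) {
    stop("(max_age - start_age) must be a whole number of steps",
         call. = FALSE)
  }
  n <- as.integer(round(n))
  structure(list(start_age = start_age, max_age = max_age, step = step,
                 ages = start_age + (0:n) * step),
            class = "age_grid")
}

#' State-occupancy probabilities over an age grid
#'
#' Computes, for a covariate profile, the probabilities of occupying each
#' living state at every grid age conditional on the state at the starting
#' age: `p11`, `p12`, `p13` from CI-free and `p22`, `p23` from CI. Each grid
#' cell's transition matrix uses the piecewise constant-intensity solution
#' (intensities frozen at the cell midpoint, subdivided to at most
#' `piece_step`); cells are composed sequentially (Chapman-Kolmogorov), so
#' the curves start at the identity row.
#'
#' @inheritParams intensity_matrix
#' @param grid An [age_grid()].
#' @param piece_step Maximum piece length in years.
#' @return Data frame with columns `age`, `p11`, `p12`, `p13`, `p22`, `p23`.
#' @examples
#' p <- intensity_params(0.1, 0.05, 0.2)
#' occ <- occupancy_curve(p, grid = age_grid(65, 80))
#' occ[occ$age == 66, "p11"]  # exp(-0.15)
#' @export
occupancy_curve <- function(params, profile = NULL, grid, piece_step = 0.25) {
  stopifnot(inherits(params, "intensity_params"), inherits(grid, "age_grid"))
  ages <- grid$ages
  n <- length(ages) - 1L
  sub <- max(1L, as.integer(ceiling(grid$step / piece_step - 1e-9)))
  dt <- grid$step / sub
  mids <- rep(ages[-length(ages)], each = sub) +
    (rep(seq_len(sub), n) - 0.5) * dt
  q12 <- transition_intensity(params, "12", mids, profile)
  q13 <- transition_intensity(params, "13", mids, profile)
  q23 <- transition_intensity(params, "23", mids, profile)
  if (!all(is.finite(c(q12, q13, q23)))) {
    stop("non-finite transition intensity on the age grid", call. = FALSE)
  }
  pp <- piece_probs(q12, q13, q23, dt)

  m <- n * sub
  P11 <- exp(cumsum(pp$l11))
  P22 <- exp(cumsum(pp$l22))
  # first-order recurrence P12_k = P11_{k-1} p12_k + P12_{k-1} p22_k;
  # linear-space recursion is unconditionally stable (all terms in [0,1])
  P12 <- numeric(m)
  prev11 <- 1; prev12 <- 0
  for (k in seq_len(m)) {
    prev12 <- prev11 * pp$p12[k] + prev12 * pp$p22[k]
    prev11 <- P11[k]
    P12[k] <- prev12
  }
  keep <- seq_len(n) * sub
  p11 <- c(1, P11[keep]); p12 <- c(0, P12[keep]); p22 <- c(1, P22[keep])
  data.frame(age = ages, p11 = p11, p12 = p12,
             p13 = pmax(0, 1 - p11 - p12),
             p22 = p22, p23 = pmax(0, 1 - p22))
}

#' Life expectancies by cognitive state (multistate life table)
#'
#' Integrates the state-occupancy curves over age (trapezoidal rule) to
#' obtain the expected years lived in each state from the starting age:
#' `e11` (years CI-free, starting CI-free), `e12` (years with CI, starting
#' CI-free) and `e22` (years with CI, starting with CI). Derived summaries:
#' total life expectancy TLE = e11 + e12, CI-free life expectancy
#' CIFLE = e11, CI life expectancy CILE = e12, and the proportion of
#' remaining life free of CI, 100 * CIFLE / TLE.
#'
#' @inheritParams occupancy_curve
#' @param truncation_error Probability of being alive at `max_age` (from the
#'   CI-free start) above which an error is raised; above `1e-3` a warning
#'   is issued. Raise `max_age` if triggered.
#' @return Object of class `expectancy_result`: list with `start_age`,
#'   `profile`, `e11`, `e12`, `e22`, `tle`, `cifle`, `cile`,
#'   `proportion_cifle` (percent), `truncation_mass`.
#' @examples
#' p <- intensity_params(0.1, 0.05, 0.2)
#' ex <- expectancies(p, grid = age_grid(65, 150))
#' ex$cifle  # ~ 1 / 0.15
#' @export
expectancies <- function(params, profile = NULL, grid, piece_step = 0.25,
                         truncation_error = 0.05) {
  occ <- occupancy_curve(params, profile, grid, piece_step = piece_step)
  trunc_mass <- occ$p11[nrow(occ)] + occ$p12[nrow(occ)]
  if (trunc_mass > truncation_error) {
    stop(sprintf(paste0("probability alive at max age is %.3g; raise the ",
                        "grid's max_age"), trunc_mass), call. = FALSE)
  }
  if (trunc_mass > 1e-3) {
    warning(sprintf("truncation mass %.3g at max age %g", trunc_mass,
                    grid$max_age), call. = FALSE)
  }
  trap <- function(y) grid$step * (sum(y) - (y[1] + y[length(y)]) / 2)
  e11 <- trap(occ$p11)
  e12 <- trap(occ$p12)
  e22 <- trap(occ$p22)
  tle <- e11 + e12
  structure(list(
    start_age = grid$start_age, profile = profile,
    e11 = e11, e12 = e12, e22 = e22,
    tle = tle, cifle = e11, cile = e12,
    proportion_cifle = 100 * e11 / tle,
    truncation_mass = trunc_mass,
    grid = grid
  ), class = "expectancy_result")
}

#' @export
print.expectancy_result <- function(x, ...) {
  cat(sprintf("Cognitive health expectancy at age %g\n", x$start_age))
  if (length(x$profile)) {
    cat("  profile:",
        paste(sprintf("%s=%g", names(x$profile), as.numeric(x$profile)),
              collapse = ", "), "\n")
  }
  cat(sprintf("  TLE   %.2f years\n  CIFLE %.2f years\n  CILE  %.2f years\n",
              x$tle, x$cifle, x$cile))
  cat(sprintf("  proportion of life free of CI: %.1f%%\n", x$proportion_cifle))
  cat(sprintf("  years with CI from CI state (e22): %.2f\n", x$e22))
  if (x$truncation_mass > 1e-6) {
    cat(sprintf("  truncation mass at age %g: %.2g\n", x$grid$max_age,
                x$truncation_mass))
  }
  invisible(x)
}
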