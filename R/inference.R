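#' Point differences between two expectancy results
#'
#' Differences are taken as `b` minus `a` (reference first) for total life
#' expectancy, CI-free life expectancy and the proportion of life free of
#' CI (percentage points). The start ages must match.
#'
#' @param a,b [expectancies()] results (reference group first).
#' @return Named list: `d_tle`, `d_cifle`, `d_cile`, `d_prop`.
#' @export
expectancy_difference <- function(a, b) {
  stopifnot(inherits(a, "expectancy_result"), inherits(b, "expectancy_result"))
  if (a$start_age != b$start_age) {
    stop("expectancy results have different start ages", call. = FALSE)
  }
  list(d_tle = b$tle - a$tle,
       d_cifle = b$cifle - a$cifle,
       d_cile = b$cile - a$cile,
       d_prop = b$proportion_cifle - a$proportion_cifle)
}

#' Build a difference estimate from point values and confidence intervals
#'
#' Convenience constructor for a one-row difference record in the layout
#' produced by [bootstrap_differences()], e.g. for feeding published
#' difference tuples to [classify_change()].
#'
#' @param label Comparison label ("level vs reference").
#' @param d_tle,d_cifle,d_prop Point differences (years, years, percentage
#'   points).
#' @param tle_ci,cifle_ci,prop_ci Length-2 vectors `(lower, upper)` of the
#'   95 percent intervals.
#' @param B,seed Optional bootstrap metadata.
#' @return One-row data frame with the difference columns.
#' @examples
#' difference_estimate("healthy vs unhealthy diet",
#'   d_tle = 0.8, tle_ci = c(0.3, 1.3),
#'   d_cifle = 1.0, cifle_ci = c(0.5, 1.5),
#'   d_prop = 1.8, prop_ci = c(1.1, 3.1))
#' @export
difference_estimate <- function(label, d_tle, tle_ci, d_cifle, cifle_ci,
                                d_prop, prop_ci, B = NA_integer_,
                                seed = NA_integer_) {
  stopifnot(length(tle_ci) == 2L, length(cifle_ci) == 2L,
            length(prop_ci) == 2L)
  data.frame(comparison = label,
             d_tle = d_tle, d_tle_lo = tle_ci[1], d_tle_hi = tle_ci[2],
             d_cifle = d_cifle, d_cifle_lo = cifle_ci[1],
             d_cifle_hi = cifle_ci[2],
             d_prop = d_prop, d_prop_lo = prop_ci[1], d_prop_hi = prop_ci[2],
             B = B, seed = seed)
}

#' Bootstrap differences in expectancies between exposure levels
#'
#' Fits the illness-death model, computes expectancies at each level of one
#' exposure (other covariates held at `profile`, default reference), and
#' builds percentile bootstrap confidence intervals for the differences by
#' resampling subjects (not observations) with replacement and refitting.
#' Resampling is realized as multinomial frequency weights on the
#' precomputed likelihood structure, with each replicate's optimizer
#' started at the full-data estimate. Replicates that fail to converge are
#' dropped and counted; more than 10 percent failures flags the result
#' unreliable. Deterministic given `seed`.
#'
#' @inheritParams fit_illness_death
#' @param exposure Name of the exposure covariate (must appear in `spec`).
#' @param levels Numeric values of the exposure; the first is the
#'   reference.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param start_ages Starting ages for the expectancy calculations.
#' @param max_age,grid_step Life-table grid settings.
#' @param profile Baseline covariate profile for the non-exposure
#'   covariates (default: all at 0).
#' @param reweight Optional `function(subject_ids, counts)` returning new
#'   per-subject weights for a replicate (e.g. recomputed
#'   post-stratification weights); the default multiplies baseline weights
#'   by the resample counts.
#' @return Object of class `bootstrap_differences`: list with
#'   `differences` (data frame: `start_age`, `comparison`, point and CI
#'   columns as in [difference_estimate()]), `expectancies` (per level and
#'   age), `fit` (full-data fit), `B`, `B_failed`, `seed`, `unreliable`.
#' @export
bootstrap_differences <- function(panel, spec, exposure, levels = c(0, 1),
                                  B = 500, seed = 1L, start_ages = c(65, 85),
                                  max_age = 110, grid_step = 1 / 12,
                                  piece_step = 0.25, profile = NULL,
                                  weights = NULL, reweight = NULL) {
  stopifnot(B >= 2, length(levels) >= 2)
  if (!exposure %in% unlist(spec$covariates)) {
    stop("'", exposure, "' is not a covariate of the model spec",
         call. = FALSE)
  }
  pre <- build_intervals(panel, spec, piece_step = piece_step)
  if (!is.null(weights)) {
    w <- weights[match(pre$subj_ids, names(weights))]
    if (anyNA(w)) stop("'weights' must cover every subject id", call. = FALSE)
    pre$base_weight <- as.numeric(w)
  }
  fit <- fit_from_intervals(pre, spec)
  if (fit$convergence$code != 0) {
    stop("full-data fit did not converge", call. = FALSE)
  }

  level_profile <- function(lv) {
    pr <- if (is.null(profile)) numeric(0) else profile
    pr[exposure] <- lv
    pr
  }
  exp_for <- function(params) {
    res <- list()
    for (age in start_ages) {
      g <- age_grid(age, max_age, grid_step)
      for (lv in levels) {
        ex <- expectancies(params, level_profile(lv), g,
                           piece_step = piece_step)
        res[[paste(age, lv)]] <- c(age = age, level = lv, tle = ex$tle,
                                   cifle = ex$cifle,
                                   prop = ex$proportion_cifle)
      }
    }
    do.call(rbind, res)
  }
  point <- exp_for(fit$params)

  set.seed(seed)
  n <- pre$n_subjects
  boot <- vector("list", B)
  failed <- 0L
  for (b in seq_len(B)) {
    counts <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
    wb <- if (is.null(reweight)) {
      pre$base_weight * counts
    } else {
      reweight(pre$subj_ids, counts)
    }
    rb <- try({
      fb <- fit_from_intervals(pre, spec, weights = wb, start = fit$theta,
                               hessian = FALSE)
      if (fb$convergence$code != 0) stop("no convergence")
      suppressWarnings(exp_for(fb$params))
    }, silent = TRUE)
    if (inherits(rb, "try-error")) {
      failed <- failed + 1L
    } else {
      boot[[b]] <- rb
    }
  }
  boot <- boot[!vapply(boot, is.null, logical(1))]
  if (length(boot) < 2) {
    stop("fewer than two bootstrap replicates converged", call. = FALSE)
  }
  unreliable <- failed > 0.1 * B
  if (unreliable) {
    warning(failed, " of ", B, " bootstrap replicates failed; intervals ",
            "flagged unreliable", call. = FALSE)
  }

  row_of <- function(m, age, lv) m[m[, "age"] == age & m[, "level"] == lv, ]
  diffs <- list()
  for (age in start_ages) {
    ref <- levels[1]
    for (lv in levels[-1]) {
      pd <- row_of(point, age, lv) - row_of(point, age, ref)
      bd <- vapply(boot, function(m) {
        d <- row_of(m, age, lv) - row_of(m, age, ref)
        c(d[["tle"]], d[["cifle"]], d[["prop"]])
      }, numeric(3))
      qs <- apply(bd, 1, stats::quantile, probs = c(0.025, 0.975),
                  names = FALSE)
      diffs[[paste(age, lv)]] <- data.frame(
        start_age = age,
        comparison = paste0(exposure, "=", lv, " vs ", exposure, "=", ref),
        d_tle = pd[["tle"]], d_tle_lo = qs[1, 1], d_tle_hi = qs[2, 1],
        d_cifle = pd[["cifle"]], d_cifle_lo = qs[1, 2],
        d_cifle_hi = qs[2, 2],
        d_prop = pd[["prop"]], d_prop_lo = qs[1, 3], d_prop_hi = qs[2, 3],
        B = length(boot), seed = seed
      )
    }
  }
  exps <- as.data.frame(point)
  rownames(exps) <- NULL
  structure(list(
    differences = do.call(rbind, c(diffs, list(make.row.names = FALSE))),
    expectancies = exps, fit = fit, B = B, B_failed = failed,
    seed = seed, unreliable = unreliable
  ), class = "bootstrap_differences")
}

#' @export
print.bootstrap_differences <- function(x, ...) {
  cat(sprintf("Bootstrap expectancy differences (B = %d, %d failed%s)\n",
              x$B, x$B_failed,
              if (x$unreliable) ", UNRELIABLE" else ""))
  d <- x$differences
  for (i in seq_len(nrow(d))) {
    cat(sprintf(
      paste0("  age %g, %s: dTLE %.2f (%.2f to %.2f), dCIFLE %.2f ",
             "(%.2f to %.2f), dProp %.1f (%.1f to %.1f)\n"),
      d$start_age[i], d$comparison[i],
      d$d_tle[i], d$d_tle_lo[i], d$d_tle_hi[i],
      d$d_cifle[i], d$d_cifle_lo[i], d$d_cifle_hi[i],
      d$d_prop[i], d$d_prop_lo[i], d$d_prop_hi[i]))
  }
  invisible(x)
}

#' Classify the change in cognitive health expectancy
#'
#' Deterministic CI-based operationalization of three verbal categories of
#' change in years of life free of CI between an exposed group and its
#' reference:
#' \itemize{
#'   \item `absolute_increase` -- the gain in CI-free years is significant
#'     (its 95 percent CI excludes 0 from below) and exceeds the gain in
#'     total years, i.e. no CI years are added;
#'   \item `relative_increase` -- otherwise, the proportion of remaining
#'     life free of CI rises significantly;
#'   \item `relative_reduction` -- the proportion falls significantly;
#'   \item `no_change` -- none of the above.
#' }
#' The rule is a single function so alternative operationalizations can be
#' swapped in.
#'
#' @param diff Data frame with columns `d_tle`, `d_cifle`, `d_cifle_lo`,
#'   `d_prop_lo`, `d_prop_hi` (e.g. from [bootstrap_differences()] or
#'   [difference_estimate()]); any number of rows.
#' @return Character vector of classifications, one per row.
#' @examples
#' d <- difference_estimate("healthy diet", 0.8, c(0.3, 1.3),
#'                          1.0, c(0.5, 1.5), 1.8, c(1.1, 3.1))
#' classify_change(d)  # absolute_increase
#' @export
classify_change <- function(diff) {
  need <- c("d_tle", "d_cifle", "d_cifle_lo", "d_prop_lo", "d_prop_hi")
  if (!all(need %in% names(diff))) {
    stop("'diff' lacks column(s): ",
         paste(setdiff(need, names(diff)), collapse = ", "), call. = FALSE)
  }
  ifelse(diff$d_cifle_lo > 0 & diff$d_cifle > diff$d_tle,
         "absolute_increase",
         ifelse(diff$d_prop_lo > 0, "relative_increase",
                ifelse(diff$d_prop_hi < 0, "relative_reduction",
                       "no_change")))
}

#' Write report tables of expectancies and differences
#'
#' Produces one CSV per group x starting age in the layout of published
#' cognitive-health-expectancy tables: a Variables column, point TLE,
#' CIFLE and proportion of CIFLE, and the three formatted
#' difference-with-CI columns, with the reference level of each variable
#' marked "Reference". Comparisons requested but absent from the input are
#' listed in a `gaps.csv` rather than silently dropped.
#'
#' @param expectancies Data frame with columns `group`, `start_age`,
#'   `variable`, `level`, `is_reference`, `tle`, `cifle`, `prop`.
#' @param differences Data frame with columns `group`, `start_age`,
#'   `variable`, `level` plus the difference columns of
#'   [difference_estimate()].
#' @param dir Output directory (created if needed).
#' @param expected Optional data frame `group`, `start_age`, `variable`,
#'   `level` of comparisons that must be present.
#' @return Invisibly, the paths of the files written.
#' @export
report_tables <- function(expectancies, differences, dir, expected = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x, lo, hi, digits) {
    sprintf(paste0("%.", digits, "f (%.", digits, "f to %.", digits, "f)"),
            x, lo, hi)
  }
  header <- c("Variables", "TLE", "CIFLE", "Proportion of CIFLE (%)",
              "Difference in TLE (95%CI)", "Difference in CIFLE (95%CI)",
              "Difference in proportion of CIFLE (95%CI)")
  paths <- character(0)
  combos <- unique(expectancies[c("group", "start_age")])
  for (i in seq_len(nrow(combos))) {
    g <- combos$group[i]; a <- combos$start_age[i]
    ex <- expectancies[expectancies$group == g &
                         expectancies$start_age == a, , drop = FALSE]
    rows <- list()
    for (v in unique(ex$variable)) {
      sub <- ex[ex$variable == v, , drop = FALSE]
      sub <- sub[order(!sub$is_reference), , drop = FALSE]
      for (j in seq_len(nrow(sub))) {
        if (sub$is_reference[j]) {
          dt <- dc <- dp <- "Reference"
        } else {
          d <- differences[differences$group == g &
                             differences$start_age == a &
                             differences$variable == v &
                             differences$level == sub$level[j], ,
                           drop = FALSE]
          if (nrow(d) == 1) {
            dt <- fmt(d$d_tle, d$d_tle_lo, d$d_tle_hi, 1)
            dc <- fmt(d$d_cifle, d$d_cifle_lo, d$d_cifle_hi, 1)
            dp <- fmt(d$d_prop, d$d_prop_lo, d$d_prop_hi, 1)
          } else {
            dt <- dc <- dp <- ""
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          Variables = paste0(v, ": ", sub$level[j]),
          TLE = sprintf("%.1f", sub$tle[j]),
          CIFLE = sprintf("%.1f", sub$cifle[j]),
          Proportion = sprintf("%.1f", sub$prop[j]),
          DiffTLE = dt, DiffCIFLE = dc, DiffProp = dp
        )
      }
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
      as.data.frame(stats::setNames(rep(list(character(0)), 7),
                                    paste0("V", 1:7)))
    names(tab) <- header
    path <- file.path(dir, sprintf("expectancy_%s_age%g.csv", g, a))
    utils::write.csv(tab, path, row.names = FALSE)
    paths <- c(paths, path)
  }
  if (nrow(combos) == 0) {
    tab <- as.data.frame(stats::setNames(rep(list(character(0)), 7), header),
                         check.names = FALSE)
    path <- file.path(dir, "expectancy_empty.csv")
    utils::write.csv(tab, path, row.names = FALSE)
    paths <- c(paths, path)
  }
  if (!is.null(expected)) {
    key <- function(d) paste(d$group, d$start_age, d$variable, d$level)
    missing <- expected[!(key(expected) %in% key(differences)), ,
                        drop = FALSE]
    gpath <- file.path(dir, "gaps.csv")
    utils::write.csv(missing, gpath, row.names = FALSE)
    paths <- c(paths, gpath)
  }
  invisible(paths)
}

#' Stacked-bar figure of total life expectancy split by cognitive state
#'
#' @param expectancies Data frame with columns `label`, `cifle`, `cile`.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_expectancy_bars <- function(expectancies) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_expectancy_bars requires ggplot2", call. = FALSE)
  }
  long <- rbind(
    data.frame(label = expectancies$label, years = expectancies$cifle,
               state = "CI-free (CIFLE)"),
    data.frame(label = expectancies$label, years = expectancies$cile,
               state = "With CI (CILE)")
  )
  long$state <- factor(long$state, levels = c("With CI (CILE)",
                                              "CI-free (CIFLE)"))
  ggplot2::ggplot(long, ggplot2::aes(x = label, y = years, fill = state)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Remaining life expectancy (years)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
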