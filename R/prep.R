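#' Classify cognitive state from a cMMSE score
#'
#' Applies the education-specific cutoffs in wide use for the Chinese
#' Mini-Mental State Examination (0-30): with no formal education a score
#' of 17 or below indicates cognitive impairment (cutoff 17/18); with 1-6
#' years of schooling the cutoff is 20/21; with 7 or more years it is
#' 24/25. A missing score yields a missing state. Vectorized.
#'
#' @param score Integer cMMSE score in `[0, 30]`, or `NA`.
#' @param education One of `"none"`, `"primary"` (1-6 years),
#'   `"middle_plus"` (7+ years); recycled against `score`.
#' @return Integer vector: 1 (CI-free), 2 (CI) or `NA`.
#' @examples
#' classify_cognition(c(17, 18), "none")       # 2, 1
#' classify_cognition(21, "primary")           # 1
#' classify_cognition(24, "middle_plus")       # 2
#' @export
classify_cognition <- function(score, education) {
  education <- match_education(education)
  n <- max(length(score), length(education))
  score <- rep_len(score, n); education <- rep_len(education, n)
  ok <- is.na(score) | (score >= 0 & score <= 30 & score == round(score))
  if (!all(ok)) {
    stop("cMMSE score outside 0-30: ",
         paste(utils::head(score[!ok], 5), collapse = ", "), call. = FALSE)
  }
  cutoff <- c(none = 17, primary = 20, middle_plus = 24)[education]
  out <- ifelse(score <= cutoff, 2L, 1L)
  out[is.na(score)] <- NA_integer_
  as.integer(out)
}

match_education <- function(education) {
  lv <- c("none", "primary", "middle_plus")
  education <- as.character(education)
  if (!all(education %in% lv)) {
    stop("'education' must be one of: ", paste(lv, collapse = ", "),
         call. = FALSE)
  }
  education
}

#' Classify dietary pattern from food-frequency responses
#'
#' A diet is healthy when at least three of the four index foods (fresh
#' fruit, green leafy vegetables, legumes, fish) are eaten at least once
#' per week, i.e. with frequency `"daily"` or `"weekly"`. Vectorized over
#' subjects.
#'
#' @param fruit,vegetables,legumes,fish Frequency of consumption, each one
#'   of `"daily"`, `"weekly"`, `"monthly"`, `"occasionally"`, `"rarely"`.
#' @return Character vector: `"healthy"` or `"unhealthy"`.
#' @examples
#' classify_diet("daily", "weekly", "weekly", "rarely")    # healthy
#' classify_diet("weekly", "weekly", "monthly", "monthly") # unhealthy
#' @export
classify_diet <- function(fruit, vegetables, legumes, fish) {
  lv <- c("daily", "weekly", "monthly", "occasionally", "rarely")
  args <- list(fruit = fruit, vegetables = vegetables, legumes = legumes,
               fish = fish)
  n <- max(lengths(args))
  qualifying <- 0L
  for (nm in names(args)) {
    f <- rep_len(as.character(args[[nm]]), n)
    if (anyNA(f) || !all(f %in% lv)) {
      stop("unknown frequency level for ", nm, "; expected one of: ",
           paste(lv, collapse = ", "), call. = FALSE)
    }
    qualifying <- qualifying + (f %in% c("daily", "weekly"))
  }
  ifelse(qualifying >= 3L, "healthy", "unhealthy")
}

#' Combine modifiable factors into a risk profile
#'
#' Counts three protective components -- a healthy lifestyle (never smoking
#' and a healthy diet), being in marriage with spouse present, and engaging
#' in at least one of four leisure activities -- and maps the count to a
#' risk label: 0 components = high, 1 = medium_high, 2 = medium_low,
#' 3 = low. Vectorized; all inputs are required (missing exposures are
#' rejected rather than imputed).
#'
#' @param smoking `"never"`, `"former"` or `"current"`.
#' @param diet `"healthy"` or `"unhealthy"`.
#' @param marital `"in_marriage"` or `"not_in_marriage"`.
#' @param physical,mental,social,productive `"yes"` or `"no"` participation
#'   in each leisure-activity class.
#' @return Data frame with columns `n_components` (0-3) and `label`
#'   (factor high / medium_high / medium_low / low).
#' @examples
#' build_risk_profile("never", "healthy", "in_marriage",
#'                    "no", "no", "yes", "no")  # 3 components -> low
#' @export
build_risk_profile <- function(smoking, diet, marital,
                               physical, mental, social, productive) {
  chk <- function(x, nm, lv) {
    x <- as.character(x)
    if (anyNA(x) || !all(x %in% lv)) {
      stop("'", nm, "' must be one of: ", paste(lv, collapse = ", "),
           call. = FALSE)
    }
    x
  }
  smoking <- chk(smoking, "smoking", c("never", "former", "current"))
  diet <- chk(diet, "diet", c("healthy", "unhealthy"))
  marital <- chk(marital, "marital", c("in_marriage", "not_in_marriage"))
  physical <- chk(physical, "physical", c("yes", "no"))
  mental <- chk(mental, "mental", c("yes", "no"))
  social <- chk(social, "social", c("yes", "no"))
  productive <- chk(productive, "productive", c("yes", "no"))
  lifestyle <- smoking == "never" & diet == "healthy"
  married <- marital == "in_marriage"
  leisure <- physical == "yes" | mental == "yes" | social == "yes" |
    productive == "yes"
  ncomp <- as.integer(lifestyle) + as.integer(married) + as.integer(leisure)
  lab <- factor(c("high", "medium_high", "medium_low", "low")[ncomp + 1L],
                levels = c("high", "medium_high", "medium_low", "low"))
  data.frame(n_components = ncomp, label = lab)
}

#' Post-stratification weights against a target distribution
#'
#' Computes, for each stratum (e.g. age band x sex x residence), the ratio
#' of the target population proportion to the sample proportion, then
#' rescales so the subject-level mean weight is 1. Applying the weights
#' reproduces the target stratum distribution exactly; they correct a
#' designed oversampling (such as of the oldest-old).
#'
#' @param sample Data frame of stratum identifier columns plus a `count`
#'   column of sample sizes (all counts > 0).
#' @param target Data frame of the same identifier columns plus a
#'   `proportion` column (positive entries summing to 1; strata with zero
#'   target proportion may be omitted).
#' @return The `sample` data frame with an added `weight` column
#'   (mean-1-normalized over subjects).
#' @examples
#' s <- data.frame(band = c("65-79", "80+"), count = c(100, 100))
#' t <- data.frame(band = c("65-79", "80+"), proportion = c(0.8, 0.2))
#' post_stratification_weights(s, t)
#' @export
post_stratification_weights <- function(sample, target) {
  stopifnot("count" %in% names(sample), "proportion" %in% names(target))
  keys <- setdiff(names(sample), "count")
  if (!all(keys %in% names(target))) {
    stop("'target' lacks stratum column(s): ",
         paste(setdiff(keys, names(target)), collapse = ", "), call. = FALSE)
  }
  if (any(sample$count <= 0)) {
    stop("all sample stratum counts must be positive", call. = FALSE)
  }
  key_of <- function(d) do.call(paste, c(d[keys], sep = "\r"))
  sk <- key_of(sample); tk <- key_of(target)
  uncovered <- target$proportion > 0 & !(tk %in% sk)
  if (any(uncovered)) {
    stop("target stratum with no sample support: ",
         paste(utils::head(tk[uncovered], 5), collapse = "; "),
         call. = FALSE)
  }
  tp <- target$proportion[match(sk, tk)]
  if (anyNA(tp)) {
    stop("sample stratum missing from the target table", call. = FALSE)
  }
  n <- sum(sample$count)
  raw <- tp / (sample$count / n)
  w <- raw / (sum(raw * sample$count) / n)   # subject-level mean weight 1
  out <- sample
  out$weight <- w
  out
}

#' Attach post-stratification weights to subjects
#'
#' @param subjects Data frame with one row per subject containing the
#'   stratum identifier columns used in `weights`.
#' @param weights Output of [post_stratification_weights()].
#' @return `subjects` with an added (or replaced) `weight` column.
#' @export
attach_weights <- function(subjects, weights) {
  keys <- setdiff(names(weights), c("count", "weight"))
  if (!all(keys %in% names(subjects))) {
    stop("'subjects' lacks stratum column(s): ",
         paste(setdiff(keys, names(subjects)), collapse = ", "),
         call. = FALSE)
  }
  key_of <- function(d) do.call(paste, c(d[keys], sep = "\r"))
  m <- match(key_of(subjects), key_of(weights))
  if (anyNA(m)) stop("subject stratum missing from the weight table",
                     call. = FALSE)
  subjects$weight <- weights$weight[m]
  subjects
}

#' Assemble raw records into an analysis-ready panel
#'
#' Per subject (records ordered by age): subjects whose baseline cognitive
#' state is missing are excluded (with a logged reason); apparent
#' recoveries -- a CI-free state observed after a CI state -- are treated
#' as recording error and the offending later CI-free observation(s) are
#' set to missing (censored) rather than overwritten; living states that
#' are missing between two known states are dropped (the spanning interval
#' bridges them in the likelihood); a trailing run of missing living states
#' becomes a single right-censor record at its last age; death records keep
#' their exact age.
#'
#' @param raw Data frame with columns `subject_id`, `age`, `state` (1, 2, 3
#'   or `NA`), optional `record_kind`, plus any covariate columns (carried
#'   through from each subject's baseline row).
#' @return Panel data frame (`subject_id`, `age`, `state`, `record_kind`,
#'   covariates) with attribute `exclusions`: data frame of excluded
#'   subject ids and reasons.
#' @examples
#' raw <- data.frame(subject_id = 1, age = c(80, 83, 86),
#'                   state = c(1, 2, 1))
#' assemble_panel(raw)  # recovery at 86 censored -> right_censor record
#' @export
assemble_panel <- function(raw) {
  stopifnot(all(c("subject_id", "age", "state") %in% names(raw)))
  kind <- infer_record_kind(raw)
  ord <- order(raw$subject_id, raw$age)
  p <- raw[ord, , drop = FALSE]
  kind <- kind[ord]
  covs <- setdiff(names(p), c("subject_id", "age", "state", "record_kind"))

  out <- vector("list", length(unique(p$subject_id)))
  excl <- list()
  i <- 0L
  for (sid in unique(p$subject_id)) {
    i <- i + 1L
    rows <- p[p$subject_id == sid, , drop = FALSE]
    k <- kind[p$subject_id == sid]
    if (any(duplicated(rows$age))) {
      stop("ages not strictly increasing for subject ", sid, call. = FALSE)
    }
    living <- k == "wave"
    if (!any(living) || is.na(rows$state[which(living)[1]])) {
      excl[[length(excl) + 1L]] <-
        data.frame(subject_id = sid, reason = "baseline state missing")
      next
    }
    st <- rows$state
    # recovery-as-error: censor CI-free observations after observed CI
    seen_ci <- FALSE
    for (j in seq_len(nrow(rows))) {
      if (!living[j] || is.na(st[j])) next
      if (st[j] == 2) seen_ci <- TRUE
      else if (st[j] == 1 && seen_ci) st[j] <- NA_integer_
    }
    keep <- living & !is.na(st)
    death <- k == "death" | (!is.na(st) & st == 3)
    known_ages <- rows$age[keep | death]
    res <- rows[keep | death, , drop = FALSE]
    res$state <- st[keep | death]
    res$record_kind <- ifelse(death[keep | death], "death", "wave")
    # trailing missing living state -> right censor at its last age
    if (!any(death)) {
      na_living <- living & is.na(st)
      trail <- na_living & rows$age > max(known_ages)
      if (any(trail)) {
        rc <- rows[which(trail)[sum(trail)], , drop = FALSE]
        rc$state <- NA_integer_
        rc$record_kind <- "right_censor"
        res <- rbind(res, rc)
      }
    }
    out[[i]] <- res
  }
  panel <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(panel)) {
    panel <- p[0, , drop = FALSE]
    panel$record_kind <- character(0)
  }
  panel <- panel[, c("subject_id", "age", "state", "record_kind", covs),
                 drop = FALSE]
  rownames(panel) <- NULL
  attr(panel, "exclusions") <- if (length(excl)) {
    do.call(rbind, excl)
  } else {
    data.frame(subject_id = panel$subject_id[0], reason = character(0))
  }
  if (length(excl)) {
    message(length(excl), " subject(s) excluded: baseline state missing")
  }
  panel
}

#' Sensitivity filters on an assembled panel
#'
#' Removes whole subjects matching the active reverse-causation filters:
#' CI-free-at-baseline subjects whose first follow-up observation already
#' shows CI (`drop_first_interval_onsets`), and subjects who died within
#' one year of baseline (`drop_first_year_deaths`). With both filters off
#' the panel is returned unchanged.
#'
#' @param panel Assembled panel data frame.
#' @param drop_first_interval_onsets,drop_first_year_deaths Logical flags.
#' @return Filtered panel; attribute `removed` holds the per-rule counts.
#' @export
sensitivity_filter <- function(panel, drop_first_interval_onsets = FALSE,
                               drop_first_year_deaths = FALSE) {
  kind <- infer_record_kind(panel)
  drop <- character(0)
  n_onset <- n_death <- 0L
  sids <- unique(panel$subject_id)
  if (drop_first_interval_onsets || drop_first_year_deaths) {
    for (sid in sids) {
      rows <- panel[panel$subject_id == sid, , drop = FALSE]
      k <- kind[panel$subject_id == sid]
      living <- k == "wave" & !is.na(rows$state)
      base_age <- rows$age[1]
      if (drop_first_interval_onsets && sum(living) >= 2) {
        st <- rows$state[living]
        if (st[1] == 1 && st[2] == 2) {
          drop <- c(drop, sid); n_onset <- n_onset + 1L
          next
        }
      }
      if (drop_first_year_deaths && any(k == "death")) {
        if (rows$age[k == "death"][1] - base_age < 1) {
          drop <- c(drop, sid); n_death <- n_death + 1L
        }
      }
    }
  }
  out <- panel[!(panel$subject_id %in% drop), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(first_interval_onsets = n_onset,
                            first_year_deaths = n_death)
  out
}

#' Cohort flow accounting
#'
#' Tracks the analytical sample size through recruitment and exclusion:
#' analytical n = sum of wave entrants minus sum of exclusions.
#'
#' @param entrants Numeric vector of subjects added per recruitment wave.
#' @param exclusions Named numeric vector of exclusion counts.
#' @return List with `recruited`, `excluded`, `analytical_n`.
#' @examples
#' flow_accounting(c(15627, 7305, 8722, 1336),
#'                 c(no_followup = 5686, baseline_state_missing = 111))
#' @export
flow_accounting <- function(entrants, exclusions = numeric(0)) {
  stopifnot(all(entrants >= 0), all(exclusions >= 0))
  recruited <- sum(entrants)
  excluded <- sum(exclusions)
  if (excluded > recruited) {
    stop("more exclusions than recruits", call. = FALSE)
  }
  list(recruited = recruited, excluded = excluded,
       analytical_n = recruited - excluded)
}

#' Baseline state composition of a panel
#'
#' Percentage of subjects CI-free and with CI at their baseline (first
#' known living state).
#'
#' @param panel Panel data frame (`subject_id`, `age`, `state`).
#' @return Named list: `n`, `pct_ci_free`, `pct_ci`.
#' @export
baseline_composition <- function(panel) {
  ord <- order(panel$subject_id, panel$age)
  p <- panel[ord, , drop = FALSE]
  known <- !is.na(p$state) & p$state %in% c(1, 2)
  k <- p[known, , drop = FALSE]
  base <- k[!duplicated(k$subject_id), , drop = FALSE]
  n <- nrow(base)
  if (n == 0) stop("no subject with a known baseline state", call. = FALSE)
  list(n = n,
       pct_ci_free = 100 * mean(base$state == 1),
       pct_ci = 100 * mean(base$state == 2))
}
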