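# Cohort statistics: weight-status classification, prevalence arithmetic,
# the standard two-sample tests used on gender-stratified prevalences, and a
# synthetic cohort generator that reproduces configured margins exactly.

#' Build a BMI cutoff table
#'
#' Overweight/obesity classification uses gender- and age-band-specific BMI
#' cutoffs (the 85th and 95th percentile convention of school screening
#' standards). The numeric table is configurable because percentile cutoffs
#' differ between national standards.
#'
#' @param entries a data.frame with columns `gender` ("female"/"male"),
#'   `age_band` (label such as "13-15"), `age_min`, `age_max` (years, band is
#'   inclusive), `overweight` and `obese` (kg/m^2), and optionally
#'   `underweight` (kg/m^2, `NA` to disable).
#' @return an object of class `cutoff_table`.
#' @export
cutoff_table <- function(entries) {
  need <- c("gender", "age_min", "age_max", "overweight", "obese")
  if (!all(need %in% names(entries)))
    stop_config("cutoff table needs columns: ", paste(need, collapse = ", "))
  if (is.null(entries$underweight)) entries$underweight <- NA_real_
  if (any(entries$overweight >= entries$obese))
    stop_config("every overweight cutoff must be below the obese cutoff")
  structure(entries, class = c("cutoff_table", "data.frame"))
}

#' Default synthetic cutoff table for mid-adolescents
#'
#' Illustrative gender-specific cutoffs in the range typical of percentile
#' screening standards for 13-15 year olds. These are synthetic defaults for
#' simulation, not a reproduction of any national standard's table.
#'
#' @return a [cutoff_table()].
#' @export
default_cutoff_table <- function() {
  cutoff_table(data.frame(
    gender = c("female", "male"),
    age_band = "13-15",
    age_min = 10, age_max = 18,
    overweight = c(22.8, 23.3),
    obese = c(26.0, 26.8),
    underweight = c(NA_real_, NA_real_)
  ))
}

#' Classify weight status from BMI
#'
#' BMI at or above the obese cutoff is obese; at or above the overweight
#' cutoff (but below obese) is overweight; below an optional underweight
#' cutoff is underweight; otherwise normal. A value exactly at a cutoff
#' classifies into the higher category, matching the percentile definition of
#' the cutoffs.
#'
#' @param bmi BMI in kg/m^2 (vectorised).
#' @param gender "female" or "male" (recycled).
#' @param age age in years (recycled).
#' @param cutoffs a [cutoff_table()].
#' @return character vector in
#'   `c("underweight", "normal", "overweight", "obese")`.
#' @export
classify_weight_status <- function(bmi, gender, age, cutoffs = default_cutoff_table()) {
  if (any(!is.finite(bmi)) || any(bmi <= 0))
    stop_config("BMI values must be strictly positive and finite")
  n <- max(length(bmi), length(gender), length(age))
  bmi <- rep_len(bmi, n); gender <- rep_len(gender, n); age <- rep_len(age, n)
  out <- character(n)
  for (i in seq_len(n)) {
    row <- which(cutoffs$gender == gender[i] &
                   cutoffs$age_min <= age[i] & age[i] <= cutoffs$age_max)
    if (length(row) == 0)
      stop_config("no cutoff entry for (gender=", gender[i], ", age=", age[i], ")")
    row <- row[1]
    out[i] <-
      if (bmi[i] >= cutoffs$obese[row]) "obese"
      else if (bmi[i] >= cutoffs$overweight[row]) "overweight"
      else if (!is.na(cutoffs$underweight[row]) && bmi[i] < cutoffs$underweight[row])
        "underweight"
      else "normal"
  }
  out
}

#' Recover an integer count from a printed percentage
#'
#' Finds the integer numerator `k` minimising `|100 k / n - pct|`. Errors if
#' two numerators fit equally well or if no numerator reproduces the
#' percentage to printing precision (best absolute difference above
#' `50 / n`), so silently inconsistent tables are rejected rather than
#' guessed at.
#'
#' @param prevalence_percent printed percentage in `[0, 100]`.
#' @param n group size.
#' @return integer count `k` with `0 <= k <= n`.
#' @export
reconstruct_counts <- function(prevalence_percent, n) {
  if (n <= 0) stop_config("group size must be positive")
  if (prevalence_percent < 0 || prevalence_percent > 100)
    stop_config("percentage must lie in [0, 100]")
  k <- 0:n
  diffs <- abs(100 * k / n - prevalence_percent)
  best <- min(diffs)
  hits <- k[diffs <= best + 1e-12]
  if (length(hits) > 1)
    stop_config("ambiguous percentage ", prevalence_percent, "% for n = ", n,
                ": counts ", paste(hits, collapse = " and "), " fit equally well")
  if (best > 50 / n + 1e-9)
    stop_config("no count reproduces ", prevalence_percent, "% of ", n,
                " to printing precision (best difference ", format(best), ")")
  hits
}

#' Prevalence change in percentage points
#'
#' @param count_a count at the first time point.
#' @param count_b count at the second time point.
#' @param n common group size.
#' @return `100 * (count_b - count_a) / n`, unrounded.
#' @export
prevalence_change <- function(count_a, count_b, n) {
  if (n == 0) stop_config("group size must be positive")
  if (any(c(count_a, count_b) > n) || any(c(count_a, count_b) < 0))
    stop_config("counts must lie in [0, n]")
  100 * (count_b - count_a) / n
}

#' Two-proportion z-test (pooled)
#'
#' Pooled-proportion z statistic with a two-sided normal p-value, the
#' standard large-sample test for a difference between two proportions.
#' Degeneracy (pooled proportion exactly 0 or 1) has zero variance under the
#' null and is rejected with an error; no continuity correction is applied,
#' so the squared statistic equals the uncorrected 2x2 chi-square.
#'
#' @param k1,n1 successes and size of group 1.
#' @param k2,n2 successes and size of group 2.
#' @return list with `z`, `p`, and the pooled proportion `p_pooled`.
#' @export
two_proportion_z_test <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop_config("group sizes must be positive")
  if (k1 > n1 || k2 > n2 || k1 < 0 || k2 < 0)
    stop_config("counts must lie in [0, n]")
  pooled <- (k1 + k2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1)
    stop_config("degenerate pooled proportion ", pooled,
                ": all observations share one outcome, the z-test variance is zero")
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- (k1 / n1 - k2 / n2) / se
  list(z = z, p = 2 * pnorm(-abs(z)), p_pooled = pooled)
}

#' Pearson chi-square test on a contingency table
#'
#' Thin surface over the Pearson statistic `sum((O - E)^2 / E)` with
#' `df = (r - 1)(c - 1)`. Continuity correction is off by default and only
#' ever applies to 2x2 tables.
#'
#' @param table matrix of non-negative counts, at least 2x2.
#' @param correct apply Yates continuity correction (2x2 only).
#' @return list with `statistic`, `df`, `p`, and `expected` counts.
#' @export
chi_square_test <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop_config("need at least a 2x2 table")
  if (any(table < 0)) stop_config("counts must be non-negative")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0))
    stop_config("a zero expected count (empty row or column margin); ",
                "drop the empty margin or use an exact test")
  res <- suppressWarnings(chisq.test(table, correct = correct))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value), expected = expected)
}

#' Pearson correlation coefficient
#'
#' @param x,y numeric vectors of equal length (>= 3), neither constant.
#' @return sample Pearson `r` in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_config("x and y must have equal length")
  if (length(x) < 3) stop_config("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop_config("correlation undefined for a constant input vector")
  cor(x, y, method = "pearson")
}

#' Configuration for the synthetic cohort generator
#'
#' Margins the generator must reproduce: group sizes, per-(gender, round)
#' overweight/obesity prevalence targets and mean BMI targets, a BMI
#' dispersion, and a target (negative) Pearson correlation between final-round
#' BMI and a latent fitness score.
#'
#' @param n_total total number of students.
#' @param n_female number of female students.
#' @param rounds ordered character vector of measurement-round labels.
#' @param prevalence data.frame with columns `gender`, `round`,
#'   `prevalence_percent` (printed percentages; converted to exact counts via
#'   [reconstruct_counts()]).
#' @param mean_bmi data.frame with columns `gender`, `round`, `mean_bmi`.
#' @param bmi_sd BMI dispersion in kg/m^2.
#' @param fitness_correlation target Pearson correlation in `(-1, 0]` between
#'   final-round BMI and the latent fitness score.
#' @param mean_age,age_sd age distribution (years).
#' @param cutoffs a [cutoff_table()].
#' @param seed RNG seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_total, n_female, rounds, prevalence, mean_bmi,
                          bmi_sd = 3, fitness_correlation = -0.589,
                          mean_age = 13.35, age_sd = 0.3,
                          cutoffs = default_cutoff_table(), seed = NULL) {
  if (n_female > n_total) stop_config("n_female must not exceed n_total")
  if (any(prevalence$prevalence_percent < 0 | prevalence$prevalence_percent > 100))
    stop_config("target prevalences must lie in [0, 100]")
  if (fitness_correlation > 0 || fitness_correlation <= -1)
    stop_config("fitness_correlation must lie in (-1, 0]")
  structure(list(n_total = n_total, n_female = n_female, rounds = rounds,
                 prevalence = prevalence, mean_bmi = mean_bmi, bmi_sd = bmi_sd,
                 fitness_correlation = fitness_correlation,
                 mean_age = mean_age, age_sd = age_sd,
                 cutoffs = cutoffs, seed = seed),
            class = "cohort_config")
}

#' Default cohort configuration (study margins)
#'
#' The margins of the three-round junior-middle-school cohort the simulator
#' is parameterised against: 234 students (113 girls, 121 boys), rounds
#' labelled 2018.11 / 2019.11 / 2020.11, the printed per-gender
#' overweight/obesity prevalences and mean BMI values per round, and a
#' final-round BMI-fitness correlation of -0.589.
#'
#' @param seed RNG seed.
#' @return a [cohort_config()].
#' @export
default_cohort_config <- function(seed = NULL) {
  rounds <- c("2018.11", "2019.11", "2020.11")
  cohort_config(
    n_total = 234, n_female = 113, rounds = rounds,
    prevalence = data.frame(
      gender = rep(c("female", "male"), each = 3),
      round = rep(rounds, 2),
      prevalence_percent = c(31.86, 31.86, 40.71, 44.62, 45.45, 47.11)
    ),
    mean_bmi = data.frame(
      gender = rep(c("female", "male"), each = 3),
      round = rep(rounds, 2),
      mean_bmi = c(20.62, 21.30, 22.59, 22.17, 22.54, 24.01)
    ),
    bmi_sd = 3, fitness_correlation = -0.589, seed = seed
  )
}

# shift a BMI draw vector so that exactly `k` of the group lie at or above
# `cutoff`, preserving the within-group ordering of draws
.coerce_counts <- function(bmi, k, cutoff) {
  n <- length(bmi)
  if (k > n) stop_config("infeasible prevalence target: ", k, " of ", n)
  ord <- order(bmi, decreasing = TRUE)
  out <- bmi
  if (k > 0) {
    top <- ord[seq_len(k)]
    low <- out[top] < cutoff
    # reflect sub-cutoff draws just above the cutoff, keeping their order
    out[top[low]] <- cutoff + (cutoff - out[top[low]]) * 0.15 + 0.01
  }
  if (k < n) {
    rest <- ord[(k + 1):n]
    high <- out[rest] >= cutoff
    out[rest[high]] <- cutoff - (out[rest[high]] - cutoff) * 0.15 - 0.01
  }
  pmin(pmax(out, 10), 45)
}

#' Generate a synthetic cohort
#'
#' Draws per-(gender, round) BMI values from truncated normal distributions
#' around the configured means, then deterministically shifts draws across
#' the overweight cutoff so the per-(gender, round) overweight/obesity counts
#' match the configured prevalence targets exactly. A latent fitness score is
#' generated with the configured negative correlation to final-round BMI and
#' discretised into the four fitness-status levels. Fully reproducible under
#' a fixed seed.
#'
#' The generator reproduces margins (counts, approximate means, the
#' BMI-fitness correlation), not individual-level longitudinal dynamics: each
#' student's BMI draws are independent across rounds apart from the coercion,
#' so within-student BMI tracking is weaker than in real cohorts.
#'
#' @param config a [cohort_config()].
#' @return a data.frame of class `cohort_table` with one row per student:
#'   `student_id`, `gender`, `age`, `fitness_score`, and per-round columns
#'   `bmi_<round>`, `status_<round>` (weight status), `pf_<round>` (fitness
#'   status).
#' @export
generate_synthetic_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_total
    gender <- rep(c("female", "male"), c(config$n_female, n - config$n_female))
    age <- pmin(pmax(rnorm(n, config$mean_age, config$age_sd), 12), 16)
    df <- data.frame(student_id = sprintf("S%03d", seq_len(n)),
                     gender = gender, age = age, stringsAsFactors = FALSE)
    for (r in config$rounds) {
      bmi <- numeric(n)
      for (g in c("female", "male")) {
        idx <- which(gender == g)
        mu <- config$mean_bmi$mean_bmi[config$mean_bmi$gender == g &
                                         config$mean_bmi$round == r]
        pct <- config$prevalence$prevalence_percent[
          config$prevalence$gender == g & config$prevalence$round == r]
        if (length(mu) != 1 || length(pct) != 1)
          stop_config("missing mean BMI or prevalence target for (", g, ", ", r, ")")
        k <- reconstruct_counts(pct, length(idx))
        cutoff <- config$cutoffs$overweight[config$cutoffs$gender == g][1]
        draws <- pmin(pmax(rnorm(length(idx), mu, config$bmi_sd), 10), 45)
        bmi[idx] <- .coerce_counts(draws, k, cutoff)
      }
      df[[paste0("bmi_", r)]] <- bmi
      df[[paste0("status_", r)]] <- classify_weight_status(bmi, gender, age,
                                                           config$cutoffs)
    }
    final_bmi <- df[[paste0("bmi_", tail_round(config$rounds))]]
    rho <- config$fitness_correlation
    z <- scale(final_bmi)[, 1]
    # orthogonalise the noise against BMI so the sample correlation hits the
    # target, not just its expectation
    e <- rnorm(n)
    e <- e - z * sum(e * z) / sum(z * z)
    e <- e / sd(e)
    fitness <- rho * z + sqrt(1 - rho^2) * e
    df$fitness_score <- fitness
    q <- quantile(fitness, c(0.25, 0.5, 0.75))
    levs <- cut(fitness, c(-Inf, q, Inf),
                labels = c("fail", "fair", "good", "excellent"))
    for (r in config$rounds) df[[paste0("pf_", r)]] <- as.character(levs)
    class(df) <- c("cohort_table", "data.frame")
    df
  })
}

tail_round <- function(rounds) rounds[length(rounds)]

#' Per-(gender, round) overweight/obesity prevalence of a cohort
#'
#' @param cohort a `cohort_table`.
#' @param rounds round labels (default: all `status_` columns).
#' @return data.frame with `gender`, `round`, `n`, `count`
#'   (overweight + obese) and `prevalence_percent`.
#' @export
cohort_prevalence <- function(cohort, rounds = NULL) {
  if (is.null(rounds))
    rounds <- sub("^status_", "", grep("^status_", names(cohort), value = TRUE))
  out <- expand.grid(gender = c("female", "male"), round = rounds,
                     stringsAsFactors = FALSE)
  out$n <- NA_integer_; out$count <- NA_integer_
  for (i in seq_len(nrow(out))) {
    idx <- cohort$gender == out$gender[i]
    st <- cohort[[paste0("status_", out$round[i])]][idx]
    out$n[i] <- sum(idx)
    out$count[i] <- sum(st %in% c("overweight", "obese"))
  }
  out$prevalence_percent <- 100 * out$count / out$n
  out
}

#' Write / read a cohort as delimited text
#'
#' Comma-separated UTF-8 with one row per student and the per-round columns
#' of [generate_synthetic_cohort()].
#'
#' @param cohort a `cohort_table`.
#' @param path file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a `cohort_table`.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write test results as JSON records
#'
#' @param tests named list of test results (each a list with fields such as
#'   `statistic`, `df`, `p`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(tests, path) {
  jsonlite::write_json(tests, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
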