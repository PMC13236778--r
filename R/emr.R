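#' Build drug exposure episodes from prescription records
#'
#' Collapses prescription rows into one episode per (patient, drug), spanning
#' the earliest recorded start date to the latest recorded end date, and drops
#' episodes shorter than `min_duration_days` (a 30-day episode is kept; the
#' bound is inclusive). Rows with an end date before their start date are
#' rejected with a warning listing the offending patients.
#'
#' @param prescriptions Tibble with columns `patient_id`, `drug`,
#'   `start_date`, `end_date` (dates or ISO-8601 strings).
#' @param min_duration_days Minimum episode length in days (default 30).
#' @return Tibble with columns `patient_id`, `drug`, `start`, `end`,
#'   `duration_days`.
#' @export
build_exposure_episodes <- function(prescriptions, min_duration_days = 30L) {
  assert_cols(prescriptions, c("patient_id", "drug", "start_date", "end_date"),
              "prescriptions")
  rx <- prescriptions %>%
    mutate(start_date = as.Date(.data$start_date),
           end_date = as.Date(.data$end_date))
  bad <- rx$end_date < rx$start_date
  if (any(bad)) {
    warn(sprintf(
      "build_exposure_episodes: rejected %d row(s) with end < start (patients: %s)",
      sum(bad), paste(unique(rx$patient_id[bad]), collapse = ", ")))
    rx <- rx[!bad, , drop = FALSE]
  }
  rx %>%
    group_by(.data$patient_id, .data$drug) %>%
    summarise(start = min(.data$start_date), end = max(.data$end_date),
              .groups = "drop") %>%
    mutate(duration_days = as.integer(.data$end - .data$start)) %>%
    filter(.data$duration_days >= min_duration_days) %>%
    arrange(.data$patient_id, .data$drug)
}

#' Per-patient pre/post window means of a biomarker
#'
#' For each exposure episode, averages lab values dated in the pre window
#' `[start - window_days, start)` and the post window `(end, end + window_days]`
#' (half-open at the episode boundaries: a measurement on the start date
#' itself belongs to neither window). Patients lacking at least one
#' measurement in either window are excluded, not failed.
#'
#' @param episodes Output of [build_exposure_episodes()].
#' @param labs Tibble with columns `patient_id`, `date`, `value`; rows are
#'   restricted to the analyte of interest beforehand (or via an `analyte`
#'   column matching `analyte`).
#' @param window_days Window span in days (183 for 6 months, 365 or 730).
#' @param analyte Analyte name to keep when `labs` has an `analyte` column
#'   (case-insensitive; default "C-peptide").
#' @return Tibble with columns `patient_id`, `drug`, `n_pre`, `n_post`,
#'   `pre_mean`, `post_mean`.
#' @export
window_means <- function(episodes, labs, window_days = 365L,
                         analyte = "C-peptide") {
  assert_cols(episodes, c("patient_id", "drug", "start", "end"), "episodes")
  assert_cols(labs, c("patient_id", "date", "value"), "labs")
  window_days <- assert_count(window_days, "window_days")
  labs <- mutate(labs, date = as.Date(.data$date))
  if ("analyte" %in% names(labs)) {
    labs <- filter(labs, tolower(.data$analyte) == tolower(!!analyte))
  }
  if (any(!is.finite(labs$value)) || any(labs$value < 0)) {
    abort("lab values must be finite and non-negative")
  }
  episodes %>%
    inner_join(labs, by = "patient_id", relationship = "many-to-many") %>%
    mutate(
      in_pre = .data$date >= .data$start - window_days & .data$date < .data$start,
      in_post = .data$date > .data$end & .data$date <= .data$end + window_days
    ) %>%
    group_by(.data$patient_id, .data$drug) %>%
    summarise(
      n_pre = sum(.data$in_pre),
      n_post = sum(.data$in_post),
      pre_mean = mean(.data$value[.data$in_pre]),
      post_mean = mean(.data$value[.data$in_post]),
      .groups = "drop") %>%
    filter(.data$n_pre >= 1L, .data$n_post >= 1L) %>%
    arrange(.data$drug, .data$patient_id)
}

#' One-sided paired screen for a post-exposure biomarker increase
#'
#' Per drug, tests whether post-exposure means exceed pre-exposure means with
#' a one-sided paired t test on the differences `d_i = post_i - pre_i`
#' (`t = mean(d) / (sd(d) / sqrt(n))`, sample sd, upper tail of the t
#' distribution with n - 1 degrees of freedom), together with the two-sided
#' 95% confidence interval of the mean difference. Drugs with fewer than
#' `min_patients` paired patients are reported as untestable and never
#' flagged.
#'
#' @param pairs Output of [window_means()] (columns `drug`, `pre_mean`,
#'   `post_mean`).
#' @param alpha Significance level for flagging (default 0.05).
#' @param min_patients Minimum paired patients per drug (default 5).
#' @param window_days Optional label carried into the result.
#' @return Tibble with columns `drug`, `window_days`, `n`, `mean_diff`,
#'   `ci_low`, `ci_high`, `p_one_sided`, `testable`, `flagged`.
#' @export
paired_screen <- function(pairs, alpha = 0.05, min_patients = 5L,
                          window_days = NA_integer_) {
  assert_cols(pairs, c("drug", "pre_mean", "post_mean"), "pairs")
  assert_fraction(alpha, "alpha")
  min_patients <- assert_count(min_patients, "min_patients", min = 2L)
  out <- pairs %>%
    group_by(.data$drug) %>%
    summarise(
      n = dplyr::n(),
      mean_diff = mean(.data$post_mean - .data$pre_mean),
      sd_diff = if (dplyr::n() >= 2L) sd(.data$post_mean - .data$pre_mean)
                else NA_real_,
      .groups = "drop")
  degenerate <- !is.na(out$sd_diff) & out$sd_diff == 0 & out$mean_diff != 0
  if (any(degenerate)) {
    warn(sprintf("paired_screen: zero-variance non-zero differences for: %s",
                 paste(out$drug[degenerate], collapse = ", ")))
  }
  out %>%
    mutate(
      se = .data$sd_diff / sqrt(.data$n),
      p_one_sided = dplyr::case_when(
        .data$n < 2L ~ NA_real_,
        .data$sd_diff == 0 & .data$mean_diff > 0 ~ 0,
        .data$sd_diff == 0 & .data$mean_diff < 0 ~ 1,
        .data$sd_diff == 0 ~ 0.5,
        TRUE ~ pt(.data$mean_diff / .data$se, df = .data$n - 1L,
                  lower.tail = FALSE)
      ),
      ci_low = .data$mean_diff - qt(0.975, df = .data$n - 1L) * .data$se,
      ci_high = .data$mean_diff + qt(0.975, df = .data$n - 1L) * .data$se,
      window_days = window_days,
      testable = .data$n >= min_patients,
      flagged = .data$testable & !is.na(.data$p_one_sided) &
        .data$p_one_sided < alpha
    ) %>%
    select("drug", "window_days", "n", "mean_diff", "ci_low", "ci_high",
           "p_one_sided", "testable", "flagged") %>%
    arrange(.data$drug)
}

#' Full EMR pre/post biomarker screen
#'
#' Convenience chain: builds exposure episodes (dropping those under
#' `min_duration_days`), computes per-patient pre/post window means for every
#' requested window, and runs the one-sided paired screen per drug and window.
#' Degenerate all-zero differences get p = 0.5; zero-variance non-zero
#' differences get p = 0 or 1 with a warning from the screen.
#'
#' @param prescriptions,labs See [build_exposure_episodes()] and
#'   [window_means()].
#' @param drugs Optional character vector restricting which drugs to screen.
#' @param windows Day spans to evaluate (default `c(183, 365, 730)`).
#' @param min_duration_days Minimum exposure duration (default 30).
#' @param alpha,min_patients See [paired_screen()].
#' @param analyte Analyte to screen (default "C-peptide").
#' @return Tibble of class `emr_screen`, one row per (drug, window).
#' @export
emr_screen <- function(prescriptions, labs, drugs = NULL,
                       windows = c(183L, 365L, 730L),
                       min_duration_days = 30L, alpha = 0.05,
                       min_patients = 5L, analyte = "C-peptide") {
  episodes <- build_exposure_episodes(prescriptions, min_duration_days)
  if (!is.null(drugs)) episodes <- filter(episodes, .data$drug %in% drugs)
  out <- purrr::map_dfr(windows, function(w) {
    window_means(episodes, labs, window_days = w, analyte = analyte) %>%
      paired_screen(alpha = alpha, min_patients = min_patients,
                    window_days = as.integer(w))
  })
  structure(out, class = c("emr_screen", class(out)))
}
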