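# Behavioral and physiological scoring: Y-maze spontaneous alternation,
# clinical frailty index, open-field binning, wheel-running summaries,
# rotarod scoring, and half-LLOD censoring of assay panels.

#' The 26 frailty assessment traits
#'
#' Named aging-related traits and reflexes, each scored 0 (absent), 0.5
#' (mild) or 1 (severe) by a blinded observer.
#' @export
FRAILTY_TRAITS <- c(
  "alopecia", "loss_of_fur_color", "dermatitis", "loss_of_whiskers",
  "coat_condition", "piloerection", "cataracts", "eye_discharge",
  "microphthalmia", "nasal_discharge", "rectal_prolapse",
  "vaginal_uterine_penile_prolapse", "diarrhea", "vestibular_disturbance",
  "vision_loss", "menace_reflex", "tail_stiffening", "gait_disorders",
  "tremor", "tumors", "distended_abdomen", "kyphosis", "body_condition",
  "breathing_rate_depth", "malocclusions", "righting_reflex"
)

#' Percent spontaneous alternation from an arm-entry sequence
#'
#' Slides a window of three consecutive entries along the sequence; a triad
#' is a window visiting all three distinct arms. Opportunities are
#' `length - 2` and percent alternation is `100 * triads / opportunities`.
#' Sequences with fewer than three entries return `NA` with a QC flag rather
#' than an error, matching a QC-exclusion workflow.
#'
#' @param entries character vector of arm labels (e.g. `"A"`, `"B"`, `"C"`);
#'   consecutive duplicates are invalid because an entry requires leaving the
#'   current arm.
#' @return A list: `percent`, `triads`, `opportunities`, `qc_pass`.
#' @export
percent_alternation <- function(entries) {
  entries <- as.character(entries)
  n <- length(entries)
  if (n >= 2 && any(entries[-1] == entries[-n]))
    stop_invalid("invalid sequence: consecutive duplicate arm entries")
  if (n < 3)
    return(list(percent = NA_real_, triads = NA_integer_,
                opportunities = NA_integer_, qc_pass = FALSE))
  triads <- sum(vapply(seq_len(n - 2), function(i) {
    length(unique(entries[i:(i + 2)])) == 3L
  }, logical(1)))
  opportunities <- n - 2L
  list(percent = 100 * triads / opportunities, triads = as.integer(triads),
       opportunities = opportunities, qc_pass = TRUE)
}

#' Cumulative frailty index
#'
#' Sum of the 26 trait scores; maximum 26 when every trait scores 1.
#'
#' @param scores numeric vector of exactly 26 trait scores, each in
#'   `{0, 0.5, 1}`; names are optional.
#' @return The cumulative score in `[0, 26]`.
#' @export
frailty_index <- function(scores) {
  scores <- unlist(scores, use.names = FALSE)
  if (length(scores) != 26)
    stop_invalid("invalid assessment: expected 26 trait scores, got ",
                 length(scores))
  if (!all(scores %in% c(0, 0.5, 1)))
    stop_invalid("invalid score: trait scores must be 0, 0.5 or 1")
  sum(scores)
}

#' Cohort prevalence of a frailty trait
#'
#' Percent of subjects presenting the trait at any severity (score > 0).
#'
#' @param cohort data.frame of trait scores, one row per subject.
#' @param trait column name of the trait.
#' @return Percent in `[0, 100]`.
#' @export
trait_prevalence <- function(cohort, trait) {
  if (!trait %in% names(cohort)) stop_invalid("unknown trait: ", trait)
  if (nrow(cohort) == 0) return(0)
  100 * mean(cohort[[trait]] > 0)
}

#' Bin open-field samples into 5-minute intervals
#'
#' @param samples data.frame with `t` (seconds from test start),
#'   `distance_delta` (cm), `vertical_count`, `in_center` (logical). Sample
#'   spacing is inferred from `t` for the center/perimeter time split.
#' @param bin_min bin width in minutes (default 5).
#' @param total_min session length in minutes (default 60).
#' @return A data.frame with one row per bin (`bin`, `t_start_min`,
#'   `distance_cm`, `vertical`, `center_s`, `perimeter_s`) plus a `"total"`
#'   row.
#' @export
openfield_bins <- function(samples, bin_min = 5, total_min = 60) {
  n_bins <- total_min / bin_min
  dt <- if (nrow(samples) >= 2) median(diff(sort(samples$t))) else 1
  bin <- pmin(floor(samples$t / (bin_min * 60)) + 1, n_bins)
  out <- data.frame(bin = as.character(seq_len(n_bins)),
                    t_start_min = (seq_len(n_bins) - 1) * bin_min,
                    distance_cm = 0, vertical = 0, center_s = 0,
                    perimeter_s = 0)
  if (nrow(samples)) {
    for (b in seq_len(n_bins)) {
      sel <- bin == b & samples$t < total_min * 60
      out$distance_cm[b] <- sum(samples$distance_delta[sel])
      out$vertical[b] <- sum(samples$vertical_count[sel])
      out$center_s[b] <- sum(samples$in_center[sel]) * dt
      out$perimeter_s[b] <- sum(!samples$in_center[sel]) * dt
    }
  }
  total <- data.frame(bin = "total", t_start_min = NA_real_,
                      distance_cm = sum(out$distance_cm),
                      vertical = sum(out$vertical),
                      center_s = sum(out$center_s),
                      perimeter_s = sum(out$perimeter_s))
  rbind(out, total)
}

#' Summarize home-cage wheel running over 30-minute periods
#'
#' The 1-minute epoch log is tiled into consecutive periods from session
#' start; per period, cumulative running time is the count of epochs with
#' nonzero distance and the distance total is reported.
#'
#' @param distance_m numeric vector of per-1-minute distances (meters).
#' @param period_min period length in minutes (default 30).
#' @return A data.frame: `period`, `running_time_min`, `distance_m`.
#' @export
wheel_summary <- function(distance_m, period_min = 30) {
  n_periods <- floor(length(distance_m) / period_min)
  if (n_periods == 0)
    return(data.frame(period = integer(0), running_time_min = numeric(0),
                      distance_m = numeric(0)))
  idx <- rep(seq_len(n_periods), each = period_min)
  d <- distance_m[seq_len(n_periods * period_min)]
  data.frame(
    period = seq_len(n_periods),
    running_time_min = as.numeric(tapply(d > 0, idx, sum)),
    distance_m = as.numeric(tapply(d, idx, sum))
  )
}

#' Score rotarod trials
#'
#' Trials flagged as a fall before acceleration started score 0 s; latencies
#' are capped at the 300 s trial ceiling; the aggregate is the mean across
#' trials.
#'
#' @param latency_s numeric vector of latencies to fall (seconds).
#' @param fell_before_acceleration logical vector, same length.
#' @param cap_s trial ceiling (default 300).
#' @return A list: `trial_s` (scored per-trial latencies) and `mean_s`.
#' @export
rotarod_score <- function(latency_s, fell_before_acceleration, cap_s = 300) {
  if (length(latency_s) != length(fell_before_acceleration))
    stop_invalid("latencies and flags must have equal length")
  trial <- pmin(latency_s, cap_s)
  trial[fell_before_acceleration] <- 0
  list(trial_s = trial, mean_s = mean(trial))
}

#' Censor assay values below the lower limit of detection
#'
#' Values strictly below the per-analyte LLOD are replaced by LLOD/2 and
#' flagged; values at or above the LLOD pass through.
#'
#' @param value numeric assay values.
#' @param llod per-analyte lower limits of detection (recycled).
#' @return A data.frame: `value` (censored), `censored` (logical).
#' @export
censor_llod <- function(value, llod) {
  llod <- rep_len(llod, length(value))
  censored <- value < llod
  value[censored] <- llod[censored] / 2
  data.frame(value = value, censored = censored)
}
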