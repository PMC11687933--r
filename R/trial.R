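# Longitudinal trial endpoint evaluation
#
# Baseline-change trajectories, responder counts, upper-limit-of-normal
# (ULN) autoantibody response summaries, and the protocol safety rule for
# serious adverse events. Week-40 extension data are handled but excluded
# from the 16-week endpoint by default.

check_series <- function(series) {
  need <- c("participant", "week", "measurement", "value")
  stopifnot(all(need %in% names(series)))
  dup <- duplicated(series[, c("participant", "week", "measurement")])
  if (any(dup)) stop_config("duplicate (participant, week, measurement) rows")
  later <- unique(series$participant[series$week > 0])
  base <- unique(series$participant[series$week == 0])
  if (!all(later %in% base)) {
    stop_config("participant(s) without a baseline visit: %s",
                paste(setdiff(later, base), collapse = ", "))
  }
  invisible(series)
}

#' Change from baseline at a given week
#'
#' delta = value(week) - value(0) per participant for one measurement.
#' Participants missing either visit are reported separately, never
#' silently dropped.
#'
#' @param series trial tibble (`participant`, `week`, `measurement`,
#'   `value`).
#' @param measurement measurement name; must exist in the series.
#' @param week target week.
#' @return list: `deltas` tibble (`participant`, `baseline`, `value`,
#'   `delta`), `missing` participant ids lacking a visit.
#' @export
change_from_baseline <- function(series, measurement, week) {
  check_series(series)
  if (!measurement %in% series$measurement) {
    stop_config("unknown measurement: %s", measurement)
  }
  s <- series[series$measurement == measurement, ]
  base <- s[s$week == 0, c("participant", "value")]
  names(base)[2] <- "baseline"
  tgt <- s[s$week == week, c("participant", "value")]
  all_ids <- unique(s$participant)
  merged <- dplyr::inner_join(base, tgt, by = "participant")
  merged$delta <- merged$value - merged$baseline
  list(
    deltas = tibble::as_tibble(merged),
    missing = setdiff(all_ids, merged$participant)
  )
}

#' Count participants with decreased values at a week
#'
#' Counts strictly negative changes from baseline; a delta of exactly zero
#' counts as not decreased.
#'
#' @inheritParams change_from_baseline
#' @return list: `n_decreased`, `n_evaluable`, `decreased` participant ids.
#' @export
count_decreasing <- function(series, measurement, week) {
  cb <- change_from_baseline(series, measurement, week)
  if (nrow(cb$deltas) < 1) stop_config("no evaluable participants")
  dec <- cb$deltas$participant[cb$deltas$delta < 0]
  list(n_decreased = length(dec), n_evaluable = nrow(cb$deltas),
       decreased = dec)
}

#' Upper-limit-of-normal autoantibody response
#'
#' For a measurement with an ULN (e.g. anti-TPO at 60 U/mL, anti-TG at
#' 4 IU/mL): identifies participants strictly above the ULN at baseline; of
#' those, how many decreased (strictly) at each requested week; and how
#' many crossed below (or to) the ULN at any on-treatment visit among the
#' requested weeks.
#'
#' @param series trial tibble.
#' @param measurement measurement the rule applies to.
#' @param uln upper limit of normal, same units as the measurement.
#' @param weeks on-treatment weeks to evaluate (default weeks 8 and 16).
#' @return list: `above_at_baseline` ids, `decreased` named list of ids per
#'   week, `decreased_all_weeks` ids decreased at every requested week (with
#'   all visits present), `crossed_below` ids reaching <= ULN on treatment.
#' @export
uln_response <- function(series, measurement, uln, weeks = c(8, 16)) {
  check_series(series)
  if (!is.finite(uln)) stop_config("ULN must be finite")
  if (!measurement %in% series$measurement) {
    stop_config("unknown measurement: %s", measurement)
  }
  s <- series[series$measurement == measurement, ]
  base <- s[s$week == 0, ]
  above <- base$participant[base$value > uln]
  dec <- lapply(weeks, function(w) {
    cb <- change_from_baseline(series, measurement, w)
    d <- cb$deltas[cb$deltas$participant %in% above, ]
    d$participant[d$delta < 0]
  })
  names(dec) <- paste0("week", weeks)
  complete <- Reduce(intersect, lapply(weeks, function(w) {
    s$participant[s$week == w]
  }))
  dec_all <- Reduce(intersect, c(dec, list(complete)))
  on_trt <- s[s$week %in% weeks & s$participant %in% above, ]
  crossed <- unique(on_trt$participant[on_trt$value <= uln])
  list(
    above_at_baseline = above,
    decreased = dec,
    decreased_all_weeks = dec_all,
    crossed_below = crossed,
    uln = uln
  )
}

#' Evaluate the trial safety rule
#'
#' The primary safety endpoint passes when at most `max_definite_saes`
#' events are both serious and definitely attributed to the study drug.
#' Also tabulates events by attribution and seriousness.
#'
#' @param log safety tibble: `participant`, `event`, `grade` (1-5),
#'   `attribution` (one of unrelated/possibly/probably/definitely),
#'   `serious` logical. May have zero rows.
#' @param max_definite_saes tolerated count (default 2).
#' @return list: `pass`, `n_definite_saes`, `tabulation` (attribution x
#'   serious counts).
#' @export
evaluate_safety_rule <- function(log, max_definite_saes = 2) {
  vocab <- c("unrelated", "possibly", "probably", "definitely")
  if (nrow(log) > 0) {
    stopifnot(all(log$attribution %in% vocab),
              all(log$grade %in% 1:5),
              is.logical(log$serious))
  }
  n_def <- if (nrow(log)) sum(log$serious & log$attribution == "definitely") else 0L
  tab <- if (nrow(log)) {
    as.data.frame(table(
      attribution = factor(log$attribution, levels = vocab),
      serious = log$serious
    ))
  } else {
    data.frame(attribution = factor(character(), levels = vocab),
               serious = logical(), Freq = integer())
  }
  list(pass = n_def <= max_definite_saes, n_definite_saes = n_def,
       tabulation = tibble::as_tibble(tab))
}
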