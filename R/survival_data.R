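#' Observation schedule for a toxicity trial
#'
#' The days on which survival was counted. Standard designs observe on
#' days 1, 2, 4, 7, 10, 14 (14-d test) or 4, 7, 10, 14, 21 (21-d test);
#' irregular real-valued schedules are accepted.
#'
#' @param days Numeric vector of observation days, strictly increasing,
#'   first day >= 1. The last day is the test duration.
#' @return An `observation_schedule` object (numeric vector with class).
#' @examples
#' observation_schedule(c(1, 2, 4, 7, 10, 14))
#' @export
observation_schedule <- function(days) {
  days <- as.numeric(days)
  if (length(days) < 1 || anyNA(days)) {
    stop("schedule must be a non-empty numeric vector of days", call. = FALSE)
  }
  if (any(diff(days) <= 0)) {
    stop("observation days must be strictly increasing", call. = FALSE)
  }
  if (days[1] < 1) {
    stop("first observation day must be >= 1", call. = FALSE)
  }
  structure(days, class = "observation_schedule")
}

#' Test duration of a schedule
#' @param schedule An [observation_schedule()].
#' @return The final observation day (days).
#' @export
test_duration <- function(schedule) {
  unclass(schedule)[length(schedule)]
}

OBS_COLUMNS <- c("species", "round", "group", "replicate",
                 "day", "n_alive", "n_initial")

#' Replicate-level time-course survival data for one trial
#'
#' A trial holds counts of individuals alive per replicate vial through
#' time, for one species and test round, across test-solution groups
#' (TS1..TS7) and controls (HSB brine control, SW seawater control).
#'
#' @param observations Data frame with columns `species`, `round`,
#'   `group`, `replicate`, `day`, `n_alive`, `n_initial`.
#' @param schedule An [observation_schedule()]; defaults to the sorted
#'   unique days present in `observations`.
#' @param metadata Optional free-form list (collection site, test volume,
#'   solution chemistry, ...).
#' @return A `trial_dataset` object: list with elements `observations`,
#'   `schedule`, `metadata`.
#' @seealso [read_survival_table()], [validate_trial()]
#' @export
trial_dataset <- function(observations, schedule = NULL, metadata = list()) {
  missing_cols <- setdiff(OBS_COLUMNS, names(observations))
  if (length(missing_cols)) {
    stop("observations missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  obs <- as.data.frame(observations)[OBS_COLUMNS]
  obs$species <- as.character(obs$species)
  obs$group <- as.character(obs$group)
  for (col in c("round", "replicate", "day", "n_alive", "n_initial")) {
    obs[[col]] <- as.numeric(obs[[col]])
  }
  if (is.null(schedule)) {
    schedule <- observation_schedule(sort(unique(obs$day)))
  }
  x <- structure(list(observations = obs, schedule = schedule,
                      metadata = metadata),
                 class = "trial_dataset")
  validate_trial(x)
  x
}

#' Validate a trial dataset
#'
#' Checks count invariants. Violations of hard invariants
#' (`n_alive > n_initial`, negative counts) are errors naming the rows;
#' non-increasing survival within a replicate is reported as a warning
#' only, since recounting noise can produce apparent resurrections in
#' real data.
#'
#' @param x A `trial_dataset`.
#' @return `x` invisibly; errors/warnings as side effects.
#' @export
validate_trial <- function(x) {
  obs <- x$observations
  bad <- which(obs$n_alive > obs$n_initial | obs$n_alive < 0 |
                 obs$n_initial <= 0)
  if (length(bad)) {
    stop("invalid counts (n_alive outside [0, n_initial]) in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(obs$day <= 0)) {
    stop("observation days must be positive", call. = FALSE)
  }
  key <- interaction(obs$species, obs$round, obs$group, obs$replicate,
                     drop = TRUE)
  for (k in levels(key)) {
    sub <- obs[key == k, ]
    sub <- sub[order(sub$day), ]
    if (any(diff(sub$n_alive) > 0)) {
      warning("n_alive increases through time within replicate ", k,
              " (possible recounting noise)", call. = FALSE)
    }
  }
  invisible(x)
}

#' Read a tidy survival table
#'
#' Reads replicate-level time-course survival counts from a delimited
#' text file with a header row naming the seven observation fields
#' (`species, round, group, replicate, day, n_alive, n_initial`).
#'
#' @param path Path to a CSV or TSV file.
#' @param dialect Field delimiter: `","` (default) or `"\t"`.
#' @return A validated [trial_dataset()].
#' @export
read_survival_table <- function(path, dialect = ",") {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- read.table(path, header = TRUE, sep = dialect,
                    stringsAsFactors = FALSE)
  missing_cols <- setdiff(OBS_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("file ", path, " missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  trial_dataset(raw)
}

#' Write a trial dataset as a tidy survival table
#'
#' @param x A `trial_dataset`.
#' @param path Output path.
#' @param dialect Field delimiter, as in [read_survival_table()].
#' @return `path` invisibly.
#' @export
write_survival_table <- function(x, path, dialect = ",") {
  write.table(x$observations, path, sep = dialect, row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Groups present in a trial
#' @param x A `trial_dataset`.
#' @return Character vector of group labels.
#' @export
trial_groups <- function(x) unique(x$observations$group)

#' Replicate-level percent survival for one group
#'
#' The long-form effects data that the time-response models are fitted
#' to: one row per replicate x observation day.
#'
#' @param x A `trial_dataset`.
#' @param group Group label.
#' @return Data frame with columns `replicate`, `day`, `survival`
#'   (percent).
#' @export
replicate_survival <- function(x, group) {
  obs <- x$observations[x$observations$group == group, ]
  if (!nrow(obs)) stop("unknown group: ", group, call. = FALSE)
  data.frame(replicate = obs$replicate, day = obs$day,
             survival = 100 * obs$n_alive / obs$n_initial)
}

group_survival <- replicate_survival

#' Mean and SD of percent survival across replicates
#'
#' Percent survival is computed per replicate (100 * n_alive / n_initial)
#' and then averaged, so the reported mean +/- SD has the replicate as the
#' experimental unit (n = number of replicate vials). SD uses the n - 1
#' denominator.
#'
#' @param x A `trial_dataset`.
#' @param group Group label (test solution or control id).
#' @param day Observation day; defaults to the final scheduled day.
#' @return Named list with `mean`, `sd`, `n` (replicates).
#' @export
mean_survival <- function(x, group, day = test_duration(x$schedule)) {
  surv <- group_survival(x, group)
  at <- surv[surv$day == day, ]
  if (!nrow(at)) {
    stop("no observations for group ", group, " at day ", day,
         call. = FALSE)
  }
  list(mean = mean(at$survival),
       sd = if (nrow(at) > 1) sd(at$survival) else 0,
       n = nrow(at))
}

#' End-of-test survival difference (control minus test solution)
#'
#' The percentage-point difference in mean survival at the final
#' scheduled day between a control group (normally the HSB brine
#' control) and a test solution. Positive values mean the test solution
#' did worse than the control; negative values are possible and kept.
#'
#' @param x A `trial_dataset`.
#' @param ts Test-solution group label.
#' @param control Control group label (default `"HSB"`).
#' @return Difference in percentage points.
#' @export
end_survival_difference <- function(x, ts, control = "HSB") {
  last <- test_duration(x$schedule)
  mean_survival(x, control, last)$mean - mean_survival(x, ts, last)$mean
}
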