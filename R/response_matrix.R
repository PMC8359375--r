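#' Criterion weights for the weight-of-evidence response matrix
#'
#' Five criteria are combined with expert-judgment weights reflecting
#' their relative importance: (1) visual distinctness of the
#' test-solution time course from both controls, weight 4; (2)
#' end-of-test survival difference vs the HSB control >= 20 points,
#' weight 3; (3) end-of-test survival < 80 percent, weight 2; (4) LT10
#' confidence-interval separation from the control, weight 1; (5) LT50
#' separation, weight 1.
#'
#' @param w Numeric vector of five positive weights.
#' @return A `criterion_weights` numeric vector.
#' @export
criterion_weights <- function(w = c(4, 3, 2, 1, 1)) {
  w <- as.numeric(w)
  if (length(w) != 5 || any(!is.finite(w)) || any(w <= 0)) {
    stop("weights must be five positive numbers", call. = FALSE)
  }
  structure(w, class = "criterion_weights")
}

criterion_score <- function(criterion, score, basis = "auto",
                            evidence = "") {
  if (!score %in% c(0, 0.5, 1)) {
    stop("criterion score must be 0, 0.5 or 1", call. = FALSE)
  }
  list(criterion = criterion, score = score, basis = basis,
       evidence = evidence)
}

#' Criterion 1: test-solution time course distinct from both controls
#'
#' The study's first criterion is a visual judgment that survival in the
#' test solution is distinct from both the HSB and SW controls at one or
#' more observation days. The automatic operationalization scores 1 when
#' at any observation day the test-solution mean survival falls below
#' *both* control means by at least `margin` points, 0.5 when the
#' largest such shortfall lies in `[borderline_margin, margin)`, else 0.
#' A manually supplied score (the recorded visual judgment) overrides
#' the automatic rule.
#'
#' @param x A `trial_dataset`.
#' @param ts Test-solution group label.
#' @param margin Full-score shortfall in percentage points (default 20).
#' @param borderline_margin Lower edge of the borderline band
#'   (default 15).
#' @param controls Labels of the two control groups.
#' @param manual Optional manual score in \{0, 0.5, 1\}.
#' @return A criterion score record (list with `criterion`, `score`,
#'   `basis`, `evidence`).
#' @export
score_criterion1 <- function(x, ts, margin = 20, borderline_margin = 15,
                             controls = c("HSB", "SW"), manual = NULL) {
  if (!is.null(manual)) {
    return(criterion_score(1, manual, basis = "manual",
                           evidence = "manual visual judgment"))
  }
  present <- trial_groups(x)
  if (!all(controls %in% present)) {
    stop("control group(s) missing: ",
         paste(setdiff(controls, present), collapse = ", "),
         call. = FALSE)
  }
  days <- unclass(x$schedule)
  shortfall <- vapply(days, function(d) {
    ts_mean <- mean_survival(x, ts, d)$mean
    ctrl_means <- vapply(controls, function(g) mean_survival(x, g, d)$mean,
                         numeric(1))
    min(ctrl_means) - ts_mean
  }, numeric(1))
  worst <- max(shortfall)
  score <- if (worst >= margin) 1 else if (worst >= borderline_margin) 0.5 else 0
  criterion_score(1, score,
                  evidence = sprintf(
                    "max shortfall vs both controls %.1f points (day %g)",
                    worst, days[which.max(shortfall)]))
}

#' Criterion 2: end-of-test survival difference vs HSB control
#'
#' Scores the percentage-point difference (HSB control minus test
#' solution) in mean survival at the end of the test: `>= 20` scores 1,
#' `[15, 20)` scores 0.5, `< 15` scores 0.
#'
#' @param difference Difference in percentage points (see
#'   [end_survival_difference()]).
#' @return A criterion score record.
#' @export
score_criterion2 <- function(difference) {
  score <- if (difference >= 20) 1 else if (difference >= 15) 0.5 else 0
  criterion_score(2, score,
                  evidence = sprintf("end-survival difference %.1f points",
                                     difference))
}

#' Criterion 3: low end-of-test survival in the test solution
#'
#' Mean survival at test end `< 80` percent scores 1, `[80, 85]`
#' (borderline, both endpoints included) scores 0.5, `> 85` scores 0.
#'
#' @param end_survival Mean percent survival at the final day.
#' @return A criterion score record.
#' @export
score_criterion3 <- function(end_survival) {
  score <- if (end_survival < 80) 1 else if (end_survival <= 85) 0.5 else 0
  criterion_score(3, score,
                  evidence = sprintf("end survival %.1f%%", end_survival))
}

#' Criteria 4 and 5: lethal-time confidence-interval separation
#'
#' Compares the test solution's LT estimate range against the HSB
#' control's for the same decline level (`p = 10` for criterion 4,
#' `p = 50` for criterion 5). Scores 1 when the ranges are disjoint with
#' the test solution below (`ts$upper < ctrl$lower`); 0.5 when the test
#' solution's upper limit falls inside the control range but its point
#' estimate is below the control's lower limit; else 0. When the control
#' has no estimable LT (no control mortality), the fallback scores 1
#' only if the test solution's upper limit lies within the test
#' duration — a control with no estimable lethal time behaves as
#' "beyond test end". A test solution without an estimable LT scores 0.
#'
#' @param ts_lt `lt_estimate` for the test solution.
#' @param ctrl_lt `lt_estimate` for the HSB control, or `NULL`.
#' @param duration Test duration (days), used by the control fallback.
#' @param criterion 4 or 5 (labelling only).
#' @return A criterion score record.
#' @export
score_criterion_ci <- function(ts_lt, ctrl_lt, duration, criterion = 4) {
  if (is.null(ts_lt) || !isTRUE(ts_lt$available)) {
    return(criterion_score(criterion, 0, evidence = "not estimable"))
  }
  if (is.null(ctrl_lt) || !isTRUE(ctrl_lt$available)) {
    score <- if (ts_lt$upper < duration) 1 else 0
    return(criterion_score(criterion, score,
                           evidence = sprintf(
                             "control non-modellable; TS upper limit %.1f vs duration %g d",
                             ts_lt$upper, duration)))
  }
  score <- if (ts_lt$upper < ctrl_lt$lower) {
    1
  } else if (ts_lt$upper <= ctrl_lt$upper &&
             ts_lt$estimate < ctrl_lt$lower) {
    0.5
  } else {
    0
  }
  criterion_score(criterion, score,
                  evidence = sprintf(
                    "TS LT%g %.1f [%.1f, %.1f] vs control [%.1f, %.1f]",
                    ts_lt$p, ts_lt$estimate, ts_lt$lower, ts_lt$upper,
                    ctrl_lt$lower, ctrl_lt$upper))
}

#' Weighted response score
#'
#' The weighted sum of the five criterion scores expressed as a
#' percentage of the maximum attainable: `100 * sum(w_i s_i) / sum(w_i)`.
#' The rounded value (nearest integer, halves away from zero) is for
#' reporting; classification uses the unrounded value.
#'
#' @param scores Five criterion scores in \{0, 0.5, 1\} (numeric vector,
#'   or list of criterion score records).
#' @param weights A [criterion_weights()] vector.
#' @return List with `unrounded` and `rounded` percent.
#' @export
response_score <- function(scores, weights = criterion_weights()) {
  if (is.list(scores)) {
    scores <- vapply(scores, function(s) s$score, numeric(1))
  }
  if (length(scores) != 5 || !all(scores %in% c(0, 0.5, 1))) {
    stop("scores must be five values in {0, 0.5, 1}", call. = FALSE)
  }
  pct <- 100 * sum(weights * scores) / sum(weights)
  list(unrounded = pct, rounded = round_half_away(pct))
}

#' Classify a response score
#'
#' @param score Response score in percent (unrounded).
#' @param threshold Classification threshold (default 65); scores at or
#'   above the threshold are a Response.
#' @return `"Response"` or `"NoResponse"`.
#' @export
classify_response <- function(score, threshold = 65) {
  stopifnot(score >= 0, score <= 100)
  if (score >= threshold) "Response" else "NoResponse"
}

#' Microtox EC50 interpretation band
#'
#' Bands a 15-min Microtox EC50 (percent dilution of the test solution)
#' into the laboratory's interpretation categories: `<= 25` extremely
#' toxic, `(25, 50]` highly toxic, `(50, 75]` moderately toxic,
#' `(75, 100]` slightly toxic, `> 100` no measurable toxicity. The
#' printed band endpoints overlap at 25; the bands are resolved as
#' half-open intervals with the extreme bound inclusive. An EC50 of
#' `"NMT"`, `NA` or `Inf` is the no-measurable-toxicity marker.
#'
#' @param ec50 EC50 as percent dilution (> 0), or the marker.
#' @return Category label.
#' @export
microtox_category <- function(ec50) {
  if (is.character(ec50)) {
    if (toupper(ec50) == "NMT") return("no measurable toxicity")
    ec50 <- suppressWarnings(as.numeric(ec50))
  }
  if (is.na(ec50) || is.infinite(ec50)) return("no measurable toxicity")
  if (ec50 <= 0) stop("EC50 must be positive", call. = FALSE)
  if (ec50 <= 25) "extremely toxic"
  else if (ec50 <= 50) "highly toxic"
  else if (ec50 <= 75) "moderately toxic"
  else if (ec50 <= 100) "slightly toxic"
  else "no measurable toxicity"
}

#' Full assessment of one species x test-solution x round combination
#'
#' Scores all five criteria from a trial dataset and its lethal-time
#' estimates, combines them with the weights, and classifies the
#' combination.
#'
#' @param x A `trial_dataset` (one species and round).
#' @param ts Test-solution group label.
#' @param lt_ts Named list of `lt_estimate`s for the test solution,
#'   keyed `"10"` and `"50"`; `NULL` entries mean not estimable.
#' @param lt_ctrl Same for the HSB control.
#' @param weights A [criterion_weights()] vector.
#' @param threshold Response threshold in percent (default 65).
#' @param margin,borderline_margin Criterion 1 margins (points).
#' @param manual Optional named numeric vector of manual criterion
#'   overrides, e.g. `c("1" = 1, "4" = 0.5)`.
#' @param control,sw Control group labels.
#' @return A `response_assessment`: list with identifiers, the five
#'   criterion records, `end_survival`, `difference`, `response_score`
#'   (unrounded), `rounded`, `label`.
#' @export
assess_combination <- function(x, ts, lt_ts = list(), lt_ctrl = list(),
                               weights = criterion_weights(),
                               threshold = 65, margin = 20,
                               borderline_margin = 15, manual = NULL,
                               control = "HSB", sw = "SW") {
  duration <- test_duration(x$schedule)
  end_surv <- mean_survival(x, ts, duration)$mean
  diff_pts <- end_survival_difference(x, ts, control)
  crit <- list(
    score_criterion1(x, ts, margin, borderline_margin,
                     controls = c(control, sw),
                     manual = manual[["1"]]),
    score_criterion2(diff_pts),
    score_criterion3(end_surv),
    score_criterion_ci(lt_ts[["10"]], lt_ctrl[["10"]], duration,
                       criterion = 4),
    score_criterion_ci(lt_ts[["50"]], lt_ctrl[["50"]], duration,
                       criterion = 5)
  )
  if (!is.null(manual)) {
    for (i in 2:5) {
      key <- as.character(i)
      if (key %in% names(manual)) {
        crit[[i]] <- criterion_score(i, manual[[key]], basis = "manual",
                                     evidence = "manual override")
      }
    }
  }
  sc <- response_score(crit, weights)
  structure(list(
    species = x$observations$species[1],
    solution = ts,
    round = x$observations$round[1],
    end_survival = end_surv,
    difference = diff_pts,
    criteria = crit,
    weights = weights,
    threshold = threshold,
    response_score = sc$unrounded,
    rounded = sc$rounded,
    label = classify_response(sc$unrounded, threshold)
  ), class = "response_assessment")
}

#' Assemble a response grid from assessments and external labels
#'
#' The grid is the long form of the response-summary table: one row per
#' tested cell (`unit` x `solution` x `round`) with a
#' Response / NoResponse label. External assay results (e.g. Microtox)
#' enter as extra units of type `"assay"`. Cells absent from the grid
#' are not tested.
#'
#' @param assessments List of `response_assessment` objects.
#' @param external_labels Optional data frame with columns `unit`,
#'   `solution`, `round`, `label` (Response / NoResponse / NotTested).
#' @return Data frame with columns `unit`, `type`, `solution`, `round`,
#'   `label`.
#' @export
response_grid <- function(assessments, external_labels = NULL) {
  grid <- data.frame(
    unit = vapply(assessments, function(a) a$species, character(1)),
    type = rep("species", length(assessments)),
    solution = vapply(assessments, function(a) a$solution, character(1)),
    round = vapply(assessments, function(a) as.numeric(a$round),
                   numeric(1)),
    label = vapply(assessments, function(a) a$label, character(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(external_labels) && nrow(external_labels)) {
    ext <- data.frame(unit = as.character(external_labels$unit),
                      type = "assay",
                      solution = as.character(external_labels$solution),
                      round = as.numeric(external_labels$round),
                      label = as.character(external_labels$label),
                      stringsAsFactors = FALSE)
    grid <- rbind(grid, ext)
  }
  key <- paste(grid$unit, grid$solution, grid$round)
  if (anyDuplicated(key)) {
    stop("duplicate assessment for: ",
         paste(unique(key[duplicated(key)]), collapse = "; "),
         call. = FALSE)
  }
  grid
}

#' Summarize relative toxicity and relative sensitivity
#'
#' From a response grid, computes for each test solution the percent of
#' tested units (species and assays, both rounds pooled) classified as
#' Response ("% toxic"), and for each unit the percent of tested
#' solutions with a Response ("% toxic response"). NotTested cells are
#' excluded from denominators. Percentages are rounded to integers
#' (halves away from zero).
#'
#' @param grid A response grid (see [response_grid()]); rows labelled
#'   `NotTested` are dropped.
#' @return List with data frames `by_solution` (`solution`, `n_tested`,
#'   `n_response`, `pct_toxic`) and `by_unit` (`unit`, `type`,
#'   `n_tested`, `n_response`, `pct_toxic_response`).
#' @export
summarize_matrix <- function(grid) {
  if (!nrow(grid)) stop("empty response grid", call. = FALSE)
  grid <- grid[grid$label != "NotTested", ]
  tab <- function(split_col, pct_name) {
    parts <- split(grid, grid[[split_col]])
    out <- do.call(rbind, lapply(names(parts), function(nm) {
      g <- parts[[nm]]
      n <- nrow(g)
      r <- sum(g$label == "Response")
      data.frame(key = nm, n_tested = n, n_response = r,
                 pct = round_half_away(100 * r / n),
                 stringsAsFactors = FALSE)
    }))
    names(out) <- c(split_col, "n_tested", "n_response", pct_name)
    out
  }
  by_solution <- tab("solution", "pct_toxic")
  by_unit <- tab("unit", "pct_toxic_response")
  by_unit$type <- grid$type[match(by_unit$unit, grid$unit)]
  by_unit <- by_unit[c("unit", "type", "n_tested", "n_response",
                       "pct_toxic_response")]
  list(by_solution = by_solution, by_unit = by_unit)
}

#' Read manual criterion-score overrides
#'
#' Manual overrides let recorded expert judgments (notably the visual
#' criterion 1) replace the automatic rules.
#'
#' @param path CSV with columns `species`, `solution`, `round`,
#'   `criterion`, `score`.
#' @return Data frame of overrides.
#' @export
read_criterion_overrides <- function(path) {
  ov <- read.table(path, header = TRUE, sep = ",",
                   stringsAsFactors = FALSE)
  needed <- c("species", "solution", "round", "criterion", "score")
  missing_cols <- setdiff(needed, names(ov))
  if (length(missing_cols)) {
    stop("override file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(ov$score %in% c(0, 0.5, 1))) {
    stop("override scores must be 0, 0.5 or 1", call. = FALSE)
  }
  ov
}
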