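#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis: inputs, model
#' families, lethal-time levels, criterion margins, weights and the
#' response threshold. All expert-judgment constants are overridable to
#' support sensitivity analysis.
#'
#' @param input Path to the tidy survival CSV, or a data frame of
#'   observations.
#' @param overrides Optional path to a manual criterion-score CSV (see
#'   [read_criterion_overrides()]).
#' @param external_labels Optional path to an external-label CSV with
#'   columns `unit`, `solution`, `round`, `label` (e.g. Microtox
#'   results).
#' @param families Model families to try (default all).
#' @param lt_levels Decline levels for lethal times (default 10 and 50).
#' @param level Confidence level (default 0.95).
#' @param margin,borderline_margin Criterion 1 margins (points).
#' @param threshold Response threshold in percent, in (0, 100].
#' @param weights Five criterion weights.
#' @param control,sw Control group labels.
#' @param out_dir Output directory (created if needed).
#' @param dialect Input/output field delimiter.
#' @param seed Seed for simulation subcommands (unused by the
#'   deterministic analysis itself).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, overrides = NULL,
                            external_labels = NULL,
                            families = names(model_families),
                            lt_levels = c(10, 50), level = 0.95,
                            margin = 20, borderline_margin = 15,
                            threshold = 65,
                            weights = criterion_weights(),
                            control = "HSB", sw = "SW",
                            out_dir = "results", dialect = ",",
                            seed = 1) {
  stopifnot(threshold > 0, threshold <= 100, length(families) >= 1)
  structure(list(input = input, overrides = overrides,
                 external_labels = external_labels, families = families,
                 lt_levels = lt_levels, level = level, margin = margin,
                 borderline_margin = borderline_margin,
                 threshold = threshold,
                 weights = criterion_weights(weights),
                 control = control, sw = sw, out_dir = out_dir,
                 dialect = dialect, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a YAML (or JSON) file whose keys match the
#'   arguments of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

# fit all families to one group and derive LTs from the AIC-best fit
fit_group_lt <- function(trial, group, families, lt_levels, level) {
  dat <- group_survival(trial, group)
  fits <- fit_models(dat, families)
  best <- tryCatch(select_best(fits), error = function(e) NULL)
  lts <- setNames(vector("list", length(lt_levels)),
                  as.character(lt_levels))
  if (!is.null(best)) {
    for (p in lt_levels) {
      lts[[as.character(p)]] <- estimate_lt(best, p, level)
    }
  }
  list(best = best, lts = lts, fits = fits)
}

#' Run the full direct-toxicity-assessment analysis
#'
#' Reads the survival table, fits the candidate time-response families
#' to every group of every species x round, selects the AIC-best model,
#' derives LT10/LT50 with confidence limits, scores the five weighted
#' criteria for each test solution, classifies Response / No response,
#' merges external assay labels, and writes the lethal-time table, the
#' response matrix, the relative-toxicity summaries, a JSON detail
#' bundle, a Markdown report and a run manifest into the output
#' directory. Fit failures degrade to criterion evidence (a group is
#' reported non-modellable); they never abort the run.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `assessments`, `lt_table`,
#'   `response_table`, `grid`, `summary` and the written file paths.
#' @export
run_pipeline <- function(config) {
  obs <- if (is.character(config$input)) {
    read_survival_table(config$input, config$dialect)$observations
  } else {
    as.data.frame(config$input)
  }
  if (!nrow(obs)) {
    stop("no observations in input ",
         if (is.character(config$input)) config$input else "data frame",
         call. = FALSE)
  }
  overrides <- if (!is.null(config$overrides)) {
    read_criterion_overrides(config$overrides)
  }
  external <- if (!is.null(config$external_labels)) {
    read.table(config$external_labels, header = TRUE, sep = ",",
               stringsAsFactors = FALSE)
  }

  assessments <- list()
  lt_rows <- list()
  detail <- list()
  for (key in unique(paste(obs$species, obs$round, sep = "\r"))) {
    parts <- strsplit(key, "\r")[[1]]
    sub <- obs[obs$species == parts[1] & obs$round == parts[2], ]
    trial <- trial_dataset(sub)
    duration <- test_duration(trial$schedule)
    groups <- trial_groups(trial)
    ts_groups <- setdiff(groups, c(config$control, config$sw))

    group_lt <- lapply(setNames(nm = groups), function(g) {
      res <- fit_group_lt(trial, g, config$families, config$lt_levels,
                          config$level)
      if (is.null(res$best)) {
        message("non-modellable group: ", parts[1], " round ", parts[2],
                " ", g)
      }
      res
    })

    for (ts in ts_groups) {
      manual <- NULL
      if (!is.null(overrides)) {
        ov <- overrides[overrides$species == parts[1] &
                          overrides$solution == ts &
                          overrides$round == as.numeric(parts[2]), ]
        if (nrow(ov)) {
          manual <- setNames(ov$score, as.character(ov$criterion))
          message("manual criterion override for ", parts[1], " ", ts,
                  " round ", parts[2], ": criteria ",
                  paste(ov$criterion, collapse = ", "))
        }
      }
      a <- assess_combination(
        trial, ts,
        lt_ts = group_lt[[ts]]$lts,
        lt_ctrl = group_lt[[config$control]]$lts,
        weights = config$weights, threshold = config$threshold,
        margin = config$margin,
        borderline_margin = config$borderline_margin,
        manual = manual, control = config$control, sw = config$sw)
      assessments[[length(assessments) + 1]] <- a

      lt_rows[[length(lt_rows) + 1]] <- lt_table_row(
        parts[1], ts, as.numeric(parts[2]), duration, group_lt[[ts]])
    }
    for (ctl in intersect(c(config$control, config$sw), groups)) {
      lt_rows[[length(lt_rows) + 1]] <- lt_table_row(
        parts[1], ctl, as.numeric(parts[2]), duration, group_lt[[ctl]])
    }
    detail[[key]] <- lapply(group_lt, function(res) {
      if (is.null(res$best)) return(list(converged = FALSE))
      list(converged = TRUE, family = res$best$family,
           params = as.list(res$best$params),
           cov = unclass(res$best$cov), rss = res$best$rss,
           n_obs = res$best$n_obs, aic = res$best$aic,
           lt = lapply(res$lts, unclass))
    })
  }

  lt_table <- do.call(rbind, lt_rows)
  response_table <- do.call(rbind, lapply(assessments, assessment_row))
  grid <- response_grid(assessments, external)
  summary <- summarize_matrix(grid)

  paths <- write_pipeline_outputs(config, lt_table, response_table,
                                  grid, summary, detail)
  invisible(list(assessments = assessments, lt_table = lt_table,
                 response_table = response_table, grid = grid,
                 summary = summary, paths = paths))
}

fmt1 <- function(x) ifelse(is.na(x), "", sprintf("%.1f", x))

lt_table_row <- function(species, group, round, duration, res) {
  get <- function(p, field) {
    lt <- res$lts[[as.character(p)]]
    if (is.null(lt) || !isTRUE(lt$available)) NA_real_ else lt[[field]]
  }
  data.frame(species = species, solution = group, round = round,
             duration = duration,
             family = if (is.null(res$best)) "" else res$best$family,
             LT10 = get(10, "estimate"), LT10_LL = get(10, "lower"),
             LT10_UL = get(10, "upper"),
             LT50 = get(50, "estimate"), LT50_LL = get(50, "lower"),
             LT50_UL = get(50, "upper"),
             stringsAsFactors = FALSE)
}

assessment_row <- function(a) {
  s <- vapply(a$criteria, function(cr) cr$score, numeric(1))
  basis <- vapply(a$criteria, function(cr) cr$basis, character(1))
  data.frame(species = a$species, solution = a$solution,
             round = as.numeric(a$round),
             end_survival = a$end_survival, difference = a$difference,
             c1 = s[1], c2 = s[2], c3 = s[3], c4 = s[4], c5 = s[5],
             basis = paste(basis, collapse = "/"),
             response_score = a$rounded, judgment = a$label,
             stringsAsFactors = FALSE)
}

write_pipeline_outputs <- function(config, lt_table, response_table,
                                   grid, summary, detail) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$out_dir, f)

  lt_out <- lt_table
  for (col in c("LT10", "LT10_LL", "LT10_UL", "LT50", "LT50_LL",
                "LT50_UL")) {
    lt_out[[col]] <- fmt1(lt_out[[col]])
  }
  write.table(lt_out, path("lt_table.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)

  resp_out <- response_table
  resp_out$end_survival <- fmt1(resp_out$end_survival)
  resp_out$difference <- fmt1(resp_out$difference)
  write.table(resp_out, path("response_matrix.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)

  write.table(summary$by_solution, path("summary_by_solution.csv"),
              sep = ",", row.names = FALSE, quote = FALSE)
  write.table(summary$by_unit, path("summary_by_unit.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)

  jsonlite::write_json(detail, path("fit_detail.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       matrix = "rowmajor", force = TRUE)

  report <- c(
    "# Direct toxicity assessment report", "",
    sprintf("Combinations assessed: %d", nrow(response_table)),
    sprintf("Responses: %d (threshold %g%%)",
            sum(response_table$judgment == "Response"),
            config$threshold), "",
    "## Percent toxic by test solution", "",
    sprintf("- %s: %d%% (%d of %d)", summary$by_solution$solution,
            summary$by_solution$pct_toxic,
            summary$by_solution$n_response,
            summary$by_solution$n_tested), "",
    "## Percent toxic response by unit", "",
    sprintf("- %s: %d%% (%d of %d)", summary$by_unit$unit,
            summary$by_unit$pct_toxic_response,
            summary$by_unit$n_response, summary$by_unit$n_tested))
  writeLines(report, path("report.md"))

  manifest <- list(
    package = "toxmatrix",
    version = as.character(utils::packageVersion("toxmatrix")),
    config = config[setdiff(names(config), "input")],
    input = if (is.character(config$input)) {
      list(path = config$input,
           md5 = unname(tools::md5sum(config$input)))
    } else {
      list(rows = nrow(as.data.frame(config$input)))
    })
  jsonlite::write_json(manifest, path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)

  vapply(c("lt_table.csv", "response_matrix.csv",
           "summary_by_solution.csv", "summary_by_unit.csv",
           "fit_detail.json", "report.md", "manifest.json"),
         path, character(1))
}

#' Sample fraction after brine salinity adjustment
#'
#' A groundwater sample at salinity `s_sample` is brought up to the test
#' salinity `s_target` by adding hypersaline brine at salinity
#' `s_brine`. Mass balance gives the fraction of original sample in the
#' adjusted solution: `(s_brine - s_target) / (s_brine - s_sample)`,
#' returned as a percent. In the study this dilution left test
#' solutions at 76-88 percent of the original composite samples.
#'
#' @param s_sample Sample salinity (permille), `>= 0`.
#' @param s_target Test salinity (permille), `>= s_sample`.
#' @param s_brine Brine salinity (permille), `> s_target`.
#' @return Percent of original sample in the adjusted solution.
#' @examples
#' dilution_fraction(0, 33, 132) # 75
#' @export
dilution_fraction <- function(s_sample, s_target, s_brine) {
  if (any(s_sample < 0) || any(s_target < s_sample)) {
    stop("require 0 <= s_sample <= s_target", call. = FALSE)
  }
  if (any(s_brine <= s_target)) {
    stop("brine salinity must exceed the target salinity ",
         "(adjustment infeasible)", call. = FALSE)
  }
  100 * (s_brine - s_target) / (s_brine - s_sample)
}
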