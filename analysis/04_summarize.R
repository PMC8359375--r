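#!/usr/bin/env Rscript
# Step 4: descriptive summaries around the assessment. Recomputes the
# relative-toxicity and relative-sensitivity proportions from the
# recorded two-round response grid bundled with the package, bands the
# recorded Microtox EC50 values, and tabulates the brine mass-balance
# dilution arithmetic.

suppressPackageStartupMessages(library(toxmatrix))
dir.create("results", showWarnings = FALSE)

grid <- read.csv(system.file("extdata", "response_grid.csv",
                             package = "toxmatrix"))
sm <- summarize_matrix(grid)
write.table(sm$by_solution, "results/recorded_summary_by_solution.csv",
            sep = ",", row.names = FALSE, quote = FALSE)
write.table(sm$by_unit, "results/recorded_summary_by_unit.csv",
            sep = ",", row.names = FALSE, quote = FALSE)

cat("Recorded grid:",
    sum(sm$by_unit$n_tested[sm$by_unit$type == "species"]),
    "species cells +",
    sum(sm$by_unit$n_tested[sm$by_unit$type == "assay"]),
    "assay cells\n")
ord <- order(-sm$by_solution$pct_toxic)
cat("Relative toxicity (% toxic):",
    paste(sprintf("%s %d%%", sm$by_solution$solution[ord],
                  sm$by_solution$pct_toxic[ord]), collapse = ", "), "\n")
top <- sm$by_unit[order(-sm$by_unit$pct_toxic_response), ][1:3, ]
cat("Most sensitive units:",
    paste(sprintf("%s %d%%", top$unit, top$pct_toxic_response),
          collapse = ", "), "\n")

ec <- read.csv(system.file("extdata", "microtox_ec50.csv",
                           package = "toxmatrix"),
               colClasses = c("character", "integer", "character"))
ec$category <- vapply(ec$ec50, microtox_category, character(1))
write.table(ec, "results/microtox_categories.csv", sep = ",",
            row.names = FALSE, quote = FALSE)
cat("Microtox bands with measurable toxicity:\n")
meas <- ec[ec$category != "no measurable toxicity", ]
for (i in seq_len(nrow(meas))) {
  cat(sprintf("  %s round %d: EC50 %s%% -> %s\n", meas$solution[i],
              meas$round[i], meas$ec50[i], meas$category[i]))
}

# brine adjustment: fraction of original groundwater left after raising
# a near-fresh sample to the 33-34 permille test salinity
brine <- data.frame(s_sample = c(0, 2, 5, 10),
                    s_target = 33.5,
                    s_brine = 150)
brine$pct_sample <- round(dilution_fraction(brine$s_sample, brine$s_target,
                                            brine$s_brine), 1)
write.table(brine, "results/dilution_fractions.csv", sep = ",",
            row.names = FALSE, quote = FALSE)
cat("Sample fraction after salinity adjustment (150 permille brine):",
    paste(sprintf("%g permille -> %.1f%%", brine$s_sample,
                  brine$pct_sample), collapse = ", "), "\n")
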