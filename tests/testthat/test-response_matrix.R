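test_that("criterion 1 auto rule scores separation from both controls", {
  days <- c(1, 2, 4, 7, 10, 14)
  full <- const_counts(10, 5, 6)
  ctrl6 <- const_counts(10, 6, 6)
  # identical to controls -> 0
  x <- trial_from_counts(list(TS1 = full, HSB = ctrl6, SW = ctrl6), days)
  expect_equal(score_criterion1(x, "TS1")$score, 0)
  # total mortality from day 4 vs >=95% controls -> 1
  dead <- matrix(rep(c(10, 10, 0, 0, 0, 0), each = 5), nrow = 5)
  hsb <- matrix(rep(c(10, 10, 10, 10, 10, 9), each = 6), nrow = 6)
  y <- trial_from_counts(list(TS1 = dead, HSB = hsb, SW = ctrl6), days)
  expect_equal(score_criterion1(y, "TS1")$score, 1)
  # max shortfall 17 points -> borderline
  ts17 <- matrix(rep(c(10, 10, 10, 10, 10, 8.3 * 10 / 10), each = 5),
                 nrow = 5)
  ts17[, 6] <- c(8, 8, 8, 9, 8.5)  # mean 83 -> shortfall 17
  z <- trial_from_counts(list(TS1 = ts17, HSB = ctrl6, SW = ctrl6), days)
  expect_equal(score_criterion1(z, "TS1")$score, 0.5)
  # manual override wins
  manual <- score_criterion1(z, "TS1", manual = 1)
  expect_equal(manual$score, 1)
  expect_equal(manual$basis, "manual")
  # missing control is a scoring error
  w <- trial_from_counts(list(TS1 = full, HSB = ctrl6), days)
  expect_error(score_criterion1(w, "TS1"), "missing")
})

test_that("criteria 2 and 3 reproduce printed scores and boundary pins", {
  expect_equal(score_criterion2(78)$score, 1)
  expect_equal(score_criterion2(18)$score, 0.5)
  expect_equal(score_criterion2(10)$score, 0)
  expect_equal(score_criterion2(20)$score, 1)    # >= 20 met
  expect_equal(score_criterion2(15)$score, 0.5)  # 15 borderline
  expect_equal(score_criterion2(14.9)$score, 0)

  expect_equal(score_criterion3(85)$score, 0.5)  # pinned borderline
  expect_equal(score_criterion3(80)$score, 0.5)
  expect_equal(score_criterion3(61)$score, 1)
  expect_equal(score_criterion3(96)$score, 0)
  expect_equal(score_criterion3(79.9)$score, 1)
  expect_equal(score_criterion3(85.1)$score, 0)
})

test_that("LT interval separation criteria follow the overlap rules", {
  lt <- function(est, lo, hi) {
    structure(list(p = 10, estimate = est, lower = lo, upper = hi,
                   se = NA, level = 0.95, available = TRUE, reason = NA),
              class = "lt_estimate")
  }
  none <- structure(list(available = FALSE), class = "lt_estimate")
  ctrl <- lt(14, 10, 20)
  expect_equal(score_criterion_ci(lt(3, 2, 4), ctrl, 14)$score, 1)
  expect_equal(score_criterion_ci(lt(8, 5, 12), ctrl, 14)$score, 0.5)
  expect_equal(score_criterion_ci(lt(11, 9, 15), ctrl, 14)$score, 0)
  # control non-modellable: fall back to the test-duration rule
  expect_equal(score_criterion_ci(lt(8, 5, 12), NULL, 14)$score, 1)
  expect_equal(score_criterion_ci(lt(8, 5, 16), none, 14)$score, 0)
  # test solution not estimable scores 0 with evidence
  na_score <- score_criterion_ci(none, ctrl, 14)
  expect_equal(na_score$score, 0)
  expect_match(na_score$evidence, "not estimable")
})

test_that("weighted response scores match the worked excerpt", {
  expect_equal(response_score(c(0, 0, 0.5, 0, 0))$rounded, 9)
  expect_equal(response_score(c(1, 0.5, 1, 0, 0))$rounded, 68)
  expect_equal(response_score(c(1, 1, 1, 1, 1))$rounded, 100)
  expect_equal(response_score(c(0, 0, 0, 0, 0))$rounded, 0)
  expect_equal(response_score(c(0, 0, 1, 0, 0))$rounded, 18)
  expect_equal(response_score(c(0.5, 0, 1, 0, 0.5))$rounded, 41)
  expect_error(response_score(c(1, 1, 1, 1, 0.3)), "0, 0.5")
})

test_that("the printed 93 is inconsistent with its own criteria (formula gives 91)", {
  sc <- response_score(c(1, 1, 1, 0, 1))
  expect_equal(sc$unrounded, 1000 / 11)
  expect_equal(sc$rounded, 91)
  expect_false(sc$rounded == 93)
})

test_that("classification threshold is inclusive at 65", {
  expect_equal(classify_response(68.18), "Response")
  expect_equal(classify_response(40.9), "NoResponse")
  expect_equal(classify_response(65), "Response")
  expect_equal(classify_response(64.999), "NoResponse")
})

test_that("response score is monotone, permutation-stable and scale-free", {
  set.seed(9)
  vals <- c(0, 0.5, 1)
  for (i in 1:30) {
    s <- sample(vals, 5, replace = TRUE)
    base <- response_score(s)$unrounded
    # monotone non-decreasing in each criterion
    for (j in 1:5) {
      if (s[j] < 1) {
        up <- s; up[j] <- 1
        expect_gte(response_score(up)$unrounded, base)
      }
    }
    # permuting criteria together with weights leaves the score unchanged
    perm <- sample(5)
    expect_equal(response_score(s[perm],
                                criterion_weights(c(4, 3, 2, 1, 1)[perm]))$unrounded,
                 base)
    # classification invariant to weight rescaling
    expect_equal(classify_response(base),
                 classify_response(
                   response_score(s, criterion_weights(3.7 * c(4, 3, 2, 1, 1)))$unrounded))
  }
  # attainable scores lie on the half-step lattice of 100/22
  lattice <- sapply(1:200, function(i) {
    response_score(sample(vals, 5, replace = TRUE))$unrounded
  })
  expect_true(all(abs(lattice / (100 / 22) -
                        round(lattice / (100 / 22))) < 1e-9))
})

test_that("Microtox EC50 bands resolve as half-open intervals", {
  expect_equal(microtox_category(89), "slightly toxic")
  expect_equal(microtox_category(40), "highly toxic")
  expect_equal(microtox_category("NMT"), "no measurable toxicity")
  expect_equal(microtox_category(25), "extremely toxic")
  expect_equal(microtox_category(25.01), "highly toxic")
  expect_equal(microtox_category(50), "highly toxic")
  expect_equal(microtox_category(75), "moderately toxic")
  expect_equal(microtox_category(100), "slightly toxic")
  expect_equal(microtox_category(101), "no measurable toxicity")
  expect_equal(microtox_category(Inf), "no measurable toxicity")
  expect_error(microtox_category(-2), "positive")
})

test_that("summary proportions reproduce the published response grid", {
  grid <- read.csv(system.file("extdata", "response_grid.csv",
                               package = "toxmatrix"),
                   stringsAsFactors = FALSE)
  sm <- summarize_matrix(grid)
  by_unit <- sm$by_unit
  expect_equal(by_unit$pct_toxic_response[by_unit$unit == "Zaus sp."], 69)
  expect_equal(by_unit$pct_toxic_response[by_unit$unit == "Exosphaeroma gigas"], 29)
  expect_equal(by_unit$pct_toxic_response[by_unit$unit == "Microtox"], 31)
  by_sol <- sm$by_solution
  expect_equal(by_sol$pct_toxic[by_sol$solution == "TS1"], 58)
  expect_equal(by_sol$pct_toxic[by_sol$solution == "TS3"], 0)
  expect_equal(by_sol$pct_toxic[by_sol$solution == "TS7"], 5)
  # species cells across both rounds: 8 x 7 + 9 x 6 = 110
  expect_equal(sum(by_unit$n_tested[by_unit$type == "species"]), 110)
  # a grid of all responses saturates at 100
  all_r <- grid
  all_r$label <- "Response"
  sm2 <- summarize_matrix(all_r)
  expect_true(all(sm2$by_solution$pct_toxic == 100))
  expect_true(all(sm2$by_unit$pct_toxic_response == 100))
})
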