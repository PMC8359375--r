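test_that("model curves match their closed forms at landmark times", {
  expect_equal(model_curve("LL3u100", c(b = 3, e = 8), 8), 50)
  expect_equal(model_curve("LL3u100", c(b = 3, e = 8), 1e-9), 100,
               tolerance = 1e-6)
  expect_equal(model_curve("W14", c(b = 2, c = 0, d = 100, e = 8), 8),
               100 * exp(-1))
  expect_equal(model_curve("LL5", c(b = 2, c = 10, d = 90, e = 5, f = 1), 4),
               model_curve("LL4", c(b = 2, c = 10, d = 90, e = 5), 4))
  expect_error(model_curve("LL3u100", c(b = 3, e = 8), 0), "positive")
  expect_error(model_curve("XX", c(b = 1, e = 1), 1), "unknown")
})

test_that("noiseless data reproduce the generating curve", {
  days <- c(1, 2, 4, 7, 10, 14)
  dat <- curve_data("LL3u100", c(b = 3, e = 8), days, n_rep = 5)
  fit <- fit_model(dat, "LL3u100")
  expect_true(fit$converged)
  expect_equal(unname(fit$params["b"]), 3, tolerance = 1e-4)
  expect_equal(unname(fit$params["e"]), 8, tolerance = 1e-4)
  expect_lt(fit$rss, 1e-8)
})

test_that("degenerate and underdetermined inputs are handled", {
  days <- c(1, 2, 4, 7, 10, 14)
  flat <- data.frame(day = rep(days, 3), survival = 100)
  fit <- fit_model(flat, "LL3u100")
  expect_false(fit$converged)
  expect_false(estimate_lt(fit, 50)$available)
  expect_error(fit_model(data.frame(day = c(1, 1, 2), survival = c(90, 91, 50)),
                         "LL4"),
               "distinct")
})

test_that("Wald intervals achieve near-nominal coverage under iid noise", {
  set.seed(101)
  days <- c(1, 2, 4, 7, 10, 14)
  n_sims <- 500
  hits_b <- hits_e <- 0
  n_ok <- 0
  for (i in seq_len(n_sims)) {
    dat <- curve_data("LL3u100", c(b = 3, e = 8), days, n_rep = 5, sd = 5)
    fit <- fit_model(dat, "LL3u100")
    if (!fit$converged) next
    n_ok <- n_ok + 1
    tq <- qt(0.975, fit$df)
    se <- sqrt(diag(fit$cov))
    hits_b <- hits_b + (abs(fit$params["b"] - 3) <= tq * se["b"])
    hits_e <- hits_e + (abs(fit$params["e"] - 8) <= tq * se["e"])
  }
  expect_gt(n_ok, 0.95 * n_sims)
  # nominal 0.95 with 3-SE simulation slack
  expect_gt(hits_b / n_ok, 0.92)
  expect_lt(hits_b / n_ok, 0.98)
  expect_gt(hits_e / n_ok, 0.92)
  expect_lt(hits_e / n_ok, 0.98)
})

test_that("AIC selection prefers the generating family and breaks ties deterministically", {
  days <- c(1, 2, 4, 7, 10, 14)
  dat <- curve_data("LL3u100", c(b = 3, e = 8), days, n_rep = 5)
  single <- fit_model(dat, "LL3u100")
  expect_identical(select_best(list(single)), single)

  tie_a <- single; tie_a$aic <- 100; tie_a$k <- 3
  tie_b <- single; tie_b$aic <- 100; tie_b$k <- 4; tie_b$family <- "LL4"
  expect_equal(select_best(list(tie_b, tie_a))$k, 3)

  flat <- fit_model(data.frame(day = rep(days, 2), survival = 100),
                    "LL3u100")
  expect_error(select_best(list(flat)), "non-modellable")

  set.seed(202)
  wins <- 0
  n_sims <- 200
  for (i in seq_len(n_sims)) {
    dat <- curve_data("LL3u100", c(b = 3, e = 8), days, n_rep = 5, sd = 3)
    best <- select_best(fit_models(dat))
    d_hat <- if ("d" %in% names(best$params)) best$params[["d"]] else 100
    if (best$family == "LL3u100" ||
        (best$family == "LL3" && abs(d_hat - 100) < 5)) {
      wins <- wins + 1
    }
  }
  expect_gt(wins / n_sims, 0.5)
})

test_that("AIC depends on the fit only through rss, n and k", {
  days <- c(1, 2, 4, 7, 10, 14)
  set.seed(5)
  dat <- curve_data("LL3u100", c(b = 3, e = 8), days, n_rep = 5, sd = 4)
  fit <- fit_model(dat, "LL3u100")
  expect_equal(fit$aic,
               fit$n_obs * log(fit$rss / fit$n_obs) + 2 * (fit$k + 1))
})

test_that("lethal times invert the fitted curve (closed form vs bisection)", {
  days <- c(1, 2, 4, 7, 10, 14)
  dat <- curve_data("LL3u100", c(b = 3, e = 8), days, n_rep = 5)
  fit <- fit_model(dat, "LL3u100")
  lt50 <- estimate_lt(fit, 50)
  expect_equal(lt50$estimate, 8, tolerance = 1e-4)
  lt10 <- estimate_lt(fit, 10)
  expect_equal(lt10$estimate, 8 * (1 / 9)^(1 / 3), tolerance = 1e-4)
  expect_equal(lt10$estimate,
               lt_bisection_oracle("LL3u100", fit$params, 10),
               tolerance = 1e-8)
  expect_lt(lt10$estimate, lt50$estimate)

  set.seed(303)
  for (family in names(model_families)) {
    for (i in 1:40) {
      params <- random_params(family)
      p <- runif(1, 5, 95)
      closed <- toxmatrix:::lt_closed_form(family, params, p)
      oracle <- lt_bisection_oracle(family, params, p)
      expect_equal(closed, oracle, tolerance = 1e-8)
      expect_lt(toxmatrix:::lt_closed_form(family, params, 10),
                toxmatrix:::lt_closed_form(family, params, 50))
    }
  }
})

test_that("wrong-direction fits are flagged rather than inverted", {
  days <- c(1, 2, 4, 7, 10, 14)
  # survival increasing through time: slope comes out direction-reversed
  dat <- data.frame(day = rep(days, 3),
                    survival = rep(c(10, 20, 45, 70, 85, 95), 3))
  fit <- fit_model(dat, "LL3u100")
  expect_true(fit$converged)
  lt <- estimate_lt(fit, 50)
  expect_false(lt$available)
  expect_match(lt$reason, "non-toxic-direction")
})

test_that("refitting exact data regenerated from a fit reproduces it", {
  set.seed(11)
  days <- c(1, 2, 4, 7, 10, 14)
  dat <- curve_data("LL3u100", c(b = 3, e = 8), days, n_rep = 5, sd = 5)
  fit1 <- fit_model(dat, "LL3u100")
  regen <- curve_data("LL3u100", fit1$params, days, n_rep = 5)
  fit2 <- fit_model(regen, "LL3u100")
  expect_equal(unname(fit2$params), unname(fit1$params),
               tolerance = 1e-5)
})

test_that("delta-method limits can drop below zero for noisy fits", {
  set.seed(17)
  days <- c(4, 7, 10, 14, 21)
  found_negative <- FALSE
  for (i in 1:50) {
    dat <- curve_data("LL3u100", c(b = 0.8, e = 18), days, n_rep = 3,
                      sd = 18)
    fit <- tryCatch(fit_model(dat, "LL3u100"), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    lt <- estimate_lt(fit, 10)
    if (lt$available && lt$lower < 0) found_negative <- TRUE
  }
  expect_true(found_negative)
})
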