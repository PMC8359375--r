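#' Candidate time-response model families
#'
#' The families fitted to percent-survival-through-time data, in the
#' conventional dose-response parameterization with slope `b`, lower
#' asymptote `c` (%), upper asymptote `d` (%), inflection time `e`
#' (days) and asymmetry `f`:
#'
#' * `LL3u100` — log-logistic, `c = 0`, `d = 100` fixed (free: b, e)
#' * `LL3`     — log-logistic, `c = 0` fixed (free: b, d, e)
#' * `LL4`     — log-logistic (free: b, c, d, e)
#' * `LL5`     — asymmetric log-logistic (free: b, c, d, e, f)
#' * `W14`     — Weibull type 1 (free: b, c, d, e)
#' * `W24`     — Weibull type 2 (free: b, c, d, e)
#'
#' For survival declining through time the log-logistic and Weibull-1
#' curves decrease when `b > 0`; Weibull-2 decreases when `b < 0`.
#'
#' @format A list keyed by family name with elements `free` (names of
#'   free parameters), `fixed` (named fixed values), `k` (number of free
#'   parameters) and `order` (deterministic tie-break rank).
#' @export
model_families <- local({
  fam <- function(free, fixed, order) {
    list(free = free, fixed = fixed, k = length(free), order = order)
  }
  list(
    LL3u100 = fam(c("b", "e"), c(c = 0, d = 100), 1),
    LL3     = fam(c("b", "d", "e"), c(c = 0), 2),
    LL4     = fam(c("b", "c", "d", "e"), numeric(0), 3),
    W14     = fam(c("b", "c", "d", "e"), numeric(0), 4),
    W24     = fam(c("b", "c", "d", "e"), numeric(0), 5),
    LL5     = fam(c("b", "c", "d", "e", "f"), numeric(0), 6)
  )
})

family_info <- function(family) {
  info <- model_families[[family]]
  if (is.null(info)) {
    stop("unknown model family: ", family, call. = FALSE)
  }
  info
}

# merge free estimates with the family's fixed parameters
full_params <- function(family, params) {
  info <- family_info(family)
  full <- c(b = NA_real_, c = 0, d = 100, e = NA_real_, f = 1)
  full[names(info$fixed)] <- info$fixed
  full[names(params)] <- params
  full
}

#' Predicted percent survival from a time-response curve
#'
#' Evaluates the family's curve at exposure times `t` (days):
#' log-logistic `f(t) = c + (d-c) / (1 + exp(b (ln t - ln e)))^f`
#' (with `f = 1` unless the family is `LL5`), Weibull-1
#' `f(t) = c + (d-c) exp(-exp(b (ln t - ln e)))` and Weibull-2
#' `f(t) = c + (d-c) (1 - exp(-exp(b (ln t - ln e))))`.
#'
#' @param family Family name, one of `names(model_families)`.
#' @param params Named numeric vector with the family's free parameters
#'   (fixed parameters are filled in automatically).
#' @param t Positive exposure times (days).
#' @return Predicted percent survival at each `t`.
#' @examples
#' model_curve("LL3u100", c(b = 3, e = 8), 8) # 50 at the inflection
#' @export
model_curve <- function(family, params, t) {
  if (any(t <= 0)) stop("t must be positive", call. = FALSE)
  p <- full_params(family, params)
  z <- exp(p["b"] * (log(t) - log(p["e"])))
  span <- p["d"] - p["c"]
  val <- switch(family,
    LL3u100 = ,
    LL3 = ,
    LL4 = p["c"] + span / (1 + z),
    LL5 = p["c"] + span / (1 + z)^p["f"],
    W14 = p["c"] + span * exp(-z),
    W24 = p["c"] + span * (1 - exp(-z)),
    stop("unknown model family: ", family, call. = FALSE)
  )
  unname(val)
}

# slope sign for which the family's curve decreases through time
decreasing_sign <- function(family) if (family == "W24") -1 else 1

# central-difference step for parameter i; multiplicative for the
# positivity-constrained parameters so the step cannot cross zero
fd_step <- function(par, i) {
  up <- dn <- par
  if (names(par)[i] %in% c("e", "f")) {
    h <- 1e-6 * par[i]
    up[i] <- par[i] + h
    dn[i] <- par[i] - h
  } else {
    h <- max(1e-6, 1e-6 * abs(par[i]))
    up[i] <- par[i] + h
    dn[i] <- par[i] - h
  }
  list(up = up, dn = dn, span = up[i] - dn[i])
}

#' Fit a time-response model family by least squares
#'
#' Replicate-level percent survival at each observation day is treated
#' as independent Gaussian observations and the curve fitted by
#' Levenberg-Marquardt least squares. The parameter covariance is the
#' Gauss-Newton approximation `s2 (J'J)^-1` at the optimum with
#' `s2 = rss / (n - k)`; `AIC = n ln(rss/n) + 2 (k + 1)`, counting the
#' residual variance as an estimated parameter (only relative ordering
#' across families matters). Degenerate data (e.g. constant 100 percent
#' survival) or optimizer failure yield `converged = FALSE` rather than
#' an error.
#'
#' @param data Data frame with columns `day` and `survival` (percent),
#'   one row per replicate x day.
#' @param family Family name (see [model_families]).
#' @return A `model_fit`: list with `family`, `params` (free estimates),
#'   `fixed`, `cov`, `rss`, `n_obs`, `k`, `df`, `aic`, `converged`.
#' @export
fit_model <- function(data, family) {
  info <- family_info(family)
  day <- as.numeric(data$day)
  y <- as.numeric(data$survival)
  keep <- is.finite(day) & is.finite(y)
  day <- day[keep]; y <- y[keep]
  n <- length(y)
  k <- info$k
  if (length(unique(day)) < k) {
    stop("need at least ", k, " distinct observation days to fit ",
         family, call. = FALSE)
  }

  failed <- function() {
    structure(list(family = family, params = setNames(rep(NA_real_, k),
                                                      info$free),
                   fixed = info$fixed, cov = NULL, rss = NA_real_,
                   n_obs = n, k = k, df = n - k, aic = NA_real_,
                   converged = FALSE),
              class = "model_fit")
  }
  if (sd(y) < 1e-12) return(failed())  # flat response: slope unidentified

  sgn <- decreasing_sign(family)
  start_base <- c(b = sgn * 1, c = min(y), d = max(y),
                  e = median(day), f = 1)
  lower <- c(b = -Inf, c = -Inf, d = -Inf, e = 1e-8, f = 1e-8)

  best <- NULL
  for (b0 in sgn * c(1, 0.5, 5)) {
    start <- start_base
    start["b"] <- b0
    par0 <- as.list(start[info$free])
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = par0,
        lower = lower[info$free],
        fn = function(p) y - model_curve(family, unlist(p), day),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit) || !(fit$info %in% 1:4)) next
    est <- unlist(coef(fit))
    if (!all(is.finite(est))) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-10) {
      best <- list(est = est, rss = rss)
    }
  }
  if (is.null(best)) return(failed())

  est <- best$est
  rss <- best$rss
  # numeric Jacobian of predictions w.r.t. free parameters
  jac <- vapply(seq_along(est), function(i) {
    st <- fd_step(est, i)
    (model_curve(family, st$up, day) - model_curve(family, st$dn, day)) /
      st$span
  }, numeric(n))
  jtj <- crossprod(jac)
  cov <- tryCatch({
    s2 <- rss / (n - k)
    v <- s2 * solve(jtj)
    (v + t(v)) / 2
  }, error = function(e) NULL)
  if (is.null(cov) || !all(is.finite(cov))) return(failed())
  dimnames(cov) <- list(names(est), names(est))

  aic <- if (rss > 0) n * log(rss / n) + 2 * (k + 1) else -Inf
  structure(list(family = family, params = est, fixed = info$fixed,
                 cov = cov, rss = rss, n_obs = n, k = k, df = n - k,
                 aic = aic, converged = TRUE),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(x$family,
      if (x$converged) "fit" else "fit (NOT converged)", "\n")
  if (x$converged) {
    print(round(x$params, 4))
    cat("rss =", signif(x$rss, 5), " n =", x$n_obs,
        " AIC =", round(x$aic, 2), "\n")
  }
  invisible(x)
}

#' Fit all (or a subset of) candidate families to one group
#'
#' @param data As in [fit_model()].
#' @param families Character vector of family names to try.
#' @return Named list of `model_fit` objects; families whose fit errors
#'   out (insufficient distinct days) are dropped.
#' @export
fit_models <- function(data, families = names(model_families)) {
  data <- as.data.frame(data)
  fits <- lapply(families, function(f) {
    tryCatch(fit_model(data, f), error = function(e) NULL)
  })
  names(fits) <- families
  fits[!vapply(fits, is.null, logical(1))]
}

#' Select the best fit by AIC
#'
#' Lowest AIC among converged fits; ties broken by fewer free
#' parameters, then by the fixed family order
#' `LL3u100 < LL3 < LL4 < W14 < W24 < LL5`.
#'
#' @param fits List of `model_fit` objects.
#' @return The selected `model_fit`.
#' @export
select_best <- function(fits) {
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(conv)) {
    stop("no converged fit: group is non-modellable", call. = FALSE)
  }
  ord <- order(vapply(conv, function(f) f$aic, numeric(1)),
               vapply(conv, function(f) f$k, numeric(1)),
               vapply(conv, function(f) family_info(f$family)$order,
                      numeric(1)))
  conv[[ord[1]]]
}

# closed-form LT_p (decline relative to the fitted asymptote range)
lt_closed_form <- function(family, params, p) {
  q <- p / 100
  b <- params[["b"]]
  e <- params[["e"]]
  x <- switch(family,
    LL3u100 = ,
    LL3 = ,
    LL4 = (q / (1 - q))^(1 / b),
    LL5 = ((1 - q)^(-1 / params[["f"]]) - 1)^(1 / b),
    W14 = (-log(1 - q))^(1 / b),
    W24 = (-log(q))^(1 / b),
    stop("unknown model family: ", family, call. = FALSE)
  )
  e * x
}

# bisection-style inversion of model_curve for the absolute reference
lt_solve_absolute <- function(family, params, p) {
  target <- 100 - p
  g <- function(lt) model_curve(family, params, exp(lt)) - target
  lo <- log(1e-8); hi <- log(1e8)
  if (g(lo) * g(hi) > 0) return(NA_real_)
  exp(uniroot(g, c(lo, hi), tol = 1e-12)$root)
}

#' Lethal time with delta-method confidence limits
#'
#' Inverts a fitted time-response curve to the exposure duration at
#' which survival has declined by `p` percent. By default the decline is
#' interpreted relative to the fitted asymptote range (the curve drops
#' from `d` towards `c`; `LT_p` solves
#' `f(t) = d - (p/100)(d - c)`), which for the dominant `LL3u100` family
#' (`c = 0`, `d = 100`) coincides with the absolute reading
#' `f(t) = 100 - p` available via `reference = "absolute"`. The
#' confidence interval is the delta method on the natural scale: the
#' gradient of `LT_p` with respect to the free parameters, the
#' Gauss-Newton covariance, and a t quantile with `n_obs - k` degrees of
#' freedom. Lower limits may be negative and are reported as-is.
#'
#' @param fit A converged `model_fit`.
#' @param p Percent decline in survival (10 or 50 typically).
#' @param level Confidence level (default 0.95).
#' @param reference `"asymptote"` (default) or `"absolute"`.
#' @return An `lt_estimate`: list with `p`, `estimate`, `lower`,
#'   `upper`, `se`, `level`, `available`, `reason`.
#' @export
estimate_lt <- function(fit, p, level = 0.95, reference = "asymptote") {
  stopifnot(p > 0, p < 100)
  unavailable <- function(reason) {
    structure(list(p = p, estimate = NA_real_, lower = NA_real_,
                   upper = NA_real_, se = NA_real_, level = level,
                   available = FALSE, reason = reason),
              class = "lt_estimate")
  }
  if (!isTRUE(fit$converged)) return(unavailable("model did not converge"))
  b <- fit$params[["b"]]
  if (b * decreasing_sign(fit$family) <= 0) {
    return(unavailable("non-toxic-direction (survival not decreasing)"))
  }

  lt_of <- function(free) {
    params <- full_params(fit$family, free)
    if (reference == "absolute") {
      lt_solve_absolute(fit$family, params, p)
    } else {
      lt_closed_form(fit$family, params, p)
    }
  }
  est <- lt_of(fit$params)
  if (!is.finite(est) || est <= 0) {
    return(unavailable("lethal time not identifiable from fitted curve"))
  }
  grad <- vapply(seq_along(fit$params), function(i) {
    st <- fd_step(fit$params, i)
    (lt_of(st$up) - lt_of(st$dn)) / st$span
  }, numeric(1))
  se <- sqrt(max(0, drop(t(grad) %*% fit$cov %*% grad)))
  tq <- qt(1 - (1 - level) / 2, df = fit$df)
  structure(list(p = p, estimate = est, lower = est - tq * se,
                 upper = est + tq * se, se = se, level = level,
                 available = TRUE, reason = NA_character_),
            class = "lt_estimate")
}

#' @export
print.lt_estimate <- function(x, ...) {
  if (x$available) {
    cat(sprintf("LT%g = %.1f d (%.0f%% CI %.1f to %.1f)\n",
                x$p, x$estimate, 100 * x$level, x$lower, x$upper))
  } else {
    cat(sprintf("LT%g unavailable: %s\n", x$p, x$reason))
  }
  invisible(x)
}
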