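# Build a trial dataset from per-group matrices of counts alive
# (rows = replicates, cols = scheduled days).
trial_from_counts <- function(counts, days, species = "sp", round = 1,
                              n_initial = 10) {
  rows <- lapply(names(counts), function(g) {
    m <- counts[[g]]
    do.call(rbind, lapply(seq_len(nrow(m)), function(r) {
      data.frame(species = species, round = round, group = g,
                 replicate = r, day = days, n_alive = m[r, ],
                 n_initial = n_initial, stringsAsFactors = FALSE)
    }))
  })
  trial_dataset(do.call(rbind, rows),
                schedule = observation_schedule(days))
}

# constant-survival count matrix
const_counts <- function(n_alive, n_rep, n_day) {
  matrix(n_alive, nrow = n_rep, ncol = n_day)
}

# replicate-level percent survival generated from a curve plus iid noise
curve_data <- function(family, params, days, n_rep = 5, sd = 0) {
  truth <- model_curve(family, params, days)
  data.frame(day = rep(days, n_rep),
             survival = rep(truth, n_rep) +
               if (sd > 0) rnorm(length(days) * n_rep, 0, sd) else 0)
}

# independent inversion oracle: bisection on the model curve for the
# decline-relative-to-asymptote-range target
lt_bisection_oracle <- function(family, params, p) {
  full <- c(c = 0, d = 100, f = 1)
  full[names(params)] <- params
  target <- full[["d"]] - (p / 100) * (full[["d"]] - full[["c"]])
  g <- function(lt) model_curve(family, params, exp(lt)) - target
  exp(uniroot(g, c(log(1e-10), log(1e10)), tol = 1e-14)$root)
}

# random direction-correct parameter draw for a family
random_params <- function(family) {
  sgn <- if (family == "W24") -1 else 1
  p <- c(b = sgn * runif(1, 0.5, 5), e = runif(1, 1, 20))
  if (family %in% c("LL3", "LL4", "LL5", "W14", "W24")) {
    p["d"] <- runif(1, 70, 100)
  }
  if (family %in% c("LL4", "LL5", "W14", "W24")) {
    p["c"] <- runif(1, 0, 30)
  }
  if (family == "LL5") p["f"] <- runif(1, 0.3, 3)
  p[intersect(c("b", "c", "d", "e", "f"), names(p))]
}
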