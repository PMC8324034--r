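# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force grid search for the sigmoid least-squares optimum:
# coarse grid over (P50, S), then one local refinement around the best cell.
grid_fit_oracle <- function(P, y, p50_range = c(-6, -0.3), s_range = c(5, 300),
                            n_coarse = 61, n_fine = 41) {
  rss_at <- function(p50, s) {
    pred <- 100 / (1 + exp((s / 25) * (P - p50)))
    sum((y - pred)^2)
  }
  best <- c(NA, NA, Inf)
  p50s <- seq(p50_range[1], p50_range[2], length.out = n_coarse)
  ss <- seq(s_range[1], s_range[2], length.out = n_coarse)
  for (a in p50s) for (b in ss) {
    v <- rss_at(a, b)
    if (v < best[3]) best <- c(a, b, v)
  }
  dp <- diff(p50s[1:2]); ds <- diff(ss[1:2])
  for (lvl in 1:3) {  # successive local refinements
    p50s <- seq(best[1] - dp, best[1] + dp, length.out = n_fine)
    ss <- seq(max(1e-3, best[2] - ds), best[2] + ds, length.out = n_fine)
    for (a in p50s) for (b in ss) {
      v <- rss_at(a, b)
      if (v < best[3]) best <- c(a, b, v)
    }
    dp <- diff(p50s[1:2]); ds <- diff(ss[1:2])
  }
  list(P50 = best[1], S = best[2], rss = best[3],
       res_p50 = dp, res_s = ds)
}

# Root of the sigmoid at a given loss level by bisection (oracle for the
# closed-form inverse).
bisect_pressure_at_loss <- function(P50, S, x, lo = P50 - 20, hi = P50 + 20,
                                    tol = 1e-12) {
  f <- function(P) 100 / (1 + exp((S / 25) * (P - P50))) - x
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid  # f decreasing in P
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# LMG by explicit enumeration of all p! orderings of entry.
lmg_orderings_oracle <- function(data, response, predictors) {
  y <- data[[response]]
  r2 <- function(vars) {
    if (!length(vars)) return(0)
    summary(stats::lm(stats::reformulate(vars, response), data = data))$r.squared
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  shares <- stats::setNames(numeric(length(predictors)), predictors)
  all_perm <- perms(predictors)
  for (ord in all_perm) {
    prev <- character(0)
    for (v in ord) {
      shares[v] <- shares[v] + r2(c(prev, v)) - r2(prev)
      prev <- c(prev, v)
    }
  }
  shares / length(all_perm)
}

# a small noiseless series builder for fit tests
noiseless_series <- function(P50, S, pressures = seq(-0.5, P50 * 2, length.out = 12)) {
  data.frame(pressure_MPa = pressures,
             plc = 100 / (1 + exp((S / 25) * (pressures - P50))))
}

zero_variance_config <- function(seed = 1) {
  simulation_config(noise_sd = 0, seed = seed, measurement_cv = 0,
                    vessel_diam_cv = 0, fibre_area_cv = 0)
}

zero_variance_profile <- function(name = "acc") {
  accession_profile(name, -2.5, 50, P50_sd = 0,
                    trait_cvs = stats::setNames(
                      rep(0, length(xylemvc:::.default_trait_cvs)),
                      names(xylemvc:::.default_trait_cvs)))
}
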