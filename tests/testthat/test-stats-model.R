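test_that("backward AIC keeps overwhelming signal and drops pure noise", {
  set.seed(91)
  n <- 36
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n))
  d$y <- 5 * d$x1 + rnorm(n)  # effect 5 sd
  sel <- backward_aic(d, "y", c("x1", "x2", "x3", "x4"))
  expect_true("x1" %in% sel$final_terms)
  # the accepted trail is non-increasing in AIC
  expect_true(all(diff(sel$aic_trail$AIC) <= 1e-10))
  # agrees with the reference stepwise implementation
  ref <- step(lm(y ~ x1 + x2 + x3 + x4, data = d), direction = "backward",
              trace = 0)
  expect_setequal(sel$final_terms, attr(terms(ref), "term.labels"))
})

test_that("removing a null predictor decreases AIC at large n", {
  set.seed(92)
  n <- 500
  d <- data.frame(x1 = rnorm(n), x0 = rnorm(n))
  d$y <- 2 * d$x1 + rnorm(n)
  full <- lm(y ~ x1 + x0, data = d)
  reduced <- lm(y ~ x1, data = d)
  expect_lt(extractAIC(reduced)[2], extractAIC(full)[2])
  sel <- backward_aic(d, "y", c("x1", "x0"))
  expect_identical(sel$final_terms, "x1")
})

test_that("single strong predictor yields a one-model trail", {
  set.seed(93)
  d <- data.frame(x = rnorm(30))
  d$y <- 3 * d$x + rnorm(30, 0, 0.5)
  sel <- backward_aic(d, "y", "x")
  expect_identical(sel$final_terms, "x")
  expect_equal(nrow(sel$aic_trail), 1L)
  # empty candidate list: intercept-only
  sel0 <- backward_aic(d, "y", character(0))
  expect_length(sel0$final_terms, 0)
})

test_that("robust IRLS equals OLS on exact-fit data", {
  x <- seq(0, 5, length.out = 20)
  d <- data.frame(x = x, y = 1 + 2 * x)
  rb <- robust_irls(d, "y", "x")
  ols <- coef(lm(y ~ x, data = d))
  expect_true(rb$converged)
  expect_equal(rb$coefficients$estimate, unname(ols), tolerance = 1e-12)
  expect_equal(rb$weights, rep(1, 20))
})

test_that("robust IRLS resists a gross outlier and zero-weights it", {
  set.seed(94)
  x <- seq(0.2, 5, length.out = 20)
  y <- 2 * x + rnorm(20, 0, 0.1)
  y[7] <- y[7] + 50 * 0.1  # 50-sd outlier
  d <- data.frame(x = x, y = y)
  rb <- robust_irls(d, "y", "x")
  clean_ols <- coef(lm(y ~ x, data = d[-7, ]))
  expect_true(rb$converged)
  expect_equal(rb$coefficients$estimate[2], 2, tolerance = 0.02 / 2)
  expect_equal(rb$coefficients$estimate, unname(clean_ols), tolerance = 0.02)
  expect_identical(rb$weights[7], 0)
  # independent robust engine agrees on the slope
  mm <- MASS::rlm(y ~ x, data = d, psi = MASS::psi.bisquare, maxit = 100)
  expect_equal(rb$coefficients$estimate[2], unname(coef(mm)[2]), tolerance = 0.02)
})

test_that("LMG shares: orthogonal split, enumeration oracle, invariances", {
  # two exactly orthogonal predictors: shares equal the marginal R2s
  n <- 40
  x1 <- rep(c(-1, 1), each = n / 2)
  x2 <- rep(c(-1, 1), times = n / 2)
  set.seed(95)
  y <- sqrt(0.3) * x1 + sqrt(0.2) * x2 + rnorm(n, 0, sqrt(0.5))
  # orthogonality is exact by construction
  expect_equal(sum(x1 * x2), 0)
  d <- data.frame(y = y, x1 = x1, x2 = x2)
  sh <- lmg_importance(d, "y", c("x1", "x2"))
  r2_1 <- summary(lm(y ~ x1, data = d))$r.squared
  r2_2 <- summary(lm(y ~ x2, data = d))$r.squared
  expect_equal(unname(sh["x1"]), r2_1, tolerance = 1e-10)
  expect_equal(unname(sh["x2"]), r2_2, tolerance = 1e-10)

  # p = 3 random instance vs brute-force average over all 3! orderings
  set.seed(96)
  d3 <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  d3$b <- d3$b + 0.5 * d3$a
  d3$y <- d3$a + 0.5 * d3$b - 0.3 * d3$c + rnorm(30)
  sh3 <- lmg_importance(d3, "y", c("a", "b", "c"))
  oracle <- lmg_orderings_oracle(d3, "y", c("a", "b", "c"))
  expect_equal(sh3, oracle[names(sh3)], tolerance = 1e-12)

  # shares are non-negative, sum to the full-model R2, order-invariant
  expect_true(all(sh3 >= 0))
  r2_full <- summary(lm(y ~ a + b + c, data = d3))$r.squared
  expect_equal(sum(sh3), r2_full, tolerance = 1e-10)
  sh3b <- lmg_importance(d3, "y", c("c", "a", "b"))
  expect_equal(sh3[names(sh3b)], sh3b, tolerance = 1e-12)

  # single predictor: share is the simple-regression R2
  sh1 <- lmg_importance(d3, "y", "a")
  expect_equal(unname(sh1), summary(lm(y ~ a, data = d3))$r.squared,
               tolerance = 1e-12)
  expect_error(lmg_importance(d3, "y", rep(letters[1:3], 5)), "p > 12")
})

test_that("inference chain retains and ranks the dominant trait", {
  cfg <- simulation_config(seed = 424)
  tab <- simulate_trait_table(default_profiles(), cfg)
  rep <- run_inference_chain(tab, response = "P50")
  expect_true("T_PM" %in% rep$final_terms)
  expect_identical(names(sort(rep$lmg_shares, decreasing = TRUE))[1], "T_PM")
  expect_equal(sum(rep$lmg_shares), rep$r_squared, tolerance = 1e-10)
  expect_true(all(rep$lmg_shares >= 0))
  # Pearson table covers all candidates and the dominant link is strong
  expect_setequal(rep$pearson$trait, rep$candidates)
  expect_lt(rep$pearson$r[rep$pearson$trait == "T_PM"], -0.8)
})

test_that("permuted response leaves the correlation screen calibrated", {
  set.seed(553)
  tab <- xylemvc:::.sim_trait_table(default_profiles(), simulation_config())
  cand <- c("T_PM", "implosion", "T_V", "V_G", "P_LIG", "P_FW_F_A", "D_PC", "D_H")
  reps <- 200
  raw_rej <- numeric(reps)
  holm_any <- logical(reps)
  for (i in seq_len(reps)) {
    tab$Pperm <- sample(tab$P50)
    rep_i <- run_inference_chain(tab, response = "Pperm", candidates = cand,
                                 holm = TRUE)
    raw_rej[i] <- mean(rep_i$pearson$p < 0.05)
    holm_any[i] <- any(rep_i$pearson$p_holm < 0.05)
  }
  # per-trait raw type-I rate near nominal 5 %
  expect_gt(mean(raw_rej), 0.02)
  expect_lt(mean(raw_rej), 0.09)
  # Holm across the 8 candidates controls the familywise rate
  expect_gte(mean(!holm_any), 0.90)
})

test_that("chain handles edge inputs", {
  tab <- simulate_trait_table(default_profiles(), simulation_config(seed = 8))
  rep0 <- run_inference_chain(tab, response = "P50", candidates = character(0))
  expect_length(rep0$final_terms, 0)
  expect_equal(rep0$r_squared, 0)
  expect_error(run_inference_chain(tab, response = "nope"), "not found")
  # standardized mode keeps the selected terms meaningful
  repz <- run_inference_chain(tab, response = "P50", standardize = TRUE)
  expect_true(length(repz$final_terms) >= 1)
})
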