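test_that("identical seeds give identical output", {
  prof <- default_profiles()$`Col-0`
  cfg <- simulation_config(seed = 99)
  s1 <- simulate_spin_experiment(prof, cfg)
  s2 <- simulate_spin_experiment(prof, cfg)
  expect_identical(s1, s2)

  b1 <- simulate_study(default_profiles(), cfg)
  b2 <- simulate_study(default_profiles(), cfg)
  expect_identical(b1$traits, b2$traits)
  expect_identical(b1$series, b2$series)
})

test_that("noiseless series lie exactly on the generating sigmoid", {
  prof <- accession_profile("X", -2.14, 38, P50_sd = 0)
  s <- simulate_spin_experiment(prof, simulation_config(noise_sd = 0, seed = 5))
  plc_pts <- plc(s$points$K, s$K_max)
  expect_equal(plc_pts, sigmoid_plc(s$points$pressure_MPa, -2.14, 38),
               tolerance = 1e-12)
  expect_true(all(diff(s$points$pressure_MPa) < 0))
  # closure: refit recovers the generating parameters
  f <- fit_curve(s)
  expect_equal(f$P50_hat, -2.14, tolerance = 1e-6)
  expect_equal(f$S_hat, 38, tolerance = 1e-6)
})

test_that("spin schedule respects the configured step range and stop rule", {
  prof <- default_profiles()$soc1_ful
  s <- simulate_spin_experiment(prof, simulation_config(noise_sd = 0, seed = 2))
  steps <- -diff(s$points$pressure_MPa)
  expect_true(all(steps >= 0.2 - 1e-12 & steps <= 0.4 + 1e-12))
  true_plc <- sigmoid_plc(s$points$pressure_MPa, prof$true_P50, prof$true_S)
  expect_gte(max(true_plc), 95)
  expect_true(all(true_plc[-length(true_plc)] < 95))
})

test_that("mean refitted P50 over replicate noisy experiments is unbiased", {
  set.seed(880)
  prof <- accession_profile("Col-0", -2.14, 38, P50_sd = 0)
  cfg <- simulation_config(noise_sd = 0.05)
  hats <- replicate(200, fit_curve(xylemvc:::.sim_spin(prof, cfg))$P50_hat)
  expect_equal(mean(hats), -2.14, tolerance = 0.05 / 2.14)
})

test_that("unlinked traits are empirically uncorrelated with P50", {
  profs <- default_profiles()
  r0 <- xylemvc:::.default_trait_link_r * 0
  set.seed(31)
  cfg <- simulation_config(trait_link_r = r0)
  # pool several tables so |r| < 0.1 is a sharp check
  rs <- replicate(25, {
    tab <- xylemvc:::.sim_trait_table(profs, cfg)
    cor(tab$T_PM, tab$P50)
  })
  expect_lt(abs(mean(rs)), 0.1)
  tab <- xylemvc:::.sim_trait_table(profs, cfg)
  for (tr in c("T_PM", "implosion", "P_LIG")) {
    expect_lt(abs(cor(tab[[tr]], tab$P50)), 0.45)  # single-table noise bound
  }
})

test_that("copula calibration: mean empirical trait-P50 correlation hits the target", {
  profs <- default_profiles()
  cfg <- simulation_config()
  set.seed(7010)
  rs <- replicate(500, {
    tab <- xylemvc:::.sim_trait_table(profs, cfg)
    cor(tab$T_PM, tab$P50)
  })
  expect_equal(mean(rs), -0.93, tolerance = 0.05 / 0.93)
})

test_that("zero-variance config yields identical trait rows", {
  tab <- simulate_trait_table(zero_variance_profile(), zero_variance_config())
  expect_equal(nrow(tab), 9)
  num <- tab[vapply(tab, is.numeric, logical(1))]
  expect_true(all(vapply(num, function(x) diff(range(x)) == 0, logical(1))))
})

test_that("trait table is internally consistent with its raw measurements", {
  tab <- simulate_trait_table(default_profiles(),
                              simulation_config(seed = 17))
  raw <- attr(tab, "raw")
  i <- 13
  rederived <- derive_traits(raw[[i]])
  for (tr in names(rederived)[-(1:2)]) {
    expect_equal(tab[[tr]][i], rederived[[tr]], tolerance = 1e-12)
  }
  # copula targets reproduced exactly for the mean-type traits
  targets <- attr(tab, "targets")
  for (tr in c("T_PM", "D_PC", "T_V", "D_H", "implosion", "P_FW_F_A", "P_LIG")) {
    expect_equal(tab[[tr]], targets[[tr]], tolerance = 1e-9)
  }
})

test_that("infeasible trait correlation matrices are rejected by pair", {
  traits <- c("T_PM", "implosion")
  R <- matrix(c(1, -0.9, -0.9, 1), 2, dimnames = list(traits, traits))
  cfg <- simulation_config(
    trait_link_r = c(T_PM = -0.93, implosion = -0.88),
    trait_cor = R, seed = 1)
  # both strongly linked to P50 implies they must be strongly positively
  # correlated with each other; r = -0.9 is infeasible
  expect_error(simulate_trait_table(default_profiles(), cfg),
               "T_PM.*implosion|implosion.*T_PM")
})

test_that("study bundle counts and recorded truth", {
  profs <- default_profiles()
  cfg <- simulation_config(seed = 3)
  b <- simulate_study(profs, cfg)
  expect_length(b$series, 40)
  expect_equal(nrow(b$traits), 36)
  expect_identical(b$truth$profiles, profs)
  expect_identical(b$truth$config, cfg)
  expect_error(simulate_study(profs[1], cfg), "at least 2")
  # invalid profile parameters are rejected up front
  expect_error(accession_profile("bad", 1.5, 60), "negative")
  expect_error(accession_profile("bad", -1.5, 60, K_max_mean = 0), "positive")
})
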