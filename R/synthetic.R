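# Default marginal scales for the simulated trait set. Means and CVs are
# shared across accessions: accession-level trait differences emerge through
# the copula link between each trait and stem P50, which is the structure a
# pooled across-stem correlation analysis assumes.
.default_trait_means <- c(
  T_PM = 0.25,    # um, intervessel pit membrane thickness
  implosion = 0.02, # (T_VW / D_MAX)^2
  T_V = 1.5,      # um, vessel wall thickness
  V_G = 1.6,      # vessel grouping index
  P_LIG = 0.35,   # lignified area fraction
  P_FW_F_A = 0.60, # fibre wall fraction
  D_PC = 0.50,    # um, pit chamber depth
  D_H = 18,       # um, hydraulically weighted diameter
  V_D = 250,      # vessels mm^-2
  A_S = 2.5,      # mm^2, stem cross-section
  A_PITH = 0.8    # mm^2
)

.default_trait_cvs <- c(
  T_PM = 0.12, implosion = 0.25, T_V = 0.15, V_G = 0.12,
  P_LIG = 0.18, P_FW_F_A = 0.08, D_PC = 0.15, D_H = 0.10,
  V_D = 0.20, A_S = 0.15, A_PITH = 0.20
)

# Default across-stem target correlations between each trait and stem P50
# (negative: trait increases with embolism resistance).
.default_trait_link_r <- c(
  T_PM = -0.93, implosion = -0.88, T_V = -0.86, V_G = -0.77,
  P_LIG = -0.67, P_FW_F_A = -0.73, D_PC = -0.60, D_H = 0.30,
  V_D = 0.25, A_S = -0.30, A_PITH = -0.20
)

#' Generating truth for one accession
#'
#' @param name accession label.
#' @param true_P50 generating P50, MPa, strictly negative.
#' @param true_S generating sigmoid slope, % MPa^-1, strictly positive.
#' @param P50_sd between-stem standard deviation of P50, MPa (>= 0).
#' @param K_max_mean mean maximum conductivity, m^2 MPa^-1 s^-1, positive.
#' @param trait_means,trait_cvs named vectors of marginal trait means
#'   and coefficients of variation (defaults shared across accessions).
#' @param n_curves number of vulnerability curves to simulate.
#' @param n_stems_anatomy number of stems in the anatomical trait table.
#' @return object of class `accession_profile`.
#' @export
accession_profile <- function(name, true_P50, true_S, P50_sd = 0.15,
                              K_max_mean = 5e-4,
                              trait_means = .default_trait_means,
                              trait_cvs = .default_trait_cvs,
                              n_curves = 10L, n_stems_anatomy = 9L) {
  if (!is.finite(true_P50) || true_P50 >= 0) {
    stop("`true_P50` must be negative (MPa under tension)", call. = FALSE)
  }
  if (!is.finite(true_S) || true_S <= 0) {
    stop("`true_S` must be positive", call. = FALSE)
  }
  if (!is.finite(K_max_mean) || K_max_mean <= 0) {
    stop("`K_max_mean` must be positive", call. = FALSE)
  }
  if (P50_sd < 0) stop("`P50_sd` must be >= 0", call. = FALSE)
  if (any(trait_means <= 0)) stop("all `trait_means` must be > 0", call. = FALSE)
  if (any(trait_cvs < 0)) stop("all `trait_cvs` must be >= 0", call. = FALSE)
  if (n_curves < 1L) stop("`n_curves` must be >= 1", call. = FALSE)
  structure(
    list(name = as.character(name), true_P50 = true_P50, true_S = true_S,
         P50_sd = P50_sd, K_max_mean = K_max_mean,
         trait_means = trait_means, trait_cvs = trait_cvs,
         n_curves = as.integer(n_curves),
         n_stems_anatomy = as.integer(n_stems_anatomy)),
    class = "accession_profile"
  )
}

#' Default four-accession study profiles
#'
#' Profiles for Col-0, Cvi, Sha and the woody soc1 ful double mutant,
#' with generating (P50, S) pairs and between-stem P50 spreads at the
#' values reported for these accessions (P50 of -2.14, -1.58, -2.49 and
#' -3.07 MPa; slopes of 38, 142, 59 and 62 % MPa^-1).
#'
#' @return named list of [accession_profile()] objects.
#' @export
default_profiles <- function() {
  list(
    `Col-0` = accession_profile("Col-0", -2.14, 38, P50_sd = 0.18),
    Cvi = accession_profile("Cvi", -1.58, 142, P50_sd = 0.05),
    Sha = accession_profile("Sha", -2.49, 59, P50_sd = 0.11),
    soc1_ful = accession_profile("soc1_ful", -3.07, 62, P50_sd = 0.30)
  )
}

#' Simulation settings
#'
#' @param pressure_start first spin pressure after the reference
#'   measurement, MPa (negative).
#' @param pressure_step_range magnitudes (MPa) between which each spin
#'   step is drawn uniformly; both within `[0.05, 1]`.
#' @param plc_stop spinning stops once true PLC reaches this percent.
#' @param noise_sd standard deviation of the multiplicative lognormal
#'   noise on measured conductivities (0 = noiseless).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param trait_link_r named vector of target across-stem Pearson
#'   correlations between traits and stem P50, each in `[-1, 1]`.
#' @param trait_cor optional latent trait-trait correlation matrix
#'   (named, traits x traits). Default: correlations implied by the
#'   single-factor link, `r_i * r_j`.
#' @param measurement_cv within-stem coefficient of variation of
#'   repeated microscopy measurements around the stem's trait value.
#' @param vessel_diam_cv within-stem spread (lognormal sdlog) of vessel
#'   diameters.
#' @param fibre_area_cv within-stem spread (lognormal sdlog) of fibre
#'   cell areas.
#' @param reference_pressure near-zero pressure at which the `K_max`
#'   reference is recorded, MPa.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(pressure_start = -0.5,
                              pressure_step_range = c(0.2, 0.4),
                              plc_stop = 95,
                              noise_sd = 0.05,
                              seed = NULL,
                              trait_link_r = .default_trait_link_r,
                              trait_cor = NULL,
                              measurement_cv = 0.1,
                              vessel_diam_cv = 0.25,
                              fibre_area_cv = 0.3,
                              reference_pressure = -0.01) {
  rng <- sort(abs(pressure_step_range))
  if (length(rng) != 2L || any(rng < 0.05) || any(rng > 1)) {
    stop("`pressure_step_range` magnitudes must lie in [0.05, 1] MPa", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (any(abs(trait_link_r) > 1)) {
    stop("`trait_link_r` values must lie in [-1, 1]", call. = FALSE)
  }
  if (pressure_start >= 0) stop("`pressure_start` must be negative", call. = FALSE)
  structure(
    list(pressure_start = pressure_start, pressure_step_range = rng,
         plc_stop = plc_stop, noise_sd = noise_sd, seed = seed,
         trait_link_r = trait_link_r, trait_cor = trait_cor,
         measurement_cv = measurement_cv, vessel_diam_cv = vessel_diam_cv,
         fibre_area_cv = fibre_area_cv,
         reference_pressure = reference_pressure),
    class = "simulation_config"
  )
}

.maybe_seed <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
}

# spin schedule + conductivities without touching the seed
.sim_spin <- function(profile, config, curve_id = "curve1") {
  start <- config$pressure_start
  rng <- config$pressure_step_range
  ps <- numeric(0)
  p <- start
  repeat {
    ps <- c(ps, p)
    if (sigmoid_plc(p, profile$true_P50, profile$true_S) >= config$plc_stop) break
    if (length(ps) > 200L) break  # safety against absurd configurations
    p <- p - stats::runif(1, rng[1], rng[2])
  }
  lognoise <- function(n) {
    if (config$noise_sd == 0) rep(1, n) else exp(stats::rnorm(n, 0, config$noise_sd))
  }
  K_max <- profile$K_max_mean * lognoise(1)
  K <- K_max * (1 - sigmoid_plc(ps, profile$true_P50, profile$true_S) / 100) *
    lognoise(length(ps))
  conductance_series(curve_id, profile$name, ps, K, K_max)
}

#' Simulate one Cavitron spin experiment
#'
#' Generates a conductance series for one pooled stem batch: a noisy
#' `K_max` reference at near-zero pressure, then conductivities along a
#' spin schedule that starts at `pressure_start` and decreases by a
#' step drawn uniformly from `pressure_step_range` until the true PLC
#' reaches `plc_stop`. Conductivities are
#' `K = K_max * (1 - PLC_true(P)/100) * noise` with multiplicative
#' lognormal noise.
#'
#' @param profile an [accession_profile()].
#' @param config a [simulation_config()]; its `seed` (if non-NULL) is
#'   set on entry, so equal inputs give identical output.
#' @param curve_id label for the series.
#' @return a [conductance_series()].
#' @export
simulate_spin_experiment <- function(profile, config = simulation_config(),
                                     curve_id = "curve1") {
  stopifnot(inherits(profile, "accession_profile"),
            inherits(config, "simulation_config"))
  .maybe_seed(config)
  .sim_spin(profile, config, curve_id)
}

# Latent-correlation inflation so the post-lognormal Pearson correlation
# matches the target: corr(Z, exp(sdlog * Z')) = r * sdlog / sqrt(e^sdlog^2 - 1).
.inflate_link <- function(r, sdlog) {
  if (sdlog == 0) return(0)
  out <- r * sqrt(exp(sdlog^2) - 1) / sdlog
  max(-1, min(1, out))
}

# Feasibility check + eigen-clip repair of the latent trait correlation block.
.check_trait_cor <- function(R, r_link) {
  traits <- names(r_link)
  for (i in seq_along(traits)) {
    for (j in seq_len(i - 1L)) {
      bound <- sqrt((1 - r_link[i]^2) * (1 - r_link[j]^2))
      if (abs(R[traits[i], traits[j]] - r_link[i] * r_link[j]) > bound + 1e-8) {
        stop(sprintf(
          "infeasible correlation matrix: pair (%s, %s) with correlation %.3f is incompatible with their P50 links (%.2f, %.2f)",
          traits[i], traits[j], R[traits[i], traits[j]],
          r_link[i], r_link[j]), call. = FALSE)
      }
    }
  }
  C <- R[traits, traits, drop = FALSE] - tcrossprod(r_link)  # Schur complement
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    warning("trait correlation matrix slightly infeasible; nearest-PSD repair applied",
            call. = FALSE)
  }
  vals <- pmax(e$values, 1e-10)
  e$vectors %*% diag(sqrt(vals), length(vals))  # L with C ~ L L'
}

# Raw microscopy lists for one stem, constructed so that derive_traits()
# reproduces the target trait values (exactly for mean-type traits, to
# integer resolution for count-based ones).
.build_raw <- function(stem_id, accession, tg, config) {
  mcv <- config$measurement_cv
  jitter <- function(n, cv) if (cv == 0) rep(1, n) else exp(stats::rnorm(n, 0, cv))

  d <- tg[["D_H"]] * jitter(50, config$vessel_diam_cv)
  d <- d * tg[["D_H"]] / hydraulic_diameter(d)   # exact D_H
  areas <- pi * d^2 / 4
  D_MAX <- max(d)

  scale_to_mean <- function(n, target) {
    x <- jitter(n, mcv)
    x * target / mean(x)
  }
  tvw <- scale_to_mean(30, sqrt(tg[["implosion"]]) * D_MAX)  # exact implosion
  tv <- scale_to_mean(30, tg[["T_V"]])
  tpm <- scale_to_mean(25, tg[["T_PM"]])
  dpc <- scale_to_mean(25, tg[["D_PC"]])

  A_F <- 120 * jitter(30, config$fibre_area_cv)
  p_fw <- pmin(tg[["P_FW_F_A"]] * jitter(30, mcv), 0.97)
  p_fw <- pmin(p_fw * tg[["P_FW_F_A"]] / mean(p_fw), 0.97)
  fibres <- data.frame(A_F = A_F, A_FL = A_F * (1 - p_fw))

  # vessel groupings: 50 groups whose mean size is the V_G target
  n_groups <- 50L
  if (mcv == 0) {
    total <- max(n_groups, round(n_groups * tg[["V_G"]]))
    base <- total %/% n_groups
    sizes <- rep(base, n_groups)
    extra <- total - base * n_groups
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  } else {
    sizes <- 1L + stats::rpois(n_groups, max(tg[["V_G"]] - 1, 0))
  }

  frame_area <- 0.15 * jitter(5, mcv)
  n_vessels <- if (mcv == 0) {
    round(tg[["V_D"]] * frame_area)
  } else {
    stats::rpois(5, tg[["V_D"]] * frame_area)
  }
  n_vessels <- pmax(n_vessels, 1L)

  A_S <- tg[["A_S"]]
  A_LIG <- min(tg[["P_LIG"]], 0.97) * A_S
  A_PITH <- min(tg[["A_PITH"]], 0.9 * (A_S - A_LIG))

  suppressWarnings(anatomy_raw(
    stem_id = stem_id, accession = accession,
    vessel_lumen_areas = areas,
    vessel_wall_thicknesses = tv,
    double_intervessel_wall_thicknesses = tvw,
    fibre_areas = fibres,
    pit_membrane_thicknesses = tpm,
    pit_chamber_depths = dpc,
    vessel_group_sizes = sizes,
    xylem_count_areas = data.frame(n_vessels = n_vessels, area_mm2 = frame_area),
    A_S = A_S, A_LIG = A_LIG, A_PITH = A_PITH
  ))
}

.sim_trait_table <- function(profiles, config) {
  if (!is.list(profiles) || inherits(profiles, "accession_profile")) {
    profiles <- list(profiles)
  }
  traits <- names(config$trait_link_r)
  r_link <- config$trait_link_r

  acc <- unlist(lapply(profiles, function(p) rep(p$name, p$n_stems_anatomy)))
  n <- length(acc)
  P50_stem <- unlist(lapply(profiles, function(p) {
    stats::rnorm(p$n_stems_anatomy, p$true_P50, p$P50_sd)
  }))
  S_stem <- unlist(lapply(profiles, function(p) rep(p$true_S, p$n_stems_anatomy)))

  sdev <- stats::sd(P50_stem)
  z0 <- if (is.na(sdev) || sdev == 0) rep(0, n) else (P50_stem - mean(P50_stem)) / sdev

  # per-accession marginal parameters
  meanlog <- sdlog <- matrix(NA_real_, n, length(traits),
                             dimnames = list(NULL, traits))
  for (p in profiles) {
    idx <- acc == p$name
    for (tr in traits) {
      mu <- p$trait_means[[tr]]
      cv <- p$trait_cvs[[tr]]
      if (is.null(mu) || is.null(cv)) {
        stop("profile '", p$name, "' has no trait mean/cv for '", tr, "'",
             call. = FALSE)
      }
      sl <- sqrt(log(1 + cv^2))
      sdlog[idx, tr] <- sl
      meanlog[idx, tr] <- log(mu) - sl^2 / 2
    }
  }

  r_lat <- vapply(traits, function(tr) .inflate_link(r_link[[tr]], sdlog[1, tr]),
                  numeric(1))

  if (is.null(config$trait_cor)) {
    eps <- matrix(stats::rnorm(n * length(traits)), n)
    zt <- outer(z0, r_lat) + sweep(eps, 2, sqrt(1 - r_lat^2), `*`)
  } else {
    R <- config$trait_cor[traits, traits]
    L <- .check_trait_cor(R, r_lat)
    eps <- matrix(stats::rnorm(n * length(traits)), n) %*% t(L)
    zt <- outer(z0, r_lat) + eps
  }
  colnames(zt) <- traits

  targets <- matrix(NA_real_, n, length(traits), dimnames = list(NULL, traits))
  for (tr in traits) {
    targets[, tr] <- stats::qlnorm(stats::pnorm(zt[, tr]),
                                   meanlog[, tr], sdlog[, tr])
  }
  if (any(targets <= 0)) {
    stop("non-positive trait draw; check trait means and CVs", call. = FALSE)
  }

  stem_ids <- paste0(acc, "_s", stats::ave(seq_len(n), acc, FUN = seq_along))
  raw <- vector("list", n)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    raw[[i]] <- .build_raw(stem_ids[i], acc[i], targets[i, ], config)
    recs[[i]] <- derive_traits(raw[[i]])
  }
  tab <- do.call(rbind, recs)
  tab$P50 <- P50_stem
  tab$P12 <- pressure_at_loss(P50_stem, S_stem, 12)
  tab$P88 <- pressure_at_loss(P50_stem, S_stem, 88)
  attr(tab, "raw") <- raw
  attr(tab, "targets") <- as.data.frame(targets)
  tab
}

#' Simulate a per-stem anatomical trait table
#'
#' Draws stem-level P50 values around each accession's generating P50,
#' then generates trait values through a Gaussian copula whose latent
#' correlations are calibrated so the across-stem Pearson correlation
#' of each trait with stem P50 matches `config$trait_link_r`. Marginals
#' are lognormal (so all traits are positive by construction) with the
#' profile's trait means and CVs. For each stem, raw microscopy lists
#' are constructed to be consistent with the stem's trait values, and
#' the returned table is computed from them by [derive_traits()].
#'
#' @param profiles one or a list of [accession_profile()].
#' @param config a [simulation_config()].
#' @return data.frame of per-stem trait records with response columns
#'   `P50`, `P12`, `P88`; attribute `"raw"` holds the list of
#'   [anatomy_raw()] objects, attribute `"targets"` the copula draws.
#' @export
simulate_trait_table <- function(profiles, config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  .maybe_seed(config)
  .sim_trait_table(profiles, config)
}

#' Simulate a complete study
#'
#' Generates, for each accession, `n_curves` Cavitron experiments
#' (each a separate pooled stem batch whose generating P50 is drawn
#' with the accession's between-batch spread `P50_sd`) and the
#' anatomical trait table, and records the generating truth so
#' recovery can be tested downstream.
#'
#' @param profiles list of at least two [accession_profile()] objects.
#' @param config a [simulation_config()].
#' @return object of class `study_bundle`: list with `series` (list of
#'   [conductance_series()]), `traits` (trait table), and `truth`
#'   (the profiles and config as passed in).
#' @export
simulate_study <- function(profiles = default_profiles(),
                           config = simulation_config()) {
  if (inherits(profiles, "accession_profile")) profiles <- list(profiles)
  stopifnot(inherits(config, "simulation_config"))
  if (length(profiles) < 2L) {
    stop("need at least 2 accessions for between-accession analysis", call. = FALSE)
  }
  .maybe_seed(config)
  series <- list()
  for (p in profiles) {
    for (i in seq_len(p$n_curves)) {
      id <- sprintf("%s_c%02d", p$name, i)
      # each curve is a different pooled stem batch: its generating P50 is
      # drawn around the accession mean with the between-batch spread
      batch <- p
      if (p$P50_sd > 0) {
        batch$true_P50 <- min(stats::rnorm(1, p$true_P50, p$P50_sd), -1e-3)
      }
      series[[id]] <- .sim_spin(batch, config, curve_id = id)
    }
  }
  traits <- .sim_trait_table(profiles, config)
  structure(
    list(series = series, traits = traits,
         truth = list(profiles = profiles, config = config)),
    class = "study_bundle"
  )
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle> %d accessions, %d curves, %d stems with traits\n",
              length(x$truth$profiles), length(x$series), nrow(x$traits)))
  invisible(x)
}
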