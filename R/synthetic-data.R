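#' Define the true kinetics of a synthetic strain
#'
#' A `strain_spec` carries the ground-truth Monod kinetics of one strain for
#' each resource (light, N, P), together with the trajectory shape parameters
#' used when fluorescence growth series are generated from it: an optional lag
#' phase and an optional saturation ceiling in ln(RFU) space.
#'
#' @param strain_id,species_id character identifiers.
#' @param mu_max named numeric vector of maximum per-capita growth rates
#'   (day^-1) for resources `"light"`, `"N"`, `"P"`; all > 0.
#' @param Ks named numeric vector of half-saturation constants (same names;
#'   light in umol photons m^-2 s^-1, N and P in umol/L); all > 0.
#' @param lag_days lag phase before exponential growth, days >= 0.
#' @param sat_log_ceiling optional saturation ceiling in ln(RFU); `NULL` for
#'   unbounded exponential growth within the assay window.
#' @param ln_b0 initial ln(RFU) of the inoculum.
#' @param cell_size cell diameter (um), carried into trait tables.
#' @param cn_ratio,cp_ratio molar biomass stoichiometry, carried through.
#' @return an object of class `"strain_spec"`.
#' @export
strain_spec <- function(strain_id, species_id = strain_id,
                        mu_max, Ks, lag_days = 0, sat_log_ceiling = NULL,
                        ln_b0 = log(50), cell_size = 10,
                        cn_ratio = 6.6, cp_ratio = 106) {
  mu_max <- unlist(mu_max); Ks <- unlist(Ks)
  assert_that(all(RESOURCES %in% names(mu_max)) &&
              all(RESOURCES %in% names(Ks)),
              "strain_spec: mu_max and Ks must be named for %s",
              paste(RESOURCES, collapse = ", "))
  assert_that(all(mu_max > 0) && all(Ks > 0),
              "strain_spec '%s': mu_max and Ks must be > 0", strain_id)
  assert_that(lag_days >= 0, "strain_spec '%s': lag_days must be >= 0",
              strain_id)
  structure(list(strain_id = as.character(strain_id),
                 species_id = as.character(species_id),
                 mu_max = mu_max[RESOURCES], Ks = Ks[RESOURCES],
                 lag_days = lag_days, sat_log_ceiling = sat_log_ceiling,
                 ln_b0 = ln_b0, cell_size = cell_size,
                 cn_ratio = cn_ratio, cp_ratio = cp_ratio),
            class = "strain_spec")
}

#' Noise model for synthetic data generation
#'
#' @param sigma_log_rfu sd of additive Gaussian noise on ln(RFU), >= 0.
#'   Default 0.05 is a fixture choice, not an empirical claim.
#' @param count_sampling multinomial sample size for community counts, >= 1.
#' @param seed integer master seed; fans out to substreams per series.
#' @return an object of class `"noise_model"`.
#' @export
noise_model <- function(sigma_log_rfu = 0.05, count_sampling = 1000L,
                        seed = 1L) {
  assert_that(sigma_log_rfu >= 0, "noise_model: sigma_log_rfu must be >= 0")
  assert_that(count_sampling >= 1, "noise_model: count_sampling must be >= 1")
  structure(list(sigma_log_rfu = sigma_log_rfu,
                 count_sampling = as.integer(count_sampling),
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Monod growth response
#'
#' \eqn{\mu(R) = \mu_{max} R / (K_s + R)}.
#'
#' @param R resource concentration(s), >= 0.
#' @param mu_max maximum per-capita growth rate (day^-1).
#' @param Ks half-saturation constant (resource units).
#' @return growth rate(s), day^-1.
#' @export
monod_mu <- function(R, mu_max, Ks) mu_max * R / (Ks + R)

# Deterministic ln(RFU) trajectory: lag plateau -> exponential -> ceiling.
ln_trajectory <- function(times, ln_b0, mu, lag_days, sat_log_ceiling) {
  ln_b <- ln_b0 + mu * pmax(0, times - lag_days)
  if (!is.null(sat_log_ceiling) && mu > 0)
    ln_b <- pmin(ln_b, sat_log_ceiling)
  ln_b
}

#' Generate synthetic fluorescence growth series
#'
#' Emulates a common-garden growth assay: each strain grown at several levels
#' of one resource, its biomass tracked as relative fluorescence units (RFU).
#' The ln(RFU) trajectory is piecewise linear (lag plateau, exponential phase
#' with the Monod slope \eqn{\mu(R)}, optional ceiling) and observations get
#' multiplicative log-normal noise. Substream seeding makes every series
#' reproducible independently of generation order.
#'
#' @param spec a [strain_spec()].
#' @param resource one of `"light"`, `"N"`, `"P"`.
#' @param levels strictly positive resource concentrations (use a value much
#'   larger than `Ks` as a saturating-level proxy; a level of exactly 0 is
#'   permitted for nutrients and yields zero growth).
#' @param times observation days, increasing from 0.
#' @param n_rep replicates per level (default 3, a fixture choice).
#' @param noise a [noise_model()].
#' @return a data.frame with columns `strain`, `species`, `resource`, `level`,
#'   `replicate`, `day`, `rfu`.
#' @export
gen_growth_series <- function(spec, resource, levels, times, n_rep = 3L,
                              noise = noise_model()) {
  stopifnot(inherits(spec, "strain_spec"), inherits(noise, "noise_model"))
  resource <- match_resource(resource)
  assert_that(length(levels) > 0, "gen_growth_series: empty levels")
  assert_that(length(times) > 0, "gen_growth_series: empty times")
  assert_that(all(levels >= 0), "gen_growth_series: negative resource level")
  assert_that(!is.unsorted(times, strictly = TRUE) && times[1] >= 0,
              "gen_growth_series: times must be increasing from 0")
  mu_max <- spec$mu_max[[resource]]; Ks <- spec$Ks[[resource]]
  out <- vector("list", length(levels) * n_rep)
  k <- 0L
  for (lev in levels) {
    mu <- monod_mu(lev, mu_max, Ks)
    for (rep_i in seq_len(n_rep)) {
      ln_b <- ln_trajectory(times, spec$ln_b0, mu, spec$lag_days,
                            spec$sat_log_ceiling)
      if (noise$sigma_log_rfu > 0) {
        ss <- substream_seed(noise$seed, spec$strain_id, resource, lev, rep_i)
        eps <- with_seed(ss, stats::rnorm(length(times), 0,
                                          noise$sigma_log_rfu))
        ln_b <- ln_b + eps
      }
      k <- k + 1L
      out[[k]] <- data.frame(strain = spec$strain_id,
                             species = spec$species_id,
                             resource = resource, level = lev,
                             replicate = rep_i, day = times,
                             rfu = exp(ln_b))
    }
  }
  do.call(rbind, out)
}

#' True trait table from strain specifications
#'
#' Applies the equilibrium minimum-resource-requirement formula
#' \eqn{R^* = m K_s / (\mu_{max} - m)} to each strain's true kinetics,
#' giving the ground-truth I*, N*, P* against which the estimation pipeline
#' is validated. `mu_max_max` is the maximum `mu_max` across resources.
#'
#' @param specs list of [strain_spec()] objects.
#' @param m density-independent mortality rate (day^-1), default 0.013.
#' @return data.frame with one row per strain: identifiers, `I_star`,
#'   `N_star`, `P_star`, `mu_max_max`, `cell_size`, `cn_ratio`, `cp_ratio`.
#' @export
gen_trait_table <- function(specs, m = 0.013) {
  stopifnot(is.list(specs), length(specs) > 0)
  rows <- lapply(specs, function(sp) {
    stopifnot(inherits(sp, "strain_spec"))
    bad <- RESOURCES[sp$mu_max[RESOURCES] <= m]
    if (length(bad))
      stop_rsc("gen_trait_table: mu_max <= m for strain '%s', resource %s",
               sp$strain_id, paste(bad, collapse = ", "))
    rs <- vapply(RESOURCES, function(r)
      r_star_value(sp$mu_max[[r]], sp$Ks[[r]], m), numeric(1))
    data.frame(strain = sp$strain_id, species = sp$species_id,
               I_star = rs[["light"]], N_star = rs[["N"]], P_star = rs[["P"]],
               mu_max_max = max(sp$mu_max), cell_size = sp$cell_size,
               cn_ratio = sp$cn_ratio, cp_ratio = sp$cp_ratio)
  })
  do.call(rbind, rows)
}

#' Sample a community count table from simulated trajectories
#'
#' Wraps a competition-simulator result (or any weekly relative-biomass
#' trajectory) with multinomial count sampling, emulating microscopy counts
#' per mL without modelling detection.
#'
#' @param sim_results named list of `sim_result` objects (one per mesocosm),
#'   or a single `sim_result`. Names become mesocosm ids.
#' @param treatments character vector, one treatment label per mesocosm.
#' @param weeks integer weeks to sample at (trajectory time = 7 * week days).
#' @param noise a [noise_model()]; `count_sampling` is the cells counted per
#'   sample.
#' @return data.frame `(week, mesocosm, treatment, taxon, count)`; counts per
#'   (week, mesocosm) sum to `count_sampling`.
#' @export
gen_community_tables <- function(sim_results, treatments, weeks = 1:10,
                                 noise = noise_model()) {
  if (inherits(sim_results, "sim_result")) sim_results <- list(m1 = sim_results)
  if (is.null(names(sim_results)))
    names(sim_results) <- paste0("m", seq_along(sim_results))
  assert_that(length(treatments) == length(sim_results),
              "gen_community_tables: one treatment per mesocosm required")
  assert_that(length(weeks) >= 2,
              "gen_community_tables: need >= 2 weekly time points")
  out <- list()
  for (i in seq_along(sim_results)) {
    res <- sim_results[[i]]
    stopifnot(inherits(res, "sim_result"))
    meso <- names(sim_results)[i]
    for (w in weeks) {
      b <- biomass_at(res, 7 * w)
      tot <- sum(b)
      if (!(tot > 0))
        stop_rsc("gen_community_tables: zero total biomass (%s, week %d)",
                 meso, w)
      ss <- substream_seed(noise$seed, "community", meso, w)
      cnt <- with_seed(ss, stats::rmultinom(1, noise$count_sampling,
                                            b / tot))[, 1]
      out[[length(out) + 1L]] <-
        data.frame(week = w, mesocosm = meso, treatment = treatments[i],
                   taxon = names(b), count = as.numeric(cnt))
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' A default synthetic strain panel
#'
#' Twenty-one strains from seven species, mirroring the scale of a mesocosm
#' isolation campaign (strain-level variation around species-level kinetics).
#' Kinetics are drawn once per call under `seed`; spread of `mu_max` roughly
#' 0.3--1.2 day^-1 and `Ks` spanning an order of magnitude per resource,
#' values typical for freshwater phytoplankton.
#'
#' @param n_species number of species (default 7).
#' @param strains_per_species default 3 (7 x 3 = 21 strains).
#' @param seed integer seed.
#' @return list of [strain_spec()] objects.
#' @export
default_strain_panel <- function(n_species = 7L, strains_per_species = 3L,
                                 seed = 1L) {
  with_seed(substream_seed(seed, "panel"), {
    specs <- list()
    for (s in seq_len(n_species)) {
      # species-level kinetics; light Ks in umol photons, nutrients in umol/L
      base_mu <- stats::runif(3, 0.4, 1.1)
      base_Ks <- c(light = stats::runif(1, 5, 40),
                   N = stats::runif(1, 0.5, 8),
                   P = stats::runif(1, 0.05, 0.8))
      for (k in seq_len(strains_per_species)) {
        jit <- exp(stats::rnorm(3, 0, 0.08))
        jit_ks <- exp(stats::rnorm(3, 0, 0.1))
        specs[[length(specs) + 1L]] <- strain_spec(
          strain_id = sprintf("sp%d_st%d", s, k),
          species_id = sprintf("sp%d", s),
          mu_max = stats::setNames(base_mu * jit, RESOURCES),
          Ks = stats::setNames(base_Ks * jit_ks, RESOURCES),
          lag_days = stats::runif(1, 0, 1.5),
          cell_size = exp(stats::rnorm(1, log(12), 0.4)),
          cn_ratio = stats::rnorm(1, 6.6, 0.5),
          cp_ratio = stats::rnorm(1, 106, 15))
      }
    }
    specs
  })
}
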