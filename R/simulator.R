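#' @name rct_simulator
#' @title Resource-competition (RCT) chemostat and mesocosm simulator
#'
#' @description
#' Deterministic multi-species competition for essential resources:
#' \deqn{dB_i/dt = B_i (\min_j \mu_{ij}(R_j) - m), \quad
#'       dR_j/dt = \mathrm{supply}_j - \sum_i q_{ij}\,\mu_i B_i}
#' with Monod uptake \eqn{\mu_{ij}(R) = \mu_{max,ij} R/(K_{s,ij}+R)},
#' growth set by Liebig's minimum, quotas \eqn{q_{ij}} (resource consumed
#' per unit biomass grown) and a density-independent mortality m. Resources
#' can be chemostat-fed (continuous dilution D toward supply S), pulsed
#' (a weekly discrete replacement of a fraction f of the volume with fresh
#' medium — the mesocosm regime, f = 10/110), fixed (light: non-depletable,
#' no self-shading) or closed (no supply; used for mass-balance checks).
#' Integration uses an adaptive Dormand-Prince RK45 with relative tolerance
#' 1e-8; pulses are discrete events (biomass times 1-f, resources moved
#' toward fresh medium).
NULL

#' Construct a competition scenario
#'
#' @param species list of species entries, each a list with `name`, `B0`
#'   (initial biomass), and named-per-resource `mu_max`, `Ks`, `q` (quota;
#'   use 0 for non-depletable resources such as light).
#' @param resources list of resource entries, each a list with `name`,
#'   `type` (`"chemostat"`, `"pulse"`, `"fixed"`, `"closed"`), `S` (supply /
#'   fixed concentration), `R0` (initial concentration, default `S`), and
#'   for chemostat `D` (day^-1), for pulse `fraction` in (0,1) and `period`
#'   (days, default 7).
#' @param m density-independent mortality rate (day^-1), default 0.013.
#' @param horizon simulation length (days).
#' @param rtol,atol solver tolerances.
#' @param out_dt output grid spacing (days).
#' @return object of class `"sim_scenario"`.
#' @export
sim_scenario <- function(species, resources, m = 0.013, horizon = 70,
                         rtol = 1e-8, atol = 1e-10, out_dt = 1) {
  assert_that(horizon > 0, "sim_scenario: horizon must be > 0")
  for (r in resources) {
    assert_that(r$type %in% c("chemostat", "pulse", "fixed", "closed"),
                "sim_scenario: unknown resource type '%s'", r$type)
    if (r$type == "pulse")
      assert_that(r$fraction > 0 && r$fraction < 1,
                  "sim_scenario: pulse fraction must be in (0,1)")
  }
  rnames <- vapply(resources, `[[`, character(1), "name")
  for (sp in species) {
    assert_that(all(rnames %in% names(sp$mu_max)) &&
                all(rnames %in% names(sp$Ks)),
                "sim_scenario: species '%s' lacks kinetics for a resource",
                sp$name)
    assert_that(all(unlist(sp$mu_max) > 0) && all(unlist(sp$Ks) > 0),
                "sim_scenario: kinetics must be > 0 (species '%s')", sp$name)
  }
  structure(list(species = species, resources = resources, m = m,
                 horizon = horizon, rtol = rtol, atol = atol,
                 out_dt = out_dt),
            class = "sim_scenario")
}

# Dormand-Prince 5(4) adaptive step integrator. f(t, y) -> dy.
# Returns y at each time in `times` (times[1] is the initial time).
.rk45 <- function(f, y0, times, rtol, atol, h0 = NULL) {
  A <- list(
    c(1 / 5),
    c(3 / 40, 9 / 40),
    c(44 / 45, -56 / 15, 32 / 9),
    c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
    c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
    c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84))
  b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
  b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
          187 / 2100, 1 / 40)
  cs <- c(0, 1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)
  out <- matrix(NA_real_, length(times), length(y0))
  out[1, ] <- y0
  y <- y0
  t <- times[1]
  h <- h0 %||% min(0.1, diff(range(times)) / 100)
  k <- matrix(0, 7, length(y0))
  k1 <- f(t, y)   # FSAL
  for (ti in seq_along(times)[-1]) {
    target <- times[ti]
    while (t < target - 1e-12) {
      h <- min(h, target - t)
      k[1, ] <- k1
      for (s in 2:7) {
        ys <- y + h * drop(A[[s - 1]] %*% k[seq_len(s - 1), , drop = FALSE])
        k[s, ] <- f(t + cs[s] * h, ys)
      }
      y5 <- y + h * drop(b5 %*% k)
      y4 <- y + h * drop(b4 %*% k)
      sc <- atol + rtol * pmax(abs(y), abs(y5))
      err <- sqrt(mean(((y5 - y4) / sc)^2))
      if (!is.finite(err))
        stop_rsc("rk45: non-finite state at t = %g", t)
      if (err <= 1) {
        t <- t + h
        y <- pmax(y5, 0)          # clip tiny negatives from roundoff
        k1 <- k[7, ]              # FSAL reuse
        if (any(y5 < 0)) k1 <- f(t, y)
      }
      fac <- if (err > 0) 0.9 * err^(-0.2) else 5
      h <- h * min(5, max(0.2, fac))
    }
    out[ti, ] <- y
  }
  list(y = out, h = h, k1 = k1)
}

# scenario -> parameter matrices for the compiled integrator
.scenario_matrices <- function(scenario) {
  sp <- scenario$species
  res <- scenario$resources
  ns <- length(sp); nr <- length(res)
  rnames <- vapply(res, `[[`, character(1), "name")
  per_res <- function(field)
    t(matrix(vapply(sp, function(s) unlist(s[[field]])[rnames], numeric(nr)),
             nrow = nr))
  list(
    mu_max = per_res("mu_max"), Ks = per_res("Ks"), q = per_res("q"),
    D = vapply(res, function(r) if (r$type == "chemostat") r$D else 0,
               numeric(1)),
    S = vapply(res, function(r) r$S %||% 0, numeric(1)),
    fixedR = vapply(res, function(r) if (r$type == "fixed") r$S else 0,
                    numeric(1)),
    dyn = as.integer(vapply(res, function(r)
      r$type %in% c("chemostat", "pulse", "closed"), logical(1))))
}

# deriv factory for a scenario (R reference implementation; the compiled
# integrator is the production path, this one backs the cross-check tests)
.make_deriv <- function(scenario) {
  sp <- scenario$species
  res <- scenario$resources
  ns <- length(sp); nr <- length(res)
  rnames <- vapply(res, `[[`, character(1), "name")
  dyn <- vapply(res, function(r) r$type %in% c("chemostat", "pulse", "closed"),
                logical(1))
  fixed_R <- vapply(res, function(r) if (r$type == "fixed") r$S else NA_real_,
                    numeric(1))
  per_res <- function(field)   # species x resource matrix
    t(matrix(vapply(sp, function(s) unlist(s[[field]])[rnames], numeric(nr)),
             nrow = nr))
  mu_max <- per_res("mu_max"); Ks <- per_res("Ks"); q <- per_res("q")
  D <- vapply(res, function(r) if (r$type == "chemostat") r$D else 0,
              numeric(1))
  S <- vapply(res, function(r) r$S %||% 0, numeric(1))
  m <- scenario$m
  function(t, y) {
    B <- y[seq_len(ns)]
    R <- fixed_R
    R[dyn] <- y[ns + seq_len(sum(dyn))]
    R <- pmax(R, 0)
    mu_mat <- mu_max * rep(R, each = ns) / (Ks + rep(R, each = ns))
    mu <- apply(mu_mat, 1, min)
    dB <- B * (mu - m)
    uptake <- colSums(q * (mu * B))           # per resource
    dR <- D * (S - R) - uptake
    c(dB, dR[dyn])
  }
}

#' Run a competition scenario
#'
#' Integrates the scenario's dynamics over its horizon, applying pulse
#' events at each pulsed resource's period boundaries (all pulsed resources
#' share event times set by the shortest period; biomass is diluted once per
#' event).
#'
#' @param scenario a [sim_scenario()].
#' @return object of class `"sim_result"`: `time` grid, `biomass` matrix
#'   (time x species), `resources` matrix (time x resources; fixed resources
#'   reported at their constant level), `events` data.frame of pulses, and
#'   `winner` (species name with final relative abundance > 0.99, else NA).
#' @export
simulate_rct <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sp <- scenario$species; res <- scenario$resources
  ns <- length(sp); nr <- length(res)
  rnames <- vapply(res, `[[`, character(1), "name")
  snames <- vapply(sp, `[[`, character(1), "name")
  dyn <- vapply(res, function(r) r$type %in% c("chemostat", "pulse", "closed"),
                logical(1))
  pm <- .scenario_matrices(scenario)
  y <- c(vapply(sp, function(s) s$B0, numeric(1)),
         vapply(res[dyn], function(r) r$R0 %||% r$S, numeric(1)))
  pulsed <- which(vapply(res, function(r) r$type == "pulse", logical(1)))
  period <- if (length(pulsed))
    min(vapply(res[pulsed], function(r) r$period %||% 7, numeric(1))) else Inf
  ev_times <- if (is.finite(period))
    seq(period, scenario$horizon, by = period) else numeric(0)
  segs <- sort(unique(c(0, ev_times, scenario$horizon)))
  grid <- sort(unique(c(seq(0, scenario$horizon, by = scenario$out_dt),
                        segs)))
  traj <- matrix(NA_real_, length(grid), length(y))
  traj[1, ] <- y
  events <- list()
  h <- NULL
  for (si in seq_len(length(segs) - 1)) {
    seg_grid <- grid[grid >= segs[si] & grid <= segs[si + 1]]
    if (seg_grid[1] > segs[si]) seg_grid <- c(segs[si], seg_grid)
    r45 <- .rk45_cpp(y, seg_grid, pm$mu_max, pm$Ks, pm$q, pm$D, pm$S,
                     pm$fixedR, pm$dyn, scenario$m, scenario$rtol,
                     scenario$atol, h %||% -1)
    h <- r45$h
    keep <- match(seg_grid, grid)
    traj[keep, ] <- r45$y
    y <- r45$y[nrow(r45$y), ]
    if (segs[si + 1] %in% ev_times) {
      # pulse: fraction f of volume replaced with fresh medium
      f <- res[[pulsed[1]]]$fraction
      y[seq_len(ns)] <- y[seq_len(ns)] * (1 - f)
      di <- 0
      for (j in seq_len(nr)) {
        if (dyn[j]) {
          di <- di + 1
          if (res[[j]]$type == "pulse")
            y[ns + di] <- (1 - f) * y[ns + di] + f * res[[j]]$S
        }
      }
      traj[match(segs[si + 1], grid), ] <- y
      events[[length(events) + 1L]] <-
        data.frame(time = segs[si + 1], fraction = f)
    }
  }
  B <- traj[, seq_len(ns), drop = FALSE]
  colnames(B) <- snames
  Rm <- matrix(rep(vapply(res, function(r)
    if (r$type == "fixed") r$S else NA_real_, numeric(1)),
    each = length(grid)), length(grid), nr)
  Rm[, dyn] <- traj[, ns + seq_len(sum(dyn)), drop = FALSE]
  colnames(Rm) <- rnames
  relB <- B[nrow(B), ] / sum(B[nrow(B), ])
  winner <- if (any(relB > 0.99)) snames[which.max(relB)] else NA_character_
  structure(list(time = grid, biomass = B, resources = Rm,
                 events = if (length(events)) do.call(rbind, events)
                          else data.frame(time = numeric(),
                                          fraction = numeric()),
                 winner = winner, scenario = scenario),
            class = "sim_result")
}

# biomass vector at (or nearest not-after) time t
biomass_at <- function(result, t) {
  stopifnot(inherits(result, "sim_result"))
  i <- max(which(result$time <= t + 1e-9))
  b <- result$biomass[i, ]
  stats::setNames(as.numeric(b), colnames(result$biomass))
}

#' Analytic equilibrium resource concentration (R*)
#'
#' At chemostat equilibrium the ambient concentration of the limiting
#' resource equals the surviving species' \eqn{R^* = m K_s/(\mu_{max}-m)}
#' with m the scenario's per-capita loss rate.
#'
#' @param scenario a [sim_scenario()].
#' @param species species name or index.
#' @return named numeric vector: R* for every scenario resource.
#' @export
equilibrium_resource <- function(scenario, species = 1L) {
  sp <- if (is.character(species)) {
    idx <- match(species, vapply(scenario$species, `[[`, character(1), "name"))
    assert_that(!is.na(idx), "equilibrium_resource: unknown species '%s'",
                species)
    scenario$species[[idx]]
  } else scenario$species[[species]]
  rnames <- vapply(scenario$resources, `[[`, character(1), "name")
  vapply(stats::setNames(rnames, rnames), function(r)
    r_star_value(sp$mu_max[[r]], sp$Ks[[r]], scenario$m), numeric(1))
}

#' Run the four mesocosm treatments
#'
#' Builds and simulates four variants of a base scenario that differ only in
#' resource supply, mirroring the mesocosm design: balanced supply (Redfield,
#' N:P = 16:1 with 160 uM N and 10 uM P), N-limitation (N halved to 80 uM,
#' N:P = 8:1), P-limitation (P halved to 5 uM, N:P = 32:1) and
#' L-limitation (incident light scaled by `light_factor`, nutrients at
#' Redfield).
#'
#' @param base a [sim_scenario()] containing resources named `"N"`, `"P"`
#'   and (optionally, for the light treatment) `"light"`.
#' @param N_supply,P_supply Redfield supplies (uM), defaults 160 and 10.
#' @param light_factor multiplier on incident light under L-lim
#'   (default 0.1; neutral-density shading strength is a design choice).
#' @return named list of four `sim_result`s: `Redfield`, `N-lim`, `P-lim`,
#'   `L-lim`.
#' @export
run_treatment_suite <- function(base, N_supply = 160, P_supply = 10,
                                light_factor = 0.1) {
  rnames <- vapply(base$resources, `[[`, character(1), "name")
  assert_that(all(c("N", "P") %in% rnames),
              "run_treatment_suite: base scenario must have N and P resources")
  set_supply <- function(sc, name, value) {
    i <- match(name, rnames)
    sc$resources[[i]]$S <- value
    if (!is.null(sc$resources[[i]]$R0))
      sc$resources[[i]]$R0 <- sc$resources[[i]]$R0 *
        value / base$resources[[i]]$S
    sc
  }
  redfield <- set_supply(set_supply(base, "N", N_supply), "P", P_supply)
  nlim <- set_supply(redfield, "N", N_supply / 2)
  plim <- set_supply(redfield, "P", P_supply / 2)
  llim <- redfield
  if ("light" %in% rnames) {
    i <- match("light", rnames)
    llim$resources[[i]]$S <- llim$resources[[i]]$S * light_factor
    if (!is.null(llim$resources[[i]]$R0))
      llim$resources[[i]]$R0 <- llim$resources[[i]]$R0 * light_factor
  }
  list("Redfield" = simulate_rct(redfield),
       "N-lim" = simulate_rct(nlim),
       "P-lim" = simulate_rct(plim),
       "L-lim" = simulate_rct(llim))
}
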