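test_that("chemostat equilibrium resource equals analytic R*", {
  sc <- sim_scenario(
    species = list(list(name = "A", B0 = 0.01, mu_max = c(N = 1.0),
                        Ks = c(N = 1.0), q = c(N = 0.05))),
    resources = list(list(name = "N", type = "chemostat", S = 10, D = 0.1,
                          R0 = 10)),
    m = 0.1, horizon = 1000, out_dt = 50)
  res <- simulate_rct(sc)
  Rhat <- res$resources[nrow(res$resources), "N"]
  expect_equal(unname(Rhat), 1 / 9, tolerance = 1e-4)
  expect_equal(unname(equilibrium_resource(sc, "A")["N"]), 1 / 9,
               tolerance = 1e-12)
})

test_that("unlimited growth without mortality is exponential", {
  sc <- sim_scenario(
    species = list(list(name = "A", B0 = 1, mu_max = c(N = 0.7),
                        Ks = c(N = 1e-6), q = c(N = 0))),
    resources = list(list(name = "N", type = "fixed", S = 1e6)),
    m = 0, horizon = 10, out_dt = 1)
  res <- simulate_rct(sc)
  expect_equal(res$biomass[, "A"], exp(0.7 * res$time), tolerance = 1e-6)
})

test_that("the lower-R* species excludes its competitor", {
  h <- two_species_scenario(17)
  res <- simulate_rct(h$scenario)
  expect_identical(res$winner, "A")
  relA <- res$biomass[nrow(res$biomass), "A"] / sum(res$biomass[nrow(res$biomass), ])
  expect_gt(unname(relA), 0.99)
  # ambient resource settles at the winner's R*
  expect_equal(unname(res$resources[nrow(res$resources), "N"]),
               unname(h$pars$r_star["A"]), tolerance = 1e-4)
})

test_that("closed-mode mass balance holds", {
  sc <- sim_scenario(
    species = list(list(name = "A", B0 = 0.5, mu_max = c(N = 0.8),
                        Ks = c(N = 2), q = c(N = 0.1)),
                   list(name = "B", B0 = 0.2, mu_max = c(N = 0.5),
                        Ks = c(N = 1), q = c(N = 0.1))),
    resources = list(list(name = "N", type = "closed", S = 0, R0 = 4)),
    m = 0, horizon = 60, out_dt = 5)
  res <- simulate_rct(sc)
  total <- 0.1 * rowSums(res$biomass) + res$resources[, "N"]
  expect_equal(total, rep(total[1], length(total)), tolerance = 1e-6)
})

test_that("pulsed mode implies the stated average per-capita loss", {
  # weekly replacement of fraction f: average loss -(1/7) ln(1 - f)
  f <- 10 / 110
  loss <- -log(1 - f) / 7
  expect_equal(loss, 0.0136, tolerance = 0.01)
  # a species with mu pinned at exactly that loss (and m = 0) neither grows
  # nor declines across whole weeks
  sc <- sim_scenario(
    species = list(list(name = "A", B0 = 1, mu_max = c(N = loss),
                        Ks = c(N = 1e-9), q = c(N = 0))),
    resources = list(list(name = "N", type = "pulse", S = 100,
                          fraction = f, period = 7, R0 = 100)),
    m = 0, horizon = 28, out_dt = 7)
  res <- simulate_rct(sc)
  b_weekly <- res$biomass[res$time %in% c(0, 7, 14, 21, 28), "A"]
  expect_equal(unname(b_weekly), rep(1, 5), tolerance = 1e-6)
  expect_equal(nrow(res$events), 4)
})

test_that("Liebig: an excess resource leaves single-resource dynamics unchanged", {
  one <- sim_scenario(
    species = list(list(name = "A", B0 = 0.01, mu_max = c(N = 0.9),
                        Ks = c(N = 1), q = c(N = 0.05))),
    resources = list(list(name = "N", type = "chemostat", S = 8, D = 0.1,
                          R0 = 8)),
    m = 0.1, horizon = 120, out_dt = 10)
  two <- sim_scenario(
    species = list(list(name = "A", B0 = 0.01, mu_max = c(N = 0.9, P = 0.9),
                        Ks = c(N = 1, P = 1e-6), q = c(N = 0.05, P = 0))),
    resources = list(list(name = "N", type = "chemostat", S = 8, D = 0.1,
                          R0 = 8),
                     list(name = "P", type = "fixed", S = 1e6)),
    m = 0.1, horizon = 120, out_dt = 10)
  expect_equal(simulate_rct(two)$biomass[, "A"],
               simulate_rct(one)$biomass[, "A"], tolerance = 1e-7)
})

test_that("treatment suite sets the prescribed supply ratios and winners", {
  panel <- list(
    list(name = "lowN", B0 = 0.01,
         mu_max = c(light = 1, N = 1, P = 1),
         Ks = c(light = 5, N = 0.2, P = 0.1), q = c(light = 0, N = 0.05,
                                                    P = 0.003)),
    list(name = "lowP", B0 = 0.01,
         mu_max = c(light = 1, N = 1, P = 1),
         Ks = c(light = 5, N = 2, P = 0.01), q = c(light = 0, N = 0.05,
                                                   P = 0.003)))
  base <- sim_scenario(panel, resources = list(
    list(name = "light", type = "fixed", S = 100),
    list(name = "N", type = "chemostat", S = 160, D = 0.05, R0 = 20),
    list(name = "P", type = "chemostat", S = 10, D = 0.05, R0 = 2)),
    m = 0.05, horizon = 600, out_dt = 20)
  suite <- run_treatment_suite(base)
  supplies <- function(r) vapply(r$scenario$resources, function(x) x$S,
                                 numeric(1))
  sN <- supplies(suite[["Redfield"]])[2]; sP <- supplies(suite[["Redfield"]])[3]
  expect_equal(sN / sP, 16)                       # Redfield 16:1
  expect_equal(supplies(suite[["N-lim"]])[2], 80) # N halved
  expect_equal(supplies(suite[["N-lim"]])[2] / supplies(suite[["N-lim"]])[3], 8)
  expect_equal(supplies(suite[["P-lim"]])[3], 5)  # P halved
  expect_equal(supplies(suite[["P-lim"]])[2] / supplies(suite[["P-lim"]])[3], 32)
  # the min-N* species wins under N limitation, min-P* under P limitation
  expect_identical(suite[["N-lim"]]$winner, "lowN")
  expect_identical(suite[["P-lim"]]$winner, "lowP")
})

test_that("compiled integrator matches the R reference implementation", {
  h <- two_species_scenario(21, horizon = 200)
  res <- simulate_rct(h$scenario)                       # compiled path
  deriv <- rstarcomp:::.make_deriv(h$scenario)
  y0 <- c(0.01, 0.01, 10)
  ref <- rstarcomp:::.rk45(deriv, y0, res$time, 1e-8, 1e-10)
  expect_equal(unname(cbind(res$biomass, res$resources)), unname(ref$y),
               tolerance = 1e-6)
})

test_that("scenario JSON round trip preserves dynamics", {
  h <- two_species_scenario(5, horizon = 50)
  path <- tempfile(fileext = ".json")
  write_scenario_json(h$scenario, path)
  sc2 <- read_scenario_json(path)
  expect_equal(simulate_rct(sc2)$biomass, simulate_rct(h$scenario)$biomass)
})
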