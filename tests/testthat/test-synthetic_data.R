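test_that("noiseless growth series follow the Monod slope exactly", {
  sp <- flat_spec(0.8, 5)
  quiet <- noise_model(sigma_log_rfu = 0)

  # saturating-level proxy: slope equals mu_max
  g <- gen_growth_series(sp, "N", levels = 1e9, times = 0:14, n_rep = 1,
                         noise = quiet)
  slope <- coef(lm(log(rfu) ~ day, g))[["day"]]
  expect_equal(slope, 0.8, tolerance = 1e-7)   # mu(1e9) = mu_max to ~5e-9

  # half-saturation level: slope mu_max * R / (Ks + R) = 0.4
  g <- gen_growth_series(sp, "N", levels = 5, times = 0:14, n_rep = 1,
                         noise = quiet)
  expect_equal(coef(lm(log(rfu) ~ day, g))[["day"]], 0.4, tolerance = 1e-12)

  # zero nutrient: no growth
  g <- gen_growth_series(sp, "N", levels = 0, times = 0:14, n_rep = 1,
                         noise = quiet)
  expect_equal(sd(log(g$rfu)), 0)
})

test_that("lag and ceiling shape the ln trajectory as declared", {
  sp <- flat_spec(0.5, 1, lag_days = 3, sat_log_ceiling = log(50) + 4)
  g <- gen_growth_series(sp, "N", levels = 1e9, times = 0:14, n_rep = 1,
                         noise = noise_model(0))
  lnr <- log(g$rfu)
  expect_equal(lnr[1:4], rep(log(50), 4))            # plateau through day 3
  expect_equal(lnr[5] - lnr[4], 0.5, tolerance = 1e-7)
  expect_equal(max(lnr), log(50) + 4)                # capped at ceiling
})

test_that("generators are deterministic under (spec, seed) and respect substreams", {
  sp <- flat_spec(0.8, 5)
  nm <- noise_model(0.05, seed = 42)
  g1 <- gen_growth_series(sp, "N", levels = c(1, 10), times = 0:14,
                          n_rep = 2, noise = nm)
  g2 <- gen_growth_series(sp, "N", levels = c(1, 10), times = 0:14,
                          n_rep = 2, noise = nm)
  expect_identical(g1, g2)
  # regenerating a subset reproduces the same values (substream hashing)
  g_sub <- gen_growth_series(sp, "N", levels = 10, times = 0:14,
                             n_rep = 2, noise = nm)
  expect_equal(g_sub$rfu, g1$rfu[g1$level == 10])
})

test_that("gen_growth_series validates inputs", {
  sp <- flat_spec(0.8, 5)
  expect_error(gen_growth_series(sp, "N", numeric(0), 0:14), "empty levels")
  expect_error(gen_growth_series(sp, "N", 1, numeric(0)), "empty times")
  expect_error(gen_growth_series(sp, "N", 1, c(0, 2, 1)), "increasing")
  expect_error(noise_model(sigma_log_rfu = -1), "sigma_log_rfu")
})

test_that("gen_trait_table matches root-finding oracle and flags mu_max <= m", {
  sp <- flat_spec(1.0, 1.0)
  tt <- gen_trait_table(list(sp), m = 0.013)
  # oracle: bisection root of mu(R) = m
  root <- uniroot(function(R) monod_mu(R, 1, 1) - 0.013,
                  c(1e-12, 10), tol = 1e-14)$root
  expect_equal(tt$N_star, root, tolerance = 1e-10)
  expect_equal(tt$N_star, 0.013 * 1 / (1 - 0.013), tolerance = 1e-12)

  # m = 0 -> R* = 0
  expect_equal(gen_trait_table(list(sp), m = 0)$P_star, 0)

  # mu_max_max is the max across resources
  sp2 <- strain_spec("s2", "spB", mu_max = c(light = 0.5, N = 0.8, P = 0.6),
                     Ks = c(light = 1, N = 1, P = 1))
  expect_equal(gen_trait_table(list(sp2))$mu_max_max, 0.8)

  weak <- strain_spec("s3", "spC", mu_max = c(light = 0.01, N = 0.5, P = 0.5),
                      Ks = c(light = 1, N = 1, P = 1))
  expect_error(gen_trait_table(list(weak)), "s3.*light")
})

test_that("community sampling is multinomial on relative biomass", {
  sc <- sim_scenario(
    species = list(list(name = "A", B0 = 1, mu_max = c(N = 0.5),
                        Ks = c(N = 1), q = c(N = 0.05)),
                   list(name = "B", B0 = 1, mu_max = c(N = 0.5),
                        Ks = c(N = 1), q = c(N = 0.05))),
    resources = list(list(name = "N", type = "closed", S = 0, R0 = 5)),
    m = 0, horizon = 70)
  res <- simulate_rct(sc)

  # identical species stay 50:50; at sample size 1e6 each proportion is
  # within 0.002 of 0.5 (binomial tail bound, prob > 0.99)
  ct <- gen_community_tables(list(m1 = res), "Redfield", weeks = c(1, 10),
                             noise = noise_model(count_sampling = 1e6,
                                                 seed = 3))
  p <- ct$count[ct$week == 10] / sum(ct$count[ct$week == 10])
  expect_true(all(abs(p - 0.5) < 0.002))
  # column sums equal the sample size
  expect_equal(sum(ct$count[ct$week == 1]), 1e6)

  # single-taxon scenario: relative abundance 1 at all weeks
  sc1 <- sim_scenario(
    species = list(list(name = "A", B0 = 1, mu_max = c(N = 0.5),
                        Ks = c(N = 1), q = c(N = 0.05))),
    resources = list(list(name = "N", type = "closed", S = 0, R0 = 5)),
    m = 0, horizon = 70)
  ct1 <- gen_community_tables(list(m1 = simulate_rct(sc1)), "Redfield",
                              weeks = c(1, 10),
                              noise = noise_model(seed = 4))
  p1 <- relative_abundance(ct1)
  expect_true(all(p1$rel_abund == 1))

  # byte-identical on re-run under the same seed
  ct2 <- gen_community_tables(list(m1 = res), "Redfield", weeks = c(1, 10),
                              noise = noise_model(count_sampling = 1e6,
                                                  seed = 3))
  expect_identical(ct, ct2)
})

test_that("noise-free round trip recovers true kinetics to 1e-6 relative", {
  sp <- flat_spec(0.8, 5)
  g <- gen_growth_series(sp, "N", levels = monod_levels, times = 0:14,
                         n_rep = 2, noise = noise_model(0))
  rt <- growth_rate_table(g)
  fit <- fit_monod(rt, "s1", "N")
  expect_equal(fit$mu_max, 0.8, tolerance = 1e-6)
  expect_equal(fit$Ks, 5, tolerance = 1e-6)
  rs <- r_star(fit, 0.013)
  expect_equal(rs$r_star, 0.013 * 5 / (0.8 - 0.013), tolerance = 1e-6)
})

test_that("default panel has the declared shape and valid kinetics", {
  panel <- default_strain_panel(seed = 1)
  expect_length(panel, 21)
  expect_length(unique(vapply(panel, `[[`, "", "species_id")), 7)
  tt <- gen_trait_table(panel)
  expect_true(all(tt$I_star > 0 & tt$N_star > 0 & tt$P_star > 0))
  expect_identical(gen_trait_table(default_strain_panel(seed = 1)), tt)
})
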