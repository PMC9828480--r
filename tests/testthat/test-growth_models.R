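test_that("exact log-linear series give an exact exp fit, selected", {
  d <- data.frame(day = 0:14, rfu = exp(2 + 0.4 * (0:14)))
  fits <- fit_growth_models(d)
  expect_equal(fits$exp$mu, 0.4, tolerance = 1e-12)
  expect_equal(fits$exp$ln_b0, 2, tolerance = 1e-12)
  expect_lt(fits$exp$rss, 1e-20)
  expect_identical(select_best(fits)$model, "exp")

  # negative growth is fitted with the same machinery
  d2 <- data.frame(day = 0:14, rfu = exp(2 - 0.1 * (0:14)))
  expect_equal(fit_growth_models(d2)$exp$mu, -0.1, tolerance = 1e-12)
})

test_that("lag breakpoint is recovered on a lagged fixture", {
  sp <- flat_spec(0.5, 1, lag_days = 3)
  g <- gen_growth_series(sp, "N", levels = 1e9, times = 0:14, n_rep = 1,
                         noise = noise_model(0.01, seed = 7))
  fits <- fit_growth_models(g)
  expect_equal(fits$lag$t_lag, 3, tolerance = 0.2)
  expect_equal(fits$lag$mu, 0.5, tolerance = 0.02)
  best <- select_best(fits)
  expect_true(best$model %in% c("lag", "lagsat"))

  # breakpoint grid-search oracle on the coarse midpoint grid: the
  # refined fit can only improve on the best midpoint
  t <- g$day; y <- log(g$rfu)
  mids <- (t[-1] + t[-length(t)]) / 2
  oracle_rss <- min(vapply(mids[-1], function(tl) {
    reg <- pmax(0, t - tl)
    sum(lm(y ~ reg)$residuals^2)
  }, numeric(1)))
  expect_lte(fits$lag$rss, oracle_rss + 1e-12)
})

test_that("rss is monotone non-increasing with model nesting", {
  for (seed in 1:20) {
    sp <- flat_spec(0.6, 2, lag_days = seed %% 4,
                    sat_log_ceiling = if (seed %% 2) log(50) + 5 else NULL)
    g <- gen_growth_series(sp, "P", levels = 1e9, times = 0:14, n_rep = 1,
                           noise = noise_model(0.05, seed = seed))
    f <- fit_growth_models(g)
    expect_lte(f$lag$rss, f$exp$rss + 1e-8)
    expect_lte(f$sat$rss, f$exp$rss + 1e-8)
    expect_lte(f$lagsat$rss, f$lag$rss + 1e-8)
    expect_lte(f$lagsat$rss, f$sat$rss + 1e-8)
  }
})

test_that("AICc formula and tie-breaking follow the stated rules", {
  # AICc = n ln(rss/n) + 2k + 2k(k+1)/(n-k-1)
  d <- data.frame(day = 0:9, rfu = exp(1 + 0.3 * (0:9) + 0.01 * sin(0:9)))
  f <- fit_growth_models(d)$exp
  n <- 10; k <- 3
  expect_equal(f$aicc, n * log(f$rss / n) + 2 * k + 2 * k * (k + 1) /
                 (n - k - 1), tolerance = 1e-12)

  # exact AICc ties break toward fewer parameters, then toward exp
  mk <- function(model, k, aicc) list(model = model, k_params = k,
                                      aicc = aicc, mu = 0, selected = FALSE)
  picked <- select_best(list(mk("lag", 4L, 1), mk("exp", 3L, 1)))
  expect_identical(picked$model, "exp")
  picked <- select_best(list(mk("lagsat", 5L, 1), mk("sat", 4L, 1)))
  expect_identical(picked$model, "sat")
  expect_error(select_best(list(mk("exp", 3L, NaN))), "non-finite")
})

test_that("short series exclude models with too many parameters", {
  d <- data.frame(day = 0:4, rfu = exp(1 + 0.3 * (0:4)))
  f <- fit_growth_models(d)   # n = 5: lag/sat need n > 5, lagsat n > 6
  expect_named(f, "exp")
  d6 <- data.frame(day = 0:5, rfu = exp(1 + 0.3 * (0:5) + 0.01 * cos(0:5)))
  expect_setequal(names(fit_growth_models(d6)), c("exp", "lag", "sat"))
})

test_that("input validation", {
  expect_error(fit_growth_models(data.frame(day = 0:2, rfu = exp(0:2))),
               "fewer than 4")
  expect_error(fit_growth_models(data.frame(day = 0:4, rfu = c(1, 1, -1, 1, 1))),
               "non-positive")
  expect_error(fit_growth_models(data.frame(day = c(0, 1, 1, 2),
                                            rfu = exp(1:4))),
               "strictly increasing")
})

test_that("growth_rate_table returns one selected slope per series, sorted", {
  sp <- flat_spec(0.8, 5)
  g <- gen_growth_series(sp, "N", levels = c(20, 5), times = 0:14, n_rep = 3,
                         noise = noise_model(0))
  tab <- growth_rate_table(g)
  expect_equal(nrow(tab), 6)
  expect_false(is.unsorted(tab$level))
  expect_equal(tab$mu[tab$level == 5], rep(0.4, 3), tolerance = 1e-9)
  expect_equal(tab$mu[tab$level == 20], rep(0.8 * 20 / 25, 3),
               tolerance = 1e-9)

  # per-series oracle: slope of the selected model refit directly
  one <- g[g$level == 20 & g$replicate == 1, ]
  expect_equal(tab$mu[tab$level == 20][1],
               unname(coef(lm(log(rfu) ~ day, one))[2]), tolerance = 1e-9)

  # empty input is not an error
  expect_equal(nrow(growth_rate_table(g[0, ])), 0)
})

test_that("model selection is consistent over seeded fixtures", {
  # scaled down from the 200-fixture acceptance check (run there in full);
  # 40 fixtures each here to keep the module suite fast
  lag_hits <- exp_hits <- 0
  for (i in 1:40) {
    sp <- flat_spec(0.5, 1, lag_days = 3)
    g <- gen_growth_series(sp, "N", levels = 1e9, times = 0:14, n_rep = 1,
                           noise = noise_model(0.05, seed = i))
    lag_hits <- lag_hits +
      (select_best(fit_growth_models(g))$model %in% c("lag", "lagsat"))
    sp0 <- flat_spec(0.5, 1)
    g0 <- gen_growth_series(sp0, "N", levels = 1e9, times = 0:14, n_rep = 1,
                            noise = noise_model(0.05, seed = i + 1000))
    exp_hits <- exp_hits +
      (select_best(fit_growth_models(g0))$model == "exp")
  }
  expect_gte(lag_hits / 40, 0.9)
  expect_gte(exp_hits / 40, 0.9)
})
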