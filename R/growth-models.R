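#' @name growth_models
#' @title Growth-rate estimation from fluorescence time series
#'
#' @description
#' Per-capita population growth rates are estimated per replicate and
#' resource level by least squares in ln(RFU) space over a four-model
#' family — exponential (`exp`), lag-then-exponential (`lag`), exponential
#' capped at a ceiling (`sat`), and both (`lagsat`) — with the best model
#' chosen by small-sample-corrected AIC (AICc). The fitted slope of the
#' exponential phase is the growth rate \eqn{\mu}. Negative slopes are
#' retained: decline below the resource requirement carries information for
#' the Monod fit.
NULL

# parameter counts include the residual variance
K_PARAMS <- c(exp = 3L, lag = 4L, sat = 4L, lagsat = 5L)

aicc_gaussian <- function(rss, n, k) {
  if (n - k - 1 < 1) return(Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Linear least squares of y on a single regressor g(t): returns list(rss, coef)
.ls_fit <- function(g, y) {
  X <- cbind(1, g)
  fit <- .lm.fit(X, y)
  list(rss = sum(fit$residuals^2), coef = fit$coefficients)
}

# regressor for given breakpoints: effective growth time
.eff_time <- function(t, t_lag, t_sat) pmax(0, pmin(t, t_sat) - t_lag)

# Fit a piecewise model with breakpoints chosen by grid search over
# observation midpoints followed by local refinement of the breakpoint(s)
# with the linear parameters profiled out. Breakpoints are constrained so
# every active linear phase contains >= 2 observations: a plateau or
# ceiling supported by a single point has a free parameter fit to one
# observation and inflates spurious lag/sat selection.
.fit_breakpoint <- function(t, y, lag = FALSE, sat = FALSE,
                            extra = list()) {
  n <- length(t)
  rng <- range(t)
  mids <- (t[-1] + t[-n]) / 2
  lag_grid <- if (lag) c(rng[1], mids) else rng[1]
  sat_grid <- if (sat) c(mids, rng[2]) else rng[2]
  cands <- unlist(lapply(lag_grid, function(tl)
    lapply(sat_grid, function(ts) c(tl, ts))), recursive = FALSE)
  cands <- c(cands, extra)
  best <- NULL
  for (p in cands) {
    tl <- p[1]; ts <- p[2]
    if (!feasible2(tl, ts, lag, sat, t, rng)) next
    f <- .ls_fit(.eff_time(t, tl, ts), y)
    if (is.null(best) || f$rss < best$rss)
      best <- list(rss = f$rss, coef = f$coef, t_lag = tl, t_sat = ts)
  }
  obj <- function(p) {
    tl <- if (lag) p[1] else rng[1]
    ts <- if (sat) p[length(p)] else rng[2]
    if (!feasible2(tl, ts, lag, sat, t, rng)) return(1e300)
    .ls_fit(.eff_time(t, tl, ts), y)$rss
  }
  p0 <- c(if (lag) best$t_lag, if (sat) best$t_sat)
  if (length(p0) == 1) {
    span <- diff(rng) / (n - 1)
    op <- stats::optimize(function(x) obj(x),
                          lower = max(rng[1], p0 - span),
                          upper = min(rng[2], p0 + span))
    if (op$objective < 1e299 && op$objective < best$rss) {
      p <- op$minimum
      best$rss <- op$objective
      if (lag) best$t_lag <- p else best$t_sat <- p
      best$coef <- .ls_fit(.eff_time(t, best$t_lag, best$t_sat), y)$coef
    }
  } else if (length(p0) == 2) {
    op <- stats::optim(p0, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-10, maxit = 200))
    if (op$value < 1e299 && op$value < best$rss) {
      best$rss <- op$value
      best$t_lag <- op$par[1]; best$t_sat <- op$par[2]
      best$coef <- .ls_fit(.eff_time(t, best$t_lag, best$t_sat), y)$coef
    }
  }
  best
}

# breakpoint feasibility: each active phase must contain >= 2 observations;
# a breakpoint at the series boundary disables its phase (nested model).
feasible2 <- function(tl, ts, lag, sat, t, rng) {
  if (ts <= tl && !(tl == rng[1] && ts == rng[2])) return(FALSE)
  if (tl < rng[1] || ts > rng[2]) return(FALSE)
  lag_on <- lag && tl > rng[1]
  sat_on <- sat && ts < rng[2]
  if (lag_on && sum(t <= tl) < 2) return(FALSE)
  if (sat_on && sum(t >= ts) < 2) return(FALSE)
  sum(t > tl & t < ts) + (!lag_on) + (!sat_on) >= 2
}

.growth_fit <- function(model, mu, ln_b0, t_lag, ln_ceiling, rss, n) {
  k <- K_PARAMS[[model]]
  list(model = model, mu = mu, ln_b0 = ln_b0, t_lag = t_lag,
       ln_ceiling = ln_ceiling, rss = rss, n_obs = n, k_params = k,
       aicc = aicc_gaussian(rss, n, k), selected = FALSE)
}

#' Fit the four-model growth family to one fluorescence series
#'
#' @param series data.frame with at least columns `day` and `rfu` (one
#'   replicate at one resource level); >= 4 observations, strictly
#'   increasing days, rfu > 0.
#' @return list of fits (class `"growth_fits"`), always containing `exp`;
#'   `lag`, `sat` and `lagsat` only when `n_obs > k_params + 1`. Each fit
#'   carries `model, mu, ln_b0, t_lag, ln_ceiling, rss, n_obs, k_params,
#'   aicc`.
#' @export
fit_growth_models <- function(series) {
  t <- series$day; rfu <- series$rfu
  assert_that(length(t) >= 4, "fit_growth_models: fewer than 4 observations")
  assert_that(all(rfu > 0), "fit_growth_models: non-positive RFU")
  assert_that(!is.unsorted(t, strictly = TRUE),
              "fit_growth_models: days must be strictly increasing")
  y <- log(rfu)
  n <- length(t)
  fits <- list()

  f <- .ls_fit(t, y)
  fits$exp <- .growth_fit("exp", mu = f$coef[2], ln_b0 = f$coef[1],
                          t_lag = NA_real_, ln_ceiling = NA_real_,
                          rss = f$rss, n = n)
  b_lag <- b_sat <- NULL
  if (n > K_PARAMS[["lag"]] + 1) {
    b_lag <- .fit_breakpoint(t, y, lag = TRUE)
    fits$lag <- .growth_fit("lag", mu = b_lag$coef[2],
                            ln_b0 = b_lag$coef[1], t_lag = b_lag$t_lag,
                            ln_ceiling = NA_real_, rss = b_lag$rss, n = n)
    b_sat <- .fit_breakpoint(t, y, sat = TRUE)
    fits$sat <- .growth_fit(
      "sat", mu = b_sat$coef[2], ln_b0 = b_sat$coef[1], t_lag = NA_real_,
      ln_ceiling = b_sat$coef[1] + b_sat$coef[2] * (b_sat$t_sat - min(t)),
      rss = b_sat$rss, n = n)
  }
  if (n > K_PARAMS[["lagsat"]] + 1) {
    # seed the 2-D search with the refined 1-D solutions so the nested-model
    # rss ordering (lagsat <= lag, sat) survives the non-convex refinement
    extra <- list(c(b_lag$t_lag, max(t)), c(min(t), b_sat$t_sat),
                  c(b_lag$t_lag, b_sat$t_sat))
    b <- .fit_breakpoint(t, y, lag = TRUE, sat = TRUE, extra = extra)
    fits$lagsat <- .growth_fit(
      "lagsat", mu = b$coef[2], ln_b0 = b$coef[1], t_lag = b$t_lag,
      ln_ceiling = b$coef[1] + b$coef[2] * (b$t_sat - b$t_lag),
      rss = b$rss, n = n)
  }
  structure(fits, class = "growth_fits")
}

#' Select the best growth fit by AICc
#'
#' Ties (AICc equal to within 1e-8) are broken toward fewer parameters,
#' then toward the plain exponential model.
#'
#' @param fits result of [fit_growth_models()] (or a plain list of fits).
#' @return the selected fit, with `selected = TRUE`.
#' @export
select_best <- function(fits) {
  assert_that(length(fits) >= 1, "select_best: no fits supplied")
  aicc <- vapply(fits, function(f) f$aicc, numeric(1))
  if (all(!is.finite(aicc)))
    stop_rsc("select_best: all fits have non-finite AICc")
  k <- vapply(fits, function(f) f$k_params, integer(1))
  is_exp <- vapply(fits, function(f) f$model == "exp", logical(1))
  near <- aicc <= min(aicc, na.rm = TRUE) + 1e-8
  ord <- order(!near, k, !is_exp)
  best <- fits[[ord[1]]]
  best$selected <- TRUE
  best
}

#' Growth-rate table: one mu per series
#'
#' Fits and selects a model for every (strain, resource, level, replicate)
#' series in a long-format table and returns the selected model's
#' exponential-phase slope.
#'
#' @param data long data.frame with columns `strain`, `resource`, `level`,
#'   `replicate`, `day`, `rfu` (as written by [gen_growth_series()]).
#' @return data.frame `(strain, resource, level, replicate, mu, model)`
#'   sorted by (strain, resource, level); zero-row input gives a zero-row
#'   table.
#' @export
growth_rate_table <- function(data) {
  empty <- data.frame(strain = character(), resource = character(),
                      level = numeric(), replicate = integer(),
                      mu = numeric(), model = character())
  if (is.null(data) || nrow(data) == 0) return(empty)
  keys <- interaction(data$strain, data$resource, data$level, data$replicate,
                      drop = TRUE)
  rows <- lapply(split(data, keys), function(d) {
    d <- d[order(d$day), ]
    fit <- tryCatch(select_best(fit_growth_models(d)), error = function(e)
      stop_rsc("growth_rate_table: series (%s, %s, level %g, rep %s): %s",
               d$strain[1], d$resource[1], d$level[1], d$replicate[1],
               conditionMessage(e)))
    data.frame(strain = d$strain[1], resource = d$resource[1],
               level = d$level[1], replicate = d$replicate[1],
               mu = unname(fit$mu), model = fit$model)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$strain, out$resource, out$level, out$replicate), ]
  rownames(out) <- NULL
  out
}
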