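#' @name rct_inference
#' @title Do lab-measured R*s predict community outcomes?
#'
#' @description
#' Tests of the two across-species predictions: (1) species with lower R*
#' for the limiting resource gain relative abundance over the experiment,
#' assessed with a random-intercept mixed model of the change in relative
#' abundance on z-scored R* with resource identity as the random effect;
#' (2) under balanced (Redfield) supply, species with higher maximum growth
#' rate gain relative abundance, assessed by Spearman rank correlation.
NULL

#' Z-score traits within each resource
#'
#' Standardises R* within each resource so light, nitrogen and phosphorus
#' requirements (with incommensurable units) share one slope.
#'
#' @param traits data.frame with columns `resource` and `r_star` (plus any
#'   identifiers, carried through).
#' @return input with a `z` column; within each resource `z` has mean 0 and
#'   sample sd (n-1 denominator) 1.
#' @export
zscore_by_resource <- function(traits) {
  out <- lapply(split(traits, traits$resource), function(d) {
    assert_that(nrow(d) >= 2,
                "zscore_by_resource: < 2 values for resource '%s'",
                d$resource[1])
    s <- stats::sd(d$r_star)
    assert_that(is.finite(s) && s > 0,
                "zscore_by_resource: zero variance within resource '%s'",
                d$resource[1])
    d$z <- (d$r_star - mean(d$r_star)) / s
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pair abundance changes with the matching standardized R*
#'
#' The limiting-resource match: the change in relative abundance observed
#' under L-lim pairs with z-scored I*, N-lim with N*, and P-lim with P*.
#' Redfield rows (no single limiting resource) are excluded.
#'
#' @param delta data.frame `(species, treatment, delta)` - per-species mean
#'   change in relative abundance per treatment.
#' @param traits_z output of [zscore_by_resource()] with columns `species`,
#'   `resource`, `z`.
#' @return merged data.frame `(species, treatment, resource, delta, z)`.
#' @export
match_delta_traits <- function(delta, traits_z) {
  delta <- delta[delta$treatment %in% names(TREATMENT_RESOURCE), ]
  delta$resource <- unname(TREATMENT_RESOURCE[delta$treatment])
  out <- merge(delta, traits_z[, c("species", "resource", "z")],
               by = c("species", "resource"))
  out[order(out$resource, out$species), ]
}

#' Prediction 1: mixed model of abundance change on z-scored R*
#'
#' Fits (by maximum likelihood) the random-intercept model
#' `delta ~ z + (1 | resource)`. Reported are the fixed slope and intercept
#' with standard errors and Wald p-values, the random-intercept variance,
#' and an R^2 defined as the squared correlation between fitted and
#' observed values. With a single resource level in the data, the model is
#' degenerate and an ordinary least squares fit is returned with a warning.
#'
#' @param data data.frame with columns `delta`, `z`, `resource` (e.g. from
#'   [match_delta_traits()]).
#' @return list of class `"inference_result"`: `model`, `slope`, `slope_se`,
#'   `slope_p`, `intercept`, `intercept_se`, `intercept_p`, `ranef_var`,
#'   `r_squared`, `n`, `residuals`, `fitted`.
#' @export
fit_prediction1 <- function(data) {
  assert_that(nrow(data) >= 3, "fit_prediction1: need >= 3 observations")
  n_res <- length(unique(data$resource))
  if (n_res < 2) {
    warning("fit_prediction1: single resource; falling back to OLS",
            call. = FALSE)
    fit <- stats::lm(delta ~ z, data = data)
    cf <- summary(fit)$coefficients
    return(structure(list(
      model = "ols", slope = cf["z", 1], slope_se = cf["z", 2],
      slope_p = cf["z", 4], intercept = cf[1, 1], intercept_se = cf[1, 2],
      intercept_p = cf[1, 4], ranef_var = NA_real_,
      r_squared = summary(fit)$r.squared, n = nrow(data),
      residuals = stats::resid(fit), fitted = stats::fitted(fit)),
      class = "inference_result"))
  }
  fit <- lme4::lmer(delta ~ z + (1 | resource), data = data, REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular =
                                                  "ignore"))
  cf <- summary(fit)$coefficients
  wald_p <- 2 * stats::pnorm(-abs(cf[, "t value"]))
  vc <- as.data.frame(lme4::VarCorr(fit))
  fitted <- stats::fitted(fit)
  structure(list(
    model = "lmm", slope = cf["z", "Estimate"],
    slope_se = cf["z", "Std. Error"], slope_p = wald_p[["z"]],
    intercept = cf["(Intercept)", "Estimate"],
    intercept_se = cf["(Intercept)", "Std. Error"],
    intercept_p = wald_p[["(Intercept)"]],
    ranef_var = vc$vcov[vc$grp == "resource"],
    r_squared = stats::cor(fitted, data$delta)^2, n = nrow(data),
    residuals = stats::resid(fit), fitted = fitted),
    class = "inference_result")
}

# all permutations of 1..n (n <= 9) as an n! x n matrix
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Mid-ranks for ties; the statistic is the Pearson correlation of the
#' ranks. The two-sided p-value is computed by exhaustive enumeration of
#' all n! rank permutations for n <= 9 and by the t-approximation
#' otherwise.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return list `(rho, p_value, n, method)`.
#' @export
spearman_test <- function(x, y) {
  assert_that(length(x) == length(y), "spearman_test: length mismatch")
  n <- length(x)
  assert_that(n >= 4, "spearman_test: need n >= 4")
  assert_that(stats::sd(x) > 0 && stats::sd(y) > 0,
              "spearman_test: constant input vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    perms <- .permutations(n)
    # cor of (rx permuted, ry) for every permutation, vectorised
    rxp <- matrix(rx[perms], nrow(perms), n)
    cx <- rxp - mean(rx); cy <- ry - mean(ry)
    rho_all <- (cx %*% cy) / sqrt(sum(cy^2) * rowSums(cx^2))
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

#' Prediction 2: abundance change under balanced supply vs maximum growth rate
#'
#' @param delta_redfield per-species change in relative abundance under the
#'   balanced (Redfield) treatment, named by species or aligned with
#'   `mu_max_max`.
#' @param mu_max_max per-species maximum growth rate across all experiments.
#' @return list `(rho, p_value, n, method)` from [spearman_test()].
#' @export
fit_prediction2 <- function(delta_redfield, mu_max_max) {
  if (!is.null(names(delta_redfield)) && !is.null(names(mu_max_max)))
    mu_max_max <- mu_max_max[names(delta_redfield)]
  spearman_test(delta_redfield, mu_max_max)
}

#' Rank species by competitive ability for a limiting resource
#'
#' Ascending sort by R*: rank 1 is the predicted dominant. Ties (exact
#' equality) share rank 1 and are flagged.
#'
#' @param traits data.frame with columns `species` (or `strain`), `resource`,
#'   `r_star`.
#' @param resource the limiting resource.
#' @return data.frame `(species, r_star, rank, tie)` sorted ascending.
#' @export
predict_winner <- function(traits, resource) {
  id_col <- if ("species" %in% names(traits)) "species" else "strain"
  sub <- traits[traits$resource == resource & is.finite(traits$r_star), ]
  assert_that(nrow(sub) >= 1,
              "predict_winner: no trait data for resource '%s'", resource)
  sub <- sub[order(sub$r_star), ]
  rk <- rank(sub$r_star, ties.method = "min")
  data.frame(species = sub[[id_col]], r_star = sub$r_star, rank = rk,
             tie = duplicated(sub$r_star) | duplicated(sub$r_star,
                                                       fromLast = TRUE),
             row.names = NULL)
}
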