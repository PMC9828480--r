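#' @name trait_evolution
#' @title Within-species evolution of competitive traits
#'
#' @description
#' Tests whether a species' minimum resource requirements changed under
#' selection: replicate R* estimates from strains isolated before the
#' experiment ("Initial") and from each treatment at the end are compared
#' per resource with one-way fixed-effects ANOVA and Tukey HSD
#' (Tukey-Kramer for unbalanced groups) simultaneous contrasts. Adaptive
#' decline for a resource means the matching selection treatment's mean R*
#' is below both the Initial and the balanced-supply (Redfield) means with
#' significant adjusted p-values.
NULL

.anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  tab <- table(groups)
  assert_that(length(tab) >= 2, "anova: need >= 2 groups")
  assert_that(all(tab >= 2), "anova: every group needs n >= 2, got %s",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  grand <- mean(values)
  gm <- tapply(values, groups, mean)
  gn <- as.numeric(tab)
  ss_between <- sum(gn * (gm[names(tab)] - grand)^2)
  ss_within <- sum((values - gm[groups])^2)
  df1 <- length(tab) - 1
  df2 <- length(values) - length(tab)
  ms_b <- ss_between / df1
  ms_w <- ss_within / df2
  flag <- NULL
  if (ms_w <= 0) {
    flag <- "zero within-group variance"
    Fstat <- Inf; p <- 0
  } else {
    Fstat <- ms_b / ms_w
    p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  }
  list(F = Fstat, df1 = df1, df2 = df2, p = p, ms_within = ms_w,
       group_means = gm, group_n = stats::setNames(gn, names(tab)),
       flag = flag)
}

#' One-way ANOVA of R* across selection treatments, per resource
#'
#' @param set data.frame with columns `selection` (e.g. Initial, Redfield,
#'   L-lim, N-lim, P-lim), `resource`, and `r_star` (replicate estimates).
#' @return named list (one entry per resource) of class `"contrast_result"`
#'   elements: `F`, `df1`, `df2`, `p`, `group_means`, `group_n`, `pairwise`
#'   (filled by [tukey_hsd()]), `flag`.
#' @export
anova_by_resource <- function(set) {
  lapply(split(set, set$resource), function(d) {
    a <- .anova_oneway(d$r_star, d$selection)
    a$resource <- d$resource[1]
    a$pairwise <- tukey_pairs(a)
    class(a) <- "contrast_result"
    a
  })
}

# all Tukey-Kramer pairwise comparisons given a one-way decomposition
tukey_pairs <- function(a) {
  gs <- names(a$group_means)
  k <- length(gs)
  rows <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    diff <- a$group_means[[j]] - a$group_means[[i]]
    se <- sqrt(a$ms_within / 2 * (1 / a$group_n[[i]] + 1 / a$group_n[[j]]))
    q_obs <- if (se > 0) abs(diff) / se else Inf
    p <- if (is.finite(q_obs))
      stats::ptukey(q_obs, nmeans = k, df = a$df2, lower.tail = FALSE)
    else if (diff == 0) 1 else 0
    rows[[length(rows) + 1L]] <-
      data.frame(group_a = gs[i], group_b = gs[j], diff = diff,
                 se = se, q = q_obs, p_adj = p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tukey HSD contrasts for one resource
#'
#' Studentized-range based simultaneous pairwise comparisons
#' (Tukey-Kramer standard errors for unbalanced groups); adjusted p from
#' the studentized range distribution with the within-group df. For two
#' groups the adjusted p equals the pooled two-sample t-test p (q = t sqrt 2).
#'
#' @param set as in [anova_by_resource()].
#' @param resource which resource to contrast.
#' @return data.frame `(group_a, group_b, diff, se, q, p_adj)`.
#' @export
tukey_hsd <- function(set, resource) {
  d <- set[set$resource == resource, ]
  assert_that(nrow(d) > 0, "tukey_hsd: no rows for resource '%s'", resource)
  tukey_pairs(.anova_oneway(d$r_star, d$selection))
}

#' Per-resource evolutionary verdicts
#'
#' For each resource, the matching selection treatment (light -> L-lim,
#' N -> N-lim, P -> P-lim) is compared against Initial and Redfield:
#' verdict `"decline"` if its mean R* is below both with both Tukey-adjusted
#' p < alpha; `"increase"` if above both with both p < alpha; otherwise
#' `"no-change"`.
#'
#' @param contrasts result of [anova_by_resource()].
#' @param alpha significance level (default 0.05).
#' @return data.frame `(resource, treatment, verdict, diff_vs_initial,
#'   p_vs_initial, diff_vs_redfield, p_vs_redfield)`.
#' @export
evolution_report <- function(contrasts, alpha = 0.05) {
  rows <- lapply(contrasts, function(a) {
    res <- a$resource
    sel <- names(TREATMENT_RESOURCE)[TREATMENT_RESOURCE == res]
    need <- c(sel, "Initial", "Redfield")
    missing <- setdiff(need, names(a$group_means))
    if (length(missing))
      stop_rsc("evolution_report: resource '%s' missing condition(s): %s",
               res, paste(missing, collapse = ", "))
    pick <- function(b) {
      pw <- a$pairwise
      row <- pw[(pw$group_a == sel & pw$group_b == b) |
                (pw$group_a == b & pw$group_b == sel), ]
      sign <- if (row$group_a[1] == sel) 1 else -1
      # diff reported as selected minus reference
      list(diff = -sign * row$diff[1], p = row$p_adj[1])
    }
    vi <- pick("Initial"); vr <- pick("Redfield")
    verdict <- if (vi$diff < 0 && vr$diff < 0 &&
                   vi$p < alpha && vr$p < alpha) "decline"
    else if (vi$diff > 0 && vr$diff > 0 &&
             vi$p < alpha && vr$p < alpha) "increase"
    else "no-change"
    data.frame(resource = res, treatment = sel, verdict = verdict,
               diff_vs_initial = vi$diff, p_vs_initial = vi$p,
               diff_vs_redfield = vr$diff, p_vs_redfield = vr$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
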