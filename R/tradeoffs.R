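#' @name tradeoffs
#' @title Trade-offs among competitive traits
#'
#' @description
#' Pairwise Pearson correlations among log10-transformed strain-level
#' traits (I*, N*, P*, cell size, maximum growth rate) and partial
#' correlations controlling for one to three covariates. A significantly
#' negative correlation between two competitive-ability traits is a
#' trade-off; a significantly positive one is concordance.
NULL

.cor_p <- function(r, n, k = 0) {
  df <- n - 2 - k
  tt <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(tt), df = df)
}

#' Pairwise correlations among log10 traits
#'
#' Complete cases per pair; rows with a non-positive value in either trait
#' are excluded from that pair (log10 undefined) and noted in the
#' `excluded` attribute.
#'
#' @param traits data.frame of strain-level traits; numeric columns are the
#'   traits, an optional `strain` column identifies rows.
#' @param vars which trait columns to correlate (default: all numeric).
#' @return data.frame `(trait_a, trait_b, r, p_value, n)` with attribute
#'   `excluded` listing dropped (row, trait) pairs.
#' @export
pairwise_correlations <- function(traits, vars = NULL) {
  num <- vapply(traits, is.numeric, logical(1))
  vars <- vars %||% names(traits)[num]
  assert_that(length(vars) >= 2, "pairwise_correlations: need >= 2 traits")
  excluded <- list()
  rows <- list()
  for (i in seq_along(vars)[-length(vars)]) for (j in (i + 1):length(vars)) {
    a <- traits[[vars[i]]]; b <- traits[[vars[j]]]
    bad <- which(!is.na(a) & !is.na(b) & (a <= 0 | b <= 0))
    if (length(bad))
      excluded[[paste(vars[i], vars[j], sep = ":")]] <- bad
    ok <- which(!is.na(a) & !is.na(b) & a > 0 & b > 0)
    assert_that(length(ok) >= 4,
                "pairwise_correlations: < 4 complete strains for (%s, %s)",
                vars[i], vars[j])
    x <- log10(a[ok]); y <- log10(b[ok])
    assert_that(stats::sd(x) > 0 && stats::sd(y) > 0,
                "pairwise_correlations: zero variance in (%s, %s)",
                vars[i], vars[j])
    r <- stats::cor(x, y)
    rows[[length(rows) + 1L]] <-
      data.frame(trait_a = vars[i], trait_b = vars[j], r = r,
                 p_value = .cor_p(r, length(ok)), n = length(ok))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Partial correlation by residual-on-residual regression
#'
#' Correlation between x and y after least-squares projection of both on
#' the covariates; p-value with df = n - 2 - k. With an empty covariate set
#' this equals the plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix/data.frame with 0-3 columns, or NULL.
#' @return list `(r, p_value, n, k)`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  assert_that(length(y) == n, "partial_correlation: length mismatch")
  if (is.null(covariates) || NCOL(covariates) == 0) {
    r <- stats::cor(x, y)
    return(list(r = r, p_value = .cor_p(r, n), n = n, k = 0L))
  }
  Z <- as.matrix(covariates)
  k <- ncol(Z)
  assert_that(n >= k + 3, "partial_correlation: need n >= covariates + 3")
  X <- cbind(1, Z)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    bad <- setdiff(colnames(X) %||% as.character(seq_len(ncol(X))),
                   (colnames(X) %||% as.character(seq_len(ncol(X))))[keep])
    stop_rsc("partial_correlation: collinear covariates (%s)",
             paste(bad, collapse = ", "))
  }
  rx <- stats::resid(stats::lm.fit(X, x))
  ry <- stats::resid(stats::lm.fit(X, y))
  r <- stats::cor(rx, ry)
  list(r = r, p_value = .cor_p(r, n, k), n = n, k = k)
}

#' Classify trait pairs as trade-off, concordance, or neither
#'
#' @param report output of [pairwise_correlations()] (or any data.frame
#'   with `r` and `p_value`).
#' @param alpha significance level (default 0.05). No multiple-testing
#'   correction is applied by default; set `holm = TRUE` to Holm-adjust the
#'   p-values first.
#' @param holm logical.
#' @return the report with a `verdict` column in
#'   `{"trade-off", "concordance", "none"}` and a `note` attribute about
#'   multiplicity.
#' @export
tradeoff_verdict <- function(report, alpha = 0.05, holm = FALSE) {
  p <- if (holm) stats::p.adjust(report$p_value, "holm") else report$p_value
  report$verdict <- ifelse(p < alpha & report$r < 0, "trade-off",
                    ifelse(p < alpha & report$r > 0, "concordance", "none"))
  attr(report, "note") <- if (holm)
    sprintf("Holm-adjusted p at alpha = %g", alpha)
  else sprintf("unadjusted p at alpha = %g; %d pairs tested", alpha,
               nrow(report))
  report
}
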