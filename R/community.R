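#' @name community_metrics
#' @title Community composition summaries and permutation statistics
#'
#' @description
#' First-principles implementations of the community statistics applied to
#' the weekly mesocosm counts: relative abundance and its change between the
#' first and last week, Pielou evenness, the Hellinger transform,
#' Bray-Curtis dissimilarity, the ANOSIM rank permutation test and
#' Dufrene-Legendre indicator values (IndVal). Permutation p-values use the
#' +1 correction, p = (1 + #{perm stat >= observed}) / (1 + n_perm).
NULL

# community table -> samples x taxa matrix (one row per week:mesocosm)
community_matrix <- function(table) {
  sample_id <- paste(table$week, table$mesocosm, sep = ":")
  m <- tapply(table$count, list(sample_id, table$taxon), sum, default = 0)
  m[is.na(m)] <- 0
  m
}

#' Relative abundance per sample
#'
#' @param table data.frame `(week, mesocosm, treatment, taxon, count)`.
#' @return the same table with a `rel_abund` column; proportions sum to 1
#'   within each (week, mesocosm).
#' @export
relative_abundance <- function(table) {
  key <- interaction(table$week, table$mesocosm, drop = TRUE)
  tot <- tapply(table$count, key, sum)
  if (any(tot <= 0))
    stop_rsc("relative_abundance: all-zero sample(s): %s",
             paste(names(tot)[tot <= 0], collapse = ", "))
  table$rel_abund <- table$count / as.numeric(tot[as.character(key)])
  table
}

#' Change in a taxon's relative abundance between first and last week
#'
#' \eqn{\Delta} = p(final week) - p(first week), computed per mesocosm and
#' averaged over the replicate mesocosms of each treatment; per-replicate
#' values are retained.
#'
#' @param table community table (see [relative_abundance()]).
#' @param taxon taxon name; must occur in the table.
#' @param weeks length-2 vector: first and final week (default `c(1, 10)`).
#' @return list with `by_treatment` (data.frame `treatment, delta, sd, n`)
#'   and `by_mesocosm` (per-replicate deltas).
#' @export
delta_relative_abundance <- function(table, taxon, weeks = c(1, 10)) {
  assert_that(taxon %in% table$taxon,
              "delta_relative_abundance: taxon '%s' absent from table", taxon)
  assert_that(all(weeks %in% table$week),
              "delta_relative_abundance: weeks %s not both present",
              paste(weeks, collapse = ", "))
  tab <- relative_abundance(table[table$week %in% weeks, ])
  tx <- tab[tab$taxon == taxon, ]
  mesos <- unique(tab[, c("mesocosm", "treatment")])
  p_at <- function(meso, wk) {
    r <- tx[tx$mesocosm == meso & tx$week == wk, "rel_abund"]
    if (length(r)) sum(r) else 0
  }
  by_meso <- data.frame(
    mesocosm = mesos$mesocosm, treatment = mesos$treatment,
    delta = vapply(mesos$mesocosm, function(m)
      p_at(m, weeks[2]) - p_at(m, weeks[1]), numeric(1)))
  agg <- do.call(rbind, lapply(split(by_meso, by_meso$treatment), function(d)
    data.frame(treatment = d$treatment[1], delta = mean(d$delta),
               sd = stats::sd(d$delta), n = nrow(d))))
  rownames(agg) <- NULL
  list(by_treatment = agg, by_mesocosm = by_meso)
}

#' Pielou evenness
#'
#' \eqn{J = H'/\ln S} with Shannon entropy over the nonzero proportions and
#' S the observed richness. Undefined (NA) for a single-taxon sample.
#'
#' @param p vector of proportions (or counts; rescaled internally).
#' @return J in \[0, 1\], or NA if fewer than 2 taxa are present.
#' @export
pielou_evenness <- function(p) {
  p <- p[p > 0]
  if (length(p) < 2) return(NA_real_)
  p <- p / sum(p)
  -sum(p * log(p)) / log(length(p))
}

#' Hellinger transform
#'
#' \eqn{y' = \sqrt{y / \mathrm{rowsum}}}; every transformed row has unit
#' Euclidean norm.
#'
#' @param x nonnegative samples x taxa matrix.
#' @return transformed matrix of the same shape.
#' @export
hellinger <- function(x) {
  x <- as.matrix(x)
  assert_that(all(x >= 0), "hellinger: negative abundance")
  rs <- rowSums(x)
  assert_that(all(rs > 0), "hellinger: zero row total")
  sqrt(x / rs)
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d_{ij} = \sum_k |x_{ik} - x_{jk}| / \sum_k (x_{ik} + x_{jk})}.
#'
#' @param x samples x taxa matrix (counts or proportions).
#' @return symmetric matrix with zero diagonal, values in \[0, 1\].
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- sum(abs(x[i, ] - x[j, ])); den <- sum(x[i, ] + x[j, ])
    d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
  }
  d
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of compositional differences between groups.
#' With mid-ranked dissimilarities, \eqn{R = (\bar r_B - \bar r_W) / (M/2)},
#' M = n(n-1)/2; group labels are permuted `n_perm` times and
#' p = (1 + #{R* >= R}) / (1 + n_perm).
#'
#' @param d square symmetric dissimilarity matrix.
#' @param groups group label per sample; >= 2 groups with >= 2 samples each.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list `(statistic, p_value, n_perm, perm_stats)`.
#' @export
anosim <- function(d, groups, n_perm = 999L, seed = 1L) {
  d <- as.matrix(d)
  n <- nrow(d)
  assert_that(isSymmetric(unname(d), tol = 1e-12),
              "anosim: dissimilarity matrix not symmetric")
  groups <- as.character(groups)
  assert_that(length(groups) == n, "anosim: one group label per sample")
  tab <- table(groups)
  assert_that(length(tab) >= 2, "anosim: need >= 2 groups")
  assert_that(all(tab >= 2), "anosim: every group needs >= 2 samples")
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  r <- rank(d[upper.tri(d)])          # mid-ranks for ties
  M <- length(r)
  stat_for <- function(g) {
    within <- g[pairs[, 1]] == g[pairs[, 2]]
    (mean(r[!within]) - mean(r[within])) / (M / 2)
  }
  obs <- stat_for(groups)
  perm <- with_seed(substream_seed(seed, "anosim"), {
    vapply(seq_len(n_perm), function(i) stat_for(sample(groups)), numeric(1))
  })
  list(statistic = obs,
       p_value = (1 + sum(perm >= obs)) / (1 + n_perm),
       n_perm = n_perm, perm_stats = perm)
}

# Dufrene-Legendre indicator values for one grouping; x: samples x taxa
.indval_stat <- function(x, groups) {
  gs <- split(seq_len(nrow(x)), groups)
  mean_ab <- vapply(gs, function(ix) colMeans(x[ix, , drop = FALSE]),
                    numeric(ncol(x)))          # taxa x groups
  mean_ab <- matrix(mean_ab, ncol = length(gs),
                    dimnames = list(colnames(x), names(gs)))
  pres <- vapply(gs, function(ix) colMeans(x[ix, , drop = FALSE] > 0),
                 numeric(ncol(x)))
  pres <- matrix(pres, ncol = length(gs),
                 dimnames = list(colnames(x), names(gs)))
  tot <- rowSums(mean_ab)
  A <- mean_ab / ifelse(tot > 0, tot, 1)        # specificity
  iv <- A * pres                                # A * B (fidelity)
  best <- max.col(iv, ties.method = "first")
  list(indval = iv[cbind(seq_len(nrow(iv)), best)],
       group = colnames(iv)[best], all = iv)
}

#' Indicator value analysis (IndVal)
#'
#' Dufrene-Legendre indicator values: specificity A (a taxon's mean abundance
#' in a group over the sum of its group mean abundances) times fidelity B
#' (fraction of the group's samples where it is present); the taxon's IndVal
#' is the maximum A*B over groups, tested by permuting sample group labels.
#'
#' @param x samples x taxa abundance matrix (e.g. one week's mesocosms).
#' @param groups group (treatment) label per sample.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return data.frame `(taxon, group, indval, p_value)`; a taxon absent
#'   everywhere gets IndVal 0 and p 1.
#' @export
indval <- function(x, groups, n_perm = 999L, seed = 1L) {
  x <- as.matrix(x)
  groups <- as.character(groups)
  assert_that(length(groups) == nrow(x), "indval: one group label per sample")
  assert_that(length(unique(groups)) >= 2, "indval: need >= 2 groups")
  obs <- .indval_stat(x, groups)
  exceed <- with_seed(substream_seed(seed, "indval"), {
    cnt <- integer(ncol(x))
    for (i in seq_len(n_perm)) {
      pv <- .indval_stat(x, sample(groups))$indval
      cnt <- cnt + (pv >= obs$indval)
    }
    cnt
  })
  absent <- colSums(x) == 0
  p <- (1 + exceed) / (1 + n_perm)
  p[absent] <- 1
  data.frame(taxon = colnames(x) %||% paste0("t", seq_len(ncol(x))),
             group = obs$group, indval = obs$indval, p_value = p,
             row.names = NULL)
}
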