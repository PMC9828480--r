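# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

# a strain with identical kinetics on all three resources
flat_spec <- function(mu_max, Ks, lag_days = 0, ...) {
  strain_spec("s1", "spA",
              mu_max = c(light = mu_max, N = mu_max, P = mu_max),
              Ks = c(light = Ks, N = Ks, P = Ks),
              lag_days = lag_days, ...)
}

# replicate growth-rate rows with Gaussian noise directly on mu
noisy_rates <- function(mu_max, Ks, levels, n_rep = 3, sigma = 0.02,
                        seed = 1) {
  set.seed(seed)
  d <- data.frame(level = rep(levels, each = n_rep))
  d$mu <- monod_mu(d$level, mu_max, Ks) + rnorm(nrow(d), 0, sigma)
  d
}

monod_levels <- c(0.5, 1, 2, 4, 8, 16, 32, 64, 128, 256)

# two-species chemostat scenario with a prescribed R* ratio
two_species_scenario <- function(seed, m = 0.1, horizon = 500) {
  set.seed(seed)
  mu1 <- runif(1, 0.6, 1.0); mu2 <- runif(1, 0.6, 1.0)
  Ks1 <- runif(1, 0.5, 2)
  rs1 <- m * Ks1 / (mu1 - m)
  rs2 <- rs1 * runif(1, 2, 4)
  Ks2 <- rs2 * (mu2 - m) / m
  list(
    scenario = sim_scenario(
      species = list(
        list(name = "A", B0 = 0.01, mu_max = c(N = mu1), Ks = c(N = Ks1),
             q = c(N = 0.05)),
        list(name = "B", B0 = 0.01, mu_max = c(N = mu2), Ks = c(N = Ks2),
             q = c(N = 0.05))),
      resources = list(list(name = "N", type = "chemostat", S = 10, D = m,
                            R0 = 10)),
      m = m, horizon = horizon, out_dt = 10),
    pars = list(mu = c(A = mu1, B = mu2), Ks = c(A = Ks1, B = Ks2),
                r_star = c(A = rs1, B = rs2)))
}

# small community table: 2 treatments x 2 mesocosms x 2 weeks x 3 taxa
toy_community <- function() {
  grid <- expand.grid(week = c(1, 10),
                      mesocosm = c("m1", "m2", "m3", "m4"),
                      taxon = c("t1", "t2", "t3"),
                      stringsAsFactors = FALSE)
  grid$treatment <- ifelse(grid$mesocosm %in% c("m1", "m2"), "N-lim",
                           "Redfield")
  counts <- c(t1 = 30, t2 = 50, t3 = 20)
  grid$count <- counts[grid$taxon]
  # t1 sweeps in N-lim by week 10
  sel <- grid$week == 10 & grid$treatment == "N-lim"
  grid$count[sel & grid$taxon == "t1"] <- 90
  grid$count[sel & grid$taxon != "t1"] <- 5
  grid
}

# brute-force ANOSIM statistic from the definition (no shared code path)
anosim_oracle_stat <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  rk <- matrix(0, n, n)
  rk[upper.tri(rk)] <- rank(d[upper.tri(d)])
  rb <- rw <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (groups[i] == groups[j]) rw <- c(rw, rk[i, j]) else rb <- c(rb, rk[i, j])
  }
  (mean(rb) - mean(rw)) / (n * (n - 1) / 4)
}

# direct Dufrene-Legendre IndVal for one taxon (vector of abundances)
indval_oracle <- function(abund, groups) {
  gs <- unique(groups)
  mean_ab <- sapply(gs, function(g) mean(abund[groups == g]))
  A <- if (sum(mean_ab) > 0) mean_ab / sum(mean_ab) else rep(0, length(gs))
  B <- sapply(gs, function(g) mean(abund[groups == g] > 0))
  max(A * B)
}
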