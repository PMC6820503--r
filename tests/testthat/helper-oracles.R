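# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: brute-force grids, exhaustive enumeration, and
# closed forms only.

# Bernoulli log-likelihood of an intercept + single-slope logistic model.
loglik_logit2 <- function(b0, b1, x, y) {
  eta <- b0 + b1 * x
  sum(y * eta - log1p(exp(eta)))
}

# Two-stage brute-force grid maximizer of the 2-parameter logistic
# likelihood: coarse pass over a wide box, then a fine pass around the
# coarse argmax, final resolution 1e-5.
grid_logit2 <- function(x, y, lim = 6) {
  best <- c(0, 0)
  for (step in c(0.01, 1e-4, 1e-6)) {
    half <- if (step == 0.01) lim else step * 150
    b0s <- seq(best[1] - half, best[1] + half, by = step)
    b1s <- seq(best[2] - half, best[2] + half, by = step)
    ll <- outer(b0s, b1s, Vectorize(function(a, b) loglik_logit2(a, b, x, y)))
    ix <- arrayInd(which.max(ll), dim(ll))
    best <- c(b0s[ix[1]], b1s[ix[2]])
  }
  best
}

# Exact Mann-Whitney p by enumeration, with U computed pair-by-pair
# (independent of the rank-sum identity used in the package).
oracle_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(xa, xb) {
    sum(outer(xa, xb, function(p, q) (p > q) + 0.5 * (p == q)))
  }
  u_obs <- u_of(a, b)
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  min(1, 2 * min(mean(u_all <= u_obs + 1e-9), mean(u_all >= u_obs - 1e-9)))
}

# Exact Wilcoxon signed-rank p by enumerating sign patterns through bit
# masks (independent of the package's expand.grid construction).
oracle_wsr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  w_all <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
  }, numeric(1))
  min(1, 2 * min(mean(w_all <= w_obs + 1e-9), mean(w_all >= w_obs - 1e-9)))
}

# Fisher discriminant ratio of a direction on a labelled matrix.
fisher_ratio <- function(v, mat, labels) {
  v <- v / sqrt(sum(v^2))
  z <- drop(mat %*% v)
  classes <- unique(labels)
  grand <- mean(z)
  sb <- sum(vapply(classes, function(cl)
    sum(labels == cl) * (mean(z[labels == cl]) - grand)^2, numeric(1)))
  sw <- sum(vapply(classes, function(cl)
    sum((z[labels == cl] - mean(z[labels == cl]))^2), numeric(1)))
  sb / sw
}

# Small deterministic cell table for gating fixtures.
manual_cell_table <- function(values, channels, donor = "d1",
                              group = "control") {
  cell_table(values, channels = channels,
             meta = tibble::tibble(donor = donor, group = group),
             scale_state = "arcsinh", cofactor = 5)
}

# Null-study generator matching the calibration geometry: single
# population, no condition effects, donor effect sd tau.
null_sim_config <- function(seed, n_donors = 10, cells = 1000,
                            n_markers = 10, tau = 0.3,
                            deltas = NULL) {
  mk <- tibble::tibble(marker = sprintf("M%02d", seq_len(n_markers)),
                       mu = 1.5, sigma = 1, tau = tau, pi = 0)
  sim_config(n_donors_per_group = n_donors, cells_per_donor = cells,
             markers = mk, condition_effects = deltas,
             populations = tibble::tibble(population = "all", fraction = 1),
             offsets = list(), paired = FALSE, seed = seed)
}

arcsinh_null_study <- function(seed, ...) {
  sim <- simulate_study(null_sim_config(seed, ...),
                        include_viability = FALSE)
  list(cells = arcsinh_transform(bind_cells(sim$samples), 5),
       design = sim$design, truth = sim$truth)
}
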