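test_that("donor medians use the midpoint convention", {
  tab <- manual_cell_table(
    cbind(CD38 = c(1, 3, 2, 4, 6, 5), NKp46 = c(0, 1, 2, 2, 2, 9)),
    c("CD38", "NKp46"),
    donor = c("a", "a", "b", "b", "b", "c"))
  design <- study_design(tibble::tibble(
    donor = c("a", "b", "c"), group = c("control", "pregnant", "control")))
  med <- donor_medians(tab, c("CD38", "NKp46"), design = design)
  expect_equal(med$CD38, c(2, 4, 5))    # (1,3)->2 midpoint; (2,4,6)->4; 5
  expect_equal(med$NKp46, c(0.5, 2, 9))
  expect_identical(med$group, c("control", "pregnant", "control"))
})

test_that("donors without gated cells are excluded with a warning", {
  tab <- manual_cell_table(cbind(M = c(1, 2)), "M", donor = c("a", "b"))
  design <- study_design(tibble::tibble(
    donor = c("a", "b", "ghostly"),
    group = c("control", "control", "control")))
  expect_warning(med <- donor_medians(tab, "M", design = design),
                 "ghostly")
  expect_equal(nrow(med), 2L)
})

test_that("two-class identity-covariance axis matches the closed form", {
  set.seed(5)
  n <- 400
  X <- rbind(matrix(rnorm(n * 2), n),
             sweep(matrix(rnorm(n * 2), n), 2, c(1, 0), "+"))
  colnames(X) <- c("m1", "m2")
  df <- tibble::as_tibble(X)
  df$donor <- sprintf("d%03d", seq_len(2 * n))
  df$group <- rep(c("control", "pregnant"), each = n)
  fit <- fit_lda(df, lambda = 0)
  # closed form Fisher direction: solve(Sw) %*% (mu2 - mu1)
  Sw <- (stats::cov(X[1:n, ]) + stats::cov(X[-(1:n), ])) * (n - 1)
  v <- solve(Sw, colMeans(X[-(1:n), ]) - colMeans(X[1:n, ]))
  v <- v / sqrt(sum(v^2))
  cosine <- abs(sum(fit$axes[, 1] * v))
  expect_gt(cosine, 0.999)
  expect_equal(ncol(fit$axes), 1L)
  expect_equal(sqrt(sum(fit$axes[, 1]^2)), 1, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  df <- tibble::tibble(donor = c("a", "b"), group = "control",
                       m1 = c(1, 2), m2 = c(2, 1))
  expect_error(fit_lda(df), "2 groups")
  df2 <- tibble::tibble(donor = letters[1:3],
                        group = c("control", "control", "pregnant"),
                        m1 = 1:3, m2 = 3:1)
  expect_error(fit_lda(df2), "at least 2 donor rows")
})

test_that("axes and eigenvalues are translation invariant", {
  set.seed(6)
  df <- tibble::tibble(donor = sprintf("d%02d", 1:12),
                       group = rep(c("control", "pregnant", "postpartum"),
                                   each = 4),
                       m1 = rnorm(12), m2 = rnorm(12), m3 = rnorm(12))
  base <- fit_lda(df, lambda = 0)
  shifted <- df
  shifted$m1 <- shifted$m1 + 100
  shifted$m2 <- shifted$m2 - 7
  moved <- fit_lda(shifted, lambda = 0)
  expect_equal(moved$axes, base$axes, tolerance = 1e-9)
  expect_equal(moved$eigenvalues, base$eigenvalues, tolerance = 1e-9)
})

test_that("eigenvalues survive orthogonal rotation of marker space", {
  set.seed(7)
  X <- matrix(rnorm(15 * 3), 15)
  colnames(X) <- paste0("m", 1:3)
  df <- tibble::as_tibble(X)
  df$donor <- sprintf("d%02d", 1:15)
  df$group <- rep(c("control", "pregnant", "postpartum"), each = 5)
  base <- fit_lda(df, lambda = 0)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  Xr <- X %*% Q
  colnames(Xr) <- paste0("m", 1:3)
  dfr <- tibble::as_tibble(Xr)
  dfr$donor <- df$donor
  dfr$group <- df$group
  rot <- fit_lda(dfr, lambda = 0)
  expect_equal(rot$eigenvalues, base$eigenvalues, tolerance = 1e-8)
})

test_that("no random direction beats the first Fisher axis", {
  set.seed(8)
  n_per <- 8
  mu <- rbind(c(0, 0, 0, 0), c(1.2, 0.3, 0, 0), c(0.3, 1.1, 0.2, 0))
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(n_per * 4, sd = 0.7), n_per), 2, mu[k, ], "+")))
  colnames(X) <- paste0("m", 1:4)
  g <- rep(c("control", "pregnant", "postpartum"), each = n_per)
  df <- tibble::as_tibble(X)
  df$donor <- sprintf("d%02d", seq_len(3 * n_per))
  df$group <- g
  fit <- fit_lda(df, lambda = 0)
  Xc <- scale(X, scale = FALSE)
  ratio_ld1 <- fisher_ratio(fit$axes[, 1], Xc, g)
  set.seed(9)
  dirs <- matrix(rnorm(10000 * 4), ncol = 4)
  ratios <- apply(dirs, 1, fisher_ratio, mat = Xc, labels = g)
  expect_lt(max(ratios) - ratio_ld1, 1e-9)
})

test_that("cross-check against the reference discriminant implementation", {
  skip_if_not_installed("MASS")
  set.seed(10)
  X <- matrix(rnorm(30 * 3), 30)
  X[11:20, 1] <- X[11:20, 1] + 1.5
  X[21:30, 2] <- X[21:30, 2] - 1
  colnames(X) <- paste0("m", 1:3)
  g <- rep(c("control", "pregnant", "postpartum"), each = 10)
  df <- tibble::as_tibble(X)
  df$donor <- sprintf("d%02d", 1:30)
  df$group <- g
  fit <- fit_lda(df, lambda = 0)
  ref <- MASS::lda(X, grouping = g)
  # discriminant directions agree up to scale and sign
  for (j in 1:2) {
    cosine <- abs(sum(fit$axes[, j] * ref$scaling[, j])) /
      sqrt(sum(ref$scaling[, j]^2))
    expect_gt(cosine, 0.999)
  }
})

test_that("marker ranking is by |loading| with alphabetical ties", {
  fake <- list(axes = matrix(c(0.9, -0.8, 0.1), 3, 1,
                             dimnames = list(c("CD38", "NKp46", "CD27"),
                                             "LD1")),
               contributions = tibble::tibble(
                 marker = c("CD38", "NKp46", "CD27"),
                 axis = "LD1",
                 loading = c(0.9, -0.8, 0.1)))
  class(fake) <- "cyto_lda"
  expect_identical(rank_markers(fake, 1), c("CD38", "NKp46", "CD27"))

  fake$contributions$loading <- c(0.5, -0.5, 0.5)
  expect_identical(rank_markers(fake, 1), c("CD27", "CD38", "NKp46"))
  expect_error(rank_markers(fake, 3), "LD3")
})

test_that("markers carrying the effect top the ranking across replicates", {
  hits <- vapply(1:25, function(s) {
    cfg <- null_sim_config(seed = 400 + s, n_donors = 15, cells = 200,
                           n_markers = 6, tau = 0.2,
                           deltas = c(M01 = 0.8, M02 = 0.8))
    sim <- simulate_study(cfg, include_viability = FALSE)
    cells <- arcsinh_transform(bind_cells(sim$samples), 5)
    med <- donor_medians(cells, sprintf("M%02d", 1:6), design = sim$design)
    fit <- fit_lda(med)
    all(c("M01", "M02") %in% rank_markers(fit, 1)[1:2])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
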