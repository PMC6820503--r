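test_that("standardization hits the population-sd convention", {
  tab <- manual_cell_table(cbind(M = c(1, 2, 3), C = c(5, 5, 5)),
                           c("M", "C"))
  expect_warning(std <- standardize_markers(tab, c("M", "C")), "C")
  # sd = sqrt(2/3) under divisor-n convention
  expect_equal(unname(std$x[, "M"]),
               c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_true(std$scaling$dropped[std$scaling$marker == "C"])

  # idempotence: standardizing standardized data changes nothing
  tab2 <- manual_cell_table(std$x[, "M", drop = FALSE], "M")
  std2 <- standardize_markers(tab2, "M")
  expect_equal(std2$x, std$x[, "M", drop = FALSE], tolerance = 1e-12)

  const <- manual_cell_table(cbind(A = c(2, 2)), "A")
  expect_error(suppressWarnings(standardize_markers(const, "A")),
               "zero variance")
})

test_that("intercept-only fit reproduces the closed-form logit", {
  fit <- fit_logistic(matrix(numeric(0), 4, 0), c(1, 1, 1, 0))
  expect_equal(unname(fit$coef["(Intercept)"]), log(3), tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("a balanced class-independent predictor gives zero slopes", {
  x <- matrix(c(1, 2, 1, 2), ncol = 1, dimnames = list(NULL, "m"))
  fit <- fit_logistic(x, c(0, 0, 1, 1))
  expect_equal(unname(fit$coef), c(0, 0), tolerance = 1e-8)
})

test_that("the 6-cell fit matches a brute-force grid maximizer", {
  x <- c(-2, -1, 0, 0, 1, 2)
  # overlapping outcome: the likelihood has a finite interior maximum
  y <- c(0, 1, 0, 0, 1, 1)
  fit <- fit_logistic(matrix(x, dimnames = list(NULL, "m")), y)
  oracle <- grid_logit2(x, y)
  expect_lt(max(abs(unname(fit$coef) - oracle)), 1e-4)
})

test_that("a monotone outcome over x is flagged as quasi-separated", {
  # y = 1 exactly where x >= 0 (ties at 0 split across classes): the
  # slope diverges while the gradient vanishes, a non-existent MLE
  x <- c(-2, -1, 0, 0, 1, 2)
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_logistic(matrix(x, dimnames = list(NULL, "m")), y)
  expect_true(fit$separated)
  expect_true(all(is.finite(fit$coef)))
})

test_that("fits agree with an IRLS reference on random problems", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 200
    X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
    y <- rbinom(n, 1, plogis(0.3 + X %*% c(0.5, -0.4, 0)))
    fit <- fit_logistic(X, y)
    ref <- suppressWarnings(stats::glm.fit(cbind(1, X), y,
                                           family = stats::binomial()))
    expect_equal(unname(fit$coef), unname(ref$coefficients),
                 tolerance = 1e-6)
  }
})

test_that("separation is detected and flagged", {
  x <- matrix(c(-2, -1, 1, 2), dimnames = list(NULL, "m"))
  fit <- fit_logistic(x, c(0, 0, 1, 1))
  expect_true(fit$separated)
  expect_true(all(is.finite(fit$coef)))
  # ridge restores a finite optimum
  rfit <- fit_logistic(x, c(0, 0, 1, 1), ridge = 1e-6)
  expect_false(rfit$separated)
})

test_that("single-class outcomes are rejected", {
  x <- matrix(rnorm(4), dimnames = list(NULL, "m"))
  expect_error(fit_logistic(x, c(1, 1, 1, 1)), "single class")
})

test_that("n_boot = 0 gives point estimates with no significance calls", {
  st <- arcsinh_null_study(51, n_donors = 3, cells = 100, n_markers = 3)
  eff <- bootstrap_glm(st$cells, st$design,
                       model_spec(c("control", "pregnant"),
                                  c("M01", "M02", "M03"),
                                  n_boot = 0, seed = 1))
  expect_true(all(is.na(eff$ci_low)))
  expect_false(any(eff$significant))
  expect_true(all(eff$direction == "none"))
  expect_true(all(is.finite(eff$estimate)))
})

test_that("swapping the contrast negates estimates and reflects the CI", {
  st <- arcsinh_null_study(52, n_donors = 5, cells = 200, n_markers = 4,
                           deltas = c(M01 = 0.4))
  fwd <- bootstrap_glm(st$cells, st$design,
                       model_spec(c("control", "pregnant"),
                                  sprintf("M%02d", 1:4),
                                  n_boot = 60, seed = 7))
  rev <- bootstrap_glm(st$cells, st$design,
                       model_spec(c("pregnant", "control"),
                                  sprintf("M%02d", 1:4),
                                  n_boot = 60, seed = 7))
  expect_equal(rev$estimate, -fwd$estimate, tolerance = 1e-6)
  expect_equal(rev$ci_low, -fwd$ci_high, tolerance = 1e-6)
  expect_equal(rev$ci_high, -fwd$ci_low, tolerance = 1e-6)
  expect_identical(rev$significant, fwd$significant)
})

test_that("estimates ignore cell and donor file order under a fixed seed", {
  st <- arcsinh_null_study(53, n_donors = 4, cells = 150, n_markers = 3)
  spec <- model_spec(c("control", "pregnant"), sprintf("M%02d", 1:3),
                     n_boot = 40, seed = 3, cells_per_donor = Inf)
  a <- bootstrap_glm(st$cells, st$design, spec)
  set.seed(99)
  shuffled <- slice_cells(st$cells, sample(nrow(st$cells)))
  b <- bootstrap_glm(shuffled, st$design, spec)
  expect_equal(a$estimate, b$estimate, tolerance = 1e-6)
  expect_equal(a$ci_low, b$ci_low, tolerance = 1e-6)
})

test_that("the percentile interval brackets the bootstrap median", {
  st <- arcsinh_null_study(54, n_donors = 5, cells = 200, n_markers = 3)
  eff <- bootstrap_glm(st$cells, st$design,
                       model_spec(c("control", "pregnant"),
                                  sprintf("M%02d", 1:3),
                                  n_boot = 80, seed = 2))
  boot <- attr(eff, "boot")
  med <- apply(boot, 2, stats::median, na.rm = TRUE)
  expect_true(all(eff$ci_low <= med + 1e-12))
  expect_true(all(med <= eff$ci_high + 1e-12))
})

test_that("donor heterogeneity widens the intervals", {
  width_at <- function(tau) {
    st <- arcsinh_null_study(55, n_donors = 8, cells = 300,
                             n_markers = 3, tau = tau)
    eff <- bootstrap_glm(st$cells, st$design,
                         model_spec(c("control", "pregnant"),
                                    sprintf("M%02d", 1:3),
                                    n_boot = 80, seed = 4))
    mean(eff$ci_high - eff$ci_low)
  }
  expect_gt(width_at(1.0), width_at(0.05))
})

test_that("paired contrasts use complete pairs and resample pairs", {
  cfg <- sim_config(n_donors_per_group = 4, cells_per_donor = 200,
                    markers = tibble::tibble(
                      marker = c("M01", "M02"), mu = 1.5, sigma = 1,
                      tau = 0.3, pi = 0),
                    condition_effects = c(M01 = 0.5),
                    populations = tibble::tibble(population = "all",
                                                 fraction = 1),
                    offsets = list(), paired = TRUE, seed = 66)
  sim <- simulate_study(cfg, include_viability = FALSE)
  cells <- arcsinh_transform(bind_cells(sim$samples), 5)
  eff <- bootstrap_glm(cells, sim$design,
                       model_spec(c("postpartum", "pregnant"),
                                  c("M01", "M02"), n_boot = 40,
                                  paired = TRUE, seed = 5))
  expect_s3_class(eff, "marker_effects")
  expect_true(all(is.finite(eff$estimate)))
  expect_error(
    bootstrap_glm(cells, sim$design,
                  model_spec(c("control", "pregnant"), c("M01", "M02"),
                             paired = TRUE, seed = 1)),
    "paired")
})

test_that("effects tables order by estimate with alphabetical ties", {
  eff <- tibble::tibble(marker = c("B", "A", "C"),
                        estimate = c(0.4, -0.2, -0.2),
                        ci_low = c(0.1, -0.5, -0.4),
                        ci_high = c(0.7, 0.1, 0),
                        significant = c(TRUE, FALSE, FALSE),
                        direction = c("predicts_comparison", "none", "none"))
  out <- effects_table(eff)
  expect_identical(out$marker, c("A", "C", "B"))
})
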