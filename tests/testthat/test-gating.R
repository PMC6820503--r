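# Hand-built 10-cell fixture on the arcsinh scale. NK conjunction:
# CD3- CD19- CD20- CD14- (all <= 1.5) and CD56 > 1.2. Cells 1-4 satisfy
# it; 5 is a T cell, 6 a B cell, 7 a monocyte, 8 CD56-negative, 9 a
# boundary cell sitting exactly on both thresholds (excluded by the
# strict/nonstrict conventions), 10 another NK-like cell failing CD20.
ten_cell_fixture <- function() {
  m <- rbind(
    c(0.1, 0.1, 0.1, 0.1, 2.5, 3.0),   # NK dim-like
    c(0.3, 0.2, 0.0, 0.5, 4.5, 0.2),   # NK bright-like
    c(1.4, 1.0, 1.2, 1.1, 2.0, 2.8),   # NK, near exclusion thresholds
    c(0.0, 0.0, 0.0, 0.0, 1.3, 1.6),   # NK, just above CD56 cut
    c(3.0, 0.1, 0.1, 0.1, 2.5, 0.1),   # T cell (CD3 high)
    c(0.1, 2.9, 3.1, 0.1, 2.5, 0.1),   # B cell
    c(0.1, 0.1, 0.1, 2.8, 2.5, 1.9),   # monocyte
    c(0.1, 0.1, 0.1, 0.1, 0.4, 2.5),   # CD56 negative
    c(1.5, 0.1, 0.1, 0.1, 1.2, 2.0),   # exactly on CD3 and CD56 cuts
    c(0.1, 0.1, 1.6, 0.1, 2.6, 2.4))   # CD20 positive
  manual_cell_table(m, c("CD3", "CD19", "CD20", "CD14", "CD56", "CD16"),
                    donor = sprintf("d%d", rep(1:2, each = 5)))
}

nk_tree <- function() {
  gate_tree(tibble::tibble(
    population = "NK",
    marker = c("CD3", "CD19", "CD20", "CD14", "CD56"),
    threshold = c(1.5, 1.5, 1.5, 1.5, 1.2),
    polarity = c("below", "below", "below", "below", "above")))
}

test_that("the NK conjunction selects exactly the manually gated cells", {
  tab <- ten_cell_fixture()
  out <- apply_gate_tree(tab, nk_tree())
  expect_named(out, "NK")
  # cells 1-4 pass; cell 9 fails CD56 > 1.2 (equality); rest excluded
  expect_equal(channel_matrix(out$NK), channel_matrix(tab)[1:4, ])
  expect_identical(out$NK$donor, tab$donor[1:4])
})

test_that("gating handles empty input, all-dead input and missing markers", {
  tab <- ten_cell_fixture()
  empty <- slice_cells(tab, integer(0))
  out <- apply_gate_tree(empty, nk_tree())
  expect_equal(nrow(out$NK), 0L)

  live_tree <- gate_tree(tibble::tibble(
    population = "live_NK",
    marker = c("Viability", "CD56"),
    threshold = c(2.5, 1.2),
    polarity = c("below", "above")))
  dead <- manual_cell_table(cbind(rep(5, 4), rep(3, 4)),
                            c("Viability", "CD56"))
  expect_equal(nrow(apply_gate_tree(dead, live_tree)$live_NK), 0L)

  expect_error(apply_gate_tree(tab, live_tree), "Viability")
})

test_that("gating is idempotent and populations are disjoint", {
  tab <- ten_cell_fixture()
  tree <- gate_tree(tibble::tibble(
    population = c("T", "NK"),
    marker = c("CD3", "CD56"),
    threshold = c(1.5, 1.2),
    polarity = c("above", "above")))
  out <- apply_gate_tree(tab, tree)
  # assignment in order: T claimed first, NK gets the rest
  expect_length(intersect(
    paste(out$T$donor, out$T$CD3, out$T$CD56),
    paste(out$NK$donor, out$NK$CD3, out$NK$CD56)), 0L)
  expect_lte(nrow(out$T) + nrow(out$NK), nrow(tab))
  regated <- apply_gate_tree(out$NK, tree)
  expect_equal(as.data.frame(regated$NK), as.data.frame(out$NK))
})

test_that("panel-aware gating degrades gracefully when CD20 is absent", {
  tab <- ten_cell_fixture()
  panel <- panel_def(tibble::tibble(
    marker = c("CD3", "CD19", "CD14", "CD56", "CD16"),
    tag = paste0("Tag", 1:5)))
  expect_warning(out <- apply_gate_tree(tab, nk_tree(), panel = panel),
                 "CD20")
  # without the CD20 exclusion, cell 10 now passes
  expect_equal(nrow(out$NK), 5L)
})

test_that("CD56dim/bright split follows the threshold conventions", {
  tab <- ten_cell_fixture()
  nk <- apply_gate_tree(tab, nk_tree())$NK
  ss <- split_nk_subsets(nk, cd56_hi = 3.3, cd56_lo = 1.2, cd16_thr = 1.5)
  # bright: CD56 > 3.3 & CD16 <= 1.5 -> cell 2 only
  expect_equal(ss$bright$CD56, 4.5)
  # dim: 1.2 < CD56 <= 3.3 & CD16 > 1.5 -> cells 1, 3, 4
  expect_equal(sort(ss$dim$CD56), c(1.3, 2.0, 2.5))
  expect_error(split_nk_subsets(nk, cd56_hi = 1, cd56_lo = 2,
                                cd16_thr = 1), "cd56_lo")

  # boundary conventions
  edge <- manual_cell_table(rbind(c(4, 0), c(2, 2)), c("CD56", "CD16"))
  ss2 <- split_nk_subsets(edge, 3.3, 1.2, 1.5)
  expect_equal(nrow(ss2$bright), 1L)
  expect_equal(ss2$bright$CD16, 0)
  expect_equal(nrow(ss2$dim), 1L)
  expect_equal(ss2$dim$CD56, 2)
})

test_that("positive frequencies match manual counts and boundary cases", {
  vals <- cbind(CD38 = c(2, 2, 2, 0.1, 0.1, 2, 0.1, 0.1),
                NKp46 = c(2, 2, 2, 2, 0.1, 0.1, 0.1, 0.1))
  tab <- manual_cell_table(vals, c("CD38", "NKp46"))
  fr <- positive_frequency(tab, c("CD38", "NKp46"), c(1.5, 1.5))
  expect_equal(fr$numerator, 3L)
  expect_equal(fr$denominator, 8L)
  expect_equal(fr$percent, 37.5)
  expect_identical(fr$combination, "CD38+NKp46+")

  expect_equal(positive_frequency(tab, "CD38", -Inf)$percent, 100)
  expect_equal(positive_frequency(tab, "CD38", Inf)$percent, 0)

  # empty denominator: flagged, not dropped
  fr2 <- positive_frequency(tab, "CD38", 1.5, donors = c("d1", "ghost"))
  g <- fr2[fr2$donor == "ghost", ]
  expect_true(g$empty_denominator)
  expect_true(is.na(g$percent))
})

test_that("frequencies are invariant to order and scale with duplication", {
  set.seed(8)
  vals <- cbind(CD38 = runif(30, 0, 4), NKp46 = runif(30, 0, 4))
  tab <- manual_cell_table(vals, c("CD38", "NKp46"),
                           donor = sample(c("d1", "d2"), 30, TRUE))
  fr <- positive_frequency(tab, c("CD38", "NKp46"), c(2, 2))
  shuffled <- slice_cells(tab, sample(30))
  fr_sh <- positive_frequency(shuffled, c("CD38", "NKp46"), c(2, 2))
  expect_equal(fr, fr_sh)
  doubled <- bind_cells(list(tab, tab))
  fr2 <- positive_frequency(doubled, c("CD38", "NKp46"), c(2, 2))
  expect_equal(fr2$percent, fr$percent)
  expect_equal(fr2$numerator, 2L * fr$numerator)
})

test_that("simulated NK subsets are recovered from truth labels", {
  cfg <- sim_config(n_donors_per_group = 5, cells_per_donor = 2000,
                    paired = FALSE, seed = 17)
  sim <- simulate_study(cfg)
  cells <- arcsinh_transform(bind_cells(sim$samples), 5)
  nk <- apply_gate_tree(cells, default_nk_gates())$NK
  ss <- split_nk_subsets(nk, 3.3, 1.2, 1.5)
  n_bright_truth <- sum(cells$population == "NK_bright")
  recall <- sum(ss$bright$population == "NK_bright") / n_bright_truth
  expect_gte(recall, 0.95)
  precision <- mean(ss$bright$population == "NK_bright")
  expect_gte(precision, 0.9)
})
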