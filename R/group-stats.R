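#' Mann-Whitney U test, exact by enumeration when feasible
#'
#' U counts, over all cross-pairs, the times a value of `a` exceeds a
#' value of `b`, with half credit for ties. For small problems the exact
#' two-sided p-value is obtained by full enumeration of all
#' `choose(n1 + n2, n1)` group labelings of the pooled data (used when
#' `n1 + n2 <= 12`, or up to 20 with no ties); larger problems use the
#' normal approximation with tie-corrected variance and a 0.5 continuity
#' correction. Two-sided p doubles the smaller tail, capped at 1.
#'
#' @param a,b numeric samples (e.g. per-donor frequencies of two groups).
#' @param exact_max_total,exact_max_total_ties enumeration crossover
#'   sample sizes (tie-free and with ties respectively).
#' @return A `comparison` tibble row: `test`, `statistic`, `p`, `method`,
#'   `n1`, `n2`, `stars`.
#' @export
mann_whitney_u <- function(a, b, exact_max_total = 20L,
                           exact_max_total_ties = 12L) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (!length(a) || !length(b)) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  n1 <- length(a)
  n2 <- length(b)
  pooled <- c(a, b)
  ties <- anyDuplicated(pooled) > 0L
  u_obs <- u_statistic(a, b)

  total <- n1 + n2
  use_exact <- total <= exact_max_total_ties ||
    (!ties && total <= exact_max_total)
  if (use_exact) {
    u_all <- enumerate_u(pooled, n1)
    p_lo <- mean(u_all <= u_obs + 1e-9)
    p_hi <- mean(u_all >= u_obs - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (total * (total - 1))
    v <- n1 * n2 / 12 * ((total + 1) - tie_term)
    z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(v)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  comparison_row("mann_whitney", u_obs, p, method, n1 = n1, n2 = n2)
}

u_statistic <- function(a, b) {
  # rank-sum form handles ties with half credit
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

enumerate_u <- function(pooled, n1) {
  r <- rank(pooled)
  combos <- utils::combn(length(pooled), n1)
  colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
}

#' Wilcoxon signed-rank test for paired differences
#'
#' Zero differences are discarded (the classical convention); the
#' remaining absolute differences are ranked with midranks for ties and
#' `W` is the sum of ranks of the positive differences. Exact two-sided p
#' enumerates all `2^n` sign patterns when `n <= 15`; otherwise the normal
#' approximation with tie correction and a 0.5 continuity correction is
#' used. Two-sided p doubles the smaller tail, capped at 1.
#'
#' @param d paired differences (e.g. pregnant minus post-partum per
#'   donor).
#' @param exact_max_n enumeration crossover (default 15).
#' @return A `comparison` tibble row; `n1` holds the number of nonzero
#'   pairs. When all differences are zero the result is the degenerate
#'   `p = 1` with `method = "exact"` and `degenerate = TRUE`.
#' @export
wilcoxon_signed_rank <- function(d, exact_max_n = 15L) {
  d <- as.numeric(d)
  if (!length(d)) stop("need at least one difference", call. = FALSE)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    out <- comparison_row("wilcoxon_signed_rank", 0, 1, "exact",
                          n1 = 0L, n2 = NA_integer_)
    out$degenerate <- TRUE
    return(out)
  }
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  if (n <= exact_max_n) {
    # all 2^n sign patterns: W = sum of ranks carrying a positive sign
    grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- drop(grid %*% r)
    p_lo <- mean(w_all <= w_obs + 1e-9)
    p_hi <- mean(w_all >= w_obs - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(abs(d))
    v <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w_obs - mu - sign(w_obs - mu) * 0.5) / sqrt(v)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  out <- comparison_row("wilcoxon_signed_rank", w_obs, p, method,
                        n1 = n, n2 = NA_integer_)
  out$degenerate <- FALSE
  out
}

comparison_row <- function(test, statistic, p, method, n1, n2) {
  out <- tibble::tibble(test = test, statistic = as.numeric(statistic),
                        p = p, method = method,
                        n1 = as.integer(n1), n2 = as.integer(n2),
                        stars = p_stars(p))
  class(out) <- c("comparison", class(out))
  out
}

#' Significance stars for a p-value
#'
#' The conventional mapping: `***` for p < 0.001, `**` for p < 0.01,
#' `*` for p < 0.05, `ns` otherwise (the most extreme applicable label).
#'
#' @param p numeric vector of p-values.
#' @return Character vector of `ns`, `*`, `**`, `***`.
#' @export
p_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***",
                   p < 0.01 ~ "**",
                   p < 0.05 ~ "*",
                   TRUE ~ "ns")
}

#' Compare gated frequencies between groups
#'
#' Runs one test per (population, marker combination, contrast):
#' Mann-Whitney U for unpaired contrasts (e.g. control vs pregnant),
#' Wilcoxon signed-rank on within-pair differences for the paired
#' pregnant/post-partum contrast. Donors with empty denominators are
#' dropped from the test. Contrasts with fewer than 2 donors in a group
#' are still computed when possible but flagged `underpowered`.
#'
#' @param freq a `frequency_tbl` from [positive_frequency()] (rows from
#'   several populations may be bound together).
#' @param design a `study_design`.
#' @param contrasts list of contrasts, each
#'   `list(groups = c(reference, comparison), paired = FALSE)`.
#' @return Tibble with one row per population x combination x contrast:
#'   the `comparison` columns plus `population`, `combination`,
#'   `reference`, `comparison`, `underpowered`.
#' @export
compare_frequency_table <- function(freq, design, contrasts) {
  stopifnot(is.list(contrasts))
  freq <- dplyr::filter(tibble::as_tibble(freq), !.data$empty_denominator)
  freq$group <- design$group[match(freq$donor, design$donor)]
  if (anyNA(freq$group)) {
    stop("frequency rows reference donors absent from the design",
         call. = FALSE)
  }
  cells <- dplyr::distinct(freq, .data$population, .data$combination)
  out <- purrr::map_dfr(contrasts, function(ct) {
    gr <- ct$groups
    if (length(gr) != 2L || !all(gr %in% design$group)) {
      stop("contrast must name two groups present in the design: ",
           paste(gr, collapse = ", "), call. = FALSE)
    }
    paired <- isTRUE(ct$paired)
    purrr::pmap_dfr(cells, function(population, combination) {
      f <- freq[freq$population == population &
                  freq$combination == combination, ]
      if (paired) {
        pairs <- design_pairs(design)
        x1 <- f$percent[match(pairs$pregnant, f$donor)]
        x2 <- f$percent[match(pairs$postpartum, f$donor)]
        ok <- !is.na(x1) & !is.na(x2)
        # difference oriented comparison - reference
        dsign <- if (identical(gr[2], "pregnant")) 1 else -1
        res <- wilcoxon_signed_rank(dsign * (x1[ok] - x2[ok]))
        res$underpowered <- sum(ok) < 2
      } else {
        va <- f$percent[f$group == gr[1]]
        vb <- f$percent[f$group == gr[2]]
        res <- mann_whitney_u(va, vb)
        res$degenerate <- NA
        res$underpowered <- min(length(va), length(vb)) < 2
      }
      dplyr::bind_cols(tibble::tibble(population = population,
                                      combination = combination,
                                      reference = gr[1],
                                      comparison = gr[2]),
                       res)
    })
  })
  out
}
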