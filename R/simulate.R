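#' Configure a synthetic mass-cytometry study
#'
#' The generator emulates the structure of a three-group pregnancy study:
#' donors nested in groups (`control`, `pregnant`, and — when `paired` —
#' `postpartum` samples from the same women as the pregnant group), a
#' mixture of cell populations, donor-level random effects shared across a
#' donor's cells, cell-level Gaussian noise on the arcsinh scale,
#' zero-inflated nonnegative raw intensities, and additive condition
#' effects concentrated on a few markers.
#'
#' Latent expression for cell of population *p*, marker *m*, donor *d* is
#' `y = mu_m + offset_pm + delta_m * [group == pregnant] + u_dm + eps`,
#' with `u_dm ~ N(0, tau_m^2)` (reused in the paired post-partum sample)
#' and `eps ~ N(0, sigma_m^2)`. Raw values are `cofactor * sinh(max(y, 0))`
#' — the floor keeps raw intensities nonnegative, a deliberate truncation —
#' and with probability `pi_m` a cell is a structural zero.
#'
#' @param n_donors_per_group donors per group (default 21, a typical
#'   cohort size for this design).
#' @param cells_per_donor cells per donor-sample.
#' @param markers tibble with columns `marker`, `mu` (baseline mean,
#'   arcsinh scale), `sigma` (cell sd > 0), `tau` (donor-effect sd >= 0),
#'   `pi` (zero-inflation probability in \[0,1\]). Default: a 12-marker NK
#'   panel.
#' @param condition_effects tibble with columns `marker`, `delta` and
#'   optionally `population` (`NA` = effect in every population); applied
#'   additively in the pregnant group. Default: CD38 up in both NK
#'   subsets, NKp46 up in CD56dim NK cells, CXCR3 down in both.
#' @param populations tibble with columns `population`, `fraction`;
#'   fractions must sum to 1. Default mixture: NK_dim, NK_bright, T, B,
#'   monocyte, dead.
#' @param offsets named list: population -> named numeric vector of
#'   per-marker mean offsets (markers omitted get 0).
#' @param paired if `TRUE`, each pregnant donor contributes a paired
#'   post-partum sample reusing her donor random effects; the post-partum
#'   sample gets `postpartum_effects` (default none).
#' @param postpartum_effects like `condition_effects`, applied in the
#'   post-partum group (default empty).
#' @param cofactor arcsinh cofactor (default 5, the mass-cytometry
#'   convention).
#' @param viability list `(live_mean, dead_mean, sd)` for the cisplatin-like
#'   viability channel; dead cells stain high. The defaults separate live
#'   and dead means by 8 pooled sds so threshold gating is near-perfect.
#' @param seed integer seed; the study seed expands deterministically into
#'   per-donor streams.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_donors_per_group = 21,
                       cells_per_donor = 1000,
                       markers = default_sim_markers(),
                       condition_effects = default_condition_effects(),
                       populations = default_sim_populations(),
                       offsets = default_population_offsets(),
                       paired = TRUE,
                       postpartum_effects = NULL,
                       cofactor = 5,
                       viability = list(live_mean = 0.5, dead_mean = 4.5,
                                        sd = 0.5),
                       seed = 1L) {
  if (n_donors_per_group < 1 || cells_per_donor < 1) {
    stop("need at least one donor per group and one cell per donor",
         call. = FALSE)
  }
  markers <- tibble::as_tibble(markers)
  stopifnot(all(c("marker", "mu", "sigma", "tau", "pi") %in% names(markers)))
  if (any(markers$sigma <= 0) || any(markers$tau < 0)) {
    stop("marker sds must satisfy sigma > 0 and tau >= 0", call. = FALSE)
  }
  if (any(markers$pi < 0 | markers$pi > 1)) {
    stop("zero-inflation probabilities must lie in [0, 1]", call. = FALSE)
  }
  populations <- tibble::as_tibble(populations)
  stopifnot(all(c("population", "fraction") %in% names(populations)))
  if (abs(sum(populations$fraction) - 1) > 1e-8) {
    stop("population mixing fractions must sum to 1", call. = FALSE)
  }
  if (cofactor <= 0) stop("cofactor must be positive", call. = FALSE)
  condition_effects <- normalize_effects(condition_effects, markers$marker)
  postpartum_effects <- normalize_effects(postpartum_effects, markers$marker)
  structure(list(n_donors_per_group = as.integer(n_donors_per_group),
                 cells_per_donor = as.integer(cells_per_donor),
                 markers = markers,
                 condition_effects = condition_effects,
                 populations = populations,
                 offsets = offsets,
                 paired = isTRUE(paired),
                 postpartum_effects = postpartum_effects,
                 cofactor = cofactor,
                 viability = viability,
                 seed = as.integer(seed)),
            class = "sim_config")
}

normalize_effects <- function(eff, known_markers) {
  if (is.null(eff) || (is.data.frame(eff) && nrow(eff) == 0)) {
    return(tibble::tibble(marker = character(), delta = numeric(),
                          population = character()))
  }
  if (is.numeric(eff) && !is.null(names(eff))) {
    eff <- tibble::tibble(marker = names(eff), delta = unname(eff))
  }
  eff <- tibble::as_tibble(eff)
  stopifnot(all(c("marker", "delta") %in% names(eff)))
  if (!"population" %in% names(eff)) eff$population <- NA_character_
  missing <- setdiff(eff$marker, known_markers)
  if (length(missing)) {
    stop("condition effects on unknown markers: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  eff[, c("marker", "delta", "population")]
}

#' Default marker model for the synthetic NK panel
#'
#' Lineage and gating channels (CD3, CD19, CD20, CD14, CD56, CD16) carry no
#' structural zeros so threshold gates behave deterministically; receptor
#' channels get a small zero-inflation probability, emulating
#' non-expressing cells.
#' @return Tibble with columns `marker`, `mu`, `sigma`, `tau`, `pi`.
#' @export
default_sim_markers <- function() {
  gating <- c("CD3", "CD19", "CD20", "CD14", "CD56", "CD16")
  receptor <- c("CD38", "NKp46", "NKG2A", "NKG2D", "NKp30", "CXCR3")
  tibble::tibble(
    marker = c(gating, receptor),
    mu = 0.2,
    sigma = 0.4,
    tau = 0.15,
    pi = c(rep(0, length(gating)), rep(0.05, length(receptor)))
  )
}

#' Default population mixture
#' @return Tibble with columns `population`, `fraction`.
#' @export
default_sim_populations <- function() {
  tibble::tibble(
    population = c("NK_dim", "NK_bright", "T", "B", "monocyte", "dead"),
    fraction = c(0.12, 0.03, 0.50, 0.15, 0.15, 0.05)
  )
}

#' Default per-population marker mean offsets (arcsinh scale)
#'
#' CD56/CD16 are bimodal across the two NK subsets (bright: CD56 high,
#' CD16 low; dim: CD56 intermediate, CD16 high) so the two-threshold
#' CD56dim/bright split is exercised; lineage markers are high on their
#' own lineage only.
#' @return Named list: population -> named numeric offsets.
#' @export
default_population_offsets <- function() {
  list(
    NK_dim = c(CD56 = 2.3, CD16 = 2.8, NKp46 = 2.0, CD38 = 1.5,
               NKG2D = 1.8, NKp30 = 1.5, NKG2A = 0.8, CXCR3 = 1.0),
    NK_bright = c(CD56 = 4.3, NKG2A = 2.2, NKp46 = 1.8, CD38 = 1.8,
                  NKG2D = 1.8, NKp30 = 1.5, CXCR3 = 1.5),
    T = c(CD3 = 2.8),
    B = c(CD19 = 2.8, CD20 = 2.8),
    monocyte = c(CD14 = 2.8, CD16 = 0.8),
    dead = c()
  )
}

#' Default pregnancy condition effects
#'
#' CD38 is elevated on both NK subsets and NKp46 on CD56dim NK cells in
#' the pregnant group; CXCR3 is diminished on both.
#' @return Tibble with columns `marker`, `delta`, `population`.
#' @export
default_condition_effects <- function() {
  tibble::tibble(
    marker = c("CD38", "CD38", "NKp46", "CXCR3", "CXCR3"),
    delta = c(0.6, 0.6, 0.6, -0.4, -0.4),
    population = c("NK_dim", "NK_bright", "NK_dim", "NK_dim", "NK_bright")
  )
}

#' Generate a synthetic study
#'
#' Draws one cell table per donor-sample under the model described in
#' [sim_config()], together with the study design and a ground-truth
#' record (configured effects, per-cell population labels, realized donor
#' random effects) for parameter-recovery testing. Deterministic under the
#' config seed: the study seed expands into one independent stream per
#' donor-sample, so regenerating the same study reproduces it exactly.
#'
#' @param config a [sim_config()].
#' @param include_viability append the viability channel (default `TRUE`;
#'   required when the mixture contains a `dead` population you intend to
#'   gate out).
#' @return A list of class `cyto_sim` with elements `samples` (named list
#'   of raw-scale `cell_tbl`, one per donor-sample), `design`
#'   (`study_design`), `truth` (list: `condition_effects`, `donor_effects`,
#'   `populations` per cell), and `config`.
#' @export
simulate_study <- function(config, include_viability = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_donors_per_group
  groups <- c("control", "pregnant")
  if (config$paired) groups <- c(groups, "postpartum")

  ids <- list(
    control = sprintf("C%02d", seq_len(n)),
    pregnant = sprintf("P%02d", seq_len(n)),
    postpartum = sprintf("PP%02d", seq_len(n))
  )
  design <- tibble::tibble(
    donor = unlist(ids[groups], use.names = FALSE),
    group = rep(groups, each = n),
    cohort = "discovery",
    paired_with = NA_character_
  )
  if (config$paired) {
    design$paired_with[design$group == "pregnant"] <- ids$postpartum
    design$paired_with[design$group == "postpartum"] <- ids$pregnant
  }
  design <- study_design(design)

  mk <- config$markers
  n_mark <- nrow(mk)
  pops <- config$populations$population
  frac <- config$populations$fraction

  # population x marker offset matrix
  off <- matrix(0, length(pops), n_mark,
                dimnames = list(pops, mk$marker))
  for (p in intersect(names(config$offsets), pops)) {
    v <- config$offsets[[p]]
    common <- intersect(names(v), mk$marker)
    off[p, common] <- v[common]
  }

  effect_matrix <- function(eff) {
    d <- matrix(0, length(pops), n_mark, dimnames = dimnames(off))
    if (nrow(eff)) {
      for (i in seq_len(nrow(eff))) {
        rows <- if (is.na(eff$population[i])) pops else eff$population[i]
        d[rows, eff$marker[i]] <- d[rows, eff$marker[i]] + eff$delta[i]
      }
    }
    d
  }
  delta_pregnant <- effect_matrix(config$condition_effects)
  delta_postpartum <- effect_matrix(config$postpartum_effects)

  # hierarchical seed expansion: study stream -> per-latent-donor streams
  set.seed(config$seed)
  latent_ids <- c(ids$control[seq_len(n)], ids$pregnant[seq_len(n)])
  donor_seed <- sample.int(.Machine$integer.max - 1L,
                           2L * n + length(groups) * n)
  names(donor_seed) <- c(paste0("u_", latent_ids),
                         unlist(ids[groups], use.names = FALSE))

  # donor random effects, shared between a pregnant donor and her
  # post-partum sample
  u <- matrix(0, nrow(design), n_mark,
              dimnames = list(design$donor, mk$marker))
  for (ld in latent_ids) {
    set.seed(donor_seed[[paste0("u_", ld)]])
    u[ld, ] <- stats::rnorm(n_mark, 0, mk$tau)
  }
  if (config$paired) {
    u[ids$postpartum, ] <- u[ids$pregnant, ]
  }

  channels <- mk$marker
  samples <- vector("list", nrow(design))
  names(samples) <- design$donor
  pop_labels <- vector("list", nrow(design))

  for (j in seq_len(nrow(design))) {
    donor <- design$donor[j]
    grp <- design$group[j]
    m <- config$cells_per_donor
    set.seed(donor_seed[[donor]])
    pop_idx <- sample.int(length(pops), m, replace = TRUE, prob = frac)
    delta <- switch(grp, pregnant = delta_pregnant,
                    postpartum = delta_postpartum,
                    matrix(0, length(pops), n_mark))
    mean_mat <- matrix(mk$mu, m, n_mark, byrow = TRUE) +
      off[pop_idx, , drop = FALSE] + delta[pop_idx, , drop = FALSE] +
      matrix(u[donor, ], m, n_mark, byrow = TRUE)
    y <- mean_mat + matrix(stats::rnorm(m * n_mark), m, n_mark) *
      matrix(mk$sigma, m, n_mark, byrow = TRUE)
    raw <- config$cofactor * sinh(pmax(y, 0))
    zero <- matrix(stats::runif(m * n_mark), m, n_mark) <
      matrix(mk$pi, m, n_mark, byrow = TRUE)
    raw[zero] <- 0
    tab <- cell_table(raw, channels = channels,
                      meta = tibble::tibble(
                        sample_id = donor, donor = donor, group = grp,
                        population = pops[pop_idx]),
                      scale_state = "raw")
    if (include_viability) {
      tab <- add_viability_channel(tab, config)
    }
    samples[[donor]] <- tab
    pop_labels[[j]] <- pops[pop_idx]
  }

  truth <- list(
    condition_effects = config$condition_effects,
    postpartum_effects = config$postpartum_effects,
    donor_effects = tibble::as_tibble(cbind(
      tibble::tibble(donor = design$donor),
      tibble::as_tibble(u))),
    populations = tibble::tibble(
      donor = rep(design$donor, each = config$cells_per_donor),
      population = unlist(pop_labels))
  )
  structure(list(samples = samples, design = design, truth = truth,
                 config = config),
            class = "cyto_sim")
}

#' Append a cisplatin-like viability channel
#'
#' Dead-population cells draw the channel from a high-mean normal (on the
#' arcsinh scale, inverted to raw like every other channel), live cells
#' from a low-mean one; the configured default means differ by 8 pooled
#' sds, so a midpoint threshold separates live from dead essentially
#' perfectly.
#'
#' @param table a raw-scale `cell_tbl` with a `population` column.
#' @param config the [sim_config()] supplying `viability` parameters and
#'   the cofactor.
#' @param channel channel name (default `"Viability"`).
#' @return The table with the extra channel.
#' @export
add_viability_channel <- function(table, config, channel = "Viability") {
  v <- config$viability
  dead <- !is.na(table$population) & table$population == "dead"
  m <- nrow(table)
  y <- stats::rnorm(m, ifelse(dead, v$dead_mean, v$live_mean), v$sd)
  raw <- config$cofactor * sinh(pmax(y, 0))
  vals <- cbind(channel_matrix(table), raw)
  cell_table(vals, channels = c(channel_names(table), channel),
             meta = cell_meta(table), scale_state = "raw")
}

#' Default gate tree matched to the synthetic generator
#'
#' Live NK cells are CD3-CD19-CD20-CD14-CD56+ among viability-low events;
#' thresholds are on the arcsinh scale (cofactor 5) and sit between the
#' generator's background and lineage-positive modes.
#'
#' @param viability_thr threshold separating live (below) from dead.
#' @param lineage_thr exclusion threshold for CD3/CD19/CD20/CD14.
#' @param cd56_lo minimum CD56 for an NK cell.
#' @return A [gate_tree()] with a single `NK` terminal population.
#' @export
default_nk_gates <- function(viability_thr = 2.5, lineage_thr = 1.5,
                             cd56_lo = 1.2) {
  gate_tree(tibble::tibble(
    population = "NK",
    marker = c("Viability", "CD3", "CD19", "CD20", "CD14", "CD56"),
    threshold = c(viability_thr, rep(lineage_thr, 4), cd56_lo),
    polarity = c(rep("below", 5), "above")
  ))
}
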