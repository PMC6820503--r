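#' Configure an end-to-end analysis run
#'
#' One config drives simulate (or load) -> arcsinh transform -> gate ->
#' NK subset split -> marker-effect GLMs, LDA, and gated-frequency
#' comparisons, with every random draw derived from a single seed.
#'
#' @param simulation a [sim_config()], or `NULL` to load data from
#'   `input_files` instead.
#' @param input_files named character vector of per-donor-sample files
#'   (FCS or CSV; names = donor ids), used when `simulation` is `NULL`.
#' @param design a `study_design`; defaults to the simulated design.
#' @param cofactor arcsinh cofactor (default 5).
#' @param gates a [gate_tree()] ending in an `NK` population (default
#'   [default_nk_gates()]).
#' @param nk_thresholds list `(cd56_hi, cd56_lo, cd16_thr)` for the
#'   CD56dim/bright split.
#' @param glm_markers predictors for the marker-effect model (default: the
#'   receptor markers of the synthetic panel).
#' @param n_boot bootstrap resamples per model (default 200).
#' @param contrasts list of contrasts as in [compare_frequency_table()];
#'   each also drives one GLM per NK subset. Default: control vs pregnant
#'   (unpaired) and postpartum vs pregnant (paired).
#' @param freq_markers,freq_thresholds co-expression frequency definition
#'   (default CD38+NKp46+ above arcsinh threshold 1.5).
#' @param lda_lambda shrinkage for [fit_lda()] (`NULL` = automatic).
#' @param outdir output directory for artifacts.
#' @param seed master seed.
#' @param verbose print per-stage progress.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            input_files = NULL,
                            design = NULL,
                            cofactor = 5,
                            gates = default_nk_gates(),
                            nk_thresholds = list(cd56_hi = 3.3,
                                                 cd56_lo = 1.2,
                                                 cd16_thr = 1.5),
                            glm_markers = c("CD38", "NKp46", "NKG2A",
                                            "NKG2D", "NKp30", "CXCR3"),
                            n_boot = 200L,
                            contrasts = list(
                              list(groups = c("control", "pregnant"),
                                   paired = FALSE),
                              list(groups = c("postpartum", "pregnant"),
                                   paired = TRUE)),
                            freq_markers = c("CD38", "NKp46"),
                            freq_thresholds = c(1.5, 1.5),
                            lda_lambda = NULL,
                            outdir = tempfile("cytoboot_run_"),
                            seed = 1L,
                            verbose = FALSE) {
  if (is.null(simulation) && is.null(input_files)) {
    stop("either a simulation config or input files are required",
         call. = FALSE)
  }
  if (!(nk_thresholds$cd56_lo < nk_thresholds$cd56_hi)) {
    stop("cd56_lo must be below cd56_hi", call. = FALSE)
  }
  structure(list(simulation = simulation, input_files = input_files,
                 design = design, cofactor = cofactor, gates = gates,
                 nk_thresholds = nk_thresholds, glm_markers = glm_markers,
                 n_boot = as.integer(n_boot), contrasts = contrasts,
                 freq_markers = freq_markers,
                 freq_thresholds = freq_thresholds,
                 lda_lambda = lda_lambda, outdir = outdir,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order and writes plain-file artifacts
#' (gated subset tables, one marker-effect table per NK subset per
#' contrast, LDA projections and contributions per subset, the frequency
#' table and its comparisons) plus a manifest recording per-stage row
#' counts and an md5 checksum for every artifact. Two runs with the same
#' config and seed produce checksum-identical artifacts. A stage failure
#' aborts with the stage named in the error.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `cyto_run`: `manifest` (tibble), `effects`
#'   (named list of `marker_effects`), `lda` (named list of `cyto_lda`),
#'   `frequencies`, `comparisons`, `design`, `truth` (when simulated),
#'   `outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) if (config$verbose) message("[cytoboot] ", ...)
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  set.seed(config$seed)
  stage_seed <- sample.int(.Machine$integer.max - 1L, 64L)

  truth <- NULL
  if (!is.null(config$simulation)) {
    log_msg("simulate")
    simc <- config$simulation
    simc$seed <- stage_seed[1]
    sim <- with_stage("simulate", simulate_study(simc))
    samples <- sim$samples
    design <- sim$design
    truth <- sim$truth
    cofactor <- simc$cofactor
  } else {
    log_msg("load")
    design <- config$design
    if (is.null(design)) stop("input files need a design", call. = FALSE)
    samples <- with_stage("load", lapply(config$input_files, function(f) {
      if (grepl("\\.fcs$", f, ignore.case = TRUE)) read_fcs(f)
      else read_cell_table(f)
    }))
    for (d in names(samples)) {
      samples[[d]]$donor <- d
      samples[[d]]$group <- design$group[match(d, design$donor)]
      samples[[d]] <- restore_cell_tbl(samples[[d]], samples[[d]])
    }
    cofactor <- config$cofactor
  }

  log_msg("transform")
  cells <- with_stage("transform",
                      arcsinh_transform(bind_cells(samples), cofactor))
  with_stage("transform", validate_cells(cells, design))

  log_msg("gate")
  gated <- with_stage("gate", apply_gate_tree(cells, config$gates))
  if (!"NK" %in% names(gated)) {
    stop("stage 'gate' failed: gate tree defines no NK population",
         call. = FALSE)
  }
  nk <- gated$NK
  thr <- config$nk_thresholds
  subsets <- with_stage("gate", split_nk_subsets(
    nk, cd56_hi = thr$cd56_hi, cd56_lo = thr$cd56_lo,
    cd16_thr = thr$cd16_thr))

  artifacts <- list()
  add_artifact <- function(name, obj, artifacts) {
    path <- file.path(config$outdir, paste0(name, ".csv"))
    utils::write.table(as.data.frame(obj), path, sep = ",",
                       row.names = FALSE, quote = FALSE)
    artifacts[[name]] <- list(path = path, rows = nrow(obj))
    artifacts
  }
  for (s in names(subsets)) {
    artifacts <- add_artifact(paste0("gated_NK_", s), subsets[[s]],
                              artifacts)
  }

  log_msg("glm")
  effects <- list()
  seed_i <- 2L
  for (s in names(subsets)) {
    for (ct in config$contrasts) {
      spec <- model_spec(contrast = ct$groups,
                         markers = config$glm_markers,
                         n_boot = config$n_boot,
                         paired = isTRUE(ct$paired),
                         seed = stage_seed[seed_i])
      seed_i <- seed_i + 1L
      key <- paste0("effects_NK_", s, "_", ct$groups[1], "_vs_",
                    ct$groups[2])
      eff <- with_stage(paste0("glm:", key),
                        bootstrap_glm(subsets[[s]], design, spec))
      effects[[key]] <- eff
      artifacts <- add_artifact(key, effects_table(eff), artifacts)
    }
  }

  log_msg("lda")
  ldas <- list()
  for (s in names(subsets)) {
    key <- paste0("lda_NK_", s)
    med <- with_stage(key, donor_medians(subsets[[s]], config$glm_markers,
                                         design = design))
    fit <- with_stage(key, fit_lda(med, lambda = config$lda_lambda))
    ldas[[s]] <- fit
    artifacts <- add_artifact(paste0(key, "_projections"),
                              fit$projections, artifacts)
    artifacts <- add_artifact(paste0(key, "_contributions"),
                              fit$contributions, artifacts)
  }

  log_msg("stats")
  freqs <- with_stage("stats", dplyr::bind_rows(lapply(
    names(subsets), function(s) {
      positive_frequency(subsets[[s]], config$freq_markers,
                         config$freq_thresholds,
                         population = paste0("NK_", s),
                         donors = design$donor)
    })))
  comparisons <- with_stage("stats", compare_frequency_table(
    freqs, design, config$contrasts))
  artifacts <- add_artifact("frequencies", freqs, artifacts)
  artifacts <- add_artifact("comparisons", comparisons, artifacts)

  manifest <- tibble::tibble(
    artifact = names(artifacts),
    path = vapply(artifacts, function(a) a$path, character(1)),
    rows = vapply(artifacts, function(a) as.integer(a$rows), integer(1)),
    md5 = unname(tools::md5sum(vapply(artifacts, function(a) a$path,
                                      character(1)))))
  counts <- tibble::tibble(
    stage = c("input_cells", "gated_NK", "NK_dim", "NK_bright"),
    cells = c(nrow(cells), nrow(nk), nrow(subsets$dim),
              nrow(subsets$bright)))
  manifest_path <- file.path(config$outdir, "manifest.yaml")
  yaml::write_yaml(list(seed = config$seed,
                        stage_cells = stats::setNames(
                          as.list(counts$cells), counts$stage),
                        artifacts = stats::setNames(
                          lapply(seq_len(nrow(manifest)), function(i)
                            list(rows = manifest$rows[i],
                                 md5 = unname(manifest$md5[i]))),
                          manifest$artifact)),
                   manifest_path)

  structure(list(manifest = manifest, stage_cells = counts,
                 effects = effects, lda = ldas, frequencies = freqs,
                 comparisons = comparisons, design = design,
                 truth = truth, outdir = config$outdir,
                 config = config),
            class = "cyto_run")
}

#' @export
print.cyto_run <- function(x, ...) {
  cat("cytoboot run:", nrow(x$manifest), "artifacts in", x$outdir, "\n")
  print(x$stage_cells)
  invisible(x)
}
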