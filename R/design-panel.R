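#' Study designs: donors, groups, cohorts and pregnant/post-partum pairing
#'
#' A study design is a tibble with one row per donor-sample: `donor`,
#' `group` (one of `control`, `pregnant`, `postpartum`), `cohort`
#' (`discovery` or `validation` by convention) and `paired_with`, which for
#' a pregnant donor names the post-partum sample from the same woman (and
#' vice versa). The pairing must be a bijection on its domain and must link
#' a pregnant sample to a post-partum one.
#'
#' @param donors tibble/data frame with columns `donor`, `group`, and
#'   optionally `cohort` and `paired_with` (NA = unpaired).
#' @return A validated tibble of class `study_design`.
#' @export
study_design <- function(donors) {
  d <- tibble::as_tibble(donors)
  stopifnot(all(c("donor", "group") %in% names(d)))
  d$donor <- as.character(d$donor)
  d$group <- as.character(d$group)
  if (!"cohort" %in% names(d)) d$cohort <- "discovery"
  if (!"paired_with" %in% names(d)) d$paired_with <- NA_character_
  d$paired_with <- as.character(d$paired_with)
  d <- d[, c("donor", "group", "cohort", "paired_with")]

  if (anyDuplicated(d$donor)) {
    stop("duplicated donor ids: ",
         paste(unique(d$donor[duplicated(d$donor)]), collapse = ", "),
         call. = FALSE)
  }
  bad_group <- setdiff(unique(d$group), c("control", "pregnant", "postpartum"))
  if (length(bad_group)) {
    stop("unknown group labels: ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  }
  paired <- d[!is.na(d$paired_with), ]
  if (nrow(paired)) {
    missing <- setdiff(paired$paired_with, d$donor)
    if (length(missing)) {
      stop("paired_with references unknown donors: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (any(paired$donor == paired$paired_with)) {
      stop("a donor cannot be paired with itself", call. = FALSE)
    }
    # bijection: the partner must point back
    back <- d$paired_with[match(paired$paired_with, d$donor)]
    if (any(is.na(back)) || any(back != paired$donor)) {
      stop("pairing is not a bijection: partner does not point back",
           call. = FALSE)
    }
    g1 <- paired$group
    g2 <- d$group[match(paired$paired_with, d$donor)]
    ok <- (g1 == "pregnant" & g2 == "postpartum") |
      (g1 == "postpartum" & g2 == "pregnant")
    if (!all(ok)) {
      stop("pairs must link a pregnant sample to a postpartum sample",
           call. = FALSE)
    }
  }
  class(d) <- c("study_design", class(tibble::tibble()))
  d
}

#' Complete pregnant/post-partum pairs of a design
#' @param design a `study_design`.
#' @return Tibble with columns `pregnant`, `postpartum`, one row per pair.
#' @export
design_pairs <- function(design) {
  p <- design[design$group == "pregnant" & !is.na(design$paired_with), ]
  tibble::tibble(pregnant = p$donor, postpartum = p$paired_with)
}

#' Panel definitions
#'
#' The antibody panel maps marker names to metal/channel tags and a broad
#' functional category. Panel content is configuration, not hard-coded:
#' discovery and validation cohorts may carry different panels.
#'
#' @param entries tibble/data frame with columns `marker`, `tag` and
#'   optionally `category` (one of `lineage`, `activating`, `inhibitory`,
#'   `functional`, `viability`, `other`).
#' @return A tibble of class `panel_def`.
#' @export
panel_def <- function(entries) {
  p <- tibble::as_tibble(entries)
  stopifnot(all(c("marker", "tag") %in% names(p)))
  if (!"category" %in% names(p)) p$category <- "other"
  bad <- setdiff(unique(p$category),
                 c("lineage", "activating", "inhibitory", "functional",
                   "viability", "other"))
  if (length(bad)) {
    stop("unknown panel categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(p$marker)) {
    stop("duplicated marker names in panel", call. = FALSE)
  }
  p <- p[, c("marker", "tag", "category")]
  class(p) <- c("panel_def", class(tibble::tibble()))
  p
}

#' Check that markers resolve in a panel
#' @param markers character vector of marker names.
#' @param panel a `panel_def`.
#' @return `markers`, invisibly; errors naming unresolved markers otherwise.
#' @export
resolve_markers <- function(markers, panel) {
  missing <- setdiff(markers, panel$marker)
  if (length(missing)) {
    stop("markers not in panel: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(markers)
}
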