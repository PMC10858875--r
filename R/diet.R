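FOOD_TYPES <- c("fruit", "leaf", "flower", "animal", "other")

#' Daily diet composition from feeding bouts
#'
#' For each individual-day, feeding times of the same food type are summed
#' and divided by the total full-day feeding time. Bouts of one
#' individual-day must not overlap.
#'
#' @param bouts Tibble with `individual`, `date`, `food_type` (one of
#'   fruit/leaf/flower/animal/other), `start_min`, `end_min` (minutes since
#'   day start, `end_min > start_min`).
#' @return Tibble with one row per individual-day and proportion columns
#'   `fruit`, `leaf`, `flower`, `animal`, `other` (rows sum to 1).
#' @export
diet_composition <- function(bouts) {
  req <- c("individual", "date", "food_type", "start_min", "end_min")
  stopifnot(all(req %in% names(bouts)))
  if (!all(bouts$food_type %in% FOOD_TYPES)) {
    stop("unknown food_type: ",
         paste(setdiff(bouts$food_type, FOOD_TYPES), collapse = ", "))
  }
  if (any(bouts$end_min <= bouts$start_min)) {
    stop("bout end_min must exceed start_min")
  }
  check <- bouts |>
    dplyr::group_by(.data$individual, .data$date) |>
    dplyr::arrange(.data$start_min, .by_group = TRUE) |>
    dplyr::summarise(
      overlap = any(.data$start_min[-1] <
                      utils::head(.data$end_min, -1)),
      total = sum(.data$end_min - .data$start_min),
      .groups = "drop"
    )
  if (any(check$overlap)) stop("overlapping bouts within an individual-day")
  if (any(check$total <= 0)) stop("zero total feeding time")
  bouts |>
    dplyr::mutate(dur = .data$end_min - .data$start_min) |>
    dplyr::group_by(.data$individual, .data$date, .data$food_type) |>
    dplyr::summarise(dur = sum(.data$dur), .groups = "drop") |>
    tidyr::complete(tidyr::nesting(individual, date),
                    food_type = FOOD_TYPES, fill = list(dur = 0)) |>
    dplyr::group_by(.data$individual, .data$date) |>
    dplyr::mutate(prop = .data$dur / sum(.data$dur)) |>
    dplyr::ungroup() |>
    dplyr::select(-"dur") |>
    tidyr::pivot_wider(names_from = "food_type", values_from = "prop") |>
    dplyr::select("individual", "date", dplyr::all_of(FOOD_TYPES))
}

#' Assign high-fruit / high-leaf seasons by hierarchical clustering
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances between
#' the diet-proportion vectors) cut at k = 2; the cluster with the higher
#' mean fruit proportion is labelled `HF`, the other `HL`. The labelling is
#' invariant to the input row order. If all profiles are identical the cut
#' collapses and a single-season warning is issued.
#'
#' @param profiles Output of [diet_composition()].
#' @return `profiles` with a `season` column.
#' @export
assign_seasons <- function(profiles) {
  stopifnot(all(FOOD_TYPES %in% names(profiles)))
  if (nrow(profiles) < 4) stop("need at least 4 diet profiles")
  m <- as.matrix(profiles[, FOOD_TYPES])
  if (all(stats::dist(m) == 0)) {
    warning("all diet profiles identical: assigning a single HF season")
    return(dplyr::mutate(profiles, season = "HF"))
  }
  cl <- stats::cutree(stats::hclust(stats::dist(m), method = "ward.D2"),
                      k = 2)
  fruit_means <- tapply(profiles$fruit, cl, mean)
  hf <- as.integer(names(which.max(fruit_means)))
  dplyr::mutate(profiles, season = ifelse(cl == hf, "HF", "HL"))
}

#' Identify diet-responsive populations
#'
#' Per population, a two-sided unpaired Wilcoxon rank-sum test compares
#' abundances between the two seasons (exact distribution where
#' `stats::wilcox.test` permits, normal approximation with continuity and
#' tie correction otherwise; populations constant over all samples take
#' p = 1). P-values are BH-adjusted across the populations tested and a
#' population is called responsive iff q < `alpha`.
#'
#' @param abundance Long abundance tibble for one individual (and
#'   typically one lifestyle, which defines the BH family).
#' @param seasons Tibble `sample_id`, `season` (`HF`/`HL`).
#' @param alpha FDR threshold (default 0.05).
#' @return Tibble `population_id`, `p`, `q`, `responsive`.
#' @export
test_diet_responsive <- function(abundance, seasons, alpha = 0.05) {
  dat <- dplyr::inner_join(abundance, seasons, by = "sample_id")
  ns <- table(unique(dat[, c("sample_id", "season")])$season)
  if (!all(c("HF", "HL") %in% names(ns)) || any(ns == 0)) {
    stop("both seasons must be represented in the samples")
  }
  if (any(ns < 3)) {
    warning("fewer than 3 samples in a season: test under-powered")
  }
  res <- dat |>
    dplyr::group_by(.data$population_id) |>
    dplyr::summarise(p = {
      x <- .data$abundance[.data$season == "HF"]
      y <- .data$abundance[.data$season == "HL"]
      if (length(unique(c(x, y))) == 1) 1
      else suppressWarnings(
        stats::wilcox.test(x, y, alternative = "two.sided",
                           paired = FALSE)$p.value)
    }, .groups = "drop")
  res |>
    dplyr::mutate(q = bh_adjust(.data$p),
                  responsive = .data$q < alpha)
}

#' Seasonal abundance variation per population and host family
#'
#' The variation of a population is its mean abundance in the high-leaf
#' season minus its mean abundance in the high-fruit season. Family
#' aggregates sum the deltas of populations linked to that family;
#' populations without a host link stay in the per-population table but
#' are excluded from aggregates.
#'
#' @param abundance Long abundance tibble.
#' @param seasons Tibble `sample_id`, `season`.
#' @param host_families Optional tibble `population_id`, `family`.
#' @return List of tibbles `per_population` (`population_id`, `delta`)
#'   and `per_family` (`family`, `delta`; empty if no family map given).
#' @export
abundance_variation <- function(abundance, seasons, host_families = NULL) {
  dat <- dplyr::inner_join(abundance, seasons, by = "sample_id")
  if (!all(c("HF", "HL") %in% dat$season)) {
    stop("both seasons must be non-empty")
  }
  per_pop <- dat |>
    dplyr::group_by(.data$population_id) |>
    dplyr::summarise(
      delta = mean(.data$abundance[.data$season == "HL"]) -
        mean(.data$abundance[.data$season == "HF"]),
      .groups = "drop"
    )
  per_family <- tibble::tibble(family = character(), delta = double())
  if (!is.null(host_families)) {
    per_family <- per_pop |>
      dplyr::inner_join(host_families, by = "population_id",
                        relationship = "many-to-many") |>
      dplyr::group_by(.data$family) |>
      dplyr::summarise(delta = sum(.data$delta), .groups = "drop")
  }
  list(per_population = per_pop, per_family = per_family)
}
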