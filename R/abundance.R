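#' Filter read alignments by identity and aligned read fraction
#'
#' Keeps a hit iff its percent identity is at least `min_identity` and the
#' aligned length covers at least `min_aligned_frac` of the read.
#'
#' @param hits Alignment tibble carrying a `read_length` column.
#' @param min_identity Minimum percent identity (default 95).
#' @param min_aligned_frac Minimum aligned fraction of the read
#'   (default 0.75).
#' @return The kept hits.
#' @export
filter_read_alignments <- function(hits, min_identity = 95,
                                   min_aligned_frac = 0.75) {
  stopifnot("read_length" %in% names(hits))
  if (any(hits$read_length <= 0)) stop("read_length must be positive")
  dplyr::filter(tibble::as_tibble(hits),
                .data$pct_identity >= min_identity,
                .data$aln_length / .data$read_length >= min_aligned_frac)
}

#' Trimmed-mean (tpmean) coverage from per-base depth profiles
#'
#' For each genome-sample profile, the `floor(trim_frac * L)` positions of
#' lowest depth and the same number of highest depth are discarded
#' (rank-based, not contiguous windows) and the remaining depths averaged.
#' With `trim_frac = 0` this is the plain positional mean; the result is
#' always bounded by the minimum and maximum positional depth.
#'
#' @param depth Tibble with `genome_id`, `sample_id`, `position`, `depth`.
#' @param trim_frac Fraction trimmed from each extreme (default 0.05).
#' @return Tibble `genome_id`, `sample_id`, `coverage`.
#' @export
tpmean_coverage <- function(depth, trim_frac = 0.05) {
  stopifnot(all(c("genome_id", "sample_id", "position", "depth") %in%
                  names(depth)),
            trim_frac >= 0, trim_frac < 0.5)
  if (nrow(depth) == 0) stop("empty depth profile")
  if (any(depth$depth < 0)) stop("depths must be >= 0")
  depth |>
    dplyr::group_by(.data$genome_id, .data$sample_id) |>
    dplyr::summarise(coverage = {
      d <- sort(.data$depth)
      k <- floor(trim_frac * length(d))
      if (length(d) < 20 && trim_frac > 0) {
        warning("profile shorter than 20 positions: trimming degenerate")
      }
      mean(d[seq.int(k + 1L, length(d) - k)])
    }, .groups = "drop")
}

#' Hellinger transformation of a long abundance table
#'
#' Each value becomes `sqrt(value / sample_total)`, so within every sample
#' the squared transformed values sum to one. All-zero samples are left at
#' zero with a warning.
#'
#' @param abundance Long tibble with `population_id`, `sample_id`,
#'   `abundance` (>= 0).
#' @return Same shape with transformed `abundance`.
#' @export
hellinger_transform <- function(abundance) {
  stopifnot(all(c("population_id", "sample_id", "abundance") %in%
                  names(abundance)))
  if (any(abundance$abundance < 0)) stop("abundances must be >= 0")
  out <- abundance |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(.tot = sum(.data$abundance)) |>
    dplyr::ungroup()
  if (any(out$.tot == 0)) {
    warning("all-zero sample(s) left untransformed: ",
            paste(unique(out$sample_id[out$.tot == 0]), collapse = ", "))
  }
  out |>
    dplyr::mutate(abundance = ifelse(.data$.tot > 0,
                                     sqrt(.data$abundance / .data$.tot),
                                     0)) |>
    dplyr::select(-".tot")
}

#' Protein-cluster abundance from population abundance
#'
#' The abundance of a protein cluster in a sample is the summed abundance
#' of the distinct phage populations encoding at least one protein in that
#' cluster; a population contributing several proteins is counted once, so
#' the operation is linear in the population matrix.
#'
#' @param pc_membership Tibble with `pc_id`, `population_id` (duplicates
#'   collapse).
#' @param abundance Long population abundance tibble.
#' @return Long tibble `pc_id`, `sample_id`, `abundance`.
#' @export
pc_abundance <- function(pc_membership, abundance) {
  stopifnot(all(c("pc_id", "population_id") %in% names(pc_membership)))
  members <- dplyr::distinct(pc_membership, .data$pc_id,
                             .data$population_id)
  missing <- setdiff(members$population_id,
                     unique(abundance$population_id))
  if (length(missing) > 0) {
    warning("population(s) absent from abundance matrix treated as zero: ",
            paste(missing, collapse = ", "))
  }
  samples <- unique(abundance$sample_id)
  members |>
    dplyr::inner_join(abundance, by = "population_id",
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$pc_id, .data$sample_id) |>
    dplyr::summarise(abundance = sum(.data$abundance), .groups = "drop") |>
    tidyr::complete(pc_id = unique(members$pc_id), sample_id = samples,
                    fill = list(abundance = 0))
}

#' Prevalence and mean relative abundance per population
#'
#' Prevalence is the percentage of samples in which the population is
#' detected (abundance > 0). Relative abundance is computed within each
#' sample (value / sample total, in percent) and then averaged over all
#' samples, zeros included.
#'
#' @param abundance Long raw abundance tibble.
#' @param populations Optional character vector restricting the output.
#' @return Tibble `population_id`, `prevalence_pct`,
#'   `mean_rel_abundance_pct`.
#' @export
prevalence_and_mean_abundance <- function(abundance, populations = NULL) {
  rel <- abundance |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(rel = ifelse(sum(.data$abundance) > 0,
                               100 * .data$abundance /
                                 sum(.data$abundance), 0)) |>
    dplyr::ungroup()
  out <- rel |>
    dplyr::group_by(.data$population_id) |>
    dplyr::summarise(prevalence_pct = 100 * mean(.data$abundance > 0),
                     mean_rel_abundance_pct = mean(.data$rel),
                     .groups = "drop")
  if (!is.null(populations)) {
    out <- out[out$population_id %in% populations, ]
  }
  out
}

#' Pivot a long abundance table to a populations-by-samples matrix
#'
#' @param abundance Long tibble (`population_id`, `sample_id`,
#'   `abundance`); absent combinations fill as zero.
#' @return A numeric matrix, rows = populations, columns = samples.
#' @export
abundance_matrix <- function(abundance) {
  wide <- abundance |>
    dplyr::select("population_id", "sample_id", "abundance") |>
    tidyr::pivot_wider(names_from = "sample_id",
                       values_from = "abundance", values_fill = 0) |>
    dplyr::arrange(.data$population_id)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$population_id
  m
}
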