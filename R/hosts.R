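#' Link phage populations to prokaryotes by exact CRISPR-spacer matches
#'
#' A link is created iff the whole spacer occurs with zero mismatches in a
#' phage genome on either strand. Genome-level matches are aggregated to
#' the population level (a population links to a prokaryote as soon as any
#' member genome matches). Spacers with non-ACGT symbols are skipped with a
#' warning; spacers shorter than 20 nt are rejected.
#'
#' @param spacers Tibble `spacer_id`, `host_id`, `sequence`.
#' @param genomes Tibble `genome_id`, `sequence`.
#' @param populations Tibble `genome_id`, `population_id`.
#' @return Tibble `phage_pop_id`, `prok_id`, `evidence = "spacer"`,
#'   `detail` (matching spacer IDs, comma-separated).
#' @export
match_spacers <- function(spacers, genomes, populations) {
  stopifnot(all(c("spacer_id", "host_id", "sequence") %in% names(spacers)),
            all(c("genome_id", "sequence") %in% names(genomes)))
  clean <- grepl("^[ACGT]+$", spacers$sequence)
  if (any(!clean)) {
    warning("skipping spacer(s) with non-ACGT symbols: ",
            paste(spacers$spacer_id[!clean], collapse = ", "))
    spacers <- spacers[clean, ]
  }
  if (any(nchar(spacers$sequence) < 20)) {
    stop("spacer(s) shorter than 20 nt")
  }
  subject <- Biostrings::DNAStringSet(genomes$sequence)
  names(subject) <- genomes$genome_id
  hits <- purrr::map_dfr(seq_len(nrow(spacers)), function(i) {
    sp <- Biostrings::DNAString(spacers$sequence[i])
    fwd <- Biostrings::vcountPattern(sp, subject, max.mismatch = 0)
    rev <- Biostrings::vcountPattern(Biostrings::reverseComplement(sp),
                                     subject, max.mismatch = 0)
    hit <- which(fwd + rev > 0)
    if (length(hit) == 0) return(NULL)
    tibble::tibble(spacer_id = spacers$spacer_id[i],
                   host_id = spacers$host_id[i],
                   genome_id = genomes$genome_id[hit])
  })
  if (nrow(hits) == 0) {
    return(tibble::tibble(phage_pop_id = character(),
                          prok_id = character(),
                          evidence = character(), detail = character()))
  }
  hits |>
    dplyr::inner_join(populations, by = "genome_id") |>
    dplyr::group_by(phage_pop_id = .data$population_id,
                    prok_id = .data$host_id) |>
    dplyr::summarise(evidence = "spacer",
                     detail = paste(sort(unique(.data$spacer_id)),
                                    collapse = ","),
                     .groups = "drop")
}

#' Link phage populations to prokaryotes by genome homology
#'
#' A phage-vs-prokaryote alignment hit supports a link iff
#' `evalue <= evalue_max`, `bit_score >= bitscore_min`,
#' `aln_length >= min_len` and `pct_identity >= min_ident`
#' (all boundaries inclusive). Hits are oriented phage = query.
#'
#' @param hits Alignment tibble (phage genome = `query_id`, prokaryote =
#'   `subject_id`).
#' @param populations Tibble `genome_id`, `population_id` for the phage
#'   side.
#' @param evalue_max,bitscore_min,min_len,min_ident Thresholds
#'   (defaults 1e-3, 50, 1000, 96).
#' @return Tibble `phage_pop_id`, `prok_id`, `evidence = "homology"`,
#'   `detail`.
#' @export
match_genome_homology <- function(hits, populations, evalue_max = 1e-3,
                                  bitscore_min = 50, min_len = 1000,
                                  min_ident = 96) {
  keep <- hits |>
    dplyr::filter(.data$evalue <= evalue_max,
                  .data$bit_score >= bitscore_min,
                  .data$aln_length >= min_len,
                  .data$pct_identity >= min_ident)
  if (nrow(keep) == 0) {
    return(tibble::tibble(phage_pop_id = character(),
                          prok_id = character(),
                          evidence = character(), detail = character()))
  }
  keep |>
    dplyr::inner_join(populations, by = c(query_id = "genome_id")) |>
    dplyr::group_by(phage_pop_id = .data$population_id,
                    prok_id = .data$subject_id) |>
    dplyr::summarise(
      evidence = "homology",
      detail = sprintf("best_bits=%.1f", max(.data$bit_score)),
      .groups = "drop"
    )
}

#' Host range and phage range from a link table
#'
#' Host range is the number of distinct prokaryotic partners per phage
#' population; phage range is the number of distinct phage populations per
#' prokaryote. Prokaryotes are additionally annotated with the lifestyles
#' of the phages assigned to them (a prokaryote linked to both lifestyles
#' appears in both lifestyle groups).
#'
#' @param links Link tibble (`phage_pop_id`, `prok_id`).
#' @param lifestyles Tibble `phage_pop_id`, `lifestyle`.
#' @return List of tibbles `host_range` (`phage_pop_id`, `lifestyle`,
#'   `host_range`) and `phage_range` (`prok_id`, `lifestyle`,
#'   `phage_range` = populations of that lifestyle linked to the
#'   prokaryote).
#' @export
host_and_phage_range <- function(links, lifestyles) {
  if (nrow(links) == 0) {
    return(list(host_range = tibble::tibble(phage_pop_id = character(),
                                            lifestyle = character(),
                                            host_range = integer()),
                phage_range = tibble::tibble(prok_id = character(),
                                             lifestyle = character(),
                                             phage_range = integer())))
  }
  ll <- dplyr::left_join(links, lifestyles, by = "phage_pop_id")
  host_range <- ll |>
    dplyr::group_by(.data$phage_pop_id, .data$lifestyle) |>
    dplyr::summarise(host_range = dplyr::n_distinct(.data$prok_id),
                     .groups = "drop")
  phage_range <- ll |>
    dplyr::group_by(.data$prok_id, .data$lifestyle) |>
    dplyr::summarise(phage_range = dplyr::n_distinct(.data$phage_pop_id),
                     .groups = "drop")
  list(host_range = host_range, phage_range = phage_range)
}

#' Phage-host abundance correlations per link
#'
#' Pearson correlation between each linked phage population's and
#' prokaryote's abundance over their shared samples (at least 5 required);
#' zero-variance series are excluded with a warning. Q-values are
#' BH-adjusted across the links tested.
#'
#' @param phage_ab,prok_ab Long abundance tibbles (`population_id`,
#'   `sample_id`, `abundance`).
#' @param links Link tibble (`phage_pop_id`, `prok_id`).
#' @param lifestyles Optional tibble `phage_pop_id`, `lifestyle` for the
#'   per-lifestyle summary.
#' @return List with `correlations` (per link: `r`, `p`, `q`) and
#'   `summary` (mean r per lifestyle; empty without `lifestyles`).
#' @export
phage_host_correlation <- function(phage_ab, prok_ab, links,
                                   lifestyles = NULL) {
  res <- purrr::map_dfr(seq_len(nrow(links)), function(i) {
    px <- phage_ab[phage_ab$population_id == links$phage_pop_id[i], ]
    hx <- prok_ab[prok_ab$population_id == links$prok_id[i], ]
    shared <- intersect(px$sample_id, hx$sample_id)
    if (length(shared) < 5) return(NULL)
    x <- px$abundance[match(shared, px$sample_id)]
    y <- hx$abundance[match(shared, hx$sample_id)]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero-variance series for link ", links$phage_pop_id[i],
              " ~ ", links$prok_id[i], ": excluded")
      return(NULL)
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    tibble::tibble(phage_pop_id = links$phage_pop_id[i],
                   prok_id = links$prok_id[i],
                   n = length(shared),
                   r = unname(ct$estimate), p = ct$p.value)
  })
  if (nrow(res) > 0) res$q <- bh_adjust(res$p)
  summary <- tibble::tibble(lifestyle = character(), mean_r = double())
  if (!is.null(lifestyles) && nrow(res) > 0) {
    summary <- res |>
      dplyr::left_join(lifestyles, by = "phage_pop_id") |>
      dplyr::group_by(.data$lifestyle) |>
      dplyr::summarise(mean_r = mean(.data$r), .groups = "drop")
  }
  list(correlations = res, summary = summary)
}

#' Anti-phage defense-system burden by assigned phage lifestyle
#'
#' Sums system instances per prokaryote genome (instances, not distinct
#' system types, unless `distinct_types = TRUE`) and summarizes the totals
#' for prokaryotes assigned virulent vs temperate phages. Genomes in an
#' assignment set but absent from the defense table count 0 with a warning.
#'
#' @param defense Tibble `prok_genome_id`, `system_name`, `count`.
#' @param assignments Tibble `prok_id`, `lifestyle` (a genome may appear
#'   in both lifestyle groups).
#' @param distinct_types Count distinct system types instead of instances.
#' @return List with `per_genome` (`prok_id`, `total_systems`) and
#'   `by_group` (`lifestyle`, `n`, `mean_systems`, `sd_systems`).
#' @export
defense_burden <- function(defense, assignments, distinct_types = FALSE) {
  if (any(defense$count < 0)) stop("defense counts must be >= 0")
  per_genome <- defense |>
    dplyr::group_by(prok_id = .data$prok_genome_id) |>
    dplyr::summarise(total_systems = if (distinct_types)
      sum(.data$count > 0) else sum(.data$count), .groups = "drop")
  missing <- setdiff(unique(assignments$prok_id), per_genome$prok_id)
  if (length(missing) > 0) {
    warning("genome(s) absent from defense table counted as 0: ",
            paste(missing, collapse = ", "))
    per_genome <- dplyr::bind_rows(
      per_genome, tibble::tibble(prok_id = missing, total_systems = 0))
  }
  by_group <- assignments |>
    dplyr::distinct(.data$prok_id, .data$lifestyle) |>
    dplyr::left_join(per_genome, by = "prok_id") |>
    dplyr::group_by(.data$lifestyle) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_systems = mean(.data$total_systems),
                     sd_systems = stats::sd(.data$total_systems),
                     .groups = "drop")
  if (any(by_group$n == 0)) warning("empty assignment group")
  list(per_genome = per_genome, by_group = by_group)
}
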