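#' Screen candidate phage contigs by gene-content rule
#'
#' A contig is kept iff it has at least one phage (viral) gene, or no viral
#' gene together with either no host gene or more than two hallmark genes:
#' `viral >= 1 OR (viral == 0 AND (host == 0 OR hallmark > 2))`. The rule is
#' monotone in the viral-gene count: adding a viral gene can never flip a
#' kept contig to dropped.
#'
#' @param summaries Tibble with columns `contig_id`, `viral_genes`,
#'   `host_genes`, `hallmark_genes` (counts, >= 0).
#' @return The input with a logical `keep` column.
#' @export
screen_phage_candidates <- function(summaries) {
  req <- c("contig_id", "viral_genes", "host_genes", "hallmark_genes")
  stopifnot(all(req %in% names(summaries)))
  counts <- summaries[, c("viral_genes", "host_genes", "hallmark_genes")]
  if (any(unlist(counts) < 0)) stop("gene counts must be >= 0")
  dplyr::mutate(
    tibble::as_tibble(summaries),
    keep = .data$viral_genes >= 1 |
      (.data$viral_genes == 0 &
         (.data$host_genes == 0 | .data$hallmark_genes > 2))
  )
}

#' Select the genetic code for each contig
#'
#' Only contigs longer than 10 kb with GC content below 50% are eligible
#' for recoding. An alternative code (4, 25, 15 or 91) is chosen iff its
#' coding score is the unique maximum over all codes and at least 10%
#' higher than the standard code 11 score; everything else stays code 11.
#' A tie between two codes at the maximal score conservatively keeps 11.
#'
#' @param scores Long tibble with `contig_id`, `code` (one of 11, 4, 25,
#'   15, 91; 11 must be present for every contig), `score`.
#' @param contigs Tibble with `contig_id`, `length`, `gc` (percent).
#' @param margin Required relative advantage over code 11 (default 0.10).
#' @return Tibble `contig_id`, `genetic_code`.
#' @export
select_genetic_code <- function(scores, contigs, margin = 0.10) {
  stopifnot(all(c("contig_id", "code", "score") %in% names(scores)),
            all(c("contig_id", "length", "gc") %in% names(contigs)))
  if (!all(is.finite(scores$score))) stop("coding scores must be finite")
  per <- scores |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::group_modify(function(df, key) {
      s11 <- df$score[df$code == 11]
      if (length(s11) != 1) {
        stop("missing (or duplicated) code-11 score for ", key$contig_id)
      }
      mx <- max(df$score)
      at_max <- df$code[df$score == mx]
      best <- if (length(at_max) == 1 && at_max != 11 &&
                  mx >= (1 + margin) * s11) at_max else 11L
      tibble::tibble(candidate_code = as.integer(best))
    }) |>
    dplyr::ungroup()
  contigs |>
    dplyr::select("contig_id", "length", "gc") |>
    dplyr::left_join(per, by = "contig_id") |>
    dplyr::mutate(genetic_code = ifelse(
      .data$length > 10000 & .data$gc < 50,
      .data$candidate_code, 11L)) |>
    dplyr::select("contig_id", "genetic_code")
}

#' Validate recoded contigs by annotation support
#'
#' A recoded contig is kept iff it carries at least one hallmark protein,
#' or at least half of its annotated genes hit a phage reference. Contigs
#' with zero annotated genes are dropped with a warning (the ratio is
#' undefined).
#'
#' @param annotations Tibble with `contig_id`, `n_genes`, `n_phage_hits`,
#'   `n_hallmark`.
#' @return Input with a logical `keep` column.
#' @export
validate_recoded_contigs <- function(annotations) {
  req <- c("contig_id", "n_genes", "n_phage_hits", "n_hallmark")
  stopifnot(all(req %in% names(annotations)))
  out <- tibble::as_tibble(annotations)
  zero <- out$n_genes == 0
  if (any(zero)) {
    warning("dropping recoded contig(s) with zero annotated genes: ",
            paste(out$contig_id[zero], collapse = ", "))
  }
  dplyr::mutate(out, keep = .data$n_hallmark >= 1 |
                  (.data$n_genes > 0 &
                     .data$n_phage_hits / .data$n_genes >= 0.5))
}

#' Resolve phage lifestyle from prophage flags and episomal labels
#'
#' Prophages are temperate by definition; episomal genomes take the label
#' assigned by the lifestyle classifier. Supplying an episomal label for a
#' prophage is an input error (the label must be present iff the genome is
#' episomal).
#'
#' @param records Tibble with `genome_id`, `is_prophage` (logical) and
#'   `episomal_label` (`"virulent"`/`"temperate"`, `NA` for prophages).
#' @return Input with a `lifestyle` column.
#' @export
resolve_lifestyle <- function(records) {
  stopifnot(all(c("genome_id", "is_prophage", "episomal_label") %in%
                  names(records)))
  bad <- records$is_prophage & !is.na(records$episomal_label)
  if (any(bad)) {
    stop("episomal label supplied for prophage(s): ",
         paste(records$genome_id[bad], collapse = ", "))
  }
  bad2 <- !records$is_prophage & is.na(records$episomal_label)
  if (any(bad2)) {
    stop("missing episomal label for non-prophage genome(s): ",
         paste(records$genome_id[bad2], collapse = ", "))
  }
  if (!all(records$episomal_label[!records$is_prophage] %in%
           c("virulent", "temperate"))) {
    stop("episomal_label must be 'virulent' or 'temperate'")
  }
  dplyr::mutate(tibble::as_tibble(records),
                lifestyle = ifelse(.data$is_prophage, "temperate",
                                   .data$episomal_label))
}
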