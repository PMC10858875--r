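#' Compute ANI and aligned fractions for one genome pair
#'
#' Implements the fragment-merging convention used by CheckV's anicalc:
#' local-alignment fragments are visited in decreasing bit-score order and a
#' fragment is retained only where it covers at least one query base not
#' already covered by a previously kept fragment; the ANI is the mean of the
#' fragment identities weighted by their novel (newly covered) query length.
#' The aligned fraction of each genome is the union of kept fragment
#' intervals on that genome divided by its length.
#'
#' @param hits Alignment-hit tibble (see [read_alignment_table()]) for one
#'   ordered pair: `query_id` = genome a, `subject_id` = genome b.
#' @param len_a,len_b Genome lengths in bases.
#' @return One-row tibble: `genome_a`, `genome_b`, `ani`, `af_a`, `af_b`
#'   (percent). No hits gives `ani = 0`, `af = 0`.
#' @export
compute_ani_af <- function(hits, len_a, len_b) {
  if (nrow(hits) == 0) {
    return(tibble::tibble(genome_a = NA_character_, genome_b = NA_character_,
                          ani = 0, af_a = 0, af_b = 0))
  }
  stopifnot(length(unique(hits$query_id)) == 1,
            length(unique(hits$subject_id)) == 1)
  ord <- order(-hits$bit_score, hits$q_start)
  covered_a <- logical(len_a)
  covered_b <- logical(len_b)
  wsum <- 0; isum <- 0
  for (i in ord) {
    qs <- min(hits$q_start[i], hits$q_end[i])
    qe <- max(hits$q_start[i], hits$q_end[i])
    idx <- qs:qe
    novel <- idx[!covered_a[idx]]
    if (length(novel) >= 1) {
      covered_a[novel] <- TRUE
      ss <- min(hits$s_start[i], hits$s_end[i])
      se <- max(hits$s_start[i], hits$s_end[i])
      covered_b[ss:se] <- TRUE
      wsum <- wsum + length(novel)
      isum <- isum + length(novel) * hits$pct_identity[i]
    }
  }
  tibble::tibble(
    genome_a = hits$query_id[1], genome_b = hits$subject_id[1],
    ani = if (wsum > 0) isum / wsum else 0,
    af_a = 100 * sum(covered_a) / len_a,
    af_b = 100 * sum(covered_b) / len_b
  )
}

#' Compute the pairwise ANI/AF table from a full alignment-hit table
#'
#' @param hits Alignment hits covering any number of genome pairs
#'   (self-hits are discarded).
#' @param genomes Tibble with `genome_id`, `length`.
#' @return Tibble of per-unordered-pair records (`genome_a < genome_b`)
#'   with `ani`, `af_a`, `af_b`.
#' @export
ani_table <- function(hits, genomes) {
  stopifnot(all(c("genome_id", "length") %in% names(genomes)))
  glen <- stats::setNames(genomes$length, genomes$genome_id)
  hits <- hits[hits$query_id != hits$subject_id, ]
  if (nrow(hits) == 0) {
    return(tibble::tibble(genome_a = character(), genome_b = character(),
                          ani = double(), af_a = double(), af_b = double()))
  }
  # orient every hit so query < subject lexicographically
  flip <- hits$query_id > hits$subject_id
  oriented <- hits
  oriented[flip, c("query_id", "subject_id")] <-
    hits[flip, c("subject_id", "query_id")]
  oriented[flip, c("q_start", "q_end", "s_start", "s_end")] <-
    hits[flip, c("s_start", "s_end", "q_start", "q_end")]
  oriented |>
    dplyr::group_by(.data$query_id, .data$subject_id) |>
    dplyr::group_map(function(df, key) {
      df$query_id <- key$query_id
      df$subject_id <- key$subject_id
      compute_ani_af(df, glen[[key$query_id]], glen[[key$subject_id]])
    }) |>
    dplyr::bind_rows() |>
    dplyr::distinct(.data$genome_a, .data$genome_b, .keep_all = TRUE)
}

#' Greedy centroid clustering of genomes into vOTUs
#'
#' Genomes are visited in decreasing length order (ties broken by
#' lexicographic ID). Each genome joins the earliest-created seed it
#' matches at `ani >= ani_min` with the aligned fraction of the shorter
#' genome (or of both, per `af_rule`) `>= af_min`; otherwise it founds a
#' new cluster. The result is a partition: every genome belongs to exactly
#' one cluster, and the seed (longest member) is its representative.
#'
#' @param genomes Tibble with `genome_id`, `length` (IDs unique).
#' @param ani_records Pairwise table from [ani_table()].
#' @param ani_min,af_min Thresholds in percent (defaults 95 and 85).
#' @param af_rule `"shorter"` (default) or `"both"`.
#' @return Tibble `votu_id`, `genome_id`, `is_representative`.
#' @export
cluster_votus <- function(genomes, ani_records, ani_min = 95, af_min = 85,
                          af_rule = c("shorter", "both")) {
  af_rule <- match.arg(af_rule)
  if (anyDuplicated(genomes$genome_id)) stop("duplicate genome IDs")
  glen <- stats::setNames(genomes$length, genomes$genome_id)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  rec <- stats::setNames(
    split(ani_records, seq_len(nrow(ani_records))),
    key(ani_records$genome_a, ani_records$genome_b)
  )
  ord <- genomes$genome_id[order(-genomes$length, genomes$genome_id)]
  seeds <- character(0)
  assign <- stats::setNames(rep(NA_character_, length(ord)), ord)
  for (g in ord) {
    joined <- FALSE
    for (s in seeds) {
      r <- rec[[key(g, s)]]
      if (is.null(r)) next
      af_g <- if (r$genome_a == g) r$af_a else r$af_b
      af_s <- if (r$genome_a == g) r$af_b else r$af_a
      af_short <- if (glen[[g]] <= glen[[s]]) af_g else af_s
      af_ok <- if (af_rule == "shorter") af_short >= af_min
               else af_g >= af_min && af_s >= af_min
      if (r$ani >= ani_min && af_ok) {
        assign[[g]] <- s
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      seeds <- c(seeds, g)
      assign[[g]] <- g
    }
  }
  votu_ids <- stats::setNames(sprintf("vOTU_%04d", seq_along(seeds)), seeds)
  tibble::tibble(
    votu_id = unname(votu_ids[assign]),
    genome_id = names(assign),
    is_representative = names(assign) == assign
  ) |>
    dplyr::arrange(.data$votu_id, dplyr::desc(.data$is_representative),
                   .data$genome_id)
}

#' Split vOTU clusters into sub-populations by member attribute
#'
#' A cluster whose members carry more than one value of the attribute
#' (e.g. both virulent and temperate genomes, or both VM- and MM-derived
#' genomes) yields one sub-population per value, all sharing the parent
#' `votu_id`. The inclusion-exclusion identity
#' `sum(sub-populations) - dual clusters = clusters` holds for any
#' two-valued attribute.
#'
#' @param clusters Tibble from [cluster_votus()].
#' @param attributes Tibble with `genome_id` and the attribute column.
#' @param attribute Column name in `attributes` (e.g. `"lifestyle"` or
#'   `"source"`).
#' @return Tibble `subpop_id`, `votu_id`, attribute value column,
#'   `genome_id`.
#' @export
split_votu <- function(clusters, attributes, attribute) {
  stopifnot(attribute %in% names(attributes))
  joined <- dplyr::left_join(clusters, attributes, by = "genome_id")
  vals <- joined[[attribute]]
  if (anyNA(vals)) {
    stop("member(s) missing attribute '", attribute, "': ",
         paste(joined$genome_id[is.na(vals)], collapse = ", "))
  }
  prefix <- c(lifestyle_virulent = "Vir", lifestyle_temperate = "Tem",
              source_VM = "VM", source_MM = "MM")
  joined |>
    dplyr::mutate(.val = vals,
                  .pfx = dplyr::coalesce(
                    prefix[paste(attribute, vals, sep = "_")],
                    as.character(vals)),
                  subpop_id = paste0(.data$.pfx, "-", .data$votu_id)) |>
    dplyr::select("subpop_id", "votu_id", !!attribute := ".val",
                  "genome_id") |>
    dplyr::arrange(.data$subpop_id, .data$genome_id)
}

#' Select a representative genome per sub-population
#'
#' The longest member wins; length ties break to the lexicographically
#' smaller genome ID.
#'
#' @param subpops Tibble from [split_votu()] (or any tibble with
#'   `subpop_id`, `genome_id`).
#' @param genomes Tibble with `genome_id`, `length`.
#' @return Tibble `subpop_id`, `representative`.
#' @export
select_representatives <- function(subpops, genomes) {
  if (nrow(subpops) == 0) stop("empty sub-population set")
  subpops |>
    dplyr::left_join(genomes[, c("genome_id", "length")],
                     by = "genome_id") |>
    dplyr::group_by(.data$subpop_id) |>
    dplyr::arrange(dplyr::desc(.data$length), .data$genome_id,
                   .by_group = TRUE) |>
    dplyr::summarise(representative = .data$genome_id[1], .groups = "drop")
}
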