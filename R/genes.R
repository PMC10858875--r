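aln_params <- list(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1)

protein_alignment <- function(pattern, subject) {
  Biostrings::pairwiseAlignment(
    pattern, subject, type = "local",
    substitutionMatrix = aln_params$matrix,
    gapOpening = aln_params$gap_open, gapExtension = aln_params$gap_extend
  )
}

# identity = identical positions / alignment columns (PID1);
# coverage = aligned span on the shorter sequence / its length
aln_identity_coverage <- function(aln, len_pattern, len_subject) {
  ident <- Biostrings::pid(aln, type = "PID1") / 100
  span_p <- IRanges::width(Biostrings::pattern(aln))
  span_s <- IRanges::width(Biostrings::subject(aln))
  cov <- if (len_pattern <= len_subject) span_p / len_pattern
         else span_s / len_subject
  c(identity = ident, coverage = cov)
}

#' Greedy incremental protein clustering
#'
#' Sequences are sorted by decreasing length (ties by ID) and each joins
#' the best existing cluster whose representative aligns at
#' `identity >= 60%` over at least `cov_short = 80%` of the shorter
#' sequence, else founds a new cluster. Identity is computed from an exact
#' local alignment (BLOSUM62, gap open 11 / extend 1) as identical
#' positions over alignment columns; "best" means highest identity among
#' qualifying clusters. A shared-4-mer prefilter (analogous to cd-hit's
#' short-word filter at word size 4) skips alignments against clusters
#' whose representative shares no 4-mer with the query.
#'
#' A cluster is flagged `shared` iff its members include at least one
#' phage-origin and one prokaryote-origin protein.
#'
#' @param proteins Tibble with `protein_id`, `sequence` (amino acids,
#'   length >= 20), `origin` (`virulent`/`temperate`/`prokaryote`),
#'   `genome_id`, `population_id`.
#' @param identity Minimum fractional identity (default 0.60).
#' @param cov_short Minimum coverage of the shorter sequence
#'   (default 0.80).
#' @param prefilter Use the 4-mer prefilter (disable for oracle
#'   comparisons).
#' @return List with `membership` (`pc_id`, `protein_id`, `origin`,
#'   `genome_id`, `population_id`) and `clusters` (`pc_id`, `n_members`,
#'   `shared`).
#' @export
cluster_proteins <- function(proteins, identity = 0.60, cov_short = 0.80,
                             prefilter = TRUE) {
  req <- c("protein_id", "sequence", "origin", "genome_id", "population_id")
  stopifnot(all(req %in% names(proteins)))
  if (!all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", proteins$sequence))) {
    stop("non-amino-acid symbols in protein sequence(s)")
  }
  if (any(nchar(proteins$sequence) < 20)) {
    stop("protein(s) shorter than 20 aa")
  }
  ord <- order(-nchar(proteins$sequence), proteins$protein_id)
  proteins <- proteins[ord, ]
  seqs <- Biostrings::AAStringSet(proteins$sequence)
  lens <- nchar(proteins$sequence)

  kmers <- function(s) {
    n <- nchar(s)
    unique(substring(s, 1:(n - 3), 4:n))
  }
  word_index <- new.env(parent = emptyenv())
  rep_idx <- integer(0)      # row index of each cluster representative
  assign <- integer(nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    kms <- kmers(proteins$sequence[i])
    cand <- if (prefilter) {
      sort(unique(unlist(lapply(kms, function(k)
        word_index[[k]]), use.names = FALSE)))
    } else seq_along(rep_idx)
    best <- NA_integer_; best_id <- -1
    for (cl in cand) {
      j <- rep_idx[cl]
      aln <- protein_alignment(seqs[[i]], seqs[[j]])
      ic <- aln_identity_coverage(aln, lens[i], lens[j])
      if (ic["identity"] >= identity && ic["coverage"] >= cov_short &&
          ic["identity"] > best_id) {
        best <- cl; best_id <- ic["identity"]
      }
    }
    if (is.na(best)) {
      rep_idx <- c(rep_idx, i)
      cl <- length(rep_idx)
      for (k in kms) word_index[[k]] <- c(word_index[[k]], cl)
      assign[i] <- cl
    } else {
      assign[i] <- best
    }
  }
  membership <- proteins |>
    dplyr::mutate(pc_id = sprintf("PC_%05d", assign)) |>
    dplyr::select("pc_id", "protein_id", "origin", "genome_id",
                  "population_id")
  clusters <- membership |>
    dplyr::group_by(.data$pc_id) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      shared = any(.data$origin %in% c("virulent", "temperate")) &
        any(.data$origin == "prokaryote"),
      .groups = "drop"
    )
  list(membership = membership, clusters = clusters)
}

#' Shared-PC ratio per phage genome
#'
#' For each phage genome: the number of its distinct protein clusters that
#' are shared with prokaryotes, divided by its total number of distinct
#' protein clusters. Duplicated proteins within one cluster do not change
#' the ratio. Genomes with zero proteins are excluded with a warning.
#'
#' @param pcs Output of [cluster_proteins()].
#' @param genome_ids Optional character vector of phage genomes expected
#'   in the output (triggers the zero-protein warning).
#' @return Tibble `genome_id`, `origin`, `n_pcs`, `n_shared`, `ratio`.
#' @export
shared_pc_ratio <- function(pcs, genome_ids = NULL) {
  phage <- pcs$membership |>
    dplyr::filter(.data$origin %in% c("virulent", "temperate"))
  if (!is.null(genome_ids)) {
    none <- setdiff(genome_ids, phage$genome_id)
    if (length(none) > 0) {
      warning("genome(s) with zero proteins excluded: ",
              paste(none, collapse = ", "))
    }
  }
  phage |>
    dplyr::distinct(.data$genome_id, .data$origin, .data$pc_id) |>
    dplyr::left_join(pcs$clusters[, c("pc_id", "shared")], by = "pc_id") |>
    dplyr::group_by(.data$genome_id, .data$origin) |>
    dplyr::summarise(n_pcs = dplyr::n(), n_shared = sum(.data$shared),
                     ratio = mean(.data$shared), .groups = "drop")
}

pair_sharing_scores <- function(pcs) {
  phage_sets <- pcs$membership |>
    dplyr::filter(.data$origin != "prokaryote") |>
    dplyr::distinct(.data$population_id, .data$pc_id)
  prok_sets <- pcs$membership |>
    dplyr::filter(.data$origin == "prokaryote") |>
    dplyr::distinct(prok_id = .data$population_id, .data$pc_id)
  list(phage = split(phage_sets$pc_id, phage_sets$population_id),
       prok = split(prok_sets$pc_id, prok_sets$prok_id))
}

#' Host vs nonhost shared-PC proportions per prokaryotic family
#'
#' For every phage-prokaryote pair the score is the proportion of the
#' phage population's protein clusters also found in that prokaryote.
#' Within each family, host pairs come from the link table and nonhost
#' pairs (same phage populations, unlinked prokaryotes of the family) are
#' subsampled without replacement to the family's host-pair count using
#' `seed`; a family with fewer nonhost than host pairs keeps all of them
#' with a warning, and families without host pairs are skipped.
#'
#' @param pcs Output of [cluster_proteins()].
#' @param links Host link tibble (`phage_pop_id`, `prok_id`).
#' @param families Tibble `prok_id`, `family`.
#' @param seed Integer seed for the subsampling.
#' @return List with `pairs` (pair-level scores, `is_host` flag,
#'   `sampled` flag) and `by_family` (`family`, `n_pairs`, `host_mean`,
#'   `host_sd`, `nonhost_mean`, `nonhost_sd`).
#' @export
host_vs_nonhost_sharing <- function(pcs, links, families, seed = 1) {
  sets <- pair_sharing_scores(pcs)
  phage_pops <- names(sets$phage)
  pairs <- tidyr::crossing(phage_pop_id = phage_pops,
                           prok_id = families$prok_id) |>
    dplyr::left_join(families, by = "prok_id") |>
    dplyr::mutate(
      is_host = paste(.data$phage_pop_id, .data$prok_id) %in%
        paste(links$phage_pop_id, links$prok_id),
      score = purrr::map2_dbl(.data$phage_pop_id, .data$prok_id,
                              function(p, h) {
        ppc <- sets$phage[[p]]
        hpc <- sets$prok[[h]]
        if (is.null(hpc)) hpc <- character(0)
        length(intersect(ppc, hpc)) / length(ppc)
      })
    )
  withr::with_seed(seed, {
    sampled <- pairs |>
      dplyr::group_by(.data$family) |>
      dplyr::group_modify(function(df, key) {
        n_host <- sum(df$is_host)
        if (n_host == 0) return(df[0, ])
        nh <- which(!df$is_host)
        if (length(nh) < n_host) {
          warning("family ", key$family,
                  ": fewer nonhost than host pairs, using all")
          take <- nh
        } else {
          take <- sample(nh, n_host)
        }
        df$sampled <- FALSE
        df$sampled[df$is_host] <- TRUE
        df$sampled[take] <- TRUE
        df[df$sampled, ]
      }) |>
      dplyr::ungroup()
  })
  by_family <- sampled |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      n_pairs = sum(.data$is_host),
      host_mean = mean(.data$score[.data$is_host]),
      host_sd = stats::sd(.data$score[.data$is_host]),
      nonhost_mean = mean(.data$score[!.data$is_host]),
      nonhost_sd = stats::sd(.data$score[!.data$is_host]),
      .groups = "drop"
    )
  list(pairs = sampled, by_family = by_family)
}

#' Screen toxin-antitoxin protein clusters and correlate with diet
#'
#' For every annotated TA protein cluster with abundance data, Pearson
#' correlations of its abundance against the leaf and fruit dietary
#' proportions are computed over the sampling dates; q-values are
#' BH-adjusted across all tested cluster-by-axis pairs. Clusters absent
#' from the abundance table or with constant abundance are skipped with a
#' warning.
#'
#' @param ta_annotations Tibble `pc_id`, `ta_family` (e.g. Pemk, HicB),
#'   `role` (`toxin`/`antitoxin`).
#' @param pc_ab Long PC abundance tibble (`pc_id`, `sample_id`,
#'   `abundance`).
#' @param diet Tibble `sample_id`, `leaf`, `fruit` (proportions).
#' @param pc_lifestyles Optional tibble `pc_id`, `lifestyle` for the
#'   per-lifestyle counts.
#' @return List with `correlations` (per `pc_id` x axis: `r`, `p`, `q`)
#'   and `counts` (TA PCs per lifestyle; empty without `pc_lifestyles`).
#' @export
screen_ta_and_correlate <- function(ta_annotations, pc_ab, diet,
                                    pc_lifestyles = NULL) {
  stopifnot(all(c("pc_id", "ta_family", "role") %in% names(ta_annotations)),
            all(c("sample_id", "leaf", "fruit") %in% names(diet)))
  res <- purrr::map_dfr(unique(ta_annotations$pc_id), function(pc) {
    ab <- pc_ab[pc_ab$pc_id == pc, ]
    if (nrow(ab) == 0) {
      warning("TA PC absent from abundance matrix skipped: ", pc)
      return(NULL)
    }
    m <- dplyr::inner_join(ab, diet, by = "sample_id")
    if (stats::sd(m$abundance) == 0) {
      warning("TA PC with constant abundance excluded: ", pc)
      return(NULL)
    }
    purrr::map_dfr(c("leaf", "fruit"), function(axis) {
      ct <- stats::cor.test(m$abundance, m[[axis]], method = "pearson")
      tibble::tibble(pc_id = pc, axis = axis,
                     r = unname(ct$estimate), p = ct$p.value)
    })
  })
  if (nrow(res) > 0) res$q <- bh_adjust(res$p)
  res <- dplyr::left_join(
    res, dplyr::distinct(ta_annotations, .data$pc_id, .data$ta_family,
                         .data$role), by = "pc_id")
  counts <- tibble::tibble(lifestyle = character(), n_ta_pcs = integer())
  if (!is.null(pc_lifestyles)) {
    counts <- ta_annotations |>
      dplyr::distinct(.data$pc_id) |>
      dplyr::inner_join(pc_lifestyles, by = "pc_id") |>
      dplyr::count(.data$lifestyle, name = "n_ta_pcs")
  }
  list(correlations = res, counts = counts)
}
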