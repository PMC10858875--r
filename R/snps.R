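#' Genetic code table for translation
#'
#' Codes 11 (standard bacterial), 4 and 25 (TGA recoded to Trp/Gly) and 15
#' (TAG recoded to Gln) come from the NCBI tables; code 91 (TAA recoded to
#' Gln) is not an NCBI table and is built from the standard code.
#'
#' @param code Integer code id: one of 11, 4, 25, 15, 91.
#' @return Named character vector mapping codons to amino acids.
#' @export
genetic_code_table <- function(code) {
  code <- as.integer(code)
  if (code %in% c(11L, 4L, 25L, 15L)) {
    return(Biostrings::getGeneticCode(as.character(code)))
  }
  if (code == 91L) {
    gc <- Biostrings::getGeneticCode("11")
    gc["TAA"] <- "Q"
    return(gc)
  }
  stop("unsupported genetic code: ", code)
}

#' Select genomes eligible for SNP calling
#'
#' A genome is eligible for an individual iff its tpmean coverage is at
#' least `min_depth` in every sample of that individual (inclusive
#' boundary). A genome absent from a sample's coverage table counts as
#' zero coverage there, making it ineligible.
#'
#' @param coverage Tibble `genome_id`, `sample_id`, `coverage`.
#' @param metadata Tibble `sample_id`, `individual`.
#' @param min_depth Depth floor (default 10).
#' @return Tibble `individual`, `genome_id` of eligible genomes.
#' @export
select_genomes_for_snp <- function(coverage, metadata, min_depth = 10) {
  full <- tidyr::crossing(genome_id = unique(coverage$genome_id),
                          metadata[, c("sample_id", "individual")]) |>
    dplyr::left_join(coverage, by = c("genome_id", "sample_id")) |>
    dplyr::mutate(coverage = dplyr::coalesce(.data$coverage, 0))
  full |>
    dplyr::group_by(.data$individual, .data$genome_id) |>
    dplyr::summarise(eligible = all(.data$coverage >= min_depth),
                     .groups = "drop") |>
    dplyr::filter(.data$eligible) |>
    dplyr::select("individual", "genome_id")
}

#' Call within-population variants from pileup counts
#'
#' Base calls at quality `> qual_min` are counted per site; a variant is
#' emitted for every (site, alternative base) whose count is at least
#' `min_alt_reads` and whose frequency (count / site depth) is strictly
#' above `min_alt_freq`. Multi-allelic sites yield one record per
#' alternative base; zero-depth sites are skipped.
#'
#' @param pileup Tibble `genome_id`, `sample_id`, `position`, `ref_base`,
#'   `base`, `count`, `mean_qual`.
#' @param qual_min Quality threshold (strict, default 30).
#' @param min_alt_reads Minimum alternative reads (default 4).
#' @param min_alt_freq Minimum alternative-allele frequency (strict,
#'   default 0.01).
#' @return Tibble `genome_id`, `sample_id`, `position`, `ref_base`,
#'   `alt_base`, `alt_count`, `depth`, `alt_freq`.
#' @export
call_snps <- function(pileup, qual_min = 30, min_alt_reads = 4,
                      min_alt_freq = 0.01) {
  req <- c("genome_id", "sample_id", "position", "ref_base", "base",
           "count", "mean_qual")
  stopifnot(all(req %in% names(pileup)))
  pileup |>
    dplyr::filter(.data$mean_qual > qual_min) |>
    dplyr::group_by(.data$genome_id, .data$sample_id, .data$position,
                    .data$ref_base) |>
    dplyr::mutate(depth = sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$depth > 0,
                  .data$base != .data$ref_base,
                  .data$count >= min_alt_reads,
                  .data$count / .data$depth > min_alt_freq) |>
    dplyr::transmute(genome_id = .data$genome_id,
                     sample_id = .data$sample_id,
                     position = .data$position,
                     ref_base = .data$ref_base,
                     alt_base = .data$base,
                     alt_count = .data$count,
                     depth = .data$depth,
                     alt_freq = .data$count / .data$depth)
}

#' Fraction of an earlier date's SNPs shared with a later date
#'
#' SNP identity is the (position, alternative base) pair; frequency is
#' ignored. The fraction is the size of the intersection divided by the
#' number of SNPs at the earlier date, and is `NA` (flagged) when the
#' earlier profile is empty.
#'
#' @param earlier,later Variant tibbles for the same genome (columns
#'   `genome_id`, `position`, `alt_base`).
#' @return A single fraction in `[0, 1]`, or `NA` for an empty earlier
#'   profile.
#' @export
shared_snp_fraction <- function(earlier, later) {
  ga <- unique(earlier$genome_id); gb <- unique(later$genome_id)
  if (length(ga) > 1 || length(gb) > 1 ||
      (length(ga) == 1 && length(gb) == 1 && ga != gb)) {
    stop("profiles must belong to one genome")
  }
  if (nrow(earlier) == 0) {
    warning("empty earlier profile: shared fraction undefined")
    return(NA_real_)
  }
  a <- paste(earlier$position, earlier$alt_base)
  b <- paste(later$position, later$alt_base)
  length(intersect(a, b)) / length(unique(a))
}

#' Classify substitution effects of variants
#'
#' Each variant falling inside a gene is classified by translating the
#' reference and alternative codon with the genome's assigned genetic
#' code (synonymous iff the amino acid is unchanged); variants in
#' overlapping genes are classified once per gene. Positions outside all
#' genes are intergenic.
#'
#' @param genome_seq The genome sequence (character scalar).
#' @param genes Tibble `gene_id`, `start`, `end`, `strand` (1-based
#'   inclusive coordinates).
#' @param code Genetic code id (see [genetic_code_table()]).
#' @param variants Tibble `position`, `ref_base`, `alt_base`.
#' @return One row per variant-gene combination (intergenic variants get
#'   `gene_id = NA`): input columns plus `gene_id`, `effect`
#'   (`synonymous` / `non-synonymous` / `intergenic`).
#' @export
classify_substitution <- function(genome_seq, genes, code, variants) {
  gc_tab <- genetic_code_table(code)
  chars <- strsplit(toupper(genome_seq), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  purrr::map_dfr(seq_len(nrow(variants)), function(i) {
    pos <- variants$position[i]
    if (pos < 1 || pos > length(chars)) stop("variant outside genome")
    if (chars[pos] != variants$ref_base[i]) {
      stop("ref_base mismatch at position ", pos)
    }
    in_genes <- genes[genes$start <= pos & genes$end >= pos, ]
    if (nrow(in_genes) == 0) {
      return(dplyr::mutate(variants[i, ], gene_id = NA_character_,
                           effect = "intergenic"))
    }
    purrr::map_dfr(seq_len(nrow(in_genes)), function(g) {
      gn <- in_genes[g, ]
      if (gn$strand == "+") {
        off <- pos - gn$start                 # 0-based offset in CDS
        cstart <- gn$start + 3 * (off %/% 3)
        codon <- chars[cstart:(cstart + 2)]
        alt_codon <- codon
        alt_codon[pos - cstart + 1] <- variants$alt_base[i]
      } else {
        off <- gn$end - pos
        cend <- gn$end - 3 * (off %/% 3)
        codon <- comp[chars[cend:(cend - 2)]]
        alt_codon <- codon
        alt_codon[cend - pos + 1] <- comp[[variants$alt_base[i]]]
      }
      aa_ref <- gc_tab[[paste(codon, collapse = "")]]
      aa_alt <- gc_tab[[paste(alt_codon, collapse = "")]]
      dplyr::mutate(variants[i, ], gene_id = gn$gene_id,
                    effect = ifelse(aa_ref == aa_alt, "synonymous",
                                    "non-synonymous"))
    })
  })
}

#' Build the shared-SNP similarity series over all date pairs
#'
#' Each sampling date of a genome is compared with all subsequent dates;
#' the pair contributes (lag in days, shared fraction relative to the
#' earlier date).
#'
#' @param variants Variant tibble with `genome_id`, `date` (Date),
#'   `position`, `alt_base`.
#' @return Tibble `genome_id`, `reference_date`, `lag_days`,
#'   `shared_fraction`.
#' @export
similarity_series <- function(variants) {
  stopifnot(all(c("genome_id", "date", "position", "alt_base") %in%
                  names(variants)))
  variants |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::group_modify(function(df, key) {
      dates <- sort(unique(df$date))
      if (length(dates) < 2) return(tibble::tibble())
      combos <- utils::combn(seq_along(dates), 2)
      purrr::map_dfr(seq_len(ncol(combos)), function(k) {
        d1 <- dates[combos[1, k]]; d2 <- dates[combos[2, k]]
        e <- df[df$date == d1, ]; l <- df[df$date == d2, ]
        e$genome_id <- key$genome_id; l$genome_id <- key$genome_id
        tibble::tibble(
          reference_date = d1,
          lag_days = as.numeric(d2 - d1),
          shared_fraction = shared_snp_fraction(e, l)
        )
      })
    }) |>
    dplyr::ungroup()
}

#' Regress shared-SNP fraction on time lag, by lifestyle
#'
#' Pools (lag, fraction) points over genomes and reference dates within
#' each lifestyle and fits an ordinary least-squares line; per lag, a
#' Wilcoxon rank-sum test compares the two lifestyles' fractions. All
#' fractions identical within a lifestyle give slope 0 with an undefined
#' (NA) R-squared.
#'
#' @param series Output of [similarity_series()].
#' @param lifestyles Tibble `genome_id`, `lifestyle`.
#' @return Object of class `phagedyn_snp_fit` with elements `fits`
#'   (per-lifestyle slope, intercept, adjusted R-squared, n), `by_lag`
#'   (per-lag Wilcoxon p and group means) and `series`.
#' @export
similarity_vs_lag <- function(series, lifestyles) {
  dat <- series |>
    dplyr::left_join(lifestyles, by = "genome_id") |>
    dplyr::filter(!is.na(.data$shared_fraction))
  fits <- dat |>
    dplyr::group_by(.data$lifestyle) |>
    dplyr::group_modify(function(df, key) {
      if (dplyr::n_distinct(df$lag_days) < 3) {
        stop("need at least 3 distinct lag points per lifestyle")
      }
      if (stats::sd(df$shared_fraction) == 0) {
        return(tibble::tibble(slope = 0, intercept = df$shared_fraction[1],
                              adj_r_squared = NA_real_, n = nrow(df)))
      }
      fit <- stats::lm(shared_fraction ~ lag_days, data = df)
      tibble::tibble(slope = stats::coef(fit)[["lag_days"]],
                     intercept = stats::coef(fit)[["(Intercept)"]],
                     adj_r_squared = summary(fit)$adj.r.squared,
                     n = nrow(df))
    }) |>
    dplyr::ungroup()
  by_lag <- dat |>
    dplyr::group_by(.data$lag_days) |>
    dplyr::group_modify(function(df, key) {
      v <- df$shared_fraction[df$lifestyle == "virulent"]
      t <- df$shared_fraction[df$lifestyle == "temperate"]
      tibble::tibble(
        mean_virulent = mean(v), mean_temperate = mean(t),
        p = if (length(v) > 0 && length(t) > 0 &&
                length(unique(c(v, t))) > 1)
          suppressWarnings(stats::wilcox.test(v, t)$p.value) else NA_real_
      )
    }) |>
    dplyr::ungroup()
  structure(list(fits = fits, by_lag = by_lag, series = dat),
            class = "phagedyn_snp_fit")
}

#' Estimate the per-day variant loss rate from a similarity series
#'
#' Under geometric loss at rate rho per day the expected shared fraction
#' at lag t is `(1 - rho)^t`; the estimator regresses `log(fraction)` on
#' lag (zero fractions excluded) and returns `1 - exp(slope)`.
#'
#' @param series Output of [similarity_series()] (optionally
#'   pre-filtered to one lifestyle).
#' @return Estimated loss rate per day.
#' @export
fit_turnover_rate <- function(series) {
  dat <- series |>
    dplyr::filter(!is.na(.data$shared_fraction), .data$shared_fraction > 0)
  if (nrow(dat) < 3) stop("too few usable points to fit a loss rate")
  fit <- stats::lm(log(shared_fraction) ~ lag_days, data = dat)
  1 - exp(stats::coef(fit)[["lag_days"]])
}

#' @export
print.phagedyn_snp_fit <- function(x, ...) {
  cat("<phagedyn_snp_fit>\n")
  print(x$fits)
  invisible(x)
}
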