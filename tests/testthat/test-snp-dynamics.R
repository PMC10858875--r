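test_that("genome eligibility requires >= 10x in every sample of an individual", {
  meta <- tibble::tibble(sample_id = paste0("s", 1:3), individual = "A2")
  cov <- function(v) tibble::tibble(genome_id = "g1",
                                    sample_id = paste0("s", 1:3),
                                    coverage = v)
  expect_equal(nrow(select_genomes_for_snp(cov(c(12, 15, 11)), meta)), 1)
  expect_equal(nrow(select_genomes_for_snp(cov(c(12, 9, 11)), meta)), 0)
  expect_equal(nrow(select_genomes_for_snp(cov(c(10, 10, 10)), meta)), 1)
  # genome missing from one sample counts as zero coverage there
  partial <- cov(c(12, 15, 11))[-2, ]
  expect_equal(nrow(select_genomes_for_snp(partial, meta)), 0)
})

test_that("SNP calling applies count, frequency and quality filters per alt base", {
  site <- function(alt_count, depth, qual = 37) {
    tibble::tibble(genome_id = "g", sample_id = "s", position = 100L,
                   ref_base = "A", base = c("A", "G"),
                   count = c(depth - alt_count, alt_count),
                   mean_qual = qual)
  }
  expect_equal(nrow(call_snps(site(3, 100))), 0)        # < 4 reads
  v <- call_snps(site(5, 100))
  expect_equal(v$alt_freq, 0.05)
  expect_equal(nrow(call_snps(site(9, 1000))), 0)       # 0.9% < 1%
  expect_equal(nrow(call_snps(site(5, 100, qual = 30))), 0)  # strict > 30
  # multi-allelic: one record per alt base
  multi <- tibble::tibble(genome_id = "g", sample_id = "s",
                          position = 7L, ref_base = "A",
                          base = c("A", "C", "G"),
                          count = c(80L, 10L, 10L), mean_qual = 37)
  expect_equal(nrow(call_snps(multi)), 2)
})

test_that("SNP calling agrees with a brute-force per-site filter on random pileups", {
  withr::with_seed(77, {
    pile <- tidyr::crossing(position = 1:40,
                            base = c("A", "C", "G", "T")) |>
      dplyr::mutate(genome_id = "g", sample_id = "s", ref_base = "A",
                    count = rpois(dplyr::n(), 3),
                    mean_qual = sample(c(20, 37), dplyr::n(),
                                       replace = TRUE))
  })
  got <- call_snps(pile)
  oracle <- list()
  for (pos in unique(pile$position)) {
    rows <- pile[pile$position == pos & pile$mean_qual > 30, ]
    depth <- sum(rows$count)
    if (depth == 0) next
    for (i in seq_len(nrow(rows))) {
      if (rows$base[i] != rows$ref_base[i] && rows$count[i] >= 4 &&
          rows$count[i] / depth > 0.01) {
        oracle[[length(oracle) + 1]] <- paste(pos, rows$base[i])
      }
    }
  }
  expect_setequal(paste(got$position, got$alt_base), unlist(oracle))
})

test_that("shared-SNP fraction is the earlier-set overlap and flags emptiness", {
  prof <- function(pos, alt) tibble::tibble(genome_id = "g",
                                            position = pos, alt_base = alt)
  expect_equal(shared_snp_fraction(prof(c(100, 200), c("T", "G")),
                                   prof(c(100, 300), c("T", "A"))), 0.5)
  expect_equal(shared_snp_fraction(prof(1:3, "T"), prof(1:3, "T")), 1)
  expect_equal(shared_snp_fraction(prof(1:2, "T"), prof(3:4, "T")), 0)
  # monotone non-increasing when shared variants are removed from later
  expect_lte(shared_snp_fraction(prof(1:4, "T"), prof(2:3, "T")),
             shared_snp_fraction(prof(1:4, "T"), prof(1:4, "T")))
  expect_warning(out <- shared_snp_fraction(prof(integer(0), character(0)),
                                            prof(1, "T")), "empty")
  expect_true(is.na(out))
  expect_error(shared_snp_fraction(
    prof(1, "T"), dplyr::mutate(prof(1, "T"), genome_id = "other")),
    "one genome")
})

test_that("substitution classification honours strand, frame, and genetic code", {
  genome <- paste0("ATGGCTTAGGGA", strrep("C", 20))
  genes <- tibble::tibble(gene_id = "gene1", start = 1L, end = 12L,
                          strand = "+")
  v <- function(pos, ref, alt) tibble::tibble(position = pos,
                                              ref_base = ref,
                                              alt_base = alt)
  # codon 2 GCT: T->C keeps Ala
  expect_equal(classify_substitution(genome, genes, 11,
                                     v(6L, "T", "C"))$effect, "synonymous")
  # GCT -> GTT is Ala -> Val
  expect_equal(classify_substitution(genome, genes, 11,
                                     v(5L, "C", "T"))$effect,
               "non-synonymous")
  expect_equal(classify_substitution(genome, genes, 11,
                                     v(20L, "C", "T"))$effect,
               "intergenic")
  # codon 3 TAG -> TAA: both stops under code 11, Gln vs stop under 15
  expect_equal(classify_substitution(genome, genes, 11,
                                     v(9L, "G", "A"))$effect, "synonymous")
  expect_equal(classify_substitution(genome, genes, 15,
                                     v(9L, "G", "A"))$effect,
               "non-synonymous")
  # code 91 recodes TAA to Gln
  expect_equal(genetic_code_table(91)[["TAA"]], "Q")
  # reverse strand: gene reads revcomp; genome pos 4..6 AGC -> codon GCT
  genome2 <- "CCCAGCCAT"
  genes2 <- tibble::tibble(gene_id = "rev1", start = 1L, end = 9L,
                           strand = "-")
  # CDS = ATG GCT GGG; genome pos 4 is the 3rd base of codon GCT, so
  # A->G on the genome is T->C on the CDS: GCT->GCC stays Ala
  expect_equal(classify_substitution(genome2, genes2, 11,
                                     v(4L, "A", "G"))$effect,
               "synonymous")
  # genome pos 6 is the 1st base of codon GCT: C->T is G->A on the CDS,
  # GCT->ACT is Ala->Thr
  expect_equal(classify_substitution(genome2, genes2, 11,
                                     v(6L, "C", "T"))$effect,
               "non-synonymous")
  expect_error(classify_substitution(genome, genes, 11, v(5L, "A", "T")),
               "mismatch")
})

test_that("similarity series and fits recover the no-turnover limit", {
  com <- tiny_community()
  ss <- generate_snp_series(com$truth, com$genomes, n_dates = 4,
                            turnover_virulent = 0, turnover_temperate = 0,
                            genomes_per_lifestyle = 1, seed = 3)
  v <- call_snps(ss$pileups) |>
    dplyr::left_join(dplyr::distinct(ss$pileups, sample_id, date),
                     by = "sample_id")
  ser <- similarity_series(v)
  expect_true(all(ser$shared_fraction == 1))
  fit <- similarity_vs_lag(ser, ss$lifestyles)
  expect_true(all(fit$fits$slope == 0))
  expect_true(all(is.na(fit$fits$adj_r_squared)))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$n, nrow(fit$series))
})

test_that("fitted geometric decay matches the closed-form expectation", {
  com <- tiny_community()
  ss <- generate_snp_series(com$truth, com$genomes, n_dates = 8,
                            sites_per_genome = 40,
                            turnover_virulent = 0.2,
                            turnover_temperate = 0.2,
                            genomes_per_lifestyle = 2, seed = 29)
  ser <- similarity_series(
    ss$variant_truth |>
      dplyr::transmute(genome_id, date, position, alt_base = alt_base))
  # E[shared fraction at lag t] = (1 - rho)^t
  mean_by_lag <- tapply(ser$shared_fraction, ser$lag_days, mean)
  lags <- as.numeric(names(mean_by_lag))
  expect_equal(as.numeric(mean_by_lag), 0.8^lags, tolerance = 0.15)
  expect_lt(abs(fit_turnover_rate(ser) - 0.2), 0.05)
  fit <- similarity_vs_lag(ser, ss$lifestyles)
  expect_true(all(fit$fits$slope < 0))
})
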