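test_that("spacer matching requires exact full-length occurrence on either strand", {
  genome <- paste0(strrep("AC", 100),
                   "GATTACAGATTACAGATTACAGATTACAGATT",  # planted 32-mer
                   strrep("GT", 100))
  spacer <- "GATTACAGATTACAGATTACAGATTACAGATT"
  genomes <- tibble::tibble(genome_id = "g1", sequence = genome)
  pops <- tibble::tibble(genome_id = "g1", population_id = "v1")
  sp <- function(s) tibble::tibble(spacer_id = "sp1", host_id = "h1",
                                   sequence = s)
  expect_equal(nrow(match_spacers(sp(spacer), genomes, pops)), 1)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(spacer)))
  expect_equal(nrow(match_spacers(sp(rc), genomes, pops)), 1)
  mism <- sub("^G", "T", spacer)
  expect_equal(nrow(match_spacers(sp(mism), genomes, pops)), 0)
  expect_warning(out <- match_spacers(sp(gsub("G", "N", spacer)),
                                      genomes, pops), "non-ACGT")
  expect_equal(nrow(out), 0)
  expect_error(match_spacers(sp("ACGTACGTACGT"), genomes, pops),
               "20 nt")
})

test_that("spacer matcher agrees with a brute-force all-positions scan", {
  com <- tiny_community()
  hg <- generate_hosts(com, n_hosts = 3, spacers_per_host = 2, seed = 17)
  # genome-resolution map so the per-genome oracle comparison is exact
  pops <- com$truth$genomes |>
    dplyr::transmute(genome_id, population_id = genome_id)
  links <- match_spacers(hg$spacers, com$genomes, pops)
  for (i in seq_len(nrow(hg$spacers))) {
    for (j in seq_len(nrow(com$genomes))) {
      n_oracle <- oracle_spacer_hits(hg$spacers$sequence[i],
                                     com$genomes$sequence[j])
      gid <- com$genomes$genome_id[j]
      linked <- any(links$phage_pop_id == gid &
                      links$prok_id == hg$spacers$host_id[i] &
                      grepl(hg$spacers$spacer_id[i], links$detail))
      expect_equal(linked, n_oracle > 0)
    }
  }
})

test_that("homology links enforce all four thresholds with inclusive boundaries", {
  mk <- function(len, ident, ev, bits) {
    tibble::tibble(query_id = "g1", subject_id = "h1",
                   pct_identity = ident, aln_length = len,
                   mismatches = 0L, gap_opens = 0L, q_start = 1L,
                   q_end = len, s_start = 1L, s_end = len,
                   evalue = ev, bit_score = bits)
  }
  pops <- tibble::tibble(genome_id = "g1", population_id = "v1")
  expect_equal(nrow(match_genome_homology(mk(1200L, 97, 1e-20, 800),
                                          pops)), 1)
  expect_equal(nrow(match_genome_homology(mk(900L, 99, 1e-30, 800),
                                          pops)), 0)
  # exact boundary values link
  expect_equal(nrow(match_genome_homology(mk(1000L, 96, 1e-3, 50),
                                          pops)), 1)
  expect_equal(nrow(match_genome_homology(mk(1000L, 95.9, 1e-3, 50),
                                          pops)), 0)
})

test_that("host and phage ranges count distinct partners by lifestyle", {
  links <- tibble::tibble(
    phage_pop_id = c("P1", "P1", "P2", "P3", "P3"),
    prok_id = c("H1", "H2", "H1", "H1", "H1"))
  life <- tibble::tibble(phage_pop_id = c("P1", "P2", "P3"),
                         lifestyle = c("virulent", "virulent",
                                       "temperate"))
  r <- host_and_phage_range(links, life)
  expect_equal(r$host_range$host_range[r$host_range$phage_pop_id == "P1"],
               2)
  h1 <- r$phage_range[r$phage_range$prok_id == "H1", ]
  expect_equal(h1$phage_range[h1$lifestyle == "virulent"], 2)
  expect_equal(h1$phage_range[h1$lifestyle == "temperate"], 1)
  empty <- host_and_phage_range(links[0, ], life)
  expect_equal(nrow(empty$host_range), 0)
})

test_that("phage-host correlations hit the closed-form extremes and planted pairs", {
  samples <- paste0("s", 1:8)
  x <- c(1, 3, 2, 5, 4, 6, 8, 7)
  ab <- function(pop, v) tibble::tibble(population_id = pop,
                                        sample_id = samples, abundance = v)
  links <- tibble::tibble(phage_pop_id = c("P1", "P2"),
                          prok_id = c("H1", "H2"))
  out <- phage_host_correlation(
    dplyr::bind_rows(ab("P1", x), ab("P2", x)),
    dplyr::bind_rows(ab("H1", x), ab("H2", 10 - x)), links)
  expect_equal(out$correlations$r[out$correlations$phage_pop_id == "P1"],
               1)
  expect_equal(out$correlations$r[out$correlations$phage_pop_id == "P2"],
               -1)
  expect_warning(phage_host_correlation(
    ab("P1", x), ab("H1", rep(2, 8)),
    tibble::tibble(phage_pop_id = "P1", prok_id = "H1")), "zero-variance")
  # planted shared-multiplier pair with mild noise correlates strongly
  withr::with_seed(9, {
    shared <- rlnorm(30, 2, 1)
    px <- tibble::tibble(population_id = "P1",
                         sample_id = paste0("t", 1:30),
                         abundance = shared * rlnorm(30, 0, 0.1))
    hx <- tibble::tibble(population_id = "H1",
                         sample_id = paste0("t", 1:30),
                         abundance = shared * rlnorm(30, 0, 0.1))
  })
  out2 <- phage_host_correlation(
    px, hx, tibble::tibble(phage_pop_id = "P1", prok_id = "H1"))
  expect_gt(out2$correlations$r, 0.8)
})

test_that("defense burden sums instances and recovers the planted group order", {
  defense <- tibble::tibble(
    prok_genome_id = c("h1", "h1", "h2"),
    system_name = c("RM", "CRISPR-Cas", "RM"),
    count = c(2L, 1L, 1L))
  assign <- tibble::tibble(prok_id = c("h1", "h2"),
                           lifestyle = c("virulent", "temperate"))
  out <- defense_burden(defense, assign)
  expect_equal(out$per_genome$total_systems[
    out$per_genome$prok_id == "h1"], 3)
  expect_warning(defense_burden(defense, dplyr::bind_rows(
    assign, tibble::tibble(prok_id = "h3", lifestyle = "virulent"))),
    "absent")
  # planted higher burden on virulent-assigned hosts
  com <- tiny_community()
  hg <- generate_hosts(com, n_hosts = 6, defense_mean_virulent = 8,
                       defense_mean_temperate = 1, seed = 19)
  burden <- defense_burden(hg$defense, hg$truth$host_lifestyle |>
                             dplyr::rename(prok_id = host_id,
                                           lifestyle = assigned_lifestyle))
  bg <- burden$by_group
  expect_gt(bg$mean_systems[bg$lifestyle == "virulent"],
            bg$mean_systems[bg$lifestyle == "temperate"])
})
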