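mut_aa <- function(seq, rate) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(aa, ch[i]), 1)
  paste(ch, collapse = "")
}

rand_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

prot_tbl <- function(seqs, origin = "virulent") {
  tibble::tibble(protein_id = sprintf("p%03d", seq_along(seqs)),
                 sequence = seqs, origin = origin,
                 genome_id = "g", population_id = "v")
}

test_that("protein clustering groups homologs and separates unrelated sequences", {
  withr::with_seed(11, {
    base <- rand_aa(100)
    seqs <- c(base, mut_aa(base, 0.05), rand_aa(100))
  })
  pcs <- cluster_proteins(prot_tbl(seqs))
  expect_equal(nrow(pcs$clusters), 2)
  withr::with_seed(12, twin <- rand_aa(80))
  ident <- cluster_proteins(prot_tbl(rep(twin, 2)))
  expect_equal(nrow(ident$clusters), 1)
  expect_error(cluster_proteins(prot_tbl("ACDEFGHIKLMNPQRSTVWX")),
               "non-amino-acid")
  expect_error(cluster_proteins(prot_tbl("ACDEFGHIK")), "20 aa")
})

test_that("greedy clustering matches a brute-force best-cluster oracle", {
  withr::with_seed(23, {
    fams <- replicate(5, rand_aa(sample(60:120, 1)))
    seqs <- c(unlist(lapply(fams, function(f)
      c(f, mut_aa(f, 0.05), mut_aa(f, 0.15)))),
      replicate(8, rand_aa(sample(40:100, 1))))
  })
  prot <- prot_tbl(seqs)

  # independent oracle: literal loops, every existing cluster aligned,
  # best qualifying identity wins
  oracle_cluster <- function(seqs, ids) {
    ord <- order(-nchar(seqs), ids)
    seqs <- seqs[ord]; ids <- ids[ord]
    reps <- integer(0); assign <- integer(length(seqs))
    for (i in seq_along(seqs)) {
      best <- NA; best_id <- -1
      for (ci in seq_along(reps)) {
        j <- reps[ci]
        al <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(seqs[i]), Biostrings::AAString(seqs[j]),
          type = "local", substitutionMatrix = "BLOSUM62",
          gapOpening = 11, gapExtension = 1)
        idn <- Biostrings::pid(al, type = "PID1") / 100
        short <- min(nchar(seqs[i]), nchar(seqs[j]))
        span <- if (nchar(seqs[i]) <= nchar(seqs[j]))
          IRanges::width(Biostrings::pattern(al))
        else IRanges::width(Biostrings::subject(al))
        if (idn >= 0.6 && span / short >= 0.8 && idn > best_id) {
          best <- ci; best_id <- idn
        }
      }
      if (is.na(best)) {
        reps <- c(reps, i); assign[i] <- length(reps)
      } else assign[i] <- best
    }
    stats::setNames(assign, ids)
  }
  oracle <- oracle_cluster(prot$sequence, prot$protein_id)
  got <- cluster_proteins(prot)
  got_assign <- stats::setNames(got$membership$pc_id,
                                got$membership$protein_id)
  expect_equal(ari(got_assign[names(oracle)], oracle), 1.0)
  # and the prefilter-free path gives the same partition
  nofilter <- cluster_proteins(prot, prefilter = FALSE)
  expect_equal(ari(stats::setNames(nofilter$membership$pc_id,
                                   nofilter$membership$protein_id)[
                     names(oracle)], oracle), 1.0)
})

test_that("shared flag and sharing ratio follow the distinct-PC rule", {
  prot <- dplyr::bind_rows(
    tibble::tibble(protein_id = c("a1", "a2", "a2b"),
                   sequence = c(strrep("ACDEFGHIKL", 10),
                                strrep("MNPQRSTVWY", 10),
                                strrep("MNPQRSTVWY", 10)),
                   origin = "virulent", genome_id = "gA",
                   population_id = "vA"),
    tibble::tibble(protein_id = "h1",
                   sequence = strrep("ACDEFGHIKL", 10),
                   origin = "prokaryote", genome_id = "h01",
                   population_id = "h01"))
  pcs <- cluster_proteins(prot)
  expect_equal(sum(pcs$clusters$shared), 1)
  # audit: recomputing origins reproduces the flag
  audit <- pcs$membership |>
    dplyr::group_by(pc_id) |>
    dplyr::summarise(shared = any(origin != "prokaryote") &
                       any(origin == "prokaryote"))
  expect_equal(dplyr::arrange(audit, pc_id),
               dplyr::arrange(pcs$clusters[, c("pc_id", "shared")], pc_id))
  r <- shared_pc_ratio(pcs)
  # gA has 2 distinct PCs, 1 shared; the duplicated a2/a2b protein does
  # not change the ratio
  expect_equal(r$ratio[r$genome_id == "gA"], 0.5)
  expect_warning(shared_pc_ratio(pcs, genome_ids = c("gA", "gEmpty")),
                 "zero proteins")
})

test_that("host vs nonhost sharing subsamples to the host-pair count, seeded", {
  com <- generate_community(n_votus = 4, members_per_votu = 1,
                            genome_len = 10000, genes_per_genome = 4,
                            seed = 41)
  hg <- generate_hosts(com, n_hosts = 4, shared_genes_per_pair = 2,
                       seed = 42)
  prot <- dplyr::bind_rows(
    com$genes |>
      dplyr::inner_join(com$truth$genomes[, c("genome_id", "votu_id",
                                              "lifestyle")],
                        by = "genome_id") |>
      dplyr::transmute(protein_id, sequence = protein_seq,
                       origin = lifestyle, genome_id,
                       population_id = votu_id),
    hg$host_proteins |>
      dplyr::transmute(protein_id, sequence, origin = "prokaryote",
                       genome_id = host_id, population_id = host_id))
  pcs <- cluster_proteins(prot)
  fams <- hg$families |> dplyr::rename(prok_id = host_id)
  out <- host_vs_nonhost_sharing(pcs, hg$truth$links |>
                                   dplyr::rename(prok_id = host_id),
                                 fams, seed = 5)
  per_fam_sampled <- out$pairs |>
    dplyr::count(family, is_host)
  wide <- tidyr::pivot_wider(per_fam_sampled, names_from = is_host,
                             values_from = n, values_fill = 0)
  expect_true(all(wide$`TRUE` >= wide$`FALSE`))
  out2 <- host_vs_nonhost_sharing(pcs, hg$truth$links |>
                                    dplyr::rename(prok_id = host_id),
                                  fams, seed = 5)
  expect_identical(out$pairs, out2$pairs)
  # planted HGT goes only into true hosts
  expect_true(all(out$by_family$host_mean > out$by_family$nonhost_mean))
})

test_that("TA screening correlates PC abundance with diet axes", {
  diet <- tibble::tibble(sample_id = paste0("s", 1:10),
                         leaf = seq(0.1, 0.9, length.out = 10),
                         fruit = 1 - seq(0.1, 0.9, length.out = 10))
  pc_ab <- dplyr::bind_rows(
    tibble::tibble(pc_id = "PC_TA1", sample_id = diet$sample_id,
                   abundance = 5 * diet$leaf),
    tibble::tibble(pc_id = "PC_TA2", sample_id = diet$sample_id,
                   abundance = 3))
  ta <- tibble::tibble(pc_id = c("PC_TA1", "PC_TA2", "PC_TA3"),
                       ta_family = c("Pemk", "HicB", "YoeB"),
                       role = c("toxin", "antitoxin", "toxin"))
  expect_warning(expect_warning(
    out <- screen_ta_and_correlate(ta, pc_ab, diet,
      pc_lifestyles = tibble::tibble(pc_id = c("PC_TA1", "PC_TA2"),
                                     lifestyle = "temperate")),
    "constant"), "absent")
  r_leaf <- out$correlations$r[out$correlations$pc_id == "PC_TA1" &
                                 out$correlations$axis == "leaf"]
  expect_equal(r_leaf, 1)
  r_fruit <- out$correlations$r[out$correlations$pc_id == "PC_TA1" &
                                  out$correlations$axis == "fruit"]
  expect_equal(r_fruit, -1)
  expect_equal(out$counts$n_ta_pcs, 2L)
})
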