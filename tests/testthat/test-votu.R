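mk_hit <- function(qs, qe, ident, bits, ss = qs, se = qe) {
  tibble::tibble(query_id = "a", subject_id = "b", pct_identity = ident,
                 aln_length = qe - qs + 1L, mismatches = 0L, gap_opens = 0L,
                 q_start = qs, q_end = qe, s_start = ss, s_end = se,
                 evalue = 0, bit_score = bits)
}

test_that("ANI is the length-weighted fragment identity; AF the covered fraction", {
  hits <- dplyr::bind_rows(mk_hit(1L, 1000L, 100, 2000),
                           mk_hit(2001L, 3000L, 90, 1800))
  r <- compute_ani_af(hits, 10000, 10000)
  expect_equal(r$ani, 95)
  expect_equal(r$af_a, 20)

  full <- mk_hit(1L, 10000L, 97, 19000)
  r2 <- compute_ani_af(full, 10000, 10000)
  expect_equal(r2$ani, 97)
  expect_equal(r2$af_a, 100)

  expect_equal(compute_ani_af(mk_hit(1L, 10L, 90, 1)[0, ], 100, 100)$ani, 0)
})

test_that("fully-overlapping fragments count covered bases once, best bits first", {
  hits <- dplyr::bind_rows(mk_hit(1L, 1000L, 90, 500),
                           mk_hit(1L, 1000L, 100, 2000))
  r <- compute_ani_af(hits, 10000, 10000)
  expect_equal(r$ani, 100)       # low-bits fragment adds no novel bases
  expect_equal(r$af_a, 10)
})

test_that("AF equals an independent interval-union oracle on random fragments", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    qs <- sample.int(900, n)
    qe <- pmin(1000L, qs + sample.int(300, n))
    hits <- purrr::map_dfr(seq_len(n), function(i)
      mk_hit(qs[i], qe[i], runif(1, 80, 100), runif(1, 100, 900)))
    r <- compute_ani_af(hits, 1000, 1000)
    union_width <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(qs, qe))))
    expect_equal(r$af_a, 100 * union_width / 1000)
    expect_true(r$ani <= max(hits$pct_identity) + 1e-9)
    expect_true(r$ani >= min(hits$pct_identity) - 1e-9)
  }
})

test_that("greedy clustering applies ANI/AF thresholds in seed-length order", {
  genomes <- tibble::tibble(genome_id = c("A", "B", "C"),
                            length = c(30000, 29000, 20000))
  recs <- tibble::tibble(
    genome_a = c("A", "A", "B"), genome_b = c("B", "C", "C"),
    ani = c(97, 80, 80), af_a = c(90, 90, 90), af_b = c(90, 90, 90))
  cl <- cluster_votus(genomes, recs)
  expect_equal(dplyr::n_distinct(cl$votu_id), 2)
  expect_equal(cl$votu_id[cl$genome_id == "A"],
               cl$votu_id[cl$genome_id == "B"])
  expect_true(cl$is_representative[cl$genome_id == "A"])

  # all below threshold -> singletons
  recs0 <- dplyr::mutate(recs, ani = 80)
  expect_equal(dplyr::n_distinct(
    cluster_votus(genomes, recs0)$votu_id), 3)
  expect_error(cluster_votus(
    tibble::tibble(genome_id = c("A", "A"), length = c(1, 2)), recs),
    "duplicate")
})

test_that("clustering is a partition and recovers planted truth (oracle ANI)", {
  com <- generate_community(n_votus = 4, members_per_votu = 3,
                            genome_len = 10000, seed = 31)
  hits <- simulate_alignment_hits(com$genomes, com$truth)
  ani <- ani_table(hits, com$genomes)
  # weighted-fragment ANI agrees with whole-genome brute-force identity
  seqs <- stats::setNames(com$genomes$sequence, com$genomes$genome_id)
  for (i in seq_len(nrow(ani))) {
    expect_equal(ani$ani[i],
                 oracle_identity(seqs[[ani$genome_a[i]]],
                                 seqs[[ani$genome_b[i]]]),
                 tolerance = 1e-8)
  }
  cl <- cluster_votus(com$genomes, ani)
  expect_setequal(cl$genome_id, com$genomes$genome_id)
  expect_equal(anyDuplicated(cl$genome_id), 0)
  truth <- com$truth$genomes$votu_id[match(cl$genome_id,
                                           com$truth$genomes$genome_id)]
  expect_equal(ari(cl$votu_id, truth), 1.0)
})

test_that("lifestyle splitting obeys the inclusion-exclusion identity", {
  clusters <- tibble::tibble(
    votu_id = c("v1", "v1", "v1", "v2", "v2", "v3"),
    genome_id = paste0("g", 1:6),
    is_representative = c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))
  attrs <- tibble::tibble(
    genome_id = paste0("g", 1:6),
    lifestyle = c("virulent", "virulent", "temperate",
                  "temperate", "temperate", "virulent"))
  sp <- split_votu(clusters, attrs, "lifestyle")
  expect_equal(sort(unique(sp$subpop_id)),
               c("Tem-v1", "Tem-v2", "Vir-v1", "Vir-v3"))
  n_sub <- dplyr::n_distinct(sp$subpop_id)
  dual <- sp |>
    dplyr::distinct(votu_id, lifestyle) |>
    dplyr::count(votu_id) |>
    dplyr::filter(n > 1) |>
    nrow()
  expect_equal(n_sub - dual, dplyr::n_distinct(clusters$votu_id))
  expect_error(split_votu(clusters, attrs[-1, ], "lifestyle"), "missing")
})

test_that("the published vOTU split counts satisfy the same identity", {
  # lifestyle split: 1072 virulent + 2157 temperate sub-populations with
  # 440 dual clusters; source split: 1571 VM + 2152 MM with 934 shared
  expect_identical(1072L + 2157L - 440L, 2789L)
  expect_identical(1571L + 2152L - 934L, 2789L)
  expect_identical(637L + 934L + 1218L, 2789L)
  expect_identical(17449L + 21749L, 39198L)
  expect_identical(15495L + 23703L, 39198L)
})

test_that("representatives are the longest member, ties to the smaller ID", {
  subpops <- tibble::tibble(subpop_id = c("s1", "s1", "s2", "s2", "s3"),
                            genome_id = c("gB", "gA", "gD", "gC", "gE"))
  genomes <- tibble::tibble(genome_id = c("gA", "gB", "gC", "gD", "gE"),
                            length = c(12000, 15000, 12000, 12000, 9000))
  reps <- select_representatives(subpops, genomes)
  expect_equal(reps$representative[reps$subpop_id == "s1"], "gB")
  expect_equal(reps$representative[reps$subpop_id == "s2"], "gC")
  expect_equal(reps$representative[reps$subpop_id == "s3"], "gE")
  expect_error(select_representatives(subpops[0, ], genomes), "empty")
})
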