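# Shared fixtures and independent oracle helpers.

# adjusted Rand index between two labelings (closed-form, independent of
# any clustering code under test)
ari <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# whole-genome percent identity for equal-length ungapped sequences
# (brute-force ANI oracle for the substitution-only simulator)
oracle_identity <- function(seq_a, seq_b) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  stopifnot(length(a) == length(b))
  100 * mean(a == b)
}

# literal BH step-up definition, independent of stats::p.adjust
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(ranked)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# brute-force all-positions exact substring scan on both strands
oracle_spacer_hits <- function(spacer, genome) {
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(spacer)))
  n <- nchar(genome); k <- nchar(spacer)
  hits <- 0L
  for (i in seq_len(n - k + 1)) {
    w <- substr(genome, i, i + k - 1)
    if (w == spacer || w == rc) hits <- hits + 1L
  }
  hits
}

# a small community reused by several module tests
tiny_community <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_community(n_votus = 4, members_per_votu = 3,
                                   genome_len = 10000,
                                   genes_per_genome = 4, seed = 101)
    }
    cache
  }
})

# minimal truth object (votu/lifestyle layout only) for abundance-level
# simulations that do not need genome sequences
make_truth <- function(n_votus, frac_temperate = 0.5) {
  lifestyles <- rep(c("virulent", "temperate"),
                    length.out = n_votus)
  if (frac_temperate == 0) lifestyles[] <- "virulent"
  structure(list(
    genomes = tibble::tibble(
      genome_id = sprintf("g_%03d_1", seq_len(n_votus)),
      votu_id = sprintf("sim_vOTU_%03d", seq_len(n_votus)),
      lifestyle = lifestyles,
      source = "VM", is_prophage = FALSE
    ),
    votu_ids = sprintf("sim_vOTU_%03d", seq_len(n_votus)),
    intra_div = 0.02, genome_len = 10000
  ), class = "sim_truth")
}
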