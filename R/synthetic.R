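#' @importFrom rlang .data
NULL

DNA_BASES <- c("A", "C", "G", "T")
AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

random_aa <- function(n) {
  paste(sample(AA_LETTERS, n, replace = TRUE), collapse = "")
}

# i.i.d. substitution over the 3 alternative symbols; no indels, so the
# expected pairwise identity stays analytically 1 - rate (up to coincident
# hits at the same site).
mutate_seq <- function(seq, rate, alphabet = DNA_BASES) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(alphabet, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

gc_percent <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  100 * mean(chars %in% c("G", "C"))
}

#' Generate a synthetic phage community with planted vOTU structure
#'
#' Each vOTU descends from one random ancestor genome; members are produced
#' by i.i.d. substitution at rate `intra_div` (pairwise member divergence is
#' therefore ~ `2 * intra_div`, safely inside the 5% population boundary at
#' the default 2%). Ancestors are mutually unrelated random sequences, so
#' realized inter-vOTU divergence is far above any clustering threshold.
#' Genes are tiled along each genome with category labels and per-gene
#' protein products (members of a vOTU carry mutated copies of the ancestral
#' proteins, so they co-cluster at the 60%/80% protein thresholds).
#'
#' @param n_votus Number of planted populations.
#' @param members_per_votu Genomes per population.
#' @param genome_len Genome length in bases (>= 10 kb, the minimum
#'   admissible contig size).
#' @param intra_div Per-member substitution rate from the ancestor
#'   (must be < 0.05).
#' @param inter_div Nominal between-population divergence floor
#'   (must be > 0.05 and > `intra_div`; realized divergence of independent
#'   ancestors is ~0.75).
#' @param frac_temperate Fraction of populations given the temperate
#'   lifestyle (members inherit it; prophage flags are set on roughly half
#'   of temperate members).
#' @param genes_per_genome Number of tiled genes per genome.
#' @param protein_len Amino-acid length of each gene product.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @return A list with tibbles `genomes`, `genes`, `summaries`
#'   (CheckV-style gene-count summaries), `coding_scores`, `episomal`
#'   (lifestyle labels for non-prophage genomes) and a `truth` list
#'   recording every planted fact.
#' @export
generate_community <- function(n_votus = 20, members_per_votu = 3,
                               genome_len = 15000, intra_div = 0.02,
                               inter_div = 0.15, frac_temperate = 0.5,
                               genes_per_genome = 10, protein_len = 120,
                               seed = 1) {
  if (!(intra_div < 0.05 && inter_div > 0.05 && intra_div < inter_div)) {
    stop("inconsistent divergence ordering: need intra_div < 5% < inter_div")
  }
  if (genome_len < 10000) stop("genome_len must be >= 10 kb")
  withr::with_seed(seed, {
    votu_ids <- sprintf("sim_vOTU_%03d", seq_len(n_votus))
    n_tem <- round(frac_temperate * n_votus)
    # deterministic lifestyle layout: alternate so neither lifestyle is
    # confounded with vOTU index blocks
    lifestyles <- rep("virulent", n_votus)
    if (n_tem > 0) {
      lifestyles[seq(2, by = 2, length.out = min(n_tem, floor(n_votus / 2)))] <-
        "temperate"
      extra <- n_tem - sum(lifestyles == "temperate")
      if (extra > 0) {
        lifestyles[which(lifestyles == "virulent")[seq_len(extra)]] <-
          "temperate"
      }
    }

    genomes <- list(); genes <- list(); truth_rows <- list()
    gene_len <- 3 * ceiling((protein_len + 1) * 1.0)  # nt per tiled gene
    spacing <- max(60L, (genome_len - 100L - genes_per_genome * gene_len) %/%
                     max(1L, genes_per_genome))
    for (v in seq_len(n_votus)) {
      ancestor <- random_dna(genome_len)
      anc_prot <- vapply(seq_len(genes_per_genome), function(g)
        random_aa(protein_len), character(1))
      for (m in seq_len(members_per_votu)) {
        gid <- sprintf("g_%03d_%d", v, m)
        gseq <- mutate_seq(ancestor, intra_div)
        is_pro <- lifestyles[v] == "temperate" && (m %% 2 == 0)
        genomes[[gid]] <- tibble::tibble(
          genome_id = gid, sequence = gseq, length = genome_len,
          source = if (m %% 2 == 1) "VM" else "MM",
          is_prophage = is_pro, genetic_code = 11L
        )
        starts <- 101L + (seq_len(genes_per_genome) - 1L) *
          (gene_len + spacing)
        genes[[gid]] <- tibble::tibble(
          genome_id = gid,
          gene_id = sprintf("%s_gene%02d", gid, seq_len(genes_per_genome)),
          start = starts, end = starts + gene_len - 1L,
          strand = rep_len(c("+", "-"), genes_per_genome),
          category = c("hallmark",
                       rep("viral", genes_per_genome - 1L)),
          protein_id = sprintf("%s_prot%02d", gid,
                               seq_len(genes_per_genome)),
          protein_seq = vapply(anc_prot, function(p)
            mutate_seq(p, intra_div, AA_LETTERS), character(1),
            USE.NAMES = FALSE)
        )
        truth_rows[[gid]] <- tibble::tibble(
          genome_id = gid, votu_id = votu_ids[v],
          lifestyle = lifestyles[v],
          source = genomes[[gid]]$source,
          is_prophage = is_pro
        )
      }
    }
    genomes <- dplyr::bind_rows(genomes)
    genes <- dplyr::bind_rows(genes)
    truth_genomes <- dplyr::bind_rows(truth_rows)

    summaries <- genes |>
      dplyr::group_by(contig_id = .data$genome_id) |>
      dplyr::summarise(
        viral_genes = sum(.data$category == "viral"),
        host_genes = sum(.data$category == "host"),
        hallmark_genes = sum(.data$category == "hallmark"),
        .groups = "drop"
      ) |>
      dplyr::left_join(
        genomes |>
          dplyr::transmute(contig_id = .data$genome_id, length = .data$length,
                           gc = vapply(.data$sequence, gc_percent,
                                       numeric(1), USE.NAMES = FALSE)),
        by = "contig_id"
      )

    coding_scores <- tidyr::crossing(
      contig_id = genomes$genome_id,
      code = c(11L, 4L, 25L, 15L, 91L)
    ) |>
      dplyr::mutate(score = ifelse(.data$code == 11L,
                                   stats::runif(dplyr::n(), 95, 105),
                                   stats::runif(dplyr::n(), 50, 80)))

    episomal <- truth_genomes |>
      dplyr::filter(!.data$is_prophage) |>
      dplyr::transmute(genome_id = .data$genome_id,
                       episomal_label = .data$lifestyle)

    list(
      genomes = genomes, genes = genes, summaries = summaries,
      coding_scores = coding_scores, episomal = episomal,
      truth = structure(list(genomes = truth_genomes,
                             votu_ids = votu_ids,
                             intra_div = intra_div,
                             genome_len = genome_len),
                        class = "sim_truth")
    )
  })
}

#' Emulate an all-vs-all nucleotide alignment table for planted communities
#'
#' Fragment hits are emitted for genome pairs of the same planted vOTU only
#' (unrelated random ancestors would not produce reportable local
#' alignments). Each pair is covered by `n_fragments` equal windows whose
#' identity is the realized per-window base identity, so
#' [compute_ani_af()]'s length-weighted merge can be checked against direct
#' whole-genome identity.
#'
#' @param genomes Tibble with `genome_id`, `sequence` (equal lengths).
#' @param truth The `truth` element of [generate_community()].
#' @param n_fragments Windows per pair.
#' @return A tibble of 12-column alignment hits (both orientations).
#' @export
simulate_alignment_hits <- function(genomes, truth, n_fragments = 3) {
  pairs <- truth$genomes |>
    dplyr::select("genome_id", "votu_id") |>
    dplyr::inner_join(truth$genomes |>
                        dplyr::select(genome_id2 = "genome_id", "votu_id"),
                      by = "votu_id",
                      relationship = "many-to-many") |>
    dplyr::filter(.data$genome_id < .data$genome_id2)
  seqs <- stats::setNames(genomes$sequence, genomes$genome_id)
  out <- purrr::pmap(pairs, function(genome_id, genome_id2, votu_id) {
    a <- strsplit(seqs[[genome_id]], "")[[1]]
    b <- strsplit(seqs[[genome_id2]], "")[[1]]
    L <- length(a)
    bounds <- floor(seq(0, L, length.out = n_fragments + 1))
    purrr::map_dfr(seq_len(n_fragments), function(k) {
      from <- bounds[k] + 1L; to <- bounds[k + 1]
      ident <- 100 * mean(a[from:to] == b[from:to])
      len <- to - from + 1L
      tibble::tibble(
        query_id = c(genome_id, genome_id2),
        subject_id = c(genome_id2, genome_id),
        pct_identity = ident, aln_length = len,
        mismatches = as.integer(round(len * (1 - ident / 100))),
        gap_opens = 0L,
        q_start = from, q_end = to, s_start = from, s_end = to,
        evalue = 0, bit_score = round(2 * len * ident / 100, 1)
      )
    })
  })
  dplyr::bind_rows(out)
}

#' Generate prokaryotic hosts with planted spacers and shared genes
#'
#' Hosts are random genomes assigned phage populations grouped by lifestyle
#' (virulent populations on the first half of the hosts, temperate on the
#' rest) so lifestyle-stratified summaries have clean planted structure.
#' Family labels start with Lachnospiraceae (virulent side) and
#' Bacteroidaceae (temperate side), the families carried by the planted
#' diet-responsive populations. Each planted spacer is copied verbatim from
#' a member genome of an assigned population (reverse-complemented with
#' probability `revcomp_frac`); each host-population link receives
#' `shared_genes_per_pair` protein copies planted into the host's gene set.
#' `n_background_shared` extra copies are planted into hosts chosen at
#' random regardless of links, providing link-independent sharing for null
#' analyses.
#'
#' @param community Output of [generate_community()].
#' @param n_hosts Number of host genomes.
#' @param spacers_per_host CRISPR spacers planted per host.
#' @param shared_genes_per_pair Protein copies planted per host-population
#'   link.
#' @param n_background_shared Link-independent planted protein copies.
#' @param spacer_len Spacer length (25-45 nt window; default 32).
#' @param host_genome_len Host genome length.
#' @param host_own_proteins Unrelated proteins per host genome.
#' @param revcomp_frac Probability a spacer is placed reverse-complemented.
#' @param defense_mean_virulent,defense_mean_temperate Poisson means for
#'   planted anti-phage system counts on virulent- vs temperate-assigned
#'   hosts.
#' @param seed Integer seed.
#' @return List with tibbles `hosts`, `spacers`, `host_proteins`,
#'   `families`, `defense`, and a `truth` list (`links`, `spacer_truth`,
#'   `shared_truth`).
#' @export
generate_hosts <- function(community, n_hosts = 6, spacers_per_host = 2,
                           shared_genes_per_pair = 1,
                           n_background_shared = 0,
                           spacer_len = 32, host_genome_len = 20000,
                           host_own_proteins = 8, revcomp_frac = 0.5,
                           defense_mean_virulent = 5,
                           defense_mean_temperate = 2, seed = 1) {
  if (spacer_len < 25 || spacer_len > 45) {
    stop("spacer_len must be in 25-45 nt")
  }
  truth <- community$truth
  if (spacers_per_host > truth$genome_len - spacer_len) {
    stop("more spacers requested than available positions")
  }
  withr::with_seed(seed, {
    host_ids <- sprintf("h_%02d", seq_len(n_hosts))
    pops <- truth$genomes |>
      dplyr::distinct(.data$votu_id, .data$lifestyle)
    vir <- pops$votu_id[pops$lifestyle == "virulent"]
    tem <- pops$votu_id[pops$lifestyle == "temperate"]
    n_vir_hosts <- max(1L, min(n_hosts - 1L, round(n_hosts / 2)))
    vir_hosts <- host_ids[seq_len(n_vir_hosts)]
    tem_hosts <- host_ids[(n_vir_hosts + 1L):n_hosts]
    fam_pool <- c("Oscillospiraceae", "Ruminococcaceae", "Prevotellaceae",
                  "Rikenellaceae", "Akkermansiaceae", "Tannerellaceae")
    families <- tibble::tibble(
      host_id = host_ids,
      family = c(
        c("Lachnospiraceae",
          rep_len(fam_pool, length(vir_hosts) - 1))[seq_along(vir_hosts)],
        c("Bacteroidaceae",
          rep_len(rev(fam_pool), length(tem_hosts) - 1))[seq_along(tem_hosts)]
      )
    )
    links <- dplyr::bind_rows(
      tibble::tibble(phage_pop_id = vir,
                     host_id = rep_len(vir_hosts, length(vir))),
      tibble::tibble(phage_pop_id = tem,
                     host_id = rep_len(tem_hosts, length(tem)))
    )

    hosts <- tibble::tibble(
      host_id = host_ids,
      sequence = vapply(host_ids, function(h) random_dna(host_genome_len),
                        character(1), USE.NAMES = FALSE),
      family = families$family
    )

    # spacers: exact substrings of member genomes of linked populations
    member_of <- split(truth$genomes$genome_id, truth$genomes$votu_id)
    seqs <- stats::setNames(community$genomes$sequence,
                            community$genomes$genome_id)
    spacer_rows <- list(); spacer_truth <- list(); k <- 0L
    for (h in host_ids) {
      my_pops <- links$phage_pop_id[links$host_id == h]
      if (length(my_pops) == 0) next   # more hosts than populations
      take <- rep_len(my_pops, spacers_per_host)
      for (p in take) {
        k <- k + 1L
        gid <- sample(member_of[[p]], 1)
        pos <- sample.int(nchar(seqs[[gid]]) - spacer_len + 1L, 1)
        sp <- substr(seqs[[gid]], pos, pos + spacer_len - 1L)
        rc <- stats::runif(1) < revcomp_frac
        spacer_rows[[k]] <- tibble::tibble(
          spacer_id = sprintf("sp_%03d", k), host_id = h,
          sequence = if (rc) revcomp(sp) else sp
        )
        spacer_truth[[k]] <- tibble::tibble(
          spacer_id = sprintf("sp_%03d", k), host_id = h,
          genome_id = gid, phage_pop_id = p, position = pos,
          revcomp = rc
        )
      }
    }

    # host proteins: own random proteins + planted copies of phage proteins
    phage_prot <- community$genes |>
      dplyr::left_join(truth$genomes |>
                         dplyr::select("genome_id", "votu_id"),
                       by = "genome_id")
    prot_rows <- list(); shared_truth <- list(); j <- 0L
    for (h in host_ids) {
      for (i in seq_len(host_own_proteins)) {
        j <- j + 1L
        prot_rows[[j]] <- tibble::tibble(
          protein_id = sprintf("%s_own%02d", h, i), host_id = h,
          sequence = random_aa(120)
        )
      }
      my_pops <- links$phage_pop_id[links$host_id == h]
      for (p in my_pops) {
        cand <- phage_prot[phage_prot$votu_id == p, ]
        if (shared_genes_per_pair > 0 && nrow(cand) > 0) {
          pick <- cand[sample.int(nrow(cand),
                                  min(shared_genes_per_pair, nrow(cand))), ]
          for (r in seq_len(nrow(pick))) {
            j <- j + 1L
            prot_rows[[j]] <- tibble::tibble(
              protein_id = sprintf("%s_hgt%s_%02d", h, p, r), host_id = h,
              sequence = pick$protein_seq[r]
            )
            shared_truth[[length(shared_truth) + 1L]] <- tibble::tibble(
              host_id = h, phage_pop_id = p,
              source_protein = pick$protein_id[r], background = FALSE
            )
          }
        }
      }
    }
    if (n_background_shared > 0) {
      for (b in seq_len(n_background_shared)) {
        j <- j + 1L
        h <- sample(host_ids, 1)
        pick <- phage_prot[sample.int(nrow(phage_prot), 1), ]
        prot_rows[[j]] <- tibble::tibble(
          protein_id = sprintf("%s_bg%03d", h, b), host_id = h,
          sequence = pick$protein_seq
        )
        shared_truth[[length(shared_truth) + 1L]] <- tibble::tibble(
          host_id = h, phage_pop_id = pick$votu_id,
          source_protein = pick$protein_id, background = TRUE
        )
      }
    }

    host_lifestyle <- tibble::tibble(
      host_id = host_ids,
      assigned_lifestyle = ifelse(host_ids %in% vir_hosts,
                                  "virulent", "temperate")
    )
    defense <- tidyr::crossing(prok_genome_id = host_ids,
                               system_name = c("RM", "CRISPR-Cas")) |>
      dplyr::left_join(host_lifestyle,
                       by = c(prok_genome_id = "host_id")) |>
      dplyr::mutate(count = stats::rpois(
        dplyr::n(),
        ifelse(.data$assigned_lifestyle == "virulent",
               defense_mean_virulent / 2, defense_mean_temperate / 2))) |>
      dplyr::select("prok_genome_id", "system_name", "count")

    list(
      hosts = hosts,
      spacers = dplyr::bind_rows(spacer_rows),
      host_proteins = dplyr::bind_rows(prot_rows),
      families = families,
      defense = defense,
      truth = list(links = links,
                   spacer_truth = dplyr::bind_rows(spacer_truth),
                   shared_truth = dplyr::bind_rows(shared_truth),
                   host_lifestyle = host_lifestyle)
    )
  })
}

#' Generate a two-season abundance time series with planted responders
#'
#' Two feeding seasons (high-fruit, high-leaf) of `n_dates_per_season`
#' sampling dates each. Every population draws a lognormal baseline
#' abundance; planted responsive virulent populations are multiplied by
#' `effect_multiplier` in the high-leaf season and responsive temperate
#' populations divided by it (the direction observed for
#' Lachnospiraceae-linked virulent and Bacteroidaceae-linked temperate
#' populations). All per-sample values carry multiplicative lognormal noise.
#' Full-day feeding bouts per date give fruit proportion > 0.7 on HF dates
#' and leaf proportion > 0.7 on HL dates.
#'
#' @param truth The `truth` element of [generate_community()].
#' @param n_dates_per_season Sampling dates per season (warning if < 3:
#'   tests under-powered).
#' @param mu,sigma Lognormal baseline abundance parameters (log scale).
#' @param effect_multiplier Planted seasonal fold change (1 = no effect).
#' @param noise_sigma Lognormal noise sd (log scale).
#' @param responsive_frac Fraction of populations per lifestyle planted as
#'   responsive (ignored when `effect_multiplier` is 1, which plants none).
#' @param individual Individual label for the sample metadata.
#' @param make_depth If `TRUE`, also emit per-base depth profiles
#'   (Poisson around `depth_scale * abundance`) for one representative
#'   genome per population.
#' @param genomes Community `genomes` tibble; required when
#'   `make_depth = TRUE`.
#' @param depth_scale Multiplier from abundance to expected per-base depth.
#' @param seed Integer seed.
#' @return List with tibbles `metadata`, `abundance` (long:
#'   population_id, sample_id, abundance), `bouts`, optional `depth`, and
#'   `effects` (the planted per-population HL multipliers).
#' @export
generate_timeseries <- function(truth, n_dates_per_season = 6, mu = 2,
                                sigma = 0.8, effect_multiplier = 5,
                                noise_sigma = 0.3, responsive_frac = 0.2,
                                individual = "A2", make_depth = FALSE,
                                genomes = NULL, depth_scale = 1, seed = 1) {
  if (n_dates_per_season < 3) {
    warning("fewer than 3 dates per season: season tests are under-powered")
  }
  if (make_depth && is.null(genomes)) {
    stop("make_depth = TRUE requires the community genomes tibble")
  }
  withr::with_seed(seed, {
    pops <- truth$genomes |>
      dplyr::distinct(.data$votu_id, .data$lifestyle) |>
      dplyr::arrange(.data$votu_id)
    effects <- pops |>
      dplyr::group_by(.data$lifestyle) |>
      dplyr::mutate(rank = dplyr::row_number(),
                    responsive = effect_multiplier != 1 &
                      .data$rank <= ceiling(responsive_frac * dplyr::n())) |>
      dplyr::ungroup() |>
      dplyr::mutate(multiplier_hl = dplyr::case_when(
        !.data$responsive ~ 1,
        .data$lifestyle == "virulent" ~ effect_multiplier,
        TRUE ~ 1 / effect_multiplier
      )) |>
      dplyr::select("votu_id", "lifestyle", "responsive", "multiplier_hl")

    hf_dates <- as.Date("2018-01-01") + 2 * (seq_len(n_dates_per_season) - 1)
    hl_dates <- as.Date("2018-07-01") + 2 * (seq_len(n_dates_per_season) - 1)
    metadata <- tibble::tibble(
      sample_id = paste0(individual, "_", format(c(hf_dates, hl_dates))),
      individual = individual,
      date = c(hf_dates, hl_dates),
      season_truth = rep(c("HF", "HL"), each = n_dates_per_season)
    )

    base <- stats::rlnorm(nrow(effects), mu, sigma)
    abundance <- tidyr::crossing(
      effects |> dplyr::mutate(base = base),
      metadata |> dplyr::select("sample_id", "season_truth")
    ) |>
      dplyr::mutate(abundance = .data$base *
                      ifelse(.data$season_truth == "HL",
                             .data$multiplier_hl, 1) *
                      stats::rlnorm(dplyr::n(), 0, noise_sigma)) |>
      dplyr::transmute(population_id = .data$votu_id,
                       lifestyle = .data$lifestyle,
                       sample_id = .data$sample_id,
                       abundance = .data$abundance)

    # full-day bouts; durations jittered but proportions kept > 0.7 for the
    # season-defining food type
    bouts <- purrr::map_dfr(seq_len(nrow(metadata)), function(i) {
      hf <- metadata$season_truth[i] == "HF"
      dur <- if (hf) c(fruit = 250, leaf = 45, flower = 20, other = 15)
             else c(leaf = 260, fruit = 40, flower = 15, other = 15)
      dur <- round(dur * stats::runif(4, 0.9, 1.1))
      start <- 420 + cumsum(c(0, utils::head(dur, -1) + 5))
      tibble::tibble(
        individual = metadata$individual[i],
        date = metadata$date[i],
        food_type = names(dur),
        start_min = start, end_min = start + dur
      )
    })

    depth <- NULL
    if (make_depth) {
      reps <- truth$genomes |>
        dplyr::group_by(.data$votu_id) |>
        dplyr::slice_min(.data$genome_id, n = 1) |>
        dplyr::ungroup() |>
        dplyr::select("votu_id", "genome_id")
      glen <- stats::setNames(nchar(genomes$sequence), genomes$genome_id)
      depth <- abundance |>
        dplyr::inner_join(reps, by = c(population_id = "votu_id")) |>
        dplyr::group_by(.data$genome_id, .data$sample_id) |>
        dplyr::reframe(position = seq_len(glen[[.data$genome_id[1]]]),
                       depth = stats::rpois(glen[[.data$genome_id[1]]],
                                            depth_scale *
                                              .data$abundance[1]))
    }

    list(metadata = metadata, abundance = abundance, bouts = bouts,
         depth = depth, effects = effects)
  })
}

#' Generate SNP pileup time series with lifestyle-dependent turnover
#'
#' Each genome starts with `sites_per_genome` planted variant sites; on each
#' subsequent date every variant survives with probability `1 - turnover`
#' (turnover chosen by lifestyle) and lost variants are replaced by new ones
#' at fresh positions so the site count stays constant. Pileups encode every
#' current variant with alternative-read counts comfortably above the
#' calling filters (count >= 5 at the default depth 50, quality 37).
#'
#' @param truth The `truth` element of [generate_community()].
#' @param genomes Community `genomes` tibble (for reference bases).
#' @param n_dates Number of daily sampling dates.
#' @param sites_per_genome Planted variant sites per genome.
#' @param turnover_virulent,turnover_temperate Per-day variant loss
#'   probabilities by lifestyle.
#' @param depth Per-site read depth (must be >= 10, the downstream genome
#'   eligibility floor).
#' @param genomes_per_lifestyle How many representative genomes per
#'   lifestyle to simulate.
#' @param seed Integer seed.
#' @return List with `pileups` (tibble: genome_id, sample_id, date,
#'   position, ref_base, base, count, mean_qual), `variant_truth` (planted
#'   variant sets per genome and date) and `lifestyles` (genome_id,
#'   lifestyle).
#' @export
generate_snp_series <- function(truth, genomes, n_dates = 10,
                                sites_per_genome = 20,
                                turnover_virulent = 0.3,
                                turnover_temperate = 0.1, depth = 50,
                                genomes_per_lifestyle = 3, seed = 1) {
  if (depth < 10) {
    stop("depth must be >= 10 (violates the genome-selection rule)")
  }
  stopifnot(turnover_virulent >= 0, turnover_virulent < 1,
            turnover_temperate >= 0, turnover_temperate < 1)
  withr::with_seed(seed, {
    reps <- truth$genomes |>
      dplyr::group_by(.data$votu_id) |>
      dplyr::slice_min(.data$genome_id, n = 1) |>
      dplyr::ungroup() |>
      dplyr::group_by(.data$lifestyle) |>
      dplyr::slice_head(n = genomes_per_lifestyle) |>
      dplyr::ungroup()
    seqs <- stats::setNames(genomes$sequence, genomes$genome_id)
    dates <- as.Date("2018-03-01") + (seq_len(n_dates) - 1)

    pile <- list(); vtruth <- list()
    for (r in seq_len(nrow(reps))) {
      gid <- reps$genome_id[r]
      rho <- if (reps$lifestyle[r] == "virulent") turnover_virulent
             else turnover_temperate
      gseq <- strsplit(seqs[[gid]], "")[[1]]
      L <- length(gseq)
      new_variants <- function(n, exclude) {
        pos <- sample(setdiff(seq_len(L), exclude), n)
        tibble::tibble(
          position = pos,
          ref_base = gseq[pos],
          alt_base = vapply(gseq[pos], function(b)
            sample(setdiff(DNA_BASES, b), 1), character(1),
            USE.NAMES = FALSE),
          alt_freq = stats::runif(n, 0.1, 0.4)
        )
      }
      cur <- new_variants(sites_per_genome, integer(0))
      for (d in seq_len(n_dates)) {
        if (d > 1) {
          keep <- stats::runif(nrow(cur)) >= rho
          lost <- sum(!keep)
          cur <- cur[keep, ]
          if (lost > 0) {
            cur <- dplyr::bind_rows(cur, new_variants(lost, cur$position))
          }
        }
        alt_n <- pmax(5L, as.integer(round(cur$alt_freq * depth)))
        sid <- paste0(gid, "_", format(dates[d]))
        pile[[length(pile) + 1L]] <- tibble::tibble(
          genome_id = gid, sample_id = sid, date = dates[d],
          position = rep(cur$position, 2L),
          ref_base = rep(cur$ref_base, 2L),
          base = c(cur$ref_base, cur$alt_base),
          count = c(depth - alt_n, alt_n),
          mean_qual = 37
        )
        vtruth[[length(vtruth) + 1L]] <- cur |>
          dplyr::mutate(genome_id = gid, date = dates[d], .before = 1)
      }
    }
    list(
      pileups = dplyr::bind_rows(pile),
      variant_truth = dplyr::bind_rows(vtruth),
      lifestyles = reps |> dplyr::select("genome_id", "lifestyle")
    )
  })
}
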