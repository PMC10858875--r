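need_input <- function(manifest, key, stage) {
  if (is.null(manifest[[key]])) {
    stop("manifest is missing '", key, "' required by the ", stage,
         " stage")
  }
  manifest[[key]]
}

#' Run the full phageome pipeline
#'
#' Chains every stage end to end: candidate screening and lifestyle
#' resolution, vOTU clustering with lifestyle/source splitting, tpmean
#' abundance, diet-season assignment and responsive-population testing,
#' spacer host linkage, protein clustering with shared-PC statistics, SNP
#' calling with similarity-vs-lag fits, and community ordination with
#' PERMANOVA. Every stage output is written as a TSV under `out_dir`, plus
#' a `log.txt` with one line per stage recording input/output record
#' counts. With a fixed config seed the outputs are byte-identical across
#' runs.
#'
#' @param out_dir Output directory (created if absent).
#' @param config A [phagedyn_config()].
#' @param manifest `NULL` or `list(synthetic = TRUE, sim = list(...))` to
#'   generate all inputs with planted truth (parameters in `sim` override
#'   the generator defaults), or a named list of input file paths:
#'   `summaries`, `coding_scores`, `episomal`, `genomes_fasta`, `genes`,
#'   `ani_hits`, `depth`, `metadata`, `bouts`, `spacers`, `proteins`,
#'   `pileups`. A missing entry raises an error naming the stage that
#'   needs it.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(out_dir, config = phagedyn_config(),
                         manifest = NULL) {
  stopifnot(inherits(config, "phagedyn_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    sprintf("phagedyn pipeline; seed=%d", config$seed),
    sprintf("thresholds: ani=%s af=%s (%s) pc=%s/%s snp=q>%s,alt>=%s,f>%s",
            config$ani, config$af, config$af_rule, config$pc_identity,
            config$pc_cov_short, config$snp_qual, config$snp_min_alt_reads,
            config$snp_min_alt_freq)
  )
  note <- function(stage, n_in, n_out) {
    log_lines <<- c(log_lines,
                    sprintf("stage=%s in=%d out=%d", stage, n_in, n_out))
  }
  put <- function(x, name) write_tsv_table(x, file.path(out_dir, name))

  synthetic <- is.null(manifest) || isTRUE(manifest$synthetic)
  if (synthetic) {
    sim <- manifest$sim %||% list()
    community <- do.call(generate_community, utils::modifyList(
      list(seed = config$seed), sim[names(sim) %in%
        names(formals(generate_community))]))
    hostgen <- do.call(generate_hosts, utils::modifyList(
      list(community = community, seed = config$seed + 1),
      sim[names(sim) %in% setdiff(names(formals(generate_hosts)),
                                  "community")]))
    ts <- do.call(generate_timeseries, utils::modifyList(
      list(truth = community$truth, make_depth = TRUE,
           genomes = community$genomes, depth_scale = 5,
           seed = config$seed + 2),
      sim[names(sim) %in% setdiff(names(formals(generate_timeseries)),
                                  c("truth", "genomes", "make_depth"))]))
    snpsim <- do.call(generate_snp_series, utils::modifyList(
      list(truth = community$truth, genomes = community$genomes,
           n_dates = 6, seed = config$seed + 3),
      sim[names(sim) %in% setdiff(names(formals(generate_snp_series)),
                                  c("truth", "genomes"))]))
    summaries <- community$summaries
    coding_scores <- community$coding_scores
    episomal <- community$episomal
    genomes <- community$genomes
    genes_tab <- community$genes
    ani_hits <- simulate_alignment_hits(community$genomes, community$truth)
    depth <- ts$depth
    metadata <- ts$metadata
    bouts <- ts$bouts
    spacers <- hostgen$spacers
    pileups <- snpsim$pileups
  } else {
    required <- c(summaries = "screen", coding_scores = "screen",
                  episomal = "screen", prophages = "screen",
                  genomes_fasta = "cluster", genes = "cluster",
                  ani_hits = "cluster", depth = "abundance",
                  metadata = "abundance", bouts = "diet",
                  spacers = "hosts", proteins = "genes",
                  pileups = "snps")
    for (k in names(required)) need_input(manifest, k, required[[k]])
    summaries <- read_tsv_table(need_input(manifest, "summaries", "screen"))
    coding_scores <- read_tsv_table(
      need_input(manifest, "coding_scores", "screen"))
    episomal <- read_tsv_table(need_input(manifest, "episomal", "screen"))
    fa <- read_fasta(need_input(manifest, "genomes_fasta", "cluster"))
    genomes <- dplyr::mutate(fa, genome_id = .data$id,
                             length = nchar(.data$sequence))
    genes_tab <- read_tsv_table(need_input(manifest, "genes", "cluster"))
    ani_hits <- read_alignment_table(
      need_input(manifest, "ani_hits", "cluster"))
    depth <- read_tsv_table(need_input(manifest, "depth", "abundance"))
    metadata <- read_tsv_table(need_input(manifest, "metadata",
                                          "abundance"))
    bouts <- read_tsv_table(need_input(manifest, "bouts", "diet"))
    spacers <- read_tsv_table(need_input(manifest, "spacers", "hosts"))
    pileups <- read_tsv_table(need_input(manifest, "pileups", "snps"))
  }

  # -- screen ---------------------------------------------------------
  screened <- screen_phage_candidates(summaries)
  codes <- select_genetic_code(coding_scores, screened)
  prophage_flags <- if (synthetic) {
    genomes[, c("genome_id", "is_prophage")]
  } else {
    need_input(manifest, "prophages", "screen") |> read_tsv_table()
  }
  lifestyle_in <- prophage_flags |>
    dplyr::left_join(episomal, by = "genome_id") |>
    dplyr::mutate(episomal_label = ifelse(.data$is_prophage, NA_character_,
                                          .data$episomal_label))
  lifestyles <- resolve_lifestyle(lifestyle_in)
  note("screen", nrow(summaries), sum(screened$keep))
  put(screened, "screened.tsv"); put(codes, "genetic_codes.tsv")
  put(lifestyles[, c("genome_id", "lifestyle")], "lifestyles.tsv")

  kept <- genomes[genomes$genome_id %in%
                    screened$contig_id[screened$keep], ]

  # -- cluster --------------------------------------------------------
  ani <- ani_table(ani_hits, kept)
  clusters <- cluster_votus(kept, ani, ani_min = config$ani,
                            af_min = config$af, af_rule = config$af_rule)
  sub_life <- split_votu(clusters,
                         lifestyles[, c("genome_id", "lifestyle")],
                         "lifestyle")
  sub_src <- if ("source" %in% names(genomes)) {
    split_votu(clusters, genomes[, c("genome_id", "source")], "source")
  } else NULL
  reps <- select_representatives(sub_life, kept)
  note("cluster", nrow(kept), dplyr::n_distinct(clusters$votu_id))
  put(clusters, "votu_members.tsv")
  put(sub_life, "subpops_lifestyle.tsv")
  if (!is.null(sub_src)) put(sub_src, "subpops_source.tsv")
  put(reps, "representatives.tsv")

  # -- abundance ------------------------------------------------------
  coverage <- tpmean_coverage(depth, config$trim_frac)
  rep_pop <- reps |>
    dplyr::left_join(dplyr::distinct(sub_life, .data$subpop_id,
                                     .data$votu_id, .data$lifestyle),
                     by = "subpop_id")
  abundance <- coverage |>
    dplyr::inner_join(rep_pop, by = c(genome_id = "representative")) |>
    dplyr::transmute(population_id = .data$subpop_id,
                     lifestyle = .data$lifestyle,
                     sample_id = .data$sample_id,
                     abundance = .data$coverage)
  prev <- prevalence_and_mean_abundance(abundance)
  note("abundance", nrow(depth), nrow(abundance))
  put(coverage, "coverage.tsv"); put(abundance, "abundance.tsv")
  put(prev, "prevalence.tsv")

  # -- diet -----------------------------------------------------------
  profiles <- diet_composition(bouts)
  seasons <- assign_seasons(profiles)
  sample_seasons <- metadata |>
    dplyr::mutate(date = as.Date(.data$date)) |>
    dplyr::left_join(seasons |> dplyr::mutate(date = as.Date(.data$date)),
                     by = c("individual", "date")) |>
    dplyr::select("sample_id", "season")
  note("diet", nrow(bouts), nrow(seasons))
  put(seasons, "seasons.tsv")

  # -- respond --------------------------------------------------------
  response <- abundance |>
    dplyr::group_by(.data$lifestyle) |>
    dplyr::group_modify(function(df, key)
      test_diet_responsive(df, sample_seasons,
                           alpha = config$fdr_alpha)) |>
    dplyr::ungroup()
  variation <- abundance_variation(abundance, sample_seasons)
  note("respond", nrow(abundance), sum(response$responsive))
  put(response, "diet_response.tsv")
  put(variation$per_population, "abundance_variation.tsv")

  # -- hosts ----------------------------------------------------------
  pop_map <- sub_life |>
    dplyr::select(genome_id = "genome_id", population_id = "subpop_id")
  links <- match_spacers(spacers, kept, pop_map)
  pop_life <- dplyr::distinct(sub_life, phage_pop_id = .data$subpop_id,
                              .data$lifestyle)
  ranges <- host_and_phage_range(links, pop_life)
  note("hosts", nrow(spacers), nrow(links))
  put(links, "host_links.tsv")
  put(ranges$host_range, "host_range.tsv")
  put(ranges$phage_range, "phage_range.tsv")

  # -- genes ----------------------------------------------------------
  proteins <- if (synthetic) {
    dplyr::bind_rows(
      genes_tab |>
        dplyr::inner_join(pop_map, by = "genome_id") |>
        dplyr::inner_join(lifestyles[, c("genome_id", "lifestyle")],
                          by = "genome_id") |>
        dplyr::transmute(protein_id = .data$protein_id,
                         sequence = .data$protein_seq,
                         origin = .data$lifestyle,
                         genome_id = .data$genome_id,
                         population_id = .data$population_id),
      hostgen$host_proteins |>
        dplyr::transmute(protein_id = .data$protein_id,
                         sequence = .data$sequence,
                         origin = "prokaryote",
                         genome_id = .data$host_id,
                         population_id = .data$host_id)
    )
  } else {
    read_tsv_table(need_input(manifest, "proteins", "genes"))
  }
  pcs <- cluster_proteins(proteins, identity = config$pc_identity,
                          cov_short = config$pc_cov_short)
  ratios <- shared_pc_ratio(pcs)
  note("genes", nrow(proteins), nrow(pcs$clusters))
  put(pcs$membership, "pc_membership.tsv")
  put(pcs$clusters, "pc_clusters.tsv")
  put(ratios, "shared_pc_ratio.tsv")

  # -- snps -----------------------------------------------------------
  variants <- call_snps(pileups, qual_min = config$snp_qual,
                        min_alt_reads = config$snp_min_alt_reads,
                        min_alt_freq = config$snp_min_alt_freq)
  vdates <- variants |>
    dplyr::left_join(dplyr::distinct(pileups, .data$sample_id,
                                     .data$date), by = "sample_id") |>
    dplyr::mutate(date = as.Date(.data$date))
  series <- similarity_series(vdates)
  genome_life <- if (synthetic) snpsim$lifestyles else
    dplyr::distinct(lifestyles, .data$genome_id, .data$lifestyle)
  snp_fit <- similarity_vs_lag(series, genome_life)
  note("snps", nrow(pileups), nrow(variants))
  put(variants, "snp_variants.tsv")
  put(series, "snp_similarity.tsv")
  put(snp_fit$fits, "snp_fits.tsv")

  # -- stats ----------------------------------------------------------
  hel <- hellinger_transform(abundance)
  d <- bray_curtis(hel)
  groups <- sample_seasons$season[match(colnames(d),
                                        sample_seasons$sample_id)]
  perm <- permanova(d, groups, n_perm = config$n_perm, seed = config$seed)
  note("stats", ncol(d), 1L)
  put(tidy(perm), "permanova.tsv")

  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(screened = screened, clusters = clusters,
                 sub_life = sub_life, abundance = abundance,
                 seasons = seasons, response = response, links = links,
                 pcs = pcs, variants = variants, snp_fit = snp_fit,
                 permanova = perm))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
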