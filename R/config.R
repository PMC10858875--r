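#' Pipeline run configuration
#'
#' Collects every numeric threshold used across the pipeline stages, with
#' defaults matching the published protocol the package implements:
#' vOTU clustering at 95% ANI over 85% aligned fraction, spacer matching by
#' exact full-length occurrence (the nominal BLAST E-value 1e-10 is recorded
#' for provenance only), genome-homology host links at E <= 1e-3, bit score
#' >= 50, alignment >= 1 kb, identity >= 96%, read filtering at 95% identity
#' over 75% of the read, 5% two-sided trimmed-mean coverage, protein
#' clustering at 60% identity covering 80% of the shorter sequence, SNP
#' calling at quality > 30 with >= 4 alternative reads at > 1% frequency and
#' a 10x depth eligibility floor, BH FDR at 0.05, and 999 permutations for
#' permutation tests.
#'
#' @param ani Minimum average nucleotide identity (percent) for vOTU
#'   clustering.
#' @param af Minimum alignment fraction (percent) of the shorter genome.
#' @param af_rule Which genome's aligned fraction must pass: `"shorter"`
#'   (default) or `"both"`.
#' @param spacer_evalue Nominal spacer-match E-value (provenance only; the
#'   implemented criterion is an exact full-length match).
#' @param homology_evalue,homology_bitscore,homology_min_len,homology_min_ident
#'   Thresholds for genome-homology host links.
#' @param read_min_ident,read_min_aligned_frac Read-alignment filter.
#' @param trim_frac Fraction trimmed from each depth extreme for tpmean.
#' @param pc_identity,pc_cov_short Protein-cluster thresholds.
#' @param snp_qual,snp_min_alt_reads,snp_min_alt_freq,snp_min_depth SNP
#'   calling filters and depth eligibility floor.
#' @param fdr_alpha BH false-discovery-rate threshold.
#' @param n_perm Number of permutations for PERMANOVA/Mantel.
#' @param seed Integer seed controlling all randomness in a run.
#' @return A list of class `phagedyn_config`.
#' @examples
#' cfg <- phagedyn_config(seed = 42)
#' cfg$ani
#' @export
phagedyn_config <- function(ani = 95, af = 85, af_rule = c("shorter", "both"),
                            spacer_evalue = 1e-10,
                            homology_evalue = 1e-3, homology_bitscore = 50,
                            homology_min_len = 1000, homology_min_ident = 96,
                            read_min_ident = 95, read_min_aligned_frac = 0.75,
                            trim_frac = 0.05,
                            pc_identity = 0.60, pc_cov_short = 0.80,
                            snp_qual = 30, snp_min_alt_reads = 4,
                            snp_min_alt_freq = 0.01, snp_min_depth = 10,
                            fdr_alpha = 0.05, n_perm = 999, seed = 1L) {
  af_rule <- match.arg(af_rule)
  cfg <- list(
    ani = ani, af = af, af_rule = af_rule,
    spacer_evalue = spacer_evalue,
    homology_evalue = homology_evalue, homology_bitscore = homology_bitscore,
    homology_min_len = homology_min_len,
    homology_min_ident = homology_min_ident,
    read_min_ident = read_min_ident,
    read_min_aligned_frac = read_min_aligned_frac,
    trim_frac = trim_frac,
    pc_identity = pc_identity, pc_cov_short = pc_cov_short,
    snp_qual = snp_qual, snp_min_alt_reads = snp_min_alt_reads,
    snp_min_alt_freq = snp_min_alt_freq, snp_min_depth = snp_min_depth,
    fdr_alpha = fdr_alpha, n_perm = n_perm, seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "phagedyn_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$ani > 0, cfg$ani <= 100,
    cfg$af > 0, cfg$af <= 100,
    cfg$homology_min_ident > 0, cfg$homology_min_ident <= 100,
    cfg$read_min_ident > 0, cfg$read_min_ident <= 100,
    cfg$read_min_aligned_frac > 0, cfg$read_min_aligned_frac <= 1,
    cfg$trim_frac >= 0, cfg$trim_frac < 0.5,
    cfg$pc_identity > 0, cfg$pc_identity <= 1,
    cfg$pc_cov_short > 0, cfg$pc_cov_short <= 1,
    cfg$snp_min_alt_reads >= 1,
    cfg$snp_min_alt_freq >= 0, cfg$snp_min_alt_freq < 1,
    cfg$snp_min_depth >= 1,
    cfg$fdr_alpha > 0, cfg$fdr_alpha < 1,
    cfg$n_perm >= 1,
    is.finite(cfg$seed)
  )
  invisible(cfg)
}

#' Read or write a run configuration as YAML
#'
#' Every threshold in the file overrides the package default; unknown keys
#' are rejected so typos fail loudly.
#'
#' @param path File path of the YAML configuration.
#' @return `read_config()` returns a `phagedyn_config`; `write_config()`
#'   invisibly returns `path`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(phagedyn_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  }
  do.call(phagedyn_config, vals)
}

#' @rdname read_config
#' @param config A `phagedyn_config` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "phagedyn_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.phagedyn_config <- function(x, ...) {
  cat("<phagedyn_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
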