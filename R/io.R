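#' Read a FASTA file into a tibble
#'
#' Sequences are uppercased and record order is preserved. Duplicate IDs and
#' empty records are format errors: downstream joins key on the ID.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "acgt"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(Biostrings::width(set) == 0)) {
    stop("empty FASTA record(s): ",
         paste(ids[Biostrings::width(set) == 0], collapse = ", "))
  }
  tibble::tibble(id = ids,
                 sequence = unname(toupper(as.character(set))))
}

#' Write a tibble of sequences as FASTA
#'
#' @param seqs A data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(all(c("id", "sequence") %in% names(seqs)))
  set <- Biostrings::BStringSet(seqs$sequence)
  names(set) <- seqs$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

alignment_cols <- c("query_id", "subject_id", "pct_identity", "aln_length",
                    "mismatches", "gap_opens", "q_start", "q_end",
                    "s_start", "s_end", "evalue", "bit_score")

#' Read a 12-column tabular alignment file
#'
#' The columns follow the BLAST tabular (outfmt 6) dialect:
#' query, subject, percent identity, alignment length, mismatches, gap opens,
#' query start/end, subject start/end, E-value, bit score. Coordinates are
#' kept as read (1-based inclusive, subject start may exceed end on the minus
#' strand); consumers normalize orientation where they need it.
#'
#' @param path Path to a tab-separated file without header.
#' @return A tibble of typed alignment hits (zero rows for an empty file).
#' @export
read_alignment_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::as_tibble(stats::setNames(
      list(character(), character(), double(), integer(), integer(),
           integer(), integer(), integer(), integer(), integer(), double(),
           double()),
      alignment_cols
    )))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    stop("alignment table must have 12 tab-separated columns; line ",
         which(nf != 12)[1], " has ", nf[nf != 12][1])
  }
  m <- matrix(unlist(fields), ncol = 12, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 10)
  if (anyNA(num)) {
    stop("non-numeric value in numeric alignment column (first bad line ",
         which(rowSums(is.na(num)) > 0)[1], ")")
  }
  hits <- tibble::tibble(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = num[, 1], aln_length = as.integer(num[, 2]),
    mismatches = as.integer(num[, 3]), gap_opens = as.integer(num[, 4]),
    q_start = as.integer(num[, 5]), q_end = as.integer(num[, 6]),
    s_start = as.integer(num[, 7]), s_end = as.integer(num[, 8]),
    evalue = num[, 9], bit_score = num[, 10]
  )
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100)) {
    stop("pct_identity outside [0, 100]")
  }
  if (any(hits$aln_length < 1)) stop("aln_length must be >= 1")
  hits
}

#' @rdname read_alignment_table
#' @param hits A tibble of alignment hits.
#' @export
write_alignment_table <- function(hits, path) {
  stopifnot(all(alignment_cols %in% names(hits)))
  out <- hits[, alignment_cols]
  out$evalue <- format(out$evalue, digits = 12, scientific = TRUE,
                       trim = TRUE)
  out$pct_identity <- format(out$pct_identity, digits = 12, trim = TRUE)
  out$bit_score <- format(out$bit_score, digits = 12, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write plain tab-separated tables with a header
#'
#' Thin wrappers over readr used for every tabular interchange format
#' (depth profiles, pileups, bout records, abundance tables, link tables,
#' protein-cluster membership). Reals survive a round trip to 12
#' significant digits.
#'
#' @param path File path.
#' @return `read_tsv_table()` returns a tibble.
#' @export
read_tsv_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_tsv_table
#' @param x A data frame.
#' @export
write_tsv_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
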