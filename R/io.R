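#' Read an aligned (or unaligned) FASTA file into a sequence table
#'
#' Reads nucleotide sequences with [ape::read.FASTA()] and joins them to a
#' sample metadata table keyed by `seq_id`. The result is a tibble with one
#' row per sequence, ready to pipe into [distance_matrix()],
#' [identity_distribution()] and the rest of the pipeline.
#'
#' @param path Path to a FASTA file. Gap characters (`-`) are preserved.
#' @param metadata Optional data frame with a `seq_id` column and any of
#'   `sample_id`, `segment`, `location`, `collection_date`, `species`
#'   (see [read_metadata()]). Sequences without a metadata row are kept
#'   with `NA` fields and a warning; metadata rows without a sequence are
#'   reported with a warning.
#' @return A tibble with columns `seq_id`, `residues` (upper-case
#'   character strings) and, when metadata is supplied, the metadata
#'   columns.
#' @export
read_aligned_fasta <- function(path, metadata = NULL) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  dna <- tryCatch(
    ape::read.FASTA(path),
    error = function(e) abort(paste0("malformed FASTA '", path, "': ", conditionMessage(e)))
  )
  if (length(dna) == 0) {
    abort(paste0("FASTA file '", path, "' contains no sequences"))
  }
  ids <- names(dna)
  if (anyDuplicated(ids)) {
    abort(paste0(
      "duplicate FASTA headers: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  residues <- toupper(vapply(as.character(dna), paste, collapse = "", FUN.VALUE = character(1)))
  if (any(!nzchar(residues))) abort("empty sequence in FASTA")
  tbl <- tibble(seq_id = ids, residues = unname(residues))
  if (is.null(metadata)) {
    return(tbl)
  }
  join_sequence_metadata(tbl, metadata)
}

#' Read a sample metadata table
#'
#' Expects a tab-separated file with at least the columns `seq_id`,
#' `sample_id`, `segment`, `location`, `collection_date`, `species`.
#' Segment labels are validated against [segment_levels()].
#'
#' @param path Path to a TSV file.
#' @return A tibble, one row per sequence.
#' @export
read_metadata <- function(path) {
  md <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("seq_id", "sample_id", "segment", "location", "collection_date", "species")
  missing <- setdiff(required, names(md))
  if (length(missing) > 0) {
    abort(paste0("metadata is missing required columns: ", paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(md$segment), segment_levels())
  if (length(bad) > 0) {
    abort(paste0("unknown segment labels in metadata: ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(md$seq_id)) {
    abort("duplicate seq_id in metadata")
  }
  as_tibble(md)
}

#' Join a sequence table to sample metadata
#'
#' @param sequences Tibble with `seq_id` and `residues`.
#' @param metadata Data frame keyed by `seq_id`.
#' @return The joined tibble; unmatched sequences keep `NA` metadata.
#' @export
join_sequence_metadata <- function(sequences, metadata) {
  metadata <- as_tibble(metadata)
  if (!"seq_id" %in% names(metadata)) abort("metadata must have a seq_id column")
  if ("segment" %in% names(metadata)) {
    bad <- setdiff(unique(metadata$segment), segment_levels())
    if (length(bad) > 0) {
      abort(paste0("unknown segment labels in metadata: ", paste(bad, collapse = ", ")))
    }
  }
  unmatched_seq <- setdiff(sequences$seq_id, metadata$seq_id)
  if (length(unmatched_seq) > 0) {
    warn(paste0(
      length(unmatched_seq), " sequence(s) without metadata retained with NA fields: ",
      paste(head(unmatched_seq, 5), collapse = ", ")
    ))
  }
  unmatched_md <- setdiff(metadata$seq_id, sequences$seq_id)
  if (length(unmatched_md) > 0) {
    warn(paste0(
      length(unmatched_md), " metadata row(s) without a matching sequence: ",
      paste(head(unmatched_md, 5), collapse = ", ")
    ))
  }
  left_join(sequences, metadata, by = "seq_id")
}

#' Write a sequence table to FASTA
#'
#' @param sequences Tibble with `seq_id` and `residues`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  lines <- character(2L * nrow(sequences))
  lines[c(TRUE, FALSE)] <- paste0(">", sequences$seq_id)
  lines[c(FALSE, TRUE)] <- sequences$residues
  writeLines(lines, path)
  invisible(path)
}

# Assert that a sequence table is a usable alignment: >= `min_n` rows and
# all residue strings the same length. Returns the column count.
check_alignment <- function(sequences, min_n = 2L) {
  if (nrow(sequences) < min_n) {
    abort(paste0("need at least ", min_n, " sequences, got ", nrow(sequences)))
  }
  lens <- unique(nchar(sequences$residues))
  if (length(lens) != 1L) {
    abort("sequences are not aligned: residue strings have unequal lengths")
  }
  lens
}
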