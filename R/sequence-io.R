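#' Read a protein FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()]: names are truncated to
#' the first whitespace-delimited header token, sequences are uppercased, and
#' duplicate ids or an empty file raise an error naming the offender.
#'
#' @param path FASTA file path
#' @return an [Biostrings::AAStringSet] with one element per record
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  names(set) <- ids
  Biostrings::AAStringSet(toupper(as.character(set)))
}

#' Write protein sequences to FASTA
#'
#' @param sequences named character vector or AAStringSet
#' @param path output path
#' @return `path`, invisibly
#' @export
writeProteinFasta <- function(sequences, path) {
  if (!is(sequences, "AAStringSet"))
    sequences <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}

#' Read a sequence metadata table
#'
#' TSV with columns seq_id, form, subunit (large|small), is_reference (0/1)
#' and genome_label.
#'
#' @param path TSV path
#' @return data.frame
#' @export
readMetadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  meta <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  need <- c("seq_id", "form", "subunit", "is_reference", "genome_label")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(meta$subunit %in% c("large", "small")))
    stop("subunit must be 'large' or 'small'")
  meta
}

#' Assemble protein records from sequences and metadata
#'
#' Merges large and small subunits of the same (genome_label, form) into one
#' record; the analysis sequence is large then small. Small-subunit orphans
#' and duplicated large subunits within a (genome, form) raise errors naming
#' the sequences involved. Assembly is deterministic and independent of the
#' metadata row order: records are returned sorted by (genome_label, form).
#'
#' @param fasta an AAStringSet (see [readProteinFasta()]) or named character
#' @param metadata data.frame as from [readMetadata()]
#' @return list of [ProteinRecord-class]
#' @export
assembleRecords <- function(fasta, metadata) {
  seqs <- stats::setNames(as.character(fasta), names(fasta))
  miss <- setdiff(metadata$seq_id, names(seqs))
  if (length(miss))
    stop("metadata id(s) missing from FASTA: ", paste(miss, collapse = ", "))
  keys <- unique(metadata[order(metadata$genome_label, metadata$form),
                          c("genome_label", "form")])
  records <- list()
  for (i in seq_len(nrow(keys))) {
    rows <- metadata[metadata$genome_label == keys$genome_label[i] &
                     metadata$form == keys$form[i], , drop = FALSE]
    large <- rows[rows$subunit == "large", , drop = FALSE]
    small <- rows[rows$subunit == "small", , drop = FALSE]
    if (nrow(large) == 0L)
      stop("no large subunit for (", keys$genome_label[i], ", ",
           keys$form[i], "); orphan id(s): ",
           paste(rows$seq_id, collapse = ", "))
    if (nrow(large) > 1L)
      stop("multiple large subunits for (", keys$genome_label[i], ", ",
           keys$form[i], "): ", paste(large$seq_id, collapse = ", "))
    records[[length(records) + 1L]] <- new(
      "ProteinRecord", seq_id = large$seq_id[1], form = large$form[1],
      genome_label = large$genome_label[1],
      large_seq = seqs[[large$seq_id[1]]],
      small_seq = if (nrow(small)) seqs[[small$seq_id[1]]] else "",
      is_reference = as.logical(large$is_reference[1]))
  }
  records
}

#' Analysis sequence of a protein record
#'
#' Large subunit concatenated with the small subunit when present.
#'
#' @param record a [ProteinRecord-class]
#' @return amino-acid string
#' @export
analysisSequence <- function(record) {
  stopifnot(is(record, "ProteinRecord"))
  paste0(record@large_seq, record@small_seq)
}

#' Build per-form mesophilic references from assembled records
#'
#' Computes index vectors for every record flagged `is_reference` and builds
#' one [ReferenceStats-class] per form present among them.
#'
#' @param records list of [ProteinRecord-class]
#' @return named list of [ReferenceStats-class]
#' @export
buildReferencesFromRecords <- function(records) {
  refs <- Filter(function(r) r@is_reference, records)
  if (!length(refs)) stop("no records are flagged is_reference")
  forms <- unique(vapply(refs, function(r) r@form, character(1)))
  out <- list()
  for (f in forms) {
    vecs <- lapply(Filter(function(r) r@form == f, refs),
                   function(r) computeIndices(analysisSequence(r)))
    out[[f]] <- buildReference(vecs, f)
  }
  out
}
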