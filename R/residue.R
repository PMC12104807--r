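#' Read a multiple protein alignment from aligned FASTA
#'
#' @param path aligned FASTA file.
#' @return a [Biostrings::AAStringSet] whose sequences all have equal width.
#'   Description lines are trimmed to the first whitespace-delimited token.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  aln <- Biostrings::readAAStringSet(path)
  names(aln) <- sub("\\s.*$", "", names(aln))
  check_alignment(aln)
  aln
}

check_alignment <- function(aln) {
  if (length(aln) == 0L) stop("empty alignment")
  w <- Biostrings::width(aln)
  if (length(unique(w)) != 1L)
    stop("ragged alignment: sequence widths differ (",
         paste(range(w), collapse = "-"), ")")
  if (anyDuplicated(names(aln)))
    stop("duplicate sequence id: ", names(aln)[duplicated(names(aln))][1L])
  invisible(aln)
}

aln_char_matrix <- function(aln) {
  do.call(rbind, strsplit(toupper(as.character(aln)), ""))
}

GAP_CHARS <- c("-", ".")

#' Map an ungapped reference position to an alignment column
#'
#' Finds the alignment column holding the reference sequence's Nth ungapped
#' residue. This is how the bovine rhodopsin K296 coordinate is carried into
#' an arbitrary opsin alignment: positions are 1-based and counted on the
#' ungapped reference, matching the K296 nomenclature.
#'
#' @param alignment a [Biostrings::AAStringSet] (or path to an aligned FASTA).
#' @param reference_id id of the reference sequence in the alignment.
#' @param reference_position 1-based ungapped residue index on the reference.
#' @return the 1-based alignment column.
#' @export
map_reference_position <- function(alignment, reference_id, reference_position) {
  if (is.character(alignment) && length(alignment) == 1L && file.exists(alignment))
    alignment <- read_alignment(alignment)
  check_alignment(alignment)
  if (!reference_id %in% names(alignment))
    stop("reference sequence not in alignment: ", reference_id)
  ref <- strsplit(toupper(as.character(alignment[[reference_id]])), "")[[1L]]
  ungapped <- which(!ref %in% GAP_CHARS)
  if (reference_position < 1L || reference_position > length(ungapped))
    stop(sprintf("reference position %d outside ungapped length %d of '%s'",
                 reference_position, length(ungapped), reference_id))
  ungapped[reference_position]
}

# ambiguity codes give a conservative lysine_absent (the check demands a
# positive lysine), but the call is annotated so it can be audited
AMBIGUOUS_AA <- c("X", "B", "Z", "J", "U", "O", "*")

#' Classify sequences at the column homologous to a reference residue
#'
#' For every sequence in the alignment (the reference excluded unless
#' `include_reference = TRUE`), reports the residue observed at the column
#' homologous to `reference_position` and classifies it:
#'
#' * `lysine_present` — the residue is K (case-insensitive);
#' * `lysine_absent` — any other amino acid; ambiguity codes (X, B, Z, ...)
#'   classify here conservatively and carry a note;
#' * `undetermined_gap` — a gap with sequence on both sides of the column
#'   (an internal alignment gap, not missing data at the terminus);
#' * `undetermined_truncated` — a gap with no residue at all between the
#'   column and one sequence end (the sequence is incomplete over the region).
#'
#' The truncation rule makes mechanical the distinction between a sequence
#' that is complete yet lacks the lysine and one that simply does not span
#' the site.
#'
#' @inheritParams map_reference_position
#' @param include_reference also classify the reference itself.
#' @return data.frame of class `residue_calls`: `seq_id`, `column`, `residue`
#'   (one-letter or `"-"`), `call`, `complete` (logical: the sequence spans
#'   the column), `note`.
#' @export
classify_sequences <- function(alignment, reference_id, reference_position,
                               include_reference = FALSE) {
  if (is.character(alignment) && length(alignment) == 1L && file.exists(alignment))
    alignment <- read_alignment(alignment)
  check_alignment(alignment)
  col <- map_reference_position(alignment, reference_id, reference_position)
  chars <- aln_char_matrix(alignment)
  ids <- names(alignment)
  keep <- if (include_reference) ids else setdiff(ids, reference_id)
  rows <- lapply(keep, function(id) {
    s <- chars[match(id, ids), ]
    res <- s[col]
    gap <- res %in% GAP_CHARS
    left <- col > 1L && any(!s[seq_len(col - 1L)] %in% GAP_CHARS)
    right <- col < length(s) && any(!s[seq(col + 1L, length(s))] %in% GAP_CHARS)
    note <- ""
    if (!gap) {
      complete <- TRUE
      if (res == "K") call <- "lysine_present"
      else {
        call <- "lysine_absent"
        if (res %in% AMBIGUOUS_AA) note <- "ambiguity code scored as non-lysine"
      }
    } else if (left && right) {
      call <- "undetermined_gap"; complete <- TRUE
    } else {
      call <- "undetermined_truncated"; complete <- FALSE
    }
    data.frame(seq_id = id, column = col, residue = res, call = call,
               complete = complete, note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("residue_calls", class(out))
  out
}

#' Summarize residue calls
#'
#' Tallies calls by category and lists the sequences that should feed the
#' presence matrix's `uncertain`/note machinery: those lacking the lysine or
#' undetermined at the column.
#'
#' @param calls output of [classify_sequences()].
#' @return list with `counts` (named integer over the four call categories)
#'   and `flagged` (character vector of sequence ids with `lysine_absent` or
#'   an undetermined call).
#' @export
summarize_calls <- function(calls) {
  cats <- c("lysine_present", "lysine_absent",
            "undetermined_gap", "undetermined_truncated")
  counts <- vapply(cats, function(k) sum(calls$call == k), 0L)
  list(counts = counts,
       flagged = calls$seq_id[calls$call != "lysine_present"])
}

#' Write a residue-call report as TSV
#'
#' @param calls output of [classify_sequences()].
#' @param path output path.
#' @export
write_residue_report <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
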