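# Protein sequence container and FASTA I/O.

AA_STANDARD <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

#' Construct a validated protein sequence
#'
#' A light container for a one-letter-code protein sequence together with a
#' numbering offset that converts string indices to biological residue
#' numbers (`biological = index + offset`). Input is case-normalized to
#' uppercase; only the 20 standard amino-acid codes plus `X` (unknown) are
#' accepted.
#'
#' @param id character scalar, sequence identifier.
#' @param residues character scalar, the amino-acid sequence.
#' @param numbering_offset integer added to 1-based string indices to give
#'   biological residue numbers (default 0).
#' @return An object of class `protein_sequence`: a list with elements
#'   `id`, `residues` and `numbering_offset`.
#' @examples
#' p <- protein_sequence("MICAL1_PRM", "ALPAKPARS", numbering_offset = 827)
#' @export
protein_sequence <- function(id, residues, numbering_offset = 0L) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) < 1L)
    stop("sequence '", id, "' is empty")
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% c(AA_STANDARD, "X")))
  if (length(bad) > 0L)
    stop("sequence '", id, "' contains invalid residue code '",
         chars[bad[1L]], "' at position ", bad[1L])
  structure(list(id = id, residues = residues,
                 numbering_offset = as.integer(numbering_offset)),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s (%d aa, offset %d)\n",
              x$id, nchar(x$residues), x$numbering_offset))
  invisible(x)
}

seq_chars <- function(seq) strsplit(seq$residues, "", fixed = TRUE)[[1L]]

#' Read protein sequences from a FASTA file
#'
#' Record ids are taken up to the first whitespace; an optional
#' `offset=<int>` key anywhere in the description line sets the numbering
#' offset of that record.
#'
#' @param path path to a (multi-record) FASTA file.
#' @return A list of [protein_sequence()] objects, named by id.
#' @export
read_fasta_sequences <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  headers <- names(set)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    fields <- strsplit(headers[i], "\\s+")[[1L]]
    id <- fields[1L]
    off <- 0L
    m <- regmatches(headers[i], regexpr("offset=-?[0-9]+", headers[i]))
    if (length(m) == 1L)
      off <- as.integer(sub("offset=", "", m, fixed = TRUE))
    out[[i]] <- protein_sequence(id, as.character(set[[i]]), off)
  }
  names(out) <- vapply(out, `[[`, character(1L), "id")
  out
}

#' Write protein sequences to a FASTA file
#'
#' Non-zero numbering offsets are recorded as an `offset=<int>` key on the
#' description line so that [read_fasta_sequences()] round-trips them.
#'
#' @param seqs list of [protein_sequence()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_sequences <- function(seqs, path) {
  set <- Biostrings::AAStringSet(vapply(seqs, `[[`, character(1L), "residues"))
  names(set) <- vapply(seqs, function(s) {
    if (s$numbering_offset != 0L)
      paste0(s$id, " offset=", s$numbering_offset) else s$id
  }, character(1L))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
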