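#' Collections of barcode sequences
#'
#' A `sequence_collection` is a named character vector of nucleotide
#' sequences over the alphabet `A C G T N -` (uppercased on construction).
#' It holds OTU representatives and reference-library barcodes (~312 bp rbcL
#' fragments in the intended application).
#'
#' @param seqs named character vector of sequences.
#' @return a `sequence_collection`.
#' @export
sequence_collection <- function(seqs) {
  if (length(seqs) == 0L) stop("empty sequence collection")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("every sequence needs an id")
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  seqs <- toupper(as.character(seqs))
  if (any(!nzchar(seqs)))
    stop("empty sequence: ", ids[!nzchar(seqs)][1L])
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    ch <- regmatches(seqs[bad][1L], regexpr("[^ACGTN-]", seqs[bad][1L]))
    stop(sprintf("illegal character '%s' in sequence '%s'", ch, ids[bad][1L]))
  }
  names(seqs) <- ids
  structure(seqs, class = "sequence_collection")
}

#' @export
print.sequence_collection <- function(x, ...) {
  cat(sprintf("sequence_collection: %d sequences, lengths %d-%d\n",
              length(x), min(nchar(x)), max(nchar(x))))
  invisible(x)
}

#' @export
`[.sequence_collection` <- function(x, i) {
  sequence_collection(unclass(x)[i])
}

#' Read sequences from a FASTA file
#'
#' Accepts wrapped or single-line records. Uses Biostrings when installed,
#' with a pure-R fallback; either way the result is validated against the
#' `A C G T N -` alphabet and uppercased.
#'
#' @param path FASTA file path.
#' @return a [sequence_collection()].
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readBStringSet(path)
    seqs <- as.character(set)
    names(seqs) <- sub("\\s.*$", "", names(set))
    return(sequence_collection(seqs))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1L]) stop("not a FASTA file: ", path)
  rec <- cumsum(hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 paste0, character(1L), collapse = "")
  names(seqs) <- ids[as.integer(names(seqs))]
  sequence_collection(seqs)
}

#' Write sequences to a FASTA file
#' @param seqs a `sequence_collection`.
#' @param path output path.
#' @param width line-wrap width (0 = single line per record).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    if (width > 0L && nchar(s) > width) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    } else writeLines(s, con)
  }
  invisible(path)
}

# sequences as a character matrix (rows = sequences); requires equal lengths
seq_matrix <- function(seqs) {
  L <- nchar(seqs)
  if (length(unique(L)) != 1L)
    stop("sequences must have equal (aligned) lengths")
  m <- matrix(unlist(strsplit(unname(unclass(seqs)), "", fixed = FALSE),
                     use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  rownames(m) <- names(seqs)
  m
}
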