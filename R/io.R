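# FASTA input/output. Parsing and serialisation go through Biostrings; this
# layer splits headers into id/description and encodes residues into the
# package alphabet.

#' Read a protein FASTA file into encoded sequences
#'
#' The record id is the first whitespace-delimited token of the header, the
#' description the remainder. Wrapped sequence lines are concatenated; LF
#' and CRLF files parse identically; letters outside the alphabet are
#' encoded as `X`.
#'
#' @param path FASTA file path.
#' @param alphabet An [sw_alphabet()].
#' @return List of `encoded_seq` in file order.
#' @export
read_fasta <- function(path, alphabet = sw_alphabet()) {
  if (!file.exists(path)) stop("no such FASTA file: ", path, call. = FALSE)
  head_lines <- readLines(path, n = 100L, warn = FALSE)
  nonempty <- which(nzchar(trimws(head_lines)))
  if (!length(nonempty)) stop("empty FASTA file: ", path, call. = FALSE)
  if (!startsWith(trimws(head_lines[nonempty[1L]]), ">")) {
    stop("FASTA parse error at line ", nonempty[1L],
         ": sequence data before the first '>' header", call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("FASTA file holds no records: ", path,
                         call. = FALSE)
  headers <- names(set)
  seqs <- as.character(set)
  lapply(seq_along(set), function(i) {
    h <- trimws(headers[i])
    id <- sub("\\s.*$", "", h)
    desc <- if (grepl("\\s", h)) trimws(sub("^\\S+\\s+", "", h)) else ""
    if (!nzchar(gsub("[[:space:]]", "", seqs[i]))) {
      stop("FASTA parse error: empty record '", id, "'", call. = FALSE)
    }
    encode_sequence(seqs[i], id = id, description = desc,
                    alphabet = alphabet)
  })
}

#' Write encoded sequences as FASTA
#'
#' @param records List of `encoded_seq`.
#' @param path Output file path.
#' @param width Residues per line.
#' @param alphabet The alphabet used for decoding.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L,
                        alphabet = sw_alphabet()) {
  txt <- vapply(records, decode_sequence, character(1L), alphabet = alphabet)
  set <- Biostrings::BStringSet(txt)
  names(set) <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, character(1L))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
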