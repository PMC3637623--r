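#' Residue alphabet for protein database search
#'
#' The fixed alphabet used by every data structure in the package: the 20
#' standard amino acids plus the ambiguity/translation symbols `B`, `Z`, `X`
#' and `*`, in NCBI substitution-matrix order, followed by one reserved
#' padding symbol (`.`). The padding symbol is not a residue: it fills the
#' unused tail of short sequences inside a multi-lane sequence profile, and
#' its substitution score is pinned to the 8-bit sentinel minimum so that a
#' padded lane stays frozen at score 0.
#'
#' @return An object of class `sw_alphabet` with fields `symbols` (ordered
#'   character vector), `size` (total symbol count, including padding),
#'   `n_real` (number of scored, non-padding symbols), `pad_index` (1-based
#'   index of the padding symbol) and `x_index` (index of `X`, the sink for
#'   unknown letters).
#' @examples
#' ab <- sw_alphabet()
#' ab$symbols[ab$x_index]  # "X"
#' @export
sw_alphabet <- function() {
  symbols <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
               "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X", "*",
               ".")
  structure(
    list(symbols = symbols,
         size = length(symbols),
         n_real = length(symbols) - 1L,
         pad_index = length(symbols),
         x_index = match("X", symbols)),
    class = "sw_alphabet")
}

#' @export
print.sw_alphabet <- function(x, ...) {
  cat("<sw_alphabet> ", x$n_real, " scored symbols + padding '",
      x$symbols[x$pad_index], "'\n", sep = "")
  invisible(x)
}

#' Encode a residue string as alphabet indices
#'
#' Letters are mapped case-insensitively to their alphabet index; any letter
#' not in the alphabet (e.g. `J`, `U`, `O`) falls back to the index of `X`,
#' the ambiguous-residue symbol. Whitespace is removed before encoding.
#'
#' @param text Residue text (a single string; may contain whitespace).
#' @param id Sequence identifier.
#' @param description Free-text description (may be empty).
#' @param alphabet An [sw_alphabet()].
#' @return An `encoded_seq`: list with `id`, `description`, `residues`
#'   (integer alphabet indices) and `length`.
#' @examples
#' s <- encode_sequence("acde", id = "q1")
#' decode_sequence(s)  # "ACDE"
#' @export
encode_sequence <- function(text, id = "", description = "",
                            alphabet = sw_alphabet()) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- toupper(gsub("[[:space:]]+", "", text))
  if (!nzchar(text)) {
    stop("empty sequence", if (nzchar(id)) paste0(" for record '", id, "'"),
         call. = FALSE)
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  idx <- match(chars, alphabet$symbols[seq_len(alphabet$n_real)])
  idx[is.na(idx)] <- alphabet$x_index
  new_encoded_seq(id, description, idx)
}

new_encoded_seq <- function(id, description, residues) {
  structure(
    list(id = as.character(id), description = as.character(description),
         residues = as.integer(residues), length = length(residues)),
    class = "encoded_seq")
}

#' Decode an encoded sequence back to residue letters
#'
#' @param x An `encoded_seq`.
#' @param alphabet The alphabet used for encoding.
#' @return Single uppercase string.
#' @export
decode_sequence <- function(x, alphabet = sw_alphabet()) {
  stopifnot(inherits(x, "encoded_seq"))
  paste(alphabet$symbols[x$residues], collapse = "")
}

#' @export
print.encoded_seq <- function(x, ...) {
  cat("<encoded_seq> ", x$id, " (", x$length, " residues)\n", sep = "")
  invisible(x)
}

# internal: assert a sequence holds no padding symbol
check_no_padding <- function(x, alphabet = sw_alphabet()) {
  if (any(x$residues == alphabet$pad_index)) {
    stop("sequence '", x$id, "' contains the reserved padding symbol",
         call. = FALSE)
  }
  invisible(x)
}

# internal: coerce character or encoded_seq to encoded_seq
as_encoded <- function(x, id = "seq") {
  if (inherits(x, "encoded_seq")) x else encode_sequence(x, id = id)
}

# internal: lengths of a database (list of encoded_seq)
db_lengths <- function(db) vapply(db, `[[`, integer(1L), "length")
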