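# Substitution matrices, gap scheme and overflow score limits.

# Sentinel substitution score used for the padding symbol and for alphabet
# symbols absent from a loaded matrix: the minimum representable signed
# 8-bit value, so that after one saturating addition a padded lane's score
# collapses to the zero floor of the local-alignment recurrence.
SCORE_SENTINEL <- -128L

#' Load a substitution matrix in NCBI plain-text format
#'
#' Reads either one of the bundled matrices (`"BLOSUM62"`, `"BLOSUM50"`), a
#' file path, or literal matrix text. The format is the NCBI layout: `#`
#' comment lines, a header row of single residue letters, then one labelled
#' row of integer scores per residue. The parsed block is embedded in a full
#' `|alphabet| x |alphabet|` matrix; entries for symbols not listed in the
#' file (always including the padding symbol) are filled with the sentinel
#' minimum score.
#'
#' @param source Matrix name, file path, or matrix text.
#' @param alphabet An [sw_alphabet()].
#' @return Integer matrix of size `alphabet$size` squared with symbol
#'   dimnames, symmetric over the residues listed in the source.
#' @examples
#' m <- load_matrix("BLOSUM62")
#' m["A", "A"]  # 4
#' m["W", "W"]  # 11
#' @export
load_matrix <- function(source, alphabet = sw_alphabet()) {
  stopifnot(is.character(source), length(source) == 1L)
  builtin <- system.file("extdata", "matrices", paste0(toupper(source), ".txt"),
                         package = "swlanes")
  lines <-
    if (nzchar(builtin)) {
      readLines(builtin)
    } else if (file.exists(source) && !grepl("\n", source)) {
      readLines(source)
    } else if (grepl("\n", source) || grepl("^[A-Z* ]+$", source)) {
      strsplit(source, "\n", fixed = TRUE)[[1L]]
    } else {
      stop("unknown matrix '", source, "': not a bundled name or readable file",
           call. = FALSE)
    }
  parse_ncbi_matrix(lines, alphabet)
}

parse_ncbi_matrix <- function(lines, alphabet) {
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) < 2L) stop("matrix text has no header row", call. = FALSE)
  header_line <- keep[1L]
  header <- strsplit(trimws(lines[header_line]), "\\s+")[[1L]]
  real <- alphabet$symbols[seq_len(alphabet$n_real)]
  bad <- which(!(header %in% real) | nchar(header) != 1L)
  if (length(bad)) {
    stop("malformed matrix header at line ", header_line, ", column ", bad[1L],
         ": '", header[bad[1L]], "' is not a residue letter", call. = FALSE)
  }
  m <- matrix(SCORE_SENTINEL, alphabet$size, alphabet$size,
              dimnames = list(alphabet$symbols, alphabet$symbols))
  seen <- character(0L)
  for (ln in keep[-1L]) {
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (!length(tok)) next
    row_letter <- toupper(tok[1L])
    if (!(row_letter %in% real) || nchar(row_letter) != 1L) {
      stop("line ", ln, ": row label '", tok[1L], "' is not a residue letter",
           call. = FALSE)
    }
    vals <- suppressWarnings(as.integer(tok[-1L]))
    if (anyNA(vals)) {
      stop("line ", ln, ", column ", which(is.na(vals))[1L] + 1L,
           ": non-integer matrix cell '", tok[-1L][which(is.na(vals))[1L]],
           "'", call. = FALSE)
    }
    if (length(vals) != length(header)) {
      stop("line ", ln, ": expected ", length(header), " scores, found ",
           length(vals), call. = FALSE)
    }
    m[row_letter, header] <- vals
    seen <- c(seen, row_letter)
  }
  if (!setequal(seen, header)) {
    stop("matrix rows (", length(seen), ") do not match header letters (",
         length(header), ")", call. = FALSE)
  }
  sub <- m[header, header, drop = FALSE]
  if (!identical(sub, t(sub))) {
    stop("substitution matrix is not symmetric over its listed residues",
         call. = FALSE)
  }
  m
}

#' Construct a scoring scheme (substitution matrix + affine gap penalties)
#'
#' The gap model is affine: a gap of length `k` costs
#' `gap_open + k * gap_extend`, so the penalty applied when a gap is opened
#' is `alpha = gap_open + gap_extend` and each further extension costs
#' `beta = gap_extend`. The recurrence in this package subtracts `alpha`
#' directly from an alignment score when opening a gap; `alpha` already
#' includes the first extension.
#'
#' @param matrix Matrix name / path / text for [load_matrix()], or an already
#'   loaded full integer matrix.
#' @param gap_open Gap opening penalty (non-negative integer).
#' @param gap_extend Gap extension penalty (positive integer).
#' @param alphabet An [sw_alphabet()].
#' @param name Label for the scheme (defaults to the matrix name).
#' @return A `scoring_scheme`: list with `matrix`, `alpha`, `beta`, `name`
#'   and `alphabet`.
#' @examples
#' sc <- scoring_scheme("BLOSUM62", gap_open = 10, gap_extend = 2)
#' sc$alpha  # 12
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 10L,
                           gap_extend = 2L, alphabet = sw_alphabet(),
                           name = NULL) {
  if (is.character(matrix)) {
    if (is.null(name)) {
      name <- if (grepl("\n", matrix)) "custom" else toupper(basename(matrix))
    }
    matrix <- load_matrix(matrix, alphabet)
  } else {
    stopifnot(is.matrix(matrix),
              all(dim(matrix) == alphabet$size))
    storage.mode(matrix) <- "integer"
    if (is.null(name)) name <- "custom"
  }
  gap_open <- as.integer(gap_open)
  gap_extend <- as.integer(gap_extend)
  if (is.na(gap_open) || gap_open < 0L) {
    stop("gap_open must be a non-negative integer", call. = FALSE)
  }
  if (is.na(gap_extend) || gap_extend < 1L) {
    stop("gap_extend must be a positive integer", call. = FALSE)
  }
  pad <- alphabet$pad_index
  matrix[pad, ] <- SCORE_SENTINEL
  matrix[, pad] <- SCORE_SENTINEL
  real <- seq_len(alphabet$n_real)
  if (max(matrix[real, real]) < 0L) {
    stop("substitution matrix has no non-negative real-residue entry",
         call. = FALSE)
  }
  structure(
    list(matrix = matrix,
         alpha = gap_open + gap_extend,
         beta = gap_extend,
         gap_open = gap_open,
         gap_extend = gap_extend,
         name = name,
         alphabet = alphabet),
    class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("<scoring_scheme> ", x$name, ", gap open ", x$gap_open,
      " / extend ", x$beta, " (alpha=", x$alpha, ", beta=", x$beta, ")\n",
      sep = "")
  invisible(x)
}

# internal: maximum substitution score over scored (non-padding) residues
max_substitution_score <- function(scheme) {
  real <- seq_len(scheme$alphabet$n_real)
  max(scheme$matrix[real, real])
}

#' Overflow score limit for a saturating lane width
#'
#' A local alignment score computed in saturating signed `bit_width`-bit
#' lanes is trustworthy only while no intermediate cell could have clamped.
#' Since one cell update can raise a score by at most the maximum
#' substitution score, any reported score below
#' `2^(bit_width-1) - max(M)` is provably exact; scores at or above this
#' limit are flagged for recomputation at higher precision. At 8 bits the
#' limit is `128 - max(M)`; the 16-bit limit extends the same rule to
#' `32768 - max(M)`.
#'
#' @param scheme A [scoring_scheme()].
#' @param bit_width 8 or 16.
#' @return Integer score limit.
#' @examples
#' overflow_limit(scoring_scheme("BLOSUM62"), 8)   # 117
#' overflow_limit(scoring_scheme("BLOSUM62"), 16)  # 32757
#' @export
overflow_limit <- function(scheme, bit_width = 8L) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  bit_width <- as.integer(bit_width)
  if (!bit_width %in% c(8L, 16L)) {
    stop("bit_width must be 8 or 16", call. = FALSE)
  }
  as.integer(2^(bit_width - 1L)) - max_substitution_score(scheme)
}
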