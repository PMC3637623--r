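# Scalar exact Smith-Waterman: ground-truth oracle and final recomputation
# fallback. Scores are computed in unbounded (64-bit) integers, so no
# overflow staging is needed here.

#' Exact Smith-Waterman local alignment score
#'
#' Computes the optimal local alignment score of two protein sequences under
#' the affine-gap recurrence
#' \deqn{H_{i,j} = \max\{H_{i-1,j-1} + M(S[i], T[j]),\; E_{i,j},\; F_{i,j},\; 0\}}
#' with \eqn{E_{i,j} = \max(E_{i-1,j} - \beta, H_{i-1,j} - \alpha)} and
#' \eqn{F_{i,j} = \max(F_{i,j-1} - \beta, H_{i,j-1} - \alpha)}, where
#' `alpha` is the gap open + extension penalty and `beta` the extension
#' penalty. The score is the maximum over all cells of `H`. Memory is linear
#' in the shorter of the two sequences (two row buffers, for `H` and `E`).
#'
#' @param query,subject `encoded_seq` objects or residue strings.
#' @param scheme A [scoring_scheme()].
#' @return Non-negative numeric score (integral; returned as numeric so
#'   arbitrarily high scores are representable).
#' @examples
#' sc <- scoring_scheme("BLOSUM62")
#' sw_score("HEAGAWGHEE", "PAWHEAE", sc)
#' @export
sw_score <- function(query, subject, scheme) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  query <- as_encoded(query, "query")
  subject <- as_encoded(subject, "subject")
  check_no_padding(query, scheme$alphabet)
  check_no_padding(subject, scheme$alphabet)
  sw_score_cpp(query$residues - 1L, subject$residues - 1L, scheme$matrix,
               scheme$alpha, scheme$beta)
}

#' Exact scores of one query against many subjects
#'
#' Vectorised [sw_score()] over a database (list of `encoded_seq`). This is
#' the exact scalar path; it serves as the oracle against which the packed
#' lane engine is checked, and as the last recomputation stage for
#' alignments beyond the 16-bit overflow limit.
#'
#' @param query An `encoded_seq` or string.
#' @param db List of `encoded_seq` objects.
#' @param scheme A [scoring_scheme()].
#' @return Numeric vector of scores, one per subject, in database order.
#' @export
sw_score_many <- function(query, db, scheme) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  query <- as_encoded(query, "query")
  check_no_padding(query, scheme$alphabet)
  subjects <- lapply(db, function(s) {
    s <- as_encoded(s)
    check_no_padding(s, scheme$alphabet)
    s$residues - 1L
  })
  sw_scores_batch_cpp(query$residues - 1L, subjects, scheme$matrix,
                      scheme$alpha, scheme$beta)
}

#' Full Smith-Waterman score matrix (small instances)
#'
#' Returns the complete `(|query|+1) x (|subject|+1)` matrix `H` of the
#' affine-gap recurrence, with the zero-initialised first row and column.
#' Quadratic memory; intended for debugging and as an independent oracle on
#' small instances, hence the cell-count cap.
#'
#' @inheritParams sw_score
#' @param max_cells Refuse instances with more than this many DP cells.
#' @return Numeric matrix `H`; `max(H)` equals [sw_score()].
#' @export
sw_matrix <- function(query, subject, scheme, max_cells = 1e6) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  query <- as_encoded(query, "query")
  subject <- as_encoded(subject, "subject")
  check_no_padding(query, scheme$alphabet)
  check_no_padding(subject, scheme$alphabet)
  if (as.double(query$length) * subject$length > max_cells) {
    stop("instance of ", query$length, " x ", subject$length,
         " cells exceeds max_cells = ", max_cells, call. = FALSE)
  }
  sw_matrix_cpp(query$residues - 1L, subject$residues - 1L, scheme$matrix,
                scheme$alpha, scheme$beta)
}
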