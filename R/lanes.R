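# Packed-lane saturating-integer arithmetic and the per-cell alignment
# kernel. The R-level lane_vector / sat_arith / cell_update functions define
# the lane semantics cell by cell (and are what the tests reason about); the
# whole-alignment engine align_lanes() runs the same recurrence in compiled
# code over all cells of a sequence profile.

#' Construct a packed lane vector
#'
#' A lane vector models one register of a W-lane SIMD unit holding signed
#' `bit_width`-bit integers. Supported widths are 4 (the quad-lane
#' device-style engine), 8 (16-bit recomputation lanes) and 16 (the
#' host-style 8-bit engine).
#'
#' @param values Integer vector of length 4, 8 or 16.
#' @param bit_width 8 or 16 (signed).
#' @return A `lane_vector`.
#' @export
lane_vector <- function(values, bit_width = 8L) {
  values <- as.integer(values)
  bit_width <- as.integer(bit_width)
  if (!length(values) %in% c(4L, 8L, 16L)) {
    stop("lane width must be 4, 8 or 16", call. = FALSE)
  }
  if (!bit_width %in% c(8L, 16L)) stop("bit_width must be 8 or 16",
                                       call. = FALSE)
  hi <- as.integer(2^(bit_width - 1L)) - 1L
  if (any(values < -hi - 1L | values > hi)) {
    stop("lane value outside the signed ", bit_width, "-bit range",
         call. = FALSE)
  }
  structure(list(lanes = values, bit_width = bit_width,
                 width = length(values)),
            class = "lane_vector")
}

#' @export
print.lane_vector <- function(x, ...) {
  cat("<lane_vector ", x$width, "x", x$bit_width, "b> ",
      paste(x$lanes, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Saturating element-wise lane arithmetic
#'
#' `add` and `sub` clamp each lane to the signed `bit_width` range
#' (saturating arithmetic); `max` is exact. Operands must agree in width and
#' bit width.
#'
#' @param op `"add"`, `"sub"` or `"max"`.
#' @param a,b `lane_vector`s of identical shape.
#' @return A `lane_vector`.
#' @examples
#' sat_arith("add", lane_vector(c(100, 3, 0, -5)), lane_vector(c(50, 4, 0, -5)))
#' @export
sat_arith <- function(op = c("add", "sub", "max"), a, b) {
  op <- match.arg(op)
  stopifnot(inherits(a, "lane_vector"), inherits(b, "lane_vector"))
  if (a$width != b$width || a$bit_width != b$bit_width) {
    stop("lane vectors disagree in width or bit width", call. = FALSE)
  }
  hi <- as.integer(2^(a$bit_width - 1L)) - 1L
  lo <- -hi - 1L
  v <- switch(op,
              add = pmin(pmax(a$lanes + b$lanes, lo), hi),
              sub = pmin(pmax(a$lanes - b$lanes, lo), hi),
              max = pmax(a$lanes, b$lanes))
  lane_vector(v, a$bit_width)
}

#' Initial lane state for the per-cell kernel
#'
#' Holds the six lane vectors of the cell-update kernel: `h` (current-cell
#' scores; after an update it is the left neighbour of the next cell in the
#' row), `n` (diagonal neighbours), `h_e` (upper neighbours), `e` and `f`
#' (the affine-gap matrices E and F) and `S` (running per-lane maxima). All
#' start at zero, matching the zero boundary of the local-alignment
#' recurrence.
#'
#' @param width Lane count (4, 8 or 16).
#' @param bit_width 8 or 16.
#' @return A `lane_state`.
#' @export
lane_state <- function(width = 4L, bit_width = 8L) {
  z <- lane_vector(rep(0L, width), bit_width)
  structure(list(h = z, n = z, h_e = z, e = z, f = z, S = z),
            class = "lane_state")
}

#' One cell update of the packed-lane alignment kernel
#'
#' Advances W independent alignments by one DP cell using only saturating
#' add/subtract and exact max, per lane:
#' \preformatted{
#'   e' <- max(e (-) beta, h_e (-) alpha)
#'   f' <- max(f (-) beta, h   (-) alpha)   # h is the left-neighbour score
#'   h' <- max(n (+) sub, e', f', 0)
#'   S' <- max(S, h')
#' }
#' where `(+)`/`(-)` saturate to the lane's signed range. The caller owns the
#' neighbour rotation: before the next cell it must move this cell's upper
#' neighbour into `n` (it becomes the next diagonal) and refill `h_e` from
#' its row buffer.
#'
#' @param state A [lane_state()].
#' @param sub Substitution-score `lane_vector` for the current
#'   (query position, subject residue vector) pair.
#' @param alpha,beta Gap open+extend and extend penalties.
#' @return Updated `lane_state` (fields `h`, `e`, `f`, `S`).
#' @export
cell_update <- function(state, sub, alpha, beta) {
  stopifnot(inherits(state, "lane_state"), inherits(sub, "lane_vector"))
  bw <- state$h$bit_width
  w <- state$h$width
  scal <- function(v) lane_vector(rep(as.integer(v), w), bw)
  e_new <- sat_arith("max",
                     sat_arith("sub", state$e, scal(beta)),
                     sat_arith("sub", state$h_e, scal(alpha)))
  f_new <- sat_arith("max",
                     sat_arith("sub", state$f, scal(beta)),
                     sat_arith("sub", state$h, scal(alpha)))
  h_new <- sat_arith("max", sat_arith("add", state$n, sub),
                     sat_arith("max", e_new, f_new))
  h_new <- sat_arith("max", h_new, scal(0L))
  state$h <- h_new
  state$e <- e_new
  state$f <- f_new
  state$S <- sat_arith("max", state$S, h_new)
  state
}

#' Align one query against the lanes of a sequence profile
#'
#' Runs the saturating lane kernel over every cell of the profile: the query
#' is aligned simultaneously against the W member sequences, one per lane,
#' with two intermediate row buffers (for matrices H and E) over the subject
#' dimension. Reported lane scores are clamped at the signed maximum of the
#' lane width; a lane is flagged for recomputation iff its reported score
#' reaches [overflow_limit()] for that width. Padding lanes report 0 and are
#' never flagged.
#'
#' @param query An `encoded_seq` or string.
#' @param profile A `sequence_profile` from [build_sequence_profiles()].
#' @param scheme A [scoring_scheme()].
#' @param bit_width 8 or 16.
#' @param score_source `"profile"` (sequential query profile) or `"variant"`
#'   (K=2 query-profile variant); both deliver identical substitution scores
#'   through different lookup paths.
#' @param tables Optional precomputed lookup tables (list with `P` and/or
#'   `variant`), reused across profiles of one search.
#' @return List with `scores` (integer, one per lane, padding lanes 0) and
#'   `overflow_flags` (logical).
#' @export
align_lanes <- function(query, profile, scheme, bit_width = 8L,
                        score_source = c("profile", "variant"),
                        tables = NULL) {
  score_source <- match.arg(score_source)
  stopifnot(inherits(profile, "sequence_profile"),
            inherits(scheme, "scoring_scheme"))
  query <- as_encoded(query, "query")
  check_no_padding(query, scheme$alphabet)
  tables <- lane_tables(query, scheme, score_source, tables)
  res <- lanes_align_cpp(query$residues - 1L, profile$rows - 1L,
                         tables$P, tables$Va, tables$Vb,
                         score_source == "variant",
                         scheme$alpha, scheme$beta, as.integer(bit_width),
                         overflow_limit(scheme, bit_width))
  list(scores = res$scores, overflow_flags = as.logical(res$flags))
}

# internal: build / complete the lookup tables handed to the compiled kernel
lane_tables <- function(query, scheme, score_source, tables = NULL) {
  if (is.null(tables)) tables <- list()
  if (is.null(tables$P)) {
    tables$P <- unclass(build_query_profile(query, scheme))
  }
  if (score_source == "variant") {
    if (is.null(tables$Va)) {
      v <- build_variant(query, scheme)
      tables$Va <- v$plane_a
      tables$Vb <- v$plane_b
    }
  } else {
    empty <- matrix(0L, 1L, 1L)
    if (is.null(tables$Va)) tables$Va <- empty
    if (is.null(tables$Vb)) tables$Vb <- empty
  }
  tables
}

# internal: batch lane pass over a list of sequence profiles; returns scores
# and flags in member order (concatenated over profiles, padding lanes
# dropped by the caller using profile membership).
align_lanes_batch <- function(query, profiles, scheme, bit_width,
                              score_source, tables) {
  rowmats <- lapply(profiles, function(p) p$rows - 1L)
  res <- lanes_align_batch_cpp(query$residues - 1L, rowmats, tables$P,
                               tables$Va, tables$Vb,
                               score_source == "variant",
                               scheme$alpha, scheme$beta,
                               as.integer(bit_width),
                               overflow_limit(scheme, bit_width))
  list(scores = res$scores, flags = as.logical(res$flags))
}
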