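# Lookup and packing structures feeding the lane engine: the sequential
# query profile, its K=2 variant, and W-lane sequence profiles.

#' Build the sequential query profile
#'
#' Row `r` of the profile holds the substitution scores of alphabet residue
#' `r` against every query position: `P[r, i] = M(r, query[i])`. Replaces
#' per-cell matrix lookups with sequential reads along the query.
#'
#' @param query An `encoded_seq` or string.
#' @param scheme A [scoring_scheme()].
#' @return Integer matrix of size `|alphabet| x |query|`, class
#'   `query_profile`, with residue rownames.
#' @export
build_query_profile <- function(query, scheme) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  query <- as_encoded(query, "query")
  p <- scheme$matrix[, query$residues, drop = FALSE]
  dimnames(p) <- list(scheme$alphabet$symbols, NULL)
  class(p) <- c("query_profile", class(p))
  p
}

#' Pack two 8-bit substitution scores into one 16-bit word
#'
#' The packing rule `a || b` concatenates two signed 8-bit scores into one
#' short integer: `a` in the high byte, `b` (two's complement) in the low
#' byte. [unpack_scores()] is its exact inverse.
#'
#' @param a,b Integer vectors of scores in `[-128, 127]`.
#' @return Integer vector of packed words.
#' @export
pack_scores <- function(a, b) {
  stopifnot(all(a >= -128L & a <= 127L), all(b >= -128L & b <= 127L))
  as.integer(a) * 256L + (as.integer(b) %% 256L)
}

#' @rdname pack_scores
#' @param packed Integer vector of packed words.
#' @return For `unpack_scores`, a list with components `a` and `b`.
#' @export
unpack_scores <- function(packed) {
  packed <- as.integer(packed)
  lowraw <- packed %% 256L
  a <- (packed - lowraw) %/% 256L
  b <- ifelse(lowraw > 127L, lowraw - 256L, lowraw)
  list(a = as.integer(a), b = as.integer(b))
}

#' Build the K=2 query-profile variant
#'
#' Enumerates all ordered residue pairs `r = (r1, r2)` of the alphabet and
#' stores, for every query position `i`, the packed score pair
#' `(M(r1, query[i]), M(r2, query[i]))`. Pair `r` is encoded densely as
#' `r1 * |alphabet| + r2` (0-based). One variant fetch therefore serves two
#' lanes at once, halving lookups relative to the query profile. The scores
#' are stored as two parallel planes plus the [pack_scores()] /
#' [unpack_scores()] pair; unpacking entry `(r, i)` yields exactly rows `r1`
#' and `r2` of the query profile.
#'
#' Memory grows as `|query| * |alphabet|^K * 2` bytes; an optional budget
#' refuses variants that would exceed it.
#'
#' @param query An `encoded_seq` or string.
#' @param scheme A [scoring_scheme()].
#' @param K Tuple order; only 2 is supported.
#' @param memory_budget_bytes Optional cap on the variant footprint.
#' @return A `query_profile_variant`: list with `K`, `sigma`, planes
#'   `plane_a` / `plane_b` (`sigma^2 x |query|`), and `packed` accessor via
#'   [variant_row()].
#' @export
build_variant <- function(query, scheme, K = 2L,
                          memory_budget_bytes = NULL) {
  if (!identical(as.integer(K), 2L)) {
    stop("only K = 2 variants are supported", call. = FALSE)
  }
  stopifnot(inherits(scheme, "scoring_scheme"))
  query <- as_encoded(query, "query")
  sigma <- scheme$alphabet$size
  bytes <- variant_footprint_bytes(query$length, sigma, 2L)
  if (!is.null(memory_budget_bytes) && bytes > memory_budget_bytes) {
    stop("variant footprint ", bytes, " bytes exceeds memory budget ",
         memory_budget_bytes, call. = FALSE)
  }
  p <- unclass(build_query_profile(query, scheme))
  plane_a <- p[rep(seq_len(sigma), each = sigma), , drop = FALSE]
  plane_b <- p[rep(seq_len(sigma), times = sigma), , drop = FALSE]
  dimnames(plane_a) <- dimnames(plane_b) <- NULL
  structure(
    list(K = 2L, sigma = sigma, plane_a = plane_a, plane_b = plane_b,
         query_length = query$length, footprint_bytes = bytes),
    class = "query_profile_variant")
}

#' Memory footprint of a K-tuple query-profile variant
#'
#' @param query_length Query length in residues.
#' @param sigma Alphabet size.
#' @param K Tuple order.
#' @return Footprint in bytes (`query_length * sigma^K * 2`, two bytes per
#'   packed score pair).
#' @export
variant_footprint_bytes <- function(query_length, sigma, K = 2L) {
  as.numeric(query_length) * as.numeric(sigma)^K * 2
}

#' Packed row of a query-profile variant
#'
#' @param variant A `query_profile_variant`.
#' @param r1,r2 1-based alphabet indices of the residue pair.
#' @return Integer vector of packed score words along the query.
#' @export
variant_row <- function(variant, r1, r2) {
  stopifnot(inherits(variant, "query_profile_variant"))
  r <- (r1 - 1L) * variant$sigma + r2
  pack_scores(variant$plane_a[r, ], variant$plane_b[r, ])
}

#' Pack a length-sorted database into W-lane sequence profiles
#'
#' Groups consecutive runs of `width` adjacent sequences of the pre-sorted
#' (ascending length) database into sequence profiles. A profile stores an
#' `l x width` matrix of residue indices, where `l` is the longest member's
#' length; lane `k` beyond member `k`'s end holds the padding index. The
#' final group is padded with empty members. Keeping members adjacent in
#' sorted order minimises the padded (wasted) cells per profile. Rows are
#' also counted in fetch groups of 4 consecutive residue vectors, the
#' granularity of one packed fetch.
#'
#' @param sorted_db List of `encoded_seq`, sorted ascending by length.
#' @param width Lane count per profile (default 4, the device-style quad
#'   engine; the host-style engine uses 16).
#' @return List of `sequence_profile` objects; each has `members` (encoded
#'   sequences, possibly fewer than `width`), `member_index` (positions in
#'   `sorted_db`), `l`, `rows`, `width` and `fetch_groups`.
#' @export
build_sequence_profiles <- function(sorted_db, width = 4L) {
  width <- as.integer(width)
  stopifnot(width >= 1L)
  n <- length(sorted_db)
  if (n == 0L) return(list())
  lens <- db_lengths(sorted_db)
  if (is.unsorted(lens)) {
    stop("database must be sorted ascending by length before profile packing",
         call. = FALSE)
  }
  pad <- sw_alphabet()$pad_index
  starts <- seq.int(1L, n, by = width)
  lapply(starts, function(s) {
    idx <- s:min(s + width - 1L, n)
    members <- sorted_db[idx]
    l <- max(lens[idx])
    rows <- matrix(pad, nrow = l, ncol = width)
    for (k in seq_along(members)) {
      r <- members[[k]]$residues
      rows[seq_along(r), k] <- r
    }
    structure(
      list(members = members, member_index = idx, l = l, rows = rows,
           width = width, fetch_groups = ceiling(l / 4)),
      class = "sequence_profile")
  })
}

#' @export
print.sequence_profile <- function(x, ...) {
  cat("<sequence_profile> ", length(x$members), "/", x$width,
      " members, l = ", x$l, "\n", sep = "")
  invisible(x)
}
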