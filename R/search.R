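# The four-stage search pipeline: (i) partition the database over the
# device-style and host-style passes, (ii) run both saturating 8-bit lane
# passes, (iii) recompute flagged alignments at 16-bit lanes and, if still
# flagged, with the unbounded scalar engine, (iv) rank descending by score.
# Every emitted score is exact; partitioning, scheduling and lane width are
# performance constructs that never change the output.

#' Search configuration
#'
#' Collects every tunable of [sw_search()] and the command-line front end.
#' Partitioning keys mirror [compute_power_params()],
#' [compute_block_count()] and [split_database()].
#'
#' @param matrix Substitution matrix name, path or text (default
#'   `"BLOSUM62"`).
#' @param gap_open,gap_extend Gap penalties; the opening charge applied by
#'   the recurrence is `alpha = gap_open + gap_extend`.
#' @param top_n Rows to keep per query in ranked output (`Inf` = all).
#' @param n_host_threads,host_freq_ghz,device_sm_count,device_freq_ghz
#'   Compute-power model of the two passes.
#' @param calib_const_profile,calib_const_variant Calibration constants for
#'   the two score sources (3.2 / 5.1).
#' @param threads_per_block,max_resident_threads Dynamic-schedule worker
#'   sizing (defaults 64 / 2048).
#' @param device_length_cap Longest subject allowed on the device pass
#'   (default 3072; longer subjects always run on the host pass).
#' @param schedule `"auto"` (1% length-deviation rule), `"static"` or
#'   `"dynamic"`.
#' @param score_source `"auto"`, `"profile"` or `"variant"`.
#' @param variant_threshold `"auto"` or integer query-length switch point
#'   for the variant under dynamic scheduling (default 400).
#' @param cache_budget_bytes Cache budget for the `"auto"` variant
#'   threshold.
#' @param gpu_fraction `"auto"` (compute from the power model) or an
#'   explicit device residue fraction `R` in `[0, 1]`.
#' @param verbose Emit per-stage timing and GCUPS log lines.
#' @return A `sw_config` list.
#' @export
sw_config <- function(matrix = "BLOSUM62", gap_open = 10L, gap_extend = 2L,
                      top_n = Inf, n_host_threads = 4L, host_freq_ghz = 3.5,
                      device_sm_count = 8L, device_freq_ghz = 1.06,
                      calib_const_profile = 3.2, calib_const_variant = 5.1,
                      threads_per_block = 64L, max_resident_threads = 2048L,
                      device_length_cap = 3072L,
                      schedule = c("auto", "static", "dynamic"),
                      score_source = c("auto", "profile", "variant"),
                      variant_threshold = 400L,
                      cache_budget_bytes = 1536 * 1024,
                      gpu_fraction = "auto", verbose = FALSE) {
  schedule <- match.arg(schedule)
  score_source <- match.arg(score_source)
  if (!identical(gpu_fraction, "auto")) {
    stopifnot(is.numeric(gpu_fraction), gpu_fraction >= 0, gpu_fraction <= 1)
  }
  structure(
    list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
         top_n = top_n, n_host_threads = as.integer(n_host_threads),
         host_freq_ghz = host_freq_ghz,
         device_sm_count = as.integer(device_sm_count),
         device_freq_ghz = device_freq_ghz,
         calib_const_profile = calib_const_profile,
         calib_const_variant = calib_const_variant,
         threads_per_block = as.integer(threads_per_block),
         max_resident_threads = as.integer(max_resident_threads),
         device_length_cap = as.integer(device_length_cap),
         schedule = schedule, score_source = score_source,
         variant_threshold = variant_threshold,
         cache_budget_bytes = cache_budget_bytes,
         gpu_fraction = gpu_fraction, verbose = verbose),
    class = "sw_config")
}

#' Search a protein database with one query
#'
#' Ranks every database sequence by its exact Smith-Waterman local alignment
#' score against the query. The database is length-sorted ascending, split
#' into a device-style workload (quad-lane 8-bit engine over sequence
#' profiles, query profile or K=2 variant score source) and a host-style
#' workload (16-lane 8-bit engine over per-thread residue-balanced shares),
#' both computed with saturating arithmetic. Alignments whose 8-bit scores
#' reach the overflow limit are recomputed with 8-lane 16-bit arithmetic,
#' and any still at the 16-bit limit with the unbounded scalar engine, so
#' every reported score is exact regardless of configuration.
#'
#' @param query An `encoded_seq` or residue string.
#' @param database List of `encoded_seq` (e.g. from [read_fasta()]).
#' @param scheme A [scoring_scheme()]; defaults to the scheme implied by
#'   `config` (matrix + gap penalties).
#' @param config An [sw_config()].
#' @return A data.frame (class `sw_hits`) with columns `rank`, `score`,
#'   `id`, `description`, `db_index` (original database position) and
#'   `compute_path` (`device`, `host`, `recomputed-16` or
#'   `recomputed-exact`), ordered by descending score with ties broken by
#'   ascending `db_index`, truncated to `config$top_n`. Attribute `gcups`
#'   reports query length x database residues / wall time / 1e9.
#' @export
sw_search <- function(query, database, scheme = NULL, config = sw_config()) {
  stopifnot(inherits(config, "sw_config"))
  t0 <- proc.time()[["elapsed"]]
  if (is.null(scheme)) {
    scheme <- scoring_scheme(config$matrix, config$gap_open,
                             config$gap_extend)
  }
  query <- as_encoded(query, "query")
  check_no_padding(query, scheme$alphabet)
  if (length(database) == 0L) stop("empty database", call. = FALSE)
  if (query$length == 0L) stop("empty query", call. = FALSE)

  # stage (i): sort ascending by length, pick schedule / score source /
  # device share, split and balance
  lens <- db_lengths(database)
  ord <- order(lens, seq_along(database))
  sorted_db <- database[ord]
  schedule <- if (config$schedule == "auto") {
    select_schedule(lens)
  } else config$schedule
  score_source <- if (config$score_source == "auto") {
    choose_score_source(query$length, schedule,
                        cache_budget_bytes = config$cache_budget_bytes,
                        sigma = scheme$alphabet$size,
                        variant_threshold = config$variant_threshold)
  } else config$score_source
  calib <- if (score_source == "variant") {
    config$calib_const_variant
  } else config$calib_const_profile
  r_frac <- if (identical(config$gpu_fraction, "auto")) {
    if (config$device_sm_count == 0L) 0 else {
      compute_rate(compute_power_params(config$n_host_threads,
                                        config$host_freq_ghz,
                                        config$device_sm_count,
                                        config$device_freq_ghz, calib))
    }
  } else config$gpu_fraction
  if (config$device_sm_count == 0L) r_frac <- 0
  if (config$n_host_threads == 0L) r_frac <- 1
  plan <- split_database(sorted_db, r_frac, config$device_length_cap)
  if (length(plan$device_set) &&
      max(db_lengths(plan$device_set)) > config$device_length_cap) {
    stop("internal contract violation: over-cap sequence on the device pass",
         call. = FALSE)
  }
  t1 <- proc.time()[["elapsed"]]

  # stage (ii): the two concurrent-by-contract 8-bit lane passes
  tables <- lane_tables(query, scheme, score_source)
  tables <- lane_tables(query, scheme, "profile", tables)
  n_sorted <- length(sorted_db)
  scores <- numeric(n_sorted)
  flagged <- logical(n_sorted)
  path <- character(n_sorted)
  if (length(plan$device_index)) {
    profs <- build_sequence_profiles(plan$device_set, width = 4L)
    if (schedule == "dynamic") {
      n_blocks <- ceiling(length(profs) / config$threads_per_block)
      invisible(dynamic_assign(n_blocks,
                               compute_block_count(
                                 max(config$device_sm_count, 1L),
                                 config$max_resident_threads,
                                 config$threads_per_block)))
    }
    res <- align_lanes_batch(query, profs, scheme, 8L, score_source, tables)
    midx <- unlist(lapply(profs, lane_slots))
    real <- !is.na(midx)
    pos <- plan$device_index[midx[real]]
    scores[pos] <- res$scores[real]
    flagged[pos] <- res$flags[real]
    path[pos] <- "device"
  }
  if (length(plan$host_index)) {
    shares <- partition_host_threads(plan$host_set,
                                     max(1L, config$n_host_threads))
    share_idx <- attr(shares, "index")
    for (t in seq_along(shares)) {
      if (!length(shares[[t]])) next
      sub_lens <- db_lengths(shares[[t]])
      sub_ord <- order(sub_lens, seq_along(shares[[t]]))
      profs <- build_sequence_profiles(shares[[t]][sub_ord], width = 16L)
      res <- align_lanes_batch(query, profs, scheme, 8L, "profile", tables)
      midx <- unlist(lapply(profs, lane_slots))
      real <- !is.na(midx)
      pos <- plan$host_index[share_idx[[t]][sub_ord[midx[real]]]]
      scores[pos] <- res$scores[real]
      flagged[pos] <- res$flags[real]
      path[pos] <- "host"
    }
  }
  t2 <- proc.time()[["elapsed"]]

  # stage (iii): staged recomputation of flagged alignments
  if (any(flagged)) {
    rec <- recompute_overflows(query, sorted_db[flagged], scheme,
                               tables = tables)
    scores[flagged] <- rec$score
    path[flagged] <- rec$compute_path
  }
  t3 <- proc.time()[["elapsed"]]

  # stage (iv): rank descending, ties by original database position
  hits <- data.frame(score = scores,
                     id = vapply(sorted_db, `[[`, character(1L), "id"),
                     description = vapply(sorted_db, `[[`, character(1L),
                                          "description"),
                     db_index = ord,
                     compute_path = path,
                     stringsAsFactors = FALSE)
  hits <- rank_results(hits)
  if (is.finite(config$top_n)) hits <- utils::head(hits, config$top_n)
  t4 <- proc.time()[["elapsed"]]

  total_residues <- sum(as.numeric(lens))
  wall <- max(t4 - t0, .Machine$double.eps)
  gcups <- query$length * total_residues / wall / 1e9
  attr(hits, "gcups") <- gcups
  attr(hits, "schedule") <- schedule
  attr(hits, "score_source") <- score_source
  attr(hits, "R") <- r_frac
  if (isTRUE(config$verbose)) {
    message(sprintf(
      paste0("query %s (%d aa) vs %d seqs (%.0f residues): ",
             "partition %.3fs, lane passes %.3fs, recompute %.3fs ",
             "(%d flagged), rank %.3fs; %.4f GCUPS ",
             "[schedule=%s source=%s R=%.4f]"),
      query$id, query$length, n_sorted, total_residues, t1 - t0, t2 - t1,
      t3 - t2, sum(flagged), t4 - t3, gcups, schedule, score_source, r_frac))
  }
  class(hits) <- c("sw_hits", class(hits))
  hits
}

# internal: map a profile's lanes to member positions (NA for padding lanes)
lane_slots <- function(profile) {
  out <- rep(NA_integer_, profile$width)
  out[seq_along(profile$members)] <- profile$member_index
  out
}

#' Recompute alignments flagged by the 8-bit pass
#'
#' Flagged subjects are re-aligned with 8-lane 16-bit saturating arithmetic;
#' any score still at or above the 16-bit overflow limit falls through to
#' the unbounded scalar engine. All returned scores are exact.
#'
#' @param query An `encoded_seq` or string.
#' @param flagged_set List of flagged `encoded_seq` subjects.
#' @param scheme A [scoring_scheme()].
#' @param tables Optional precomputed lookup tables (see [align_lanes()]).
#' @return A data.frame with `score` and `compute_path`
#'   (`recomputed-16` or `recomputed-exact`), one row per flagged subject in
#'   input order.
#' @export
recompute_overflows <- function(query, flagged_set, scheme, tables = NULL) {
  if (!length(flagged_set)) {
    return(data.frame(score = numeric(0), compute_path = character(0),
                      stringsAsFactors = FALSE))
  }
  query <- as_encoded(query, "query")
  tables <- lane_tables(query, scheme, "profile", tables)
  lens <- db_lengths(flagged_set)
  ord <- order(lens, seq_along(flagged_set))
  profs <- build_sequence_profiles(flagged_set[ord], width = 8L)
  res <- align_lanes_batch(query, profs, scheme, 16L, "profile", tables)
  midx <- unlist(lapply(profs, function(p) {
    out <- rep(NA_integer_, p$width)
    out[seq_along(p$members)] <- p$member_index
    out
  }))
  real <- !is.na(midx)
  score <- numeric(length(flagged_set))
  score[ord[midx[real]]] <- res$scores[real]
  still <- logical(length(flagged_set))
  still[ord[midx[real]]] <- res$flags[real]
  path <- rep("recomputed-16", length(flagged_set))
  if (any(still)) {
    score[still] <- sw_score_many(query, flagged_set[still], scheme)
    path[still] <- "recomputed-exact"
  }
  data.frame(score = score, compute_path = path, stringsAsFactors = FALSE)
}

#' Rank hit records
#'
#' Orders records by descending score; ties are broken by ascending original
#' database position (`db_index`), so ranking is deterministic.
#'
#' @param records A data.frame with at least `score` and `db_index`.
#' @return The same records, reordered, with a `rank` column prepended.
#' @export
rank_results <- function(records) {
  stopifnot(all(c("score", "db_index") %in% names(records)))
  out <- records[order(-records$score, records$db_index), , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' @export
print.sw_hits <- function(x, n = 10L, ...) {
  cat("<sw_hits> ", nrow(x), " ranked hits",
      if (!is.null(attr(x, "gcups")))
        sprintf(" (%.4f GCUPS, schedule=%s, source=%s)",
                attr(x, "gcups"), attr(x, "schedule"),
                attr(x, "score_source")),
      "\n", sep = "")
  print.data.frame(utils::head(x, n))
  invisible(x)
}
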