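# Workload distribution between the device-style and host-style passes,
# host-thread residue balancing, worker sizing and schedule/score-source
# policy. Partitioning is purely a performance construct: ranked search
# output is identical for every partition, thread count and schedule.

#' Compute-power parameters of the heterogeneous platform
#'
#' @param n_host_threads Host worker (CPU thread) count `N_C`.
#' @param host_freq_ghz Host core frequency `f_C` in GHz.
#' @param device_sm_count Device multiprocessor count `N_G` (summed over
#'   devices when several are modelled).
#' @param device_freq_ghz Device core frequency `f_G` in GHz.
#' @param calib_const Calibration constant `C` relating host and device
#'   per-core throughput: 3.2 when the device pass uses the query profile,
#'   5.1 when it uses the K=2 variant.
#' @return A `compute_power_params` list.
#' @export
compute_power_params <- function(n_host_threads = 4, host_freq_ghz = 3.5,
                                 device_sm_count = 8, device_freq_ghz = 1.06,
                                 calib_const = 3.2) {
  stopifnot(n_host_threads >= 0, device_sm_count >= 0, host_freq_ghz > 0,
            device_freq_ghz > 0, calib_const > 0)
  if (n_host_threads == 0 && device_sm_count == 0) {
    stop("at least one of host threads or device multiprocessors must be > 0",
         call. = FALSE)
  }
  structure(list(N_C = n_host_threads, f_C = host_freq_ghz,
                 N_G = device_sm_count, f_G = device_freq_ghz,
                 C = calib_const),
            class = "compute_power_params")
}

#' Device share of the database residues
#'
#' The fraction `R` of all database residues routed to the device-style pass
#' is set by the relative compute power of the two sides:
#' \deqn{R = \frac{N_G f_G}{N_G f_G + N_C f_C / C}}
#'
#' @param params A [compute_power_params()].
#' @return `R` in `[0, 1]`.
#' @examples
#' compute_rate(compute_power_params(4, 3.5, 8, 1.06, 3.2))  # ~0.6597
#' @export
compute_rate <- function(params) {
  stopifnot(inherits(params, "compute_power_params"))
  dev <- params$N_G * params$f_G
  host <- params$N_C * params$f_C / params$C
  if (dev + host <= 0) {
    stop("total compute power is zero", call. = FALSE)
  }
  dev / (dev + host)
}

# nearest integer, ties rounded up
round_half_up <- function(x) floor(x + 0.5)

#' Split a length-sorted database into device and host workloads
#'
#' The device residue quota is `N_R = round(R * total residues)` (ties up).
#' Device sequences are taken as the shortest prefix, in ascending length
#' order, of the cap-eligible sequences whose cumulative length reaches
#' `N_R` (all eligible sequences if the quota is never reached). Sequences
#' longer than `device_length_cap` always go to the host, mirroring the
#' statically sized per-alignment row buffers of the device pass.
#'
#' @param sorted_db List of `encoded_seq` sorted ascending by length.
#' @param R Device residue fraction in `[0, 1]`.
#' @param device_length_cap Maximum device-pass subject length (default
#'   3072).
#' @return A `partition_plan`: list with `R`, `N_R`, `device_index` /
#'   `host_index` (positions in `sorted_db`), `device_set` / `host_set`
#'   (the sequences) and `device_residues`.
#' @export
split_database <- function(sorted_db, R, device_length_cap = 3072L) {
  stopifnot(R >= 0, R <= 1)
  lens <- db_lengths(sorted_db)
  if (is.unsorted(lens)) {
    stop("database must be sorted ascending by length", call. = FALSE)
  }
  total <- sum(as.numeric(lens))
  n_r <- round_half_up(R * total)
  eligible <- which(lens <= device_length_cap)
  cum <- cumsum(as.numeric(lens[eligible]))
  k <- if (n_r <= 0) 0L else {
    hit <- which(cum >= n_r)
    if (length(hit)) hit[1L] else length(eligible)
  }
  device_index <- eligible[seq_len(k)]
  host_index <- setdiff(seq_along(sorted_db), device_index)
  structure(
    list(R = R, N_R = n_r,
         device_index = device_index, host_index = host_index,
         device_set = sorted_db[device_index],
         host_set = sorted_db[host_index],
         device_residues = if (k > 0) cum[k] else 0,
         device_length_cap = device_length_cap),
    class = "partition_plan")
}

#' @export
print.partition_plan <- function(x, ...) {
  cat("<partition_plan> R = ", signif(x$R, 4), ", quota ", x$N_R,
      " residues; device ", length(x$device_index), " seqs (",
      x$device_residues, " residues), host ", length(x$host_index),
      " seqs\n", sep = "")
  invisible(x)
}

#' Balance host-pass sequences over worker threads
#'
#' Distributes sequences so every thread holds (nearly) the same number of
#' residues, using a sequence as the indivisible unit: greedy longest-first
#' assignment to the currently least-loaded thread (ties to the lowest
#' thread id). The max/min thread loads then differ by at most the longest
#' sequence length.
#'
#' @param host_set List of `encoded_seq`.
#' @param n_threads Worker count (>= 1).
#' @return List of `n_threads` lists of sequences; attribute `loads` gives
#'   per-thread residue totals, attribute `index` the positions in
#'   `host_set` per thread.
#' @export
partition_host_threads <- function(host_set, n_threads) {
  n_threads <- as.integer(n_threads)
  stopifnot(n_threads >= 1L)
  lens <- db_lengths(host_set)
  loads <- numeric(n_threads)
  assign_to <- integer(length(host_set))
  for (i in order(-lens, seq_along(lens))) {
    t <- which.min(loads)
    assign_to[i] <- t
    loads[t] <- loads[t] + lens[i]
  }
  shares <- lapply(seq_len(n_threads), function(t) {
    host_set[which(assign_to == t)]
  })
  attr(shares, "loads") <- loads
  attr(shares, "index") <- lapply(seq_len(n_threads),
                                  function(t) which(assign_to == t))
  shares
}

#' Worker-block count for the dynamic schedule
#'
#' Number of worker blocks launched for dynamic scheduling:
#' `N_T = floor(2 * N_SM * N_MRT / N_TPB)`, i.e. twice the resident-thread
#' capacity of the device divided by the block size.
#'
#' @param n_sm Multiprocessor count `N_SM`.
#' @param max_resident_threads Maximum resident threads per multiprocessor
#'   `N_MRT` (default 2048).
#' @param threads_per_block Block size `N_TPB` (default 64).
#' @return Integer block count `N_T`.
#' @examples
#' compute_block_count(8)  # 512
#' @export
compute_block_count <- function(n_sm, max_resident_threads = 2048L,
                                threads_per_block = 64L) {
  stopifnot(n_sm > 0, max_resident_threads > 0, threads_per_block > 0)
  as.integer((2 * n_sm * max_resident_threads) %/% threads_per_block)
}

#' Choose static or dynamic scheduling from length deviation
#'
#' Static scheduling (all work units assigned up front) is selected when the
#' database's sequence lengths are nearly uniform: population standard
#' deviation at most `threshold` (default 1%) of the mean. Any larger
#' deviation selects dynamic scheduling (workers pull units from a shared
#' counter).
#'
#' @param lengths Sequence length vector.
#' @param threshold Deviation-to-mean ratio cutoff (default 0.01).
#' @return `"static"` or `"dynamic"`.
#' @export
select_schedule <- function(lengths, threshold = 0.01) {
  stopifnot(length(lengths) >= 1L)
  m <- mean(lengths)
  sdev <- sqrt(mean((lengths - m)^2))
  if (sdev / m <= threshold) "static" else "dynamic"
}

#' Choose between query profile and its K=2 variant
#'
#' Under static scheduling the variant is always used. Under dynamic
#' scheduling the variant is used only for queries shorter than a threshold
#' `Q`: the variant's halved fetch count wins for short queries, while its
#' `|alphabet|^2`-row footprint loses to the compact query profile once the
#' query grows. With `variant_threshold = "auto"`, `Q` is estimated as the
#' query length at which the variant fills a cache budget:
#' `Q = floor(cache_budget_bytes / (2 * sigma^K))`. The default is the fixed
#' empirical switch point 400.
#'
#' @param query_length Query length in residues.
#' @param schedule `"static"` or `"dynamic"`.
#' @param cache_budget_bytes Cache budget for the `"auto"` estimate
#'   (default 1536 KB).
#' @param sigma Alphabet size used in the footprint estimate.
#' @param K Tuple order (2).
#' @param variant_threshold `"auto"` or an explicit integer `Q`.
#' @return `"variant"` or `"profile"`.
#' @examples
#' choose_score_source(300, "dynamic", variant_threshold = "auto",
#'                     cache_budget_bytes = 524288, sigma = 32)  # Q = 256
#' @export
choose_score_source <- function(query_length, schedule,
                                cache_budget_bytes = 1536 * 1024,
                                sigma = sw_alphabet()$size, K = 2L,
                                variant_threshold = 400L) {
  stopifnot(identical(as.integer(K), 2L),
            schedule %in% c("static", "dynamic"))
  if (schedule == "static") return("variant")
  q <- if (identical(variant_threshold, "auto")) {
    floor(cache_budget_bytes / (2 * sigma^K))
  } else {
    as.numeric(variant_threshold)
  }
  if (query_length < q) "variant" else "profile"
}

#' Dynamic work-unit assignment trace
#'
#' Emulates workers pulling units off a shared monotone counter: each unit
#' is consumed exactly once, in counter order, by the next free worker
#' (cyclic in this deterministic emulation). The trace is bookkeeping only;
#' search results never depend on it.
#'
#' @param n_units Work-unit count.
#' @param n_workers Worker count (>= 1).
#' @return A data.frame with columns `worker` and `unit` (1-based, in
#'   assignment order); attribute `counter` holds the final counter value
#'   (= `n_units`).
#' @export
dynamic_assign <- function(n_units, n_workers) {
  n_units <- as.integer(n_units)
  n_workers <- as.integer(n_workers)
  stopifnot(n_workers >= 1L, n_units >= 0L)
  units <- seq_len(n_units)
  trace <- data.frame(
    worker = if (n_units) ((units - 1L) %% n_workers) + 1L else integer(0),
    unit = units)
  attr(trace, "counter") <- n_units
  trace
}

#' Longest device-pass subject supported by the per-alignment buffers
#'
#' The device-style pass holds two statically allocated row buffers (for
#' matrices H and E) per alignment in a fixed local-memory budget. With
#' 4-byte packed lane cells, the longest supportable subject is
#' `floor(local_mem_bytes / (n_buffers * bytes_per_cell))`: 65536 for the
#' default 512 KB budget.
#'
#' @param local_mem_bytes Per-alignment local memory budget (default
#'   `512 * 1024`).
#' @param n_buffers Row buffers per alignment (2: H and E).
#' @param bytes_per_cell Bytes per packed lane cell (4).
#' @return Maximum subject length.
#' @export
max_device_subject_length <- function(local_mem_bytes = 512 * 1024,
                                      n_buffers = 2L, bytes_per_cell = 4L) {
  floor(local_mem_bytes / (n_buffers * bytes_per_cell))
}
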