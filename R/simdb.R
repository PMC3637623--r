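# Synthetic protein database generation: equal-length databases (the
# idealised benchmark input, where every lane of every vector finishes at
# the same time) and variable-length databases with a lognormal length
# model (Swiss-Prot-like spread). Residues are drawn uniformly from the 20
# standard amino acids; generation is seeded and bit-reproducible, and can
# stream in chunks so full-scale databases never need to be materialised.

#' Specification of a synthetic database
#'
#' @param mode `"equal"` (all sequences of `fixed_length`) or `"lognormal"`
#'   (lengths drawn from a lognormal with the given mean and standard
#'   deviation, truncated to >= 1).
#' @param n_sequences Sequence count.
#' @param fixed_length Length of every sequence in `"equal"` mode.
#' @param length_mean,length_sd Target mean / sd of lengths in
#'   `"lognormal"` mode.
#' @param seed RNG seed; generation is deterministic given the spec.
#' @return A `db_spec`.
#' @export
db_spec <- function(mode = c("equal", "lognormal"), n_sequences,
                    fixed_length = 3000L, length_mean = 350,
                    length_sd = 300, seed = 1L) {
  mode <- match.arg(mode)
  n_sequences <- as.integer(n_sequences)
  stopifnot(n_sequences >= 1L)
  if (mode == "equal") stopifnot(fixed_length >= 1L)
  if (mode == "lognormal") stopifnot(length_mean > 0, length_sd > 0)
  structure(list(mode = mode, n_sequences = n_sequences,
                 fixed_length = as.integer(fixed_length),
                 length_mean = length_mean, length_sd = length_sd,
                 seed = as.integer(seed)),
            class = "db_spec")
}

# internal: draw all sequence lengths for a spec (RNG already seeded)
draw_lengths <- function(spec) {
  if (spec$mode == "equal") {
    rep(spec$fixed_length, spec$n_sequences)
  } else {
    sdlog <- sqrt(log(1 + (spec$length_sd / spec$length_mean)^2))
    meanlog <- log(spec$length_mean) - sdlog^2 / 2
    pmax(1L, as.integer(round(stats::rlnorm(spec$n_sequences, meanlog,
                                            sdlog))))
  }
}

#' Generate a synthetic protein database
#'
#' Draws residues uniformly from the 20 standard amino acids with the
#' spec's seed. With `path = NULL` the database is returned as a list of
#' `encoded_seq`; with a path it is streamed to FASTA in chunks of
#' `chunk_size` sequences, so arbitrarily large databases can be written
#' without full materialisation. Both sinks consume the RNG identically, so
#' they produce the same sequences for the same spec.
#'
#' @param spec A [db_spec()].
#' @param path Optional FASTA output path.
#' @param chunk_size Sequences per streaming chunk.
#' @return With `path = NULL`, a list of `encoded_seq`; otherwise `path`,
#'   invisibly.
#' @export
generate_db <- function(spec, path = NULL, chunk_size = 1000L) {
  stopifnot(inherits(spec, "db_spec"))
  if (is.null(path)) {
    out <- vector("list", spec$n_sequences)
    stream_generate(spec, chunk_size, function(first, records) {
      out[first + seq_along(records) - 1L] <<- records
    })
    out
  } else {
    if (file.exists(path)) file.remove(path)
    alphabet <- sw_alphabet()
    stream_generate(spec, chunk_size, function(first, records) {
      txt <- vapply(records, decode_sequence, character(1L),
                    alphabet = alphabet)
      set <- Biostrings::BStringSet(txt)
      names(set) <- vapply(records, `[[`, character(1L), "id")
      Biostrings::writeXStringSet(set, path, append = file.exists(path),
                                  width = 60L)
    })
    invisible(path)
  }
}

# internal: chunked generation driver; sink(first_index, records) is called
# per chunk. RNG state is isolated from the caller's.
stream_generate <- function(spec, chunk_size, sink) {
  withr::with_seed(spec$seed, {
    lens <- draw_lengths(spec)
    i <- 1L
    while (i <= spec$n_sequences) {
      idx <- i:min(i + chunk_size - 1L, spec$n_sequences)
      codes <- sample.int(20L, sum(lens[idx]), replace = TRUE)
      ends <- cumsum(lens[idx])
      starts <- c(1L, utils::head(ends, -1L) + 1L)
      records <- lapply(seq_along(idx), function(k) {
        new_encoded_seq(sprintf("sim%06d", idx[k]), "",
                        codes[starts[k]:ends[k]])
      })
      sink(i, records)
      i <- idx[length(idx)] + 1L
    }
    invisible(lens)
  })
}

#' Summary statistics of a database
#'
#' Works on a list of `encoded_seq`, a FASTA path (lengths are read without
#' loading residues), or a [db_spec()] — in which case the spec is streamed
#' through the seeded generator with a running counter, never materialising
#' the database. The standard deviation is the population standard
#' deviation, as used by the 1% scheduling rule.
#'
#' @param database List of `encoded_seq`, FASTA path, or `db_spec`.
#' @param chunk_size Streaming chunk size for the `db_spec` method.
#' @return List with `n_sequences`, `n_residues`, `max_length`,
#'   `mean_length`, `sd_length` and `ratio` (sd/mean).
#' @export
db_stats <- function(database, chunk_size = 1000L) {
  lens <-
    if (inherits(database, "db_spec")) {
      n_res <- 0
      all_lens <- numeric(0)
      stream_generate(database, chunk_size, function(first, records) {
        chunk_lens <- vapply(records, `[[`, integer(1L), "length")
        n_res <<- n_res + sum(as.numeric(chunk_lens))
        all_lens <<- c(all_lens, chunk_lens)
      })
      all_lens
    } else if (is.character(database)) {
      as.numeric(Biostrings::fasta.seqlengths(database))
    } else {
      as.numeric(db_lengths(database))
    }
  if (!length(lens)) stop("empty database", call. = FALSE)
  m <- mean(lens)
  sdev <- sqrt(mean((lens - m)^2))
  list(n_sequences = length(lens), n_residues = sum(lens),
       max_length = max(lens), mean_length = m, sd_length = sdev,
       ratio = if (m > 0) sdev / m else 0)
}

#' Stream-count the residues of a synthetic database
#'
#' Runs the seeded generator over the full spec in chunks, counting
#' generated residues without storing sequences or writing files. Useful
#' for verifying full-scale database sizes (e.g. 200,000 sequences of
#' length 3,000 = 600,000,000 residues) in bounded memory.
#'
#' @param spec A [db_spec()].
#' @param chunk_size Sequences per chunk.
#' @return Total residue count (numeric).
#' @export
stream_residue_count <- function(spec, chunk_size = 5000L) {
  n_res <- 0
  stream_generate(spec, chunk_size, function(first, records) {
    n_res <<- n_res + sum(vapply(records, `[[`, integer(1L), "length"))
  })
  n_res
}
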