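# Shared fixtures: random sequence/database builders, toy scoring schemes,
# constructed overflow pairs, and a pure-R lane aligner assembled from
# cell_update() that serves as an independent route to the compiled engine.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_seq <- function(n, id = "s") {
  swlanes:::new_encoded_seq(id, "", sample.int(20L, n, replace = TRUE))
}

random_db <- function(n_seqs, min_len, max_len, prefix = "s") {
  lapply(seq_len(n_seqs), function(i) {
    random_seq(sample.int(max_len - min_len + 1L, 1L) + min_len - 1L,
               paste0(prefix, i))
  })
}

# match +2 / mismatch -1 over A, C, G, T; gap open 2 + extend 1 (alpha 3)
toy_scheme <- function() {
  scoring_scheme(paste("  A  C  G  T",
                       "A  2 -1 -1 -1",
                       "C -1  2 -1 -1",
                       "G -1 -1  2 -1",
                       "T -1 -1 -1  2", sep = "\n"),
                 gap_open = 2, gap_extend = 1, name = "toy")
}

# self-alignments with exact scores 116/117/118/130/40000 under BLOSUM62
# (sums of positive diagonal entries: W=11, N=6, C=9, H=8, A=4)
overflow_seqs <- function() {
  list(s116 = encode_sequence(paste0(strrep("W", 10), "N"), id = "s116"),
       s117 = encode_sequence(paste0(strrep("W", 9), "CC"), id = "s117"),
       s118 = encode_sequence(paste0(strrep("W", 10), "H"), id = "s118"),
       s130 = encode_sequence(paste0(strrep("W", 11), "C"), id = "s130"),
       s40000 = encode_sequence(paste0(strrep("W", 3636), "A"),
                                id = "s40000"))
}

overflow_true_scores <- c(s116 = 116, s117 = 117, s118 = 118, s130 = 130,
                          s40000 = 40000)

# Pure-R lane engine driven cell by cell through cell_update(): outer loop
# over query positions, inner over subject positions, row buffers for H and
# E, carries for F and the left/diagonal H. Slow; for tiny cross-checks of
# the compiled engine only.
lane_align_r <- function(query, profile, scheme, bit_width = 8L) {
  query <- swlanes:::as_encoded(query)
  W <- profile$width
  l <- profile$l
  lo <- -as.integer(2^(bit_width - 1L))
  lv <- function(v) lane_vector(pmax(as.integer(v), lo), bit_width)
  Hbuf <- matrix(0L, l, W)
  Ebuf <- matrix(0L, l, W)
  S <- lv(rep(0L, W))
  for (i in seq_len(query$length)) {
    st <- lane_state(W, bit_width)
    st$S <- S
    hdiag <- rep(0L, W)
    for (j in seq_len(l)) {
      st$n <- lv(hdiag)
      st$h_e <- lv(Hbuf[j, ])
      st$e <- lv(Ebuf[j, ])
      sub <- lv(scheme$matrix[query$residues[i], profile$rows[j, ]])
      hdiag <- Hbuf[j, ]
      st <- cell_update(st, sub, scheme$alpha, scheme$beta)
      Hbuf[j, ] <- st$h$lanes
      Ebuf[j, ] <- st$e$lanes
    }
    S <- st$S
  }
  S$lanes
}
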