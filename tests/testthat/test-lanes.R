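test_that("saturating arithmetic clamps to the signed lane range", {
  a <- lane_vector(c(100L, 3L, 0L, -5L))
  b <- lane_vector(c(50L, 4L, 0L, -5L))
  expect_identical(sat_arith("add", a, b)$lanes, c(127L, 7L, 0L, -10L))
  a2 <- lane_vector(c(-100L, 0L, 5L, 1L))
  b2 <- lane_vector(c(50L, 0L, 3L, 1L))
  expect_identical(sat_arith("sub", a2, b2)$lanes, c(-128L, 0L, 2L, 0L))
  set.seed(2)
  for (k in 1:10) {
    x <- lane_vector(sample(-128:127, 8), 8)
    y <- lane_vector(sample(-128:127, 8), 8)
    expect_identical(sat_arith("max", x, y)$lanes,
                     sat_arith("max", y, x)$lanes)
  }
  w16 <- lane_vector(rep(30000L, 8), 16)
  expect_identical(sat_arith("add", w16, w16)$lanes, rep(32767L, 8))
  expect_error(sat_arith("add", a, lane_vector(rep(0L, 8))), "width")
  expect_error(lane_vector(c(1L, 200L, 0L, 0L), 8), "range")
})

test_that("one cell update follows the recurrence with saturation", {
  st <- lane_state(4, 8)
  st$n <- lane_vector(c(5L, 0L, 120L, 0L))
  st$e <- lane_vector(c(3L, 0L, 0L, 0L))
  st$f <- lane_vector(c(2L, 0L, 0L, 0L))
  sub <- lane_vector(c(4L, -4L, 20L, -128L))
  out <- cell_update(st, sub, alpha = 12L, beta = 2L)
  expect_identical(out$h$lanes[1], 9L)      # n + sub wins
  expect_identical(out$h$lanes[2], 0L)      # zero floor on negative sub
  expect_identical(out$h$lanes[3], 127L)    # saturated add
  expect_identical(out$h$lanes[4], 0L)      # sentinel (padding) lane
  expect_identical(out$S$lanes, out$h$lanes)
  expect_true(all(out$S$lanes >= out$h$lanes))
})

test_that("unflagged lane scores equal the exact oracle; flags track the limit", {
  sc <- scoring_scheme("BLOSUM62")
  lim <- overflow_limit(sc, 8)
  set.seed(101)
  for (k in 1:25) {
    members <- random_db(4, 5, 60)
    members <- members[order(db_len <- vapply(members, `[[`, integer(1),
                                              "length"))]
    q <- random_seq(sample(10:50, 1), "q")
    prof <- build_sequence_profiles(members, 4)[[1]]
    res <- align_lanes(q, prof, sc, 8, "profile")
    truth <- sw_score_many(q, members, sc)
    expect_identical(res$overflow_flags, truth >= lim)
    ok <- !res$overflow_flags
    expect_identical(as.numeric(res$scores[ok]), truth[ok])
  }
})

test_that("padding lanes report zero and are never flagged", {
  sc <- scoring_scheme("BLOSUM62")
  set.seed(42)
  members <- random_db(2, 10, 30)
  members <- members[order(vapply(members, `[[`, integer(1), "length"))]
  prof <- build_sequence_profiles(members, 4)[[1]]
  q <- random_seq(25, "q")
  res <- align_lanes(q, prof, sc, 8)
  expect_identical(res$scores[3:4], c(0L, 0L))
  expect_identical(res$overflow_flags[3:4], c(FALSE, FALSE))
  expect_identical(as.numeric(res$scores[1:2]), sw_score_many(q, members, sc))
})

test_that("lanes are independent: identical subjects and permutations", {
  sc <- scoring_scheme("BLOSUM62")
  set.seed(12)
  s <- random_seq(40)
  q <- random_seq(30, "q")
  prof <- build_sequence_profiles(list(s, s, s, s), 4)[[1]]
  res <- align_lanes(q, prof, sc, 8)
  expect_true(all(res$scores == sw_score(q, s, sc)))
  members <- random_db(4, 20, 20)  # equal lengths so any order is sorted
  prof1 <- build_sequence_profiles(members, 4)[[1]]
  perm <- c(3, 1, 4, 2)
  prof2 <- build_sequence_profiles(members[perm], 4)[[1]]
  r1 <- align_lanes(q, prof1, sc, 8)
  r2 <- align_lanes(q, prof2, sc, 8)
  expect_identical(r2$scores, r1$scores[perm])
})

test_that("4-, 8- and 16-lane engines give identical per-sequence results", {
  sc <- scoring_scheme("BLOSUM62")
  set.seed(77)
  db <- random_db(19, 10, 80)
  db <- db[order(vapply(db, `[[`, integer(1), "length"))]
  q <- random_seq(35, "q")
  per_width <- lapply(c(4L, 8L, 16L), function(w) {
    profs <- build_sequence_profiles(db, w)
    unlist(lapply(profs, function(p) {
      align_lanes(q, p, sc, 8)$scores[seq_along(p$members)]
    }))
  })
  expect_identical(per_width[[1]], per_width[[2]])
  expect_identical(per_width[[1]], per_width[[3]])
})

test_that("16-bit lanes are exact below the 16-bit limit", {
  sc <- scoring_scheme("BLOSUM62")
  s130 <- overflow_seqs()$s130
  prof <- build_sequence_profiles(list(s130), 8)[[1]]
  res8 <- align_lanes(s130, prof, sc, 8)
  expect_identical(res8$scores[1], 127L)  # clamped
  expect_true(res8$overflow_flags[1])
  res16 <- align_lanes(s130, prof, sc, 16)
  expect_identical(res16$scores[1], 130L)
  expect_false(res16$overflow_flags[1])
})

test_that("compiled engine matches the cell_update kernel cell for cell", {
  sc <- scoring_scheme("BLOSUM62")
  set.seed(303)
  for (bw in c(8L, 16L)) {
    members <- random_db(3, 4, 10)
    members <- members[order(vapply(members, `[[`, integer(1), "length"))]
    prof <- build_sequence_profiles(members, 4)[[1]]
    q <- random_seq(8, "q")
    expect_identical(align_lanes(q, prof, sc, bw)$scores,
                     lane_align_r(q, prof, sc, bw))
  }
})
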