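test_that("query profile rows are substitution scores along the query", {
  toy <- scoring_scheme("A B\nA 2 -1\nB -1 2", gap_open = 2, gap_extend = 1)
  p <- build_query_profile("ABA", toy)
  expect_identical(unname(p["A", ]), c(2L, -1L, 2L))
  expect_identical(unname(p["B", ]), c(-1L, 2L, -1L))
  sc <- scoring_scheme("BLOSUM62")
  set.seed(21)
  q <- random_seq(50, "q")
  p62 <- build_query_profile(q, sc)
  for (k in 1:100) {
    r <- sample.int(sc$alphabet$size, 1)
    i <- sample.int(q$length, 1)
    expect_identical(unname(p62[r, i]),
                     unname(sc$matrix[r, q$residues[i]]))
  }
})

test_that("pack/unpack is an exact inverse over the full score range", {
  grid <- expand.grid(a = seq(-128L, 127L, by = 15L),
                      b = seq(-128L, 127L, by = 15L))
  packed <- pack_scores(grid$a, grid$b)
  un <- unpack_scores(packed)
  expect_identical(un$a, as.integer(grid$a))
  expect_identical(un$b, as.integer(grid$b))
})

test_that("the K=2 variant packs exactly the paired query-profile rows", {
  toy <- scoring_scheme("A B\nA 2 -1\nB -1 2", gap_open = 2, gap_extend = 1)
  v <- build_variant("ABA", toy)
  a_i <- 1L
  b_i <- match("B", toy$alphabet$symbols)
  row_ab <- unpack_scores(variant_row(v, a_i, b_i))
  expect_identical(row_ab$a, c(2L, -1L, 2L))
  expect_identical(row_ab$b, c(-1L, 2L, -1L))
  row_aa <- unpack_scores(variant_row(v, a_i, a_i))
  expect_identical(row_aa$a, row_aa$b)
  # random probes against paired profile rows, full alphabet
  sc <- scoring_scheme("BLOSUM62")
  set.seed(31)
  q <- random_seq(30, "q")
  p <- build_query_profile(q, sc)
  v62 <- build_variant(q, sc)
  for (k in 1:50) {
    r1 <- sample.int(sc$alphabet$size, 1)
    r2 <- sample.int(sc$alphabet$size, 1)
    un <- unpack_scores(variant_row(v62, r1, r2))
    expect_identical(un$a, unname(p[r1, ]))
    expect_identical(un$b, unname(p[r2, ]))
  }
  expect_identical(v62$sigma * v62$sigma, nrow(v62$plane_a))
})

test_that("variant memory accounting matches its stated complexity", {
  sc <- scoring_scheme("BLOSUM62")
  sigma <- sc$alphabet$size
  expect_identical(variant_footprint_bytes(144, sigma),
                   144 * sigma^2 * 2)
  v <- build_variant(random_seq(20, "q"), sc)
  expect_identical(v$footprint_bytes, 20 * sigma^2 * 2)
  expect_error(build_variant(random_seq(100, "q"), sc, K = 2,
                             memory_budget_bytes = 1000),
               "memory budget")
  expect_error(build_variant(random_seq(5, "q"), sc, K = 4), "K = 2")
})

test_that("sequence profiles group, pad and conserve residues", {
  set.seed(8)
  db <- random_db(5, 10, 40)
  db <- db[order(vapply(db, `[[`, integer(1), "length"))]
  profs <- build_sequence_profiles(db, 4)
  expect_length(profs, 2)
  expect_length(profs[[1]]$members, 4)
  expect_length(profs[[2]]$members, 1)
  pad <- sw_alphabet()$pad_index
  non_pad <- sum(vapply(profs, function(p) sum(p$rows != pad), numeric(1)))
  expect_equal(non_pad, sum(vapply(db, `[[`, integer(1), "length")))

  lens <- c(3L, 3L, 4L, 5L)
  db2 <- lapply(seq_along(lens), function(i) random_seq(lens[i],
                                                        paste0("t", i)))
  p <- build_sequence_profiles(db2, 4)[[1]]
  expect_identical(p$l, 5L)
  expect_true(all(p$rows[4:5, 1] == pad))
  expect_true(all(p$rows[1:3, 1] != pad))
  expect_identical(p$fetch_groups, ceiling(5 / 4))

  expect_error(build_sequence_profiles(rev(db), 4), "sorted")
})

test_that("profile and variant score sources agree through the engine", {
  sc <- scoring_scheme("BLOSUM62")
  set.seed(55)
  db <- random_db(30, 10, 120)
  db <- db[order(vapply(db, `[[`, integer(1), "length"))]
  q <- random_seq(60, "q")
  profs <- build_sequence_profiles(db, 4)
  for (p in profs) {
    a <- align_lanes(q, p, sc, 8, "profile")
    b <- align_lanes(q, p, sc, 8, "variant")
    expect_identical(a$scores, b$scores)
    expect_identical(a$overflow_flags, b$overflow_flags)
  }
})
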