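test_that("pipeline scores equal the exact oracle for every subject", {
  sc <- scoring_scheme("BLOSUM62")
  set.seed(2024)
  db <- random_db(200, 20, 200)
  q <- random_seq(100, "q")
  hits <- sw_search(q, db, sc, sw_config(top_n = Inf))
  truth <- sw_score_many(q, db, sc)
  expect_identical(nrow(hits), 200L)
  expect_identical(hits$score[order(hits$db_index)], truth)
  expect_true(all(hits$compute_path %in%
                    c("device", "host", "recomputed-16", "recomputed-exact")))
  expect_true(all(diff(hits$score) <= 0))
  expect_gt(attr(hits, "gcups"), 0)
})

test_that("a single-sequence database returns the self-alignment at rank 1", {
  sc <- scoring_scheme("BLOSUM62")
  set.seed(4)
  s <- random_seq(40, "self")
  hits <- sw_search(s, list(s), sc, sw_config())
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$rank, 1L)
  expect_identical(hits$score, sw_score(s, s, sc))
})

test_that("ranked output is invariant to schedule, threads and split", {
  sc <- scoring_scheme("BLOSUM62")
  set.seed(99)
  db <- random_db(120, 20, 150)
  q <- random_seq(80, "q")
  reference <- NULL
  for (sched in c("static", "dynamic")) {
    for (threads in c(1L, 4L)) {
      for (r in list(0, 0.5, 1)) {
        hits <- sw_search(q, db, sc,
                          sw_config(top_n = Inf, schedule = sched,
                                    n_host_threads = threads,
                                    gpu_fraction = r))
        tab <- hits[, c("rank", "score", "id", "db_index")]
        if (is.null(reference)) reference <- tab else {
          expect_identical(tab, reference)
        }
      }
    }
  }
})

test_that("ranking sorts descending with ties broken by database position", {
  rec <- data.frame(score = c(5, 9, 9, 1), db_index = c(10, 11, 12, 13),
                    id = paste0("s", 1:4))
  out <- rank_results(rec)
  expect_identical(out$db_index, c(11, 12, 10, 13))
  expect_identical(out$rank, 1:4)
  expect_identical(sort(out$score), sort(rec$score))
  one <- rank_results(rec[2, ])
  expect_identical(one$rank, 1L)
})

test_that("flagged alignments are recomputed exactly through the stages", {
  sc <- scoring_scheme("BLOSUM62")
  empty <- recompute_overflows("ACD", list(), sc)
  expect_identical(nrow(empty), 0L)
  seqs <- overflow_seqs()
  rec <- recompute_overflows(seqs$s130, list(seqs$s130), sc)
  expect_identical(rec$score, 130)
  expect_identical(rec$compute_path, "recomputed-16")
  rec2 <- recompute_overflows(seqs$s40000, list(seqs$s40000), sc)
  expect_identical(rec2$score, 40000)
  expect_identical(rec2$compute_path, "recomputed-exact")
})

test_that("degenerate inputs are rejected", {
  sc <- scoring_scheme("BLOSUM62")
  expect_error(sw_search("ACD", list(), sc), "empty database")
  expect_error(sw_search("", list(encode_sequence("ACD")), sc), "empty")
})

test_that("top-N truncation keeps the best-ranked hits", {
  sc <- scoring_scheme("BLOSUM62")
  set.seed(17)
  db <- random_db(50, 20, 60)
  q <- random_seq(30, "q")
  all_hits <- sw_search(q, db, sc, sw_config(top_n = Inf))
  top5 <- sw_search(q, db, sc, sw_config(top_n = 5))
  expect_identical(nrow(top5), 5L)
  expect_identical(top5$score, all_hits$score[1:5])
})
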