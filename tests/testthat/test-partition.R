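test_that("device residue rate follows the compute-power formula", {
  # 8 SMs at 1.06 GHz vs 4 cores at 3.5 GHz, C = 3.2
  p <- compute_power_params(4, 3.5, 8, 1.06, 3.2)
  expect_equal(compute_rate(p), 0.659665499805523, tolerance = 1e-12)
  expect_identical(compute_rate(compute_power_params(0, 3.5, 8, 1.06)), 1)
  balanced <- compute_power_params(4, 3.2, 4, 1.0, 3.2)  # N_C f_C / C = N_G f_G
  expect_equal(compute_rate(balanced), 0.5)
  expect_error(compute_power_params(0, 3.5, 0, 1.06), "at least one")
})

test_that("rate is monotone in the two compute powers", {
  base <- compute_rate(compute_power_params(4, 3.5, 8, 1.06))
  expect_gt(compute_rate(compute_power_params(4, 3.5, 16, 1.06)), base)
  expect_gt(compute_rate(compute_power_params(4, 3.5, 8, 2.0)), base)
  expect_lt(compute_rate(compute_power_params(8, 3.5, 8, 1.06)), base)
  expect_lt(compute_rate(compute_power_params(4, 4.5, 8, 1.06)), base)
})

test_that("database split takes the shortest eligible prefix to the quota", {
  mk <- function(lens) lapply(seq_along(lens), function(i)
    swlanes:::new_encoded_seq(paste0("s", i), "",
                              rep(1L, lens[i])))
  plan <- split_database(mk(c(10, 20, 30, 40)), R = 0.6)
  expect_identical(plan$N_R, 60)
  expect_identical(plan$device_index, 1:3)
  expect_identical(plan$host_index, 4L)

  expect_identical(split_database(mk(c(10, 20)), R = 0)$device_index,
                   integer(0))

  plan_cap <- split_database(mk(c(100, 4000)), R = 1,
                             device_length_cap = 3072)
  expect_identical(plan_cap$device_index, 1L)
  expect_identical(swlanes:::db_lengths(plan_cap$host_set), 4000L)

  # quota rounding: ties go up
  plan_tie <- split_database(mk(c(1, 2)), R = 0.5)
  expect_identical(plan_tie$N_R, 2)

  # quota bracket: device residues within one longest-device-sequence of N_R
  set.seed(14)
  lens <- sort(sample(20:500, 300, TRUE))
  for (r in c(0.25, 0.5, 0.9)) {
    plan_r <- split_database(mk(lens), R = r)
    got <- plan_r$device_residues
    expect_lte(abs(got - plan_r$N_R), max(lens[plan_r$device_index]))
  }
  expect_error(split_database(rev(mk(c(10, 20))), R = 0.5), "sorted")
})

test_that("host threads receive residue-balanced shares", {
  mk <- function(lens) lapply(seq_along(lens), function(i)
    swlanes:::new_encoded_seq(paste0("s", i), "", rep(1L, lens[i])))
  s1 <- partition_host_threads(mk(c(10, 10, 10, 10)), 2)
  expect_identical(sort(attr(s1, "loads")), c(20, 20))
  s2 <- partition_host_threads(mk(c(30, 10, 10)), 2)
  expect_identical(sort(attr(s2, "loads")), c(20, 30))
  s3 <- partition_host_threads(mk(c(5, 6)), 1)
  expect_identical(attr(s3, "loads"), 11)
  set.seed(6)
  lens <- sample(20:400, 120, TRUE)
  sh <- partition_host_threads(mk(lens), 7)
  loads <- attr(sh, "loads")
  expect_lte(max(loads) - min(loads), max(lens))
  expect_identical(sum(vapply(sh, length, integer(1))), 120L)
})

test_that("dynamic-schedule worker sizing follows the block formula", {
  expect_identical(compute_block_count(8, 2048, 64), 512L)
  expect_identical(compute_block_count(8, 2048, 2 * 8 * 2048), 1L)
  expect_identical(compute_block_count(16, 2048, 64),
                   2L * compute_block_count(8, 2048, 64))
  expect_identical(compute_block_count(8, 2048, 100), 327L)  # floor
})

test_that("the 1% deviation rule picks the schedule", {
  expect_identical(select_schedule(rep(3000, 50)), "static")
  expect_identical(select_schedule(c(100, 200)), "dynamic")
  # boundary: sd/mean exactly at the threshold stays static
  lens <- c(99, 101)  # sd = 1, mean = 100
  expect_identical(select_schedule(lens, threshold = 0.01), "static")
})

test_that("score source choice: static always variant, dynamic by threshold", {
  expect_identical(choose_score_source(5000, "static"), "variant")
  expect_identical(choose_score_source(144, "dynamic"), "variant")
  expect_identical(choose_score_source(5478, "dynamic"), "profile")
  # cache-derived threshold: 524288 bytes / (2 * 32^2) = 256
  expect_identical(choose_score_source(255, "dynamic",
                                       cache_budget_bytes = 524288,
                                       sigma = 32,
                                       variant_threshold = "auto"),
                   "variant")
  expect_identical(choose_score_source(256, "dynamic",
                                       cache_budget_bytes = 524288,
                                       sigma = 32,
                                       variant_threshold = "auto"),
                   "profile")
})

test_that("dynamic assignment consumes every unit exactly once", {
  t1 <- dynamic_assign(10, 1)
  expect_identical(t1$unit, 1:10)
  expect_true(all(t1$worker == 1L))
  t3 <- dynamic_assign(10, 3)
  expect_identical(sort(t3$unit), 1:10)
  expect_identical(attr(t3, "counter"), 10L)
  t0 <- dynamic_assign(0, 4)
  expect_identical(nrow(t0), 0L)
})

test_that("local-memory bound on device subject length", {
  expect_identical(max_device_subject_length(), 65536)
  expect_identical(max_device_subject_length(512 * 1024, 2, 4), 65536)
})
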