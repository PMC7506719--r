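test_that("default breath-hold protocol totals 435 s with the expected stages", {
  tl <- make_protocol()
  expect_identical(protocol_duration(tl), 435)
  expect_identical(sum(tl$label == "hold"), 3L)
  expect_identical(sum(tl$label == "exhale"), 3L)
  # every exhale is immediately followed by its hold
  ex <- which(tl$label == "exhale")
  expect_true(all(tl$label[ex + 1] == "hold"))
  ht <- hold_times(tl)
  expect_equal(ht$exhale_start_s, c(120, 205, 290))
  expect_equal(ht$hold_end_s, c(145, 230, 315))
})

test_that("protocol duration follows the stage summation for any hold count", {
  # closed-form oracle: rest_pre + rest_post + n*(exhale+hold) + (n-1)*rest_between
  oracle <- function(n) 240 + 25 * n + 60 * max(n - 1, 0)
  expect_identical(protocol_duration(make_protocol(n_holds = 0)), oracle(0))
  expect_identical(protocol_duration(make_protocol(n_holds = 1)), oracle(1))
  for (n in c(2, 5, 9)) {
    expect_identical(protocol_duration(make_protocol(n_holds = n)), oracle(n))
  }
  expect_identical(oracle(0), 240)
  expect_identical(oracle(1), 265)
})

test_that("stage bookkeeping is internally consistent", {
  tl <- make_protocol(n_holds = 2, rest_pre = 30, exhale = 4, hold = 15,
                      rest_between = 20, rest_post = 10)
  expect_equal(sum(tl$duration_s), protocol_duration(tl))
  expect_equal(tl$end_s - tl$start_s, tl$duration_s)
  expect_equal(tl$start_s[-1], tl$end_s[-nrow(tl)])
  expect_true(all(tl$duration_s > 0))
})

test_that("invalid protocol parameters are rejected", {
  expect_error(make_protocol(rest_pre = -1), class = "earox_config_error")
  expect_error(make_protocol(n_holds = -2), class = "earox_config_error")
  expect_error(make_protocol(n_holds = 1.5), class = "earox_config_error")
})
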