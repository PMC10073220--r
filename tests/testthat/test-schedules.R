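test_that("VR requirement sampler matches the geometric distribution", {
  set.seed(101)
  expect_equal(sampleVRRequirements(1, 10), rep(1L, 10))

  req <- sampleVRRequirements(15, 10000)
  expect_true(all(req >= 1))
  expect_lt(abs(mean(req) - 15) / 15, 0.10)

  # Kolmogorov distance against the closed-form geometric CDF
  req5 <- sampleVRRequirements(5, 1000)
  ks <- max(vapply(1:60, function(k) {
    abs(mean(req5 <= k) - stats::pgeom(k - 1, prob = 1 / 5))
  }, numeric(1)))
  expect_lt(ks, 0.05)

  expect_error(sampleVRRequirements(0.5, 10), "ratio")
  expect_error(sampleVRRequirements(5, 0), "nRewards")
})

test_that("VI interval sampler matches the exponential distribution", {
  set.seed(102)
  iv <- sampleVIIntervals(60, 10000)
  expect_true(all(iv > 0))
  expect_lt(abs(mean(iv) - 60) / 60, 0.10)

  iv10 <- sampleVIIntervals(10, 1000)
  grid <- seq(0.1, 60, by = 0.1)
  ks <- max(vapply(grid, function(x) {
    abs(mean(iv10 <= x) - stats::pexp(x, rate = 1 / 10))
  }, numeric(1)))
  expect_lt(ks, 0.05)

  expect_error(sampleVIIntervals(0, 10), "meanInterval")
})

test_that("fixed-ratio arms deliver exactly every k-th operant response", {
  st <- newScheduleState(scheduleFR(1), nRewards = 20, response = 1L)
  expect_true(all(replicate(10, scheduleStep(st, 1L)$delivered)))

  st <- newScheduleState(scheduleFR(3), nRewards = 20, response = 1L)
  d <- replicate(10, scheduleStep(st, 1L)$delivered)
  expect_equal(sum(d), 3L)            # floor(10 / 3)
  expect_equal(which(d), c(3L, 6L, 9L))

  # non-operant responses never progress a ratio arm
  st <- newScheduleState(scheduleFR(2), nRewards = 20, response = 1L)
  expect_false(any(replicate(10, scheduleStep(st, 2L)$delivered)))
})

test_that("VR deliveries never exceed the minimum-requirement bound", {
  set.seed(103)
  st <- newScheduleState(scheduleVR(4), nRewards = 200, response = 1L)
  minReq <- min(st[[1]]$seq)
  n <- 300
  d <- replicate(n, scheduleStep(st, 1L)$delivered)
  expect_lte(sum(d), floor(n / minReq))
})

test_that("an armed VI reward is held until the operant response collects it", {
  set.seed(104)
  st <- newScheduleState(scheduleVI(2), nRewards = 50, response = 1L)
  # let the interval elapse with non-operant responding until armed
  while (!st[[1]]$armed) invisible(scheduleStep(st, 2L))
  waited <- replicate(100, scheduleStep(st, 2L)$delivered)
  expect_false(any(waited))
  expect_true(st[[1]]$armed)
  expect_true(scheduleStep(st, 1L)$delivered)
  expect_false(st[[1]]$armed)
})

test_that("VI arming is single-capacity: a long wait yields one reward", {
  set.seed(105)
  st <- newScheduleState(scheduleVI(3), nRewards = 200, response = 1L)
  for (i in 1:500) invisible(scheduleStep(st, 2L))  # many intervals elapse
  # only one interval's reward is held; collecting it resets the timer, so
  # the next reward needs a fresh interval to elapse from zero
  expect_true(scheduleStep(st, 1L)$delivered)
  expect_false(st[[1]]$armed)
  expect_equal(st[[1]]$elapsed, 0)
})

test_that("VT delivery times are independent of the response sequence", {
  seqs <- list(rep(1L, 400), rep(2L, 400), rep(1:4, 100))
  deliveries <- lapply(seqs, function(resp) {
    set.seed(42)
    st <- newScheduleState(scheduleVT(25), nRewards = 20, response = 1L)
    which(vapply(resp, function(a) scheduleStep(st, a)$delivered, logical(1)))
  })
  expect_equal(deliveries[[1]], deliveries[[2]])
  expect_equal(deliveries[[1]], deliveries[[3]])
})

test_that("tandem components complete in order and only the last delivers", {
  # ratio 2 then a zero-interval VI: the VI arms instantly when reached but
  # still needs a collecting response, so delivery is on the third response
  st <- newScheduleState(scheduleTandem(scheduleFR(2), scheduleVI(0)),
                         nRewards = 10, response = 1L)
  d <- vapply(1:6, function(i) scheduleStep(st, 1L)$delivered, logical(1))
  expect_equal(which(d), c(3L, 6L))

  # a zero-interval VT tail needs no response and completes within the same
  # step as the first component
  st <- newScheduleState(scheduleTandem(scheduleFR(2), scheduleVT(0)),
                         nRewards = 10, response = 1L)
  d <- vapply(1:6, function(i) scheduleStep(st, 1L)$delivered, logical(1))
  expect_equal(which(d), c(2L, 4L, 6L))
})

test_that("a tandem with a zero-length time-based tail equals its first component", {
  for (spec1 in list(scheduleVR(4), scheduleVI(7))) {
    set.seed(77)
    stSimple <- newScheduleState(spec1, nRewards = 30, response = 1L)
    set.seed(77)
    stTandem <- newScheduleState(scheduleTandem(spec1, scheduleVT(0)),
                                 nRewards = 30, response = 1L)
    resp <- rep(c(1L, 1L, 2L), 200)
    a <- vapply(resp, function(x) scheduleStep(stSimple, x)$delivered, logical(1))
    b <- vapply(resp, function(x) scheduleStep(stTandem, x)$delivered, logical(1))
    expect_equal(which(a), which(b))
  }
})

test_that("concurrent arms run independently and deliver for their own response", {
  set.seed(106)
  spec <- scheduleConcurrent(list(scheduleFR(2), scheduleFR(3)),
                             responses = c(1L, 2L))
  st <- newScheduleState(spec, nRewards = 20)
  resp <- c(1L, 1L, 2L, 2L, 2L, 1L, 1L)
  hits <- t(vapply(resp, function(a) scheduleStep(st, a)$delivered, logical(2)))
  expect_equal(which(hits[, 1]), c(2L, 7L))  # arm 1 on its 2nd and 4th response
  expect_equal(which(hits[, 2]), 5L)         # arm 2 on its 3rd response
})

test_that("exhausting the pre-generated sequence signals session end", {
  set.seed(107)
  st <- newScheduleState(scheduleVR(1), nRewards = 1, response = 1L)
  nSeq <- length(st[[1]]$seq)
  expect_error(
    for (i in seq_len(nSeq + 1)) scheduleStep(st, 1L),
    class = "habitnet_sequence_exhausted")
})

test_that("schedule spec validity catches malformed arrangements", {
  expect_error(scheduleVR(0.5), "ratio")
  expect_error(scheduleVI(-1), "interval")
  expect_error(scheduleTandem(scheduleVI(5)), "components")
  expect_error(
    scheduleConcurrent(list(scheduleVI(5), scheduleVI(5)), responses = c(1, 1)),
    "distinct")
})

test_that("yoked VI value is the mean observed inter-reward interval", {
  expect_equal(yokeVIToVR(c(10, 20, 40)), 15)
  expect_equal(yokeVIToVR(c(5, 5 + 7)), 7)
  expect_error(yokeVIToVR(c(5)), "at least 2")

  # against the direct count: total span / number of intervals
  set.seed(108)
  tr <- trainAgent(scheduleVR(15), nRewards = 500)
  steps <- trainingLog(tr)$step[trainingLog(tr)$delivered]
  expect_equal(yokeVIToVR(tr), (max(steps) - min(steps)) / (length(steps) - 1))
  # and within 15% of ratio x mean steps per operant response
  opResp <- sum(trainingLog(tr)$response == 1L)
  expect_lt(abs(yokeVIToVR(tr) - 15 * tr@nSteps / opResp) /
              (15 * tr@nSteps / opResp), 0.15)
})
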