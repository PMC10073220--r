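test_that("softmax choice probabilities follow the Boltzmann form", {
  Q <- matrix(0, 5, 5)
  expect_equal(responseProbabilities(Q, 1, 3), rep(1 / 5, 5))

  Q <- matrix(0, 3, 3)
  Q[1, ] <- c(1, 0, 0)
  p <- responseProbabilities(Q, 1, 3)
  expect_equal(p, exp(3 * c(1, 0, 0)) / sum(exp(3 * c(1, 0, 0))))
  expect_equal(round(p, 4), c(0.9094, 0.0453, 0.0453))

  # invariance to adding a constant to the row (max-shift normalization)
  Q2 <- Q; Q2[1, ] <- Q2[1, ] + 1000
  expect_equal(responseProbabilities(Q2, 1, 3), p)

  # a dominant entry takes essentially all the mass
  Q[1, 2] <- 500
  expect_gt(responseProbabilities(Q, 1, 3)[2], 1 - 1e-12)
})

test_that("TD errors match hand evaluation for both rules", {
  Q <- matrix(0, 4, 4)
  expect_equal(tdError(Q, 1, 2, reward = 1, gamma = 0.5), 1)

  # fixed point: Q = r / (1 - gamma) gives zero error
  Q[] <- 2
  expect_equal(tdError(Q, 1, 2, reward = 1, gamma = 0.5), 0)

  Q <- matrix(0, 4, 4)
  Q[2, 3] <- 0.4
  Q[1, 2] <- 0.1
  expect_equal(tdError(Q, 1, 2, reward = 0, gamma = 0.5, rule = "sarsa",
                       aNext = 3), 0.1)
  expect_error(tdError(Q, 1, 2, reward = 0, gamma = 0.5, rule = "sarsa"),
               "aNext")
})

test_that("applyUpdate changes only the visited transition", {
  Q <- matrix(0, 3, 3)
  expect_equal(applyUpdate(Q, 1, 2, delta = 0, alpha = 0.1), Q)

  Q1 <- applyUpdate(Q, 1, 2, delta = 1, alpha = 0.1)
  expect_equal(Q1[1, 2], 0.1)
  expect_equal(sum(Q1 != 0), 1L)

  # two-step iteration with gamma = 0 and reward 1 from zero initialization
  d1 <- tdError(Q, 1, 2, reward = 1, gamma = 0)
  Qa <- applyUpdate(Q, 1, 2, d1, 0.1)
  expect_equal(Qa[1, 2], 0.1)
  d2 <- tdError(Qa, 1, 2, reward = 1, gamma = 0)
  Qb <- applyUpdate(Qa, 1, 2, d2, 0.1)
  expect_equal(Qb[1, 2], 0.19)
})

test_that("training with no rewards leaves the Q-matrix at zero", {
  tr <- trainAgent(scheduleVR(5), nRewards = 0, nResponses = 10)
  expect_equal(qMatrix(tr), matrix(0, 10, 10))
  expect_equal(tr@nSteps, 0L)
})

test_that("training stops at the reward criterion and logs faithfully", {
  set.seed(201)
  tr <- trainAgent(scheduleVR(3), nRewards = 40, nResponses = 10)
  log <- trainingLog(tr)
  expect_equal(sum(log$delivered), 40L)
  expect_equal(nrow(log), tr@nSteps)
  expect_true(log$delivered[nrow(log)])  # session ends on the criterion reward
  # rewarded steps carry the operant magnitude, non-operant steps the 0.001
  expect_true(all(log$reward[log$delivered] == 1))
  expect_true(all(log$reward[log$response != 1 & !log$delivered] == 0.001))
  expect_true(all(log$reward[log$response == 1 & !log$delivered] == 0))
})

test_that("Q entries stay within the contraction bound during training", {
  set.seed(202)
  for (spec in list(scheduleVR(3), scheduleVI(5))) {
    tr <- trainAgent(spec, nRewards = 150, nResponses = 12)
    expect_true(all(qMatrix(tr) >= 0))
    expect_true(all(qMatrix(tr) <= 1 / (1 - 0.5)))  # R_max / (1 - gamma)
  }
})

test_that("a fixed seed reproduces training bit for bit on both engines", {
  for (eng in c("cpp", "R")) {
    set.seed(203)
    a <- trainAgent(scheduleVR(4), nRewards = 30, nResponses = 8, engine = eng)
    set.seed(203)
    b <- trainAgent(scheduleVR(4), nRewards = 30, nResponses = 8, engine = eng)
    expect_identical(qMatrix(a), qMatrix(b))
    expect_identical(trainingLog(a), trainingLog(b))
  }
})

test_that("replaying the training log through the update rule recovers Q", {
  set.seed(204)
  tr <- trainAgent(scheduleVR(3), nRewards = 25, nResponses = 6, engine = "R")
  log <- trainingLog(tr)
  Q <- matrix(0, 6, 6)
  for (i in seq_len(nrow(log))) {
    d <- tdError(Q, log$prev[i], log$response[i], log$reward[i], gamma = 0.5)
    expect_equal(d, log$delta[i])
    Q <- applyUpdate(Q, log$prev[i], log$response[i], d, alpha = 0.1)
  }
  expect_equal(Q, qMatrix(tr))
})

test_that("the compiled and reference engines agree in distribution", {
  # same schedule semantics: both must deliver the requested reward count and
  # produce step counts of the same order under matched conditions
  set.seed(205)
  stepsC <- replicate(8, trainAgent(scheduleVR(2), nRewards = 50,
                                    nResponses = 6, engine = "cpp")@nSteps)
  set.seed(205)
  stepsR <- replicate(8, trainAgent(scheduleVR(2), nRewards = 50,
                                    nResponses = 6, engine = "R")@nSteps)
  expect_lt(abs(mean(stepsC) - mean(stepsR)) / mean(stepsR), 0.25)
})

test_that("SARSA training applies the on-policy update", {
  set.seed(206)
  tr <- trainAgent(scheduleVR(3), nRewards = 25, nResponses = 6,
                   params = learningParams(rule = "sarsa"), engine = "R")
  log <- trainingLog(tr)
  expect_true(is.na(log$delta[nrow(log)]))  # last transition never updated
  Q <- matrix(0, 6, 6)
  for (i in seq_len(nrow(log) - 1L)) {
    d <- tdError(Q, log$prev[i], log$response[i], log$reward[i], gamma = 0.5,
                 rule = "sarsa", aNext = log$response[i + 1L])
    expect_equal(d, log$delta[i])
    Q <- applyUpdate(Q, log$prev[i], log$response[i], d, alpha = 0.1)
  }
  expect_equal(Q, qMatrix(tr))
})

test_that("VR training elevates the operant self-transition value", {
  # the self-transition of the operant response collects the same reward
  # probability as any in-transition under VR but is revisited with the
  # operant column's bootstrap, ending above the median in-transition value
  set.seed(207)
  wins <- replicate(12, {
    tr <- trainAgent(scheduleVR(15), nRewards = 300)
    Q <- qMatrix(tr)
    Q[1, 1] > median(Q[-1, 1])
  })
  expect_gt(mean(wins), 0.5)
})
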