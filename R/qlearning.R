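#' Temporal-difference learning parameters
#'
#' Parameters of the tabular TD agent that learns transition values between
#' responses during training. The previous response plays the role of the
#' state, so values live in an N x N Q-matrix indexed (previous response,
#' next response). Defaults are the values used throughout the simulations:
#' learning rate `alpha = 0.1`, discount `gamma = 0.5`, and choice inverse
#' temperature `betaC = 3.0`.
#'
#' @slot alpha learning rate in [0, 1].
#' @slot gamma discount factor in [0, 1).
#' @slot betaC inverse temperature of the softmax response choice, > 0.
#' @slot rule `"qlearning"` (off-policy max backup) or `"sarsa"` (on-policy).
#' @export
setClass("LearningParams",
  representation(alpha = "numeric", gamma = "numeric", betaC = "numeric",
                 rule = "character"),
  prototype(alpha = 0.1, gamma = 0.5, betaC = 3.0, rule = "qlearning"))

setValidity("LearningParams", function(object) {
  if (object@alpha < 0 || object@alpha > 1) return("alpha must be in [0, 1]")
  if (object@gamma < 0 || object@gamma >= 1) return("gamma must be in [0, 1)")
  if (object@betaC <= 0) return("betaC must be > 0")
  if (!object@rule %in% c("qlearning", "sarsa"))
    return("rule must be 'qlearning' or 'sarsa'")
  TRUE
})

#' @rdname LearningParams-class
#' @param alpha,gamma,betaC,rule see slots.
#' @return a `LearningParams` object.
#' @export
learningParams <- function(alpha = 0.1, gamma = 0.5, betaC = 3.0,
                           rule = c("qlearning", "sarsa")) {
  new("LearningParams", alpha = alpha, gamma = gamma, betaC = betaC,
      rule = match.arg(rule))
}

setMethod("show", "LearningParams", function(object) {
  cat(sprintf("LearningParams: alpha=%g gamma=%g betaC=%g rule=%s\n",
              object@alpha, object@gamma, object@betaC, object@rule))
  invisible(object)
})

#' Result of one training session
#'
#' @slot Q the learned N x N Q-matrix (row = previous response, column = next
#'   response).
#' @slot log per-step `data.frame` with columns `step`, `prev`, `response`,
#'   `reward`, `delta`, `delivered` (TRUE when a response-contingent arm
#'   delivered this step).
#' @slot nSteps total number of time steps taken.
#' @slot params the [LearningParams-class] used.
#' @export
setClass("TrainingResult",
  representation(Q = "matrix", log = "data.frame", nSteps = "integer",
                 params = "LearningParams"))

#' @rdname TrainingResult-class
#' @param x a `TrainingResult`.
#' @return `qMatrix()` the Q-matrix; `trainingLog()` the per-step log.
#' @export
qMatrix <- function(x) {
  stopifnot(is(x, "TrainingResult"))
  x@Q
}

#' @rdname TrainingResult-class
#' @export
trainingLog <- function(x) {
  stopifnot(is(x, "TrainingResult"))
  x@log
}

setMethod("show", "TrainingResult", function(object) {
  cat(sprintf("TrainingResult: %d responses, %d steps, %d rewards delivered\n",
              nrow(object@Q), object@nSteps, sum(object@log$delivered)))
  invisible(object)
})

# Flatten a compiled arm environment (see R/schedules.R) into the plain-list
# form consumed by the compiled training loop.
.armToList <- function(arm) {
  compToList <- function(e) {
    list(kind = e$kind, value = e$value,
         seq = if (is.null(e$seq)) NULL else e$seq,
         idx = e$idx, progress = e$progress, elapsed = e$elapsed,
         armed = e$armed)
  }
  if (arm$kind == "tandem") {
    list(tandem = TRUE, id = arm$id, magnitude = arm$magnitude,
         compIdx = arm$compIdx, comps = lapply(arm$comps, compToList))
  } else {
    list(tandem = FALSE, id = arm$id, magnitude = arm$magnitude,
         compIdx = 1L, comps = list(compToList(arm)))
  }
}

# Numerically stable softmax over a vector of values.
.softmax <- function(x, beta) {
  z <- exp(beta * (x - max(x)))
  z / sum(z)
}

#' Softmax response-choice probabilities during training
#'
#' Probability of choosing each next response given the previous response:
#' `p_i = exp(betaC * Q[prev, i]) / sum_j exp(betaC * Q[prev, j])`, computed
#' with max-subtraction so the result is invariant to adding a constant to
#' the row and never overflows.
#'
#' @param Q the Q-matrix.
#' @param prev previous response id (row index).
#' @param betaC inverse temperature (default 3).
#' @return probability vector over all responses.
#' @export
responseProbabilities <- function(Q, prev, betaC = 3.0) {
  stopifnot(all(is.finite(Q)))
  .softmax(Q[prev, ], betaC)
}

#' @rdname responseProbabilities
#' @return `chooseTrainingResponse()` a sampled response id.
#' @export
chooseTrainingResponse <- function(Q, prev, betaC = 3.0) {
  sample.int(ncol(Q), 1L, prob = responseProbabilities(Q, prev, betaC))
}

#' Temporal-difference error for a response transition
#'
#' Reward prediction error for the transition `aPrev -> aCur`:
#' Q-learning uses `delta = reward + gamma * max_j Q[aCur, j] - Q[aPrev, aCur]`;
#' SARSA replaces the max by the value of the actually chosen next response,
#' `Q[aCur, aNext]`.
#'
#' @param Q the Q-matrix.
#' @param aPrev,aCur previous and current response ids.
#' @param reward reward magnitude obtained on this transition.
#' @param gamma discount factor.
#' @param rule `"qlearning"` or `"sarsa"`.
#' @param aNext next response id; required for SARSA.
#' @return the scalar TD error.
#' @examples
#' Q <- matrix(0, 3, 3)
#' tdError(Q, 1, 2, reward = 1, gamma = 0.5)  # 1: zero bootstrap
#' @export
tdError <- function(Q, aPrev, aCur, reward, gamma,
                    rule = c("qlearning", "sarsa"), aNext = NULL) {
  rule <- match.arg(rule)
  boot <- if (rule == "qlearning") {
    max(Q[aCur, ])
  } else {
    if (is.null(aNext)) stop("SARSA requires `aNext`")
    Q[aCur, aNext]
  }
  reward + gamma * boot - Q[aPrev, aCur]
}

#' Apply one TD update to the Q-matrix
#'
#' Changes only entry `(aPrev, aCur)`, by `alpha * delta`.
#'
#' @inheritParams tdError
#' @param delta the TD error.
#' @param alpha learning rate in [0, 1].
#' @return the updated Q-matrix.
#' @export
applyUpdate <- function(Q, aPrev, aCur, delta, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  Q[aPrev, aCur] <- Q[aPrev, aCur] + alpha * delta
  Q
}

#' Train an agent on a free-operant schedule
#'
#' Runs the training phase: on each time step the agent chooses a response by
#' softmax over the row of the Q-matrix indexed by its previous response, the
#' schedule is advanced one step, and the transition value is updated by the
#' TD rule. Operant responses are rewarded by `schedule` (magnitude taken from
#' the spec, 1.0 by default); every other response is rewarded FR 1 with
#' magnitude `otherMagnitude` (0.001 by default), or by its own copy of
#' `otherSchedule` if one is supplied. A reward delivered by a
#' response-independent VT arm is credited to the transition just completed.
#' Training stops when the response-contingent (operant) arms have delivered
#' `nRewards` rewards in total; the amount of training is therefore the number
#' of rewards, not steps. Q is initialized at zero.
#'
#' Under SARSA the update for a transition requires the subsequently chosen
#' response, so each update is applied one step late and the last transition
#' of the session is left un-updated (its logged `delta` is `NA`).
#'
#' @param schedule a [ScheduleSpec-class]: a simple/tandem schedule for the
#'   operant response, or a concurrent arrangement whose arms carry response
#'   ids.
#' @param nRewards stop after this many operant-arm rewards (>= 0).
#' @param params a [LearningParams-class].
#' @param nResponses number of responses N (default 50).
#' @param operant response id of the operant response for simple/tandem
#'   schedules (default 1).
#' @param otherMagnitude FR 1 reward magnitude for non-operant responses.
#' @param otherSchedule optional [ScheduleSpec-class] applied independently to
#'   every non-operant response in place of FR 1.
#' @param maxSteps safety bound on session length.
#' @param engine `"cpp"` (default, compiled inner loop) or `"R"` (reference
#'   implementation). Both implement identical update and schedule
#'   semantics; the alternative non-FR-1 `otherSchedule` variant runs on
#'   the R engine.
#' @return a [TrainingResult-class].
#' @examples
#' set.seed(1)
#' tr <- trainAgent(scheduleVR(5), nRewards = 20, nResponses = 10)
#' qMatrix(tr)[1, 1]
#' @export
trainAgent <- function(schedule, nRewards, params = learningParams(),
                       nResponses = 50L, operant = 1L,
                       otherMagnitude = 0.001, otherSchedule = NULL,
                       maxSteps = 2e6, engine = c("cpp", "R")) {
  stopifnot(is(schedule, "ScheduleSpec"), is(params, "LearningParams"))
  engine <- match.arg(engine)
  nResponses <- as.integer(nResponses)
  nRewards <- as.integer(nRewards)
  stopifnot(nResponses >= 2L, nRewards >= 0L)
  Q <- matrix(0, nResponses, nResponses)
  empty <- data.frame(step = integer(), prev = integer(), response = integer(),
                      reward = numeric(), delta = numeric(),
                      delivered = logical())
  if (nRewards == 0L)
    return(new("TrainingResult", Q = Q, log = empty, nSteps = 0L,
               params = params))

  state <- newScheduleState(schedule, nRewards, response = operant)

  if (engine == "cpp" && is.null(otherSchedule)) {
    first <- sample.int(nResponses, 1L)
    out <- .trainLoopCpp(Q, lapply(state, .armToList), nRewards,
                         params@alpha, params@gamma, params@betaC,
                         params@rule == "sarsa", otherMagnitude,
                         maxSteps, first)
    log <- data.frame(step = out$step, prev = out$prev,
                      response = out$response, reward = out$reward,
                      delta = out$delta, delivered = as.logical(out$delivered))
    return(new("TrainingResult", Q = out$Q, log = log,
               nSteps = as.integer(out$nSteps), params = params))
  }
  operantIds <- vapply(state, function(a) a$id, integer(1))
  isOperant <- rep(FALSE, nResponses)
  isOperant[operantIds[!is.na(operantIds)]] <- TRUE
  otherStates <- NULL
  if (!is.null(otherSchedule)) {
    otherStates <- vector("list", nResponses)
    for (j in seq_len(nResponses))
      if (!isOperant[j])
        otherStates[[j]] <- newScheduleState(otherSchedule, nRewards,
                                             response = j)
  }

  alpha <- params@alpha; gamma <- params@gamma; betaC <- params@betaC
  sarsa <- params@rule == "sarsa"

  cap <- 4096L
  logStep <- integer(cap); logPrev <- integer(cap); logResp <- integer(cap)
  logRew <- numeric(cap); logDelta <- rep(NA_real_, cap); logDel <- logical(cap)

  prev <- sample.int(nResponses, 1L)
  delivered <- 0L
  t <- 0L
  pPrev <- NA_integer_; pCur <- NA_integer_; pRew <- NA_real_  # SARSA lag

  while (delivered < nRewards) {
    t <- t + 1L
    if (t > maxSteps)
      stop("training did not reach the reward criterion within `maxSteps`")
    if (t > cap) {
      cap <- cap * 2L
      length(logStep) <- cap; length(logPrev) <- cap; length(logResp) <- cap
      length(logRew) <- cap; length(logDelta) <- cap; length(logDel) <- cap
    }
    qrow <- Q[prev, ]
    a <- sample.int(nResponses, 1L, prob = exp(betaC * (qrow - max(qrow))))

    if (sarsa && !is.na(pPrev)) {
      d <- pRew + gamma * Q[pCur, a] - Q[pPrev, pCur]
      Q[pPrev, pCur] <- Q[pPrev, pCur] + alpha * d
      logDelta[t - 1L] <- d
    }

    out <- scheduleStep(state, a)
    reward <- sum(out$magnitude)
    opDelivered <- any(out$delivered & out$operant)
    if (opDelivered) delivered <- delivered + sum(out$delivered & out$operant)
    if (!isOperant[a]) {
      if (is.null(otherStates)) {
        reward <- reward + otherMagnitude
      } else {
        oo <- scheduleStep(otherStates[[a]], a)
        reward <- reward + sum(oo$magnitude) * otherMagnitude
      }
    }

    if (sarsa) {
      pPrev <- prev; pCur <- a; pRew <- reward
      d <- NA_real_
    } else {
      d <- reward + gamma * max(Q[a, ]) - Q[prev, a]
      Q[prev, a] <- Q[prev, a] + alpha * d
    }

    logStep[t] <- t; logPrev[t] <- prev; logResp[t] <- a
    logRew[t] <- reward; logDelta[t] <- d; logDel[t] <- opDelivered
    prev <- a
  }

  keep <- seq_len(t)
  log <- data.frame(step = logStep[keep], prev = logPrev[keep],
                    response = logResp[keep], reward = logRew[keep],
                    delta = logDelta[keep], delivered = logDel[keep])
  new("TrainingResult", Q = Q, log = log, nSteps = t, params = params)
}
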