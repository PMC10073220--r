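#' @include habitnet-package.R
NULL

.SCHEDULE_KINDS <- c("FR", "VR", "VI", "VT", "tandem", "concurrent")

#' Reinforcement schedule specification
#'
#' An S4 class describing one reinforcement schedule used to arrange reward
#' delivery during training. Simple kinds are ratio schedules (\code{FR},
#' \code{VR}: reward after a fixed / geometrically distributed number of
#' operant responses) and time-based schedules (\code{VI}: reward armed after
#' an exponentially distributed interval and held until the next operant
#' response; \code{VT}: reward delivered on elapse regardless of responding).
#' Compound kinds are \code{tandem} (components completed in unsignalled
#' succession, reward only on the final component) and \code{concurrent}
#' (independently armed schedules tied to distinct responses).
#'
#' The simulation clock is discrete: one agent response is one time step, and
#' VI/VT timers advance by one per step.
#'
#' @slot kind one of \code{"FR"}, \code{"VR"}, \code{"VI"}, \code{"VT"},
#'   \code{"tandem"}, \code{"concurrent"}.
#' @slot value ratio (FR/VR, >= 1) or mean interval in time steps (VI/VT,
#'   >= 0); unused for compound kinds.
#' @slot components ordered list of \code{ScheduleSpec} (tandem only).
#' @slot arms list of \code{list(response =, spec =)} entries (concurrent
#'   only); \code{response} is the response id collecting from that arm, or
#'   \code{NA} for a response-independent VT arm.
#' @slot magnitude reward magnitude delivered on completion (default 1).
#'
#' @seealso [scheduleVR()], [scheduleVI()], [scheduleVT()], [scheduleFR()],
#'   [scheduleTandem()], [scheduleConcurrent()], [newScheduleState()],
#'   [scheduleStep()]
#' @export
setClass("ScheduleSpec",
  representation(kind = "character", value = "numeric", components = "list",
                 arms = "list", magnitude = "numeric"),
  prototype(kind = "FR", value = 1, components = list(), arms = list(),
            magnitude = 1))

setValidity("ScheduleSpec", function(object) {
  k <- object@kind
  if (length(k) != 1L || !k %in% .SCHEDULE_KINDS)
    return(sprintf("kind must be one of %s", paste(.SCHEDULE_KINDS, collapse = ", ")))
  if (length(object@magnitude) != 1L || object@magnitude < 0)
    return("magnitude must be a single value >= 0")
  if (k %in% c("FR", "VR")) {
    if (length(object@value) != 1L || is.na(object@value) || object@value < 1)
      return("ratio value must be >= 1 for FR/VR")
  }
  if (k %in% c("VI", "VT")) {
    if (length(object@value) != 1L || is.na(object@value) || object@value < 0)
      return("interval value must be >= 0 for VI/VT")
  }
  if (k == "tandem") {
    if (length(object@components) < 2L)
      return("tandem requires at least 2 components")
    ok <- vapply(object@components, is, logical(1), class2 = "ScheduleSpec")
    if (!all(ok)) return("tandem components must be ScheduleSpec objects")
    if (any(vapply(object@components, slot, character(1), "kind") %in%
            c("tandem", "concurrent")))
      return("tandem components must be simple schedules")
  }
  if (k == "concurrent") {
    if (length(object@arms) < 1L) return("concurrent requires at least one arm")
    for (a in object@arms) {
      if (!is.list(a) || !all(c("response", "spec") %in% names(a)))
        return("each concurrent arm must be list(response =, spec =)")
      if (!is(a$spec, "ScheduleSpec") ||
          a$spec@kind %in% c("concurrent"))
        return("concurrent arm spec must be a non-concurrent ScheduleSpec")
    }
    ids <- vapply(object@arms, function(a) as.integer(a$response), integer(1))
    ids <- ids[!is.na(ids)]
    if (anyDuplicated(ids)) return("concurrent arms must map distinct response ids")
  }
  TRUE
})

#' Schedule constructors
#'
#' Build [ScheduleSpec-class] objects for the schedule kinds used in
#' free-operant training. `value` is a response ratio for `scheduleFR()` /
#' `scheduleVR()` and a mean interval in time steps for `scheduleVI()` /
#' `scheduleVT()`. `scheduleTandem(a, b, ...)` chains simple components in
#' unsignalled succession (e.g. `scheduleTandem(scheduleVI(15), scheduleVR(3))`);
#' only completion of the final component delivers reward.
#' `scheduleConcurrent()` arranges independent arms tied to distinct response
#' ids (use `response = NA` for a response-independent VT arm).
#'
#' @param value ratio (>= 1) or mean interval in steps (>= 0).
#' @param magnitude reward magnitude on delivery (default 1).
#' @param ... simple `ScheduleSpec` components, in order.
#' @param specs list of `ScheduleSpec`, one per concurrent arm.
#' @param responses integer vector of response ids (NA for a VT arm), parallel
#'   to `specs`.
#' @return a [ScheduleSpec-class].
#' @examples
#' scheduleVR(15)
#' scheduleTandem(scheduleVR(10), scheduleVI(5))
#' scheduleConcurrent(list(scheduleVI(60), scheduleVI(60)), responses = c(1, 2))
#' @name schedule-constructors
NULL

#' @rdname schedule-constructors
#' @export
scheduleFR <- function(value, magnitude = 1)
  new("ScheduleSpec", kind = "FR", value = as.numeric(value), magnitude = magnitude)

#' @rdname schedule-constructors
#' @export
scheduleVR <- function(value, magnitude = 1)
  new("ScheduleSpec", kind = "VR", value = as.numeric(value), magnitude = magnitude)

#' @rdname schedule-constructors
#' @export
scheduleVI <- function(value, magnitude = 1)
  new("ScheduleSpec", kind = "VI", value = as.numeric(value), magnitude = magnitude)

#' @rdname schedule-constructors
#' @export
scheduleVT <- function(value, magnitude = 1)
  new("ScheduleSpec", kind = "VT", value = as.numeric(value), magnitude = magnitude)

#' @rdname schedule-constructors
#' @export
scheduleTandem <- function(..., magnitude = 1)
  new("ScheduleSpec", kind = "tandem", components = list(...),
      magnitude = magnitude)

#' @rdname schedule-constructors
#' @export
scheduleConcurrent <- function(specs, responses) {
  stopifnot(length(specs) == length(responses))
  arms <- mapply(function(s, r) list(response = as.integer(r), spec = s),
                 specs, responses, SIMPLIFY = FALSE)
  new("ScheduleSpec", kind = "concurrent", arms = arms)
}

setMethod("show", "ScheduleSpec", function(object) {
  fmt <- function(s) {
    switch(s@kind,
      tandem = paste("tandem", paste(vapply(s@components, fmt, character(1)),
                                     collapse = " ")),
      concurrent = paste("conc", paste(vapply(s@arms, function(a) {
        sprintf("%s[resp %s]", fmt(a$spec),
                ifelse(is.na(a$response), "-", a$response))
      }, character(1)), collapse = " ")),
      sprintf("%s %g", s@kind, s@value))
  }
  cat("ScheduleSpec:", fmt(object), "\n")
  if (object@kind %in% c("FR", "VR", "VI", "VT"))
    cat("  magnitude:", object@magnitude, "\n")
  invisible(object)
})

# ---- stratified inverse-CDF samplers -------------------------------------

#' Quantile-stratified sampler for variable-ratio response requirements
#'
#' Draws `nRewards` response requirements for a VR schedule with mean `ratio`.
#' Requirements follow the geometric distribution on \{1, 2, ...\} with
#' success probability `1/ratio` (each operant response is rewarded with that
#' probability, a Bernoulli process). Rather than i.i.d. draws, the unit
#' interval is divided into `nRewards` equal strata and the geometric quantile
#' function is evaluated at the stratum midpoints ((k - 0.5)/n), so the
#' empirical distribution converges to the target even for short sessions;
#' the resulting requirements are then uniformly permuted.
#'
#' @param ratio mean responses per reward, >= 1. `ratio = 1` degenerates to
#'   every response rewarded.
#' @param nRewards number of requirements to generate, >= 1.
#' @return integer vector of length `nRewards`, all >= 1, in random order.
#' @seealso [sampleVIIntervals()]
#' @examples
#' mean(sampleVRRequirements(15, 1000))
#' @export
sampleVRRequirements <- function(ratio, nRewards) {
  if (length(ratio) != 1L || is.na(ratio) || ratio < 1)
    stop("`ratio` must be a single value >= 1")
  if (length(nRewards) != 1L || is.na(nRewards) || nRewards < 1)
    stop("`nRewards` must be a single value >= 1")
  nRewards <- as.integer(nRewards)
  grid <- (seq_len(nRewards) - 0.5) / nRewards
  # qgeom counts failures before the first success; shift support to {1,2,...}
  req <- stats::qgeom(grid, prob = 1 / ratio) + 1L
  sample(req)
}

#' Quantile-stratified sampler for variable-interval durations
#'
#' Draws `nRewards` inter-reward intervals for a VI (or VT) schedule with mean
#' `meanInterval` time steps. Arming follows a Poisson process, so intervals
#' are exponential; the exponential quantile function is evaluated on the
#' interior stratum midpoints ((k - 0.5)/n) of (0, 1) — endpoints are excluded
#' to avoid infinite quantiles — and the result is uniformly permuted.
#'
#' @param meanInterval mean interval in time steps, > 0.
#' @param nRewards number of intervals to generate, >= 1.
#' @return numeric vector of length `nRewards`, all > 0, in random order.
#' @seealso [sampleVRRequirements()]
#' @examples
#' mean(sampleVIIntervals(60, 1000))
#' @export
sampleVIIntervals <- function(meanInterval, nRewards) {
  if (length(meanInterval) != 1L || is.na(meanInterval) || meanInterval <= 0)
    stop("`meanInterval` must be a single value > 0")
  if (length(nRewards) != 1L || is.na(nRewards) || nRewards < 1)
    stop("`nRewards` must be a single value >= 1")
  nRewards <- as.integer(nRewards)
  grid <- (seq_len(nRewards) - 0.5) / nRewards
  sample(stats::qexp(grid, rate = 1 / meanInterval))
}

# ---- mutable run state ----------------------------------------------------

# Compile one simple spec into a mutable arm environment. `response` is the
# response id whose emissions count for ratio progress / reward collection.
.compileSimple <- function(spec, response, nRewards) {
  e <- new.env(parent = emptyenv())
  e$kind <- spec@kind
  e$id <- as.integer(response)
  e$value <- spec@value
  e$magnitude <- spec@magnitude
  e$idx <- 1L
  e$progress <- 0
  e$elapsed <- 0
  e$armed <- FALSE
  n <- max(2L * as.integer(nRewards) + 50L, 16L)
  if (spec@kind == "VR") e$seq <- sampleVRRequirements(spec@value, n)
  if (spec@kind %in% c("VI", "VT")) {
    e$seq <- if (spec@value == 0) rep(0, n) else sampleVIIntervals(spec@value, n)
  }
  e
}

.compileArm <- function(spec, response, nRewards) {
  if (spec@kind == "tandem") {
    e <- new.env(parent = emptyenv())
    e$kind <- "tandem"
    e$id <- as.integer(response)
    e$magnitude <- spec@magnitude
    e$compIdx <- 1L
    e$comps <- lapply(spec@components, .compileSimple, response = response,
                      nRewards = nRewards)
    # a VI/VT component that starts the cycle may arm/complete at activation
    .advanceActivation(e)
    e
  } else {
    .compileSimple(spec, response, nRewards)
  }
}

#' Initialize the mutable run state of a schedule
#'
#' Pre-generates requirement/interval sequences (with head-room beyond
#' `nRewards`) and returns a mutable state object to be advanced with
#' [scheduleStep()]. For a simple or tandem spec, `response` names the operant
#' response whose emissions drive the schedule; for a concurrent spec the arm
#' response ids in the spec are used.
#'
#' @param spec a [ScheduleSpec-class].
#' @param nRewards number of rewards the session is expected to deliver;
#'   sequences are pre-generated with head-room beyond this.
#' @param response operant response id for simple/tandem specs (default 1).
#' @return an opaque schedule-state object (a list of mutable arm
#'   environments with attributes `kind` and `magnitude`).
#' @export
newScheduleState <- function(spec, nRewards, response = 1L) {
  stopifnot(is(spec, "ScheduleSpec"))
  arms <- if (spec@kind == "concurrent") {
    lapply(spec@arms, function(a) .compileArm(a$spec, a$response, nRewards))
  } else {
    list(.compileArm(spec, response, nRewards))
  }
  structure(arms, class = "habitnet_schedule_state")
}

.exhausted <- function() {
  stop(structure(class = c("habitnet_sequence_exhausted", "error", "condition"),
                 list(message = "pre-generated schedule sequence exhausted: session end",
                      call = sys.call(-1))))
}

.currentSeq <- function(arm) {
  if (arm$idx > length(arm$seq)) .exhausted()
  arm$seq[[arm$idx]]
}

# Completion check applied when a tandem component becomes active, before any
# time step or response is consumed: zero-requirement time-based components
# can arm (VI) or complete outright (VT); ratio components always need
# responses.
.activateComp <- function(comp) {
  if (comp$kind == "VI" && comp$elapsed >= .currentSeq(comp)) {
    comp$armed <- TRUE
    return(FALSE)  # armed, but still needs the collecting response
  }
  if (comp$kind == "VT" && comp$elapsed >= .currentSeq(comp)) {
    comp$idx <- comp$idx + 1L
    comp$elapsed <- 0
    return(TRUE)
  }
  FALSE
}

# Advance one simple arm/component by one time step in which `response` was
# emitted. Returns TRUE if the arm completed (delivered) this step.
.stepSimple <- function(arm, response) {
  switch(arm$kind,
    FR = {
      if (!is.na(arm$id) && response == arm$id) {
        arm$progress <- arm$progress + 1
        if (arm$progress >= arm$value) {
          arm$progress <- 0
          return(TRUE)
        }
      }
      FALSE
    },
    VR = {
      if (!is.na(arm$id) && response == arm$id) {
        arm$progress <- arm$progress + 1
        if (arm$progress >= .currentSeq(arm)) {
          arm$progress <- 0
          arm$idx <- arm$idx + 1L
          return(TRUE)
        }
      }
      FALSE
    },
    VI = {
      # the timer advances every step regardless of the response; arming is
      # single-capacity and held until collected by the operant response
      arm$elapsed <- arm$elapsed + 1
      if (!arm$armed && arm$elapsed >= .currentSeq(arm)) arm$armed <- TRUE
      if (arm$armed && !is.na(arm$id) && response == arm$id) {
        arm$armed <- FALSE
        arm$elapsed <- 0
        arm$idx <- arm$idx + 1L
        return(TRUE)
      }
      FALSE
    },
    VT = {
      arm$elapsed <- arm$elapsed + 1
      if (arm$elapsed >= .currentSeq(arm)) {
        arm$elapsed <- 0
        arm$idx <- arm$idx + 1L
        return(TRUE)
      }
      FALSE
    },
    stop("unknown arm kind: ", arm$kind))
}

# Advance through instantly-complete time-based components on activation
# (cannot itself deliver: delivery is handled by the step cascade).
.advanceActivation <- function(arm) {
  while (.activateComp(arm$comps[[arm$compIdx]]) &&
         arm$compIdx < length(arm$comps))
    arm$compIdx <- arm$compIdx + 1L
  invisible(arm)
}

.stepTandem <- function(arm, response) {
  comp <- arm$comps[[arm$compIdx]]
  if (!.stepSimple(comp, response)) return(FALSE)
  # current component completed; cascade through any zero-requirement
  # time-based successors without consuming another step
  repeat {
    if (arm$compIdx == length(arm$comps)) {
      arm$compIdx <- 1L
      .advanceActivation(arm)
      return(TRUE)
    }
    arm$compIdx <- arm$compIdx + 1L
    if (!.activateComp(arm$comps[[arm$compIdx]])) return(FALSE)
  }
}

.stepArm <- function(arm, response) {
  if (arm$kind == "tandem") .stepTandem(arm, response) else .stepSimple(arm, response)
}

#' Advance a schedule by one time step
#'
#' One agent response equals one time step. Ratio arms progress only when the
#' emitted `response` matches their operant response id; VI/VT timers advance
#' every step regardless of the response; a VI reward, once armed, is held
#' until the operant response collects it; VT delivers on elapse regardless of
#' responding; tandem components complete in order with reward only on the
#' final component; concurrent arms are stepped independently.
#'
#' @param state a state created by [newScheduleState()] (modified in place).
#' @param response the response id emitted this step.
#' @return list with `delivered` (logical, one per arm), `magnitude` (numeric
#'   reward magnitude per arm, 0 where not delivered) and `operant` (logical,
#'   whether each arm is response-contingent, i.e. has a response id).
#' @examples
#' st <- newScheduleState(scheduleFR(2), nRewards = 10, response = 1)
#' scheduleStep(st, 1)$delivered  # first response: not yet
#' scheduleStep(st, 1)$delivered  # second response: delivered
#' @export
scheduleStep <- function(state, response) {
  stopifnot(inherits(state, "habitnet_schedule_state"))
  delivered <- vapply(state, .stepArm, logical(1), response = response)
  mags <- vapply(state, function(a) a$magnitude, numeric(1)) * delivered
  list(delivered = delivered, magnitude = mags,
       operant = !vapply(state, function(a) is.na(a$id), logical(1)))
}

#' Yoke a variable-interval value to an observed variable-ratio session
#'
#' Computes the mean of successive inter-reward intervals (in time steps) from
#' a completed VR training session, to be used as the mean interval of a yoked
#' VI schedule so that the two schedules are matched in reward rate.
#'
#' @param x either a [TrainingResult-class] / its training-log `data.frame`
#'   (columns `step` and `delivered`), or a numeric vector of reward step
#'   times.
#' @return mean inter-reward interval in time steps.
#' @export
yokeVIToVR <- function(x) {
  if (is(x, "TrainingResult")) x <- trainingLog(x)
  if (is.data.frame(x)) {
    stopifnot(all(c("step", "delivered") %in% names(x)))
    x <- x$step[x$delivered]
  }
  x <- sort(as.numeric(x))
  if (length(x) < 2L)
    stop("need at least 2 reward events to compute inter-reward intervals")
  mean(diff(x))
}
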