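#' Derive a per-agent seed from a master seed
#'
#' Counter-based spawning so each (condition, agent) cell is independently
#' reproducible from the master seed. Stays within 32-bit integer range.
#'
#' @param masterSeed master seed (integer).
#' @param index positive counter (agent/condition cell).
#' @return an integer seed.
#' @export
deriveSeed <- function(masterSeed, index) {
  as.integer((as.numeric(masterSeed) + 7919 * as.numeric(index)) %% 2147483629 + 1)
}

# One agent's baseline -> devaluation -> post pipeline on a fixed network.
# Returns the resistance statistics plus both phase proportions.
.devaluationAssay <- function(net, nLoops, focal = operantIds(net)[1L]) {
  r <- rewardValues(nNodes(net), operant = operantIds(net))
  baseline <- runPhase(net, r, nLoops = nLoops, operant = focal)
  post <- runPhase(net, devalue(r, focal), nLoops = nLoops, operant = focal)
  res <- suppressWarnings(resistanceToDevaluation(baseline, post))
  list(resistance_ratio = unname(res["ratio"]),
       resistance_difference = unname(res["difference"]),
       baseline_proportion = operantProportion(baseline),
       post_proportion = operantProportion(post))
}

.metricRows <- function(metrics, agent, simulation, condition, sweepValue, seed) {
  data.frame(agent_id = agent, simulation = simulation, condition = condition,
             sweep_value = sweepValue, metric = names(metrics),
             value = unname(unlist(metrics)), seed = seed,
             stringsAsFactors = FALSE)
}

#' Simulation 1: which network structure produces habit
#'
#' Sweeps the hypothetical operant value `qOperant`: for each level and each
#' agent, a Q-matrix is built with [hypotheticalQ()], a network is generated,
#' and the devaluation assay (baseline phase, devaluation, post phase) is
#' run. No learning is involved. Emitted metrics per agent: resistance to
#' devaluation (ratio and difference), operant degree, operant betweenness,
#' average path length, edge count, and both phase proportions.
#'
#' @param qGrid grid of operant values (default `c(0, .25, .5, .75, 1)`).
#' @param nAgents agents per grid level (default 20).
#' @param nNodes network size N (default 50).
#' @param nLoops goal choices per phase (default 500).
#' @param seed master seed.
#' @param qOther value of non-operant responses (default 0.001).
#' @param netParams a [NetworkParams-class].
#' @return tidy `data.frame` with one row per (agent, metric).
#' @export
runSim1 <- function(qGrid = c(0, 0.25, 0.5, 0.75, 1), nAgents = 20L,
                    nNodes = 50L, nLoops = 500L, seed = 1L, qOther = 0.001,
                    netParams = networkParams()) {
  if (length(qGrid) < 1L || any(qGrid < 0 | qGrid > 1))
    stop("`qGrid` must be values in [0, 1]")
  rows <- list()
  cell <- 0L
  for (q in qGrid) {
    for (a in seq_len(nAgents)) {
      cell <- cell + 1L
      s <- deriveSeed(seed, cell)
      set.seed(s)
      Q <- hypotheticalQ(q, qOther = qOther, nResponses = nNodes)
      net <- buildNetwork(Q, params = netParams, operant = 1L)
      m <- networkMetrics(net)
      assay <- .devaluationAssay(net, nLoops)
      rows[[cell]] <- .metricRows(
        c(assay, operant_degree = m$degree, betweenness = m$betweenness,
          avg_path_length = m$avgPathLength, n_edges = m$nEdges),
        agent = a, simulation = "sim1", condition = sprintf("q=%g", q),
        sweepValue = q, seed = s)
    }
  }
  do.call(rbind, rows)
}

# Build the ScheduleSpec + phase geometry for one sim2/sim3 condition.
.sim2Condition <- function(condition, yokedInterval) {
  switch(condition,
    VR = list(spec = scheduleVR(15), operant = 1L, focal = 1L),
    VI = list(spec = scheduleVI(yokedInterval), operant = 1L, focal = 1L),
    choice = list(spec = scheduleConcurrent(list(scheduleVI(60), scheduleVI(60)),
                                            responses = c(1L, 2L)),
                  operant = c(1L, 2L), focal = 1L),
    nochoice = list(spec = scheduleConcurrent(list(scheduleVI(60), scheduleVT(60)),
                                              responses = c(1L, NA)),
                    operant = 1L, focal = 1L),
    stop("unknown sim2 condition: ", condition))
}

# Train one agent, generate its network, run the devaluation assay, and
# return one block of tidy rows. The yoked-VI condition first runs its own
# VR 15 session at the same reward count to compute the matched interval.
.runScheduleAgent <- function(condition, spec, operant, focal, nRewards,
                              agent, simulation, sweepValue, seed,
                              nNodes, nLoops, params, netParams) {
  set.seed(seed)
  tr <- trainAgent(spec, nRewards = nRewards, params = params,
                   nResponses = nNodes, operant = operant[1L])
  Q <- qMatrix(tr)
  net <- buildNetwork(Q, params = netParams, operant = operant)
  m <- networkMetrics(net, operant = focal)
  assay <- .devaluationAssay(net, nLoops, focal = focal)
  .metricRows(
    c(assay, operant_degree = m$degree, betweenness = m$betweenness,
      avg_path_length = m$avgPathLength, n_edges = m$nEdges,
      q_self = Q[focal, focal], training_steps = tr@nSteps),
    agent = agent, simulation = simulation, condition = condition,
    sweepValue = sweepValue, seed = seed)
}

#' Simulation 2: learned schedules, amount of training, and choice
#'
#' The pipeline of simulation 1 with the hypothetical Q-matrix replaced by
#' training: each agent learns its Q-matrix under a reinforcement schedule,
#' generates its network once, then runs the devaluation assay with the
#' Q-matrix and network frozen. Conditions:
#' \describe{
#'   \item{`"VR"`}{variable ratio 15 on the operant response.}
#'   \item{`"VI"`}{variable interval yoked to a VR 15 session: the agent
#'     first runs its own VR 15 session at the same reward count and the mean
#'     inter-reward interval observed there sets the VI value.}
#'   \item{`"choice"`}{concurrent VI 60 VI 60 on two operant responses, both
#'     worth 1.0; only the first is devalued.}
#'   \item{`"nochoice"`}{concurrent VI 60 VT 60: one operant response plus
#'     response-independent rewards matching the second goal's rate.}
#' }
#' Metrics additionally include the self-transition value
#' `Q[operant, operant]` and the session length in steps.
#'
#' @param conditions subset of `c("VR", "VI", "choice", "nochoice")`.
#' @param trainingAmounts vector of reward counts defining the amount of
#'   training (default 500).
#' @param nAgents agents per condition x amount cell (default 20).
#' @param nNodes number of responses N (default 50).
#' @param nLoops goal choices per phase (default 500).
#' @param seed master seed.
#' @param params a [LearningParams-class].
#' @param netParams a [NetworkParams-class].
#' @return tidy `data.frame` with one row per (agent, metric).
#' @export
runSim2 <- function(conditions = c("VR", "VI", "choice", "nochoice"),
                    trainingAmounts = 500L, nAgents = 20L, nNodes = 50L,
                    nLoops = 500L, seed = 1L, params = learningParams(),
                    netParams = networkParams()) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  if (any(trainingAmounts < 1L)) stop("`trainingAmounts` must be >= 1")
  rows <- list()
  cell <- 0L
  for (cond in conditions) {
    for (amt in trainingAmounts) {
      for (a in seq_len(nAgents)) {
        cell <- cell + 1L
        s <- deriveSeed(seed, cell)
        yoked <- NA_real_
        if (cond == "VI") {
          set.seed(deriveSeed(s, 1L))
          vr <- trainAgent(scheduleVR(15), nRewards = amt, params = params,
                           nResponses = nNodes, operant = 1L)
          yoked <- yokeVIToVR(vr)
        }
        cnd <- .sim2Condition(cond, yoked)
        rows[[cell]] <- .runScheduleAgent(
          condition = cond, spec = cnd$spec, operant = cnd$operant,
          focal = cnd$focal, nRewards = amt, agent = a, simulation = "sim2",
          sweepValue = amt, seed = s, nNodes = nNodes, nLoops = nLoops,
          params = params, netParams = netParams)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulation 3: tandem schedule orderings
#'
#' Compares habit formation under simple and tandem schedules: `"VI"`
#' (VI 15), `"VR"` (VR 15), `"tandemVIVR"` (tandem VI 15 VR 3) and
#' `"tandemVRVI"` (tandem VR 10 VI 5). The model predicts habit (higher
#' resistance, operant degree, betweenness) under the schedules whose reward
#' is time-gated at the point of delivery — VI and tandem VR VI — and higher
#' operant self-transition values under VR and tandem VI VR.
#'
#' @param conditions subset of `c("VI", "tandemVIVR", "VR", "tandemVRVI")`.
#' @inheritParams runSim2
#' @return tidy `data.frame` with one row per (agent, metric).
#' @export
runSim3 <- function(conditions = c("VI", "tandemVIVR", "VR", "tandemVRVI"),
                    trainingAmounts = 500L, nAgents = 20L, nNodes = 50L,
                    nLoops = 500L, seed = 1L, params = learningParams(),
                    netParams = networkParams()) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  specs <- list(
    VI = scheduleVI(15),
    VR = scheduleVR(15),
    tandemVIVR = scheduleTandem(scheduleVI(15), scheduleVR(3)),
    tandemVRVI = scheduleTandem(scheduleVR(10), scheduleVI(5)))
  rows <- list()
  cell <- 0L
  for (cond in conditions) {
    for (amt in trainingAmounts) {
      for (a in seq_len(nAgents)) {
        cell <- cell + 1L
        s <- deriveSeed(seed, cell)
        rows[[cell]] <- .runScheduleAgent(
          condition = cond, spec = specs[[cond]], operant = 1L, focal = 1L,
          nRewards = amt, agent = a, simulation = "sim3", sweepValue = amt,
          seed = s, nNodes = nNodes, nLoops = nLoops, params = params,
          netParams = netParams)
      }
    }
  }
  do.call(rbind, rows)
}

#' Build a ScheduleSpec from a plain configuration list
#'
#' Converts the list form used in YAML/JSON run configurations, e.g.
#' `list(kind = "tandem", components = list(list(kind = "VI", value = 15),
#' list(kind = "VR", value = 3)))`, into a [ScheduleSpec-class]. Errors name
#' the offending field.
#'
#' @param x a named list with `kind` and, per kind, `value`, `components`
#'   (tandem) or `arms` (concurrent: entries with `response` and `spec`).
#' @return a [ScheduleSpec-class].
#' @export
scheduleFromConfig <- function(x) {
  if (!is.list(x) || is.null(x$kind)) stop("schedule config: missing field 'kind'")
  kind <- as.character(x$kind)
  mag <- if (is.null(x$magnitude)) 1 else as.numeric(x$magnitude)
  if (kind %in% c("FR", "VR", "VI", "VT")) {
    if (is.null(x$value)) stop("schedule config: missing field 'value' for kind ", kind)
    return(new("ScheduleSpec", kind = kind, value = as.numeric(x$value),
               magnitude = mag))
  }
  if (kind == "tandem") {
    if (is.null(x$components)) stop("schedule config: missing field 'components'")
    comps <- lapply(x$components, scheduleFromConfig)
    return(new("ScheduleSpec", kind = "tandem", components = comps,
               magnitude = mag))
  }
  if (kind == "concurrent") {
    if (is.null(x$arms)) stop("schedule config: missing field 'arms'")
    arms <- lapply(x$arms, function(a) {
      if (is.null(a$spec)) stop("schedule config: missing field 'spec' in arm")
      list(response = if (is.null(a$response)) NA_integer_ else as.integer(a$response),
           spec = scheduleFromConfig(a$spec))
    })
    return(new("ScheduleSpec", kind = "concurrent", arms = arms))
  }
  stop("schedule config: unknown kind '", kind, "'")
}

#' Write experiment results and a run manifest
#'
#' Writes the tidy results to CSV and, when `jsonlite` is available, a
#' sidecar JSON manifest recording the seed, row count and package version.
#'
#' @param results tidy `data.frame` from [runSim1()], [runSim2()] or
#'   [runSim3()].
#' @param path output CSV path.
#' @param seed master seed used for the run.
#' @return `path`, invisibly.
#' @export
writeResults <- function(results, path, seed = NA_integer_) {
  utils::write.csv(results, path, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    manifest <- list(
      seed = seed, rows = nrow(results),
      simulations = unique(results$simulation),
      package_version = as.character(utils::packageVersion("habitnet")),
      written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
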