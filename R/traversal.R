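#' Per-response reward values
#'
#' The goal values driving response choice during the baseline and
#' post-devaluation phases: the operant response is worth 1.0, every other
#' response 0.001. Devaluation ([devalue()]) sets one operant entry to 0.
#'
#' @param nResponses number of responses N.
#' @param operant integer vector of operant response ids.
#' @param operantValue value of each operant response (default 1.0).
#' @param otherValue value of every other response (default 0.001).
#' @return numeric vector of length N.
#' @export
rewardValues <- function(nResponses, operant = 1L, operantValue = 1.0,
                         otherValue = 0.001) {
  r <- rep(otherValue, nResponses)
  r[operant] <- operantValue
  r
}

#' Goal-choice probabilities by proportional reward allocation
#'
#' The probability of choosing response `i` as the next goal is
#' `r_i / sum_j r_j`.
#'
#' @param r reward-value vector (all >= 0, positive sum).
#' @return probability vector.
#' @examples
#' goalProbabilities(rewardValues(50))[1]  # 1 / 1.049
#' @export
goalProbabilities <- function(r) {
  stopifnot(all(r >= 0))
  s <- sum(r)
  if (s <= 0) stop("all reward values are zero: no goal can be chosen")
  r / s
}

#' @rdname goalProbabilities
#' @return `chooseGoal()` a sampled response id.
#' @export
chooseGoal <- function(r) {
  sample.int(length(r), 1L, prob = goalProbabilities(r))
}

#' Devalue the reward of an operant response
#'
#' Sets the goal value of `target` to 0 and leaves everything else unchanged;
#' no learning accompanies devaluation (the Q-matrix and network are frozen).
#' In the choice condition only one of the two operant responses is devalued.
#'
#' @param r reward-value vector.
#' @param target response id to devalue.
#' @return the modified reward-value vector.
#' @export
devalue <- function(r, target) {
  r[target] <- 0
  r
}

#' Uniformly tie-broken shortest path
#'
#' Returns a minimal-edge-count path from `from` to `to`; when several
#' geodesics exist one is chosen uniformly at random among them (all
#' geodesics are enumerated and one is sampled). `from == to` returns the
#' single-node path.
#'
#' @param net a [BehavioralNetwork-class].
#' @param from,to node ids.
#' @return integer vector of node ids from `from` to `to`, or `NULL` when
#'   `to` is unreachable from `from`.
#' @export
shortestPathBetween <- function(net, from, to) {
  if (from == to) return(as.integer(from))
  paths <- igraph::all_shortest_paths(asIgraph(net), from = from,
                                      to = to)$vpaths
  if (length(paths) == 0L) return(NULL)
  pick <- if (length(paths) == 1L) 1L else sample.int(length(paths), 1L)
  as.integer(paths[[pick]])
}

#' Result of one baseline or post-devaluation phase
#'
#' @slot counts integer vector of engagement counts per response.
#' @slot nLoops number of goal choices made.
#' @slot operantProportion operant engagements / total engagements, for the
#'   focal operant response.
#' @slot pathLog integer vector: the full sequence of engaged responses.
#' @export
setClass("PhaseResult",
  representation(counts = "integer", nLoops = "integer",
                 operantProportion = "numeric", pathLog = "integer"))

setValidity("PhaseResult", function(object) {
  if (sum(object@counts) != length(object@pathLog))
    return("counts must sum to the number of engaged responses")
  TRUE
})

#' @rdname PhaseResult-class
#' @param x a `PhaseResult`.
#' @return `engagementCounts()` the per-response counts;
#'   `operantProportion()` the focal operant's share of all engagements.
#' @export
engagementCounts <- function(x) {
  stopifnot(is(x, "PhaseResult"))
  x@counts
}

#' @rdname PhaseResult-class
#' @export
operantProportion <- function(x) {
  stopifnot(is(x, "PhaseResult"))
  x@operantProportion
}

setMethod("show", "PhaseResult", function(object) {
  cat(sprintf("PhaseResult: %d loops, %d engagements, operant proportion %.4f\n",
              object@nLoops, sum(object@counts), object@operantProportion))
  invisible(object)
})

#' Simulate one traversal phase (baseline or post-devaluation)
#'
#' The agent starts on a uniformly random response, then loops `nLoops`
#' times: (1) choose a goal by proportional reward allocation
#' ([chooseGoal()]), (2) find a uniformly tie-broken shortest path from the
#' current response to the goal, (3) engage every response on the path after
#' the current one. The goal of one loop is the start of the next. Neither
#' the Q-matrix nor the network changes during a phase.
#'
#' Engagement counting: the initial response counts once; each loop counts
#' the traversed responses excluding its starting node (so nothing is double
#' counted across loops); a goal equal to the current response counts as one
#' re-engagement.
#'
#' @param net a [BehavioralNetwork-class].
#' @param r reward-value vector of length `nNodes(net)`.
#' @param nLoops number of goal choices (default 500).
#' @param operant focal operant response for the proportion (default: the
#'   network's first operant id).
#' @param maxResample resampling bound when a chosen goal is unreachable from
#'   the current response (disconnected network).
#' @return a [PhaseResult-class].
#' @examples
#' set.seed(1)
#' net <- buildNetwork(hypotheticalQ(1.0, nResponses = 20))
#' runPhase(net, rewardValues(20), nLoops = 100)
#' @export
runPhase <- function(net, r, nLoops = 500L, operant = operantIds(net)[1L],
                     maxResample = 1000L) {
  n <- nNodes(net)
  stopifnot(length(r) == n, nLoops >= 1L)
  goalProbabilities(r)  # validates sum(r) > 0
  counts <- integer(n)
  cur <- sample.int(n, 1L)
  counts[cur] <- 1L
  pathLog <- integer(nLoops * 4L)
  pathLog[1L] <- cur
  m <- 1L
  for (loop in seq_len(as.integer(nLoops))) {
    goal <- chooseGoal(r)
    if (goal == cur) {
      engaged <- cur
    } else {
      tries <- 0L
      repeat {
        path <- shortestPathBetween(net, cur, goal)
        if (!is.null(path)) break
        tries <- tries + 1L
        if (tries > maxResample)
          stop("network too disconnected: could not reach any sampled goal")
        goal <- chooseGoal(r)
        if (goal == cur) {
          path <- c(cur, cur)
          break
        }
      }
      engaged <- path[-1L]
    }
    ne <- length(engaged)
    if (m + ne > length(pathLog)) length(pathLog) <- 2L * (m + ne)
    pathLog[(m + 1L):(m + ne)] <- engaged
    m <- m + ne
    counts[engaged] <- counts[engaged] + 1L
    # tabulate-style: duplicated engagements within one path are impossible
    # on a geodesic, so the vectorized increment is exact
    cur <- goal
  }
  new("PhaseResult", counts = counts, nLoops = as.integer(nLoops),
      operantProportion = counts[operant] / sum(counts),
      pathLog = pathLog[seq_len(m)])
}

#' Resistance to devaluation
#'
#' Compares the operant-response proportion after devaluation with the
#' proportion at baseline. High values mean the operant response persisted
#' despite its reward being worthless — the operational definition of habit.
#' Two statistics are returned: `ratio` (post / baseline; the default
#' summary, scale-free across conditions) and `difference`
#' (baseline - post).
#'
#' @param baseline,post [PhaseResult-class] objects for the two phases.
#' @return named numeric vector `c(ratio =, difference =)`; `ratio` is `NA`
#'   with a warning when the baseline proportion is zero.
#' @export
resistanceToDevaluation <- function(baseline, post) {
  b <- operantProportion(baseline)
  p <- operantProportion(post)
  ratio <- if (b > 0) p / b else {
    warning("baseline operant proportion is zero: ratio undefined")
    NA_real_
  }
  c(ratio = ratio, difference = b - p)
}
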