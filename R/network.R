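#' Network-generation parameters
#'
#' Parameters of the softmax edge sampler that turns a Q-matrix into an
#' unweighted behavioral network. For every node, `edgesPerNode` distinct
#' targets are sampled with probability proportional to
#' `exp(betaN * Q[i, j])` over `j != i`, so every node ends with degree at
#' least `edgesPerNode`. Defaults are `betaN = 50` and two edges per node.
#'
#' `softmaxSign = "as_printed"` switches to `exp(-betaN * Q[i, j])`, under
#' which high-valued targets are the least likely to be attached; it is kept
#' for audit only, since it cannot concentrate edges on the operant response.
#'
#' @slot betaN inverse temperature of edge sampling, > 0.
#' @slot edgesPerNode number of targets sampled per node, >= 1.
#' @slot softmaxSign `"positive"` (default) or `"as_printed"`.
#' @export
setClass("NetworkParams",
  representation(betaN = "numeric", edgesPerNode = "integer",
                 softmaxSign = "character"),
  prototype(betaN = 50, edgesPerNode = 2L, softmaxSign = "positive"))

setValidity("NetworkParams", function(object) {
  if (object@betaN <= 0) return("betaN must be > 0")
  if (object@edgesPerNode < 1L) return("edgesPerNode must be >= 1")
  if (!object@softmaxSign %in% c("positive", "as_printed"))
    return("softmaxSign must be 'positive' or 'as_printed'")
  TRUE
})

#' @rdname NetworkParams-class
#' @param betaN,edgesPerNode,softmaxSign see slots.
#' @return a `NetworkParams` object.
#' @export
networkParams <- function(betaN = 50, edgesPerNode = 2L,
                          softmaxSign = c("positive", "as_printed")) {
  new("NetworkParams", betaN = betaN, edgesPerNode = as.integer(edgesPerNode),
      softmaxSign = match.arg(softmaxSign))
}

#' Behavioral network of responses
#'
#' An undirected simple graph whose nodes are the N responses an agent can
#' engage in and whose edges are possible direct transitions, generated from
#' a Q-matrix by [buildNetwork()]. Self-loops are excluded: the traversal
#' model cannot treat self-transitions, although self-transition Q-values are
#' still learned and reported.
#'
#' @slot graph the underlying `igraph` object.
#' @slot nNodes number of responses N.
#' @slot operant integer vector of operant response ids.
#' @seealso [buildNetwork()], [networkMetrics()], [runPhase()]
#' @export
setClass("BehavioralNetwork",
  representation(graph = "ANY", nNodes = "integer", operant = "integer"))

setValidity("BehavioralNetwork", function(object) {
  if (!igraph::is_igraph(object@graph)) return("graph must be an igraph object")
  if (igraph::vcount(object@graph) != object@nNodes)
    return("graph order must equal nNodes")
  if (igraph::any_loop(object@graph)) return("self-loops are not allowed")
  if (igraph::any_multiple(object@graph)) return("multi-edges are not allowed")
  if (any(object@operant < 1L | object@operant > object@nNodes))
    return("operant ids out of range")
  TRUE
})

#' @rdname BehavioralNetwork-class
#' @param x a `BehavioralNetwork`.
#' @return `asIgraph()` the underlying igraph; `nNodes()` the node count;
#'   `operantIds()` the operant response ids.
#' @export
asIgraph <- function(x) {
  stopifnot(is(x, "BehavioralNetwork"))
  x@graph
}

#' @rdname BehavioralNetwork-class
#' @export
nNodes <- function(x) {
  stopifnot(is(x, "BehavioralNetwork"))
  x@nNodes
}

#' @rdname BehavioralNetwork-class
#' @export
operantIds <- function(x) {
  stopifnot(is(x, "BehavioralNetwork"))
  x@operant
}

setMethod("show", "BehavioralNetwork", function(object) {
  cat(sprintf("BehavioralNetwork: %d responses, %d edges, operant: %s\n",
              object@nNodes, igraph::ecount(object@graph),
              paste(object@operant, collapse = ", ")))
  invisible(object)
})

#' Edge-attachment probabilities from a Q-matrix row
#'
#' Probability that node `i` attaches an edge to each other node `j`,
#' proportional to `exp(betaN * Q[i, j])` over `j != i` (softmax excluding
#' the self-transition, renormalized). With `softmaxSign = "as_printed"` the
#' exponent is negated.
#'
#' @param Q the N x N Q-matrix.
#' @param i source node.
#' @param params a [NetworkParams-class].
#' @return probability vector of length N with a 0 at position `i`, summing
#'   to 1.
#' @export
edgeProbabilities <- function(Q, i, params = networkParams()) {
  n <- ncol(Q)
  if (n < 3L) stop("need at least 3 nodes for a degree-2 simple graph")
  stopifnot(all(is.finite(Q)))
  s <- if (params@softmaxSign == "positive") 1 else -1
  x <- s * params@betaN * Q[i, -i]
  p <- exp(x - max(x))
  p <- p / sum(p)
  out <- numeric(n)
  out[-i] <- p
  out
}

#' Generate a behavioral network from a Q-matrix
#'
#' For every node `i`, samples `edgesPerNode` distinct targets `j != i`
#' without replacement with probabilities [edgeProbabilities()]; the edge set
#' is the union over nodes as an undirected simple graph, so every node has
#' degree at least `edgesPerNode` by construction.
#'
#' @param Q the N x N Q-matrix (learned or hypothetical).
#' @param params a [NetworkParams-class].
#' @param operant integer vector of operant response ids (default 1).
#' @return a [BehavioralNetwork-class].
#' @examples
#' set.seed(1)
#' net <- buildNetwork(hypotheticalQ(1.0, nResponses = 20))
#' min(igraph::degree(asIgraph(net)))
#' @export
buildNetwork <- function(Q, params = networkParams(), operant = 1L) {
  n <- ncol(Q)
  if (n <= params@edgesPerNode)
    stop("need more nodes than edgesPerNode")
  edges <- matrix(0L, nrow = n * params@edgesPerNode, ncol = 2L)
  k <- 0L
  for (i in seq_len(n)) {
    p <- edgeProbabilities(Q, i, params)
    # sequential without-replacement draws with renormalization between
    # draws: base R's one-shot weighted sampling loses the residual mass to
    # cancellation when one weight is within machine epsilon of 1
    for (e in seq_len(params@edgesPerNode)) {
      j <- sample.int(n, 1L, prob = p)
      p[j] <- 0
      k <- k + 1L
      edges[k, ] <- c(i, j)
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  g <- igraph::simplify(g)
  new("BehavioralNetwork", graph = g, nNodes = as.integer(n),
      operant = as.integer(operant))
}

#' @rdname BehavioralNetwork-class
#' @param edges two-column matrix of node pairs (1-based ids).
#' @param nNodes number of responses N.
#' @param operant integer vector of operant response ids.
#' @return `behavioralNetwork()` a new [BehavioralNetwork-class] from an
#'   explicit edge list.
#' @export
behavioralNetwork <- function(edges, nNodes, operant = 1L) {
  g <- igraph::make_empty_graph(nNodes, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, t(as.matrix(edges)))
  g <- igraph::simplify(g)
  new("BehavioralNetwork", graph = g, nNodes = as.integer(nNodes),
      operant = as.integer(operant))
}

#' Read and write behavioral networks as edge-list text files
#'
#' The on-disk format is one `"u v"` pair per line (1-based node ids), with a
#' header comment carrying the node count and operant ids, so a network can
#' round-trip without a sidecar.
#'
#' @param net a [BehavioralNetwork-class].
#' @param path file path.
#' @return `writeNetwork()` returns `path` invisibly; `readNetwork()` a
#'   [BehavioralNetwork-class].
#' @export
writeNetwork <- function(net, path) {
  el <- igraph::as_edgelist(asIgraph(net))
  header <- sprintf("# nodes %d operant %s", nNodes(net),
                    paste(operantIds(net), collapse = " "))
  writeLines(c(header, sprintf("%d %d", el[, 1], el[, 2])), path)
  invisible(path)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(path) {
  lines <- readLines(path)
  header <- strsplit(sub("^# ", "", lines[1L]), " ")[[1L]]
  stopifnot(header[1L] == "nodes")
  n <- as.integer(header[2L])
  operant <- as.integer(header[-(1:3)])
  body <- lines[-1L]
  body <- body[nzchar(body)]
  edges <- if (length(body)) {
    do.call(rbind, lapply(strsplit(body, " "), as.integer))
  } else {
    matrix(integer(), ncol = 2L)
  }
  behavioralNetwork(edges, n, operant)
}

#' Hypothetical Q-matrix from a response-value vector
#'
#' Builds the Q-matrix used to generate arbitrary networks without training:
#' a Q-vector `(qOperant, qOther, ..., qOther)` assigns one value per
#' response (first element = operant response) and is expanded to a matrix.
#' The default expansion replicates the vector across rows
#' (`Q[i, j] = q_j`), so the attachment probability of a target is the same
#' from every source. `expansion = "outer"` gives the literal outer product
#' `Q[i, j] = q_i * q_j`, retained for comparison; with values <= 1 its
#' off-operant-row contrasts are of order `qOther * qOperant` and are far
#' too weak at `betaN = 50` to concentrate edges.
#'
#' @param qOperant value of the operant response, in [0, 1].
#' @param qOther value of every other response (default 0.001).
#' @param nResponses number of responses N (default 50).
#' @param expansion `"replicate"` (default) or `"outer"`.
#' @return an N x N matrix.
#' @export
hypotheticalQ <- function(qOperant, qOther = 0.001, nResponses = 50L,
                          expansion = c("replicate", "outer")) {
  expansion <- match.arg(expansion)
  stopifnot(qOperant >= 0, qOperant <= 1, qOther >= 0, qOther <= 1)
  n <- as.integer(nResponses)
  qvec <- c(qOperant, rep(qOther, n - 1L))
  if (expansion == "replicate") {
    matrix(qvec, nrow = n, ncol = n, byrow = TRUE)
  } else {
    outer(qvec, qvec)
  }
}

#' Structural metrics of the behavioral network
#'
#' Computes the statistics used to explain habit formation: the degree of the
#' operant node, its normalized shortest-path betweenness centrality (the
#' probability that the operant response lies on the shortest path connecting
#' two other nodes), and the average shortest-path length over connected node
#' pairs. If the network is disconnected, the average path length is computed
#' on the largest component and `connected` is `FALSE`.
#'
#' @param net a [BehavioralNetwork-class].
#' @param operant the node to report degree/betweenness for (default: the
#'   network's first operant id).
#' @return list with `degree`, `betweenness`, `avgPathLength`, `nEdges`,
#'   `connected`.
#' @examples
#' g <- igraph::make_star(10, mode = "undirected", center = 1)
#' net <- new("BehavioralNetwork", graph = g, nNodes = 10L, operant = 1L)
#' networkMetrics(net)$betweenness  # 1: every leaf pair routes via the hub
#' @export
networkMetrics <- function(net, operant = operantIds(net)[1L]) {
  g <- asIgraph(net)
  if (igraph::vcount(g) == 0L) stop("empty graph")
  comps <- igraph::components(g)
  connected <- comps$no == 1L
  gl <- if (connected) g else {
    igraph::induced_subgraph(g, which(comps$membership == which.max(comps$csize)))
  }
  list(degree = as.integer(igraph::degree(g, operant)),
       betweenness = unname(igraph::betweenness(g, v = operant,
                                                normalized = TRUE)),
       avgPathLength = igraph::mean_distance(gl),
       nEdges = igraph::ecount(g),
       connected = connected)
}
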